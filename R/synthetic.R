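# Synthetic fixtures with exact ground truth: an elongated hexameric
# "head-neck-legs" phantom (closed planar ring or helical lock-washer with
# programmable opening angle and axial rise), noisy projection sets, and
# half-map pairs with a designed per-shell spectral signal-to-noise ratio.
# Every generator is a pure function of (spec, seed).

#' Specification of the hexamer phantom
#'
#' Defaults emulate an elongated AAA+ protease particle: a ~230 Angstrom
#' long hexamer, 143 Angstrom across the head, narrowing to a 93 Angstrom
#' trimeric neck about 10 Angstrom long, with three pairs of legs in a
#' trimer-of-dimers arrangement, an axial channel of ~15 Angstrom and a
#' ~20 Angstrom C-terminal opening. The lock-washer conformation opens the
#' ring to `opening_angle` (> 60) and spreads the six subunits over
#' `total_rise` Angstrom of axial displacement.
#'
#' @param conformation `"planar"` or `"lockwasher"`.
#' @param opening_angle ring opening in degrees (planar: 60).
#' @param total_rise total axial rise across the ring in Angstrom
#'   (planar: 0).
#' @param head_length,head_width head dimensions, Angstrom.
#' @param neck_width,neck_length neck dimensions, Angstrom.
#' @param channel_diameter,c_gate_diameter axial channel and C-terminal
#'   gate diameters, Angstrom (approximate in the blob phantom).
#' @param n_gate `"auto"` (closed when planar, open when lock-washer),
#'   `"open"`, or `"closed"`.
#' @param total_length overall particle length, Angstrom.
#' @param box box side in voxels; `voxel_size` Angstrom per voxel.
#' @param resolution rendering resolution of the pseudo-atom blobs,
#'   Angstrom.
#' @param seed integer seed recorded in the spec (the phantom itself is
#'   deterministic; the seed feeds derived noisy data).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(conformation = c("planar", "lockwasher"),
                         opening_angle = NULL, total_rise = NULL,
                         head_length = 90, head_width = 143,
                         neck_width = 93, neck_length = 10,
                         channel_diameter = 15, c_gate_diameter = 20,
                         n_gate = c("auto", "open", "closed"),
                         total_length = 230,
                         box = 128, voxel_size = 2.5, resolution = 20,
                         seed = 1) {
  conformation <- match.arg(conformation)
  n_gate <- match.arg(n_gate)
  if (is.null(opening_angle))
    opening_angle <- if (conformation == "planar") 60 else 81
  if (is.null(total_rise))
    total_rise <- if (conformation == "planar") 0 else 20
  if (conformation == "planar") {
    stopifnot(abs(opening_angle - 60) < 1e-9, abs(total_rise) < 1e-9)
  } else {
    if (opening_angle < 60) stop("lock-washer opening_angle must be >= 60")
  }
  if (total_length > box * voxel_size - 4 * voxel_size)
    stop("total_length does not fit in the box")
  if (head_width > box * voxel_size - 4 * voxel_size)
    stop("head_width does not fit in the box")
  structure(list(conformation = conformation,
                 opening_angle = opening_angle, total_rise = total_rise,
                 head_length = head_length, head_width = head_width,
                 neck_width = neck_width, neck_length = neck_length,
                 channel_diameter = channel_diameter,
                 c_gate_diameter = c_gate_diameter, n_gate = n_gate,
                 total_length = total_length,
                 box = box, voxel_size = voxel_size,
                 resolution = resolution, seed = seed),
            class = "phantom_spec")
}

# The rigid pseudo-subunit: a chiral 8-blob cluster in a local frame with
# +x radially outward, z along the particle axis, centre of mass at the
# origin. Spans ~head_length axially and ~head_width/3 laterally.
subunit_blob_model <- function(head_length = 90, head_width = 143) {
  sz <- head_length / 90
  sx <- head_width / 143
  b <- rbind(
    c( 10,   0, -35, 1200),
    c( -8,   6, -22,  900),
    c(  6, -10, -10, 1100),
    c( 12,   8,   4, 1000),
    c(-10,  -5,  16,  950),
    c(  0,  12,  26, 1050),
    c(  8,  -8,  34, 1150),
    c( -4,   2,  40,  850))
  xyz <- cbind(b[, 1] * sx, b[, 2] * sx, b[, 3] * sz)
  m <- atomic_model(rep("X", nrow(b)), xyz[, 1], xyz[, 2], xyz[, 3],
                    weight = b[, 4], chain = "S",
                    resid = seq_len(nrow(b)))
  com <- model_com(m)
  m$x <- m$x - com[1]; m$y <- m$y - com[2]; m$z <- m$z - com[3]
  m
}

# Anchor point (nucleotide-pocket stand-in) in the subunit local frame.
SUBUNIT_ANCHOR_LOCAL <- c(18, 4, -12)

# Ring-anchor layout for a programmed (opening angle, total rise) pair.
# The measurement the layout must round-trip through fits a
# total-least-squares plane to the anchors and takes azimuths about their
# centroid; so the layout (i) places anchors at the programmed azimuths
# with radii perturbed minimally so the centroid falls exactly on the
# axis, and (ii) replaces the natural linear rise ramp by its constrained
# least-squares projection with zero in-plane moments (the reference plane
# then stays exactly perpendicular to the axis) while keeping the axial
# step across the ring opening, s6 - s1, exactly at `total_rise`.
ring_anchor_layout <- function(az_deg, radius0, total_rise) {
  phi <- az_deg * pi / 180
  B <- rbind(cos(phi), sin(phi))
  rho <- rep(radius0, 6)
  resid <- B %*% rho
  if (max(abs(resid)) > 1e-12) {
    delta <- -t(B) %*% solve(B %*% t(B), resid)
    rho <- rho + as.numeric(delta)
  }
  if (total_rise == 0) {
    s <- rep(0, 6)
  } else {
    ramp <- (seq_len(6) - 1) / 5 * total_rise
    A <- rbind(rep(1, 6), rho * cos(phi), rho * sin(phi),
               c(-1, 0, 0, 0, 0, 1))
    b <- c(0, 0, 0, total_rise)
    lam <- solve(A %*% t(A), b - A %*% ramp)
    s <- as.numeric(ramp + t(A) %*% lam)
  }
  list(radius = rho, rise = s)
}

#' Build a hexamer phantom with known ground truth
#'
#' Assembles six copies of a rigid pseudo-subunit on a ring (planar or
#' lock-washer per the spec), a trimeric neck, and three pairs of tiered
#' leg blobs, renders everything as Gaussian density, and returns the map
#' together with the exact subunit poses and anchor points.
#'
#' @param spec a [phantom_spec()].
#' @param drop_subunit optional subunit index (1-6) left out of the
#'   rendered map (emulating a flexible, invisible copy); poses and anchors
#'   still describe all six ground-truth positions.
#' @param render render the density map (default TRUE); with FALSE only
#'   the geometry (poses, anchors, pseudo-atom model) is built and `grid`
#'   is NULL.
#' @return a list: `grid` ([voxel_grid()]), `subunit` (the local-frame
#'   [atomic_model()]), `poses` (list of six [rigid_pose()]s),
#'   `anchors` (6 x 3 matrix, Angstrom), `spec`.
#' @export
make_hexamer_phantom <- function(spec = phantom_spec(), drop_subunit = NULL,
                                 render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$total_length
  sub <- subunit_blob_model(spec$head_length, spec$head_width)
  # blob half-max radius; extreme blobs are placed so their half-max
  # surface touches the nominal particle envelope
  sigma_blob <- resolution_sigma(spec$resolution)
  hw_blob <- sigma_blob * sqrt(2 * log(2))
  ring_radius <- spec$head_width / 2 - max(abs(c(sub$x, sub$y))) - hw_blob
  # layout along z (box-centre coordinates): legs | neck | head; the top
  # subunit blob's half maximum touches the nominal particle top
  head_top <- L / 2
  head_z <- head_top - hw_blob - max(sub$z)      # head centre
  neck_top <- head_top - spec$head_length
  neck_z <- neck_top - spec$neck_length / 2
  legs_top <- neck_top - spec$neck_length
  legs_bottom <- -L / 2
  # subunit azimuths and rises
  g <- spec$opening_angle
  th <- (seq_len(6) - 1) * (360 - g) / 5
  a_loc <- SUBUNIT_ANCHOR_LOCAL
  anchor_radius0 <- sqrt((ring_radius + a_loc[1])^2 + a_loc[2]^2)
  lay <- ring_anchor_layout(th, anchor_radius0, spec$total_rise)
  poses <- vector("list", 6)
  all_atoms <- list()
  anchors <- matrix(0, 6, 3)
  for (k in 1:6) {
    phi <- th[k] * pi / 180
    anchors[k, ] <- c(lay$radius[k] * cos(phi), lay$radius[k] * sin(phi),
                      head_z + a_loc[3] + lay$rise[k])
    R <- euler_zyz_matrix(th[k], 0, 0)
    tr <- anchors[k, ] - as.numeric(R %*% a_loc)
    poses[[k]] <- rigid_pose(alpha = th[k], beta = 0, gamma = 0,
                             translation = tr)
    posed <- apply_pose(sub, poses[[k]])
    posed$chain <- paste0("S", k)
    if (is.null(drop_subunit) || k != drop_subunit)
      all_atoms[[length(all_atoms) + 1L]] <- posed
  }
  # neck: three rods at 0/120/240 degrees (trimeric), radius set by
  # neck_width; each rod two blobs across the short neck
  rod_r <- spec$neck_width / 2 - 9
  for (t3 in c(0, 120, 240)) {
    for (zz in seq(neck_z - spec$neck_length / 2, neck_z + spec$neck_length / 2,
                   length.out = 2)) {
      all_atoms[[length(all_atoms) + 1L]] <- atomic_model(
        "X", rod_r * cos(t3 * pi / 180), rod_r * sin(t3 * pi / 180), zz,
        weight = 700, chain = "N")
    }
  }
  # legs: trimer of dimers, each dimer two touching columns of two tiered
  # blobs
  leg_r <- 40 * spec$head_width / 143
  # bottom tier touches the particle envelope at its half maximum
  leg_z <- c(legs_top - 0.3 * (legs_top - legs_bottom),
             legs_bottom + hw_blob)
  for (t3 in c(0, 120, 240)) {
    for (s in c(-1, 1)) {
      tt <- (t3 + s * 16) * pi / 180
      for (zz in leg_z) {
        all_atoms[[length(all_atoms) + 1L]] <- atomic_model(
          "X", leg_r * cos(tt), leg_r * sin(tt), zz,
          weight = 1200, chain = "L")
      }
    }
  }
  # N-terminal gate of the head: capped when closed
  gate <- spec$n_gate
  if (gate == "auto")
    gate <- if (spec$conformation == "planar") "closed" else "open"
  if (gate == "closed") {
    all_atoms[[length(all_atoms) + 1L]] <- atomic_model(
      "X", 0, 0, neck_top + 8, weight = 1000, chain = "G")
  }
  combined <- do.call(rbind, all_atoms)
  class(combined) <- c("atomic_model", "data.frame")
  # place the assembly so the anchor centroid sits on the z axis: ring
  # azimuths (and hence the programmed opening angle) are then measured
  # about the axis exactly, even for an open ring whose centroid would
  # otherwise drift sideways
  off <- c(colMeans(anchors[, 1:2, drop = FALSE]), 0)
  combined$x <- combined$x - off[1]
  combined$y <- combined$y - off[2]
  anchors <- sweep(anchors, 2, off)
  for (k in 1:6) poses[[k]]$translation <- poses[[k]]$translation - off
  grid <- if (render)
    model_to_density(combined, spec$voxel_size, spec$resolution, spec$box)
  else NULL
  list(grid = grid, subunit = sub, poses = poses, anchors = anchors,
       model = combined, gate = gate, spec = spec)
}

#' Noisy projection set with known orientations
#'
#' Projects the grid at listed or random orientations and adds white
#' Gaussian noise scaled to the requested signal-to-noise ratio, defined as
#' signal variance over noise variance inside the particle support (pixels
#' where the noiseless projection exceeds 5 percent of its maximum).
#'
#' @param grid a [voxel_grid()].
#' @param n number of projections (ignored when `orientations` given).
#' @param orientations optional n x 3 matrix of zyz Euler degrees; random
#'   uniform orientations (uniform in cos beta) otherwise.
#' @param snr per-image SNR; `Inf` for noiseless.
#' @param seed integer seed; the same seed gives a bit-identical set.
#' @return a list with `images` (list of [image2d()]), `orientations`
#'   (n x 3), `snr`, `seed`.
#' @export
make_projection_set <- function(grid, n = 10, orientations = NULL,
                                snr = Inf, seed = 1) {
  stopifnot(is_voxel_grid(grid))
  set.seed(seed)
  if (is.null(orientations)) {
    orientations <- cbind(stats::runif(n, 0, 360),
                          acos(stats::runif(n, -1, 1)) * 180 / pi,
                          stats::runif(n, 0, 360))
  } else {
    orientations <- as.matrix(orientations)
    n <- nrow(orientations)
  }
  images <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- project(grid, orientations[i, ])
    if (is.finite(snr)) {
      support <- pr$data > 0.05 * max(pr$data)
      svar <- stats::var(pr$data[support])
      noise <- matrix(stats::rnorm(length(pr$data), sd = sqrt(svar / snr)),
                      nrow(pr$data))
      pr <- image2d(pr$data + noise, pr$pixel_size)
    }
    images[[i]] <- pr
  }
  list(images = images, orientations = orientations, snr = snr, seed = seed)
}

#' Half-map pair with designed per-shell SSNR
#'
#' Adds two independent realizations of noise, spectrally coloured so that
#' each Fourier shell has the requested spectral signal-to-noise ratio,
#' to the input map. The expected half-map FSC is then
#' `ssnr / (ssnr + 1)` per shell, which makes the pair a closed-form oracle
#' for the FSC machinery.
#'
#' @param grid a [voxel_grid()] (the common signal).
#' @param ssnr either a single number, a function of spatial frequency
#'   (1/Angstrom), or a vector with one value per 1-pixel shell.
#' @param seed integer seed.
#' @return a list: `half1`, `half2` ([voxel_grid()]s), `ssnr_per_shell`,
#'   `freq` (shell centres, 1/Angstrom).
#' @export
make_half_maps <- function(grid, ssnr, seed = 1) {
  stopifnot(is_voxel_grid(grid))
  set.seed(seed)
  n <- grid_n(grid)
  vs <- grid$voxel_size
  r <- freq_radius_3d(n)
  shell <- ceiling(r)
  shell[r == 0] <- 0L
  smax <- max(shell)
  nshell_nyq <- floor(n / 2)
  freq <- (seq_len(smax) - 0.5) / (n * vs)
  s_target <- if (is.function(ssnr)) ssnr(freq)
              else if (length(ssnr) == 1L) rep(ssnr, smax)
              else c(ssnr, rep(ssnr[length(ssnr)], max(0, smax - length(ssnr))))
  s_target <- pmax(s_target[seq_len(smax)], 1e-12)
  S <- stats::fft(grid$data)
  Ps <- as.numeric(rowsum(Mod(S[shell >= 1])^2,
                          shell[shell >= 1]))[seq_len(smax)]
  mk_half <- function() {
    noise <- array(stats::rnorm(n^3), dim = c(n, n, n))
    Nf <- stats::fft(noise)
    Pn <- as.numeric(rowsum(Mod(Nf[shell >= 1])^2,
                            shell[shell >= 1]))[seq_len(smax)]
    fac <- sqrt(Ps / (s_target * pmax(Pn, .Machine$double.xmin)))
    fac[Ps <= 0] <- 0
    facmap <- array(0, dim = dim(shell))
    facmap[shell >= 1] <- fac[shell[shell >= 1]]
    coloured <- Re(stats::fft(Nf * facmap, inverse = TRUE)) / n^3
    voxel_grid(grid$data + coloured, vs, grid$origin)
  }
  h1 <- mk_half()
  h2 <- mk_half()
  list(half1 = h1, half2 = h2,
       ssnr_per_shell = s_target[seq_len(nshell_nyq)],
       freq = freq[seq_len(nshell_nyq)])
}
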