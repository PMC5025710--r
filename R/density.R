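# Simulated density from atomic coordinates and projection matching.
# Each atom is rendered as one isotropic 3D Gaussian whose standard
# deviation is tied to the target resolution, sigma = resolution/(pi*sqrt(2))
# (amplitude halved at spatial frequency 1/resolution), with amplitude
# proportional to the atomic weight. One-Gaussian-per-atom is the standard
# low-resolution simulation scheme; scattering-factor form factors are out
# of scope.

#' Gaussian width for a target resolution
#'
#' @param resolution resolution in Angstrom.
#' @param constant width convention constant; the default `pi * sqrt(2)`
#'   makes the Gaussian's Fourier amplitude fall to 1/2 at `1/resolution`.
#' @return sigma in Angstrom.
#' @export
resolution_sigma <- function(resolution, constant = pi * sqrt(2)) {
  stopifnot(resolution > 0)
  resolution / constant
}

#' Render an atomic model as a density map
#'
#' Places one isotropic Gaussian per atom, centred on the atom position
#' (coordinates are interpreted in Angstrom relative to the box centre),
#' with per-atom voxel sums normalized so that the integrated density of
#' the map equals the summed atomic weights exactly.
#'
#' @param model an [atomic_model()]; coordinates relative to box centre.
#' @param voxel_size Angstrom per voxel.
#' @param resolution target resolution in Angstrom; sets the Gaussian width
#'   via [resolution_sigma()].
#' @param box box side in voxels.
#' @param sigma_constant width convention, see [resolution_sigma()].
#' @param truncate kernel support radius in sigmas (default 4).
#' @return a [voxel_grid()].
#' @export
model_to_density <- function(model, voxel_size, resolution, box,
                             sigma_constant = pi * sqrt(2), truncate = 4) {
  stopifnot(is_atomic_model(model), voxel_size > 0, box > 1)
  sigma <- resolution_sigma(resolution, sigma_constant)
  sig_vox <- sigma / voxel_size
  r <- max(1L, ceiling(truncate * sig_vox))
  c0 <- centre_index(box)
  ixa <- (model$x / voxel_size) + c0
  iya <- (model$y / voxel_size) + c0
  iza <- (model$z / voxel_size) + c0
  out_of_box <- ixa < 1 | ixa > box | iya < 1 | iya > box | iza < 1 | iza > box
  if (any(out_of_box))
    stop("atoms outside the box: indices ",
         paste(utils::head(which(out_of_box), 10), collapse = ", "),
         if (sum(out_of_box) > 10) " ..." else "")
  data <- array(0, dim = c(box, box, box))
  two_s2 <- 2 * sig_vox^2
  for (a in seq_len(nrow(model))) {
    ix <- max(1L, floor(ixa[a] - r)):min(box, ceiling(ixa[a] + r))
    iy <- max(1L, floor(iya[a] - r)):min(box, ceiling(iya[a] + r))
    iz <- max(1L, floor(iza[a] - r)):min(box, ceiling(iza[a] + r))
    gx <- exp(-(ix - ixa[a])^2 / two_s2)
    gy <- exp(-(iy - iya[a])^2 / two_s2)
    gz <- exp(-(iz - iza[a])^2 / two_s2)
    kern <- outer(outer(gx, gy), gz)
    kern <- kern * (model$weight[a] / sum(kern))
    data[ix, iy, iz] <- data[ix, iy, iz] + kern
  }
  voxel_grid(data, voxel_size)
}

#' Project a volume along a view direction
#'
#' Actively rotates the grid by the zyz Euler rotation and sums along the
#' third (z) index; the identity orientation is therefore an exact sum over
#' z. The pixel sum of the projection equals the voxel sum of the grid up
#' to tri-linear resampling losses at the box edge.
#'
#' @param grid a cubic [voxel_grid()].
#' @param orientation zyz Euler angles in degrees, `c(alpha, beta, gamma)`.
#'   `alpha` is an in-plane rotation of the projection.
#' @return an [image2d()] with pixel size = voxel size.
#' @export
project <- function(grid, orientation = c(0, 0, 0)) {
  stopifnot(is_voxel_grid(grid), length(orientation) == 3L)
  if (all(abs(orientation %% 360) < 1e-12)) {
    return(image2d(apply(grid$data, c(1, 2), sum), grid$voxel_size))
  }
  g <- rotate_grid(grid, orientation[1], orientation[2], orientation[3])
  image2d(apply(g$data, c(1, 2), sum), grid$voxel_size)
}

# Cyclic normalized cross-correlation of two same-size images over all
# integer shifts (whole-frame mean/sd normalization). Returns the NCC
# matrix with shift (0,0) at index (1,1), wrapped.
ncc2d_translations <- function(a, b) {
  n <- nrow(a)
  N <- length(a)
  ma <- mean(a); mb <- mean(b)
  sa <- sqrt(mean((a - ma)^2)); sb <- sqrt(mean((b - mb)^2))
  if (sa == 0 || sb == 0) stop("zero-variance image in NCC")
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / N
  (cc / N - ma * mb) / (sa * sb)
}

# Best shift and score from a wrapped NCC matrix/array.
wrapped_peak <- function(cc) {
  i <- which.max(cc)
  d <- dim(cc)
  idx <- arrayInd(i, d)
  shift <- ((idx - 1 + floor(d / 2)) %% d) - floor(d / 2)
  list(score = cc[i], shift = as.numeric(shift))
}

# Approximately uniform orientation grid: beta levels uniform in cos(beta),
# azimuth count scaled by sin(beta), in-plane alpha on a regular grid.
orientation_grid <- function(angular_step, in_plane = TRUE) {
  stopifnot(angular_step > 0, angular_step <= 45)
  nb <- max(2L, round(180 / angular_step) + 1L)
  betas <- acos(seq(1, -1, length.out = nb)) * 180 / pi
  rows <- list()
  for (b in betas) {
    ng <- max(1L, round(360 * sin(b * pi / 180) / angular_step))
    gammas <- seq(0, 360, length.out = ng + 1L)[seq_len(ng)]
    rows[[length(rows) + 1L]] <- expand.grid(beta = b, gamma = gammas)
  }
  bg <- do.call(rbind, rows)
  if (in_plane) {
    na <- max(1L, round(360 / angular_step))
    alphas <- seq(0, 360, length.out = na + 1L)[seq_len(na)]
    out <- merge(data.frame(alpha = alphas), bg)
  } else {
    out <- cbind(alpha = 0, bg)
  }
  out <- out[order(out$alpha, out$beta, out$gamma), c("alpha", "beta", "gamma")]
  rownames(out) <- NULL
  out
}

#' Match an image against projections of a volume
#'
#' Exhaustively scans an approximately uniform orientation grid: the volume
#' is projected once per viewing direction `(beta, gamma)`, the projection
#' is rotated in-plane over the `alpha` grid, and each candidate is scored
#' by normalized cross-correlation against the image with a full FFT
#' translation search. The best orientation, its score, and the full score
#' table are returned.
#'
#' @param image an [image2d()].
#' @param grid a [voxel_grid()] with the same pixel/voxel size as `image`.
#' @param angular_step orientation grid spacing in degrees (<= 30).
#' @return a list with `orientation` (zyz degrees), `shift` (pixels),
#'   `score` (NCC), and `table` (a data frame of all scores).
#' @export
match_projections <- function(image, grid, angular_step = 15) {
  stopifnot(is_image2d(image), is_voxel_grid(grid))
  if (angular_step > 30) stop("angular_step must be <= 30 degrees")
  if (abs(image$pixel_size - grid$voxel_size) > 1e-6 * grid$voxel_size)
    stop("pixel/voxel size mismatch; resample first")
  if (nrow(image$data) != grid_n(grid))
    stop("image and grid box sizes differ; resample first")
  og <- orientation_grid(angular_step, in_plane = FALSE)
  na <- max(1L, round(360 / angular_step))
  alphas <- seq(0, 360, length.out = na + 1L)[seq_len(na)]
  tab <- vector("list", nrow(og) * na)
  best <- list(score = -Inf)
  row <- 0L
  for (i in seq_len(nrow(og))) {
    pr <- project(grid, c(0, og$beta[i], og$gamma[i]))
    for (al in alphas) {
      cand <- if (al == 0) pr else rotate_image2d(pr, al)
      cc <- ncc2d_translations(image$data, cand$data)
      pk <- wrapped_peak(cc)
      row <- row + 1L
      tab[[row]] <- data.frame(alpha = al, beta = og$beta[i],
                               gamma = og$gamma[i],
                               shift_x = pk$shift[1], shift_y = pk$shift[2],
                               ncc = pk$score)
      if (pk$score > best$score) {
        best <- list(orientation = c(al, og$beta[i], og$gamma[i]),
                     shift = pk$shift, score = pk$score)
      }
    }
  }
  best$table <- do.call(rbind, tab)
  best$table <- best$table[order(-best$table$ncc), ]
  rownames(best$table) <- NULL
  best
}
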