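# Rigid-body docking of atomic subunits into density maps by exhaustive
# FFT cross-correlation over translations at every node of a deterministic
# orientation grid, with optional local refinement. The score is plain
# normalized cross-correlation (whole-box statistics); no randomness is
# used anywhere, and ties are broken lexicographically in (alpha, beta,
# gamma), so results are reproducible bit for bit.

#' A rigid pose
#'
#' Rotation as zyz Euler angles (degrees, canonicalized to `[0, 360)` x
#' `[0, 180]` x `[0, 360)`) plus a translation of the probe's centre of
#' mass from the map box centre, in Angstrom.
#'
#' @param alpha,beta,gamma zyz Euler angles, degrees.
#' @param translation length-3 numeric, Angstrom.
#' @return an object of class `rigid_pose`.
#' @export
rigid_pose <- function(alpha = 0, beta = 0, gamma = 0,
                       translation = c(0, 0, 0)) {
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  alpha <- alpha %% 360
  gamma <- gamma %% 360
  if (beta < 0 || beta > 180) {
    # re-canonicalize via the rotation matrix
    R <- euler_zyz_matrix(alpha, beta, gamma)
    e <- matrix_to_euler_zyz(R)
    alpha <- e[1]; beta <- e[2]; gamma <- e[3]
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 translation = as.numeric(translation)),
            class = "rigid_pose")
}

pose_matrix <- function(pose) euler_zyz_matrix(pose$alpha, pose$beta, pose$gamma)

matrix_to_euler_zyz <- function(R) {
  beta <- acos(pmin(1, pmax(-1, R[3, 3]))) * 180 / pi
  if (abs(R[3, 3]) > 1 - 1e-12) {
    alpha <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    gamma <- 0
    if (R[3, 3] < 0) { beta <- 180 }
  } else {
    alpha <- atan2(R[2, 3], R[1, 3]) * 180 / pi
    gamma <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  }
  c(alpha %% 360, beta, gamma %% 360)
}

#' Apply a rigid pose to an atomic model
#'
#' Rotates the model about its (weighted) centre of mass and places that
#' centre at `translation` relative to the map box centre. Coordinates of
#' the returned model are in box-centre Angstrom.
#'
#' @param model an [atomic_model()].
#' @param pose a [rigid_pose()].
#' @return the transformed [atomic_model()].
#' @export
apply_pose <- function(model, pose) {
  stopifnot(is_atomic_model(model), inherits(pose, "rigid_pose"))
  com <- model_com(model)
  xyz <- sweep(model_coords(model), 2, com)
  xyz <- xyz %*% t(pose_matrix(pose))
  xyz <- sweep(xyz, 2, pose$translation, `+`)
  out <- model
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

#' FFT normalized cross-correlation over all translations
#'
#' Computes the cyclic normalized cross-correlation between a map and a
#' probe density of the same box over every integer voxel shift, by FFT.
#' Means and standard deviations are the whole-box values, so the peak for
#' a probe against itself is exactly 1.
#'
#' @param map,probe same-size [voxel_grid()]s.
#' @return a 3D array of NCC values, wrapped with shift (0,0,0) at index
#'   (1,1,1); see [wrapped_peak()]-style indexing.
#' @export
cross_correlate_translations <- function(map, probe) {
  stopifnot(is_voxel_grid(map), is_voxel_grid(probe))
  if (grid_n(map) != grid_n(probe)) stop("box size mismatch")
  if (abs(map$voxel_size - probe$voxel_size) > 1e-6 * map$voxel_size)
    stop("voxel size mismatch")
  a <- map$data; b <- probe$data
  N <- length(a)
  ma <- mean(a); mb <- mean(b)
  sa <- sqrt(mean((a - ma)^2)); sb <- sqrt(mean((b - mb)^2))
  if (sa == 0) stop("map has zero variance")
  if (sb == 0) stop("probe has zero variance")
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / N
  (cc / N - ma * mb) / (sa * sb)
}

# Render `model` at orientation R (rotation about its COM, COM at box
# centre) and return the NCC translation search against `map`.
score_orientation <- function(map, model, alpha, beta, gamma, resolution,
                              sigma_constant = pi * sqrt(2)) {
  pose <- rigid_pose(alpha, beta, gamma, c(0, 0, 0))
  posed <- apply_pose(model, pose)
  dens <- model_to_density(posed, map$voxel_size, resolution, grid_n(map),
                           sigma_constant = sigma_constant)
  cc <- cross_correlate_translations(map, dens)
  pk <- wrapped_peak(cc)
  list(score = pk$score, shift_vox = pk$shift, cc = cc)
}

# Parabolic sub-voxel refinement of a wrapped correlation peak along each
# axis.
subvoxel_peak <- function(cc, shift_vox) {
  d <- dim(cc)
  idx <- ((shift_vox %% d) + 1)
  out <- shift_vox
  for (ax in 1:3) {
    im <- idx; ip <- idx
    im[ax] <- ((idx[ax] - 2) %% d[ax]) + 1
    ip[ax] <- (idx[ax] %% d[ax]) + 1
    y0 <- cc[matrix(im, 1)]; y1 <- cc[matrix(idx, 1)]; y2 <- cc[matrix(ip, 1)]
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && den < 0) out[ax] <- out[ax] + 0.5 * (y0 - y2) / den
  }
  out
}

#' Exhaustive rigid-body fit of a model into a map
#'
#' Renders the model at `resolution`, scans a deterministic,
#' approximately-uniform zyz orientation grid with an FFT translation
#' search at each node, and locally refines the best candidates
#' (golden-section line search per Euler angle, parabolic sub-voxel
#' interpolation on the shift).
#'
#' @param map a cubic [voxel_grid()].
#' @param model an [atomic_model()] (coordinates in any frame; it is
#'   re-centred on its COM).
#' @param angular_step orientation grid spacing in degrees, in `[5, 45]`.
#' @param resolution rendering resolution in Angstrom.
#' @param n_best number of top orientations to keep and refine.
#' @param refine logical; run local refinement on the best candidate(s).
#' @param sigma_constant Gaussian width convention for rendering.
#' @return a list of `fit_result` objects (pose, score, rank), sorted by
#'   score descending.
#' @export
rigid_fit <- function(map, model, angular_step = 15, resolution = 15,
                      n_best = 3, refine = TRUE,
                      sigma_constant = pi * sqrt(2)) {
  stopifnot(is_voxel_grid(map), is_atomic_model(model))
  if (angular_step < 5 || angular_step > 45)
    stop("angular_step must lie in [5, 45] degrees")
  if (stats::sd(as.vector(map$data)) == 0) stop("map has zero variance")
  og <- orientation_grid(angular_step, in_plane = TRUE)
  scores <- numeric(nrow(og))
  shifts <- matrix(0, nrow(og), 3)
  for (i in seq_len(nrow(og))) {
    s <- score_orientation(map, model, og$alpha[i], og$beta[i], og$gamma[i],
                           resolution, sigma_constant)
    scores[i] <- s$score
    shifts[i, ] <- subvoxel_peak(s$cc, s$shift_vox)
  }
  ord <- order(-scores, og$alpha, og$beta, og$gamma)
  keep <- utils::head(ord, n_best)
  pose_ncc <- function(ang, sh) {
    pose <- rigid_pose(ang[1], ang[2], ang[3], sh * map$voxel_size)
    tryCatch({
      dens <- model_to_density(apply_pose(model, pose), map$voxel_size,
                               resolution, grid_n(map),
                               sigma_constant = sigma_constant)
      stats::cor(as.vector(map$data), as.vector(dens$data))
    }, error = function(e) -Inf)  # posed atoms outside the box
  }
  results <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    ang <- c(og$alpha[i], og$beta[i], og$gamma[i])
    sc <- scores[i]
    sh <- shifts[i, ]
    if (refine) {
      ang0 <- ang; sh0 <- sh
      half <- angular_step / 2
      obj <- function(a, b, g) {
        score_orientation(map, model, a, b, g, resolution, sigma_constant)$score
      }
      for (pass in 1:2) {
        o1 <- stats::optimize(function(a) -obj(a, ang[2], ang[3]),
                              lower = ang[1] - half, upper = ang[1] + half,
                              tol = angular_step / 20)
        ang[1] <- o1$minimum
        o2 <- stats::optimize(function(b) -obj(ang[1], b, ang[3]),
                              lower = max(0, ang[2] - half),
                              upper = min(180, ang[2] + half),
                              tol = angular_step / 20)
        ang[2] <- o2$minimum
        o3 <- stats::optimize(function(g) -obj(ang[1], ang[2], g),
                              lower = ang[3] - half, upper = ang[3] + half,
                              tol = angular_step / 20)
        ang[3] <- o3$minimum
      }
      s <- score_orientation(map, model, ang[1], ang[2], ang[3], resolution,
                             sigma_constant)
      sh <- subvoxel_peak(s$cc, s$shift_vox)
      # final score: direct NCC of the probe re-rendered at the fractional
      # pose (the translation search only sees integer shifts); refinement
      # must never lose to the grid candidate it started from
      sc_ref <- pose_ncc(ang, sh)
      sc_grid <- pose_ncc(ang0, sh0)
      if (sc_grid > sc_ref) {
        ang <- ang0; sh <- sh0; sc <- sc_grid
      } else if (is.finite(sc_ref)) {
        sc <- sc_ref
      }
    }
    results[[j]] <- structure(list(
      pose = rigid_pose(ang[1], ang[2], ang[3], sh * map$voxel_size),
      score = sc, rank = NA_integer_, clash_count = NA_integer_),
      class = "fit_result")
  }
  results <- results[order(-vapply(results, `[[`, 0, "score"))]
  for (j in seq_along(results)) results[[j]]$rank <- j
  results
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit: NCC %.4f, euler (%.1f, %.1f, %.1f) deg, shift (%.1f, %.1f, %.1f) A%s>\n",
    x$score, x$pose$alpha, x$pose$beta, x$pose$gamma,
    x$pose$translation[1], x$pose$translation[2], x$pose$translation[3],
    if (!is.na(x$clash_count)) sprintf(", clashes %d", x$clash_count) else ""))
  invisible(x)
}

#' Count steric clashes between two placed models
#'
#' Number of inter-model atom pairs closer than `cutoff` Angstrom, found
#' with spatial hashing on a `cutoff`-sized cell grid.
#'
#' @param a,b [atomic_model()]s (already posed).
#' @param cutoff clash distance in Angstrom (default 2.0).
#' @return integer pair count.
#' @export
clash_count <- function(a, b, cutoff = 2.0) {
  stopifnot(is_atomic_model(a), is_atomic_model(b), cutoff > 0)
  pa <- model_coords(a); pb <- model_coords(b)
  keyify <- function(p) {
    cl <- floor(p / cutoff)
    paste(cl[, 1], cl[, 2], cl[, 3], sep = ",")
  }
  kb <- keyify(pb)
  cells <- split(seq_len(nrow(pb)), kb)
  cla <- floor(pa / cutoff)
  count <- 0L
  c2 <- cutoff^2
  for (i in seq_len(nrow(pa))) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      key <- paste(cla[i, 1] + dx, cla[i, 2] + dy, cla[i, 3] + dz, sep = ",")
      js <- cells[[key]]
      if (is.null(js)) next
      d2 <- (pb[js, 1] - pa[i, 1])^2 + (pb[js, 2] - pa[i, 2])^2 +
        (pb[js, 3] - pa[i, 3])^2
      count <- count + sum(d2 < c2)
    }
  }
  count
}

#' Sequentially fit several copies of a subunit into a map
#'
#' Fits one copy with [rigid_fit()], subtracts its rendered density from
#' further consideration by masking (binary mask at the rendered half-max,
#' dilated 2 voxels, with a 2-voxel cosine edge), and repeats. Each placed
#' copy is clash-checked against all previous ones.
#'
#' @param map a [voxel_grid()].
#' @param model an [atomic_model()].
#' @param n_copies number of copies to place (default 6).
#' @param angular_step,resolution,refine,sigma_constant as in [rigid_fit()].
#' @param score_floor abort (with a warning, returning a partial result)
#'   when the best remaining score falls below this.
#' @return list of `fit_result`, in placement order, with `clash_count`
#'   filled in against previously placed copies.
#' @export
sequential_multifit <- function(map, model, n_copies = 6, angular_step = 15,
                                resolution = 15, refine = TRUE,
                                sigma_constant = pi * sqrt(2),
                                score_floor = 0.1) {
  stopifnot(n_copies >= 1)
  work <- map
  placed <- list()
  placed_models <- list()
  for (k in seq_len(n_copies)) {
    if (stats::sd(as.vector(work$data)) == 0) {
      warning("map exhausted after ", k - 1, " copies; returning partial result")
      break
    }
    fits <- rigid_fit(work, model, angular_step = angular_step,
                      resolution = resolution, n_best = 1, refine = refine,
                      sigma_constant = sigma_constant)
    best <- fits[[1]]
    if (best$score < score_floor) {
      warning("score ", signif(best$score, 3), " below floor after ",
              k - 1, " copies; returning partial result")
      break
    }
    pm <- apply_pose(model, best$pose)
    best$clash_count <- if (length(placed_models))
      sum(vapply(placed_models, function(m) clash_count(pm, m), 0L))
    else 0L
    best$rank <- k
    placed[[k]] <- best
    placed_models[[k]] <- pm
    # mask out the placed copy
    dens <- model_to_density(pm, map$voxel_size, resolution, grid_n(map),
                             sigma_constant = sigma_constant)
    msk <- mask_from_density(dens$data, level = 0.5 * max(dens$data),
                             extend_px = 2, soft_edge_px = 2)
    work <- voxel_grid(work$data * (1 - msk), work$voxel_size, work$origin)
  }
  placed
}
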