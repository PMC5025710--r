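# Initial-model generation: extend a single 2D side-view class average to a
# rotationally symmetric 3D volume by sweeping its Fourier transform about
# the long axis. The 3D spectrum F(kx,ky,kz) is filled, at each axial
# frequency kz, by linear interpolation of the 2D radial profile P(k, kz)
# at radius k = sqrt(kx^2 + ky^2); an inverse 3D FFT then yields the model.
# The input is mirror-symmetrized about the long axis first so that the
# swept spectrum satisfies Friedel symmetry and the volume comes out real.

#' Symmetrization parameters
#'
#' @param pre_lowpass low-pass cutoff in Angstrom applied to the class
#'   average before symmetrization (default 120).
#' @param final_lowpass low-pass applied to the finished 3D model
#'   (default 120).
#' @param mirror_symmetrize average the image with its mirror about the
#'   long axis before sweeping (default TRUE; required for a strictly real
#'   output volume).
#' @param center_method `"com"` (centre of mass) — reserved for future
#'   cross-correlation centering variants.
#' @param edge_width raised-cosine edge of the low-pass filters, Fourier px.
#' @return a list of class `symm_params`.
#' @export
symm_params <- function(pre_lowpass = 120, final_lowpass = 120,
                        mirror_symmetrize = TRUE, center_method = "com",
                        edge_width = 3) {
  stopifnot(pre_lowpass > 0, final_lowpass > 0)
  structure(list(pre_lowpass = pre_lowpass, final_lowpass = final_lowpass,
                 mirror_symmetrize = isTRUE(mirror_symmetrize),
                 center_method = match.arg(center_method, "com"),
                 edge_width = edge_width),
            class = "symm_params")
}

#' Centre a particle image and align its long axis vertically
#'
#' Shifts the centre of mass of the (background-subtracted, positive part
#' of the) image to the box centre and rotates so that the principal axis
#' of the thresholded density lies along the image vertical (second index).
#' Background is taken as the image median; negative values are clamped to
#' zero for the moment computation only. Resampling is bilinear.
#'
#' @param image an [image2d()].
#' @return the centred, aligned [image2d()], with attributes
#'   `shift` (pixels) and `rotation` (degrees) recording the transform.
#' @export
center_and_align <- function(image) {
  stopifnot(is_image2d(image))
  n <- nrow(image$data)
  c0 <- centre_index(n)
  w <- image$data - stats::median(image$data)
  w[w < 0] <- 0
  if (sum(w) <= 0) stop("empty image: no positive density above background")
  ax <- seq_len(n) - c0
  tot <- sum(w)
  cx <- sum(rowSums(w) * ax) / tot
  cy <- sum(colSums(w) * ax) / tot
  # principal axis of the second moments
  X <- outer(ax - cx, rep(1, n))
  Y <- outer(rep(1, n), ax - cy)
  mxx <- sum(w * X * X) / tot
  myy <- sum(w * Y * Y) / tot
  mxy <- sum(w * X * Y) / tot
  # angle of the major axis from the +y (vertical) direction
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)  # major axis from +x, radians
  rot_deg <- 90 - theta * 180 / pi
  rot_deg <- ((rot_deg + 90) %% 180) - 90    # smallest equivalent rotation
  if (myy >= mxx && abs(mxy) < 1e-9 * (mxx + myy)) rot_deg <- 0
  # shift COM to centre, then rotate about the centre
  px <- rep(ax, times = n)
  py <- rep(ax, each = n)
  t <- rot_deg * pi / 180
  qx <- cos(t) * px + sin(t) * py + cx
  qy <- -sin(t) * px + cos(t) * py + cy
  vals <- interp2_bilinear(image$data, qx + c0, qy + c0)
  out <- image2d(matrix(vals, n, n), image$pixel_size)
  attr(out, "shift") <- c(cx, cy)
  attr(out, "rotation") <- rot_deg
  out
}

# Mirror an image about the long (vertical) axis using the cyclic flip that
# corresponds exactly to kx -> -kx.
mirror_image_x <- function(img) {
  idx <- wrap_flip_index(nrow(img$data))
  image2d(img$data[idx, , drop = FALSE], img$pixel_size)
}

#' Sweep a side view into a rotationally symmetric 3D model
#'
#' The core initial-model construction: the (optionally mirror-symmetrized)
#' image is Fourier transformed; at each axial frequency level the radial
#' profile of the 2D spectrum is swept about the long axis by evaluating it
#' at the in-plane radius of every 3D frequency sample, linearly
#' interpolating between adjacent integer radii; frequencies beyond the 2D
#' support are zero. The inverse 3D transform is real up to numerical
#' residue, which is checked and discarded.
#'
#' @param image a centred, aligned [image2d()] with even side length (odd
#'   sides are symmetrically padded).
#' @param params a [symm_params()]; only `mirror_symmetrize` and the
#'   residue tolerance matter here (low-passes are applied by
#'   [make_initial_model()]).
#' @param residue_tol maximum imaginary residue relative to the volume RMS
#'   before a warning is raised (default 1e-6).
#' @return a cubic [voxel_grid()] with side = image side.
#' @export
cylindrize <- function(image, params = symm_params(), residue_tol = 1e-6) {
  stopifnot(is_image2d(image))
  image <- pad_even_image(image)
  n <- nrow(image$data)
  c0 <- centre_index(n)
  img <- image$data
  if (params$mirror_symmetrize) {
    img <- (img + mirror_image_x(image)$data) / 2
  }
  G <- cfft2(img)  # centred spectrum, index j <-> frequency j - c0
  # radial profiles per kz: P[r+1, jz], r = 0..n/2-1, plus a zero guard row
  nr <- n %/% 2L
  P <- matrix(0 + 0i, nr + 1L, n)
  P[1, ] <- G[c0, ]
  for (r in seq_len(nr - 1L)) {
    P[r + 1L, ] <- (G[c0 + r, ] + G[c0 - r, ]) / 2
  }
  # P[nr + 1, ] stays 0: radii >= n/2 are outside the sampled support
  kx <- seq_len(n) - c0
  kr <- sqrt(outer(kx^2, kx^2, `+`))
  i0 <- pmin(floor(kr), nr)       # integer radius below
  wgt <- kr - floor(kr)
  inside <- floor(kr) <= nr - 1L  # need P[i0] and P[i0+1]
  idx_lo <- i0 + 1L
  idx_hi <- pmin(i0 + 2L, nr + 1L)
  F3 <- array(0 + 0i, dim = c(n, n, n))
  for (jz in seq_len(n)) {
    pz <- P[, jz]
    plane <- matrix(0 + 0i, n, n)
    plane[inside] <- (1 - wgt[inside]) * pz[idx_lo[inside]] +
      wgt[inside] * pz[idx_hi[inside]]
    F3[, , jz] <- plane
  }
  # zero the unpaired Nyquist planes so the spectrum is strictly Hermitian
  F3[1, , ] <- 0; F3[, 1, ] <- 0; F3[, , 1] <- 0
  vol <- cifft3(F3)
  re <- Re(vol)
  resid <- max(abs(Im(vol))) / max(sqrt(mean(re^2)), .Machine$double.eps)
  if (resid > residue_tol)
    warning(sprintf(
      "complex residue %.3g of volume RMS (asymmetric input? mirror_symmetrize=%s)",
      resid, params$mirror_symmetrize))
  g <- voxel_grid(re, image$pixel_size)
  attr(g, "complex_residue") <- resid
  g
}

#' Soft-edged reference cylinder
#'
#' A cylinder of the given length and diameter with value 1 inside, 0
#' outside, and a raised-cosine ramp of width `edge_width` across the
#' surface, both radially and axially; the density is exactly 0.5 at the
#' nominal surface. The long axis is z.
#'
#' @param length,diameter cylinder dimensions in Angstrom.
#' @param box box side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param edge_width soft-edge width in Angstrom (default 10).
#' @return a [voxel_grid()].
#' @export
soft_cylinder <- function(length, diameter, box = 224, voxel_size = 1.8,
                          edge_width = 10) {
  stopifnot(length > 0, diameter > 0, box > 1, voxel_size > 0, edge_width >= 0)
  extent <- box * voxel_size
  if (length + edge_width > extent || diameter + edge_width > extent)
    stop("cylinder plus soft edge exceeds the box")
  ax <- axis_coords(box, voxel_size)
  ramp <- function(u, e) {
    # u: signed distance beyond the nominal surface (positive outside)
    if (e <= 0) return(as.numeric(u < 0) + 0.5 * (u == 0))
    v <- numeric(length(u))
    v[u <= -e / 2] <- 1
    mid <- u > -e / 2 & u < e / 2
    v[mid] <- 0.5 * (1 + cos(pi * (u[mid] + e / 2) / e))
    v
  }
  r <- sqrt(outer(ax^2, ax^2, `+`))
  radial <- ramp(r - diameter / 2, edge_width)
  axial <- ramp(abs(ax) - length / 2, edge_width)
  data <- array(0, dim = c(box, box, box))
  for (k in seq_len(box)) data[, , k] <- radial * axial[k]
  voxel_grid(data, voxel_size)
}

#' Build an initial model from one side-view class average
#'
#' Full pipeline: centre and align the image, low-pass filter it (default
#' 120 Angstrom), sweep it into a rotationally symmetric volume with
#' [cylindrize()], and low-pass filter the volume again (default 120
#' Angstrom), mirroring the common practice of heavily band-limiting
#' references handed to 3D classification.
#'
#' @param image an [image2d()] side-view class average.
#' @param params a [symm_params()].
#' @return a [voxel_grid()] with provenance recorded in
#'   `attr(, "provenance")`.
#' @export
make_initial_model <- function(image, params = symm_params()) {
  stopifnot(is_image2d(image))
  if (params$pre_lowpass < 2 * image$pixel_size)
    stop("pre_lowpass below Nyquist limit")
  # a near-constant image sweeps into a featureless artifact: flag it and
  # skip the (undefined) centring step
  near_constant <- stats::sd(as.vector(image$data)) <=
    1e-8 * (max(abs(image$data)) + .Machine$double.eps)
  if (near_constant) {
    warning("input image is (near-)constant; output is a featureless artifact")
    aligned <- image
  } else {
    aligned <- center_and_align(image)
  }
  filtered <- low_pass_filter(aligned, params$pre_lowpass, params$edge_width)
  vol <- cylindrize(filtered, params)
  out <- low_pass_filter(vol, params$final_lowpass, params$edge_width)
  attr(out, "provenance") <- list(
    pre_lowpass = params$pre_lowpass, final_lowpass = params$final_lowpass,
    mirror_symmetrize = params$mirror_symmetrize,
    shift = attr(aligned, "shift"), rotation = attr(aligned, "rotation"),
    complex_residue = attr(vol, "complex_residue"))
  out
}

#' Side projection of a volume
#'
#' Rotates the volume about its long axis (z) by `phi` degrees and sums
#' along y, producing the side-view image (x horizontal, z vertical) that a
#' projection at that azimuth would give.
#'
#' @param grid a [voxel_grid()].
#' @param phi azimuth in degrees (default 0, which is an exact sum).
#' @return an [image2d()].
#' @export
side_projection <- function(grid, phi = 0) {
  stopifnot(is_voxel_grid(grid))
  n <- grid_n(grid)
  if (abs(phi %% 360) < 1e-12) {
    img <- apply(grid$data, c(1, 3), sum)
    return(image2d(img, grid$voxel_size))
  }
  g <- rotate_grid(grid, phi, 0, 0)
  image2d(apply(g$data, c(1, 3), sum), grid$voxel_size)
}
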