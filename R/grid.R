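# Core data model: cubic voxel grids and square 2D images with a physical
# pixel size. Index convention: data[x, y, z] with z (third index) the
# particle long axis. Physical coordinates are in Angstrom relative to the
# box centre, which sits at index floor(n/2) + 1 (the DC position of a
# centred discrete Fourier transform).

#' Construct a 3D density grid
#'
#' A `voxel_grid` is a cubic, real-valued 3D array with an isotropic voxel
#' size in Angstrom. It is the universal container for density maps in this
#' package. The third array index is the particle long axis (z); physical
#' coordinates are measured in Angstrom from the box centre at index
#' `floor(n/2) + 1`.
#'
#' @param data numeric 3D array; all three dimensions must be equal.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical coordinate of voxel (1,1,1), length-3 numeric.
#'   Carried through I/O; geometric operations use box-centre coordinates.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  d <- dim(data)
  if (d[1] != d[2] || d[2] != d[3])
    stop("grid must be cubic; got ", paste(d, collapse = "x"),
         " (pad or crop before constructing)")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains non-finite values")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' Construct a 2D image
#'
#' An `image2d` is a square, real-valued 2D array with a pixel size in
#' Angstrom. Class averages and projections use this type. The second index
#' is the particle long axis for side views.
#'
#' @param data numeric matrix, square.
#' @param pixel_size pixel edge in Angstrom (> 0).
#' @return an object of class `image2d`.
#' @export
image2d <- function(data, pixel_size) {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (nrow(data) != ncol(data))
    stop("image must be square; got ", nrow(data), "x", ncol(data))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (Angstrom)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains non-finite values")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "image2d")
}

#' @export
print.voxel_grid <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<voxel_grid %d^3, %.4g A/voxel, box %.1f A, range [%.3g, %.3g]>\n",
              n, x$voxel_size, n * x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<image2d %dx%d, %.4g A/px, range [%.3g, %.3g]>\n",
              n, n, x$pixel_size, min(x$data), max(x$data)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")
is_image2d   <- function(x) inherits(x, "image2d")

grid_n <- function(g) dim(g$data)[1]

# Centre index of an n-point axis (DC position of the centred spectrum).
centre_index <- function(n) as.integer(n %/% 2 + 1)

# Physical coordinates (Angstrom, from box centre) of the voxel centres
# along one axis.
axis_coords <- function(n, voxel_size) {
  (seq_len(n) - centre_index(n)) * voxel_size
}

# Signed integer DFT frequencies in "Fourier pixel" units for an n-point
# axis as laid out by stats::fft (index 1 = DC).
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Radius |k| in Fourier pixels for every voxel of an n^3 (or n^2) unshifted
# spectrum.
freq_radius_3d <- function(n) {
  k <- fft_freqs(n)
  k2 <- k^2
  r2 <- outer(outer(k2, k2, `+`), k2, `+`)
  sqrt(r2)
}

freq_radius_2d <- function(n) {
  k2 <- fft_freqs(n)^2
  sqrt(outer(k2, k2, `+`))
}

# Checkerboard (-1)^(i+j[+k]) used to obtain a transform whose real-space
# AND frequency-space origins both sit at the centre index. Exact for even n.
checker2 <- function(n) {
  s <- (-1)^(seq_len(n) - 1)
  outer(s, s)
}

checker3 <- function(n) {
  s <- (-1)^(seq_len(n) - 1)
  array(outer(outer(s, s), s), dim = c(n, n, n))
}

# Centred 2D FFT: spectrum index j corresponds to frequency j - (n/2+1),
# phases relative to the box centre. Requires even n.
cfft2 <- function(m) {
  n <- nrow(m)
  stopifnot(n %% 2L == 0L)
  ch <- checker2(n)
  ch * stats::fft(ch * m)
}

cifft2 <- function(M) {
  n <- nrow(M)
  ch <- checker2(n)
  ch * stats::fft(ch * M, inverse = TRUE) / (n * n)
}

cfft3 <- function(a) {
  n <- dim(a)[1]
  stopifnot(n %% 2L == 0L)
  ch <- checker3(n)
  ch * stats::fft(ch * a)
}

cifft3 <- function(A) {
  n <- dim(A)[1]
  ch <- checker3(n)
  ch * stats::fft(ch * A, inverse = TRUE) / (n^3)
}

# Trilinear interpolation of `vol` (n^3 array) at fractional 1-based index
# coordinates; points outside the box evaluate to 0.
interp3_trilinear <- function(vol, ix, iy, iz) {
  n <- dim(vol)[1]
  # points exactly on the upper boundary belong to the last cell
  ix[ix == n] <- n - 1e-9; iy[iy == n] <- n - 1e-9; iz[iz == n] <- n - 1e-9
  i0 <- floor(ix); j0 <- floor(iy); k0 <- floor(iz)
  fx <- ix - i0;  fy <- iy - j0;  fz <- iz - k0
  ok <- i0 >= 1 & i0 < n & j0 >= 1 & j0 < n & k0 >= 1 & k0 < n
  out <- numeric(length(ix))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  v <- as.vector(vol)
  base <- i0 + (j0 - 1) * n + (k0 - 1) * n * n
  n2 <- n * n
  c000 <- v[base];               c100 <- v[base + 1]
  c010 <- v[base + n];           c110 <- v[base + n + 1]
  c001 <- v[base + n2];          c101 <- v[base + n2 + 1]
  c011 <- v[base + n + n2];      c111 <- v[base + n + n2 + 1]
  out[ok] <-
    c000 * (1 - fx) * (1 - fy) * (1 - fz) +
    c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy * (1 - fz) +
    c110 * fx * fy * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz +
    c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy * fz +
    c111 * fx * fy * fz
  out
}

# Bilinear interpolation of matrix `m` at fractional 1-based indices;
# outside -> 0.
interp2_bilinear <- function(m, ix, iy) {
  n <- nrow(m); p <- ncol(m)
  ix[ix == n] <- n - 1e-9; iy[iy == p] <- p - 1e-9
  i0 <- floor(ix); j0 <- floor(iy)
  fx <- ix - i0;  fy <- iy - j0
  ok <- i0 >= 1 & i0 < n & j0 >= 1 & j0 < p
  out <- numeric(length(ix))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; fx <- fx[ok]; fy <- fy[ok]
  v <- as.vector(m)
  base <- i0 + (j0 - 1) * n
  out[ok] <-
    v[base] * (1 - fx) * (1 - fy) +
    v[base + 1] * fx * (1 - fy) +
    v[base + n] * (1 - fx) * fy +
    v[base + n + 1] * fx * fy
  out
}

# zyz intrinsic Euler rotation (degrees): R = Rz(alpha) Ry(beta) Rz(gamma).
# Acts on column vectors of (x, y, z) coordinates.
euler_zyz_matrix <- function(alpha, beta, gamma) {
  rz <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# Angle (degrees) between two rotation matrices.
rotation_angle_between <- function(Ra, Rb) {
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Rotate a density grid in real space
#'
#' Returns the grid actively rotated by the zyz Euler rotation
#' `R = Rz(alpha) Ry(beta) Rz(gamma)` about the box centre, resampled by
#' tri-linear interpolation. Voxels mapped from outside the box are zero.
#'
#' @param grid a [voxel_grid()].
#' @param alpha,beta,gamma zyz Euler angles in degrees.
#' @return a rotated [voxel_grid()].
#' @export
rotate_grid <- function(grid, alpha, beta, gamma) {
  stopifnot(is_voxel_grid(grid))
  R <- euler_zyz_matrix(alpha, beta, gamma)
  rotate_grid_matrix(grid, R)
}

rotate_grid_matrix <- function(grid, R) {
  n <- grid_n(grid)
  c0 <- centre_index(n)
  ax <- seq_len(n) - c0
  Rt <- t(R)   # inverse rotation: sample source at R^-1 p
  out <- array(0, dim = c(n, n, n))
  xy_x <- rep(ax, times = n)
  xy_y <- rep(ax, each = n)
  for (k in seq_len(n)) {
    z <- ax[k]
    qx <- Rt[1, 1] * xy_x + Rt[1, 2] * xy_y + Rt[1, 3] * z
    qy <- Rt[2, 1] * xy_x + Rt[2, 2] * xy_y + Rt[2, 3] * z
    qz <- Rt[3, 1] * xy_x + Rt[3, 2] * xy_y + Rt[3, 3] * z
    out[, , k] <- interp3_trilinear(grid$data, qx + c0, qy + c0, qz + c0)
  }
  voxel_grid(out, grid$voxel_size, grid$origin)
}

# Rotate a square image about its centre by `angle` degrees (bilinear).
rotate_image2d <- function(img, angle) {
  n <- nrow(img$data)
  c0 <- centre_index(n)
  ax <- seq_len(n) - c0
  t <- angle * pi / 180
  px <- rep(ax, times = n)
  py <- rep(ax, each = n)
  # inverse mapping
  qx <- cos(t) * px + sin(t) * py
  qy <- -sin(t) * px + cos(t) * py
  vals <- interp2_bilinear(img$data, qx + c0, qy + c0)
  image2d(matrix(vals, n, n), img$pixel_size)
}

# Cyclic (wrapped) flip of one axis: i -> ((n - (i - 1)) %% n) + 1.
# Keeps both index 1 and the centre index fixed (even n), i.e. corresponds
# exactly to coordinate negation in the DFT frame.
wrap_flip_index <- function(n) c(1L, seq.int(n, 2L))

#' Mirror a grid to invert its handedness
#'
#' Mirrors the map along the x axis (first index) about the box centre.
#' Projection data determine a reconstruction only up to mirror chirality;
#' this operation flips it to match an external reference. Applying it
#' twice is the identity.
#'
#' @param grid a [voxel_grid()].
#' @return the mirrored [voxel_grid()].
#' @export
flip_hand <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  idx <- wrap_flip_index(grid_n(grid))
  voxel_grid(grid$data[idx, , , drop = FALSE], grid$voxel_size, grid$origin)
}

#' Resolution corresponding to a fraction of Nyquist
#'
#' The Nyquist frequency of sampling at `pixel_size` is `1/(2 pixel_size)`;
#' a spatial frequency at `fraction` of Nyquist corresponds to a resolution
#' of `2 * pixel_size / fraction` Angstrom. At 1.8 A/pixel, 0.25 x Nyquist
#' is 14.4 A.
#'
#' @param pixel_size pixel size in Angstrom.
#' @param fraction fraction of Nyquist, in (0, 1].
#' @return resolution in Angstrom.
#' @export
resolution_at_nyquist_fraction <- function(pixel_size, fraction) {
  if (!is.numeric(pixel_size) || any(pixel_size <= 0))
    stop("`pixel_size` must be positive")
  if (!is.numeric(fraction) || any(fraction <= 0) || any(fraction > 1))
    stop("`fraction` must lie in (0, 1]")
  2 * pixel_size / fraction
}

#' Low-pass filter a map or image
#'
#' Attenuates spatial frequencies beyond `1/cutoff` with a raised-cosine
#' (soft) edge. The transfer function is 1 up to the cutoff frequency,
#' falls as a half-cosine over `edge_width` Fourier pixels, and is 0
#' beyond. DC (and hence the mean) is preserved exactly.
#'
#' @param x a [voxel_grid()] or [image2d()].
#' @param cutoff resolution cutoff in Angstrom; must be at least twice the
#'   voxel/pixel size (the Nyquist limit).
#' @param edge_width width of the cosine edge in Fourier pixels (default 3).
#' @return filtered object of the same class.
#' @export
low_pass_filter <- function(x, cutoff, edge_width = 3) {
  if (is_voxel_grid(x)) {
    ps <- x$voxel_size; n <- grid_n(x)
  } else if (is_image2d(x)) {
    ps <- x$pixel_size; n <- nrow(x$data)
  } else stop("`x` must be a voxel_grid or image2d")
  if (cutoff < 2 * ps)
    stop(sprintf("cutoff %.3g A is below the Nyquist limit %.3g A", cutoff, 2 * ps))
  # frequencies in Fourier-pixel units; cutoff frequency in the same units
  kc <- n * ps / cutoff
  r <- if (is_voxel_grid(x)) freq_radius_3d(n) else freq_radius_2d(n)
  H <- raised_cosine_lowpass(r, kc, edge_width)
  if (is_voxel_grid(x)) {
    filt <- Re(stats::fft(stats::fft(x$data) * H, inverse = TRUE)) / n^3
    voxel_grid(filt, ps, x$origin)
  } else {
    filt <- Re(stats::fft(stats::fft(x$data) * H, inverse = TRUE)) / n^2
    image2d(filt, ps)
  }
}

raised_cosine_lowpass <- function(r, kc, edge_width) {
  H <- array(0, dim = dim(r))
  H[r <= kc] <- 1
  if (edge_width > 0) {
    e <- r > kc & r < kc + edge_width
    H[e] <- 0.5 * (1 + cos(pi * (r[e] - kc) / edge_width))
  }
  H
}

# Pad (or crop) a cubic grid symmetrically to side n_out, keeping the box
# centre fixed. Used to make non-cubic MRC input usable downstream.
pad_to_cube <- function(data, voxel_size, origin = c(0, 0, 0)) {
  d <- dim(data)
  n <- max(d)
  if (n %% 2L == 1L) n <- n + 1L
  out <- array(0, dim = c(n, n, n))
  off <- centre_index(n) - vapply(d, centre_index, 1L)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- data
  voxel_grid(out, voxel_size, origin)
}

# Pad a square image symmetrically to even side.
pad_even_image <- function(img) {
  n <- nrow(img$data)
  if (n %% 2L == 0L) return(img)
  out <- matrix(0, n + 1L, n + 1L)
  out[seq_len(n) + 1L, seq_len(n) + 1L] <- img$data
  image2d(out, img$pixel_size)
}
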