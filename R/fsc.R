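# Fourier shell correlation, threshold-crossing resolution, and soft
# masks. Shells are 1 Fourier pixel wide by default and exclude DC. The
# gold-standard criterion takes the resolution at the 0.143 crossing of
# the FSC between two independently treated half-maps.

#' Fourier shell correlation between two maps
#'
#' Per-shell normalized complex correlation
#' `Re(sum(A * Conj(B))) / sqrt(sum(|A|^2) * sum(|B|^2))` over concentric
#' frequency shells of width `shell_width` Fourier pixels. DC is excluded.
#' Shells with zero power in either map get correlation 0 and are flagged.
#'
#' @param a,b same-size, same-voxel-size [voxel_grid()]s.
#' @param shell_width shell width in Fourier pixels (default 1).
#' @return an `fsc_curve`: data frame with columns `shell`, `freq` (1/A,
#'   shell centre), `fsc`, `n_voxels`, `zero_power`.
#' @export
fsc <- function(a, b, shell_width = 1) {
  stopifnot(is_voxel_grid(a), is_voxel_grid(b), shell_width > 0)
  n <- grid_n(a)
  if (grid_n(b) != n) stop("box size mismatch")
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    stop("voxel size mismatch")
  A <- stats::fft(a$data)
  B <- stats::fft(b$data)
  r <- freq_radius_3d(n)
  shell <- ceiling(r / shell_width)
  shell[r == 0] <- 0L                       # DC, dropped
  nmax <- floor((n / 2) / shell_width)      # up to Nyquist
  keep <- shell >= 1L & shell <= nmax
  sh <- shell[keep]
  num <- as.numeric(rowsum(Re(A[keep] * Conj(B[keep])), sh))
  pa <- as.numeric(rowsum(Mod(A[keep])^2, sh))
  pb <- as.numeric(rowsum(Mod(B[keep])^2, sh))
  cnt <- as.numeric(rowsum(rep(1, sum(keep)), sh))
  zero <- pa <= 0 | pb <= 0
  corr <- ifelse(zero, 0, num / sqrt(pmax(pa, .Machine$double.xmin) *
                                       pmax(pb, .Machine$double.xmin)))
  out <- data.frame(shell = seq_len(nmax),
                    freq = (seq_len(nmax) - 0.5) * shell_width /
                      (n * a$voxel_size),
                    fsc = corr, n_voxels = cnt, zero_power = zero)
  class(out) <- c("fsc_curve", "data.frame")
  attr(out, "voxel_size") <- a$voxel_size
  attr(out, "box") <- n
  out
}

#' Resolution at an FSC threshold crossing
#'
#' Locates the first downward crossing of the curve through `threshold`
#' (walking from low to high frequency) by linear interpolation between the
#' two flanking shells, and returns the reciprocal of the crossing
#' frequency in Angstrom. If the curve never drops below the threshold the
#' Nyquist resolution is returned with attribute `at_nyquist = TRUE`.
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold FSC threshold (default 0.143, the gold-standard
#'   half-map criterion).
#' @return resolution in Angstrom.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  f <- curve$fsc
  if (f[1] < threshold)
    stop("FSC is below the threshold already in the first shell")
  below <- which(f < threshold)
  if (!length(below)) {
    vs <- attr(curve, "voxel_size")
    res <- 2 * vs
    attr(res, "at_nyquist") <- TRUE
    return(res)
  }
  i <- below[1]
  f0 <- f[i - 1]; f1 <- f[i]
  x0 <- curve$freq[i - 1]; x1 <- curve$freq[i]
  xc <- x0 + (f0 - threshold) / (f0 - f1) * (x1 - x0)
  1 / xc
}

# Clamped squared Euclidean distance transform to a foreground set.
# Exact for distances <= rmax; larger distances saturate. Separable
# min-convolution with offsets limited to rmax voxels per axis.
edt_clamped <- function(fg, rmax) {
  d <- dim(fg)
  big <- (rmax + 1)^2 * 3
  D <- array(ifelse(fg, 0, big), dim = d)
  offs <- seq.int(-rmax, rmax)
  for (ax in 1:3) {
    Dn <- D
    for (k in offs) {
      if (k == 0) next
      src <- shift_axis(D, ax, k)
      Dn <- pmin(Dn, src + k^2)
    }
    D <- Dn
  }
  D
}

# Shift a 3D array along one axis by k voxels, padding with a large
# sentinel (used as +Inf by the distance transform).
shift_axis <- function(A, ax, k) {
  d <- dim(A)
  out <- array(max(A) + 1, dim = d)
  n <- d[ax]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  switch(ax,
         out[dst, , ] <- A[src, , ],
         out[, dst, ] <- A[, src, ],
         out[, , dst] <- A[, , src])
  out
}

# Mask in [0, 1] from a binary/threshold stage: 1 inside the dilated
# foreground, raised-cosine falloff over soft_edge_px, 0 beyond.
mask_from_density <- function(data, level, extend_px, soft_edge_px) {
  fg <- data >= level
  if (!any(fg)) stop("threshold leaves an empty mask")
  rmax <- ceiling(extend_px + soft_edge_px) + 1L
  dist <- sqrt(edt_clamped(fg, rmax))
  m <- array(0, dim = dim(data))
  m[dist <= extend_px] <- 1
  if (soft_edge_px > 0) {
    e <- dist > extend_px & dist < extend_px + soft_edge_px
    m[e] <- 0.5 * (1 + cos(pi * (dist[e] - extend_px) / soft_edge_px))
  }
  m
}

#' Soft mask around the particle support
#'
#' Binarizes the map at `level_fraction` of its maximum, dilates the
#' foreground by `extend_px` voxels, and applies a raised-cosine edge of
#' `soft_edge_px` voxels as a function of Euclidean distance to the
#' dilated support. The binarization stage is idempotent: masking a mask
#' reproduces it.
#'
#' @param grid a [voxel_grid()].
#' @param level_fraction threshold as a fraction of the map maximum
#'   (default 0.02).
#' @param extend_px dilation in voxels (default 3).
#' @param soft_edge_px cosine edge width in voxels (default 6).
#' @return a [voxel_grid()] with values in `[0, 1]`; the parameters are
#'   attached as `attr(, "mask_params")` so any resolution reported with
#'   the mask can carry them.
#' @export
soft_mask <- function(grid, level_fraction = 0.02, extend_px = 3,
                      soft_edge_px = 6) {
  stopifnot(is_voxel_grid(grid), level_fraction > 0)
  mx <- max(grid$data)
  if (mx <= 0) stop("map has no positive density; cannot build a mask")
  m <- mask_from_density(grid$data, level_fraction * mx, extend_px,
                         soft_edge_px)
  out <- voxel_grid(m, grid$voxel_size, grid$origin)
  attr(out, "mask_params") <- list(level_fraction = level_fraction,
                                   extend_px = extend_px,
                                   soft_edge_px = soft_edge_px)
  out
}

#' Apply a mask to a map
#'
#' @param grid a [voxel_grid()].
#' @param mask a mask [voxel_grid()] (values in `[0, 1]`).
#' @return the masked [voxel_grid()].
#' @export
apply_mask <- function(grid, mask) {
  stopifnot(is_voxel_grid(grid), is_voxel_grid(mask))
  if (grid_n(grid) != grid_n(mask)) stop("box size mismatch")
  voxel_grid(grid$data * mask$data, grid$voxel_size, grid$origin)
}
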