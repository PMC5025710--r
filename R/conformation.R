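# Hexamer ring geometry and map morphology. A reference plane is fitted
# through six per-subunit anchor points (nucleotide-site centroids or
# subunit centres of mass); azimuthal gaps about the plane normal give the
# ring opening angle, and signed distances to the plane give the axial
# (lock-washer) displacements. Map-space metrics: per-slab bending curve,
# cross-section extents, axial extent, and the state of the axial gate.

#' Ring geometry of six placed subunits
#'
#' Fits a total-least-squares plane through six anchor points, projects the
#' anchors onto it, and reports sorted azimuths, the six adjacent azimuthal
#' gaps (summing to 360 degrees), the opening angle (largest gap), and the
#' signed axial displacement of every subunit from the plane. For a closed
#' planar hexamer the opening angle is 60 degrees and all displacements are
#' zero; a lock-washer shows a larger opening and an axial step across it.
#'
#' @param anchors either a 6 x 3 numeric matrix of anchor points (Angstrom),
#'   or a list of six posed [atomic_model()]s from which anchors are taken
#'   per `anchor_rule`.
#' @param anchor_rule `"com"` (subunit centre of mass) or `"resid"`
#'   (centroid of `anchor_resid` residues, e.g. a nucleotide pocket).
#' @param anchor_resid residue numbers defining the pocket when
#'   `anchor_rule = "resid"`.
#' @return a `ring_geometry` list: `anchors`, `centroid`, `normal`,
#'   `azimuths` (sorted, degrees), `gaps` (adjacent, degrees),
#'   `opening_angle` (degrees), `gap_index` (the pair of anchor rows
#'   flanking the largest gap), `axial_displacements` (Angstrom, in input
#'   order), `gap_axial_difference` (Angstrom), `anchor_rule`.
#' @export
ring_geometry <- function(anchors, anchor_rule = c("com", "resid"),
                          anchor_resid = NULL) {
  anchor_rule <- match.arg(anchor_rule)
  if (is.list(anchors) && !is.matrix(anchors)) {
    pts <- t(vapply(anchors, function(m) {
      stopifnot(is_atomic_model(m))
      if (anchor_rule == "resid") {
        sub <- m[!is.na(m$resid) & m$resid %in% anchor_resid, , drop = FALSE]
        if (nrow(sub) == 0L) {
          # pocket not present in this model: fall back to the COM
          model_com(m)
        } else model_com(sub)
      } else model_com(m)
    }, numeric(3)))
  } else {
    pts <- as.matrix(anchors)
  }
  if (nrow(pts) != 6L || ncol(pts) != 3L)
    stop("exactly six 3D anchor points are required")
  if (any(dist(pts) < 1e-6)) stop("coincident anchor points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * sv$d[1]) stop("anchors are collinear")
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal      # orient with +z (long axis)
  # in-plane basis
  e1 <- sv$v[, 1]
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  az <- atan2(X %*% e2, X %*% e1)[, 1] * 180 / pi
  az <- az %% 360
  ord <- order(az)
  az_sorted <- az[ord]
  gaps <- diff(c(az_sorted, az_sorted[1] + 360))
  gi <- which.max(gaps)
  axial <- (X %*% normal)[, 1]
  pair <- c(ord[gi], ord[(gi %% 6L) + 1L])
  structure(list(
    anchors = pts, centroid = ctr, normal = normal,
    azimuths = az_sorted, gaps = gaps,
    opening_angle = max(gaps),
    gap_index = pair,
    axial_displacements = axial,
    gap_axial_difference = abs(axial[pair[1]] - axial[pair[2]]),
    anchor_rule = anchor_rule), class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf(
    "<ring_geometry: opening %.1f deg (subunits %d-%d), axial step %.1f A>\n",
    x$opening_angle, x$gap_index[1], x$gap_index[2], x$gap_axial_difference))
  cat("  gaps (deg):", paste(sprintf("%.1f", x$gaps), collapse = " "), "\n")
  cat("  axial (A): ",
      paste(sprintf("%+.1f", x$axial_displacements), collapse = " "), "\n")
  invisible(x)
}

#' Bending curve of a map
#'
#' Splits the map into z-slabs, thresholds each slab at
#' `threshold_fraction` of its own maximum, and records the density-weighted
#' centre of mass of the retained voxels. The bend score is the maximum
#' perpendicular distance of the slab centres from the straight chord
#' joining the first and last centre.
#'
#' @param grid a [voxel_grid()].
#' @param slab_thickness slab thickness in Angstrom (default 10).
#' @param threshold_fraction per-slab threshold as a fraction of the slab
#'   maximum (default 0.5).
#' @param min_slab_fraction slabs whose maximum is below this fraction of
#'   the global maximum are skipped and reported as gaps (default 0.05).
#' @return a list: `curve` (data frame z, x, y in Angstrom), `bend_score`
#'   (Angstrom), `gaps` (z of skipped slabs).
#' @export
bending_curve <- function(grid, slab_thickness = 10, threshold_fraction = 0.5,
                          min_slab_fraction = 0.05) {
  stopifnot(is_voxel_grid(grid), slab_thickness > 0)
  n <- grid_n(grid)
  vs <- grid$voxel_size
  ax <- axis_coords(n, vs)
  per_slab <- max(1L, round(slab_thickness / vs))
  starts <- seq(1L, n, by = per_slab)
  gmax <- max(grid$data)
  rows <- list(); gaps <- numeric(0)
  for (s in starts) {
    ks <- s:min(n, s + per_slab - 1L)
    slab <- grid$data[, , ks, drop = FALSE]
    zc <- mean(ax[ks])
    smax <- max(slab)
    if (smax < min_slab_fraction * gmax) { gaps <- c(gaps, zc); next }
    w <- slab
    w[w < threshold_fraction * smax] <- 0
    tot <- sum(w)
    xs <- sum(apply(w, 1, sum) * ax) / tot
    ys <- sum(apply(w, 2, sum) * ax) / tot
    rows[[length(rows) + 1L]] <- data.frame(z = zc, x = xs, y = ys)
  }
  curve <- do.call(rbind, rows)
  if (is.null(curve) || nrow(curve) < 2L)
    stop("not enough occupied slabs for a bending curve")
  p0 <- as.numeric(curve[1, c("x", "y", "z")])
  p1 <- as.numeric(curve[nrow(curve), c("x", "y", "z")])
  u <- p1 - p0
  un <- sqrt(sum(u^2))
  bend <- 0
  if (un > 0) {
    u <- u / un
    for (i in seq_len(nrow(curve))) {
      v <- as.numeric(curve[i, c("x", "y", "z")]) - p0
      perp <- v - sum(v * u) * u
      bend <- max(bend, sqrt(sum(perp^2)))
    }
  }
  list(curve = curve, bend_score = bend, gaps = gaps,
       threshold_fraction = threshold_fraction)
}

# Flood fill (4-connectivity) of the component of `mask` containing pixel
# (i0, j0), by iterated dilation restricted to the mask.
flood_component <- function(mask, i0, j0) {
  n <- nrow(mask); p <- ncol(mask)
  comp <- matrix(FALSE, n, p)
  if (!mask[i0, j0]) return(comp)
  comp[i0, j0] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-n, ]
    grown[-n, ] <- grown[-n, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -p]
    grown[, -p] <- grown[, -p] | comp[, -1]
    grown <- grown & mask
    if (all(grown == comp)) return(comp)
    comp <- grown
  }
}

# Lumen analysis of one binary section: the background component containing
# the axis pixel. Returns list(open, diameter) where diameter is the
# equivalent-circle diameter of the enclosed component (NA when closed).
section_lumen <- function(fg, voxel_size) {
  n <- nrow(fg)
  c0 <- centre_index(n)
  if (fg[c0, c0]) return(list(open = FALSE, diameter = NA_real_))
  comp <- flood_component(!fg, c0, c0)
  touches_border <- any(comp[1, ]) || any(comp[n, ]) ||
    any(comp[, 1]) || any(comp[, n])
  if (touches_border) {
    # no enclosing density ring around the axis at this level
    return(list(open = FALSE, diameter = NA_real_))
  }
  area <- sum(comp) * voxel_size^2
  list(open = TRUE, diameter = 2 * sqrt(area / pi))
}

#' Cross-section extent at a given height
#'
#' Binarizes the z-section nearest to `z` (Angstrom from the box centre) at
#' a fraction of the section maximum (or a fixed level), and reports the
#' maximum caliper diameter, the minimum caliper width, and the lumen: the
#' equivalent-circle diameter of the enclosed background region containing
#' the axis, or `"closed"` when the axis is covered by density or not
#' enclosed by it.
#'
#' @param grid a [voxel_grid()].
#' @param z section height in Angstrom from the box centre (default 0).
#' @param threshold_fraction threshold as a fraction of the section maximum
#'   (default 0.5); ignored when `level` is given.
#' @param level optional absolute threshold level.
#' @return a list: `max_diameter`, `min_diameter`, `lumen` (Angstrom or
#'   `"closed"`), `threshold` (the absolute level used), `z` (the exact
#'   section height).
#' @export
section_extent <- function(grid, z = 0, threshold_fraction = 0.5,
                           level = NULL) {
  stopifnot(is_voxel_grid(grid))
  n <- grid_n(grid)
  vs <- grid$voxel_size
  ax <- axis_coords(n, vs)
  k <- which.min(abs(ax - z))
  sl <- grid$data[, , k]
  if (max(sl) <= 0) stop("section at z = ", z, " A is empty")
  thr <- if (is.null(level)) threshold_fraction * max(sl) else level
  fg <- sl >= thr
  if (!any(fg)) stop("section at z = ", z, " A is empty at this threshold")
  idx <- which(fg, arr.ind = TRUE)
  pts <- cbind(ax[idx[, 1]], ax[idx[, 2]])
  hull <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  # caliper over the hull points, with a half-pixel support correction
  # along the caliper direction (pixel centres underestimate the extent of
  # the square-pixel set by half a footprint on either side on average)
  dd <- as.matrix(stats::dist(hull))
  im <- which(dd == max(dd), arr.ind = TRUE)[1, ]
  u <- hull[im[1], ] - hull[im[2], ]
  u <- u / sqrt(sum(u^2))
  dmax <- max(dd) + vs * (abs(u[1]) + abs(u[2])) / 2
  angles <- seq(0, pi, length.out = 181)[-181]
  widths <- vapply(angles, function(t) {
    pr <- hull[, 1] * cos(t) + hull[, 2] * sin(t)
    max(pr) - min(pr) + vs * (abs(cos(t)) + abs(sin(t))) / 2
  }, 0)
  dmin <- min(widths)
  lum <- section_lumen(fg, vs)
  list(max_diameter = dmax, min_diameter = dmin,
       lumen = if (lum$open) lum$diameter else "closed",
       threshold = thr, z = ax[k])
}

#' Axial extent of the thresholded density
#'
#' Extent along z of voxels at or above `threshold_fraction` of the global
#' maximum.
#'
#' @param grid a [voxel_grid()].
#' @param threshold_fraction fraction of the map maximum (default 0.5).
#' @return extent in Angstrom, with the threshold attached as an attribute.
#' @export
axial_extent <- function(grid, threshold_fraction = 0.5) {
  stopifnot(is_voxel_grid(grid))
  mx <- max(grid$data)
  if (mx <= 0) stop("empty grid: no positive density")
  thr <- threshold_fraction * mx
  occ <- apply(grid$data, 3, max) >= thr
  if (!any(occ)) stop("no voxels above threshold")
  ks <- range(which(occ))
  # + 1 voxel for the footprint of the outermost occupied sections
  ext <- (ks[2] - ks[1] + 1) * grid$voxel_size
  attr(ext, "threshold") <- thr
  ext
}

#' State of the axial gate over a z-region
#'
#' Walks the z-sections across `axis_region` (Angstrom from the box
#' centre), binarizing each at `threshold_fraction` of the global maximum,
#' and tests whether an enclosed background channel containing the axis
#' runs through every section. Because the channel must contain the axis in
#' each section, slice-wise openness implies a continuous axis-following
#' channel in 3D.
#'
#' @param grid a [voxel_grid()].
#' @param axis_region `c(zmin, zmax)` in Angstrom from the box centre.
#' @param threshold_fraction fraction of the global maximum (default 0.5).
#' @return a list: `state` (`"open"` or `"closed"`), `min_lumen` (Angstrom,
#'   NA when closed), `profile` (data frame z, lumen diameter or NA).
#' @export
gate_state <- function(grid, axis_region, threshold_fraction = 0.5) {
  stopifnot(is_voxel_grid(grid), length(axis_region) == 2L)
  n <- grid_n(grid)
  vs <- grid$voxel_size
  ax <- axis_coords(n, vs)
  ks <- which(ax >= min(axis_region) & ax <= max(axis_region))
  if (!length(ks)) stop("axis_region contains no sections")
  thr <- threshold_fraction * max(grid$data)
  lum <- vapply(ks, function(k) {
    fg <- grid$data[, , k] >= thr
    l <- section_lumen(fg, vs)
    if (l$open) l$diameter else NA_real_
  }, 0)
  open <- !anyNA(lum)
  list(state = if (open) "open" else "closed",
       min_lumen = if (open) min(lum) else NA_real_,
       profile = data.frame(z = ax[ks], lumen = lum),
       threshold = thr)
}

#' Full width at half maximum of a sampled profile
#'
#' Linear interpolation of the half-maximum crossings on either side of the
#' profile peak.
#'
#' @param profile numeric vector of samples.
#' @param spacing sample spacing (e.g. Angstrom per voxel).
#' @return FWHM in the units of `spacing`.
#' @export
profile_fwhm <- function(profile, spacing = 1) {
  stopifnot(length(profile) >= 3)
  m <- max(profile)
  if (m <= 0) stop("profile has no positive values")
  half <- m / 2
  imax <- which.max(profile)
  # left crossing
  li <- which(profile[seq_len(imax)] < half)
  if (!length(li)) stop("profile does not drop below half maximum on the left")
  l <- max(li)
  xl <- l + (half - profile[l]) / (profile[l + 1] - profile[l])
  # right crossing
  ri <- which(profile[imax:length(profile)] < half) + imax - 1L
  if (!length(ri)) stop("profile does not drop below half maximum on the right")
  r <- min(ri)
  xr <- r - 1 + (half - profile[r - 1]) / (profile[r] - profile[r - 1])
  (xr - xl) * spacing
}

#' Axial density profile of a map
#'
#' @param grid a [voxel_grid()].
#' @return numeric vector: per-section density sum along z.
#' @export
axial_profile <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  apply(grid$data, 3, sum)
}
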