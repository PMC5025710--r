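# Shared fixtures and independent oracles, all built in code.

nrms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
rms_rel <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Smooth, compactly supported, axially symmetric phantom: a ring of
# z-varying radius plus an axial blob, under a Gaussian axial envelope.
# Generous padding keeps the radial-interpolation bias of the Fourier
# sweep small.
make_smooth_axisym_phantom <- function(n = 96, vs = 2, rad0 = 20,
                                       rad_amp = 5, ring_sig = 10,
                                       blob_sig = 12, env_sig = 20) {
  ax <- (seq_len(n) - (floor(n / 2) + 1)) * vs
  r <- sqrt(outer(ax^2, ax^2, `+`))
  vol <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    rad <- rad0 + rad_amp * sin(ax[k] / 25)
    vol[, , k] <- (exp(-((r - rad)^2) / (2 * ring_sig^2)) +
                     0.6 * exp(-r^2 / (2 * blob_sig^2))) *
      exp(-ax[k]^2 / (2 * env_sig^2))
  }
  voxel_grid(vol, vs)
}

# Independent real-space oracle for the Fourier sweep: per-z-level onion
# peeling (discrete inverse Abel transform). The side projection of an
# axially symmetric object is p(x) = sum_j L_ij f_j with analytic chord
# lengths L_ij of ray i through annulus j; solving the triangular system
# recovers the radial profile, from which the volume is rebuilt by linear
# interpolation in radius. No Fourier transform is involved anywhere.
abel_invert_volume <- function(image) {
  stopifnot(inherits(image, "image2d"))
  n <- nrow(image$data)
  vs <- image$pixel_size
  c0 <- floor(n / 2) + 1
  nr <- n %/% 2 - 1
  # chord-length matrix: ray at x_i = (i-1)*vs through annulus j with
  # edges (j-1)*vs, j*vs
  L <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    x <- (i - 1) * vs
    for (j in seq_len(nr)) {
      r_in <- (j - 1) * vs
      r_out <- j * vs
      if (r_out > x)
        L[i, j] <- 2 * (sqrt(r_out^2 - x^2) - sqrt(max(r_in^2 - x^2, 0)))
    }
  }
  # annulus-centre radii for resampling
  r_ctr <- (seq_len(nr) - 0.5) * vs
  ax <- (seq_len(n) - c0) * vs
  rr <- sqrt(outer(ax^2, ax^2, `+`))
  vol <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    # symmetrized half-profile of the projection at this z level
    prof <- vapply(seq_len(nr), function(i) {
      d <- i - 1
      (image$data[c0 + d, k] + image$data[c0 - d, k]) / 2
    }, 0)
    f <- solve(L, prof * vs)  # projection sums are per-pixel, chords in A
    vol[, , k] <- matrix(stats::approx(r_ctr, f, xout = as.vector(rr),
                                       rule = 2, yleft = f[1])$y, n, n)
  }
  vol[rr >= max(r_ctr)] <- 0
  vol
}

# Down-scaled hexamer spec that keeps docking tests fast (box 48).
small_hexamer_spec <- function(conformation = "planar", opening_angle = NULL,
                               total_rise = NULL, seed = 1) {
  phantom_spec(conformation, opening_angle = opening_angle,
               total_rise = total_rise,
               total_length = 108, head_length = 44, head_width = 70,
               neck_width = 46, neck_length = 6,
               box = 48, voxel_size = 2.5, resolution = 16, seed = seed)
}

# Direct-space cyclic NCC at one integer shift: b displaced by +shift
# voxels (wrapped), whole-box population statistics. Oracle for the FFT
# translation search.
direct_ncc_at_shift <- function(a, b, shift) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1 - shift[ax]) %% d[ax]) + 1)
  bs <- b[idx[[1]], idx[[2]], idx[[3]]]
  ma <- mean(a); mb <- mean(bs)
  sa <- sqrt(mean((a - ma)^2)); sb <- sqrt(mean((bs - mb)^2))
  (mean(a * bs) - ma * mb) / (sa * sb)
}

# A small synthetic PDB file content (two chains, glycine-like atoms).
write_test_pdb <- function(path) {
  lines <- c(
    sprintf("ATOM  %5d  N   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
            1, 1, 1.0, 2.0, 3.0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2, 1, 2.5, 2.0, 3.0),
    sprintf("ATOM  %5d  C   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            3, 2, 4.0, 2.5, 3.5),
    sprintf("ATOM  %5d  O   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            4, 2, 5.0, 1.8, 3.2),
    sprintf("ATOM  %5d  CA  GLY B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            5, 3, -3.0, 0.0, 1.0),
    sprintf("HETATM%5d FE   HEM B%4d    %8.3f%8.3f%8.3f  1.00  0.00          FE",
            6, 99, 0.0, 0.0, 0.0),
    "END")
  writeLines(lines, path)
  path
}
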