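test_that("MRC volumes round-trip losslessly at float32 precision", {
  set.seed(1)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), voxel_size = 1.8)
  tf <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(g, tf)
  g2 <- read_mrc(tf)
  expect_equal(g2$voxel_size, 1.8, tolerance = 1e-6)
  expect_equal(g2$data, g$data, tolerance = 1e-6)
  # a second round trip through float32 is bit-exact
  write_mrc(g2, tf)
  g3 <- read_mrc(tf)
  expect_identical(g3$data, g2$data)
})

test_that("MRC images round-trip and carry nz = 1", {
  set.seed(2)
  img <- image2d(matrix(rnorm(12^2), 12, 12), pixel_size = 1.8)
  tf <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(img, tf)
  con <- file(tf, "rb")
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  close(con)
  expect_identical(nxyz, c(12L, 12L, 1L))
  back <- read_mrc(tf)
  expect_s3_class(back, "image2d")
  expect_equal(back$data, img$data, tolerance = 1e-6)
  expect_equal(back$pixel_size, 1.8, tolerance = 1e-6)
})

test_that("malformed and unsupported MRC inputs are rejected", {
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), tf)
  expect_error(read_mrc(tf), "malformed")
  # header claiming absurd dimensions
  con <- file(tf, "wb")
  writeBin(as.integer(c(-5, 4, 4, 2)), con, size = 4, endian = "little")
  writeBin(raw(1024 - 16), con)
  close(con)
  expect_error(read_mrc(tf), "malformed")
  # anisotropic voxels: tamper with the cell of a valid file
  g <- voxel_grid(array(runif(4^3), c(4, 4, 4)), 2)
  write_mrc(g, tf)
  con <- file(tf, "r+b")
  seek(con, 40, rw = "write")
  writeBin(as.numeric(c(8, 8, 24)), con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(tf), "anisotropic")
})

test_that("non-cubic volumes are padded on request and rejected otherwise", {
  # write a 4 x 4 x 6 mode-2 file by hand
  tf <- withr::local_tempfile(fileext = ".mrc")
  con <- file(tf, "wb")
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(4, 4, 6)); wi(2); wi(c(0, 0, 0)); wi(c(4, 4, 6))
  wf(c(8, 8, 12)); wf(c(90, 90, 90)); wi(c(1, 2, 3))
  wf(c(0, 1, 0.5)); wi(0); wi(0)
  writeBin(raw(100), con); wf(c(0, 0, 0))
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0.3); wi(0); writeBin(raw(800), con)
  wf(seq_len(4 * 4 * 6))
  close(con)
  g <- read_mrc(tf, pad = TRUE)
  expect_s3_class(g, "voxel_grid")
  expect_identical(dim(g$data), c(6L, 6L, 6L))
  expect_equal(sum(g$data), sum(seq_len(96)))
  expect_error(read_mrc(tf, pad = FALSE), "non-cubic")
})

test_that("PDB parsing honours chain, residue-range and element fallbacks", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(tf)
  m <- read_structure(tf)
  expect_s3_class(m, "atomic_model")
  expect_equal(nrow(m), 6)
  expect_equal(sort(unique(m$chain)), c("A", "B"))
  # iron should get the iron mass, not carbon
  expect_equal(m$weight[m$element == "FE"], 55.845)
  a_only <- read_structure(tf, chain = "A")
  expect_equal(nrow(a_only), 4)
  r1 <- read_structure(tf, residue_range = c(1, 2))
  expect_true(all(r1$resid <= 2))
  expect_error(read_structure(tf, chain = "Z"), "empty")
  # unknown element symbol degrades with a warning
  writeLines(c(
    "ATOM      1  Q1  UNK A   1       0.000   0.000   0.000  1.00  0.00           Q",
    "END"), tf)
  expect_warning(m2 <- read_structure(tf), "unrecognised|unknown")
  expect_equal(nrow(m2), 1)
})

test_that("resolution_at_nyquist_fraction implements 2*apix/fraction", {
  expect_equal(resolution_at_nyquist_fraction(1.8, 0.25), 14.4)
  expect_equal(resolution_at_nyquist_fraction(1.8, 1.0), 3.6)
  expect_equal(resolution_at_nyquist_fraction(1.42, 0.5), 5.68)
  expect_error(resolution_at_nyquist_fraction(1.8, 0), "fraction")
  expect_error(resolution_at_nyquist_fraction(1.8, 1.2), "fraction")
  # monotone decreasing in fraction, linear in pixel size
  fr <- seq(0.1, 1, by = 0.1)
  res <- resolution_at_nyquist_fraction(1.8, fr)
  expect_true(all(diff(res) < 0))
  expect_equal(resolution_at_nyquist_fraction(3.6, fr),
               2 * resolution_at_nyquist_fraction(1.8, fr))
})

test_that("low-pass filter passes DC, kills the stopband, preserves the mean", {
  set.seed(3)
  g <- make_smooth_axisym_phantom(n = 48, vs = 2)
  filt <- low_pass_filter(g, cutoff = 40)
  expect_equal(mean(filt$data), mean(g$data), tolerance = 1e-12)
  # constant input is untouched
  const <- voxel_grid(array(2.5, c(16, 16, 16)), 2)
  expect_equal(low_pass_filter(const, 30)$data, const$data, tolerance = 1e-12)
  # power beyond cutoff + edge is annihilated
  n <- 48
  r <- cyclomap:::freq_radius_3d(n)
  kc <- n * g$voxel_size / 40
  P <- Mod(stats::fft(filt$data))^2
  expect_lt(sum(P[r > kc + 3]) / sum(P), 1e-10)
  # exactly idempotent on content already inside the passband: the 60-A
  # filter's edge ends at 1.6 + 3 Fourier px, below the 20-A filter's
  # passband edge at 4.8 px
  band <- low_pass_filter(g, cutoff = 60)
  again <- low_pass_filter(band, cutoff = 20)
  expect_equal(again$data, band$data, tolerance = 1e-10)
  expect_error(low_pass_filter(g, cutoff = 1), "Nyquist")
})

test_that("flip_hand is an involution, fixes achiral maps, flips chirality", {
  set.seed(4)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 2)
  expect_identical(flip_hand(flip_hand(g))$data, g$data)
  cyl <- soft_cylinder(40, 24, box = 32, voxel_size = 2, edge_width = 8)
  expect_equal(flip_hand(cyl)$data, cyl$data, tolerance = 1e-12)
  # chirality metric on a lock-washer: the signed axial step across the
  # ring opening reverses when x is mirrored
  p <- make_hexamer_phantom(small_hexamer_spec("lockwasher",
                                               opening_angle = 80,
                                               total_rise = 12))
  signed_step <- function(anchors) {
    rg <- ring_geometry(anchors)
    rg$axial_displacements[rg$gap_index[1]] -
      rg$axial_displacements[rg$gap_index[2]]
  }
  mirrored <- p$anchors
  mirrored[, 1] <- -mirrored[, 1]
  expect_equal(signed_step(mirrored), -signed_step(p$anchors),
               tolerance = 1e-9)
  # and the map-level flip matches rendering the mirrored model
  mm <- p$model
  mm$x <- -mm$x
  direct <- model_to_density(mm, p$grid$voxel_size, p$spec$resolution,
                             p$spec$box)
  expect_equal(flip_hand(p$grid)$data, direct$data, tolerance = 1e-9)
})

test_that("constructors enforce the documented invariants", {
  expect_error(voxel_grid(array(0, c(4, 4, 5)), 1), "cubic")
  expect_error(voxel_grid(array(c(NA, rep(0, 63)), c(4, 4, 4)), 1), "finite")
  expect_error(voxel_grid(array(0, c(4, 4, 4)), -1), "positive")
  expect_error(image2d(matrix(0, 3, 4), 1), "square")
  expect_error(atomic_model(character(0), numeric(0), numeric(0), numeric(0)),
               "empty")
  expect_error(atomic_model("C", Inf, 0, 0), "finite")
})
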