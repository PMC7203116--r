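test_that("projection renders atoms as localised density with linear intensity", {
  su <- subunit_model(data.frame(elety = "C", resid = "ALA", resno = 1L,
                                 x = 0, y = 8, z = 0))
  img <- project_model(build_filament(su, wide_sym(), 1),
                       pixel_size = 1, box = c(64L, 64L), blur_sigma = 1.5)
  peak <- which(img$grid == max(img$grid), arr.ind = TRUE)
  # single atom: peak at its (z, y) projection, here the box centre row and
  # centre column + 8 pixels
  expect_lt(abs(peak[1] - 32.5), 1)
  expect_lt(abs(peak[2] - (32.5 + 8)), 1)

  # integrated intensity proportional to atom count
  su5 <- make_toy_subunit(seed = 6, n_atoms = 9, radial_extent = 10,
                          axial_extent = 10)$subunit
  i4 <- project_model(build_filament(su5, wide_sym(), 4), 1, c(128L, 64L))
  i5 <- project_model(build_filament(su5, wide_sym(), 5), 1, c(128L, 64L))
  expect_equal(sum(i5$grid) / sum(i4$grid), 5 / 4, tolerance = 1e-6)

  expect_error(project_model(build_filament(su5, wide_sym(), 50), 1,
                             c(64L, 64L)), "larger")
})

test_that("power spectrum satisfies Parseval and locates pure frequencies", {
  # constant image: all energy at zero frequency
  const <- power_spectrum(matrix(3, 32, 32), window = "none", pixel_size = 1)
  zero <- which(const$grid == max(const$grid), arr.ind = TRUE)
  expect_equal(const$axial_freq[zero[1]], 0)
  expect_equal(const$radial_freq[zero[2]], 0)
  expect_equal(sum(const$grid) - const$grid[zero], 0, tolerance = 1e-20)

  # vertical cosine of period p: peaks at axial frequency +/- 1/p
  n <- 128; p <- 8
  img <- matrix(cos(2 * pi * (0:(n - 1)) / p), n, 32)
  ps <- power_spectrum(img, window = "none", pixel_size = 1)
  top2 <- order(apply(ps$grid, 1, max), decreasing = TRUE)[1:2]
  expect_equal(sort(ps$axial_freq[top2]), c(-1 / p, 1 / p))

  # Parseval with the window applied
  ps2 <- power_spectrum(project_model(
    build_filament(make_toy_subunit(seed = 8, n_atoms = 10)$subunit,
                   wide_sym(), 8), 1, c(256L, 128L)))
  expect_equal(sum(ps2$grid), ps2$window_energy, tolerance = 1e-6)
})

test_that("layer-line detection finds the meridional at the rise", {
  gen <- make_filament_image(wide_sym(), n_subunits = 40, seed = 21,
                             box = c(512L, 128L))
  ps <- power_spectrum(gen$image)
  ll <- detect_layer_lines(ps)
  mer <- ll[ll$is_meridional & ll$axial_spacing < 15, , drop = FALSE]
  expect_gte(nrow(mer), 1L)
  # within one Fourier sample of the true rise
  f_true <- 1 / 9.33
  df <- 1 / (512 * 1)
  expect_lt(min(abs(1 / mer$axial_spacing - f_true)), df + 1e-12)

  # narrow form: off-meridional (or near-meridional order-1) line at ~48.1
  genn <- make_filament_image(narrow_sym(), n_subunits = 40, seed = 22,
                              box = c(512L, 128L))
  lln <- detect_layer_lines(power_spectrum(genn$image))
  expect_lt(min(abs(1 / lln$axial_spacing - 1 / 48.1)), df + 1e-12)

  # atoms on the axis: a featureless rod has no layer lines between the
  # equator and the meridional
  rod <- subunit_model(data.frame(elety = "C", resid = "ALA", resno = 1L,
                                  x = 0, y = 0, z = 0))
  psr <- power_spectrum(project_model(build_filament(rod, wide_sym(), 40),
                                      1, c(512L, 64L)))
  llr <- detect_layer_lines(psr)
  expect_false(any(!llr$is_meridional & llr$axial_spacing > 15))
})

test_that("spectrum amplitudes are invariant to axial shifts and handedness", {
  su <- make_toy_subunit(seed = 9, n_atoms = 12)$subunit
  f <- build_filament(su, wide_sym(), 30)
  shifted <- f
  shifted$atoms$z <- shifted$atoms$z + 3.7
  ps1 <- power_spectrum(project_model(f, 1, c(512L, 128L)))
  ps2 <- power_spectrum(project_model(shifted, 1, c(512L, 128L)))
  # projection recentres the filament, so the spectra agree closely; compare
  # on the log scale used for scoring
  expect_gt(cor(as.vector(log1p(sqrt(ps1$grid))),
                as.vector(log1p(sqrt(ps2$grid)))), 0.99)

  # handedness ambiguity: the enantiomer (mirrored subunit, flipped twist)
  # projects to the column-mirror image, so its amplitude spectrum carries
  # exactly the same values — power spectra cannot determine the hand
  su_m <- su
  su_m$atoms$y <- -su_m$atoms$y
  left <- build_filament(su_m, helical_symmetry(9.33, 92.5, handedness = -1),
                         30)
  psl <- power_spectrum(project_model(left, 1, c(512L, 128L)))
  expect_equal(sort(as.vector(psl$grid)), sort(as.vector(ps1$grid)),
               tolerance = 1e-9)
})

test_that("candidate scoring favours the true lattice", {
  gen <- make_filament_image(wide_sym(), n_subunits = 40, seed = 23,
                             box = c(512L, 128L))
  ps <- power_spectrum(gen$image)
  truth <- lattice_estimate(36.31135, 3.891892)
  s_truth <- score_candidate(ps, truth, gen$subunit)$score
  expect_gt(s_truth, 0.9)  # near-self comparison
  for (upt in c(3.84, 3.95, 4.10)) {  # wrong by >= 0.05 units/turn
    s_wrong <- score_candidate(ps, lattice_estimate(36.31135, upt),
                               gen$subunit)$score
    expect_gt(s_truth, s_wrong)
  }
  # half the true pitch scores lower
  s_half <- score_candidate(ps, lattice_estimate(36.31135 / 2, 3.891892),
                            gen$subunit)$score
  expect_gt(s_truth, s_half)
})

test_that("image files round-trip through MRC and TSV", {
  img <- make_filament_image(wide_sym(), n_subunits = 10, seed = 31,
                             box = c(192L, 96L))$image
  mrc <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(img, mrc)
  back <- read_mrc(mrc)
  expect_equal(dim(back$grid), dim(img$grid))
  expect_equal(back$pixel_size, img$pixel_size)
  expect_lt(max(abs(back$grid - img$grid)), 1e-5)  # float32 storage

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_image_tsv(img, tsv)
  back2 <- read_image_tsv(tsv)
  expect_equal(back2$grid, img$grid, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(dim(read_image(mrc)$grid), dim(img$grid))
})
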