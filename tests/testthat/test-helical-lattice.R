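test_that("lattice-to-symmetry conversion reproduces published filament parameters", {
  wide <- symmetry_from_lattice(lattice_estimate(36.3, 3.89))
  expect_equal(round(wide$rise, 2), 9.33)
  expect_equal(round(wide$twist, 1), 92.5)

  narrow <- symmetry_from_lattice(lattice_estimate(48.1, 4.27))
  expect_equal(round(narrow$rise, 2), 11.26)
  expect_equal(round(narrow$twist, 1), 84.3)

  integer_case <- symmetry_from_lattice(lattice_estimate(10.0, 4.0))
  expect_equal(integer_case$rise, 2.5)
  expect_equal(integer_case$twist, 90.0)

  expect_error(lattice_estimate(-1, 4), "positive")
  expect_error(lattice_estimate(10, 0.5), "> 1")
})

test_that("symmetry and lattice conversions are exact inverses", {
  lat <- lattice_from_symmetry(helical_symmetry(2.5, 90))
  expect_equal(lat$pitch, 10.0)
  expect_equal(lat$units_per_turn, 4.0)

  lat2 <- lattice_from_symmetry(helical_symmetry(9.33, 92.5))
  expect_equal(lat2$pitch, 36.31135, tolerance = 1e-6)
  expect_equal(lat2$units_per_turn, 3.891892, tolerance = 1e-6)

  set.seed(42)
  for (i in 1:100) {
    s <- helical_symmetry(runif(1, 1, 30), runif(1, 10, 180))
    s2 <- symmetry_from_lattice(lattice_from_symmetry(s))
    expect_equal(s2$rise, s$rise, tolerance = 1e-9)
    expect_equal(s2$twist, s$twist, tolerance = 1e-9)
  }
})

test_that("subunits per turn follows from meridional and pitch spacings", {
  expect_equal(units_per_turn_from_spacings(9, 36), 4.0)
  expect_equal(round(units_per_turn_from_spacings(11.3, 48.1), 2), 4.26)
  expect_equal(round(360 / units_per_turn_from_spacings(11.3, 48.1), 1), 84.6)
  for (s in c(5, 9.33, 48.1))
    expect_equal(units_per_turn_from_spacings(s, s), 1.0)
  expect_warning(units_per_turn_from_spacings(36, 9), "cannot lie beyond")
  expect_error(units_per_turn_from_spacings(-3, 10), "positive")
})

test_that("rational repeat search matches an exhaustive sweep", {
  r <- best_rational_repeat(3.89, 20)
  expect_equal(c(r$subunits, r$turns), c(35L, 9L))  # repeats after 9 turns
  expect_identical(c(r$subunits, r$turns), brute_force_repeat(3.89, 20))

  r2 <- best_rational_repeat(4.27, 20)
  expect_equal(c(r2$subunits, r2$turns), c(47L, 11L))
  expect_identical(c(r2$subunits, r2$turns), brute_force_repeat(4.27, 20))

  expect_equal(unlist(best_rational_repeat(4.0, 20)[c("subunits", "turns")]),
               c(subunits = 4L, turns = 1L))

  # exact rationals round-trip for coprime u/t
  set.seed(7)
  for (i in 1:40) {
    t <- sample(1:15, 1)
    u <- sample((t + 1):(5 * t), 1)
    g <- pilihelix:::gcd(u, t)
    u <- u / g; t <- t / g
    if (u / t <= 1) next
    r <- best_rational_repeat(u / t, max_turns = 20)
    expect_equal(c(r$subunits, r$turns), c(u, t))
  }
  expect_error(best_rational_repeat(3.89, 0), "max_turns")
})

test_that("selection rule identifies allowed Bessel orders", {
  r <- best_rational_repeat(3.89, 20)  # (35, 9)
  expect_identical(allowed_bessel_orders(9, r, 1), 1L)   # order-1 pitch line
  expect_identical(allowed_bessel_orders(0, r, 0), 0L)   # equator
  expect_true(0L %in% allowed_bessel_orders(35, r, 1))   # meridional, m = 1

  # agree with direct enumeration over a spread of layer lines
  for (l in c(0:12, 26, 35, 44, 70))
    for (mm in 0:3)
      expect_identical(allowed_bessel_orders(l, r, mm),
                       brute_force_bessel(l, 35, 9, mm))

  # for any repeat: l = 0 gives order 0, l = t gives order 1
  set.seed(11)
  for (i in 1:20) {
    t <- sample(1:12, 1)
    u <- t * sample(2:5, 1) + sample(1:max(1, t - 1), 1)
    if (pilihelix:::gcd(u, t) != 1) next
    rs <- structure(list(subunits = u, turns = t), class = "repeat_solution")
    expect_identical(allowed_bessel_orders(0, rs, 0), 0L)
    expect_identical(allowed_bessel_orders(t, rs, 0), 1L)
  }
})

test_that("layer-line spacings are consistent with rise and pitch", {
  r <- best_rational_repeat(3.89, 20)
  expect_equal(layer_line_spacing(35, r, 9.33), 9.33)      # meridional = rise
  expect_equal(layer_line_spacing(9, r, 9.33), 35 * 9.33 / 9)
  r41 <- best_rational_repeat(4.0, 20)
  expect_equal(layer_line_spacing(1, r41, 2.5), 10.0)      # integer-helix pitch
  # the l = t line sits at the pitch implied by rise and twist
  for (upt in c(3.89, 4.27, 4.0)) {
    rr <- best_rational_repeat(upt, 20)
    rise <- 5.5
    expect_equal(layer_line_spacing(rr$turns, rr, rise),
                 rise * rr$subunits / rr$turns)
  }
  expect_error(layer_line_spacing(0, r, 9.33), "equator")
})

test_that("candidate grids cover the published candidate sets", {
  g <- enumerate_symmetry_candidates(36.3, c(3.5, 4.5), 0.01)
  expect_equal(nrow(g), 101L)
  for (v in c(3.89, 4.10))
    expect_true(any(abs(g$units_per_turn - v) < 1e-9))

  g2 <- enumerate_symmetry_candidates(48.1, c(4.0, 4.5), 0.01)
  for (v in c(4.11, 4.14, 4.27, 4.30))
    expect_true(any(abs(g2$units_per_turn - v) < 1e-9))

  expect_equal(nrow(enumerate_symmetry_candidates(36.3, c(4.0, 4.0), 0.01)),
               1L)
  expect_error(enumerate_symmetry_candidates(36.3, c(4.5, 3.5), 0.01),
               "empty")
})

test_that("asymmetric-unit bookkeeping is multiplicative in segments", {
  expect_equal(asymmetric_units(65656, 27.99, 9.33), 196968L)
  expect_equal(asymmetric_units(51301, 33.78, 11.26), 153903L)
  for (r in c(2.5, 9.33, 11.26)) expect_equal(asymmetric_units(1, r, r), 1L)
  # linear in n_segments
  for (n in c(10, 100, 1000))
    expect_equal(asymmetric_units(n, 27.99, 9.33),
                 n * asymmetric_units(1, 27.99, 9.33))
  expect_error(asymmetric_units(100, 25, 9.33), "integer multiple")
})
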