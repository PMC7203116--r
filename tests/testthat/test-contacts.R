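test_that("interaction partners match the engineered contact offsets", {
  fx <- make_contact_fixture(c(1, 3), wide_sym(), n = 16)
  im <- interaction_partners(fx$filament)
  expect_setequal(as.integer(names(im$partners)), c(-3, -1, 1, 3))
  expect_equal(im$per_direction, 2L)

  # empty offset set: radially separated subunits never touch
  fx0 <- make_contact_fixture(integer(0), wide_sym(), n = 8)
  expect_length(interaction_partners(fx0$filament)$partners, 0L)

  # wide-pilus analogue: 6 partners per direction, +5 absent
  fx6 <- make_contact_fixture(c(1, 2, 3, 4, 6, 7), wide_sym(), n = 16)
  im6 <- interaction_partners(fx6$filament)
  expect_equal(im6$per_direction, 6L)
  expect_setequal(as.integer(names(im6$partners)),
                  c(-7, -6, -4, -3, -2, -1, 1, 2, 3, 4, 6, 7))
  expect_false("5" %in% names(im6$partners))

  # interior maps are symmetric: +k present iff -k present
  off <- as.integer(names(im6$partners))
  expect_setequal(off, -off)

  # end-proximity guard
  expect_error(interaction_partners(fx6$filament, center = 1,
                                    max_offset = 7), "filament end")
})

test_that("interaction map is invariant under the screw symmetry", {
  fx <- make_contact_fixture(c(1, 2, 4), wide_sym(), n = 14)
  maps <- lapply(5:8, function(ctr)
    interaction_partners(fx$filament, center = ctr))
  for (m in maps[-1]) {
    expect_identical(names(m$partners), names(maps[[1]]$partners))
    expect_identical(unname(m$partners), unname(maps[[1]]$partners))
  }
})

test_that("pruned pair counting agrees exactly with the all-pairs oracle", {
  set.seed(19)
  for (i in 1:10) {
    a <- matrix(runif(3 * sample(20:80, 1), -30, 30), ncol = 3)
    b <- matrix(runif(3 * sample(20:80, 1), -30, 30), ncol = 3)
    cutoff <- runif(1, 2, 25)
    expect_identical(pilihelix:::count_close_pairs(a, b, cutoff),
                     pilihelix:::count_close_pairs_brute(a, b, cutoff))
  }
  # and on a real fixture across all subunit pairs
  fil <- make_contact_fixture(c(1, 3), wide_sym(), n = 10)$filament
  for (j in 1:9) {
    a <- as.matrix(fil$atoms[fil$atoms$subunit == 0, c("x", "y", "z")])
    b <- as.matrix(fil$atoms[fil$atoms$subunit == j, c("x", "y", "z")])
    expect_identical(pilihelix:::count_close_pairs(a, b, 4.5),
                     pilihelix:::count_close_pairs_brute(a, b, 4.5))
  }
})

test_that("salt-bridge detection respects the distance cutoff and monotonicity", {
  sym <- wide_sym()
  # acidic and basic probes engineered 3.0 A apart across offset +3
  base <- make_contact_fixture(c(3), sym, n = 12)$filament$subunit$atoms
  p <- c(25, 0, 1)
  q <- drop(pilihelix:::screw_transform(matrix(p, 1), sym, 3L))
  u <- c(q[1], q[2], 0) / sqrt(q[1]^2 + q[2]^2)
  probes <- data.frame(
    elety = c("NZ", "OD1"), resid = c("LYS", "ASP"), resno = c(9L, 80L),
    x = c(p[1], (q + 3 * u)[1]), y = c(p[2], (q + 3 * u)[2]),
    z = c(p[3], (q + 3 * u)[3]), charge_class = c("basic", "acidic"))
  su <- subunit_model(rbind(base, probes))
  fil <- build_filament(su, sym, 12)
  br <- find_salt_bridges(fil)
  inter <- br[br$kind == "intermolecular", ]
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$offset, 3L)  # basic partner sits 3 subunits above
  expect_equal(inter$distance, 3.0, tolerance = 1e-9)
  expect_equal(inter$acid_resno, 80L)
  expect_equal(inter$basic_resno, 9L)

  # same probes 10 A apart: nothing under the 4 A cutoff
  probes10 <- probes
  far <- q + 10 * u
  probes10[2, c("x", "y", "z")] <- far
  fil10 <- build_filament(subunit_model(rbind(base, probes10)), sym, 12)
  expect_equal(nrow(find_salt_bridges(fil10)), 0L)

  # monotonicity: every bridge at cutoff c is present at any cutoff >= c
  pil <- make_synthetic_pilin("wide")$filament
  for (c1 in c(3.2, 3.6, 4.0)) {
    b1 <- find_salt_bridges(pil, contact_settings(salt_bridge_cutoff = c1))
    b2 <- find_salt_bridges(pil, contact_settings(salt_bridge_cutoff = c1 + 0.5))
    key <- function(d) paste(d$acid_resno, d$basic_resno, d$kind, d$offset)
    expect_true(all(key(b1) %in% key(b2)))
  }

  # no charged atoms at all: empty result
  neutral <- make_contact_fixture(c(1), sym, n = 6)$filament
  expect_equal(nrow(find_salt_bridges(neutral)), 0L)
})

test_that("synthetic pilin stand-ins reproduce the published interaction topology", {
  wide <- make_synthetic_pilin("wide")
  imw <- interaction_partners(wide$filament)
  expect_equal(imw$per_direction, 6L)

  br <- find_salt_bridges(wide$filament)
  inter <- br[br$kind == "intermolecular", ]
  # Asp53-Arg30 across +3 and Glu48-Arg28 across +4 (acid -> base offsets)
  expect_true(any(inter$acid_resno == 53 & inter$basic_resno == 30 &
                  abs(inter$offset) == 3))
  expect_true(any(inter$acid_resno == 48 & inter$basic_resno == 28 &
                  abs(inter$offset) == 4))
  intra <- br[br$kind == "intramolecular", ]
  expect_true(any(intra$acid_resno == 42 & intra$basic_resno == 45))
  expect_true(any(intra$acid_resno == 125 & intra$basic_resno == 107))

  narrow <- make_synthetic_pilin("narrow")
  expect_equal(interaction_partners(narrow$filament)$per_direction, 7L)
  brn <- find_salt_bridges(narrow$filament)
  expect_true(any(brn$acid_resno == 68 & brn$basic_resno == 23 &
                  abs(brn$offset) == 3))

  # Glu5 is the nearest acidic group to every subunit's own N-terminus
  for (fil in list(wide$filament, narrow$filament)) {
    nt <- nearest_acidic_to_nterm(fil)
    expect_true(all(nt$acid_resid == "GLU" & nt$acid_resno == 5))
    expect_true(all(nt$intramolecular))
  }
})

test_that("nearest-acidic search picks the closer probe and handles none", {
  sym <- wide_sym()
  base <- data.frame(elety = c("N", "OE1", "OD1"),
                     resid = c("PHE", "GLU", "ASP"),
                     resno = c(1L, 5L, 40L),
                     x = c(20, 20, 20), y = c(0, 0, 0), z = c(0, 4, 8),
                     charge_class = c("n_terminus", "acidic", "acidic"))
  fil <- build_filament(subunit_model(base), sym, 4)
  nt <- nearest_acidic_to_nterm(fil)
  expect_true(all(nt$acid_resno == 5))
  expect_equal(nt$distance, rep(4, 4))

  gly <- data.frame(elety = c("N", "CA"), resid = "GLY", resno = c(1L, 1L),
                    x = c(15, 16), y = 0, z = c(0, 1))
  filg <- build_filament(subunit_model(gly), sym, 3)
  # glycine-only filament (termini present but no acidic side chains other
  # than the C-terminal carboxylate, absent here): explicit NA result
  filg$atoms$charge_class[filg$atoms$charge_class == "c_terminus"] <- "neutral"
  ntg <- nearest_acidic_to_nterm(filg)
  expect_true(all(is.na(ntg$acid_resno)))
})

test_that("net formal charge counts acidic and basic residues", {
  expect_equal(net_formal_charge("GGGG"), 0L)
  expect_equal(net_formal_charge("DKDE"), -2L)  # -3 acids, +1 Lys, termini cancel
  expect_equal(net_formal_charge("DKDE", termini = "neutral"), -2L)
  expect_equal(net_formal_charge("HHHH"), 0L)  # His neutral
  # synthetic analogues of the two pilins' stated net charges
  balanced <- paste0(strrep("G", 50), "DDKK", strrep("A", 20))
  expect_equal(net_formal_charge(balanced), 0L)
  minus2 <- paste0(strrep("G", 50), "DDDDKK", strrep("A", 20))
  expect_equal(net_formal_charge(minus2), -2L)
  expect_error(net_formal_charge("GGXG"), "position")
})
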