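# Seeded generators for every input the pipeline consumes. Each generator is
# a pure function of its parameter record (seed included) and returns the
# object together with a machine-readable ground-truth record.

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards: generators never touch process-global
# randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth record of a synthetic input
#'
#' @param kind One of "subunit", "filament", "image", "traces".
#' @param parameters Full generator settings, seed included; regeneration
#'   from this record is bit-identical.
#' @param expected Truth values (symmetry, contact offsets, bridge list,
#'   fraction above threshold, ...).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kind, parameters, expected) {
  stopifnot(kind %in% c("subunit", "filament", "image", "traces"))
  structure(list(kind = kind, parameters = parameters, expected = expected),
            class = "ground_truth")
}

#' Serialize / restore a ground-truth record
#'
#' @param truth A [ground_truth()] object.
#' @param path JSON file path.
#' @return `read_ground_truth` returns the restored `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$kind, x$parameters, x$expected)
}

#' Generate a toy pilin-like subunit
#'
#' An asymmetric random point cloud emulating an elongated pilin subunit:
#' atoms spread over `axial_extent` Angstrom along z and out to exactly
#' `radial_extent` from the axis (so a filament built from it has diameter
#' 2 x radial_extent, emulating a ~70 Angstrom wide pilus at the default 35).
#' Optional charged probe atoms are placed at requested positions with their
#' charge class set explicitly.
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param n_atoms Number of body atoms (>= 3).
#' @param radial_extent Maximum atom radius from the z axis, Angstrom.
#' @param axial_extent Axial span of the subunit, Angstrom.
#' @param charged_probes Optional data.frame with columns `resid`, `resno`,
#'   `elety`, `charge_class`, `x`, `y`, `z` appended as probe atoms.
#' @return List: `subunit` (a [subunit_model()]), `truth` (a
#'   [ground_truth()]).
#' @export
make_toy_subunit <- function(seed = 1L, n_atoms = 40L, radial_extent = 35,
                             axial_extent = 45, charged_probes = NULL) {
  if (n_atoms < 3L) stop("`n_atoms` must be >= 3")
  if (radial_extent <= 0) stop("`radial_extent` must be positive")
  atoms <- with_seed(seed, {
    r <- stats::runif(n_atoms, 0.05, 1)
    r <- r * (radial_extent / max(r))  # max radius exactly radial_extent
    phi <- stats::runif(n_atoms, 0, 2 * pi)
    z <- stats::runif(n_atoms, 0, axial_extent)
    data.frame(elety = "C", resid = "ALA", resno = seq_len(n_atoms),
               x = r * cos(phi), y = r * sin(phi), z = z,
               charge_class = "neutral", stringsAsFactors = FALSE)
  })
  if (!is.null(charged_probes)) {
    probes <- charged_probes[, c("elety", "resid", "resno", "x", "y", "z",
                                 "charge_class")]
    probes$elety <- as.character(probes$elety)
    atoms <- rbind(atoms, probes)
  }
  su <- subunit_model(atoms, label = sprintf("toy-subunit-seed%d", seed))
  truth <- ground_truth("subunit",
                        parameters = list(seed = seed, n_atoms = n_atoms,
                                          radial_extent = radial_extent,
                                          axial_extent = axial_extent),
                        expected = list(diameter = 2 * radial_extent,
                                        n_atoms = nrow(atoms)))
  list(subunit = su, truth = truth)
}

#' Generate a filament with contacts at chosen subunit offsets
#'
#' Engineers a subunit from hook/arm atom pairs so that, after symmetry
#' expansion, heavy-atom contacts exist exactly at the requested signed
#' offsets under `contact_distance` (placed just inside the default 4.5
#' Angstrom interaction cutoff). Construction: for each offset k the subunit
#' carries a hook atom at an anchor point p_k and an arm atom at the k-th
#' screw image of p_k displaced radially by `contact_distance`, so every
#' subunit pair (i, i + k) touches through exactly that hook/arm pair.
#' The realised contact set is verified internally by brute-force all-pairs
#' distances and the generator errors if it differs from the request.
#'
#' @param offsets Set of positive integer offsets where contacts must exist;
#'   empty set gives a contact-free filament.
#' @param sym A [helical_symmetry()].
#' @param n Number of subunits (default 16).
#' @param contact_distance Engineered hook-arm distance, Angstrom (default
#'   4.0).
#' @param base_radius Anchor radius, Angstrom (default 20).
#' @param cutoff Cutoff used for the internal verification (default 4.5).
#' @return List: `filament`, `truth`.
#' @export
make_contact_fixture <- function(offsets, sym, n = 16L,
                                 contact_distance = 4.0, base_radius = 20,
                                 cutoff = 4.5) {
  offsets <- sort(unique(as.integer(offsets)))
  if (length(offsets) > 0 && any(offsets < 1L))
    stop("`offsets` must be positive integers")
  golden <- 137.50776405003785  # degrees; spreads anchors azimuthally
  atoms <- if (length(offsets) == 0L) {
    data.frame(elety = "C", resid = "ALA", resno = 1L,
               x = base_radius, y = 0, z = 0, charge_class = "neutral",
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_along(offsets), function(i) {
      k <- offsets[i]
      phi <- (i - 1) * golden * pi / 180
      p <- c(base_radius * cos(phi), base_radius * sin(phi),
             (i - 1) * 0.9)
      q <- drop(screw_transform(matrix(p, 1), sym, k))
      u <- c(q[1], q[2], 0) / sqrt(q[1]^2 + q[2]^2)  # outward radial
      a <- q + contact_distance * u
      data.frame(elety = c("C", "C"), resid = "ALA",
                 resno = c(2L * i - 1L, 2L * i),
                 x = c(p[1], a[1]), y = c(p[2], a[2]), z = c(p[3], a[3]),
                 charge_class = "neutral", stringsAsFactors = FALSE)
    }))
  }
  su <- subunit_model(atoms, label = sprintf("contact-fixture-%s",
                                             paste(offsets, collapse = "+")))
  fil <- build_filament(su, sym, n)
  realized <- brute_force_offsets(fil, cutoff)
  if (!identical(realized, offsets))
    stop("infeasible offset set for this symmetry: requested {",
         paste(offsets, collapse = ","), "} but construction realises {",
         paste(realized, collapse = ","), "}")
  truth <- ground_truth("filament",
                        parameters = list(offsets = offsets,
                                          rise = sym$rise, twist = sym$twist,
                                          n = n,
                                          contact_distance = contact_distance,
                                          base_radius = base_radius,
                                          cutoff = cutoff),
                        expected = list(offsets = offsets,
                                        partners_per_direction =
                                          length(offsets)))
  list(filament = fil, truth = truth)
}

# Offsets (positive) at which any two subunits of the central portion of the
# filament share at least one atom pair within `cutoff`; plain all-pairs.
brute_force_offsets <- function(fil, cutoff) {
  subs <- sort(unique(fil$atoms$subunit))
  center <- subs[ceiling(length(subs) / 2)]
  a <- as.matrix(fil$atoms[fil$atoms$subunit == center, c("x", "y", "z")])
  hits <- integer(0)
  for (j in setdiff(subs, center)) {
    b <- as.matrix(fil$atoms[fil$atoms$subunit == j, c("x", "y", "z")])
    if (count_close_pairs_brute(a, b, cutoff) >= 1L)
      hits <- c(hits, j - center)
  }
  sort(unique(abs(hits)))
}

#' Generate a noisy projection image of a known filament
#'
#' Builds a toy-subunit filament with the given symmetry, projects it, and
#' adds seeded white Gaussian noise — emulating a boxed, straight filament
#' segment. The noise level can be set directly (`noise_sigma`) or through a
#' signal-to-noise ratio `snr` = sd(noise-free image) / noise sigma.
#'
#' @param sym A [helical_symmetry()].
#' @param n_subunits Number of subunits (default 60).
#' @param noise_sigma Additive Gaussian noise sd (default 0).
#' @param snr If given, overrides `noise_sigma`.
#' @param seed Integer seed controlling subunit generation and noise.
#' @param pixel_size,box,blur_sigma Projection geometry (see
#'   [project_model()]).
#' @param subunit Optional explicit subunit; default is
#'   `make_toy_subunit(seed)`.
#' @return List: `image` (projection_image), `subunit`, `truth`.
#' @export
make_filament_image <- function(sym, n_subunits = 60L, noise_sigma = 0,
                                snr = NULL, seed = 1L, pixel_size = 1.0,
                                box = c(1024L, 128L), blur_sigma = 1.5,
                                subunit = NULL) {
  if (is.null(subunit)) subunit <- make_toy_subunit(seed)$subunit
  fil <- build_filament(subunit, sym, n_subunits)
  img <- project_model(fil, pixel_size = pixel_size, box = box,
                       blur_sigma = blur_sigma)
  if (!is.null(snr)) noise_sigma <- stats::sd(as.vector(img$grid)) / snr
  if (noise_sigma > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(img$grid),
                                                 sd = noise_sigma),
                                    nrow(img$grid)))
    img$grid <- img$grid + noise
  }
  truth <- ground_truth("image",
                        parameters = list(rise = sym$rise, twist = sym$twist,
                                          n_subunits = n_subunits,
                                          noise_sigma = noise_sigma,
                                          seed = seed,
                                          pixel_size = pixel_size,
                                          box = as.integer(box),
                                          blur_sigma = blur_sigma),
                        expected = list(rise = sym$rise, twist = sym$twist,
                                        pitch = pitch(sym),
                                        units_per_turn = units_per_turn(sym)))
  list(image = img, subunit = subunit, truth = truth)
}

#' Generate a trace population with a stated curvature mixture
#'
#' Exactly `round(n * fraction_high)` traces are constant-curvature circular
#' arcs with curvature drawn above the threshold (from `kappa_high`), the
#' rest below (from `kappa_low`); arc lengths are uniform in `length_range`
#' and each arc is randomly rotated and translated. At zero point noise,
#' [classify_population()] recovers `fraction_high` exactly.
#'
#' @param n Number of traces.
#' @param fraction_high Fraction of high-curvature traces in [0, 1].
#' @param kappa_low,kappa_high Curvature ranges (1/um) strictly below/above
#'   `threshold`.
#' @param length_range Arc length range, um.
#' @param threshold Classification threshold, 1/um (default 2).
#' @param point_spacing Sampling interval along the arc, um (default 0.02).
#' @param noise_sd Gaussian point noise sd, um (default 0).
#' @param seed Integer seed.
#' @param label Label given to every trace.
#' @return List: `traces` (list of [filament_trace()]), `truth`.
#' @export
make_trace_population <- function(n = 100L, fraction_high = 0.4,
                                  kappa_low = c(0.2, 1.5),
                                  kappa_high = c(2.5, 6),
                                  length_range = c(1, 3), threshold = 2,
                                  point_spacing = 0.02, noise_sd = 0,
                                  seed = 1L, label = "unknown") {
  if (fraction_high < 0 || fraction_high > 1)
    stop("`fraction_high` must be in [0, 1]")
  if (max(kappa_low) >= threshold)
    stop("`kappa_low` must lie strictly below the threshold")
  if (length(kappa_high) && min(kappa_high) <= threshold)
    stop("`kappa_high` must lie strictly above the threshold")
  n_high <- round(n * fraction_high)
  out <- with_seed(seed, {
    is_high <- sample(rep(c(TRUE, FALSE), c(n_high, n - n_high)))
    kappa <- ifelse(is_high,
                    stats::runif(n, kappa_high[1], kappa_high[2]),
                    stats::runif(n, kappa_low[1], kappa_low[2]))
    traces <- lapply(seq_len(n), function(i) {
      R <- 1 / kappa[i]
      L <- stats::runif(1, length_range[1], length_range[2])
      L <- min(L, (300 / 360) * 2 * pi * R)  # avoid self-overlapping arcs
      theta <- seq(0, L / R, by = point_spacing / R)
      pts <- cbind(R * cos(theta), R * sin(theta))
      rot <- stats::runif(1, 0, 2 * pi)
      Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
      pts <- pts %*% Rm
      pts <- sweep(pts, 2, stats::runif(2, -5, 5), `+`)
      if (noise_sd > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                            ncol = 2)
      filament_trace(pts, label = label, id = i)
    })
    list(traces = traces, is_high = is_high, kappa = kappa)
  })
  truth <- ground_truth("traces",
                        parameters = list(n = n,
                                          fraction_high = fraction_high,
                                          kappa_low = kappa_low,
                                          kappa_high = kappa_high,
                                          length_range = length_range,
                                          threshold = threshold,
                                          point_spacing = point_spacing,
                                          noise_sd = noise_sd, seed = seed,
                                          label = label),
                        expected = list(fraction_high = n_high / n,
                                        is_high = out$is_high,
                                        kappa = out$kappa))
  list(traces = out$traces, truth = truth)
}

#' Synthetic pilin filament stand-ins for the wide and narrow pili
#'
#' Constructed analogues (not the deposited structures) of the two
#' filament forms, for exercising the contact and salt-bridge analysis at
#' the published parameter values. The wide form uses the wide-pilus
#' symmetry (rise 9.33 Angstrom, twist 92.5 degrees) with contacts
#' engineered at offsets {1, 2, 3, 4, 6, 7} — six partners per direction,
#' +5 absent — and the narrow form the narrow-pilus symmetry (11.26 / 84.3)
#' with contacts at {1, ..., 7} — seven per direction. Charged probe
#' residues reproduce the published salt-bridge topology: for the wide form
#' intermolecular Asp53-Arg30 at offset +3 and Glu48-Arg28 at +4, and
#' intramolecular Asp42-Lys45 and Lys107-C-terminus (Pro125); for the
#' narrow form intermolecular Glu68-Arg23 at +3 and intramolecular
#' Asp37-Arg104 and Asp81-Arg99. In both, a Glu5 carboxylate is placed as
#' the nearest acidic group to the subunit's own N-terminal amine (Phe1).
#'
#' These are labelled synthetic throughout: geometry is engineered, only the
#' interaction topology mimics the real filaments.
#'
#' @param form "wide" or "narrow".
#' @param n Number of subunits (default 16).
#' @return List: `filament`, `truth`.
#' @export
make_synthetic_pilin <- function(form = c("wide", "narrow"), n = 16L) {
  form <- match.arg(form)
  if (form == "wide") {
    sym <- helical_symmetry(9.33, 92.5)
    offsets <- c(1L, 2L, 3L, 4L, 6L, 7L)
    inter <- list(list(acid = c("ASP", 53L, "OD1"),
                       base = c("ARG", 30L, "NH1"), offset = 3L, d = 3.0),
                  list(acid = c("GLU", 48L, "OE1"),
                       base = c("ARG", 28L, "NH2"), offset = 4L, d = 3.2))
    intra <- list(list(acid = c("ASP", 42L, "OD1"),
                       base = c("LYS", 45L, "NZ"), d = 3.1),
                  list(acid = c("PRO", 125L, "OXT"),
                       base = c("LYS", 107L, "NZ"), d = 3.0))
    last_resno <- 125L
  } else {
    sym <- helical_symmetry(11.26, 84.3)
    offsets <- 1L:7L
    inter <- list(list(acid = c("GLU", 68L, "OE1"),
                       base = c("ARG", 23L, "NH1"), offset = 3L, d = 3.1))
    intra <- list(list(acid = c("ASP", 37L, "OD1"),
                       base = c("ARG", 104L, "NH2"), d = 3.2),
                  list(acid = c("ASP", 81L, "OD2"),
                       base = c("ARG", 99L, "NE"), d = 3.3))
    last_resno <- 111L
  }
  fx <- make_contact_fixture(offsets, sym, n)
  base_atoms <- fx$filament$subunit$atoms
  probes <- list()
  radius <- 30  # anchor probe pairs outside the contact scaffold
  slot <- 0
  place <- function(resid, resno, elety, cls, pos) {
    data.frame(elety = elety, resid = resid, resno = as.integer(resno),
               x = pos[1], y = pos[2], z = pos[3], charge_class = cls,
               stringsAsFactors = FALSE)
  }
  next_anchor <- function() {
    slot <<- slot + 1
    phi <- (slot * 71 + 13) * pi / 180
    c(radius * cos(phi), radius * sin(phi), 2.1 * slot)
  }
  # intermolecular bridges: basic probe at p in each subunit; the acidic
  # probe of subunit i is placed `d` away (radially) from the basic probe's
  # image in subunit i + offset, so acid(A)-base(A+offset) bridges exist
  for (b in inter) {
    p <- next_anchor()
    q <- drop(screw_transform(matrix(p, 1), sym, as.integer(b$offset)))
    u <- c(q[1], q[2], 0) / sqrt(q[1]^2 + q[2]^2)
    a_pos <- q + b$d * u
    probes <- c(probes,
                list(place(b$base[1], b$base[2], b$base[3], "basic", p),
                     place(b$acid[1], b$acid[2], b$acid[3], "acidic", a_pos)))
  }
  # intramolecular bridges: both probes in the same subunit, d apart
  for (b in intra) {
    p <- next_anchor()
    cls <- if (b$acid[3] == "OXT") "c_terminus" else "acidic"
    probes <- c(probes,
                list(place(b$base[1], b$base[2], b$base[3], "basic", p),
                     place(b$acid[1], b$acid[2], b$acid[3], cls,
                           p + c(0, 0, b$d))))
  }
  # N-terminal amine (Phe1) with Glu5 as its nearest acidic neighbour
  p <- next_anchor()
  probes <- c(probes,
              list(place("PHE", 1L, "N", "n_terminus", p),
                   place("GLU", 5L, "OE2", "acidic", p + c(0, 0, 3.4))))
  atoms <- rbind(base_atoms, do.call(rbind, probes))
  su <- subunit_model(atoms, label = sprintf("synthetic-%s-pilin", form))
  fil <- build_filament(su, sym, n)
  realized <- brute_force_offsets(fil, 4.5)
  if (!identical(realized, offsets))
    stop("synthetic pilin construction for the ", form, " form realises ",
         "contact offsets {", paste(realized, collapse = ","),
         "} instead of {", paste(offsets, collapse = ","), "}")
  truth <- ground_truth("filament",
                        parameters = list(form = form, n = n,
                                          rise = sym$rise,
                                          twist = sym$twist),
                        expected = list(
                          offsets = offsets,
                          partners_per_direction = length(offsets),
                          inter_bridges = lapply(inter, function(b)
                            list(acid = b$acid[1:2], base = b$base[1:2],
                                 offset = b$offset)),
                          intra_bridges = lapply(intra, function(b)
                            list(acid = b$acid[1:2], base = b$base[1:2])),
                          nearest_acidic_to_nterm = "GLU5"))
  list(filament = fil, truth = truth)
}
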