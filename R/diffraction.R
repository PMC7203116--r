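#' Project a filament model into a 2D image
#'
#' Atoms are rendered as 2D Gaussian densities (sigma `blur_sigma`, Angstrom)
#' summed along the viewing (x) direction. The filament axis (z) runs
#' vertically: image rows are axial positions, columns transverse. Atom
#' centres are deposited with bilinear (cloud-in-cell) weighting and the grid
#' is blurred once with a Gaussian kernel applied in Fourier space, so the
#' integrated intensity is proportional to the atom count.
#'
#' @param filament A `filament_model` (or `subunit_model`).
#' @param pixel_size Angstrom per pixel (default 1.0).
#' @param box Integer c(rows, cols): image height (axial) and width
#'   (transverse) in pixels.
#' @param blur_sigma Gaussian rendering width in Angstrom (default 1.5;
#'   resolves a ~9 Angstrom meridional while keeping boxes small).
#' @return An object of class `projection_image`: `grid` (rows x cols matrix),
#'   `pixel_size`, `blur_sigma`.
#' @export
project_model <- function(filament, pixel_size = 1.0, box = c(1024L, 128L),
                          blur_sigma = 1.5) {
  atoms <- filament$atoms
  if (is.null(atoms) || nrow(atoms) == 0L) stop("model has no atoms")
  if (!is.finite(blur_sigma) || blur_sigma <= 0)
    stop("`blur_sigma` must be > 0")
  nr <- as.integer(box[1]); nc <- as.integer(box[2])
  # centre the filament in the box
  zc <- (min(atoms$z) + max(atoms$z)) / 2
  yc <- 0  # helical axis is x = y = 0 by construction
  row_pos <- (atoms$z - zc) / pixel_size + (nr + 1) / 2
  col_pos <- (atoms$y - yc) / pixel_size + (nc + 1) / 2
  margin <- 4 * blur_sigma / pixel_size
  if (any(row_pos < 1 + margin) || any(row_pos > nr - margin) ||
      any(col_pos < 1 + margin) || any(col_pos > nc - margin))
    stop("filament does not fit in the box (with blur margin); ",
         "use a larger `box` or fewer subunits")
  grid <- deposit_bilinear(row_pos, col_pos, nr, nc)
  grid <- gaussian_blur_fft(grid, blur_sigma / pixel_size)
  structure(list(grid = grid, pixel_size = pixel_size,
                 blur_sigma = blur_sigma),
            class = "projection_image")
}

# Cloud-in-cell deposit of unit masses at fractional (row, col) positions.
deposit_bilinear <- function(row_pos, col_pos, nr, nc) {
  r0 <- floor(row_pos); c0 <- floor(col_pos)
  fr <- row_pos - r0; fc <- col_pos - c0
  rows <- c(r0, r0 + 1, r0, r0 + 1)
  cols <- c(c0, c0, c0 + 1, c0 + 1)
  w <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
  keep <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc & w > 0
  ind <- (cols[keep] - 1) * nr + rows[keep]
  agg <- rowsum(w[keep], group = ind)
  grid <- matrix(0, nr, nc)
  grid[as.integer(rownames(agg))] <- agg[, 1]
  grid
}

# Signed DFT frequency indices for length n (unshifted layout).
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k - n * (k >= ceiling(n / 2))
}

# Gaussian blur with standard deviation sigma_px (pixels) via FFT; the
# transfer function of a unit-integral Gaussian is exp(-2 pi^2 sigma^2 f^2).
gaussian_blur_fft <- function(grid, sigma_px) {
  nr <- nrow(grid); nc <- ncol(grid)
  fr <- fft_freq(nr) / nr
  fc <- fft_freq(nc) / nc
  tf <- outer(exp(-2 * pi^2 * sigma_px^2 * fr^2),
              exp(-2 * pi^2 * sigma_px^2 * fc^2))
  Re(stats::fft(stats::fft(grid) * tf, inverse = TRUE)) / (nr * nc)
}

#' Power spectrum of a projection image
#'
#' Squared modulus of the 2D discrete Fourier transform after windowing,
#' normalised so that the sum of squared amplitudes equals the windowed-image
#' energy (Parseval). Zero frequency is at the grid centre; per-row axial and
#' per-column radial spatial frequencies (1/Angstrom) are attached.
#'
#' @param image A [project_model()] result, or a plain matrix (then
#'   `pixel_size` must be given).
#' @param window "tukey" (raised-cosine 10 percent taper, default; segments
#'   are not periodic in the box) or "none".
#' @param taper Taper fraction for the Tukey window.
#' @param pixel_size Angstrom per pixel if `image` is a bare matrix.
#' @return An object of class `power_spectrum`: `grid`, `axial_freq` (rows),
#'   `radial_freq` (cols), `pixel_size`.
#' @export
power_spectrum <- function(image, window = c("tukey", "none"), taper = 0.1,
                           pixel_size = NULL) {
  window <- match.arg(window)
  if (inherits(image, "projection_image")) {
    grid <- image$grid
    pixel_size <- image$pixel_size
  } else {
    grid <- image
    if (is.null(pixel_size)) stop("`pixel_size` required for a bare matrix")
  }
  if (length(grid) == 0L) stop("image is empty")
  nr <- nrow(grid); nc <- ncol(grid)
  if (window == "tukey")
    grid <- grid * outer(tukey_window(nr, taper), tukey_window(nc, taper))
  amp <- stats::fft(grid) / sqrt(nr * nc)
  ps <- Mod(amp)^2
  ord_r <- order(fft_freq(nr))
  ord_c <- order(fft_freq(nc))
  structure(list(grid = ps[ord_r, ord_c, drop = FALSE],
                 axial_freq = sort(fft_freq(nr)) / (nr * pixel_size),
                 radial_freq = sort(fft_freq(nc)) / (nc * pixel_size),
                 pixel_size = pixel_size,
                 window_energy = sum(grid^2)),
            class = "power_spectrum")
}

# Tukey (raised-cosine taper) window; r is the total taper fraction.
tukey_window <- function(n, r = 0.1) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < r / 2
  hi <- x > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / r + 1)))
  w
}

#' Detect layer lines in a filament power spectrum
#'
#' For each axial-frequency row above the equator, the maximum squared
#' amplitude over radial columns forms a 1D profile; local maxima of that
#' profile with amplitude at least `min_prominence` times the profile maximum
#' are reported as layer lines, mimicking visual indexing of a diffraction
#' pattern. A line is meridional when its peak sits within 2 columns of zero
#' radial frequency.
#'
#' @param ps A [power_spectrum()].
#' @param min_prominence Relative threshold (default 0.1 of the strongest
#'   non-equatorial peak).
#' @param equator_exclude Rows within this many axial-frequency samples of
#'   the equator are ignored (default 2; suppresses window leakage).
#' @return data.frame with columns `axial_spacing` (Angstrom), `axial_freq`,
#'   `radial_freq_at_peak`, `amplitude`, `is_meridional`, sorted by spacing
#'   descending. Empty when nothing exceeds the threshold.
#' @export
detect_layer_lines <- function(ps, min_prominence = 0.1,
                               equator_exclude = 2L) {
  stopifnot(inherits(ps, "power_spectrum"))
  rows <- which(ps$axial_freq > 0)
  zero_row <- which.min(abs(ps$axial_freq))
  rows <- rows[rows > zero_row + equator_exclude]
  if (length(rows) < 3L) return(empty_layer_lines())
  prof <- apply(ps$grid[rows, , drop = FALSE], 1, max)
  thr <- min_prominence * max(prof)
  n <- length(prof)
  is_peak <- prof >= thr &
    prof > c(-Inf, prof[-n]) &
    prof >= c(prof[-1], -Inf)
  pk <- which(is_peak)
  if (length(pk) == 0L) return(empty_layer_lines())
  zero_col <- which.min(abs(ps$radial_freq))
  out <- do.call(rbind, lapply(pk, function(i) {
    r <- rows[i]
    j <- which.max(ps$grid[r, ])
    data.frame(axial_spacing = 1 / ps$axial_freq[r],
               axial_freq = ps$axial_freq[r],
               radial_freq_at_peak = ps$radial_freq[j],
               amplitude = prof[i],
               is_meridional = abs(j - zero_col) <= 2L)
  }))
  out[order(-out$axial_spacing), , drop = FALSE]
}

empty_layer_lines <- function() {
  data.frame(axial_spacing = numeric(0), axial_freq = numeric(0),
             radial_freq_at_peak = numeric(0), amplitude = numeric(0),
             is_meridional = logical(0))
}

#' Score a symmetry candidate against an observed power spectrum
#'
#' Builds a filament from the candidate lattice (same subunit, pixel size and
#' box as the observation), projects it, computes its power spectrum, and
#' returns the Pearson correlation of log(1 + amplitude) over an annulus that
#' excludes the equator and radial frequencies below 1/diameter (the
#' dominant equatorial envelope). This mirrors the comparison of simulated
#' and experimental Fourier transforms used to pick the correct symmetry.
#'
#' @param observed A [power_spectrum()] of the observed image.
#' @param lattice A [lattice_estimate()] candidate.
#' @param subunit The [subunit_model()] used for simulation.
#' @param settings List: `blur_sigma` (default 1.5), `n_subunits` (default:
#'   fills ~85 percent of the box), `equator_exclude` (rows, default 2),
#'   `rmin` (1/Angstrom; default 1/diameter of the simulated filament).
#' @return List of class `candidate_score`: `lattice`, `score`.
#' @export
score_candidate <- function(observed, lattice, subunit, settings = list()) {
  stopifnot(inherits(observed, "power_spectrum"),
            inherits(lattice, "lattice_estimate"),
            inherits(subunit, "subunit_model"))
  nr <- nrow(observed$grid); nc <- ncol(observed$grid)
  px <- observed$pixel_size
  sym <- symmetry_from_lattice(lattice)
  n <- settings$n_subunits
  if (is.null(n)) {
    zspan <- diff(range(subunit$atoms$z))
    n <- max(2L, floor((0.85 * nr * px - zspan) / sym$rise) + 1L)
  }
  blur <- if (is.null(settings$blur_sigma)) 1.5 else settings$blur_sigma
  fil <- build_filament(subunit, sym, n)
  sim <- power_spectrum(project_model(fil, pixel_size = px,
                                      box = c(nr, nc), blur_sigma = blur))
  eq <- if (is.null(settings$equator_exclude)) 2L else settings$equator_exclude
  rmin <- if (is.null(settings$rmin)) 1 / filament_diameter(fil) else settings$rmin
  zero_row <- which.min(abs(observed$axial_freq))
  row_ok <- abs(seq_len(nr) - zero_row) > eq
  col_ok <- abs(observed$radial_freq) >= rmin
  mask <- outer(row_ok, col_ok, `&`)
  score <- stats::cor(log1p(sqrt(observed$grid[mask])),
                      log1p(sqrt(sim$grid[mask])))
  structure(list(lattice = lattice, score = score),
            class = "candidate_score")
}

#' Recover helical symmetry from projection images
#'
#' Full determination pipeline: average the power spectra of the input
#' images, detect layer lines, form pitch hypotheses, enumerate
#' subunits-per-turn candidates at each pitch, score every candidate with
#' [score_candidate()], and rank by score. Deterministic given its inputs.
#'
#' When `pitch_hint` is given (pitch read directly from 2D class averages,
#' as is possible for strongly zigzagged filaments), it is the single pitch
#' used. Otherwise every detected layer line is carried forward as two
#' candidate families: one treating its spacing as the pitch (it may be the
#' order-1 line) and one treating it as the rise (it may be the meridional),
#' because before indexing neither assignment is known and peak amplitudes
#' alone do not identify them reliably. The candidate scoring arbitrates:
#' wrong lattices cannot reproduce the full two-dimensional amplitude
#' pattern. A coarse-to-fine scan (coarse step 0.025 subunits/turn over all
#' families, then the requested `step` around the best candidate at fixed
#' pitch and at fixed rise) keeps the search inexpensive.
#'
#' @param images List of [project_model()] images (all the same geometry).
#' @param subunit The [subunit_model()] used for candidate simulation.
#' @param units_range c(lo, hi) subunits-per-turn search range.
#' @param step Grid step (default 0.01).
#' @param pitch_hint Optional pitch in Angstrom overriding layer-line
#'   detection.
#' @param max_pitch_lines Number of detected layer lines carried forward as
#'   pitch/rise hypotheses (default 12, strongest first).
#' @param settings Passed to [score_candidate()].
#' @return data.frame of candidates with columns `pitch`, `units_per_turn`,
#'   `rise`, `twist`, `score`, sorted by score descending; the detected
#'   layer-line table is attached as attribute `"layer_lines"`.
#' @export
recover_symmetry <- function(images, subunit, units_range = c(3.5, 4.5),
                             step = 0.01, pitch_hint = NULL,
                             max_pitch_lines = 12L, settings = list()) {
  if (inherits(images, "projection_image")) images <- list(images)
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list of projection images")
  specs <- lapply(images, power_spectrum)
  avg <- specs[[1]]
  if (length(specs) > 1L) {
    g <- Reduce(`+`, lapply(specs, `[[`, "grid")) / length(specs)
    avg$grid <- g
  }
  lines <- detect_layer_lines(avg)

  score_set <- function(cands) {
    cands$score <- vapply(seq_len(nrow(cands)), function(i) {
      lat <- lattice_estimate(cands$pitch[i], cands$units_per_turn[i])
      score_candidate(avg, lat, subunit, settings)$score
    }, numeric(1))
    cands
  }

  if (!is.null(pitch_hint)) {
    cands <- score_set(enumerate_symmetry_candidates(pitch_hint, units_range,
                                                     step))
  } else {
    if (nrow(lines) == 0L)
      stop("no layer lines detected and no `pitch_hint` given; ",
           "cannot form symmetry candidates")
    spac <- utils::head(lines$axial_spacing[order(-lines$amplitude)],
                        max_pitch_lines)
    coarse_step <- max(step, 0.025)
    fams <- list()
    for (s in spac) {
      # hypothesis 1: the line is the order-1 (pitch) line
      if (s > units_range[1] * 1.5)  # a pitch below ~1.5 rises is unphysical
        fams <- c(fams, list(enumerate_symmetry_candidates(
          s, units_range, coarse_step)))
      # hypothesis 2: the line is the meridional (rise) line
      anchored <- enumerate_symmetry_candidates(1, units_range, coarse_step)
      anchored$pitch <- anchored$units_per_turn * s
      fams <- c(fams, list(anchored))
    }
    coarse <- score_set(unique(do.call(rbind, fams)))
    best <- coarse[which.max(coarse$score), ]
    # refine at full resolution around the coarse winner, both holding its
    # pitch fixed and holding its rise fixed
    lo <- max(units_range[1], best$units_per_turn - 2 * coarse_step)
    hi <- min(units_range[2], best$units_per_turn + 2 * coarse_step)
    fine_p <- enumerate_symmetry_candidates(best$pitch, c(lo, hi), step)
    fine_r <- enumerate_symmetry_candidates(1, c(lo, hi), step)
    fine_r$pitch <- fine_r$units_per_turn * (best$pitch / best$units_per_turn)
    fine <- score_set(unique(rbind(fine_p, fine_r)))
    cands <- rbind(coarse, fine)
    cands <- cands[!duplicated(cands[, c("pitch", "units_per_turn")]), ,
                   drop = FALSE]
  }
  out <- data.frame(pitch = cands$pitch,
                    units_per_turn = cands$units_per_turn,
                    rise = cands$pitch / cands$units_per_turn,
                    twist = 360 / cands$units_per_turn,
                    score = cands$score)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "layer_lines") <- lines
  out
}
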