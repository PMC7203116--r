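#' Helical symmetry of a 1-start helix
#'
#' A filament's helical symmetry is the rigid screw operation relating
#' consecutive subunits: an axial translation (`rise`, in Angstrom) combined
#' with an azimuthal rotation (`twist`, in degrees) about the filament axis.
#' Amplitude (power-spectrum) data cannot determine the hand of the screw, so
#' the twist is stored as a positive angle together with a separate
#' `handedness` flag that defaults to +1 (right-handed) and is a documented
#' convention, not a measurement.
#'
#' @param rise Axial translation between consecutive subunits, Angstrom (> 0).
#' @param twist Azimuthal rotation between consecutive subunits, degrees
#'   (0 < twist <= 360).
#' @param handedness +1 (right-handed, default) or -1 (left-handed).
#' @return An object of class `helical_symmetry` with fields `rise`, `twist`
#'   and `handedness`.
#' @examples
#' wide <- helical_symmetry(rise = 9.33, twist = 92.5)
#' pitch(wide)            # rise * 360 / twist
#' units_per_turn(wide)   # 360 / twist
#' @export
helical_symmetry <- function(rise, twist, handedness = 1L) {
  stopifnot(is.numeric(rise), length(rise) == 1L, is.numeric(twist),
            length(twist) == 1L)
  if (!is.finite(rise) || rise <= 0)
    stop("`rise` must be a finite positive length in Angstrom, got ", rise)
  if (!is.finite(twist) || twist <= 0 || twist > 360)
    stop("`twist` must satisfy 0 < twist <= 360 degrees, got ", twist)
  if (!handedness %in% c(-1L, 1L, -1, 1))
    stop("`handedness` must be +1 or -1")
  structure(list(rise = as.numeric(rise), twist = as.numeric(twist),
                 handedness = as.integer(handedness)),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf(
    "Helical symmetry: rise %.2f A, twist %.1f deg (%s-handed convention)\n",
    x$rise, x$twist, if (x$handedness > 0) "right" else "left"))
  cat(sprintf("  pitch %.2f A, %.3f subunits per turn\n",
              pitch(x), units_per_turn(x)))
  invisible(x)
}

#' Pitch of a helical symmetry
#'
#' Axial distance covered by one full turn: `rise * 360 / twist`, Angstrom.
#' @param sym A [helical_symmetry()] object.
#' @export
pitch <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  sym$rise * 360 / sym$twist
}

#' Subunits per turn of a helical symmetry
#'
#' `360 / twist`; non-integer for most natural filaments.
#' @param sym A [helical_symmetry()] object.
#' @export
units_per_turn <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  360 / sym$twist
}

#' Lattice estimate: pitch and subunits per turn
#'
#' The pair read off a filament power spectrum (pitch from the order-1 layer
#' line, subunits per turn from the meridional/pitch spacing ratio), before
#' conversion to rise and twist.
#'
#' @param pitch Helical pitch, Angstrom (> 0).
#' @param units_per_turn Subunits per turn (> 1 for in-scope filaments).
#' @return An object of class `lattice_estimate`.
#' @export
lattice_estimate <- function(pitch, units_per_turn) {
  stopifnot(is.numeric(pitch), is.numeric(units_per_turn))
  if (!is.finite(pitch) || pitch <= 0)
    stop("`pitch` must be a finite positive length in Angstrom")
  if (!is.finite(units_per_turn) || units_per_turn <= 1)
    stop("`units_per_turn` must be > 1")
  structure(list(pitch = as.numeric(pitch),
                 units_per_turn = as.numeric(units_per_turn)),
            class = "lattice_estimate")
}

#' @export
print.lattice_estimate <- function(x, ...) {
  cat(sprintf("Lattice estimate: pitch %.2f A, %.3f subunits per turn\n",
              x$pitch, x$units_per_turn))
  invisible(x)
}

#' Convert a lattice estimate to rise and twist
#'
#' rise = pitch / units_per_turn; twist = 360 / units_per_turn. Full precision
#' is always retained internally; `digits` only controls an attached rounded
#' display copy used when comparing against published values (which are
#' conventionally printed with rise to 2 decimals and twist to 1).
#'
#' @param lattice A [lattice_estimate()].
#' @param digits Optional named vector `c(rise = , twist = )` of decimal
#'   places for the rounded display copy (attribute `"rounded"`).
#' @return A [helical_symmetry()] at full precision.
#' @examples
#' symmetry_from_lattice(lattice_estimate(36.3, 3.89))  # 9.33 A / 92.5 deg
#' symmetry_from_lattice(lattice_estimate(48.1, 4.27))  # 11.26 A / 84.3 deg
#' @export
symmetry_from_lattice <- function(lattice, digits = c(rise = 2, twist = 1)) {
  stopifnot(inherits(lattice, "lattice_estimate"))
  sym <- helical_symmetry(rise = lattice$pitch / lattice$units_per_turn,
                          twist = 360 / lattice$units_per_turn)
  attr(sym, "rounded") <- c(rise = round(sym$rise, digits[["rise"]]),
                            twist = round(sym$twist, digits[["twist"]]))
  sym
}

#' Convert rise and twist back to a lattice estimate
#'
#' Exact inverse of [symmetry_from_lattice()].
#' @param sym A [helical_symmetry()].
#' @return A [lattice_estimate()].
#' @export
lattice_from_symmetry <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  lattice_estimate(pitch = pitch(sym), units_per_turn = units_per_turn(sym))
}

#' Subunits per turn from meridional and pitch spacings
#'
#' The meridional reflection sits at 1/rise and the order-1 layer line at
#' 1/pitch, so their spacing ratio is the number of subunits per turn.
#'
#' @param meridional_spacing Spacing of the meridional reflection, Angstrom
#'   (equals the rise).
#' @param pitch_spacing Spacing of the order-1 layer line, Angstrom (equals
#'   the pitch).
#' @return Subunits per turn (pitch_spacing / meridional_spacing).
#' @examples
#' units_per_turn_from_spacings(9, 36)      # ~4 subunits per turn
#' units_per_turn_from_spacings(11.3, 48.1) # 4.26 at printed precision
#' @export
units_per_turn_from_spacings <- function(meridional_spacing, pitch_spacing) {
  if (!is.finite(meridional_spacing) || meridional_spacing <= 0 ||
      !is.finite(pitch_spacing) || pitch_spacing <= 0)
    stop("both spacings must be finite positive lengths in Angstrom")
  if (pitch_spacing < meridional_spacing)
    warning("pitch spacing below meridional spacing: the order-1 layer line ",
            "cannot lie beyond the meridional reflection")
  pitch_spacing / meridional_spacing
}

#' Best rational approximation to the helical repeat
#'
#' Finds coprime integers (subunits `u`, turns `t`) with `t <= max_turns`
#' minimising `|u/t - units_per_turn|`: the exact helical repeat consistent
#' with the measured subunits per turn. Ties are broken toward smaller `t`,
#' matching the practice of reading the repeat off the lowest-index order-1
#' layer line.
#'
#' @param units_per_turn Measured subunits per turn (> 1).
#' @param max_turns Largest number of turns to consider (>= 1).
#' @return An object of class `repeat_solution` with integer fields
#'   `subunits` and `turns`.
#' @examples
#' best_rational_repeat(3.89, 20)  # 35 subunits in 9 turns
#' best_rational_repeat(4.27, 20)  # 47 subunits in 11 turns
#' @export
best_rational_repeat <- function(units_per_turn, max_turns = 20L) {
  if (!is.finite(units_per_turn) || units_per_turn <= 1)
    stop("`units_per_turn` must be > 1")
  if (!is.numeric(max_turns) || max_turns < 1)
    stop("`max_turns` must be >= 1")
  max_turns <- as.integer(max_turns)
  best <- NULL
  best_err <- Inf
  for (t in seq_len(max_turns)) {
    u <- as.integer(round(units_per_turn * t))
    if (u < 1L) u <- 1L
    if (gcd(u, t) != 1L) next  # reduced form already seen at a smaller t
    err <- abs(u / t - units_per_turn)
    if (err < best_err - 1e-15) {   # strict improvement; ties keep smaller t
      best_err <- err
      best <- c(u, t)
    }
  }
  structure(list(subunits = best[1], turns = best[2]),
            class = "repeat_solution")
}

#' @export
print.repeat_solution <- function(x, ...) {
  cat(sprintf("Helical repeat: %d subunits in %d turns (%.4f per turn)\n",
              x$subunits, x$turns, x$subunits / x$turns))
  invisible(x)
}

#' Bessel orders allowed on a layer line
#'
#' Helical selection rule: layer line `l` of a (u, t) repeat carries Bessel
#' order `n` whenever `l = t*n + u*m` for some integer `m`. Only small |m|
#' contribute within the resolved radial range, so `m` is restricted to
#' `|m| <= max_abs_m`.
#'
#' @param index_l Layer-line index (integer; 0 is the equator).
#' @param repeat_sol A [best_rational_repeat()] solution.
#' @param max_abs_m Largest |m| considered (default 3).
#' @return Integer vector of allowed orders `n`, sorted by |n|.
#' @examples
#' r <- best_rational_repeat(3.89, 20)    # (35, 9)
#' allowed_bessel_orders(9, r, 1)         # order 1: the pitch line
#' allowed_bessel_orders(35, r, 1)        # contains 0: the meridional
#' @export
allowed_bessel_orders <- function(index_l, repeat_sol, max_abs_m = 3L) {
  stopifnot(inherits(repeat_sol, "repeat_solution"))
  if (max_abs_m < 0) stop("`max_abs_m` must be >= 0")
  l <- as.integer(index_l)
  u <- repeat_sol$subunits
  t <- repeat_sol$turns
  n <- integer(0)
  for (m in seq.int(-max_abs_m, max_abs_m)) {
    num <- l - u * m
    if (num %% t == 0L) n <- c(n, num %/% t)
  }
  n <- unique(n)
  n[order(abs(n), n)]
}

#' Axial spacing of a layer line
#'
#' The repeat length is `u * rise`; layer line `l` sits at axial frequency
#' `l / (u * rise)`, i.e. spacing `(u * rise) / l`. The equator (l = 0) has
#' no axial spacing.
#'
#' @param index_l Layer-line index (>= 1).
#' @param repeat_sol A [best_rational_repeat()] solution.
#' @param rise Helical rise, Angstrom.
#' @return Spacing in Angstrom.
#' @export
layer_line_spacing <- function(index_l, repeat_sol, rise) {
  stopifnot(inherits(repeat_sol, "repeat_solution"))
  l <- as.integer(index_l)
  if (l < 1L) stop("`index_l` must be >= 1: the equator has no axial spacing")
  if (!is.finite(rise) || rise <= 0) stop("`rise` must be positive")
  (repeat_sol$subunits * rise) / l
}

#' Grid of candidate lattices at a fixed pitch
#'
#' Symmetry determination scans subunits-per-turn candidates at the pitch
#' read from the order-1 layer line; each candidate is scored against the
#' observed power spectrum downstream.
#'
#' @param pitch Fixed pitch, Angstrom.
#' @param units_range Numeric `c(lo, hi)` with `lo > 1`, `hi >= lo`.
#' @param step Grid step in subunits per turn (> 0).
#' @return A data.frame with columns `pitch` and `units_per_turn`.
#' @examples
#' g <- enumerate_symmetry_candidates(36.3, c(3.5, 4.5), 0.01)
#' nrow(g)  # 101 candidates
#' @export
enumerate_symmetry_candidates <- function(pitch, units_range, step) {
  if (!is.finite(pitch) || pitch <= 0) stop("`pitch` must be positive")
  lo <- units_range[1]; hi <- units_range[2]
  if (!is.finite(lo) || lo <= 1) stop("lower bound of `units_range` must be > 1")
  if (hi < lo) stop("`units_range` is empty (hi < lo)")
  if (hi > lo && (!is.finite(step) || step <= 0))
    stop("`step` must be > 0")
  k <- if (hi > lo) floor((hi - lo) / step + 1e-9) else 0
  upt <- lo + step * seq.int(0L, k)
  data.frame(pitch = pitch, units_per_turn = upt)
}

#' Asymmetric units contributed by extracted segments
#'
#' Segments extracted along a filament at a step of k times the helical rise
#' each contribute k asymmetric units (one per subunit of unique signal), so
#' the total is `n_segments * round(step_distance / rise)`. The step must be
#' an integer multiple of the rise to within 0.01.
#'
#' @param n_segments Number of extracted segments.
#' @param step_distance Extraction step, Angstrom.
#' @param rise Helical rise, Angstrom.
#' @return Integer count of asymmetric units.
#' @examples
#' asymmetric_units(65656, 27.99, 9.33)   # 196968
#' asymmetric_units(51301, 33.78, 11.26)  # 153903
#' @export
asymmetric_units <- function(n_segments, step_distance, rise) {
  if (any(c(n_segments, step_distance, rise) <= 0))
    stop("all inputs must be positive")
  ratio <- step_distance / rise
  k <- round(ratio)
  if (abs(ratio - k) > 0.01)
    stop(sprintf(
      "step/rise = %.4f is not an integer multiple within 0.01 of an integer",
      ratio))
  as.integer(n_segments) * as.integer(k)
}

# Greatest common divisor (non-negative integers).
gcd <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) { tmp <- b; b <- a %% b; a <- tmp }
  a
}
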