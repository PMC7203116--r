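# Shared fixtures, built in code at test time.

wide_sym <- function() helical_symmetry(9.33, 92.5)
narrow_sym <- function() helical_symmetry(11.26, 84.3)

# A minimal rigid subunit with one off-axis atom (closed-form transforms).
one_atom_subunit <- function(r = 10) {
  subunit_model(data.frame(elety = "CA", resid = "GLY", resno = 1L,
                           x = r, y = 0, z = 0))
}

# Independent oracle for best_rational_repeat: exhaustive sweep over every
# (u, t) with t <= max_turns, coprimality enforced by reduction.
brute_force_repeat <- function(upt, max_turns) {
  best <- NULL
  best_err <- Inf
  for (t in seq_len(max_turns)) {
    for (u in seq.int(max(1, floor(upt * t) - 2), ceiling(upt * t) + 2)) {
      g <- t
      a <- u
      while (g != 0) { tmp <- g; g <- a %% g; a <- tmp }  # a = gcd(u, t)
      if (a != 1) next
      err <- abs(u / t - upt)
      if (err < best_err - 1e-15) { best_err <- err; best <- c(u, t) }
    }
  }
  best
}

# Independent oracle for the selection rule: enumerate n directly.
brute_force_bessel <- function(l, u, t, max_abs_m, max_abs_n = 200) {
  n <- integer(0)
  for (nn in seq.int(-max_abs_n, max_abs_n))
    for (m in seq.int(-max_abs_m, max_abs_m))
      if (l == t * nn + u * m) n <- c(n, nn)
  n <- unique(n)
  n[order(abs(n), n)]
}
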