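#' Contact analysis settings
#'
#' Distance criteria defining a "physical interaction partner" and a salt
#' bridge. 4.5 Angstrom between heavy atoms (with at least `min_atom_pairs`
#' pairs) and 4.0 Angstrom between charged side-chain N/O atoms are standard
#' structural-biology conventions; partner counts can shift at other cutoffs,
#' so every output records the settings used.
#'
#' @param interaction_cutoff Heavy-atom distance cutoff, Angstrom (default
#'   4.5).
#' @param salt_bridge_cutoff Charged-atom distance cutoff, Angstrom (default
#'   4.0).
#' @param min_atom_pairs Minimum number of atom pairs within the interaction
#'   cutoff for two subunits to count as partners (default 1).
#' @return An object of class `contact_settings`.
#' @export
contact_settings <- function(interaction_cutoff = 4.5,
                             salt_bridge_cutoff = 4.0,
                             min_atom_pairs = 1L) {
  if (interaction_cutoff <= 0 || salt_bridge_cutoff <= 0)
    stop("cutoffs must be positive")
  if (min_atom_pairs < 1L) stop("`min_atom_pairs` must be >= 1")
  structure(list(interaction_cutoff = interaction_cutoff,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 min_atom_pairs = as.integer(min_atom_pairs)),
            class = "contact_settings")
}

# Count atom pairs between coordinate matrices a and b within `cutoff`.
# Production path: prune by axial (z) slab overlap, then exact distances on
# the surviving block. The plain all-pairs oracle is count_close_pairs_brute.
count_close_pairs <- function(a, b, cutoff) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  zb <- range(b[, 3])
  keep_a <- a[, 3] >= zb[1] - cutoff & a[, 3] <= zb[2] + cutoff
  a <- a[keep_a, , drop = FALSE]
  if (nrow(a) == 0L) return(0L)
  za <- range(a[, 3])
  keep_b <- b[, 3] >= za[1] - cutoff & b[, 3] <= za[2] + cutoff
  b <- b[keep_b, , drop = FALSE]
  if (nrow(b) == 0L) return(0L)
  d2 <- cross_dist2(a, b)
  sum(d2 <= cutoff^2)
}

count_close_pairs_brute <- function(a, b, cutoff) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  sum(cross_dist2(a, b) <= cutoff^2)
}

# Squared cross-distance matrix between n x 3 and m x 3 coordinate matrices.
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}

#' Interaction partner map of a filament subunit
#'
#' For a chosen centre subunit, counts heavy-atom pairs within the
#' interaction cutoff to every other subunit; subunits with at least
#' `min_atom_pairs` such pairs are physical interaction partners. For an
#' interior subunit of a helical filament the map is symmetric: offset +k is
#' a partner iff -k is.
#'
#' @param filament A `filament_model`.
#' @param center Subunit index of the centre subunit (default: middle).
#' @param settings A [contact_settings()].
#' @param max_offset Largest |offset| required to be available on both sides
#'   (default: all offsets present in the model). If the centre subunit is
#'   too close to a filament end, an error names the required length.
#' @return An object of class `interaction_map`: `center`, `partners` (named
#'   integer vector, signed offset -> atom-pair count), `per_direction`
#'   (number of partners with positive offset), `settings`.
#' @export
interaction_partners <- function(filament, center = NULL,
                                 settings = contact_settings(),
                                 max_offset = NULL) {
  stopifnot(inherits(filament, "filament_model"),
            inherits(settings, "contact_settings"))
  subs <- sort(unique(filament$atoms$subunit))
  if (is.null(center)) center <- subs[ceiling(length(subs) / 2)]
  if (!center %in% subs) stop("`center` is not a subunit of the model")
  if (!is.null(max_offset)) {
    need <- c(center - max_offset, center + max_offset)
    if (need[1] < min(subs) || need[2] > max(subs))
      stop(sprintf(
        "centre subunit %d is too close to a filament end for offsets up to ",
        center), sprintf(
        "%d; a filament spanning subunits %d..%d is required",
        max_offset, need[1], need[2]))
  }
  atoms <- filament$atoms
  heavy <- !grepl("^H", trimws(atoms$elety))
  atoms <- atoms[heavy, , drop = FALSE]
  a <- as.matrix(atoms[atoms$subunit == center, c("x", "y", "z")])
  others <- setdiff(subs, center)
  counts <- vapply(others, function(j) {
    b <- as.matrix(atoms[atoms$subunit == j, c("x", "y", "z")])
    count_close_pairs(a, b, settings$interaction_cutoff)
  }, numeric(1))
  offsets <- others - center
  keep <- counts >= settings$min_atom_pairs
  partners <- as.integer(counts[keep])
  names(partners) <- offsets[keep]
  structure(list(center = center, partners = partners,
                 per_direction = sum(offsets[keep] > 0),
                 settings = settings),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("Interaction map for subunit %d (cutoff %.2f A, >= %d pairs)\n",
              x$center, x$settings$interaction_cutoff,
              x$settings$min_atom_pairs))
  cat(sprintf("  %d partners per direction; offsets: %s\n", x$per_direction,
              paste(names(x$partners), collapse = ", ")))
  invisible(x)
}

# Charged-atom tables for salt-bridge work. Acidic groups include the
# C-terminal carboxylate; basic groups include the N-terminal amine.
charged_atoms <- function(atoms) {
  if (is.null(atoms$charge_class))
    atoms$charge_class <- annotate_charge_classes(atoms)
  if (is.null(atoms$subunit)) atoms$subunit <- 0L
  list(acidic = atoms[atoms$charge_class %in% c("acidic", "c_terminus"), ,
                      drop = FALSE],
       basic = atoms[atoms$charge_class %in% c("basic", "n_terminus"), ,
                     drop = FALSE])
}

#' Find salt bridges in a filament model
#'
#' A salt bridge is an acidic group (Asp OD1/OD2, Glu OE1/OE2, or C-terminal
#' carboxylate) and a basic group (Lys NZ, Arg NE/NH1/NH2, or N-terminal
#' amine) within the salt-bridge cutoff. Bridges are reported per unique
#' residue pair with the closest atom-pair distance; intermolecular bridges
#' are reduced modulo the helical symmetry to one representative per
#' (acidic residue, basic residue, subunit offset) triple.
#'
#' @param filament A `filament_model` (or `subunit_model`).
#' @param settings A [contact_settings()].
#' @param scope "inter", "intra" or "both" (default).
#' @return data.frame with columns `acid_resid`, `acid_resno`, `acid_subunit`,
#'   `basic_resid`, `basic_resno`, `basic_subunit`, `offset`, `distance`,
#'   `kind`. Empty when no charged residues are present.
#' @export
find_salt_bridges <- function(filament, settings = contact_settings(),
                              scope = c("both", "inter", "intra")) {
  scope <- match.arg(scope)
  atoms <- filament$atoms
  ch <- charged_atoms(atoms)
  empty <- data.frame(acid_resid = character(0), acid_resno = integer(0),
                      acid_subunit = integer(0), basic_resid = character(0),
                      basic_resno = integer(0), basic_subunit = integer(0),
                      offset = integer(0), distance = numeric(0),
                      kind = character(0))
  if (nrow(ch$acidic) == 0L || nrow(ch$basic) == 0L) return(empty)
  d2 <- cross_dist2(as.matrix(ch$acidic[, c("x", "y", "z")]),
                    as.matrix(ch$basic[, c("x", "y", "z")]))
  hit <- which(d2 <= settings$salt_bridge_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  df <- data.frame(acid_resid = ch$acidic$resid[hit[, 1]],
                   acid_resno = ch$acidic$resno[hit[, 1]],
                   acid_subunit = ch$acidic$subunit[hit[, 1]],
                   basic_resid = ch$basic$resid[hit[, 2]],
                   basic_resno = ch$basic$resno[hit[, 2]],
                   basic_subunit = ch$basic$subunit[hit[, 2]],
                   distance = sqrt(pmax(d2[hit], 0)))
  # a residue cannot bridge to itself within the same subunit
  df <- df[!(df$acid_resno == df$basic_resno &
             df$acid_subunit == df$basic_subunit), , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  df$offset <- df$basic_subunit - df$acid_subunit
  df$kind <- ifelse(df$offset == 0L, "intramolecular", "intermolecular")
  if (scope == "inter") df <- df[df$kind == "intermolecular", , drop = FALSE]
  if (scope == "intra") df <- df[df$kind == "intramolecular", , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  # closest atom pair per residue pair; intermolecular pairs reduced modulo
  # the screw symmetry (one representative per residue pair and offset)
  key_intra <- paste(df$acid_resno, df$basic_resno, df$acid_subunit,
                     df$basic_subunit)
  key_inter <- paste(df$acid_resno, df$basic_resno, df$offset)
  key <- ifelse(df$kind == "intramolecular",
                paste0("a", key_intra), paste0("e", key_inter))
  df <- df[order(df$distance), , drop = FALSE]
  df <- df[!duplicated(key[order(df$distance)]), , drop = FALSE]
  # for intramolecular bridges, keep one representative subunit as well
  key2 <- ifelse(df$kind == "intramolecular",
                 paste("a", df$acid_resno, df$basic_resno),
                 paste("e", df$acid_resno, df$basic_resno, df$offset))
  df <- df[!duplicated(key2), , drop = FALSE]
  df <- df[order(df$kind, df$offset, df$acid_resno), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("acid_resid", "acid_resno", "acid_subunit", "basic_resid",
         "basic_resno", "basic_subunit", "offset", "distance", "kind")]
}

#' Nearest acidic group to each subunit's N-terminus
#'
#' For every subunit, finds the acidic group (Asp/Glu carboxylate or
#' C-terminal carboxylate, any subunit) closest to that subunit's N-terminal
#' amine nitrogen, and whether it belongs to the same subunit. Used to ask
#' which negatively charged residue could neutralise the buried N-terminal
#' positive charge.
#'
#' @param filament A `filament_model`.
#' @return data.frame with one row per subunit: `subunit`, `acid_resid`,
#'   `acid_resno`, `acid_subunit`, `distance`, `intramolecular`. Residue
#'   fields are NA when the model has no acidic groups.
#' @export
nearest_acidic_to_nterm <- function(filament) {
  atoms <- filament$atoms
  if (is.null(atoms$charge_class))
    atoms$charge_class <- annotate_charge_classes(atoms)
  if (is.null(atoms$subunit)) atoms$subunit <- 0L
  subs <- sort(unique(atoms$subunit))
  acid <- atoms[atoms$charge_class %in% c("acidic", "c_terminus"), ,
                drop = FALSE]
  out <- lapply(subs, function(s) {
    nt <- atoms[atoms$subunit == s & atoms$charge_class == "n_terminus", ,
                drop = FALSE]
    if (nrow(nt) == 0L)
      stop("subunit ", s, " has no identifiable N-terminal amine")
    if (nrow(acid) == 0L)
      return(data.frame(subunit = s, acid_resid = NA_character_,
                        acid_resno = NA_integer_, acid_subunit = NA_integer_,
                        distance = NA_real_, intramolecular = NA))
    d2 <- cross_dist2(as.matrix(nt[1, c("x", "y", "z"), drop = FALSE]),
                      as.matrix(acid[, c("x", "y", "z")]))
    j <- which.min(d2[1, ])
    data.frame(subunit = s, acid_resid = acid$resid[j],
               acid_resno = acid$resno[j], acid_subunit = acid$subunit[j],
               distance = sqrt(max(d2[1, j], 0)),
               intramolecular = acid$subunit[j] == s)
  })
  do.call(rbind, out)
}

#' Net formal charge of a protein sequence
#'
#' Counts -1 per Asp/Glu, +1 per Lys/Arg, 0 for His (treated as neutral at
#' physiological pH), plus +1/-1 for charged N-/C-termini (which cancel).
#'
#' @param sequence One-letter amino-acid string.
#' @param termini "charged" (default) or "neutral".
#' @return Integer net charge.
#' @examples
#' net_formal_charge("DKDE")  # -1
#' @export
net_formal_charge <- function(sequence, termini = c("charged", "neutral")) {
  termini <- match.arg(termini)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(valid))
    stop("unknown residue letter(s) at position(s): ",
         paste(which(!valid), collapse = ", "))
  charge <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  if (termini == "charged") charge <- charge + 1L - 1L
  as.integer(charge)
}
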