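#' Pilin subunit model
#'
#' A rigid subunit represented as an ordered atom table. Columns `elety`
#' (atom name), `resid` (3-letter residue name), `resno` (residue number,
#' >= 1) and Cartesian coordinates `x`, `y`, `z` in Angstrom are required;
#' `charge_class` (one of acidic, basic, neutral, n_terminus, c_terminus) is
#' derived from residue/atom names with [annotate_charge_classes()] when not
#' supplied.
#'
#' @param atoms data.frame with columns `elety`, `resid`, `resno`, `x`, `y`,
#'   `z` and optionally `charge_class`.
#' @param sequence Optional one-letter residue string.
#' @param label Identifier for the subunit.
#' @return An object of class `subunit_model`.
#' @export
subunit_model <- function(atoms, sequence = NULL, label = "subunit") {
  req <- c("elety", "resid", "resno", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop("`atoms` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(atoms) == 0L) stop("`atoms` must be non-empty")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$resno < 1L)) stop("residue numbers must be >= 1")
  if (is.null(atoms$charge_class))
    atoms$charge_class <- annotate_charge_classes(atoms)
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) != length(unique(atoms$resno)))
      stop("`sequence` length must equal the number of distinct residues")
  }
  structure(list(atoms = atoms, sequence = sequence, label = label),
            class = "subunit_model")
}

#' @export
print.subunit_model <- function(x, ...) {
  cat(sprintf("Subunit model '%s': %d atoms, %d residues\n", x$label,
              nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Classify atoms into formal charge classes
#'
#' Standard structural-biology convention: Asp OD1/OD2 and Glu OE1/OE2 are
#' acidic; Lys NZ and Arg NE/NH1/NH2 are basic; the backbone amine nitrogen
#' of the first residue is the (charged) N-terminus and the carboxylate
#' oxygens (O/OXT) of the last residue the (charged) C-terminus. Histidine
#' is treated as neutral.
#'
#' @param atoms Atom data.frame (see [subunit_model()]).
#' @return Character vector of charge classes, one per atom.
#' @export
annotate_charge_classes <- function(atoms) {
  cls <- rep("neutral", nrow(atoms))
  cls[atoms$resid == "ASP" & atoms$elety %in% c("OD1", "OD2")] <- "acidic"
  cls[atoms$resid == "GLU" & atoms$elety %in% c("OE1", "OE2")] <- "acidic"
  cls[atoms$resid == "LYS" & atoms$elety == "NZ"] <- "basic"
  cls[atoms$resid == "ARG" & atoms$elety %in% c("NE", "NH1", "NH2")] <- "basic"
  first <- min(atoms$resno)
  last <- max(atoms$resno)
  cls[atoms$resno == first & atoms$elety == "N"] <- "n_terminus"
  cls[atoms$resno == last & atoms$elety %in% c("O", "OXT")] <- "c_terminus"
  cls
}

#' Build a filament model by applying helical symmetry
#'
#' Subunit copy i is the input subunit rotated by `i * twist` about the
#' z axis (counterclockwise viewed from +z for handedness +1) and translated
#' by `i * rise` along z. Subunit 0 (or `start_index`) is untransformed. This
#' mirrors how filament coordinate models are generated from a single refined
#' chain.
#'
#' @param subunit A [subunit_model()].
#' @param sym A [helical_symmetry()].
#' @param n Number of subunits (>= 1).
#' @param start_index Index of the first subunit copy (default 0).
#' @return An object of class `filament_model`: atom table with a `subunit`
#'   index column, the symmetry, and the template subunit.
#' @examples
#' su <- subunit_model(data.frame(elety = "CA", resid = "GLY", resno = 1,
#'                                x = 10, y = 0, z = 0))
#' fil <- build_filament(su, helical_symmetry(10, 90), n = 4)
#' fil$atoms[, c("subunit", "x", "y", "z")]
#' @export
build_filament <- function(subunit, sym, n, start_index = 0L) {
  stopifnot(inherits(subunit, "subunit_model"),
            inherits(sym, "helical_symmetry"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  idx <- seq.int(start_index, length.out = n)
  xyz <- as.matrix(subunit$atoms[, c("x", "y", "z")])
  pieces <- lapply(idx, function(i) {
    a <- subunit$atoms
    p <- screw_transform(xyz, sym, i)
    a$x <- p[, 1]; a$y <- p[, 2]; a$z <- p[, 3]
    a$subunit <- i
    a
  })
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, symmetry = sym, subunit = subunit,
                 n_subunits = n, label = subunit$label),
            class = "filament_model")
}

# Apply the i-th power of the helical screw operation to an n x 3 matrix.
screw_transform <- function(xyz, sym, i) {
  theta <- sym$handedness * i * sym$twist * pi / 180
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * xyz[, 1] - st * xyz[, 2],
        st * xyz[, 1] + ct * xyz[, 2],
        xyz[, 3] + i * sym$rise)
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("Filament model '%s': %d subunits, %d atoms\n", x$label,
              x$n_subunits, nrow(x$atoms)))
  if (!is.null(x$symmetry)) print(x$symmetry)
  invisible(x)
}

#' Filament diameter
#'
#' Twice the maximum radial distance of any atom from the z (helical) axis.
#' @param filament A `filament_model` or `subunit_model`.
#' @return Diameter in Angstrom.
#' @export
filament_diameter <- function(filament) {
  atoms <- filament$atoms
  if (is.null(atoms) || nrow(atoms) == 0L) stop("model has no atoms")
  2 * max(sqrt(atoms$x^2 + atoms$y^2))
}

# Chain identifiers available for PDB output: 62 single characters.
chain_ids <- function() c(LETTERS, letters, as.character(0:9))

#' Read a subunit or filament model from a PDB file
#'
#' One chain is mapped to one subunit, chains in order of appearance getting
#' consecutive subunit indices from 0. A single-chain file yields a
#' `subunit_model`; a multi-chain file yields a `filament_model` whose
#' symmetry is unknown (NULL) until assigned.
#'
#' @param path Path to a PDB file.
#' @return A [subunit_model()] or `filament_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records (empty model): ", path)
  atoms <- data.frame(elety = at$elety, resid = at$resid, resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  chains <- at$chain
  chains[is.na(chains)] <- " "
  uc <- unique(chains)
  if (length(uc) == 1L) {
    atoms$charge_class <- annotate_charge_classes(atoms)
    return(subunit_model(atoms, label = basename(path)))
  }
  sub_idx <- match(chains, uc) - 1L
  pieces <- lapply(seq_along(uc), function(k) {
    a <- atoms[sub_idx == (k - 1L), , drop = FALSE]
    a$charge_class <- annotate_charge_classes(a)
    a$subunit <- k - 1L
    a
  })
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  template <- atoms[atoms$subunit == 0L,
                    c("elety", "resid", "resno", "x", "y", "z",
                      "charge_class")]
  structure(list(atoms = atoms, symmetry = NULL,
                 subunit = subunit_model(template, label = basename(path)),
                 n_subunits = length(uc), label = basename(path)),
            class = "filament_model")
}

#' Write a filament (or subunit) model to a PDB file
#'
#' One chain per subunit, chain identifiers A, B, C, ... in subunit-index
#' order. At most 62 subunits fit in the single-character chain-ID space.
#'
#' @param model A `filament_model` or `subunit_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  atoms <- model$atoms
  if (is.null(atoms) || nrow(atoms) == 0L) stop("model has no atoms")
  if (is.null(atoms$subunit)) atoms$subunit <- 0L
  n_sub <- length(unique(atoms$subunit))
  if (n_sub > 62L)
    stop("more than 62 subunits cannot be written with single-character ",
         "chain IDs; split the model into multiple files")
  chain <- chain_ids()[match(atoms$subunit, sort(unique(atoms$subunit)))]
  elesym <- substr(trimws(atoms$elety), 1, 1)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = chain, elesy = elesym)
  invisible(path)
}
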