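#' Construct a force-field topology
#'
#' The engine-neutral container for one molecule's atoms, bonded terms and
#' parameter tables. Both supported file dialects (GROMOS11 block format and
#' GROMACS `[ section ]` format) are read into, and written from, this one
#' representation; the MCS search, scoring and perturbation building all
#' operate on it.
#'
#' Atom indices are 1-based and contiguous, matching both R and the on-disk
#' dialects. Bonded terms refer to atoms by index and carry a parameter
#' reference (`ref`) that must resolve in `params`. Proper dihedral parameters
#' carry an integer multiplicity.
#'
#' @param atoms Data frame with columns `name`, `type_id`, `mass`, `charge`
#'   and optionally `charge_group` (required by the GROMOS dialect). An
#'   `index` column is added/overwritten as `1:nrow`.
#' @param bonds Data frame with columns `i`, `j`, `ref` (may be empty/NULL).
#' @param angles Data frame with columns `i`, `j`, `k`, `ref`.
#' @param dihedrals,impropers Data frames with columns `i`, `j`, `k`, `l`, `ref`.
#' @param params Named list of parameter entries, each a list with fields
#'   `kind` (one of `"bond"`, `"angle"`, `"dihedral"`, `"improper"`),
#'   `values` (numeric vector: force constant and equilibrium value(s)) and,
#'   for proper dihedrals, `mult` (integer multiplicity).
#' @param exclusions List of integer vectors, one per atom (may be NULL).
#' @param pairs14 Data frame with columns `i`, `j` of 1-4 interaction pairs.
#' @param dialect Source dialect, `"gromos"` or `"gromacs"`.
#' @param title Molecule title used in file headers.
#' @return An object of class `fftop`.
#' @export
ff_topology <- function(atoms,
                        bonds = NULL, angles = NULL,
                        dihedrals = NULL, impropers = NULL,
                        params = list(),
                        exclusions = NULL, pairs14 = NULL,
                        dialect = c("gromos", "gromacs"),
                        title = "molecule") {
  dialect <- match.arg(dialect)
  atoms <- tibble::as_tibble(atoms)
  if (!"charge_group" %in% names(atoms)) atoms$charge_group <- NA_integer_
  atoms$index <- seq_len(nrow(atoms))
  atoms <- atoms[, c("index", "name", "type_id", "mass", "charge", "charge_group")]
  empty2 <- tibble::tibble(i = integer(), j = integer(), ref = character())
  empty3 <- tibble::tibble(i = integer(), j = integer(), k = integer(), ref = character())
  empty4 <- tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer(),
                           ref = character())
  norm <- function(x, empty) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0L) return(empty)
    x <- tibble::as_tibble(x)
    for (cc in setdiff(names(empty), "ref")) x[[cc]] <- as.integer(x[[cc]])
    x$ref <- as.character(x$ref)
    x[, names(empty)]
  }
  if (is.null(exclusions)) exclusions <- rep(list(integer()), nrow(atoms))
  exclusions <- lapply(exclusions, function(e) sort(unique(as.integer(e))))
  pairs14 <- if (is.null(pairs14) || nrow(as.data.frame(pairs14)) == 0L) {
    tibble::tibble(i = integer(), j = integer())
  } else {
    p <- tibble::as_tibble(pairs14)
    tibble::tibble(i = as.integer(pmin(p$i, p$j)), j = as.integer(pmax(p$i, p$j)))
  }
  top <- structure(
    list(
      title = title,
      atoms = atoms,
      bonds = canonical_terms(norm(bonds, empty2)),
      angles = canonical_terms(norm(angles, empty3)),
      dihedrals = canonical_terms(norm(dihedrals, empty4)),
      impropers = norm(impropers, empty4),
      params = params,
      exclusions = exclusions,
      pairs14 = pairs14,
      dialect = dialect
    ),
    class = "fftop"
  )
  validate_fftop(top)
  top
}

# canonical atom order inside a term: bonds i<j; angles ends sorted around the
# centre; dihedrals oriented so the first atom index is <= the last.
canonical_terms <- function(tb) {
  if (nrow(tb) == 0L) return(tb)
  if (all(c("i", "j") %in% names(tb)) && !"k" %in% names(tb)) {
    ii <- pmin(tb$i, tb$j); jj <- pmax(tb$i, tb$j)
    tb$i <- as.integer(ii); tb$j <- as.integer(jj)
  } else if ("k" %in% names(tb) && !"l" %in% names(tb)) {
    flip <- tb$i > tb$k
    tmp <- tb$i[flip]; tb$i[flip] <- tb$k[flip]; tb$k[flip] <- tmp
  } else if ("l" %in% names(tb)) {
    flip <- tb$i > tb$l | (tb$i == tb$l & tb$j > tb$k)
    tmpi <- tb$i[flip]; tmpj <- tb$j[flip]
    tb$i[flip] <- tb$l[flip]; tb$j[flip] <- tb$k[flip]
    tb$k[flip] <- tmpj; tb$l[flip] <- tmpi
  }
  tb[order(tb$i, tb$j), , drop = FALSE]
}

#' Validate a force-field topology
#'
#' Checks the `fftop` invariants: contiguous 1-based atom indices, non-negative
#' masses, non-empty atom types, bonded terms referring to existing distinct
#' atoms, and every parameter reference resolving in the parameter table.
#'
#' @param top An `fftop` object.
#' @return `top`, invisibly; aborts with a descriptive error on violation.
#' @export
validate_fftop <- function(top) {
  stopifnot(inherits(top, "fftop"))
  n <- nrow(top$atoms)
  if (n == 0L) rlang::abort("topology has no atoms", class = "perttop_validation_error")
  if (!identical(top$atoms$index, seq_len(n)))
    rlang::abort("atom indices must be contiguous starting at 1",
                 class = "perttop_validation_error")
  if (any(!nzchar(top$atoms$type_id)) || anyNA(top$atoms$type_id))
    rlang::abort("every atom needs a non-empty type_id",
                 class = "perttop_validation_error")
  if (any(top$atoms$mass < 0))
    rlang::abort("atom masses must be >= 0", class = "perttop_validation_error")
  check_terms <- function(tb, arity, what) {
    if (nrow(tb) == 0L) return(invisible())
    idx <- as.matrix(tb[, seq_len(arity)])
    if (any(idx < 1L | idx > n))
      rlang::abort(sprintf("%s term refers to atom index outside 1..%d", what, n),
                   class = "perttop_validation_error")
    if (any(apply(idx, 1L, anyDuplicated) > 0L))
      rlang::abort(sprintf("%s term repeats an atom", what),
                   class = "perttop_validation_error")
    bad <- setdiff(tb$ref, names(top$params))
    if (length(bad))
      rlang::abort(sprintf("unresolved %s parameter reference: %s",
                           what, paste(bad, collapse = ", ")),
                   class = "perttop_validation_error")
  }
  check_terms(top$bonds, 2L, "bond")
  check_terms(top$angles, 3L, "angle")
  check_terms(top$dihedrals, 4L, "dihedral")
  check_terms(top$impropers, 4L, "improper")
  if (anyDuplicated(paste(top$bonds$i, top$bonds$j)))
    rlang::abort("duplicate bond", class = "perttop_validation_error")
  if (length(top$exclusions) != n)
    rlang::abort("exclusions list length must equal atom count",
                 class = "perttop_validation_error")
  invisible(top)
}

#' @export
print.fftop <- function(x, ...) {
  cat(sprintf("<fftop '%s' (%s): %d atoms, %d bonds, %d angles, %d dihedrals, %d impropers>\n",
              x$title, x$dialect, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals), nrow(x$impropers)))
  invisible(x)
}

#' Resolve a parameter reference
#' @param top An `fftop`.
#' @param ref Parameter reference string.
#' @return The parameter entry (list with `kind`, `values`, optional `mult`).
#' @export
ff_params <- function(top, ref) {
  p <- top$params[[ref]]
  if (is.null(p)) rlang::abort(sprintf("unresolved parameter reference '%s'", ref),
                               class = "perttop_validation_error")
  p
}

# Numeric parameter equality. Identical physics under different labels must
# not count as a perturbation, so comparison is on resolved values with a
# relative tolerance of 1e-9.
params_equal <- function(pa, pb, rel_tol = 1e-9) {
  if (!identical(pa$kind, pb$kind)) return(FALSE)
  if (length(pa$values) != length(pb$values)) return(FALSE)
  scale <- pmax(abs(pa$values), abs(pb$values), 1)
  all(abs(pa$values - pb$values) <= rel_tol * scale)
}

charges_equal <- function(qa, qb, abs_tol = 1e-6) abs(qa - qb) <= abs_tol
masses_equal <- function(ma, mb, rel_tol = 1e-9) {
  abs(ma - mb) <= rel_tol * pmax(abs(ma), abs(mb), 1)
}

#' Semantic equality of two topologies
#'
#' Field-by-field comparison used by the round-trip tests: atom names, types,
#' masses, charges and charge groups; bonded-term sets with *resolved* numeric
#' parameters (labels are ignored); exclusion and 1-4 sets. Dialect and title
#' are not compared.
#'
#' @param a,b `fftop` objects.
#' @param check_charge_groups Compare charge groups (GROMACS files regenerate
#'   them, so cross-dialect comparisons switch this off).
#' @return TRUE/FALSE.
#' @export
fftop_equal <- function(a, b, check_charge_groups = TRUE) {
  if (nrow(a$atoms) != nrow(b$atoms)) return(FALSE)
  at <- a$atoms; bt <- b$atoms
  ok <- all(at$name == bt$name) && all(at$type_id == bt$type_id) &&
    all(masses_equal(at$mass, bt$mass)) && all(charges_equal(at$charge, bt$charge))
  if (check_charge_groups)
    ok <- ok && identical(is.na(at$charge_group), is.na(bt$charge_group)) &&
      all(at$charge_group == bt$charge_group, na.rm = TRUE)
  if (!ok) return(FALSE)
  term_key <- function(top, tb, arity) {
    if (nrow(tb) == 0L) return(character())
    vapply(seq_len(nrow(tb)), function(r) {
      p <- ff_params(top, tb$ref[r])
      paste(paste(as.integer(tb[r, seq_len(arity)]), collapse = "-"),
            paste(signif(p$values, 12), collapse = ","),
            if (is.null(p$mult) || is.na(p$mult)) "" else p$mult)
    }, character(1))
  }
  for (sl in list(c("bonds", 2L), c("angles", 3L), c("dihedrals", 4L),
                  c("impropers", 4L))) {
    ka <- sort(term_key(a, a[[sl[1]]], as.integer(sl[2])))
    kb <- sort(term_key(b, b[[sl[1]]], as.integer(sl[2])))
    if (!identical(ka, kb)) return(FALSE)
  }
  if (!identical(lapply(a$exclusions, sort), lapply(b$exclusions, sort))) return(FALSE)
  pk <- function(p) sort(paste(pmin(p$i, p$j), pmax(p$i, p$j)))
  identical(pk(a$pairs14), pk(b$pairs14))
}

#' Total charge of a topology
#' @param top An `fftop`.
#' @return Sum of partial charges (e).
#' @export
ff_total_charge <- function(top) sum(top$atoms$charge)

#' Atom table of a topology
#'
#' @param x An `fftop`.
#' @param ... Unused.
#' @return The atom tibble.
#' @export
as_tibble.fftop <- function(x, ...) x$atoms

#' A coordinate set paired with a topology
#'
#' @param positions Numeric matrix, one row per atom, columns x/y/z in nm.
#' @param top Optional `fftop` to check the atom count against.
#' @return Object of class `coordset`.
#' @export
coord_set <- function(positions, top = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    rlang::abort("positions must have 3 columns", class = "perttop_validation_error")
  if (any(!is.finite(positions)))
    rlang::abort("positions must be finite", class = "perttop_validation_error")
  if (!is.null(top) && nrow(positions) != nrow(top$atoms))
    rlang::abort(sprintf("coordinate count (%d) does not match atom count (%d)",
                         nrow(positions), nrow(top$atoms)),
                 class = "perttop_validation_error")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions), class = "coordset")
}

#' @export
print.coordset <- function(x, ...) {
  cat(sprintf("<coordset: %d atoms (nm)>\n", nrow(x$positions)))
  invisible(x)
}
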