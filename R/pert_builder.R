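#' Build a single-topology perturbation from a match solution
#'
#' Converts a complete match solution into the union molecule used for
#' alchemical free-energy calculations: one merged atom set carrying
#' per-state type, mass and charge, where atoms matched to a dummy appear
#' with the noninteracting dummy type and zero charge in the state in which
#' they do not exist. The bond list is identical across states (the search
#' never creates or removes bonds); bonded terms that exist in only one
#' state because they involve dummy atoms keep their real-state parameters
#' in both states, preserving the dummy-region geometry.
#'
#' @param sol A complete `match_solution` (pairwise, or multistate — then
#'   `state_a`/`state_b` select the pair).
#' @param state_a,state_b Indices of the two end states.
#' @param dummy_type Atom-type name used for dummy-state atoms.
#' @return Object of class `pert_topology`.
#' @export
build_pert_topology <- function(sol, state_a = 1L, state_b = 2L,
                                dummy_type = "DUM") {
  if (!isTRUE(sol$complete))
    rlang::abort("solution is not complete", class = "perttop_validation_error")
  ns <- length(sol$states)
  if (any(c(state_a, state_b) < 1L) || any(c(state_a, state_b) > ns) ||
      state_a == state_b)
    rlang::abort("invalid state selection", class = "perttop_validation_error")
  ta <- sol$states[[state_a]]; tb <- sol$states[[state_b]]
  mat <- sol$matches[, c(state_a, state_b), drop = FALSE]
  mat <- mat[rowSums(!is.na(mat)) > 0L, , drop = FALSE]
  ord <- order(is.na(mat[, 1]), mat[, 1], mat[, 2])
  mat <- mat[ord, , drop = FALSE]
  nu <- nrow(mat)
  inv_a <- rep(NA_integer_, nrow(ta$atoms)); inv_b <- rep(NA_integer_, nrow(tb$atoms))
  inv_a[mat[!is.na(mat[, 1]), 1]] <- which(!is.na(mat[, 1]))
  inv_b[mat[!is.na(mat[, 2]), 2]] <- which(!is.na(mat[, 2]))
  pick <- function(state_top, idx, col) {
    ifelse(is.na(idx), NA, state_top$atoms[[col]][idx])
  }
  atoms <- tibble::tibble(
    index = seq_len(nu),
    orig_a = mat[, 1], orig_b = mat[, 2],
    name_a = as.character(pick(ta, mat[, 1], "name")),
    name_b = as.character(pick(tb, mat[, 2], "name")),
    dummy_a = is.na(mat[, 1]), dummy_b = is.na(mat[, 2]),
    type_a = as.character(pick(ta, mat[, 1], "type_id")),
    mass_a = as.numeric(pick(ta, mat[, 1], "mass")),
    charge_a = as.numeric(pick(ta, mat[, 1], "charge")),
    type_b = as.character(pick(tb, mat[, 2], "type_id")),
    mass_b = as.numeric(pick(tb, mat[, 2], "mass")),
    charge_b = as.numeric(pick(tb, mat[, 2], "charge")),
    cg_a = as.integer(pick(ta, mat[, 1], "charge_group")),
    cg_b = as.integer(pick(tb, mat[, 2], "charge_group"))
  )
  atoms$name <- ifelse(!atoms$dummy_a, atoms$name_a, atoms$name_b)
  atoms$name_a[atoms$dummy_a] <- atoms$name_b[atoms$dummy_a]
  atoms$name_b[atoms$dummy_b] <- atoms$name_a[atoms$dummy_b]
  atoms$charge_group <- ifelse(!atoms$dummy_a, atoms$cg_a, atoms$cg_b)
  atoms$cg_a[atoms$dummy_a] <- atoms$cg_b[atoms$dummy_a]
  atoms$cg_b[atoms$dummy_b] <- atoms$cg_a[atoms$dummy_b]
  # dummy-state parameters: noninteracting type, zero charge, real-state mass
  atoms$type_a[atoms$dummy_a] <- dummy_type
  atoms$charge_a[atoms$dummy_a] <- 0
  atoms$mass_a[atoms$dummy_a] <- atoms$mass_b[atoms$dummy_a]
  atoms$type_b[atoms$dummy_b] <- dummy_type
  atoms$charge_b[atoms$dummy_b] <- 0
  atoms$mass_b[atoms$dummy_b] <- atoms$mass_a[atoms$dummy_b]
  params <- c(stats::setNames(ta$params, paste0("A:", names(ta$params))),
              stats::setNames(tb$params, paste0("B:", names(tb$params))))
  merge_terms <- function(tb_a, tb_b, arity) {
    keyf <- switch(as.character(arity), "2" = key2, "3" = key3,
                   "4" = if (identical(attr(tb_a, "improper"), TRUE)) key4s else key4)
    rows <- new.env(parent = emptyenv())
    order_keys <- character()
    addside <- function(tb_x, inv, side) {
      for (r in seq_len(nrow(tb_x))) {
        av <- inv[as.integer(tb_x[r, seq_len(arity)])]
        kk <- do.call(keyf, as.list(av))
        cur <- get0(kk, envir = rows)
        if (is.null(cur)) {
          cur <- list(atoms = av, ref_a = NA_character_, ref_b = NA_character_)
          order_keys <<- c(order_keys, kk)
        }
        cur[[paste0("ref_", side)]] <- paste0(toupper(side), ":", tb_x$ref[r])
        assign(kk, cur, envir = rows)
      }
    }
    addside(tb_a, inv_a, "a")
    addside(tb_b, inv_b, "b")
    if (!length(order_keys)) {
      cols <- c("i", "j", "k", "l")[seq_len(arity)]
      out <- tibble::as_tibble(stats::setNames(rep(list(integer()), arity), cols))
      out$ref_a <- character(); out$ref_b <- character()
      return(out)
    }
    recs <- lapply(order_keys, get, envir = rows)
    idx <- t(vapply(recs, function(x) as.integer(x$atoms), integer(arity)))
    out <- tibble::as_tibble(stats::setNames(as.data.frame(idx),
                                             c("i", "j", "k", "l")[seq_len(arity)]))
    out$ref_a <- vapply(recs, function(x) x$ref_a, character(1))
    out$ref_b <- vapply(recs, function(x) x$ref_b, character(1))
    # terms present in one state only: dummy-region terms carry the
    # real-state parameters in both states; terms among fully real atoms
    # remain absent in the other state (created/removed term)
    for (r in seq_len(nrow(out))) {
      av <- as.integer(out[r, seq_len(arity)])
      if (is.na(out$ref_a[r]) && any(atoms$dummy_a[av])) out$ref_a[r] <- out$ref_b[r]
      if (is.na(out$ref_b[r]) && any(atoms$dummy_b[av])) out$ref_b[r] <- out$ref_a[r]
    }
    out
  }
  imp_a <- ta$impropers; attr(imp_a, "improper") <- TRUE
  bonds <- merge_terms(ta$bonds, tb$bonds, 2L)
  if (any(is.na(bonds$ref_a)) || any(is.na(bonds$ref_b)))
    rlang::abort("internal: bond present in one state only",
                 class = "perttop_validation_error")
  map_excl <- function(top_x, inv, other_excl_src) {
    out <- vector("list", nu)
    for (u in seq_len(nu)) out[[u]] <- integer()
    for (a in seq_along(top_x$exclusions)) {
      u <- inv[a]
      if (!is.na(u)) out[[u]] <- sort(inv[top_x$exclusions[[a]]][!is.na(inv[top_x$exclusions[[a]]])])
    }
    out
  }
  excl_a <- map_excl(ta, inv_a)
  excl_b <- map_excl(tb, inv_b)
  # dummy atoms inherit the exclusions of the state in which they are real
  for (u in seq_len(nu)) {
    if (atoms$dummy_a[u]) excl_a[[u]] <- excl_b[[u]]
    if (atoms$dummy_b[u]) excl_b[[u]] <- excl_a[[u]]
  }
  map_p14 <- function(top_x, inv) {
    p <- top_x$pairs14
    if (!nrow(p)) return(tibble::tibble(i = integer(), j = integer()))
    ui <- inv[p$i]; uj <- inv[p$j]
    keep <- !is.na(ui) & !is.na(uj)
    tibble::tibble(i = pmin(ui[keep], uj[keep]), j = pmax(ui[keep], uj[keep]))
  }
  structure(list(
    atoms = atoms,
    bonds = bonds,
    angles = merge_terms(ta$angles, tb$angles, 3L),
    dihedrals = merge_terms(ta$dihedrals, tb$dihedrals, 4L),
    impropers = merge_terms(imp_a, tb$impropers, 4L),
    params = params,
    excl_a = excl_a, excl_b = excl_b,
    p14_a = map_p14(ta, inv_a), p14_b = map_p14(tb, inv_b),
    state_labels = c(ta$title, tb$title),
    dummy_type = dummy_type,
    solution = sol
  ), class = "pert_topology")
}

#' @export
print.pert_topology <- function(x, ...) {
  cat(sprintf("<pert_topology %s -> %s: %d atoms (%d dummy in A, %d dummy in B)>\n",
              x$state_labels[1], x$state_labels[2], nrow(x$atoms),
              sum(x$atoms$dummy_a), sum(x$atoms$dummy_b)))
  invisible(x)
}

#' Restrict a perturbation or EDS topology to one end state
#'
#' Drops the atoms that are dummies in the selected state and returns that
#' state's plain topology (its atoms in their original order with that
#' state's parameters and bonded terms). For every valid input this
#' reproduces the corresponding input topology exactly.
#'
#' @param x A `pert_topology` or `eds_topology`.
#' @param state For `pert_topology`: `"A"` or `"B"`; for `eds_topology`: the
#'   state index.
#' @return An `fftop`.
#' @export
restrict_state <- function(x, state) UseMethod("restrict_state")

#' @rdname restrict_state
#' @export
restrict_state.pert_topology <- function(x, state = c("A", "B")) {
  state <- match.arg(state)
  lo <- tolower(state)
  keep <- !x$atoms[[paste0("dummy_", lo)]]
  orig <- x$atoms[[paste0("orig_", lo)]]
  ord <- order(orig[keep])
  sel <- which(keep)[ord]
  newidx <- rep(NA_integer_, nrow(x$atoms))
  newidx[sel] <- seq_along(sel)
  atoms <- tibble::tibble(
    name = x$atoms[[paste0("name_", lo)]][sel],
    type_id = x$atoms[[paste0("type_", lo)]][sel],
    mass = x$atoms[[paste0("mass_", lo)]][sel],
    charge = x$atoms[[paste0("charge_", lo)]][sel],
    charge_group = x$atoms[[paste0("cg_", lo)]][sel])
  remap <- function(tb, arity) {
    refc <- tb[[paste0("ref_", lo)]]
    ok <- !is.na(refc)
    if (any(ok)) {
      idx <- as.matrix(tb[ok, seq_len(arity)])
      allreal <- apply(idx, 1L, function(v) all(!is.na(newidx[v])))
      ok[ok] <- allreal
    }
    if (!any(ok)) return(NULL)
    idx <- as.matrix(tb[ok, seq_len(arity)])
    out <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(newidx[idx], ncol = arity)),
      c("i", "j", "k", "l")[seq_len(arity)]))
    out$ref <- tb[[paste0("ref_", lo)]][ok]
    out
  }
  excl <- lapply(x[[paste0("excl_", lo)]][sel],
                 function(e) newidx[e][!is.na(newidx[e])])
  p14 <- x[[paste0("p14_", lo)]]
  p14 <- if (nrow(p14)) {
    keep14 <- !is.na(newidx[p14$i]) & !is.na(newidx[p14$j])
    tibble::tibble(i = newidx[p14$i[keep14]], j = newidx[p14$j[keep14]])
  } else NULL
  ff_topology(atoms, bonds = remap(x$bonds, 2L), angles = remap(x$angles, 3L),
              dihedrals = remap(x$dihedrals, 4L), impropers = remap(x$impropers, 4L),
              params = x$params, exclusions = excl, pairs14 = p14,
              dialect = "gromos",
              title = x$state_labels[if (state == "A") 1L else 2L])
}

#' Audit dummy-atom anchoring
#'
#' Dummy atoms must be attached to the unperturbed part of the molecule by
#' three nonredundant bonded interactions (one bond, one angle, one proper
#' or improper dihedral positioning the atom); additional bonded terms to
#' the non-dummy region are redundant and can bias free-energy results, so
#' they are detected and reported — never removed automatically.
#'
#' For every atom that is a dummy in one state, the audit counts the bonded
#' terms joining it to otherwise non-dummy atoms. A count above three flags
#' redundant terms; a count of one or two flags under-anchoring. Atoms
#' anchored purely through other dummy atoms (count 0) are positioned by the
#' dummy-region terms and are not flagged.
#'
#' @param pert A `pert_topology`.
#' @param quiet Suppress the warning messages (the returned table always
#'   carries the flags).
#' @return Tibble with one row per dummy atom: `atom`, `name`, `dummy_in`,
#'   `n_anchor_terms`, `n_redundant`, `under_anchored`, `warning`.
#' @export
audit_dummies <- function(pert, quiet = FALSE) {
  at <- pert$atoms
  core <- which(!at$dummy_a & !at$dummy_b)
  dummies <- which(at$dummy_a | at$dummy_b)
  rows <- list()
  term_sets <- list(list(pert$bonds, 2L), list(pert$angles, 3L),
                    list(pert$dihedrals, 4L), list(pert$impropers, 4L))
  for (d in dummies) {
    cnt <- 0L
    for (tsp in term_sets) {
      tb <- tsp[[1]]; arity <- tsp[[2]]
      if (!nrow(tb)) next
      idx <- as.matrix(tb[, seq_len(arity)])
      has_d <- rowSums(idx == d) > 0L
      others_core <- apply(idx, 1L, function(v) all(setdiff(v, d) %in% core))
      cnt <- cnt + sum(has_d & others_core)
    }
    red <- max(0L, cnt - 3L)
    under <- cnt >= 1L && cnt < 3L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      atom = d, name = at$name[d],
      dummy_in = if (at$dummy_a[d]) "A" else "B",
      n_anchor_terms = cnt, n_redundant = red,
      under_anchored = under, warning = red > 0L || under)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(atom = integer(), name = character(), dummy_in = character(),
                   n_anchor_terms = integer(), n_redundant = integer(),
                   under_anchored = logical(), warning = logical())
  if (!quiet) {
    for (r in which(out$warning)) {
      if (out$n_redundant[r] > 0L)
        rlang::warn(sprintf("dummy atom %s: %d bonded interactions with unperturbed atoms (%d redundant terms); consider manual curation",
                            out$name[r], out$n_anchor_terms[r], out$n_redundant[r]),
                    class = "perttop_dummy_warning")
      else
        rlang::warn(sprintf("dummy atom %s: only %d bonded interaction(s) with unperturbed atoms (three nonredundant terms recommended)",
                            out$name[r], out$n_anchor_terms[r]),
                    class = "perttop_dummy_warning")
    }
  }
  out
}
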