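#' Simultaneous MCS search over three or more topologies
#'
#' Runs the MCS search over all states at once: the resulting match is the
#' minimum structure of which each individual compound is a substructure — a
#' common scaffold. By default any perturbation of bonded interactions is
#' forbidden (the perturbation is restricted to switching atom types,
#' charges and masses), which is the setting aimed at generating EDS
#' (enveloping distribution sampling) reference topologies; pass
#' `restrict_bonded = FALSE` to allow bonded perturbations as in the
#' pairwise search.
#'
#' @param states List of `fftop` objects (N >= 2; N = 2 reduces exactly to
#'   the pairwise search under the same options).
#' @param options A [search_options()]; `enumerate_all_best` defaults to off
#'   here.
#' @param spec A [score_spec()]; bonded categories are added to its `forbid`
#'   list when `restrict_bonded` is on.
#' @param restrict_bonded Forbid bonded-term perturbations (default).
#' @return The best `match_solution`, or an object of class
#'   `perttop_no_solution` when no cross-state atom match is feasible under
#'   the forbids.
#' @export
multistate_search <- function(states, options = search_options(),
                              spec = score_spec(), restrict_bonded = TRUE) {
  if (length(states) < 2L)
    rlang::abort("need at least two states", class = "perttop_validation_error")
  if (restrict_bonded)
    spec$forbid <- union(spec$forbid,
                         c("bond", "angle", "dihedral", "improper", "multiplicity",
                           "make_break"))
  if (is.null(options$enumerate_all_best)) options$enumerate_all_best <- FALSE
  sols <- mcs_search(states, options, spec)
  if (!length(sols))
    return(structure(list(reason = "search returned no feasible solution"),
                     class = "perttop_no_solution"))
  sol <- sols[[1]]
  if (!any(rowSums(!is.na(sol$matches)) >= 2L))
    return(structure(list(reason = "no cross-state atom match is feasible under the active forbids"),
                     class = "perttop_no_solution"))
  sol
}

#' @export
print.perttop_no_solution <- function(x, ...) {
  cat("<no solution:", x$reason, ">\n")
  invisible(x)
}

#' Build an EDS reference topology from a multistate solution
#'
#' A single union topology representing all states by switching atom types:
#' per-state type, charge and mass for every union atom, dummy designations
#' where a state lacks the atom, and one shared set of bonded terms (the
#' solution must not contain any bonded-term perturbation; dummy-region
#' terms keep their real-state parameters in every state).
#'
#' @param sol A complete multistate `match_solution`.
#' @param dummy_type Atom-type name for dummy-state atoms.
#' @return Object of class `eds_topology`.
#' @export
build_eds_topology <- function(sol, dummy_type = "DUM") {
  if (inherits(sol, "perttop_no_solution"))
    rlang::abort("cannot build an EDS topology from a no-solution result",
                 class = "perttop_validation_error")
  if (!isTRUE(sol$complete))
    rlang::abort("solution is not complete", class = "perttop_validation_error")
  bd <- solution_breakdown(sol$states, sol$matches, sol$options, detail = TRUE)
  bonded <- c("bond", "angle", "dihedral", "improper", "multiplicity", "make_break")
  viol <- bd$details[bd$details$category %in% bonded, , drop = FALSE]
  if (nrow(viol))
    rlang::abort(sprintf("solution contains bonded-term perturbations: %s (%s)",
                         viol$category[1], viol$atoms[1]),
                 class = "perttop_validation_error")
  ns <- length(sol$states)
  mat <- sol$matches
  ord <- do.call(order, c(lapply(seq_len(ns), function(s) is.na(mat[, s])),
                          lapply(seq_len(ns), function(s) mat[, s])))
  mat <- mat[ord, , drop = FALSE]
  nu <- nrow(mat)
  invs <- lapply(seq_len(ns), function(s) {
    inv <- rep(NA_integer_, nrow(sol$states[[s]]$atoms))
    inv[mat[!is.na(mat[, s]), s]] <- which(!is.na(mat[, s]))
    inv
  })
  types <- charges <- masses <- matrix(NA, nu, ns)
  types <- matrix(NA_character_, nu, ns)
  dummy <- is.na(mat)
  first_real <- apply(mat, 1L, function(r) which(!is.na(r))[1])
  for (s in seq_len(ns)) {
    re <- !is.na(mat[, s])
    types[re, s] <- sol$states[[s]]$atoms$type_id[mat[re, s]]
    charges[re, s] <- sol$states[[s]]$atoms$charge[mat[re, s]]
    masses[re, s] <- sol$states[[s]]$atoms$mass[mat[re, s]]
  }
  names_mat <- matrix(NA_character_, nu, ns)
  cg_mat <- matrix(NA_integer_, nu, ns)
  for (s in seq_len(ns)) {
    re <- !is.na(mat[, s])
    names_mat[re, s] <- sol$states[[s]]$atoms$name[mat[re, s]]
    cg_mat[re, s] <- as.integer(sol$states[[s]]$atoms$charge_group[mat[re, s]])
  }
  real_mass <- vapply(seq_len(nu), function(u) masses[u, first_real[u]], numeric(1))
  for (s in seq_len(ns)) {
    types[dummy[, s], s] <- dummy_type
    charges[dummy[, s], s] <- 0
    masses[dummy[, s], s] <- real_mass[dummy[, s]]
    names_mat[dummy[, s], s] <-
      names_mat[cbind(which(dummy[, s]), first_real[dummy[, s]])]
    cg_mat[dummy[, s], s] <-
      cg_mat[cbind(which(dummy[, s]), first_real[dummy[, s]])]
  }
  name <- names_mat[cbind(seq_len(nu), first_real)]
  cg <- cg_mat[cbind(seq_len(nu), first_real)]
  params <- do.call(c, lapply(seq_len(ns), function(s)
    stats::setNames(sol$states[[s]]$params,
                    paste0("S", s, ":", names(sol$states[[s]]$params)))))
  merge_terms <- function(kind, arity) {
    keyf <- switch(kind, bonds = key2, angles = key3, impropers = key4s,
                   dihedrals = key4)
    seen <- new.env(parent = emptyenv())
    order_keys <- character(); recs <- list()
    for (s in seq_len(ns)) {
      tb_x <- sol$states[[s]][[kind]]
      for (r in seq_len(nrow(tb_x))) {
        av <- invs[[s]][as.integer(tb_x[r, seq_len(arity)])]
        kk <- do.call(keyf, as.list(av))
        if (is.null(get0(kk, envir = seen))) {
          assign(kk, TRUE, envir = seen)
          recs[[length(recs) + 1L]] <-
            list(atoms = av, ref = paste0("S", s, ":", tb_x$ref[r]))
        }
      }
    }
    if (!length(recs)) {
      cols <- c("i", "j", "k", "l")[seq_len(arity)]
      out <- tibble::as_tibble(stats::setNames(rep(list(integer()), arity), cols))
      out$ref <- character()
      return(out)
    }
    idx <- t(vapply(recs, function(x) as.integer(x$atoms), integer(arity)))
    out <- tibble::as_tibble(stats::setNames(as.data.frame(idx),
                                             c("i", "j", "k", "l")[seq_len(arity)]))
    out$ref <- vapply(recs, function(x) x$ref, character(1))
    out
  }
  excl <- lapply(seq_len(ns), function(s) {
    e <- vector("list", nu)
    inv <- invs[[s]]
    for (u in seq_len(nu)) e[[u]] <- integer()
    for (a in seq_along(sol$states[[s]]$exclusions)) {
      u <- inv[a]
      if (!is.na(u)) {
        m <- inv[sol$states[[s]]$exclusions[[a]]]
        e[[u]] <- sort(m[!is.na(m)])
      }
    }
    e
  })
  p14 <- lapply(seq_len(ns), function(s) {
    p <- sol$states[[s]]$pairs14
    inv <- invs[[s]]
    if (!nrow(p)) return(tibble::tibble(i = integer(), j = integer()))
    ui <- inv[p$i]; uj <- inv[p$j]
    keep <- !is.na(ui) & !is.na(uj)
    tibble::tibble(i = pmin(ui[keep], uj[keep]), j = pmax(ui[keep], uj[keep]))
  })
  structure(list(
    n_states = ns,
    atoms = tibble::tibble(index = seq_len(nu), name = name, charge_group = cg),
    orig = mat, types = types, charges = charges, masses = masses,
    names_mat = names_mat, cg_mat = cg_mat,
    dummy = dummy,
    bonds = merge_terms("bonds", 2L), angles = merge_terms("angles", 3L),
    dihedrals = merge_terms("dihedrals", 4L),
    impropers = merge_terms("impropers", 4L),
    params = params, excl = excl, p14 = p14,
    state_labels = vapply(sol$states, function(s) s$title, character(1)),
    dummy_type = dummy_type, solution = sol
  ), class = "eds_topology")
}

#' @export
print.eds_topology <- function(x, ...) {
  cat(sprintf("<eds_topology: %d states (%s), %d union atoms, %d dummy designations>\n",
              x$n_states, paste(x$state_labels, collapse = ", "),
              nrow(x$atoms), sum(x$dummy)))
  invisible(x)
}

#' @rdname restrict_state
#' @export
restrict_state.eds_topology <- function(x, state) {
  s <- as.integer(state)
  if (s < 1L || s > x$n_states)
    rlang::abort("state index out of range", class = "perttop_validation_error")
  keep <- which(!x$dummy[, s])
  ord <- order(x$orig[keep, s])
  sel <- keep[ord]
  newidx <- rep(NA_integer_, nrow(x$atoms))
  newidx[sel] <- seq_along(sel)
  atoms <- tibble::tibble(name = x$names_mat[sel, s], type_id = x$types[sel, s],
                          mass = x$masses[sel, s], charge = x$charges[sel, s],
                          charge_group = x$cg_mat[sel, s])
  remap <- function(tb, arity) {
    if (!nrow(tb)) return(NULL)
    idx <- as.matrix(tb[, seq_len(arity)])
    ok <- apply(idx, 1L, function(v) all(!is.na(newidx[v])))
    if (!any(ok)) return(NULL)
    out <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(newidx[as.matrix(tb[ok, seq_len(arity)])], ncol = arity)),
      c("i", "j", "k", "l")[seq_len(arity)]))
    out$ref <- tb$ref[ok]
    out
  }
  excl <- lapply(x$excl[[s]][sel], function(e) newidx[e][!is.na(newidx[e])])
  p14 <- x$p14[[s]]
  p14 <- if (nrow(p14)) {
    k14 <- !is.na(newidx[p14$i]) & !is.na(newidx[p14$j])
    tibble::tibble(i = newidx[p14$i[k14]], j = newidx[p14$j[k14]])
  } else NULL
  ff_topology(atoms, bonds = remap(x$bonds, 2L), angles = remap(x$angles, 3L),
              dihedrals = remap(x$dihedrals, 4L), impropers = remap(x$impropers, 4L),
              params = x$params, exclusions = excl, pairs14 = p14,
              dialect = "gromos", title = x$state_labels[s])
}

#' Pairwise perturbation topologies from one multistate solution
#'
#' Extracts all N(N-1)/2 pairwise perturbation topologies from a multistate
#' match, each consistent with the shared mapping — composing the atom maps
#' around any cycle of states gives the identity on commonly matched atoms,
#' so the set defines a closed thermodynamic cycle.
#'
#' @param sol A complete multistate `match_solution` over N >= 3 states.
#' @param dummy_type Atom-type name for dummy-state atoms.
#' @return Named list of `pert_topology` objects (`"1-2"`, `"1-3"`, ...).
#' @export
pairwise_from_multistate <- function(sol, dummy_type = "DUM") {
  if (inherits(sol, "perttop_no_solution"))
    rlang::abort("cannot extract pairs from a no-solution result",
                 class = "perttop_validation_error")
  ns <- length(sol$states)
  if (ns < 3L)
    rlang::abort("need at least three states; use the pairwise search for two",
                 class = "perttop_validation_error")
  out <- list()
  for (s in seq_len(ns - 1L)) for (t in (s + 1L):ns)
    out[[paste0(s, "-", t)]] <- build_pert_topology(sol, s, t, dummy_type)
  out
}
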