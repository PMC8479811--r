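#' Options controlling the MCS search
#'
#' The matching policies the search enforces, independent of the penalty
#' weights.
#'
#' Ring matching (`ring_policy`): `"complete_individual_rings"` (default)
#' allows partial matches of polycyclic systems in which each individual ring
#' is either matched completely or not at all — only fused rings participate
#' in such partial polycyclic matches, bridged systems match all-or-nothing,
#' spiro rings are independent; `"complete_only"` requires the whole
#' (poly)cyclic system to match completely or not at all.
#'
#' Ring-to-nonring matching (`ring_nonring_policy`): at most two atoms that
#' share a bond (default), at most one atom, or no match at all. The same
#' budget governs partial matches between two rings for which neither a
#' complete nor a fused-partial correspondence exists.
#'
#' Dihedral matching (`dihedral_match`): `"all_four_atoms"` pairs a dihedral
#' only with the dihedral on exactly the four mapped atoms (preferred when
#' dihedrals are generated exhaustively from connectivity);
#' `"middle_two_atoms"` pairs dihedrals that share the mapped central bond
#' (preferred when one dihedral is defined per rotatable bond).
#'
#' Creating/removing bonds is never allowed; `allow_make_break_bonded`
#' optionally permits creating/removing other bonded terms (mainly improper
#' dihedrals). `allow_multiplicity_change` permits perturbing the
#' multiplicity of proper dihedrals.
#'
#' @param ring_policy Ring-to-ring policy (see Details).
#' @param ring_nonring_policy Ring-to-nonring atom budget.
#' @param dihedral_match Dihedral pairing procedure.
#' @param allow_multiplicity_change Allow dihedral-multiplicity perturbation.
#' @param allow_make_break_bonded Allow creation/removal of angles and
#'   (proper/improper) dihedrals; never applies to bonds.
#' @param max_solutions Cap on the number of equal-score solutions returned.
#' @param enumerate_all_best Enumerate every best-scoring solution (default:
#'   on for pairwise searches, off for multistate).
#' @param node_budget Abort the search with a diagnostic after this many node
#'   expansions (subgraph matching is exponential in the worst case).
#' @param prune Use the admissible lower bound to prune the enumeration;
#'   disabling it never changes the best score, only the runtime.
#' @return Object of class `search_options`.
#' @export
search_options <- function(ring_policy = c("complete_individual_rings", "complete_only"),
                           ring_nonring_policy = c("two_bonded_atoms", "one_atom", "none"),
                           dihedral_match = c("all_four_atoms", "middle_two_atoms"),
                           allow_multiplicity_change = FALSE,
                           allow_make_break_bonded = FALSE,
                           max_solutions = 100L,
                           enumerate_all_best = NULL,
                           node_budget = 500000L,
                           prune = TRUE) {
  structure(list(
    ring_policy = match.arg(ring_policy),
    ring_nonring_policy = match.arg(ring_nonring_policy),
    dihedral_match = match.arg(dihedral_match),
    allow_multiplicity_change = isTRUE(allow_multiplicity_change),
    allow_make_break_bonded = isTRUE(allow_make_break_bonded),
    max_solutions = as.integer(max_solutions),
    enumerate_all_best = enumerate_all_best,
    node_budget = as.integer(node_budget),
    prune = isTRUE(prune)
  ), class = "search_options")
}

new_match_solution <- function(states, mat, options, spec = score_spec(),
                               complete = TRUE) {
  sol <- structure(list(states = states, matches = mat, options = options,
                        complete = complete, score = NULL,
                        perturbed_terms = NULL),
                   class = "match_solution")
  ev <- evaluate_solution(sol, spec)
  sol$score <- ev[c("total", "breakdown", "key", "lower_bound")]
  sol$perturbed_terms <- ev$details[ev$details$category != "dihedral_matched", ,
                                    drop = FALSE]
  sol
}

#' @export
print.match_solution <- function(x, ...) {
  mat <- x$matches
  nreal <- sum(rowSums(!is.na(mat)) >= 2L)
  cat(sprintf("<match_solution: %d states, %d tuples (%d cross-state matches, %d dummy entries)>\n",
              ncol(mat), nrow(mat), nreal, sum(is.na(mat))))
  cat(sprintf("  score total: %s  breakdown: %s\n", format(x$score$total),
              paste(names(x$score$breakdown)[x$score$breakdown > 0],
                    x$score$breakdown[x$score$breakdown > 0],
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Initial candidate atom pairs
#'
#' The search is seeded from the list of all available cross-state atom
#' tuples: for two states of n and m atoms this is the full n x m pair list;
#' for more states, every combination anchored on the first state.
#'
#' @param states List of at least two `fftop` objects.
#' @return Tibble with one column per state.
#' @export
initial_pairs <- function(states) {
  if (length(states) < 2L)
    rlang::abort("need at least two states", class = "perttop_validation_error")
  lapply(states, validate_fftop)
  grids <- lapply(states, function(s) seq_len(nrow(s$atoms)))
  out <- tibble::as_tibble(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE))
  out <- out[, rev(seq_along(states))]
  names(out) <- paste0("state", seq_along(states))
  out[do.call(order, as.list(out)), ]
}

# ---- internal engine ---------------------------------------------------

engine_env <- function(states, options, spec) {
  ns <- length(states)
  graphs <- lapply(states, build_graph)
  rings <- lapply(graphs, perceive_rings)
  e <- new.env(parent = emptyenv())
  e$states <- states; e$options <- options; e$spec <- spec
  e$graphs <- graphs; e$rings <- rings
  e$ring_atom <- lapply(rings, function(rs) lengths(rs$membership) > 0L)
  e$sizes <- vapply(states, function(s) nrow(s$atoms), integer(1))
  e$nmax <- sum(e$sizes)
  e$mat <- matrix(NA_integer_, nrow = e$nmax, ncol = ns)
  e$nrows <- 0L
  e$assigned <- lapply(states, function(s) rep(FALSE, nrow(s$atoms)))
  e$rowof <- lapply(states, function(s) rep(NA_integer_, nrow(s$atoms)))
  e$real_matched <- lapply(states, function(s) rep(FALSE, nrow(s$atoms)))
  e$nassigned <- integer(ns)
  e$counts <- empty_counts() + 0
  e$mult_viol <- 0L
  e$deltas <- vector("list", e$nmax)
  e$best_key <- NULL
  e$best <- list()
  e$nodes <- 0L
  # under the middle-two-atoms procedure dihedral pairing is only fixed at
  # completion; the incremental bookkeeping then skips dihedrals
  e$skip_dihedrals <- !identical(options$dihedral_match, "all_four_atoms")
  e$fast <- lapply(states, engine_fast_state)
  e
}

# canonical numeric code of a term's atom tuple (base B = n_atoms + 1)
enc_code <- function(v, B, kind) {
  if (kind == "bonds") {
    if (v[1] > v[2]) v <- v[2:1]
    return(v[1] * B + v[2])
  }
  if (kind == "angles") {
    if (v[1] > v[3]) v <- v[3:1]
    return((v[1] * B + v[2]) * B + v[3])
  }
  if (kind == "impropers") v <- sort(v)
  else if (v[1] > v[4] || (v[1] == v[4] && v[2] > v[3])) v <- v[4:1]
  ((v[1] * B + v[2]) * B + v[3]) * B + v[4]
}

# plain-vector/matrix mirrors of a topology for the hot search path,
# with parameters resolved up front and per-atom term incidence lists
engine_fast_state <- function(top) {
  kinds <- list(bonds = 2L, angles = 3L, dihedrals = 4L, impropers = 4L)
  n <- nrow(top$atoms)
  B <- n + 1
  adj <- matrix(FALSE, n, n)
  if (nrow(top$bonds)) {
    adj[cbind(top$bonds$i, top$bonds$j)] <- TRUE
    adj[cbind(top$bonds$j, top$bonds$i)] <- TRUE
  }
  out <- list(type = top$atoms$type_id, mass = top$atoms$mass,
              charge = top$atoms$charge, B = B, adj = adj,
              terms = list(), incid = list())
  for (kn in names(kinds)) {
    arity <- kinds[[kn]]
    tb <- top[[kn]]
    m <- if (nrow(tb)) as.matrix(tb[, seq_len(arity)]) else
      matrix(integer(), 0L, arity)
    pars <- lapply(seq_len(nrow(m)), function(r) {
      p <- ff_params(top, tb$ref[r])
      list(values = p$values,
           mult = if (is.null(p$mult)) NA_integer_ else p$mult)
    })
    codes <- vapply(seq_len(nrow(m)), function(r) enc_code(m[r, ], B, kn),
                    numeric(1))
    incid <- rep(list(integer()), n)
    for (r in seq_len(nrow(m))) for (a in m[r, ])
      incid[[a]] <- c(incid[[a]], r)
    out$terms[[kn]] <- list(idx = m, pars = pars, arity = arity, codes = codes)
    out$incid[[kn]] <- incid
  }
  out
}

vals_equal <- function(a, b, rel_tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= rel_tol * pmax(abs(a), abs(b), 1))
}

cur_mat <- function(e) e$mat[seq_len(e$nrows), , drop = FALSE]

matched_real_atoms <- function(e, s) which(e$real_matched[[s]])

# bond-preservation check of a new tuple against all existing rows
tuple_bond_ok <- function(e, tup) {
  real <- which(!is.na(tup))
  if (length(real) < 2L || !e$nrows) return(TRUE)
  for (r in seq_len(e$nrows)) {
    for (ii in seq_along(real)[-length(real)]) for (jj in (ii + 1L):length(real)) {
      s <- real[ii]; t <- real[jj]
      ms <- e$mat[r + (s - 1L) * e$nmax]
      mt <- e$mat[r + (t - 1L) * e$nmax]
      if (is.na(ms) || is.na(mt)) next
      if (e$fast[[s]]$adj[tup[s], ms] != e$fast[[t]]$adj[tup[t], mt]) return(FALSE)
    }
  }
  TRUE
}

# incremental ring policy screen for a candidate tuple: the ring-to-nonring
# atom budget, applied in both directions for every state pair in the tuple
tuple_ring_ok <- function(e, tup) {
  real <- which(!is.na(tup))
  if (length(real) < 2L) return(TRUE)
  pol <- e$options$ring_nonring_policy
  m <- cur_mat(e)
  for (ii in seq_along(real)[-length(real)]) for (jj in (ii + 1L):length(real)) {
    s <- real[ii]; t <- real[jj]
    for (dir in 1:2) {
      if (dir == 2L) { tmp <- s; s <- t; t <- tmp }
      a <- tup[s]; b <- tup[t]
      if (!e$ring_atom[[s]][a] || e$ring_atom[[t]][b]) next
      # ring atom matched to a nonring atom
      if (pol == "none") return(FALSE)
      for (rid in e$rings[[s]]$membership[[a]]) {
        ring <- e$rings[[s]]$rings[[rid]]
        prev <- integer()
        if (nrow(m)) {
          both <- !is.na(m[, s]) & !is.na(m[, t])
          for (r in which(both)) {
            aa <- m[r, s]
            if (aa %in% ring && !e$ring_atom[[t]][m[r, t]])
              prev <- c(prev, aa)
          }
        }
        if (pol == "one_atom" && length(prev) >= 1L) return(FALSE)
        if (pol == "two_bonded_atoms") {
          if (length(prev) >= 2L) return(FALSE)
          if (length(prev) == 1L && !e$fast[[s]]$adj[a, prev]) return(FALSE)
        }
      }
    }
  }
  TRUE
}

# full ring-policy validation of a complete solution (per state pair):
# every ring is completely matched, untouched, or — under the default policy
# — partially covered only through atoms shared with a completely matched
# fused sibling ring, with any remaining partially matched atoms subject to
# the ring-to-nonring budget
validate_ring_policy_full <- function(states, mat, rings, graphs, opts) {
  ns <- length(states)
  budget <- switch(opts$ring_nonring_policy,
                   two_bonded_atoms = 2L, one_atom = 1L, none = 0L)
  for (s in seq_len(ns)) for (t in seq_len(ns)) {
    if (s == t) next
    both <- !is.na(mat[, s]) & !is.na(mat[, t])
    if (!any(both)) next
    map <- rep(NA_integer_, nrow(states[[s]]$atoms))
    map[mat[both, s]] <- mat[both, t]
    rs <- rings[[s]]; rt <- rings[[t]]
    is_ring_t <- lengths(rt$membership) > 0L
    nr <- length(rs$rings)
    if (!nr) next
    complete_ring <- vapply(seq_len(nr), function(id) {
      ring <- rs$rings[[id]]
      all(!is.na(map[ring])) && all(is_ring_t[map[ring]])
    }, logical(1))
    for (id in seq_len(nr)) {
      ring <- rs$rings[[id]]
      matched <- ring[!is.na(map[ring])]
      if (!length(matched) || complete_ring[id]) next
      if (opts$ring_policy == "complete_only") return(FALSE)
      # atoms excused by a completely matched fused sibling
      allowance <- integer()
      rel <- rs$relations
      sib <- c(rel$ring2[rel$ring1 == id & rel$relation == "fused"],
               rel$ring1[rel$ring2 == id & rel$relation == "fused"])
      for (sb in sib) if (complete_ring[sb])
        allowance <- union(allowance, intersect(ring, rs$rings[[sb]]))
      partial <- setdiff(matched, allowance)
      if (length(partial) > budget) return(FALSE)
      if (length(partial) == 2L &&
          !graph_has_edge(graphs[[s]], partial[1], partial[2])) return(FALSE)
    }
  }
  TRUE
}

# candidate tuples for the next anchor atom, sorted cheap-first
anchor_candidates <- function(e, a) {
  ns <- length(e$states)
  opt_lists <- vector("list", ns)
  opt_lists[[1]] <- a
  for (s in 2:ns) {
    mr <- matched_real_atoms(e, s)
    avail <- if (length(mr)) {
      setdiff(first_neighbors(e$graphs[[s]], mr), which(e$assigned[[s]]))
    } else {
      which(!e$assigned[[s]])
    }
    opt_lists[[s]] <- c(avail, NA_integer_)
  }
  tuples <- as.matrix(expand.grid(opt_lists, KEEP.OUT.ATTRS = FALSE))
  colnames(tuples) <- NULL
  keep <- logical(nrow(tuples))
  for (r in seq_len(nrow(tuples))) {
    tup <- as.integer(tuples[r, ])
    keep[r] <- tuple_bond_ok(e, tup) && tuple_ring_ok(e, tup)
  }
  tuples <- tuples[keep, , drop = FALSE]
  if (!nrow(tuples)) return(tuples)
  # sort: fewest dummies first, then fewest atom-level mismatches, then index
  nna <- rowSums(is.na(tuples))
  mism <- vapply(seq_len(nrow(tuples)), function(r) {
    tup <- as.integer(tuples[r, ])
    real <- which(!is.na(tup))
    mm <- 0L
    if (length(real) >= 2L)
      for (ii in seq_along(real)[-length(real)]) for (jj in (ii + 1L):length(real)) {
        s <- real[ii]; t <- real[jj]
        fs <- e$fast[[s]]; ft <- e$fast[[t]]
        mm <- mm + (fs$type[tup[s]] != ft$type[tup[t]]) +
          !masses_equal(fs$mass[tup[s]], ft$mass[tup[t]]) +
          !charges_equal(fs$charge[tup[s]], ft$charge[tup[t]])
      }
    mm
  }, integer(1))
  ordargs <- c(list(nna, mism),
               lapply(seq_len(ncol(tuples)), function(cc) tuples[, cc]))
  tuples[do.call(order, ordargs), , drop = FALSE]
}

# Add one tuple and incrementally update the penalty counts: atom-level
# mismatches within the tuple, and every bonded term that just became fully
# assigned in its home state, compared against its image in each other state
# (counted once, from the lower-index state's term; image-missing terms are
# created/removed). The delta is recorded so backtracking is exact.
push_row <- function(e, tup) {
  e$nrows <- e$nrows + 1L
  rw <- e$nrows
  e$mat[rw, ] <- tup
  real <- which(!is.na(tup))
  for (s in real) {
    e$assigned[[s]][tup[s]] <- TRUE
    e$rowof[[s]][tup[s]] <- rw
    e$nassigned[s] <- e$nassigned[s] + 1L
  }
  dc <- empty_counts() + 0
  dmv <- 0L
  dc["dummy"] <- length(tup) - length(real)
  if (length(real) >= 2L) {
    for (s in real) e$real_matched[[s]][tup[s]] <- TRUE
    for (ii in seq_along(real)[-length(real)]) for (jj in (ii + 1L):length(real)) {
      s <- real[ii]; t <- real[jj]
      fs <- e$fast[[s]]; ft <- e$fast[[t]]
      a <- tup[s]; b <- tup[t]
      if (fs$type[a] != ft$type[b]) dc["atom_type"] <- dc["atom_type"] + 1
      if (!masses_equal(fs$mass[a], ft$mass[b])) dc["mass"] <- dc["mass"] + 1
      if (!charges_equal(fs$charge[a], ft$charge[b])) dc["charge"] <- dc["charge"] + 1
    }
  }
  ns <- ncol(e$mat)
  for (s in real) {
    a <- tup[s]
    fs <- e$fast[[s]]
    for (kn in names(fs$terms)) {
      if (kn == "dihedrals" && e$skip_dihedrals) next
      trm <- fs$terms[[kn]]
      for (tid in fs$incid[[kn]][[a]]) {
        av <- trm$idx[tid, ]
        if (!all(e$assigned[[s]][av])) next
        rows_ <- e$rowof[[s]][av]
        for (t in seq_len(ns)) {
          if (t == s) next
          bv <- e$mat[rows_ + (t - 1L) * e$nmax]
          if (anyNA(bv)) next
          ft <- e$fast[[t]]
          oid <- match(enc_code(bv, ft$B, kn), ft$terms[[kn]]$codes)
          if (s < t) {
            if (is.na(oid)) { dc["make_break"] <- dc["make_break"] + 1; next }
            pa <- trm$pars[[tid]]; pb <- ft$terms[[kn]]$pars[[oid]]
            if (kn == "dihedrals" && !identical(pa$mult, pb$mult)) {
              if (isTRUE(e$options$allow_multiplicity_change))
                dc["multiplicity"] <- dc["multiplicity"] + 1
              else dmv <- dmv + 1L
            }
            if (!vals_equal(pa$values, pb$values)) {
              cat_kind <- substr(kn, 1L, nchar(kn) - 1L)
              dc[cat_kind] <- dc[cat_kind] + 1
            }
          } else if (is.na(oid)) {
            dc["make_break"] <- dc["make_break"] + 1
          }
        }
      }
    }
  }
  e$counts <- e$counts + dc
  e$mult_viol <- e$mult_viol + dmv
  e$deltas[[rw]] <- list(dc = dc, dmv = dmv)
}

pop_row <- function(e) {
  rw <- e$nrows
  d <- e$deltas[[rw]]
  tup <- e$mat[rw, ]
  e$counts <- e$counts - d$dc
  e$mult_viol <- e$mult_viol - d$dmv
  for (s in which(!is.na(tup))) {
    e$assigned[[s]][tup[s]] <- FALSE
    e$rowof[[s]][tup[s]] <- NA_integer_
    e$real_matched[[s]][tup[s]] <- FALSE
    e$nassigned[s] <- e$nassigned[s] - 1L
  }
  e$mat[rw, ] <- NA_integer_
  e$deltas[rw] <- list(NULL)
  e$nrows <- rw - 1L
}

engine_violated <- function(e) {
  e$mult_viol > 0L ||
    (e$counts[["make_break"]] > 0 && !isTRUE(e$options$allow_make_break_bonded)) ||
    (length(e$spec$forbid) && any(e$counts[e$spec$forbid] > 0))
}

# Minimal number of dummy entries any completion must still add. Every
# future search row carries a real anchor-state atom and consumes at most
# one atom per state; atoms left over in the other states end up in
# single-atom rows with N-1 dummy entries each. Both facts bound the count
# from below without excluding any reachable completion.
future_dummy_min <- function(rem) {
  ns <- length(rem)
  r1 <- rem[1]
  extra <- 0
  for (s in 2:ns)
    extra <- extra + max(0, r1 - rem[s]) + (ns - 1) * max(0, rem[s] - r1)
  extra
}

engine_lb_key <- function(e) {
  counts <- e$counts
  counts["dummy"] <- counts["dummy"] + future_dummy_min(e$sizes - e$nassigned)
  score_key(counts, e$spec)
}

complete_current <- function(e) {
  ns <- length(e$states)
  rows <- list()
  n_left <- 0L
  for (s in seq_len(ns)) {
    for (a in which(!e$assigned[[s]])) {
      tup <- rep(NA_integer_, ns); tup[s] <- a
      rows[[length(rows) + 1L]] <- tup
      n_left <- n_left + 1L
    }
  }
  full <- rbind(cur_mat(e), do.call(rbind, c(rows, list(matrix(integer(), 0, ns)))))
  if (!validate_ring_policy_full(e$states, full, e$rings, e$graphs, e$options))
    return(invisible())
  if (e$skip_dihedrals) {
    # middle-two-atoms dihedral pairing is a completion-time computation
    bd <- solution_breakdown(e$states, full, e$options, partial = FALSE)
    if (length(bd$violations)) return(invisible())
    counts <- bd$counts
  } else {
    if (engine_violated(e)) return(invisible())
    counts <- e$counts
    counts["dummy"] <- counts["dummy"] + n_left * (ns - 1L)
  }
  key <- score_key(counts, e$spec)
  if (!is.finite(key[1])) return(invisible())
  if (is.null(e$best_key) || key_less(key, e$best_key)) {
    e$best_key <- key
    e$best <- list(full)
  } else if (key_equal(key, e$best_key)) {
    if (isTRUE(e$enumerate_all_best) && length(e$best) < e$options$max_solutions)
      e$best[[length(e$best) + 1L]] <- full
  }
  invisible()
}

search_step <- function(e) {
  unassigned1 <- which(!e$assigned[[1]])
  if (!length(unassigned1)) { complete_current(e); return(invisible()) }
  mr1 <- matched_real_atoms(e, 1L)
  if (length(mr1)) {
    frontier <- intersect(first_neighbors(e$graphs[[1]], mr1), unassigned1)
    if (!length(frontier)) { complete_current(e); return(invisible()) }
    a <- min(frontier)
  } else {
    a <- min(unassigned1)
  }
  cands <- anchor_candidates(e, a)
  for (r in seq_len(nrow(cands))) {
    tup <- as.integer(cands[r, ])
    e$nodes <- e$nodes + 1L
    if (e$nodes > e$options$node_budget)
      rlang::abort(sprintf("node expansion budget (%d) exceeded; the MCS search space is too large for these inputs/options",
                           e$options$node_budget),
                   class = "perttop_budget_error")
    push_row(e, tup)
    skip <- engine_violated(e)
    if (!skip && e$options$prune && !is.null(e$best_key)) {
      lb <- engine_lb_key(e)
      if (key_less(e$best_key, lb)) skip <- TRUE
      else if (key_equal(e$best_key, lb) && !isTRUE(e$enumerate_all_best) &&
               length(e$best)) skip <- TRUE
    }
    if (!skip) search_step(e)
    pop_row(e)
  }
  invisible()
}

#' Maximum-common-substructure search over topologies
#'
#' Iterative branch-and-bound enumeration of common substructures of two or
#' more molecular topologies. Starting from the full cross-state pair list,
#' the current solution is grown by one atom tuple per step, candidates being
#' drawn from the first neighbours of the already-matched atoms in every
#' state (dummy matches are explicit candidates). Each added tuple updates
#' the penalty bookkeeping — nonmatching atom types, masses, charges and
#' bonded-term parameters as well as dummy matches all contribute — and an
#' admissible estimate of the minimal achievable score of the current branch
#' prunes the enumeration whenever it already exceeds the best enumerated
#' solution. Bonds are never created or removed across the match: a bond
#' between two matched tuples must exist in every state in which both atoms
#' are real.
#'
#' A solution is complete when every atom of every input topology is present
#' (matched to a real atom or explicitly to a dummy). The best-scoring
#' solutions are returned in a deterministic canonical order.
#'
#' @param states List of >= 2 `fftop` objects (the first is the anchor state
#'   for multistate tuple seeding).
#' @param options A [search_options()].
#' @param spec A [score_spec()].
#' @return List of complete `match_solution` objects with equal best score
#'   (a single one unless `enumerate_all_best`).
#' @export
mcs_search <- function(states, options = search_options(), spec = score_spec()) {
  if (length(states) < 2L)
    rlang::abort("need at least two states", class = "perttop_validation_error")
  lapply(states, validate_fftop)
  e <- engine_env(states, options, spec)
  e$enumerate_all_best <- if (is.null(options$enumerate_all_best))
    length(states) == 2L else isTRUE(options$enumerate_all_best)
  search_step(e)
  mats <- e$best
  sigs <- vapply(mats, solution_signature, character(1))
  mats <- mats[order(sigs)]
  lapply(mats, function(m) new_match_solution(states, m, options, spec))
}

# rebuild an engine environment positioned at a given partial solution
engine_at <- function(sol, spec = score_spec()) {
  e <- engine_env(sol$states, sol$options, spec)
  m <- sol$matches
  for (r in seq_len(nrow(m))) push_row(e, as.integer(m[r, ]))
  e
}

#' Candidate extensions of a partial solution
#'
#' Generates the list of allowed next atom matches for a partial solution:
#' tuples drawn from the first neighbours of the matched atoms in every
#' state, plus explicit dummy pairings, excluding candidates that violate
#' bond preservation or the ring policies, sorted so that extensions
#' estimated to lead to low-penalty completions come first.
#'
#' @param sol A partial `match_solution`.
#' @param options A [search_options()] (defaults to the solution's own).
#' @param spec A [score_spec()].
#' @return Tibble of candidate tuples, one column per state (NA = dummy);
#'   zero rows when every atom is already in the solution.
#' @export
expand_candidates <- function(sol, options = NULL, spec = score_spec()) {
  if (!is.null(options)) sol$options <- options
  e <- engine_at(sol, spec)
  unassigned1 <- which(!e$assigned[[1]])
  empty <- tibble::as_tibble(matrix(integer(), 0, length(sol$states),
                                    dimnames = list(NULL, paste0("state", seq_along(sol$states)))))
  if (!length(unassigned1)) return(empty)
  mr1 <- matched_real_atoms(e, 1L)
  if (length(mr1)) {
    frontier <- intersect(first_neighbors(e$graphs[[1]], mr1), unassigned1)
    if (!length(frontier)) return(empty)
    a <- min(frontier)
  } else a <- min(unassigned1)
  cands <- anchor_candidates(e, a)
  out <- tibble::as_tibble(cands, .name_repair = "minimal")
  names(out) <- paste0("state", seq_along(sol$states))
  out
}

#' Start an empty partial solution
#'
#' @param states List of `fftop` objects.
#' @param options A [search_options()].
#' @param spec A [score_spec()].
#' @return An empty (partial) `match_solution`.
#' @export
empty_solution <- function(states, options = search_options(), spec = score_spec()) {
  new_match_solution(states, matrix(NA_integer_, 0L, length(states)),
                     options, spec, complete = FALSE)
}

#' Add one atom match to a partial solution
#'
#' Validates the candidate tuple (atoms unmatched, bond preservation against
#' every existing tuple, connectivity through first neighbours, ring
#' policies) and returns the grown solution with its penalty bookkeeping
#' updated: newly determined bonded terms are compared across states and
#' atom-level mismatches recorded.
#'
#' @param sol A partial `match_solution`.
#' @param match Integer vector, one entry per state; NA marks a dummy match.
#' @param spec A [score_spec()].
#' @return The extended partial `match_solution`.
#' @export
add_match <- function(sol, match, spec = score_spec()) {
  match <- as.integer(match)
  if (length(match) != length(sol$states))
    rlang::abort("match must have one entry per state", class = "perttop_validation_error")
  if (all(is.na(match)))
    rlang::abort("a match needs at least one real atom", class = "perttop_validation_error")
  e <- engine_at(sol, spec)
  for (s in which(!is.na(match))) {
    if (match[s] < 1L || match[s] > nrow(sol$states[[s]]$atoms))
      rlang::abort("atom index out of range", class = "perttop_validation_error")
    if (e$assigned[[s]][match[s]])
      rlang::abort(sprintf("atom %d of state %d is already matched", match[s], s),
                   class = "perttop_validation_error")
  }
  if (!tuple_bond_ok(e, match))
    rlang::abort("match would create or remove a bond", class = "perttop_validation_error")
  if (!tuple_ring_ok(e, match))
    rlang::abort("match violates the ring policy", class = "perttop_validation_error")
  # connectivity: a real entry must neighbour the matched-real set of its state
  if (sum(!is.na(match)) >= 2L) {
    for (s in which(!is.na(match))) {
      mr <- matched_real_atoms(e, s)
      if (length(mr) && !match[s] %in% first_neighbors(e$graphs[[s]], mr))
        rlang::abort("match is not connected to the current solution",
                     class = "perttop_validation_error")
    }
  }
  new_match_solution(sol$states, rbind(sol$matches, match, deparse.level = 0),
                     sol$options, spec, complete = FALSE)
}

#' Ring-policy screen for a candidate extension
#'
#' Applies the incremental part of the ring matching rules to a candidate
#' tuple on top of a partial solution: the ring-to-nonring atom budget
#' (at most two bonded atoms / one atom / none) in both directions for every
#' state pair. The complete-ring rules are enforced on complete solutions.
#'
#' @param sol A partial `match_solution`.
#' @param match Candidate tuple (integer vector, NA = dummy).
#' @param options A [search_options()] (defaults to the solution's own).
#' @return TRUE if the extension is allowed.
#' @export
enforce_ring_policy <- function(sol, match, options = NULL) {
  if (!is.null(options)) sol$options <- options
  e <- engine_at(sol)
  tuple_ring_ok(e, as.integer(match))
}

#' Classify dihedral matches of a complete solution
#'
#' Runs the selected dihedral matching procedure over every state pair of a
#' complete solution and reports each proper dihedral's classification:
#' matched (parameters equal), perturbed (parameters differ), multiplicity
#' (multiplicity perturbed), or created/removed.
#'
#' @param sol A complete `match_solution`.
#' @param options A [search_options()] (defaults to the solution's own).
#' @return Tibble with columns `category`, `states`, `atoms`, `info`.
#' @export
match_dihedrals <- function(sol, options = NULL) {
  if (!is.null(options)) sol$options <- options
  bd <- solution_breakdown(sol$states, sol$matches, sol$options,
                           partial = FALSE, detail = TRUE)
  d <- bd$details
  keep <- d$category %in% c("dihedral", "dihedral_matched", "multiplicity") |
    (d$category == "make_break" & grepl("dihedral", d$info))
  d <- d[keep, , drop = FALSE]
  d$category[d$category == "make_break"] <- "created_removed"
  d$category[d$category == "dihedral_matched"] <- "matched"
  d$category[d$category == "dihedral"] <- "perturbed"
  d
}
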