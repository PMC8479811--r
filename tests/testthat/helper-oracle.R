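# Independent oracles used across the test files.
#
# brute_force_best(): exhaustive enumeration of every complete pairwise
# solution — all injective, bond-preserving, per-state-connected mappings
# A -> B plus dummies, validated against the ring policies post hoc and
# scored through evaluate_solution(). Shares no code with the search engine's
# enumeration, ordering or pruning.

bf_connected <- function(adj, atoms) {
  if (length(atoms) <= 1L) return(TRUE)
  seen <- atoms[1]
  queue <- atoms[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- intersect(adj[[v]], atoms)
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  length(seen) == length(atoms)
}

# ring-policy validation written independently of the engine's validator
bf_ring_ok <- function(stA, stB, map, opts, gA, gB, rA, rB) {
  budget <- switch(opts$ring_nonring_policy,
                   two_bonded_atoms = 2L, one_atom = 1L, none = 0L)
  check_side <- function(rs, rt, gs, map_st) {
    is_ring_t <- lengths(rt$membership) > 0L
    nr <- length(rs$rings)
    if (!nr) return(TRUE)
    complete <- vapply(seq_len(nr), function(id) {
      ring <- rs$rings[[id]]
      all(!is.na(map_st[ring])) && all(is_ring_t[map_st[ring]])
    }, logical(1))
    for (id in seq_len(nr)) {
      ring <- rs$rings[[id]]
      matched <- ring[!is.na(map_st[ring])]
      if (!length(matched) || complete[id]) next
      if (opts$ring_policy == "complete_only") return(FALSE)
      allow <- integer()
      rel <- rs$relations
      sib <- c(rel$ring2[rel$ring1 == id & rel$relation == "fused"],
               rel$ring1[rel$ring2 == id & rel$relation == "fused"])
      for (sb in sib) if (complete[sb])
        allow <- union(allow, intersect(ring, rs$rings[[sb]]))
      extra <- setdiff(matched, allow)
      if (length(extra) > budget) return(FALSE)
      if (length(extra) == 2L && !(extra[2] %in% gs$adj[[extra[1]]])) return(FALSE)
    }
    TRUE
  }
  mapA <- map
  mapB <- rep(NA_integer_, nrow(stB$atoms))
  mapB[map[!is.na(map)]] <- which(!is.na(map))
  check_side(rA, rB, gA, mapA) && check_side(rB, rA, gB, mapB)
}

bf_solution <- function(stA, stB, map, opts, spec) {
  rows <- list()
  for (a in seq_along(map)) rows[[a]] <- c(a, map[a])
  for (b in setdiff(seq_len(nrow(stB$atoms)), map[!is.na(map)]))
    rows[[length(rows) + 1L]] <- c(NA_integer_, b)
  mat <- do.call(rbind, rows)
  sol <- structure(list(states = list(stA, stB), matches = mat, options = opts,
                        complete = TRUE), class = "match_solution")
  sol
}

# enumerate all valid mappings; returns list(key = best key, sigs = canonical
# signatures of all best complete solutions)
brute_force_best <- function(stA, stB, opts = search_options(),
                             spec = score_spec()) {
  gA <- build_graph(stA); gB <- build_graph(stB)
  rA <- perceive_rings(gA); rB <- perceive_rings(gB)
  nA <- nrow(stA$atoms); nB <- nrow(stB$atoms)
  states <- list(stA, stB)
  best <- NULL
  best_sigs <- character()
  map <- rep(NA_integer_, nA)
  used <- rep(FALSE, nB)
  consider <- function() {
    mA <- which(!is.na(map))
    # per-state connectivity of the matched subgraph
    if (!bf_connected(gA$adj, mA)) return()
    if (!bf_connected(gB$adj, map[mA])) return()
    if (!bf_ring_ok(stA, stB, map, opts, gA, gB, rA, rB)) return()
    mat <- canonical_pair_mat(map, nB)
    bd <- solution_breakdown(states, mat, opts)
    key <- score_key(bd$counts, spec, length(bd$violations) > 0)
    if (!is.finite(key[1])) return()
    if (is.null(best) || key_less(key, best)) {
      best <<- key
      best_sigs <<- solution_signature(mat)
    } else if (key_equal(key, best)) {
      best_sigs <<- union(best_sigs, solution_signature(mat))
    }
  }
  recurse <- function(a) {
    if (a > nA) { consider(); return() }
    # bond preservation against already-assigned atoms (both directions)
    for (b in c(which(!used), NA_integer_)) {
      ok <- TRUE
      if (!is.na(b)) {
        for (a2 in which(!is.na(map[seq_len(a - 1L)]))) {
          bondA <- a2 %in% gA$adj[[a]]
          bondB <- map[a2] %in% gB$adj[[b]]
          if (bondA != bondB) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      map[a] <<- b
      if (!is.na(b)) used[b] <<- TRUE
      recurse(a + 1L)
      if (!is.na(b)) used[b] <<- FALSE
      map[a] <<- NA_integer_
    }
  }
  recurse(1L)
  list(key = best, sigs = sort(best_sigs))
}

# canonical row layout matching the engine's completion: state-A atoms in
# order, then unmatched state-B atoms
canonical_pair_mat <- function(map, nB) {
  rows <- lapply(seq_along(map), function(a) c(a, map[a]))
  for (b in setdiff(seq_len(nB), map[!is.na(map)]))
    rows[[length(rows) + 1L]] <- c(NA_integer_, b)
  do.call(rbind, rows)
}

# canonical signature of an engine solution, independent of row order
engine_sig <- function(sol) {
  mat <- sol$matches
  map <- rep(NA_integer_, nrow(sol$states[[1]]$atoms))
  both <- !is.na(mat[, 1]) & !is.na(mat[, 2])
  map[mat[both, 1]] <- mat[both, 2]
  solution_signature(canonical_pair_mat(map, nrow(sol$states[[2]]$atoms)))
}

# random connected attributed united-atom molecule for property tests
random_molecule <- function(n, rng_types = c("CH3", "CH2", "OA", "N"),
                            title = "rand") {
  stopifnot(n >= 2L)
  # random tree plus a few extra edges (possibly forming rings)
  edges <- list()
  for (v in 2:n) edges[[length(edges) + 1L]] <- sort(c(v, sample(v - 1L, 1L)))
  n_extra <- sample(0:1, 1L)
  for (q in seq_len(n_extra)) {
    cand <- t(utils::combn(n, 2L))
    have <- do.call(rbind, edges)
    key <- paste(cand[, 1], cand[, 2])
    free <- cand[!key %in% paste(have[, 1], have[, 2]), , drop = FALSE]
    if (nrow(free)) {
      pick <- free[sample(nrow(free), 1L), ]
      edges[[length(edges) + 1L]] <- pick
    }
  }
  em <- unique(do.call(rbind, edges))
  types <- sample(rng_types, n, replace = TRUE)
  masses <- c(CH3 = 15.035, CH2 = 14.027, OA = 15.9994, N = 14.0067)
  charges <- c(CH3 = 0, CH2 = 0.05, OA = -0.4, N = -0.2)
  atoms <- tibble::tibble(name = paste0("A", seq_len(n)), type_id = types,
                          mass = unname(masses[types]),
                          charge = unname(charges[types]),
                          charge_group = 1L)
  bond_pool <- c("b_X", "b_Y")
  params <- list(b_X = list(kind = "bond", values = c(700000, 0.15)),
                 b_Y = list(kind = "bond", values = c(800000, 0.12)),
                 a_X = list(kind = "angle", values = c(500, 110)),
                 a_Y = list(kind = "angle", values = c(550, 120)))
  bonds <- tibble::tibble(i = em[, 1], j = em[, 2],
                          ref = sample(bond_pool, nrow(em), replace = TRUE))
  # angles generated from connectivity, parameter by centre type
  adj <- rep(list(integer()), n)
  for (r in seq_len(nrow(em))) {
    adj[[em[r, 1]]] <- c(adj[[em[r, 1]]], em[r, 2])
    adj[[em[r, 2]]] <- c(adj[[em[r, 2]]], em[r, 1])
  }
  ang <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2L) {
      pr <- t(utils::combn(nb, 2L))
      for (r in seq_len(nrow(pr)))
        ang[[length(ang) + 1L]] <- c(pr[r, 1], j, pr[r, 2],
                                     if (types[j] %in% c("OA", "N")) "a_Y" else "a_X")
    }
  }
  angles <- if (length(ang)) {
    tibble::tibble(i = as.integer(vapply(ang, `[[`, "", 1)),
                   j = as.integer(vapply(ang, `[[`, "", 2)),
                   k = as.integer(vapply(ang, `[[`, "", 3)),
                   ref = vapply(ang, `[[`, "", 4))
  } else NULL
  ff_topology(atoms, bonds = bonds, angles = angles, params = params,
              dialect = "gromos", title = title)
}
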