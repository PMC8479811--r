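#' Build the bond graph of a topology
#'
#' The MCS search and the ring policies operate on the undirected bond graph:
#' nodes are atom indices, edges are bonds. Parallel edges cannot occur
#' (duplicate bonds are rejected at topology validation).
#'
#' @param top An `fftop`.
#' @return Object of class `molgraph` with fields `n`, `edges` (2-column
#'   matrix, i < j) and `adj` (per-node integer neighbour vectors).
#' @export
build_graph <- function(top) {
  validate_fftop(top)
  n <- nrow(top$atoms)
  edges <- cbind(pmin(top$bonds$i, top$bonds$j), pmax(top$bonds$i, top$bonds$j))
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
      adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  structure(list(n = n, edges = edges, adj = adj), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d nodes, %d edges>\n", x$n, nrow(x$edges)))
  invisible(x)
}

graph_has_edge <- function(graph, a, b) b %in% graph$adj[[a]]

#' First neighbours of an atom set
#'
#' Candidate atom matches are generated from the first neighbours of the
#' atoms already in the current solution: this returns the union of nodes
#' adjacent to `atoms`, minus `atoms` itself.
#'
#' @param graph A `molgraph`.
#' @param atoms Integer vector of node indices (may be empty).
#' @return Sorted integer vector of neighbouring nodes.
#' @export
first_neighbors <- function(graph, atoms) {
  atoms <- as.integer(atoms)
  if (length(atoms) && (any(atoms < 1L) || any(atoms > graph$n)))
    rlang::abort("unknown atom index", class = "perttop_validation_error")
  if (!length(atoms)) return(integer())
  setdiff(sort(unique(unlist(graph$adj[atoms]))), atoms)
}

# Shortest cycle through an edge (a,b): BFS from a to b in the graph with
# that edge removed. Returns the cycle as an atom vector, or NULL.
shortest_cycle_through_edge <- function(graph, a, b, max_size = 12L) {
  prev <- rep(NA_integer_, graph$n)
  dist <- rep(NA_integer_, graph$n)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in graph$adj[[v]]) {
      if (v == a && w == b) next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        prev[w] <- v
        if (w == b) {
          path <- w
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          if (length(path) > max_size) return(NULL)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

canonical_cycle <- function(cyc) {
  k <- length(cyc)
  i0 <- which.min(cyc)
  rot <- c(cyc[i0:k], if (i0 > 1) cyc[1:(i0 - 1)])
  rev_rot <- c(rot[1], rev(rot[-1]))
  if (paste(rev_rot, collapse = ",") < paste(rot, collapse = ",")) rev_rot else rot
}

cycle_edge_vec <- function(cyc, edge_id, n) {
  v <- integer(length(edge_id))
  k <- length(cyc)
  for (t in seq_len(k)) {
    a <- cyc[t]; b <- cyc[if (t == k) 1L else t + 1L]
    v[edge_id[[paste(min(a, b), max(a, b))]]] <- 1L
  }
  v
}

# GF(2) independence test against a row-reduced basis (list of 0/1 vectors).
gf2_reduce <- function(v, basis) {
  for (b in basis) {
    piv <- which(b == 1L)[1]
    if (v[piv] == 1L) v <- (v + b) %% 2L
  }
  v
}

#' Perceive rings and classify ring-pair relations
#'
#' Finds a smallest set of smallest rings (SSSR) and classifies every pair of
#' rings sharing atoms: `fused` when exactly one edge (two atoms) is shared,
#' `spiro` when exactly one atom is shared, `bridged` when two or more atoms
#' are shared in any other pattern. The matching policies treat these classes
#' differently: fused systems admit complete-individual-ring partial matches,
#' bridged systems only match as a whole, spiro rings are independent.
#'
#' Rings larger than `max_size` atoms are not perceived (treated as acyclic);
#' macrocycles are outside the intended scope.
#'
#' @param graph A `molgraph`.
#' @param max_size Largest ring size perceived (default 12).
#' @return Object of class `ring_system`: `rings` (list of atom cycles),
#'   `relations` (tibble: ring1, ring2, relation), `membership` (per-atom list
#'   of ring ids), `systems` (per-ring id of its fused/bridged component).
#' @export
perceive_rings <- function(graph, max_size = 12L) {
  m <- nrow(graph$edges)
  comp <- graph_components(graph)
  dim_cycle <- m - graph$n + length(unique(comp))
  rings <- list()
  if (dim_cycle > 0L && m > 0L) {
    edge_id <- list()
    for (r in seq_len(m))
      edge_id[[paste(graph$edges[r, 1], graph$edges[r, 2])]] <- r
    cand <- list()
    for (r in seq_len(m)) {
      cyc <- shortest_cycle_through_edge(graph, graph$edges[r, 1],
                                         graph$edges[r, 2], max_size)
      if (!is.null(cyc)) cand[[length(cand) + 1L]] <- canonical_cycle(cyc)
    }
    if (length(cand)) {
      keys <- vapply(cand, paste, character(1), collapse = ",")
      cand <- cand[!duplicated(keys)]
      ord <- order(lengths(cand),
                   vapply(cand, function(c) paste(sprintf("%06d", c), collapse = ","),
                          character(1)))
      cand <- cand[ord]
      basis <- list()
      for (cyc in cand) {
        v <- gf2_reduce(cycle_edge_vec(cyc, edge_id, graph$n), basis)
        if (any(v == 1L)) {
          basis[[length(basis) + 1L]] <- v
          rings[[length(rings) + 1L]] <- cyc
          if (length(rings) == dim_cycle) break
        }
      }
    }
  }
  nr <- length(rings)
  membership <- rep(list(integer()), graph$n)
  for (id in seq_len(nr))
    for (a in rings[[id]]) membership[[a]] <- c(membership[[a]], id)
  relations <- tibble::tibble(ring1 = integer(), ring2 = integer(),
                              relation = character())
  ring_edges <- lapply(rings, function(cyc) {
    k <- length(cyc)
    e <- cbind(cyc, cyc[c(2:k, 1)])
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  })
  if (nr >= 2L) {
    for (r1 in seq_len(nr - 1L)) for (r2 in (r1 + 1L):nr) {
      shared_atoms <- intersect(rings[[r1]], rings[[r2]])
      shared_edges <- intersect(ring_edges[[r1]], ring_edges[[r2]])
      rel <- if (length(shared_atoms) == 0L) "disjoint"
      else if (length(shared_atoms) == 1L) "spiro"
      else if (length(shared_edges) == 1L && length(shared_atoms) == 2L) "fused"
      else "bridged"
      relations <- dplyr::bind_rows(relations,
        tibble::tibble(ring1 = r1, ring2 = r2, relation = rel))
    }
  }
  # ring systems: connected components over fused/bridged relations
  parent <- seq_len(max(nr, 1L))
  if (nr >= 2L) {
    link <- relations[relations$relation %in% c("fused", "bridged"), ]
    for (r in seq_len(nrow(link))) {
      ra <- link$ring1[r]; while (parent[ra] != ra) ra <- parent[ra]
      rb <- link$ring2[r]; while (parent[rb] != rb) rb <- parent[rb]
      parent[ra] <- rb
    }
  }
  find_root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  systems <- if (nr) vapply(seq_len(nr), find_root, integer(1)) else integer()
  structure(list(rings = rings, relations = relations,
                 membership = membership, systems = systems),
            class = "ring_system")
}

#' @export
print.ring_system <- function(x, ...) {
  cat(sprintf("<ring_system: %d rings (%s)>\n", length(x$rings),
              paste(lengths(x$rings), collapse = ", ")))
  invisible(x)
}

graph_components <- function(graph) {
  comp <- rep(NA_integer_, graph$n)
  cid <- 0L
  for (s in seq_len(graph$n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in graph$adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}
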