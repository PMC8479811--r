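test_that("initial candidate list is the full cross-state pair grid", {
  m <- fx_top("methanol_ua"); e <- fx_top("ethane_ua")
  ip <- initial_pairs(list(m, e))
  expect_equal(nrow(ip), 6L)           # 3 x 2 atoms
  expect_equal(ncol(ip), 2L)
  top4 <- fx_top("lysine_side")
  expect_equal(nrow(initial_pairs(list(top4, top4))), 64L)
  expect_error(initial_pairs(list(m)), class = "perttop_validation_error")
})

test_that("candidates grow from first neighbours with explicit dummy options", {
  m <- fx_top("methanol_ua"); e <- fx_top("ethane_ua")
  sol <- add_match(empty_solution(list(m, e)), c(1L, 1L))  # methyls matched
  cands <- expand_candidates(sol)
  sigs <- apply(as.matrix(cands), 1L, paste, collapse = ":")
  expect_true("2:2" %in% sigs)    # (O, other methyl)
  expect_true("2:NA" %in% sigs)   # (O, dummy)
  # the hydrogen is not adjacent to the matched region yet
  expect_false(any(cands$state1 == 3L, na.rm = TRUE))
  # after O enters, H becomes available
  sol2 <- add_match(sol, c(2L, 2L))
  cands2 <- expand_candidates(sol2)
  expect_true(all(cands2$state1 == 3L))
  # complete solutions have nothing to expand
  sol3 <- add_match(sol2, c(3L, NA))
  expect_equal(nrow(expand_candidates(sol3)), 0L)
})

test_that("add_match updates penalties and rejects invalid extensions", {
  m <- fx_top("methanol_ua"); e <- fx_top("ethane_ua")
  sol <- add_match(empty_solution(list(m, e)), c(1L, 1L))
  expect_true(all(sol$score$breakdown[c("atom_type", "mass", "bond")] == 0L))
  sol2 <- add_match(sol, c(2L, 2L))
  expect_gte(sol2$score$breakdown[["atom_type"]], 1L)
  expect_gte(sol2$score$breakdown[["bond"]], 1L)
  expect_gte(sol2$score$breakdown[["charge"]], 1L)
  # identity pair between identical molecules adds nothing
  top <- fx_top("lysine_side")
  si <- add_match(empty_solution(list(top, top)), c(1L, 1L))
  expect_equal(unname(si$score$total), 0)
  # re-matching a used atom
  expect_error(add_match(sol, c(1L, 2L)), class = "perttop_validation_error")
  # bond creation: H bonded to O in methanol, target not bonded to image
  hex <- fx_top("hexane_ua")
  s <- add_match(empty_solution(list(hex, hex)), c(1L, 1L))
  expect_error(add_match(s, c(2L, 6L)), class = "perttop_validation_error")
  expect_error(add_match(s, c(NA, NA)), class = "perttop_validation_error")
})

test_that("engine equals exhaustive enumeration on named fixture pairs", {
  pairs <- list(c("methanol_ua", "ethane_ua"),
                c("lysine_side", "trimethyllysine_side"),
                c("lysine_side", "acetyllysine_side"),
                c("cyclohexane", "hexane_ua"),
                c("cyclohexane", "methylcyclohexane"))
  for (pr in pairs) {
    A <- fx_top(pr[1]); B <- fx_top(pr[2])
    bf <- brute_force_best(A, B)
    sols <- mcs_search(list(A, B), search_options(enumerate_all_best = TRUE,
                                                  max_solutions = 2000L))
    expect_equal(sols[[1]]$score$key, bf$key, label = paste(pr, collapse = " vs "))
    sigs <- sort(unique(vapply(sols, engine_sig, character(1))))
    expect_equal(sigs, bf$sigs, label = paste(pr, collapse = " vs "))
  }
})

test_that("self-match of every fixture is the zero-penalty identity with no dummies", {
  for (nm in c("methanol_ua", "lysine_side", "acetyllysine_side",
               "fused_bicycle", "spiro_bicycle", "hf_ligand_b")) {
    top <- fx_top(nm)
    sols <- mcs_search(list(top, top), search_options(enumerate_all_best = FALSE))
    expect_equal(unname(sols[[1]]$score$total), 0, label = nm)
    expect_equal(sum(is.na(sols[[1]]$matches)), 0L, label = nm)
  }
})

test_that("search is symmetric in its arguments", {
  for (pr in list(c("methanol_ua", "ethane_ua"),
                  c("lysine_side", "acetyllysine_side"))) {
    A <- fx_top(pr[1]); B <- fx_top(pr[2])
    sab <- mcs_search(list(A, B), search_options(enumerate_all_best = TRUE))
    sba <- mcs_search(list(B, A), search_options(enumerate_all_best = TRUE))
    expect_equal(sab[[1]]$score$key, sba[[1]]$score$key)
    fwd <- sort(vapply(sab, function(s) {
      m <- s$matches; b <- !is.na(m[, 1]) & !is.na(m[, 2])
      paste(sort(paste(m[b, 1], m[b, 2])), collapse = ";")
    }, character(1)))
    rev_ <- sort(vapply(sba, function(s) {
      m <- s$matches; b <- !is.na(m[, 1]) & !is.na(m[, 2])
      paste(sort(paste(m[b, 2], m[b, 1])), collapse = ";")
    }, character(1)))
    expect_equal(fwd, rev_)
  }
})

test_that("disabling pruning never changes the best score", {
  set.seed(53)
  pairs <- list(list(fx_top("methanol_ua"), fx_top("ethane_ua")),
                list(fx_top("cyclohexane"), fx_top("hexane_ua")),
                list(random_molecule(5, title = "A"), random_molecule(6, title = "B")))
  for (st in pairs) {
    s1 <- mcs_search(st, search_options(prune = TRUE))
    s2 <- mcs_search(st, search_options(prune = FALSE))
    expect_equal(s1[[1]]$score$key, s2[[1]]$score$key)
    expect_identical(s1[[1]]$matches, s2[[1]]$matches)
  }
})

test_that("two runs on identical inputs produce identical output lists", {
  A <- fx_top("lysine_side"); B <- fx_top("trimethyllysine_side")
  r1 <- mcs_search(list(A, B), search_options(enumerate_all_best = TRUE))
  r2 <- mcs_search(list(A, B), search_options(enumerate_all_best = TRUE))
  expect_identical(lapply(r1, `[[`, "matches"), lapply(r2, `[[`, "matches"))
})

test_that("returned solutions satisfy bond preservation and the ring policy post hoc", {
  for (pr in list(c("cyclohexane", "hexane_ua"),
                  c("fused_bicycle", "cyclohexane"),
                  c("lysine_side", "acetyllysine_side"))) {
    A <- fx_top(pr[1]); B <- fx_top(pr[2])
    gA <- build_graph(A); gB <- build_graph(B)
    rA <- perceive_rings(gA); rB <- perceive_rings(gB)
    for (sol in mcs_search(list(A, B), search_options(enumerate_all_best = TRUE))) {
      mat <- sol$matches
      both <- which(!is.na(mat[, 1]) & !is.na(mat[, 2]))
      for (r1 in both) for (r2 in setdiff(both, r1)) {
        expect_equal(mat[r2, 1] %in% gA$adj[[mat[r1, 1]]],
                     mat[r2, 2] %in% gB$adj[[mat[r1, 2]]])
      }
      map <- rep(NA_integer_, nrow(A$atoms))
      map[mat[both, 1]] <- mat[both, 2]
      expect_true(bf_ring_ok(A, B, map, sol$options, gA, gB, rA, rB))
    }
  }
})

test_that("ring policies restrict ring-nonring and partial polycyclic matches", {
  ch <- fx_top("cyclohexane"); hx <- fx_top("hexane_ua")
  n_matched <- function(sol) sum(rowSums(!is.na(sol$matches)) == 2L)
  sizes <- vapply(c("two_bonded_atoms", "one_atom", "none"), function(p) {
    n_matched(mcs_search(list(ch, hx), search_options(ring_nonring_policy = p))[[1]])
  }, numeric(1))
  expect_equal(unname(sizes), c(2, 1, 0))
  # enforce_ring_policy refuses a second nonbonded ring atom under one_atom
  sol <- add_match(empty_solution(list(ch, hx),
                                  search_options(ring_nonring_policy = "one_atom")),
                   c(1L, 2L))
  expect_false(enforce_ring_policy(sol, c(2L, 3L)))
  # fused bicyclic vs monocyclic: complete-individual-ring partial match
  fb <- fx_top("fused_bicycle")
  s_def <- mcs_search(list(fb, ch))[[1]]
  expect_equal(n_matched(s_def), 6)
  s_comp <- mcs_search(list(fb, ch), search_options(ring_policy = "complete_only"))[[1]]
  expect_equal(n_matched(s_comp), 0)
})

test_that("dihedral procedures and make/break flags reproduce the two acetylation pathways", {
  lys <- fx_top("lysine_side"); kac <- fx_top("acetyllysine_side")
  # restrictive settings: the amide hydrogen is matched, the acetyl group
  # grows from dummies (5 dummy entries), and no bonded term is perturbed
  s_b <- mcs_search(list(lys, kac))[[1]]
  expect_equal(sum(is.na(s_b$matches)), 5L)
  expect_true(all(s_b$score$breakdown[c("bond", "angle", "dihedral", "improper",
                                        "multiplicity", "make_break")] == 0L))
  # the same pathway is found when bond perturbations are forbidden outright
  s_b2 <- mcs_search(list(lys, kac), spec = score_spec(forbid = "bond"))[[1]]
  expect_equal(sum(is.na(s_b2$matches)), 5L)
  # permissive settings (middle-two dihedral matching + term removal allowed):
  # a hydrogen is alchemically changed into the acetyl carbon instead
  s_a <- mcs_search(list(lys, kac),
                    search_options(dihedral_match = "middle_two_atoms",
                                   allow_make_break_bonded = TRUE))[[1]]
  expect_equal(sum(is.na(s_a$matches)), 3L)
  expect_gte(s_a$score$breakdown[["make_break"]], 1L)
  expect_gte(s_a$score$breakdown[["bond"]], 1L)
  # multiplicity change + all-four matching + removal also reaches it
  s_a2 <- mcs_search(list(lys, kac),
                     search_options(allow_multiplicity_change = TRUE,
                                    allow_make_break_bonded = TRUE))[[1]]
  expect_equal(sum(is.na(s_a2$matches)), 3L)
})

test_that("dihedral classification reports matched and perturbed dihedrals", {
  top <- fx_top("lysine_side")
  n <- nrow(top$atoms)
  sol <- structure(list(states = list(top, top),
                        matches = matrix(rep(seq_len(n), 2), ncol = 2),
                        options = search_options(), complete = TRUE),
                   class = "match_solution")
  md <- match_dihedrals(sol)
  expect_true(all(md$category == "matched"))
  expect_equal(sum(md$category == "matched"), nrow(top$dihedrals))
  md2 <- match_dihedrals(sol, search_options(dihedral_match = "middle_two_atoms"))
  expect_true(all(md2$category == "matched"))
})

test_that("the node-expansion budget aborts with a diagnostic", {
  A <- fx_top("lysine_side"); B <- fx_top("trimethyllysine_side")
  expect_error(mcs_search(list(A, B), search_options(node_budget = 5L)),
               class = "perttop_budget_error")
})

test_that("search agrees with exhaustive enumeration on random attributed graphs", {
  set.seed(2024)
  for (q in 1:10) {
    A <- random_molecule(sample(4:7, 1), title = "A")
    B <- random_molecule(sample(4:7, 1), title = "B")
    bf <- brute_force_best(A, B)
    sols <- mcs_search(list(A, B), search_options(enumerate_all_best = TRUE,
                                                  max_solutions = 2000L))
    expect_equal(sols[[1]]$score$key, bf$key)
    expect_equal(sort(unique(vapply(sols, engine_sig, character(1)))), bf$sigs)
  }
})
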