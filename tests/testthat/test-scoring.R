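identity_solution <- function(top) {
  n <- nrow(top$atoms)
  structure(list(states = list(top, top),
                 matches = matrix(rep(seq_len(n), 2L), ncol = 2L),
                 options = search_options(), complete = TRUE),
            class = "match_solution")
}

test_that("identity self-matches score zero in every category", {
  for (nm in c("methanol_ua", "lysine_side", "acetyllysine_side", "cyclohexane")) {
    ev <- evaluate_solution(identity_solution(fx_top(nm)))
    expect_equal(unname(ev$total), 0)
    expect_true(all(ev$breakdown == 0L))
    expect_equal(ev$lower_bound, ev$total)
  }
})

test_that("the methanol-ethane mapping is penalised term by term", {
  sol <- mcs_search(list(fx_top("methanol_ua"), fx_top("ethane_ua")))[[1]]
  bd <- sol$score$breakdown
  # independent expectation computed directly from the two fixture tables:
  # O matched to a methyl differs in type, mass, charge; the C-O bond differs
  # from C-C; methanol's methyl carries a partial charge ethane's does not;
  # the hydrogen can only match a dummy
  expect_equal(unname(bd["dummy"]), 1L)
  expect_gte(bd["atom_type"], 1L)
  expect_gte(bd["mass"], 1L)
  expect_gte(bd["charge"], 1L)
  expect_gte(bd["bond"], 1L)
  spec <- score_spec()
  expect_equal(sol$score$total,
               sum(spec$weights * bd[names(spec$weights)]))
})

test_that("forbidden categories reject solutions with an infinite-score sentinel", {
  m <- fx_top("methanol_ua"); e <- fx_top("ethane_ua")
  sol <- mcs_search(list(m, e))[[1]]
  ev <- evaluate_solution(sol, score_spec(forbid = "bond"))
  expect_identical(unname(ev$total), Inf)
  # searching under the forbid finds a different (dummy-heavier) pathway
  sols2 <- mcs_search(list(m, e), spec = score_spec(forbid = "bond"))
  expect_true(is.finite(sols2[[1]]$score$total))
  expect_equal(unname(sols2[[1]]$score$breakdown["bond"]), 0L)
})

test_that("lower bound is admissible along prefixes of the optimal solution", {
  set.seed(31)
  for (q in 1:6) {
    A <- random_molecule(sample(4:6, 1), title = "A")
    B <- random_molecule(sample(4:6, 1), title = "B")
    bf <- brute_force_best(A, B)
    # default weights: total = w_dummy * dummies + unit-weighted mismatches
    best_total <- score_spec()$weights[["dummy"]] * bf$key[1] + bf$key[2]
    # empty solution
    sol <- empty_solution(list(A, B))
    expect_lte(lower_bound(sol), best_total)
    # prefixes of the engine's best solution must never be bounded above it
    eng <- mcs_search(list(A, B))[[1]]
    mat <- eng$matches
    cross <- which(rowSums(!is.na(mat)) == 2L)
    part <- sol
    for (r in cross) {
      part <- add_match(part, as.integer(mat[r, ]))
      expect_lte(lower_bound(part), eng$score$total)
    }
    # complete solutions: the bound equals the total
    expect_equal(lower_bound(eng), eng$score$total)
  }
})

test_that("empty solution of two identical molecules has zero lower bound", {
  top <- fx_top("cyclohexane")
  expect_equal(lower_bound(empty_solution(list(top, top))), 0)
})

test_that("pairwise RMSD uses the coordinates as posed, without fitting", {
  m <- fx("methanol_ua")
  sol <- identity_solution(m$top)
  expect_equal(rmsd_of_mapping(sol, list(m$coords, m$coords)), 0)
  shifted <- coord_set(m$coords$positions + 0.1)
  # a rigid shift is NOT removed: no superposition
  expect_equal(rmsd_of_mapping(sol, list(m$coords, shifted)),
               sqrt(3) * 0.1, tolerance = 1e-12)
})

test_that("RMSD distinguishes the six symmetric methylation solutions and select_best picks the minimum", {
  lys <- fx("lysine_side"); k3c <- fx("trimethyllysine_side")
  sols <- mcs_search(list(lys$top, k3c$top), search_options(enumerate_all_best = TRUE))
  expect_length(sols, 6L)
  coords <- list(lys$coords, k3c$coords)
  r <- vapply(sols, rmsd_of_mapping, numeric(1), coords = coords)
  expect_equal(length(unique(round(r, 9))), 6L)
  best <- select_best(sols, coords)
  expect_equal(rmsd_of_mapping(best, coords), min(r))
  # without coordinates the choice is deterministic and canonical
  b1 <- select_best(sols)
  b2 <- select_best(rev(sols))
  expect_identical(b1$matches, b2$matches)
  expect_error(select_best(list()), class = "perttop_validation_error")
})

test_that("multistate spread: RMSF form and pairwise-RMSD form obey the 2N/(N-1) identity", {
  set.seed(99)
  for (N in c(2L, 3L, 5L)) {
    top <- fx_top("hexane_ua")
    n <- nrow(top$atoms)
    sol <- structure(list(states = rep(list(top), N),
                          matches = matrix(rep(seq_len(n), N), ncol = N),
                          options = search_options(), complete = TRUE),
                     class = "match_solution")
    coords <- replicate(N, coord_set(matrix(stats::rnorm(n * 3), ncol = 3)),
                        simplify = FALSE)
    msd <- rmsd_of_mapping(sol, coords, "rmsd")^2
    msf <- rmsd_of_mapping(sol, coords, "rmsf")^2
    expect_lt(abs(msd - 2 * N / (N - 1) * msf), 1e-10)
  }
})

test_that("score evaluation is invariant under consistent atom relabelling", {
  set.seed(17)
  A <- fx_top("lysine_side"); B <- fx_top("trimethyllysine_side")
  sol <- mcs_search(list(A, B))[[1]]
  t0 <- sol$score$total
  n <- nrow(A$atoms)
  perm <- sample(n)
  at2 <- A$atoms[order(perm), -1]
  remap <- function(tb, cols) { for (cc in cols) tb[[cc]] <- perm[tb[[cc]]]; tb }
  A2 <- ff_topology(at2, bonds = remap(A$bonds, c("i", "j")),
                    angles = remap(A$angles, c("i", "j", "k")),
                    dihedrals = remap(A$dihedrals, c("i", "j", "k", "l")),
                    params = A$params, dialect = "gromos", title = "perm")
  mat2 <- sol$matches
  real <- !is.na(mat2[, 1])
  mat2[real, 1] <- perm[mat2[real, 1]]
  sol2 <- structure(list(states = list(A2, B), matches = mat2,
                         options = sol$options, complete = TRUE),
                    class = "match_solution")
  expect_equal(evaluate_solution(sol2)$total, t0)
})

test_that("score and option settings load from a flat key-value config", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cfg.txt")
  writeLines(c("# comment", "w_dummy 500", "w_bond 3", "forbid bond,angle",
               "ring_policy complete_only", "allow_make_break_bonded TRUE",
               "max_solutions 7"), f)
  cfg <- read_search_config(f)
  expect_equal(unname(cfg$spec$weights["dummy"]), 500)
  expect_equal(unname(cfg$spec$weights["bond"]), 3)
  expect_setequal(cfg$spec$forbid, c("bond", "angle"))
  expect_equal(cfg$options$ring_policy, "complete_only")
  expect_true(cfg$options$allow_make_break_bonded)
  expect_equal(cfg$options$max_solutions, 7L)
  writeLines("nonsense_key 1", f)
  expect_error(read_search_config(f), class = "perttop_parse_error")
})
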