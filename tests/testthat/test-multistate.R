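lysine_triple <- function() list(fx_top("lysine_side"),
                                 fx_top("trimethyllysine_side"),
                                 fx_top("acetyllysine_side"))

msol_cache <- new.env(parent = emptyenv())
lysine_msol <- function() {
  if (is.null(msol_cache$sol)) msol_cache$sol <- multistate_search(lysine_triple())
  msol_cache$sol
}

test_that("multistate search on two states reduces to the pairwise search", {
  A <- fx_top("lysine_side"); B <- fx_top("trimethyllysine_side")
  spec_eds <- score_spec(forbid = c("bond", "angle", "dihedral", "improper",
                                    "multiplicity", "make_break"))
  s_multi <- multistate_search(list(A, B))
  s_pair <- mcs_search(list(A, B), search_options(enumerate_all_best = FALSE),
                       spec_eds)[[1]]
  expect_equal(s_multi$score$key, s_pair$score$key)
  expect_identical(s_multi$matches, s_pair$matches)
})

test_that("the lysine modification triple yields a shared scaffold with per-state dummies", {
  sol <- lysine_msol()
  mat <- sol$matches
  # backbone + amine nitrogen matched across all three states
  expect_equal(sum(rowSums(!is.na(mat)) == 3L), 5L)
  # no bonded-term perturbation under the default multistate settings
  expect_true(all(sol$score$breakdown[c("bond", "angle", "dihedral", "improper",
                                        "multiplicity", "make_break")] == 0L))
  eds <- build_eds_topology(sol)
  expect_equal(eds$n_states, 3L)
  # the three methyls, the acetyl group and the surplus amine hydrogens are
  # dummies in the states that lack them
  expect_true(all(colSums(eds$dummy) > 0L))
})

test_that("EDS restriction reproduces every input topology exactly", {
  eds <- build_eds_topology(lysine_msol())
  ins <- lysine_triple()
  for (s in 1:3)
    expect_true(fftop_equal(restrict_state(eds, s), ins[[s]]),
                label = paste("state", s))
  expect_error(restrict_state(eds, 9L), class = "perttop_validation_error")
})

test_that("identical molecules give an EDS topology without dummies", {
  top <- fx_top("cyclohexane")
  sol <- multistate_search(list(top, top, top))
  eds <- build_eds_topology(sol)
  expect_equal(sum(eds$dummy), 0L)
  expect_equal(nrow(eds$atoms), nrow(top$atoms))
})

test_that("solutions with bonded perturbations are rejected for EDS building", {
  # the default pairwise search perturbs the N-H bonds into N-CH3 bonds
  sol <- mcs_search(list(fx_top("lysine_side"), fx_top("trimethyllysine_side")))[[1]]
  expect_gte(sol$score$breakdown[["bond"]], 1L)
  expect_error(build_eds_topology(sol), class = "perttop_validation_error",
               regexp = "bonded")
})

test_that("ring-compound multistate: each EDS state is dummy exactly where its molecule lacks atoms", {
  states <- list(fx_top("cyclohexane"), fx_top("methylcyclohexane"),
                 fx_top("dimethylcyclohexane_12"))
  sol <- multistate_search(states)
  eds <- build_eds_topology(sol)
  n_atoms <- vapply(states, function(s) nrow(s$atoms), integer(1))
  expect_equal(nrow(eds$atoms) - colSums(!eds$dummy), nrow(eds$atoms) - n_atoms)
  # the shared six-ring is fully matched across all states
  expect_equal(sum(rowSums(!is.na(sol$matches)) == 3L), 6L)
  for (s in 1:3)
    expect_true(fftop_equal(restrict_state(eds, s), states[[s]]))
})

test_that("H/F congeneric series: common scaffold with one hydrogen and one fluoride attached", {
  series <- lapply(make_fixture("hf_ligand_series"), `[[`, "top")
  sol <- multistate_search(series)
  mat <- sol$matches
  # all six ring atoms of every ligand matched across the three states
  allreal <- mat[rowSums(!is.na(mat)) == 3L, , drop = FALSE]
  for (s in 1:3) expect_true(all(1:6 %in% allreal[, s]))
  eds <- build_eds_topology(sol)
  types_by_state <- eds$types
  # each fluoride exists in exactly one state and is dummy elsewhere
  f_rows <- which(apply(types_by_state, 1L, function(r) any(r == "F")))
  expect_length(f_rows, 2L)
  for (r in f_rows)
    expect_equal(sum(types_by_state[r, ] == "DUM"), 2L)
  # hydrogens attached to the core alongside them
  expect_true(any(apply(types_by_state, 1L, function(r) any(r == "H"))))
  for (s in 1:3)
    expect_true(fftop_equal(restrict_state(eds, s), series[[s]]))
})

test_that("pairwise extraction gives all cycle legs, consistent with the shared mapping", {
  sol <- lysine_msol()
  perts <- pairwise_from_multistate(sol)
  expect_named(perts, c("1-2", "1-3", "2-3"))
  ins <- lysine_triple()
  for (nm in names(perts)) {
    si <- as.integer(strsplit(nm, "-")[[1]])
    expect_true(fftop_equal(restrict_state(perts[[nm]], "A"), ins[[si[1]]]))
    expect_true(fftop_equal(restrict_state(perts[[nm]], "B"), ins[[si[2]]]))
  }
  # cycle consistency: composing the atom maps around 1->2->3->1 is identity
  get_map <- function(p, from_n) {
    m <- rep(NA_integer_, from_n)
    at <- p$atoms
    both <- !is.na(at$orig_a) & !is.na(at$orig_b)
    m[at$orig_a[both]] <- at$orig_b[both]
    m
  }
  n1 <- nrow(ins[[1]]$atoms)
  m12 <- get_map(perts[["1-2"]], n1)
  m23 <- get_map(perts[["2-3"]], nrow(ins[[2]]$atoms))
  m13 <- get_map(perts[["1-3"]], n1)
  for (a in seq_len(n1)) {
    if (!is.na(m12[a]) && !is.na(m23[m12[a]]) && !is.na(m13[a]))
      expect_equal(m23[m12[a]], m13[a])
  }
  expect_error(pairwise_from_multistate(
    mcs_search(list(ins[[1]], ins[[2]]))[[1]]), class = "perttop_validation_error")
  # N = 4 gives 6 legs
  states4 <- list(fx_top("methanol_ua"), fx_top("methanol_ua"),
                  fx_top("ethane_ua"), fx_top("ethane_ua"))
  sol4 <- multistate_search(states4)
  expect_length(pairwise_from_multistate(sol4), 6L)
})

test_that("no cross-state match under the forbids yields an explicit no-solution result", {
  # with every mismatch category forbidden, chemically disjoint molecules
  # admit no cross-state atom match at all
  res <- multistate_search(list(fx_top("methanol_ua"), fx_top("ethane_ua")),
                           spec = score_spec(forbid = c("atom_type", "mass",
                                                        "charge")))
  expect_s3_class(res, "perttop_no_solution")
  expect_error(build_eds_topology(res), class = "perttop_validation_error")
})

test_that("EDS topologies serialize to both dialects and re-read per state", {
  dir <- withr::local_tempdir()
  eds <- build_eds_topology(lysine_msol())
  files_gmx <- write_eds_topology(eds, file.path(dir, "eds"), "gromacs")
  expect_length(files_gmx, 3L)
  for (s in 1:3) {
    t_s <- read_topology(files_gmx[s], "gromacs")
    expect_equal(nrow(t_s$atoms), nrow(eds$atoms))
    expect_equal(sum(t_s$atoms$type_id == "DUM"), sum(eds$dummy[, s]))
  }
  files_g <- write_eds_topology(eds, file.path(dir, "edsg"), "gromos")
  expect_true(all(file.exists(files_g)))
  ptp <- readLines(files_g[2])
  expect_true("MPERTATOM" %in% ptp)
})
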