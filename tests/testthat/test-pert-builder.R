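fig1_pert <- function() {
  sol <- mcs_search(list(fx_top("methanol_ua"), fx_top("ethane_ua")))[[1]]
  build_pert_topology(sol)
}

test_that("methanol-to-ethane union carries the hydrogen as a dummy in state B", {
  pert <- fig1_pert()
  # 3 union atoms: both ethane methyls are matched, only H lacks a partner
  expect_equal(nrow(pert$atoms), 3L)
  h <- pert$atoms[pert$atoms$name == "H", ]
  expect_false(h$dummy_a)
  expect_true(h$dummy_b)
  expect_equal(h$type_b, "DUM")
  expect_equal(h$charge_b, 0)
  expect_equal(h$mass_b, h$mass_a)  # dummies keep their real-state mass
  expect_false(any(pert$atoms$dummy_a & pert$atoms$dummy_b))
  # bond list identical across states
  expect_false(any(is.na(pert$bonds$ref_a)))
  expect_false(any(is.na(pert$bonds$ref_b)))
})

test_that("identity perturbations have no dummies and no perturbed terms", {
  top <- fx_top("lysine_side")
  sol <- mcs_search(list(top, top))[[1]]
  pert <- build_pert_topology(sol)
  expect_equal(sum(pert$atoms$dummy_a | pert$atoms$dummy_b), 0L)
  td <- tidy(pert)
  expect_true(all(td$status == "unperturbed"))
  aud <- audit_dummies(pert, quiet = TRUE)
  expect_equal(nrow(aud), 0L)
})

test_that("the bond-conserving methylation pathway yields three dummies per side", {
  sol <- mcs_search(list(fx_top("lysine_side"), fx_top("trimethyllysine_side")),
                    spec = score_spec(forbid = "bond"))[[1]]
  pert <- build_pert_topology(sol)
  expect_equal(sum(pert$atoms$dummy_b), 3L)  # hydrogens vanish in state B
  expect_equal(sum(pert$atoms$dummy_a), 3L)  # methyls grow from dummies
  expect_equal(sum(!pert$atoms$dummy_a & !pert$atoms$dummy_b), 5L)
  expect_error(build_pert_topology(empty_solution(list(fx_top("ethane_ua"),
                                                       fx_top("ethane_ua")))),
               class = "perttop_validation_error")
})

test_that("state restriction reproduces the inputs exactly for every fixture pair", {
  pairs <- list(c("methanol_ua", "ethane_ua"),
                c("lysine_side", "trimethyllysine_side"),
                c("lysine_side", "acetyllysine_side"),
                c("fused_bicycle", "cyclohexane"),
                c("hf_ligand_a", "hf_ligand_b"))
  for (pr in pairs) {
    A <- fx_top(pr[1]); B <- fx_top(pr[2])
    pert <- build_pert_topology(mcs_search(list(A, B))[[1]])
    expect_true(fftop_equal(restrict_state(pert, "A"), A),
                label = paste(pr[1], "restriction"))
    expect_true(fftop_equal(restrict_state(pert, "B"), B),
                label = paste(pr[2], "restriction"))
    # dummy neutrality: per-state total charges match the inputs
    expect_equal(sum(pert$atoms$charge_a), ff_total_charge(A), tolerance = 1e-9)
    expect_equal(sum(pert$atoms$charge_b), ff_total_charge(B), tolerance = 1e-9)
  }
})

test_that("dummy audit flags redundant anchoring and under-anchoring per the three-term rule", {
  lys <- fx_top("lysine_side"); kac <- fx_top("acetyllysine_side")
  # restrictive pathway: the acetyl carbon is a dummy with one bond, two
  # angles, one proper and one improper dihedral to the unperturbed region
  pert_b <- build_pert_topology(mcs_search(list(lys, kac))[[1]])
  aud <- audit_dummies(pert_b, quiet = TRUE)
  ac <- aud[aud$name == "C", ]
  expect_equal(ac$n_anchor_terms, 5L)
  expect_equal(ac$n_redundant, 2L)
  expect_true(ac$warning)
  expect_warning(audit_dummies(pert_b), class = "perttop_dummy_warning")
  # permissive pathway: every dummy is anchored by exactly three terms
  s_a <- mcs_search(list(lys, kac),
                    search_options(dihedral_match = "middle_two_atoms",
                                   allow_make_break_bonded = TRUE))[[1]]
  aud_a <- audit_dummies(build_pert_topology(s_a), quiet = TRUE)
  expect_true(all(aud_a$n_anchor_terms == 3L))
  expect_false(any(aud_a$warning))
  # a dummy anchored by a single bond is under-anchored
  pert1 <- fig1_pert()
  audh <- audit_dummies(pert1, quiet = TRUE)
  h <- audh[audh$name == "H", ]
  expect_true(h$under_anchored)
  expect_true(h$warning)
})

test_that("perturbation files round-trip in both dialects", {
  dir <- withr::local_tempdir()
  for (pr in list(c("lysine_side", "acetyllysine_side"),
                  c("methanol_ua", "ethane_ua"))) {
    pert <- build_pert_topology(mcs_search(list(fx_top(pr[1]), fx_top(pr[2])))[[1]])
    for (d in c("gromos", "gromacs")) {
      pfx <- file.path(dir, paste(pr[1], d, sep = "_"))
      files <- write_perturbation(pert, pfx, d)
      expect_true(all(file.exists(files)))
      expect_true(pert_equal(pert, read_perturbation(pfx, d)),
                  label = paste(pr[1], d))
    }
  }
})

test_that("GROMACS perturbation rows carry the dummy type and zero charge in state B", {
  dir <- withr::local_tempdir()
  pert <- fig1_pert()
  write_perturbation(pert, file.path(dir, "p"), "gromacs")
  lines <- readLines(file.path(dir, "p.top"))
  hrow <- grep("^\\s*\\d+\\s+H\\s", lines, value = TRUE)
  expect_length(hrow, 1L)
  tok <- strsplit(trimws(hrow), "[ \t]+")[[1]]
  expect_equal(tok[9], "DUM")
  expect_equal(as.numeric(tok[10]), 0)
  # identity perturbation: A and B columns identical everywhere
  top <- fx_top("ethane_ua")
  pid <- build_pert_topology(mcs_search(list(top, top))[[1]])
  write_perturbation(pid, file.path(dir, "id"), "gromacs")
  at_lines <- readLines(file.path(dir, "id.top"))
  rows <- grep("^\\s*\\d+\\s+\\S+\\s+\\d+\\s+MOL", at_lines, value = TRUE)
  for (r in rows) {
    tk <- strsplit(trimws(r), "[ \t]+")[[1]]
    expect_equal(tk[2], tk[9])
    expect_equal(as.numeric(tk[7]), as.numeric(tk[10]))
    expect_equal(as.numeric(tk[8]), as.numeric(tk[11]))
  }
})

test_that("tidy/glance/autoplot summarise perturbation results", {
  pert <- fig1_pert()
  td <- tidy(pert)
  expect_setequal(td$status[td$name == "H"], "dummy_B")
  g <- glance(pert)
  expect_equal(g$n_atoms, 3L)
  expect_equal(g$n_dummy_b, 1L)
  p <- autoplot(pert)
  expect_s3_class(p, "ggplot")
  sol <- mcs_search(list(fx_top("methanol_ua"), fx_top("ethane_ua")))[[1]]
  expect_s3_class(autoplot(sol), "ggplot")
  gs <- glance(sol)
  expect_equal(gs$n_matched, 2L)
  expect_equal(gs$n_dummy_entries, 1L)
})
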