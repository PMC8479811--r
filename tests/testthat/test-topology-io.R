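roundtrip_names <- setdiff(fixture_names(), "hf_ligand_series")

test_that("every fixture round-trips through both dialects on all semantic fields", {
  dir <- withr::local_tempdir()
  for (nm in roundtrip_names) {
    top <- fx_top(nm)
    f_g <- file.path(dir, paste0(nm, ".top"))
    write_topology(top, f_g, "gromos")
    expect_true(fftop_equal(top, read_topology(f_g, "gromos")), label = paste(nm, "gromos"))
    f_x <- file.path(dir, paste0(nm, ".itp"))
    write_topology(top, f_x, "gromacs")
    expect_true(fftop_equal(top, read_topology(f_x, "gromacs")), label = paste(nm, "gromacs"))
  }
})

test_that("a GROMOS topology rewritten as GROMACS and re-read keeps atoms, bonds, masses, charges", {
  dir <- withr::local_tempdir()
  top <- fx_top("acetyllysine_side")
  f1 <- file.path(dir, "x.itp")
  write_topology(top, f1, "gromacs")
  back <- read_topology(f1, "gromacs")
  expect_equal(nrow(back$atoms), nrow(top$atoms))
  expect_equal(back$atoms$mass, top$atoms$mass)
  expect_equal(back$atoms$charge, top$atoms$charge, tolerance = 1e-6)
  expect_identical(back$bonds[, c("i", "j")], top$bonds[, c("i", "j")])
  f2 <- file.path(dir, "x.top")
  write_topology(back, f2, "gromos")
  expect_true(fftop_equal(top, read_topology(f2, "gromos")))
})

test_that("known small topologies parse to the expected counts", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "methanol.itp")
  write_topology(fx_top("methanol_ua"), f, "gromacs")
  top <- read_topology(f, "gromacs")
  expect_equal(nrow(top$atoms), 3L)
  expect_equal(nrow(top$bonds), 2L)
  expect_equal(nrow(top$angles), 1L)
  f2 <- file.path(dir, "ethane.top")
  write_topology(fx_top("ethane_ua"), f2, "gromos")
  top2 <- read_topology(f2, "gromos")
  expect_equal(nrow(top2$atoms), 2L)
  expect_equal(nrow(top2$bonds), 1L)
})

test_that("parser rejects structurally broken files with parse errors", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.top")
  write_topology(fx_top("methanol_ua"), f, "gromos")
  lines <- readLines(f)
  # a bond referencing an undefined type code
  mut <- sub("^1 2 1$", "1 2 99", lines)
  writeLines(mut, f)
  expect_error(read_topology(f, "gromos"), class = "perttop_parse_error")
  # unknown block name
  writeLines(c("BOGUSBLOCK", "1", "END", lines), f)
  expect_error(read_topology(f, "gromos"), class = "perttop_parse_error")
  # missing file -> I/O error
  expect_error(read_topology(file.path(dir, "nope.top"), "gromos"),
               class = "perttop_io_error")
  # gromacs: bonded term beyond atom count
  f3 <- file.path(dir, "m.itp")
  write_topology(fx_top("methanol_ua"), f3, "gromacs")
  l3 <- readLines(f3)
  l3 <- sub("^(\\s*)1\\s+2(\\s+1 .*)$", "\\11     9\\2", l3)
  writeLines(l3, f3)
  expect_error(read_topology(f3, "gromacs"), class = "perttop_parse_error")
})

test_that("fuzzed block deletions are rejected", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.top")
  write_topology(fx_top("lysine_side"), f, "gromos")
  lines <- readLines(f)
  # drop one END -> unclosed block
  writeLines(lines[-max(which(lines == "END"))], f)
  expect_error(read_topology(f, "gromos"), class = "perttop_parse_error")
  # truncate the SOLUTEATOM block body (drop the first atom record)
  i <- which(lines == "SOLUTEATOM")
  writeLines(lines[-(i + 4L)], f)
  expect_error(read_topology(f, "gromos"), class = "perttop_parse_error")
})

test_that("serialization errors name the problem", {
  top <- fx_top("ethane_ua")
  top$bonds$ref[1] <- "nonexistent"
  dir <- withr::local_tempdir()
  expect_error(write_topology(top, file.path(dir, "x.top"), "gromos"),
               class = "perttop_serialization_error")
  top2 <- fx_top("ethane_ua")
  top2$atoms$charge_group <- NA_integer_
  expect_error(write_topology(top2, file.path(dir, "y.top"), "gromos"),
               class = "perttop_serialization_error")
  # gromacs does not need charge groups
  expect_silent(write_topology(top2, file.path(dir, "y.itp"), "gromacs"))
})

test_that("GROMACS include inlining and define resolution work; unresolved includes error", {
  dir <- withr::local_tempdir()
  write_topology(fx_top("ethane_ua"), file.path(dir, "base.itp"), "gromacs")
  base <- readLines(file.path(dir, "base.itp"))
  bond_line <- grep("^\\s*1\\s+2\\s+1 ", base, value = TRUE)[1]
  parts <- strsplit(trimws(bond_line), "[ \t]+")[[1]]
  main <- c("#define BND_CC  0.153 700000.0",
            base[seq_len(grep("\\[ bonds \\]", base) )],
            "    1     2   1 BND_CC")
  writeLines(main, file.path(dir, "macro.itp"))
  top <- read_topology(file.path(dir, "macro.itp"), "gromacs")
  expect_equal(unname(ff_params(top, top$bonds$ref[1])$values), c(700000, 0.153))
  # include
  writeLines(c("#include \"base.itp\""), file.path(dir, "inc.itp"))
  top2 <- read_topology(file.path(dir, "inc.itp"), "gromacs")
  expect_true(fftop_equal(top2, fx_top("ethane_ua"), check_charge_groups = TRUE))
  writeLines(c("#include \"missing.itp\""), file.path(dir, "bad.itp"))
  expect_error(read_topology(file.path(dir, "bad.itp"), "gromacs"),
               class = "perttop_parse_error")
})

test_that("coordinate files read in nm, with PDB Angstrom conversion and pairing checks", {
  dir <- withr::local_tempdir()
  m <- fx("methanol_ua")
  f_gro <- file.path(dir, "m.gro")
  write_coordinates(m$coords, m$top, f_gro)
  c1 <- read_coordinates(f_gro, top = m$top)
  expect_equal(nrow(c1$positions), 3L)
  # GRO stores %.3f nm
  expect_lt(max(abs(c1$positions - m$coords$positions)), 5e-4)
  f_pdb <- file.path(dir, "m.pdb")
  write_coordinates(m$coords, m$top, f_pdb)
  c2 <- read_coordinates(f_pdb, top = m$top)
  expect_lt(max(abs(c2$positions - m$coords$positions)), 5e-5)
  # PDB values are in Angstrom on disk: raw columns are 10x the nm values
  raw <- readLines(f_pdb)[2]
  expect_equal(as.numeric(substr(raw, 31, 38)),
               unname(m$coords$positions[2, 1]) * 10, tolerance = 1e-3)
  # atom-count mismatch at pairing time
  expect_error(read_coordinates(f_gro, top = fx_top("ethane_ua")),
               class = "perttop_validation_error")
  # empty file
  fe <- file.path(dir, "empty.gro")
  file.create(fe)
  expect_error(read_coordinates(fe), class = "perttop_parse_error")
})

test_that("topology invariants are enforced at construction", {
  at <- tibble::tibble(name = c("A", "B"), type_id = c("X", "X"),
                       mass = c(1, 1), charge = c(0, 0), charge_group = 1L)
  pars <- list(b = list(kind = "bond", values = c(1, 1)))
  expect_error(ff_topology(at, bonds = tibble::tibble(i = 1L, j = 3L, ref = "b"),
                           params = pars), class = "perttop_validation_error")
  expect_error(ff_topology(at, bonds = tibble::tibble(i = 1L, j = 1L, ref = "b"),
                           params = pars), class = "perttop_validation_error")
  expect_error(ff_topology(at, bonds = tibble::tibble(i = 1L, j = 2L, ref = "zz"),
                           params = pars), class = "perttop_validation_error")
  expect_error(ff_topology(at[0, ], params = pars), class = "perttop_validation_error")
})
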