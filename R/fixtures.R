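# United-atom toy systems used throughout the package: methyl groups are
# single particles, as in united-atom force fields. All force-field constants
# below are invented but fixed: they stand in for real parameter sets, are
# internally consistent (shared types across molecules where the chemistry is
# shared), and every test expectation about them is computed by an oracle at
# test time rather than assumed.

fixture_params <- function() {
  bond <- function(kb, b0) list(kind = "bond", values = c(kb, b0))
  ang <- function(ka, th0) list(kind = "angle", values = c(ka, th0))
  dih <- function(k, phase, mult) list(kind = "dihedral", values = c(k, phase),
                                       mult = as.integer(mult))
  imp <- function(k, xi0) list(kind = "improper", values = c(k, xi0))
  list(
    b_CC = bond(700000, 0.153),
    b_CO = bond(800000, 0.143),
    b_OH = bond(900000, 0.100),
    b_NH = bond(950000, 0.104),   # identical in amine and amide forms
    b_CN = bond(750000, 0.147),   # C4-N, identical across lysine forms
    b_NM = bond(730000, 0.148),   # N-CH3 (methylated amine)
    b_NCac = bond(760000, 0.133), # N-C amide
    b_CO2 = bond(1200000, 0.123), # C=O
    b_ring = bond(690000, 0.139),
    b_CH = bond(820000, 0.109),
    b_CF = bond(850000, 0.136),
    a_CCC = ang(530, 111.0),
    a_CCO = ang(520, 109.5),
    a_COH = ang(450, 108.5),
    a_CCN = ang(510, 111.0),
    a_CNH = ang(400, 109.5),      # identical in amine and amide forms
    a_CNM = ang(420, 112.0),
    a_CNC = ang(430, 121.0),
    a_HNC = ang(410, 117.0),
    a_NCO = ang(560, 122.0),
    a_NCC = ang(540, 116.0),
    a_OCC = ang(550, 122.0),
    a_ring = ang(560, 120.0),
    a_CCH = ang(505, 120.0),
    a_CCF = ang(495, 119.0),
    d_CCCC = dih(5.9, 0, 3),
    d_CCCN = dih(5.9, 0, 3),
    d_CCNH = dih(1.0, 0, 3),
    d_CCNM = dih(1.0, 0, 3),
    d_CCNC = dih(1.0, 180, 2),    # amide C4-N torsion: different multiplicity
    d_NCO = dih(33.5, 180, 2),
    d_NCC = dih(0.4, 0, 3),
    i_flat = imp(167.4, 0)
  )
}

fixture_masses <- c(CH3 = 15.035, CH2 = 14.027, CH1 = 13.019, CR1 = 13.019,
                    OA = 15.9994, O = 15.9994, N = 14.0067, NL = 14.0067,
                    NT = 14.0067, H = 1.008, C = 12.011, F = 18.9984)

fixture_atoms <- function(names, types, charges, groups = NULL) {
  tibble::tibble(
    name = names, type_id = unname(types), mass = unname(fixture_masses[types]),
    charge = unname(charges),
    charge_group = if (is.null(groups)) rep(1L, length(names)) else as.integer(groups)
  )
}

# build a term tibble from rows like c(i, j, ..., "ref")
tt <- function(arity, rows) {
  if (!length(rows)) {
    cols <- c("i", "j", "k", "l")[seq_len(arity)]
    out <- tibble::as_tibble(stats::setNames(rep(list(integer()), arity), cols))
    out$ref <- character()
    return(out)
  }
  idx <- t(vapply(rows, function(r) as.integer(r[seq_len(arity)]), integer(arity)))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(idx),
                                           c("i", "j", "k", "l")[seq_len(arity)]))
  out$ref <- vapply(rows, function(r) as.character(r[arity + 1L]), character(1))
  out
}

# exclusions = 1st+2nd bonded neighbours; 1-4 pairs = 3rd neighbours
derive_exclusions <- function(top) {
  g <- build_graph(top)
  n <- g$n
  excl <- vector("list", n)
  p14 <- list()
  for (a in seq_len(n)) {
    d1 <- g$adj[[a]]
    d2 <- setdiff(first_neighbors(g, c(a, d1)), a)
    d3 <- setdiff(first_neighbors(g, c(a, d1, d2)), a)
    excl[[a]] <- sort(union(d1, d2))
    for (b in d3) if (b > a) p14[[length(p14) + 1L]] <- c(a, b)
  }
  list(exclusions = excl,
       pairs14 = if (length(p14)) {
         m <- do.call(rbind, p14)
         tibble::tibble(i = m[, 1], j = m[, 2])
       } else NULL)
}

fixture_top <- function(name, atoms, bonds, angles = list(), dihedrals = list(),
                        impropers = list()) {
  pars <- fixture_params()
  top <- ff_topology(atoms,
                     bonds = tt(2L, bonds), angles = tt(3L, angles),
                     dihedrals = tt(4L, dihedrals), impropers = tt(4L, impropers),
                     params = pars, dialect = "gromos", title = name)
  ex <- derive_exclusions(top)
  ff_topology(top$atoms[, -1], bonds = top$bonds, angles = top$angles,
              dihedrals = top$dihedrals, impropers = top$impropers,
              params = pars, exclusions = ex$exclusions, pairs14 = ex$pairs14,
              dialect = "gromos", title = name)
}

ring_coords <- function(k, r = 0.15, z = 0) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  cbind(r * cos(th), r * sin(th), rep(z, k))
}

# three tetrahedral-ish substituent directions around a terminal centre,
# deterministically jittered so symmetric mappings have distinct RMSDs
subst_dirs <- function(jit = 0) {
  d <- rbind(c(0.5, 0.866, 0), c(0.5, -0.433, 0.75), c(0.5, -0.433, -0.75))
  d <- d / sqrt(rowSums(d^2))
  d + jit * rbind(c(0.01, 0.02, -0.01), c(-0.02, 0.01, 0.015), c(0.012, -0.018, 0.02))
}

chain_coords <- function(n, step = 0.153) cbind(step * (seq_len(n) - 1), 0, 0)

fixture_builders <- function() {
  list(
    methanol_ua = function() {
      at <- fixture_atoms(c("CH3", "OA", "H"), c("CH3", "OA", "H"),
                          c(0.176, -0.574, 0.398))
      top <- fixture_top("methanol_ua", at,
                         bonds = list(c(1, 2, "b_CO"), c(2, 3, "b_OH")),
                         angles = list(c(1, 2, 3, "a_COH")))
      co <- coord_set(rbind(c(0, 0, 0), c(0.143, 0, 0),
                            c(0.143 + 0.1 * 0.5, 0.1 * 0.866, 0)), top)
      list(top = top, coords = co)
    },
    ethane_ua = function() {
      at <- fixture_atoms(c("CH3A", "CH3B"), c("CH3", "CH3"), c(0, 0))
      top <- fixture_top("ethane_ua", at, bonds = list(c(1, 2, "b_CC")))
      list(top = top, coords = coord_set(rbind(c(0, 0, 0), c(0.153, 0, 0)), top))
    },
    lysine_side = function() {
      at <- fixture_atoms(c("C1", "C2", "C3", "C4", "N", "H1", "H2", "H3"),
                          c("CH2", "CH2", "CH2", "CH2", "NL", "H", "H", "H"),
                          c(0, 0, 0, 0.127, 0.129, 0.248, 0.248, 0.248),
                          groups = c(1, 1, 1, 2, 2, 2, 2, 2))
      top <- fixture_top("lysine_side", at,
        bonds = list(c(1, 2, "b_CC"), c(2, 3, "b_CC"), c(3, 4, "b_CC"),
                     c(4, 5, "b_CN"), c(5, 6, "b_NH"), c(5, 7, "b_NH"),
                     c(5, 8, "b_NH")),
        angles = list(c(1, 2, 3, "a_CCC"), c(2, 3, 4, "a_CCC"),
                      c(3, 4, 5, "a_CCN"), c(4, 5, 6, "a_CNH"),
                      c(4, 5, 7, "a_CNH"), c(4, 5, 8, "a_CNH")),
        dihedrals = list(c(1, 2, 3, 4, "d_CCCC"), c(2, 3, 4, 5, "d_CCCN"),
                         c(3, 4, 5, 6, "d_CCNH"), c(3, 4, 5, 7, "d_CCNH"),
                         c(3, 4, 5, 8, "d_CCNH")))
      xyz <- rbind(chain_coords(4), c(0.606, 0, 0))
      xyz <- rbind(xyz, sweep(0.104 * subst_dirs(1), 2, xyz[5, ], `+`))
      list(top = top, coords = coord_set(xyz, top))
    },
    trimethyllysine_side = function() {
      at <- fixture_atoms(c("C1", "C2", "C3", "C4", "N", "M1", "M2", "M3"),
                          c("CH2", "CH2", "CH2", "CH2", "NT", "CH3", "CH3", "CH3"),
                          c(0, 0, 0, 0.25, 0, 0.25, 0.25, 0.25),
                          groups = c(1, 1, 1, 2, 2, 2, 2, 2))
      top <- fixture_top("trimethyllysine_side", at,
        bonds = list(c(1, 2, "b_CC"), c(2, 3, "b_CC"), c(3, 4, "b_CC"),
                     c(4, 5, "b_CN"), c(5, 6, "b_NM"), c(5, 7, "b_NM"),
                     c(5, 8, "b_NM")),
        angles = list(c(1, 2, 3, "a_CCC"), c(2, 3, 4, "a_CCC"),
                      c(3, 4, 5, "a_CCN"), c(4, 5, 6, "a_CNM"),
                      c(4, 5, 7, "a_CNM"), c(4, 5, 8, "a_CNM")),
        dihedrals = list(c(1, 2, 3, 4, "d_CCCC"), c(2, 3, 4, 5, "d_CCCN"),
                         c(3, 4, 5, 6, "d_CCNM"), c(3, 4, 5, 7, "d_CCNM"),
                         c(3, 4, 5, 8, "d_CCNM")))
      xyz <- rbind(chain_coords(4), c(0.606, 0, 0))
      xyz <- rbind(xyz, sweep(0.148 * subst_dirs(0.6), 2, xyz[5, ], `+`))
      list(top = top, coords = coord_set(xyz, top))
    },
    acetyllysine_side = function() {
      at <- fixture_atoms(c("C1", "C2", "C3", "C4", "N", "H", "C", "O", "CH3"),
                          c("CH2", "CH2", "CH2", "CH2", "N", "H", "C", "O", "CH3"),
                          c(0, 0, 0, 0, -0.31, 0.31, 0.38, -0.38, 0),
                          groups = c(1, 1, 1, 1, 2, 2, 3, 3, 3))
      top <- fixture_top("acetyllysine_side", at,
        bonds = list(c(1, 2, "b_CC"), c(2, 3, "b_CC"), c(3, 4, "b_CC"),
                     c(4, 5, "b_CN"), c(5, 6, "b_NH"), c(5, 7, "b_NCac"),
                     c(7, 8, "b_CO2"), c(7, 9, "b_CC")),
        angles = list(c(1, 2, 3, "a_CCC"), c(2, 3, 4, "a_CCC"),
                      c(3, 4, 5, "a_CCN"), c(4, 5, 6, "a_CNH"),
                      c(4, 5, 7, "a_CNC"), c(6, 5, 7, "a_HNC"),
                      c(5, 7, 8, "a_NCO"), c(5, 7, 9, "a_NCC"),
                      c(8, 7, 9, "a_OCC")),
        dihedrals = list(c(1, 2, 3, 4, "d_CCCC"), c(2, 3, 4, 5, "d_CCCN"),
                         c(3, 4, 5, 6, "d_CCNH"), c(3, 4, 5, 7, "d_CCNC"),
                         c(4, 5, 7, 8, "d_NCO"), c(4, 5, 7, 9, "d_NCC")),
        impropers = list(c(5, 4, 7, 6, "i_flat"),   # planarity at amide N
                         c(7, 5, 8, 9, "i_flat")))  # planarity at carbonyl C
      xyz <- rbind(chain_coords(4), c(0.606, 0, 0))
      dirs <- subst_dirs(0.3)
      xyz <- rbind(xyz,
                   xyz[5, ] + 0.104 * dirs[1, ],   # H
                   xyz[5, ] + 0.133 * dirs[2, ])   # C
      xyz <- rbind(xyz,
                   xyz[7, ] + 0.123 * dirs[3, ],   # O
                   xyz[7, ] + 0.153 * dirs[1, ])   # CH3
      list(top = top, coords = coord_set(xyz, top))
    },
    hexane_ua = function() {
      at <- fixture_atoms(paste0("C", 1:6),
                          c("CH3", rep("CH2", 4), "CH3"), rep(0, 6))
      top <- fixture_top("hexane_ua", at,
        bonds = lapply(1:5, function(i) c(i, i + 1, "b_CC")),
        angles = lapply(1:4, function(i) c(i, i + 1, i + 2, "a_CCC")),
        dihedrals = lapply(1:3, function(i) c(i, i + 1, i + 2, i + 3, "d_CCCC")))
      list(top = top, coords = coord_set(chain_coords(6), top))
    },
    cyclohexane = function() {
      at <- fixture_atoms(paste0("C", 1:6), rep("CH2", 6), rep(0, 6))
      top <- fixture_top("cyclohexane", at,
        bonds = lapply(1:6, function(i) c(i, i %% 6 + 1, "b_CC")),
        angles = lapply(1:6, function(i) c(i, i %% 6 + 1, (i + 1) %% 6 + 1, "a_CCC")))
      list(top = top, coords = coord_set(ring_coords(6, 0.153), top))
    },
    methylcyclohexane = function() {
      at <- fixture_atoms(c(paste0("C", 1:6), "M1"),
                          c("CH1", rep("CH2", 5), "CH3"), rep(0, 7))
      top <- fixture_top("methylcyclohexane", at,
        bonds = c(lapply(1:6, function(i) c(i, i %% 6 + 1, "b_CC")),
                  list(c(1, 7, "b_CC"))),
        angles = c(lapply(1:6, function(i) c(i, i %% 6 + 1, (i + 1) %% 6 + 1, "a_CCC")),
                   list(c(7, 1, 2, "a_CCC"), c(7, 1, 6, "a_CCC"))))
      xyz <- ring_coords(6, 0.153)
      xyz <- rbind(xyz, xyz[1, ] * 2)
      list(top = top, coords = coord_set(xyz, top))
    },
    dimethylcyclohexane_12 = function() {
      at <- fixture_atoms(c(paste0("C", 1:6), "M1", "M2"),
                          c("CH1", "CH1", rep("CH2", 4), "CH3", "CH3"), rep(0, 8))
      top <- fixture_top("dimethylcyclohexane_12", at,
        bonds = c(lapply(1:6, function(i) c(i, i %% 6 + 1, "b_CC")),
                  list(c(1, 7, "b_CC"), c(2, 8, "b_CC"))),
        angles = c(lapply(1:6, function(i) c(i, i %% 6 + 1, (i + 1) %% 6 + 1, "a_CCC")),
                   list(c(7, 1, 2, "a_CCC"), c(7, 1, 6, "a_CCC"),
                        c(8, 2, 1, "a_CCC"), c(8, 2, 3, "a_CCC"))))
      xyz <- ring_coords(6, 0.153)
      xyz <- rbind(xyz, xyz[1, ] * 2, xyz[2, ] * 2)
      list(top = top, coords = coord_set(xyz, top))
    },
    dimethylcyclohexane_13 = function() {
      at <- fixture_atoms(c(paste0("C", 1:6), "M1", "M2"),
                          c("CH1", "CH2", "CH1", rep("CH2", 3), "CH3", "CH3"),
                          rep(0, 8))
      top <- fixture_top("dimethylcyclohexane_13", at,
        bonds = c(lapply(1:6, function(i) c(i, i %% 6 + 1, "b_CC")),
                  list(c(1, 7, "b_CC"), c(3, 8, "b_CC"))),
        angles = c(lapply(1:6, function(i) c(i, i %% 6 + 1, (i + 1) %% 6 + 1, "a_CCC")),
                   list(c(7, 1, 2, "a_CCC"), c(7, 1, 6, "a_CCC"),
                        c(8, 3, 2, "a_CCC"), c(8, 3, 4, "a_CCC"))))
      xyz <- ring_coords(6, 0.153)
      xyz <- rbind(xyz, xyz[1, ] * 2, xyz[3, ] * 2)
      list(top = top, coords = coord_set(xyz, top))
    },
    fused_bicycle = function() {
      # decalin-like: rings (1,3,4,5,6,2) and (1,7,8,9,10,2) share edge 1-2
      at <- fixture_atoms(paste0("C", 1:10),
                          c("CH1", "CH1", rep("CH2", 8)), rep(0, 10))
      top <- fixture_top("fused_bicycle", at,
        bonds = list(c(1, 2, "b_CC"), c(1, 3, "b_CC"), c(3, 4, "b_CC"),
                     c(4, 5, "b_CC"), c(5, 6, "b_CC"), c(6, 2, "b_CC"),
                     c(1, 7, "b_CC"), c(7, 8, "b_CC"), c(8, 9, "b_CC"),
                     c(9, 10, "b_CC"), c(10, 2, "b_CC")),
        angles = list(c(2, 1, 3, "a_CCC"), c(1, 3, 4, "a_CCC"),
                      c(3, 4, 5, "a_CCC"), c(4, 5, 6, "a_CCC"),
                      c(5, 6, 2, "a_CCC"), c(6, 2, 1, "a_CCC"),
                      c(2, 1, 7, "a_CCC"), c(1, 7, 8, "a_CCC"),
                      c(7, 8, 9, "a_CCC"), c(8, 9, 10, "a_CCC"),
                      c(9, 10, 2, "a_CCC"), c(10, 2, 1, "a_CCC"),
                      c(3, 1, 7, "a_CCC"), c(6, 2, 10, "a_CCC")))
      ra <- ring_coords(6, 0.153)
      rb <- ra[3:6, , drop = FALSE]
      rb[, 2] <- -rb[, 2]
      rb[, 1] <- rb[, 1] + 0.153
      xyz <- rbind(ra[1, ], ra[2, ], ra[3:6, , drop = FALSE], rb)
      list(top = top, coords = coord_set(xyz, top))
    },
    bridged_bicycle = function() {
      # norbornane-like: bridgeheads 1 and 4, bridge atom 7
      at <- fixture_atoms(paste0("C", 1:7),
                          c("CH1", "CH2", "CH2", "CH1", "CH2", "CH2", "CH2"),
                          rep(0, 7))
      top <- fixture_top("bridged_bicycle", at,
        bonds = list(c(1, 2, "b_CC"), c(2, 3, "b_CC"), c(3, 4, "b_CC"),
                     c(1, 5, "b_CC"), c(5, 6, "b_CC"), c(6, 4, "b_CC"),
                     c(1, 7, "b_CC"), c(7, 4, "b_CC")),
        angles = list(c(1, 2, 3, "a_CCC"), c(2, 3, 4, "a_CCC"),
                      c(1, 5, 6, "a_CCC"), c(5, 6, 4, "a_CCC"),
                      c(1, 7, 4, "a_CCC")))
      xyz <- rbind(c(0, 0, 0), c(0.1, 0.14, 0), c(0.25, 0.14, 0),
                   c(0.35, 0, 0), c(0.1, -0.14, 0), c(0.25, -0.14, 0),
                   c(0.175, 0.02, 0.12))
      list(top = top, coords = coord_set(xyz, top))
    },
    spiro_bicycle = function() {
      # spiro[4.4]: atom 1 shared between rings (1..5) and (1,6..9)
      at <- fixture_atoms(paste0("C", 1:9),
                          c("CH1", rep("CH2", 8)), rep(0, 9))
      top <- fixture_top("spiro_bicycle", at,
        bonds = list(c(1, 2, "b_CC"), c(2, 3, "b_CC"), c(3, 4, "b_CC"),
                     c(4, 5, "b_CC"), c(5, 1, "b_CC"),
                     c(1, 6, "b_CC"), c(6, 7, "b_CC"), c(7, 8, "b_CC"),
                     c(8, 9, "b_CC"), c(9, 1, "b_CC")),
        angles = list(c(1, 2, 3, "a_CCC"), c(2, 3, 4, "a_CCC"),
                      c(3, 4, 5, "a_CCC"), c(4, 5, 1, "a_CCC"),
                      c(5, 1, 2, "a_CCC"),
                      c(1, 6, 7, "a_CCC"), c(6, 7, 8, "a_CCC"),
                      c(7, 8, 9, "a_CCC"), c(8, 9, 1, "a_CCC"),
                      c(9, 1, 6, "a_CCC")))
      r1 <- ring_coords(5, 0.13)
      r2 <- ring_coords(5, 0.13)
      r2[, 1] <- -r2[, 1] + 2 * r1[1, 1]
      r2 <- r2[2:5, , drop = FALSE]
      list(top = top, coords = coord_set(rbind(r1, r2), top))
    },
    hf_ligand_a = function() hf_ligand("hf_ligand_a", "H", "H"),
    hf_ligand_b = function() hf_ligand("hf_ligand_b", "F", "H"),
    hf_ligand_c = function() hf_ligand("hf_ligand_c", "H", "F")
  )
}

# benzothiadiazine-style congeneric ligand reduced to a six-membered
# united-atom ring with substituents (H or F) at positions 1 and 4
hf_ligand <- function(name, sub1, sub2) {
  sub_type <- c(H = "H", F = "F")
  sub_bond <- c(H = "b_CH", F = "b_CF")
  sub_ang <- c(H = "a_CCH", F = "a_CCF")
  c_charge <- c(H = -0.011, F = 0.11)
  s_charge <- c(H = 0.011, F = -0.11)
  ch <- rep(0, 6); ch[1] <- c_charge[sub1]; ch[4] <- c_charge[sub2]
  at <- fixture_atoms(c(paste0("C", 1:6), paste0("R", 1:2)),
                      c(rep("CR1", 6), sub_type[sub1], sub_type[sub2]),
                      c(ch, s_charge[sub1], s_charge[sub2]))
  top <- fixture_top(name, at,
    bonds = c(lapply(1:6, function(i) c(i, i %% 6 + 1, "b_ring")),
              list(c(1, 7, sub_bond[sub1]), c(4, 8, sub_bond[sub2]))),
    angles = c(lapply(1:6, function(i) c(i, i %% 6 + 1, (i + 1) %% 6 + 1, "a_ring")),
               list(c(7, 1, 2, sub_ang[sub1]), c(7, 1, 6, sub_ang[sub1]),
                    c(8, 4, 3, sub_ang[sub2]), c(8, 4, 5, sub_ang[sub2]))))
  xyz <- ring_coords(6, 0.139)
  xyz <- rbind(xyz, xyz[1, ] * 1.8, xyz[4, ] * 1.8)
  list(top = top, coords = coord_set(xyz, top))
}

#' Names of the registered toy systems
#' @return Character vector of fixture names accepted by [make_fixture()].
#' @export
fixture_names <- function() c(names(fixture_builders()), "hf_ligand_series")

#' Build a registered toy topology
#'
#' Deterministic united-atom toy systems emulating the classes of
#' perturbation problems the package targets: a methanol/ethane pair, the
#' lysine side chain and its trimethylated and acetylated forms, alkanes,
#' cyclohexanes with methyl substituents, fused/bridged/spiro polycycles, and
#' a halogen-substituted congeneric ligand series. Each fixture carries a
#' deterministic coordinate set for RMSD-based solution ranking.
#'
#' @param name Fixture name; see [fixture_names()]. `"hf_ligand_series"`
#'   returns a list of the three congeneric ligands.
#' @return A list with elements `top` (an `fftop`) and `coords` (a
#'   `coordset`), or a list of such lists for the series.
#' @export
make_fixture <- function(name) {
  builders <- fixture_builders()
  if (identical(name, "hf_ligand_series"))
    return(list(builders$hf_ligand_a(), builders$hf_ligand_b(),
                builders$hf_ligand_c()))
  if (!name %in% names(builders))
    rlang::abort(sprintf("unknown fixture '%s'; known fixtures: %s", name,
                         paste(fixture_names(), collapse = ", ")),
                 class = "perttop_registry_error")
  builders[[name]]()
}
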