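# Serialization of perturbation and EDS topologies.
#
# GROMACS: a single topology whose [ atoms ] lines carry
#   nr type resnr residue atom cgnr charge mass typeB chargeB massB
# and whose bonded lines carry the A-state parameters followed by the
# B-state parameters. A bonded term absent in one state is written with a
# zero force constant in that state (and the other state's equilibrium
# value); reading maps zero force constants back to "absent".
#
# GROMOS: a reference topology (state A, dummies typed as the dummy type
# with zero charge) plus a perturbation file with PERTATOMPARAM /
# PERTBONDSTRETCH / PERTBONDANGLE / PERTPROPERDIH / PERTIMPROPERDIH blocks.
# Parameters are written inline (values, not type codes) and atom types by
# name, which keeps the files self-contained and round-trippable.

pert_blocks <- c("TITLE", "PERTATOMPARAM", "PERTBONDSTRETCH", "PERTBONDANGLE",
                 "PERTPROPERDIH", "PERTIMPROPERDIH", "MPERTATOM")

pert_ref_values <- function(pert, ref) {
  if (is.na(ref)) return(NULL)
  p <- pert$params[[ref]]
  if (is.null(p)) rlang::abort(sprintf("unresolved parameter reference '%s'", ref),
                               class = "perttop_serialization_error")
  p
}

# A/B parameter columns for one term; absent side = zero force constant
pert_term_cols <- function(pert, ref_a, ref_b, kind) {
  pa <- pert_ref_values(pert, ref_a); pb <- pert_ref_values(pert, ref_b)
  if (is.null(pa) && is.null(pb))
    rlang::abort("term absent in both states", class = "perttop_serialization_error")
  mk <- function(p, other) {
    if (!is.null(p)) return(p)
    out <- other
    out$values[1] <- 0
    out
  }
  list(a = mk(pa, pb), b = mk(pb, pa))
}

#' Write a perturbation topology
#'
#' Serializes a [build_pert_topology()] result for free-energy calculations:
#' the GROMACS dialect writes one topology with per-atom and per-term A/B
#' state parameters (`<prefix>.top`); the GROMOS dialect writes a reference
#' topology (`<prefix>.top`, state A with dummy atoms carrying the dummy
#' type) plus perturbation blocks (`<prefix>.ptp`). Files are re-readable
#' with [read_perturbation()]. Per-state exclusions are merged on output.
#'
#' @param pert A `pert_topology`.
#' @param prefix Output path prefix (extensions are appended).
#' @param dialect `"gromos"` or `"gromacs"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_perturbation <- function(pert, prefix, dialect = c("gromos", "gromacs")) {
  dialect <- match.arg(dialect)
  at <- pert$atoms
  if (dialect == "gromos" && anyNA(at$charge_group))
    rlang::abort("GROMOS dialect requires charge groups",
                 class = "perttop_serialization_error")
  excl_u <- lapply(seq_len(nrow(at)), function(u)
    sort(union(pert$excl_a[[u]], pert$excl_b[[u]])))
  p14_u <- dplyr::distinct(dplyr::bind_rows(pert$p14_a, pert$p14_b))
  if (dialect == "gromacs") {
    out <- c("; perturbation topology (A/B state columns)", "[ moleculetype ]",
             paste(gsub("[ \t]", "_", paste0(pert$state_labels[1], "_to_",
                                             pert$state_labels[2])), 3),
             "", "[ atoms ]",
             ";  nr typeA resnr res atom cgnr chargeA massA typeB chargeB massB")
    cg <- at$charge_group
    if (anyNA(cg)) cg <- seq_len(nrow(at))
    for (u in seq_len(nrow(at)))
      out <- c(out, sprintf("%5d %-6s %4d %-5s %-6s %4d %10.6f %10.5f %-6s %10.6f %10.5f",
                            u, at$type_a[u], 1L, "MOL", at$name[u], cg[u],
                            at$charge_a[u], at$mass_a[u],
                            at$type_b[u], at$charge_b[u], at$mass_b[u]))
    emit <- function(header, tb, arity, funct, par_cols) {
      if (!nrow(tb)) return(character())
      ll <- c("", sprintf("[ %s ]", header))
      for (r in seq_len(nrow(tb))) {
        pc <- pert_term_cols(pert, tb$ref_a[r], tb$ref_b[r], NULL)
        ll <- c(ll, paste(c(sprintf("%5d", as.integer(tb[r, seq_len(arity)])),
                            sprintf("%3d", funct),
                            par_cols(pc$a), par_cols(pc$b)), collapse = " "))
      }
      ll
    }
    kb_cols <- function(p) fmt_num(c(p$values[2], p$values[1]))
    dih_cols <- function(p) c(fmt_num(c(p$values[2], p$values[1])), p$mult)
    out <- c(out,
             emit("bonds", pert$bonds, 2L, 1L, kb_cols),
             emit("angles", pert$angles, 3L, 1L, kb_cols),
             emit("dihedrals", pert$dihedrals, 4L, 1L, dih_cols),
             emit("dihedrals", pert$impropers, 4L, 2L, kb_cols))
    if (nrow(p14_u)) {
      out <- c(out, "", "[ pairs ]",
               sprintf("%5d %5d %3d", p14_u$i, p14_u$j, 1L))
    }
    if (any(lengths(excl_u) > 0)) {
      out <- c(out, "", "[ exclusions ]")
      for (u in seq_along(excl_u))
        if (length(excl_u[[u]]))
          out <- c(out, paste(c(u, excl_u[[u]]), collapse = " "))
    }
    f <- paste0(prefix, ".top")
    writeLines(out, f)
    return(invisible(f))
  }
  # GROMOS: reference topology + .ptp perturbation blocks
  ref_top <- pert_reference_topology(pert, excl_u, p14_u)
  f_top <- paste0(prefix, ".top")
  write_topology(ref_top, f_top, "gromos")
  ptp <- c("TITLE",
           sprintf("perturbation %s -> %s", pert$state_labels[1], pert$state_labels[2]),
           "END", "PERTATOMPARAM", "# NJLA", nrow(at),
           "#  NR NAME IACA MASSA CHARGEA IACB MASSB CHARGEB")
  for (u in seq_len(nrow(at)))
    ptp <- c(ptp, paste(u, at$name[u], at$type_a[u],
                        sprintf("%.5f", at$mass_a[u]), sprintf("%.6f", at$charge_a[u]),
                        at$type_b[u],
                        sprintf("%.5f", at$mass_b[u]), sprintf("%.6f", at$charge_b[u])))
  ptp <- c(ptp, "END")
  emit_pert_terms <- function(block, tb, arity, with_mult = FALSE) {
    rows <- character()
    for (r in seq_len(nrow(tb))) {
      pa <- pert_ref_values(pert, tb$ref_a[r]); pb <- pert_ref_values(pert, tb$ref_b[r])
      perturbed <- is.null(pa) || is.null(pb) || !params_equal(pa, pb) ||
        (with_mult && !identical(pa$mult, pb$mult))
      if (!perturbed) next
      pc <- pert_term_cols(pert, tb$ref_a[r], tb$ref_b[r], NULL)
      rows <- c(rows, paste(c(as.integer(tb[r, seq_len(arity)]),
                              fmt_num(pc$a$values), if (with_mult) pc$a$mult,
                              fmt_num(pc$b$values), if (with_mult) pc$b$mult),
                            collapse = " "))
    }
    if (!length(rows)) return(character())
    c(block, "# N", length(rows), rows, "END")
  }
  ptp <- c(ptp,
           emit_pert_terms("PERTBONDSTRETCH", pert$bonds, 2L),
           emit_pert_terms("PERTBONDANGLE", pert$angles, 3L),
           emit_pert_terms("PERTPROPERDIH", pert$dihedrals, 4L, with_mult = TRUE),
           emit_pert_terms("PERTIMPROPERDIH", pert$impropers, 4L))
  f_ptp <- paste0(prefix, ".ptp")
  writeLines(ptp, f_ptp)
  invisible(c(f_top, f_ptp))
}

# state-A reference topology holding the full union (dummy atoms typed as
# the dummy type; one-state-only terms carry that state's parameters)
pert_reference_topology <- function(pert, excl_u, p14_u) {
  at <- pert$atoms
  atoms <- tibble::tibble(name = at$name, type_id = at$type_a, mass = at$mass_a,
                          charge = at$charge_a, charge_group = at$charge_group)
  taketb <- function(tb, arity) {
    if (!nrow(tb)) return(NULL)
    ref <- ifelse(is.na(tb$ref_a), tb$ref_b, tb$ref_a)
    out <- tb[, seq_len(arity)]
    out$ref <- ref
    out
  }
  ff_topology(atoms, bonds = taketb(pert$bonds, 2L),
              angles = taketb(pert$angles, 3L),
              dihedrals = taketb(pert$dihedrals, 4L),
              impropers = taketb(pert$impropers, 4L),
              params = pert$params, exclusions = excl_u, pairs14 = p14_u,
              dialect = "gromos",
              title = paste0(pert$state_labels[1], "_to_", pert$state_labels[2]))
}

#' Read a perturbation topology from files
#'
#' Inverse of [write_perturbation()]: reconstructs a `pert_topology` (without
#' search provenance) from `<prefix>.top` (+ `<prefix>.ptp` for GROMOS).
#' Atoms typed with `dummy_type` in a state are that state's dummies; bonded
#' terms with a zero force constant in one state are treated as absent in
#' that state.
#'
#' @param prefix Path prefix used at write time.
#' @param dialect `"gromos"` or `"gromacs"`.
#' @param dummy_type Dummy atom-type name.
#' @return A `pert_topology` (fields `solution`, per-state exclusions merged).
#' @export
read_perturbation <- function(prefix, dialect = c("gromos", "gromacs"),
                              dummy_type = "DUM") {
  dialect <- match.arg(dialect)
  f_top <- paste0(prefix, ".top")
  if (dialect == "gromacs") {
    pert <- parse_gromacs_pert(f_top, dummy_type)
  } else {
    pert <- parse_gromos_pert(f_top, paste0(prefix, ".ptp"), dummy_type)
  }
  pert
}

finish_read_pert <- function(atoms, terms, params, excl, p14, labels, dummy_type) {
  atoms$dummy_a <- atoms$type_a == dummy_type
  atoms$dummy_b <- atoms$type_b == dummy_type
  # original per-state indices are not stored on disk; file order follows the
  # state-A order, so it is reconstructed positionally
  atoms$name_a <- atoms$name; atoms$name_b <- atoms$name
  atoms$cg_a <- atoms$charge_group; atoms$cg_b <- atoms$charge_group
  atoms$orig_a <- NA_integer_; atoms$orig_b <- NA_integer_
  atoms$orig_a[!atoms$dummy_a] <- seq_len(sum(!atoms$dummy_a))
  atoms$orig_b[!atoms$dummy_b] <- seq_len(sum(!atoms$dummy_b))
  structure(list(atoms = atoms, bonds = terms$bonds, angles = terms$angles,
                 dihedrals = terms$dihedrals, impropers = terms$impropers,
                 params = params, excl_a = excl, excl_b = excl,
                 p14_a = p14, p14_b = p14, state_labels = labels,
                 dummy_type = dummy_type, solution = NULL),
            class = "pert_topology")
}

parse_gromacs_pert <- function(path, dummy_type) {
  if (!file.exists(path))
    rlang::abort(sprintf("cannot read perturbation file: %s", path),
                 class = "perttop_io_error")
  lines <- gromacs_preprocess(readLines(path, warn = FALSE), path)
  section <- NA_character_
  title <- "pert"
  atoms <- list(); params <- list()
  terms <- list(bonds = list(), angles = list(), dihedrals = list(),
                impropers = list())
  excl_rows <- list(); pairs <- list()
  pkey <- function(kind, values, mult = NULL) {
    if (values[1] == 0) return(NA_character_)
    key <- paste0(kind, ":", paste(signif(values, 12), collapse = ","),
                  if (!is.null(mult)) paste0(";m", mult))
    if (is.null(params[[key]]))
      params[[key]] <<- c(list(kind = kind, values = values),
                          if (!is.null(mult)) list(mult = as.integer(mult)))
    key
  }
  for (li in seq_along(lines)) {
    t <- trimws(lines[li])
    if (!nzchar(t)) next
    if (grepl("^\\[", t)) { section <- trimws(gsub("[][]", "", t)); next }
    tok <- strsplit(t, "[ \t]+")[[1]]
    if (identical(section, "moleculetype")) title <- tok[1]
    else if (identical(section, "atoms")) {
      if (length(tok) < 11L)
        rlang::abort(sprintf("%s:%d: perturbation atom line needs 11 fields", path, li),
                     class = "perttop_parse_error")
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        type_a = tok[2], name = tok[5], charge_group = as.integer(tok[6]),
        charge_a = num(tok[7]), mass_a = num(tok[8]),
        type_b = tok[9], charge_b = num(tok[10]), mass_b = num(tok[11]))
    } else if (identical(section, "bonds")) {
      v <- num(tok[4:7])
      terms$bonds[[length(terms$bonds) + 1L]] <-
        c(tok[1:2], pkey("bond", c(v[2], v[1])), pkey("bond", c(v[4], v[3])))
    } else if (identical(section, "angles")) {
      v <- num(tok[5:8])
      terms$angles[[length(terms$angles) + 1L]] <-
        c(tok[1:3], pkey("angle", c(v[2], v[1])), pkey("angle", c(v[4], v[3])))
    } else if (identical(section, "dihedrals")) {
      funct <- as.integer(tok[5])
      if (identical(funct, 1L)) {
        v <- num(tok[6:11])
        terms$dihedrals[[length(terms$dihedrals) + 1L]] <-
          c(tok[1:4], pkey("dihedral", c(v[2], v[1]), as.integer(v[3])),
            pkey("dihedral", c(v[5], v[4]), as.integer(v[6])))
      } else {
        v <- num(tok[6:9])
        terms$impropers[[length(terms$impropers) + 1L]] <-
          c(tok[1:4], pkey("improper", c(v[2], v[1])), pkey("improper", c(v[4], v[3])))
      }
    } else if (identical(section, "pairs")) {
      pairs[[length(pairs) + 1L]] <- as.integer(tok[1:2])
    } else if (identical(section, "exclusions")) {
      excl_rows[[length(excl_rows) + 1L]] <- as.integer(tok)
    }
  }
  atoms <- dplyr::bind_rows(atoms)
  atoms$index <- seq_len(nrow(atoms))
  term_tb <- function(rows, arity) {
    cols <- c("i", "j", "k", "l")[seq_len(arity)]
    if (!length(rows)) {
      out <- tibble::as_tibble(stats::setNames(rep(list(integer()), arity), cols))
      out$ref_a <- character(); out$ref_b <- character()
      return(out)
    }
    idx <- t(vapply(rows, function(r) as.integer(r[seq_len(arity)]), integer(arity)))
    out <- tibble::as_tibble(stats::setNames(as.data.frame(idx), cols))
    out$ref_a <- vapply(rows, function(r) r[arity + 1L], character(1))
    out$ref_b <- vapply(rows, function(r) r[arity + 2L], character(1))
    out
  }
  excl <- rep(list(integer()), nrow(atoms))
  for (row in excl_rows) excl[[row[1]]] <- sort(union(excl[[row[1]]], row[-1]))
  p14 <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    tibble::tibble(i = m[, 1], j = m[, 2])
  } else tibble::tibble(i = integer(), j = integer())
  labels <- strsplit(title, "_to_")[[1]]
  if (length(labels) != 2L) labels <- c("A", "B")
  tt <- list(bonds = term_tb(terms$bonds, 2L), angles = term_tb(terms$angles, 3L),
             dihedrals = term_tb(terms$dihedrals, 4L),
             impropers = term_tb(terms$impropers, 4L))
  finish_read_pert(atoms, tt, params, excl, p14, labels, dummy_type)
}

parse_gromos_pert <- function(f_top, f_ptp, dummy_type) {
  ref <- read_topology(f_top, "gromos")
  if (!file.exists(f_ptp))
    rlang::abort(sprintf("cannot read perturbation file: %s", f_ptp),
                 class = "perttop_io_error")
  blocks <- split_gromos_blocks(readLines(f_ptp, warn = FALSE), f_ptp,
                                known = pert_blocks)
  n <- nrow(ref$atoms)
  atoms <- tibble::tibble(index = seq_len(n), name = ref$atoms$name,
                          charge_group = ref$atoms$charge_group,
                          type_a = ref$atoms$type_id, mass_a = ref$atoms$mass,
                          charge_a = ref$atoms$charge,
                          type_b = ref$atoms$type_id, mass_b = ref$atoms$mass,
                          charge_b = ref$atoms$charge)
  if (!is.null(blocks$PERTATOMPARAM)) {
    ts <- token_stream(gromos_tokens(blocks$PERTATOMPARAM), f_ptp, "PERTATOMPARAM")
    na <- as.integer(ts$take())
    for (q in seq_len(na)) {
      rec <- ts$take(8L)
      u <- as.integer(rec[1])
      atoms$type_a[u] <- rec[3]; atoms$mass_a[u] <- num(rec[4])
      atoms$charge_a[u] <- num(rec[5])
      atoms$type_b[u] <- rec[6]; atoms$mass_b[u] <- num(rec[7])
      atoms$charge_b[u] <- num(rec[8])
    }
  }
  params <- ref$params
  pkey <- function(kind, values, mult = NULL) {
    if (values[1] == 0) return(NA_character_)
    key <- paste0("P:", kind, ":", paste(signif(values, 12), collapse = ","),
                  if (!is.null(mult)) paste0(";m", mult))
    if (is.null(params[[key]]))
      params[[key]] <<- c(list(kind = kind, values = values),
                          if (!is.null(mult)) list(mult = as.integer(mult)))
    key
  }
  term_init <- function(tb, arity) {
    cols <- c("i", "j", "k", "l")[seq_len(arity)]
    out <- tb[, cols, drop = FALSE]
    out$ref_a <- tb$ref; out$ref_b <- tb$ref
    out
  }
  tt <- list(bonds = term_init(ref$bonds, 2L), angles = term_init(ref$angles, 3L),
             dihedrals = term_init(ref$dihedrals, 4L),
             impropers = term_init(ref$impropers, 4L))
  keyfs <- list(bonds = key2, angles = key3, dihedrals = key4, impropers = key4s)
  apply_block <- function(bn, kind, arity, nvals, with_mult = FALSE) {
    if (is.null(blocks[[bn]])) return()
    ts <- token_stream(gromos_tokens(blocks[[bn]]), f_ptp, bn)
    nterm <- as.integer(ts$take())
    tb <- tt[[kind]]
    keys <- vapply(seq_len(nrow(tb)), function(r)
      do.call(keyfs[[kind]], as.list(as.integer(tb[r, seq_len(arity)]))),
      character(1))
    per_side <- nvals + if (with_mult) 1L else 0L
    for (q in seq_len(nterm)) {
      rec <- ts$take(arity + 2L * per_side)
      av <- as.integer(rec[seq_len(arity)])
      va <- num(rec[arity + seq_len(per_side)])
      vb <- num(rec[arity + per_side + seq_len(per_side)])
      kk <- do.call(keyfs[[kind]], as.list(av))
      hit <- match(kk, keys)
      ra <- pkey(sub("s$", "", kind), va[seq_len(nvals)],
                 if (with_mult) as.integer(va[nvals + 1L]))
      rbv <- pkey(sub("s$", "", kind), vb[seq_len(nvals)],
                  if (with_mult) as.integer(vb[nvals + 1L]))
      if (is.na(hit)) {
        newrow <- as.list(av)
        names(newrow) <- c("i", "j", "k", "l")[seq_len(arity)]
        newrow$ref_a <- ra; newrow$ref_b <- rbv
        tb <- dplyr::bind_rows(tb, tibble::as_tibble(newrow))
        keys <- c(keys, kk)
      } else {
        tb$ref_a[hit] <- ra; tb$ref_b[hit] <- rbv
      }
    }
    tt[[kind]] <<- tb
  }
  apply_block("PERTBONDSTRETCH", "bonds", 2L, 2L)
  apply_block("PERTBONDANGLE", "angles", 3L, 2L)
  apply_block("PERTPROPERDIH", "dihedrals", 4L, 2L, with_mult = TRUE)
  apply_block("PERTIMPROPERDIH", "impropers", 4L, 2L)
  excl <- ref$exclusions
  labels <- strsplit(ref$title, "_to_")[[1]]
  if (length(labels) != 2L) labels <- c("A", "B")
  finish_read_pert(atoms, tt, params, excl, ref$pairs14, labels, dummy_type)
}

#' Semantic equality of two perturbation topologies
#'
#' Field-by-field comparison on the semantic content: per-state atom types,
#' masses, charges and dummy designations, and the bonded-term sets with
#' per-state resolved parameters (absent states compare as absent).
#'
#' @param a,b `pert_topology` objects.
#' @return TRUE/FALSE.
#' @export
pert_equal <- function(a, b) {
  if (nrow(a$atoms) != nrow(b$atoms)) return(FALSE)
  aa <- a$atoms; ab <- b$atoms
  ok <- all(aa$name == ab$name) &&
    all(aa$type_a == ab$type_a) && all(aa$type_b == ab$type_b) &&
    identical(aa$dummy_a, ab$dummy_a) && identical(aa$dummy_b, ab$dummy_b) &&
    all(masses_equal(aa$mass_a, ab$mass_a)) &&
    all(masses_equal(aa$mass_b, ab$mass_b)) &&
    all(charges_equal(aa$charge_a, ab$charge_a)) &&
    all(charges_equal(aa$charge_b, ab$charge_b))
  if (!ok) return(FALSE)
  side_sig <- function(p, ref) {
    if (is.na(ref)) return("absent")
    pp <- p$params[[ref]]
    paste(paste(signif(pp$values, 9), collapse = ","),
          if (is.null(pp$mult) || is.na(pp$mult)) "" else pp$mult)
  }
  for (sl in list(c("bonds", 2L), c("angles", 3L), c("dihedrals", 4L),
                  c("impropers", 4L))) {
    ta <- a[[sl[1]]]; tb <- b[[sl[1]]]
    arity <- as.integer(sl[2])
    sig <- function(p, tb) {
      if (!nrow(tb)) return(character())
      sort(vapply(seq_len(nrow(tb)), function(r)
        paste(paste(as.integer(tb[r, seq_len(arity)]), collapse = "-"),
              side_sig(p, tb$ref_a[r]), side_sig(p, tb$ref_b[r])),
        character(1)))
    }
    if (!identical(sig(a, ta), sig(b, tb))) return(FALSE)
  }
  TRUE
}

#' Write an EDS reference topology
#'
#' GROMOS dialect: a reference topology (`<prefix>.top`, state-1 parameters,
#' dummies typed as the dummy type) plus an MPERTATOM multistate block
#' (`<prefix>.ptp`) listing each union atom's type and charge in every
#' state. GROMACS dialect: one full topology per state
#' (`<prefix>_state<k>.top`) sharing the union atom list and bonded terms.
#'
#' @param eds An `eds_topology`.
#' @param prefix Output path prefix.
#' @param dialect `"gromos"` or `"gromacs"`.
#' @return Character vector of files written, invisibly.
#' @export
write_eds_topology <- function(eds, prefix, dialect = c("gromos", "gromacs")) {
  dialect <- match.arg(dialect)
  nu <- nrow(eds$atoms)
  excl_u <- lapply(seq_len(nu), function(u)
    sort(Reduce(union, lapply(eds$excl, function(e) e[[u]]))))
  p14_u <- dplyr::distinct(dplyr::bind_rows(eds$p14))
  state_union_top <- function(s) {
    atoms <- tibble::tibble(name = eds$names_mat[, s], type_id = eds$types[, s],
                            mass = eds$masses[, s], charge = eds$charges[, s],
                            charge_group = eds$cg_mat[, s])
    ff_topology(atoms, bonds = eds$bonds, angles = eds$angles,
                dihedrals = eds$dihedrals, impropers = eds$impropers,
                params = eds$params, exclusions = excl_u, pairs14 = p14_u,
                dialect = "gromos", title = eds$state_labels[s])
  }
  if (dialect == "gromacs") {
    files <- character()
    for (s in seq_len(eds$n_states)) {
      f <- sprintf("%s_state%d.top", prefix, s)
      write_topology(state_union_top(s), f, "gromacs")
      files <- c(files, f)
    }
    return(invisible(files))
  }
  f_top <- paste0(prefix, ".top")
  write_topology(state_union_top(1L), f_top, "gromos")
  ptp <- c("TITLE",
           paste("EDS reference over:", paste(eds$state_labels, collapse = " ")),
           "END", "MPERTATOM", "# NJLA NPTB", paste(nu, eds$n_states),
           paste(eds$state_labels, collapse = " "),
           "#  NR NAME IAC[1..N] CHARGE[1..N]")
  for (u in seq_len(nu))
    ptp <- c(ptp, paste(c(u, eds$atoms$name[u], eds$types[u, ],
                          sprintf("%.6f", eds$charges[u, ])), collapse = " "))
  ptp <- c(ptp, "END")
  f_ptp <- paste0(prefix, ".ptp")
  writeLines(ptp, f_ptp)
  invisible(c(f_top, f_ptp))
}
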