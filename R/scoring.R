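#' Penalty weights for the MCS score function
#'
#' The search minimises a penalty score over candidate atom mappings. Every
#' individual perturbation contributes a user-weighted penalty: matching an
#' atom to a dummy, matched atoms with differing type/mass/charge, perturbed
#' bonds, angles, proper and improper dihedrals, and dihedral-multiplicity
#' changes. Categories listed in `forbid` carry infinite penalty, which is
#' how alternative pathway definitions (e.g. "no perturbed bonds") are
#' expressed.
#'
#' The default maximises the number of matched atoms: the dummy penalty
#' strictly dominates all parameter-mismatch penalties, and with
#' `lexicographic = TRUE` (default) solutions are compared on the exact
#' (dummy count, weighted mismatch) pair instead of a single float, so the
#' weight magnitudes cannot introduce round-off artifacts.
#'
#' @param w_dummy Penalty per atom matched to a dummy.
#' @param w_atom_type,w_mass,w_charge Penalties per matched atom pair with
#'   differing type / mass / partial charge.
#' @param w_bond,w_angle,w_dihedral,w_improper Penalties per perturbed bonded
#'   term of each kind.
#' @param w_multiplicity Penalty per dihedral multiplicity change (applies
#'   only when the search options allow multiplicity changes).
#' @param w_make_break Penalty per bonded term created/removed (applies only
#'   when the search options allow creating/removing bonded terms).
#' @param forbid Character vector of categories with infinite penalty; any of
#'   `"atom_type"`, `"mass"`, `"charge"`, `"bond"`, `"angle"`, `"dihedral"`,
#'   `"improper"`, `"multiplicity"`, `"make_break"`, `"dummy"`.
#' @param lexicographic Compare scores on the exact (dummy count, weighted
#'   mismatch) key. Set `FALSE` to compare on the single weighted total.
#' @param custom_score Optional function of the breakdown count vector
#'   returning a numeric total, replacing the weighted sum (the comparison
#'   then uses that total; `forbid` still applies).
#' @return Object of class `score_spec`.
#' @export
score_spec <- function(w_dummy = 1000, w_atom_type = 1, w_mass = 1,
                       w_charge = 1, w_bond = 1, w_angle = 1, w_dihedral = 1,
                       w_improper = 1, w_multiplicity = 1, w_make_break = 1,
                       forbid = character(), lexicographic = TRUE,
                       custom_score = NULL) {
  w <- c(dummy = w_dummy, atom_type = w_atom_type, mass = w_mass,
         charge = w_charge, bond = w_bond, angle = w_angle,
         dihedral = w_dihedral, improper = w_improper,
         multiplicity = w_multiplicity, make_break = w_make_break)
  if (any(w < 0) || any(!is.finite(w)))
    rlang::abort("penalty weights must be finite and >= 0",
                 class = "perttop_validation_error")
  bad <- setdiff(forbid, names(w))
  if (length(bad))
    rlang::abort(sprintf("unknown forbid category: %s", paste(bad, collapse = ", ")),
                 class = "perttop_validation_error")
  if (!is.null(custom_score)) lexicographic <- FALSE
  structure(list(weights = w, forbid = forbid, lexicographic = lexicographic,
                 custom_score = custom_score),
            class = "score_spec")
}

score_categories <- function() {
  c("dummy", "atom_type", "mass", "charge", "bond", "angle", "dihedral",
    "improper", "multiplicity", "make_break")
}

empty_counts <- function() stats::setNames(rep(0L, 10L), score_categories())

# comparison key: lexicographic (dummy, weighted mismatch) pair by default,
# plain weighted total otherwise; (Inf, Inf) is the rejected-solution sentinel
score_key <- function(counts, spec, violated = FALSE) {
  if (violated || any(counts[spec$forbid] > 0)) return(c(Inf, Inf))
  if (!is.null(spec$custom_score)) return(c(spec$custom_score(counts), 0))
  w <- spec$weights
  if (spec$lexicographic) {
    mism <- sum(w[-1] * counts[names(w)[-1]])
    c(unname(counts["dummy"]), mism)
  } else {
    c(sum(w * counts[names(w)]), 0)
  }
}

score_total <- function(counts, spec, violated = FALSE) {
  if (violated || any(counts[spec$forbid] > 0)) return(Inf)
  if (!is.null(spec$custom_score)) return(spec$custom_score(counts))
  sum(spec$weights * counts[names(spec$weights)])
}

key_less <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
key_equal <- function(a, b) identical(a[1], b[1]) && identical(a[2], b[2])

key2 <- function(i, j) paste0(min(i, j), "-", max(i, j))
key3 <- function(i, j, k) if (i <= k) paste0(i, "-", j, "-", k) else paste0(k, "-", j, "-", i)
key4 <- function(i, j, k, l) {
  if (i < l || (i == l && j <= k)) paste0(i, "-", j, "-", k, "-", l)
  else paste0(l, "-", k, "-", j, "-", i)
}
key4s <- function(i, j, k, l) paste(sort(c(i, j, k, l)), collapse = "-")

# per-state lookup tables used by the breakdown computation
state_ctx <- function(top) {
  env_of <- function(tb, keyf, arity) {
    e <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(tb))) {
      kk <- do.call(keyf, as.list(as.integer(tb[r, seq_len(arity)])))
      assign(kk, tb$ref[r], envir = e)
    }
    e
  }
  list(top = top,
       bond_env = env_of(top$bonds, key2, 2L),
       angle_env = env_of(top$angles, key3, 3L),
       dih_env = env_of(top$dihedrals, key4, 4L),
       imp_env = env_of(top$impropers, key4s, 4L))
}

param_sig <- function(p) paste(signif(p$values, 12), collapse = ",")

# Core penalty accounting over a (possibly partial) multistate match matrix.
# `mat` has one column per state; NA entries are dummy matches. With
# `partial = TRUE` only counts that can no longer change are accumulated
# (atoms in added tuples; bonded terms all of whose atoms are assigned) so
# that the result is an admissible lower-bound component; dihedral bookkeeping
# under the middle-two-atoms procedure is deferred to complete solutions
# because its within-bond pairing is only fixed at completion.
solution_breakdown <- function(states, mat, opts, ctxs = NULL,
                               partial = FALSE, detail = FALSE) {
  ns <- length(states)
  if (is.null(ctxs)) ctxs <- lapply(states, state_ctx)
  counts <- empty_counts()
  violations <- character()
  details <- list()
  note <- function(category, s, t, atoms_s, info = "") {
    if (detail)
      details[[length(details) + 1L]] <<- tibble::tibble(
        category = category, states = paste0(s, "-", t),
        atoms = paste(atoms_s, collapse = ","), info = info)
  }
  counts["dummy"] <- sum(is.na(mat))
  nr <- nrow(mat)
  assigned <- lapply(seq_len(ns), function(s) {
    a <- rep(FALSE, nrow(states[[s]]$atoms))
    v <- mat[, s]; a[v[!is.na(v)]] <- TRUE
    a
  })
  maps <- list()  # maps[[paste(s,t)]]: vector over s atoms -> t atom (NA if dummy/unassigned)
  for (s in seq_len(ns)) for (t in seq_len(ns)) {
    if (s == t) next
    m <- rep(NA_integer_, nrow(states[[s]]$atoms))
    if (nr) {
      both <- !is.na(mat[, s]) & !is.na(mat[, t])
      m[mat[both, s]] <- mat[both, t]
    }
    maps[[paste(s, t)]] <- m
  }
  # atom-level mismatches
  if (nr) for (r in seq_len(nr)) {
    real <- which(!is.na(mat[r, ]))
    if (length(real) < 2L) next
    for (a in seq_along(real)[-length(real)]) for (b in (a + 1L):length(real)) {
      s <- real[a]; t <- real[b]
      as_ <- states[[s]]$atoms[mat[r, s], ]; at_ <- states[[t]]$atoms[mat[r, t], ]
      if (as_$type_id != at_$type_id) {
        counts["atom_type"] <- counts["atom_type"] + 1L
        note("atom_type", s, t, as_$name, paste(as_$type_id, "->", at_$type_id))
      }
      if (!masses_equal(as_$mass, at_$mass)) {
        counts["mass"] <- counts["mass"] + 1L
        note("mass", s, t, as_$name)
      }
      if (!charges_equal(as_$charge, at_$charge)) {
        counts["charge"] <- counts["charge"] + 1L
        note("charge", s, t, as_$name)
      }
    }
  }
  term_status <- function(av, s, t) {
    # "skip" (dummy region / undetermined), "ok" (image computable), or NULL
    m <- maps[[paste(s, t)]]
    if (any(!assigned[[s]][av])) return(if (partial) "undet" else "skip")
    if (any(is.na(m[av]))) return("skip")
    "ok"
  }
  for (s in seq_len(ns - 1L)) for (t in (s + 1L):ns) {
    m_st <- maps[[paste(s, t)]]
    m_ts <- maps[[paste(t, s)]]
    tops <- states[[s]]; topt <- states[[t]]
    # bonds
    consumed <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(tops$bonds))) {
      av <- c(tops$bonds$i[r], tops$bonds$j[r])
      st <- term_status(av, s, t)
      if (st != "ok") next
      kk <- key2(m_st[av[1]], m_st[av[2]])
      ref_t <- get0(kk, envir = ctxs[[t]]$bond_env)
      if (is.null(ref_t)) { violations <- c(violations, "bond_preservation"); next }
      assign(kk, TRUE, envir = consumed)
      if (!params_equal(ff_params(tops, tops$bonds$ref[r]), ff_params(topt, ref_t))) {
        counts["bond"] <- counts["bond"] + 1L
        note("bond", s, t, tops$atoms$name[av])
      }
    }
    # angles (and impropers, which match on the unordered atom set)
    for (kind in c("angle", "improper")) {
      tb_s <- if (kind == "angle") tops$angles else tops$impropers
      tb_t <- if (kind == "angle") topt$angles else topt$impropers
      keyf <- if (kind == "angle") key3 else key4s
      env_t <- if (kind == "angle") ctxs[[t]]$angle_env else ctxs[[t]]$imp_env
      consumed <- new.env(parent = emptyenv())
      arity <- if (kind == "angle") 3L else 4L
      for (r in seq_len(nrow(tb_s))) {
        av <- as.integer(tb_s[r, seq_len(arity)])
        st <- term_status(av, s, t)
        if (st != "ok") next
        kk <- do.call(keyf, as.list(m_st[av]))
        ref_t <- get0(kk, envir = env_t)
        if (is.null(ref_t)) {
          counts["make_break"] <- counts["make_break"] + 1L
          note("make_break", s, t, tops$atoms$name[av], paste(kind, "removed"))
          next
        }
        assign(kk, TRUE, envir = consumed)
        if (!params_equal(ff_params(tops, tb_s$ref[r]), ff_params(topt, ref_t))) {
          counts[kind] <- counts[kind] + 1L
          note(kind, s, t, tops$atoms$name[av])
        }
      }
      for (r in seq_len(nrow(tb_t))) {
        av <- as.integer(tb_t[r, seq_len(arity)])
        st <- term_status(av, t, s)
        if (st != "ok") next
        kk <- do.call(keyf, as.list(av))
        if (is.null(get0(kk, envir = consumed))) {
          counts["make_break"] <- counts["make_break"] + 1L
          note("make_break", s, t, topt$atoms$name[av], paste(kind, "created"))
        }
      }
    }
    # proper dihedrals
    if (identical(opts$dihedral_match, "all_four_atoms")) {
      consumed <- new.env(parent = emptyenv())
      for (r in seq_len(nrow(tops$dihedrals))) {
        av <- as.integer(tops$dihedrals[r, 1:4])
        st <- term_status(av, s, t)
        if (st != "ok") next
        kk <- key4(m_st[av[1]], m_st[av[2]], m_st[av[3]], m_st[av[4]])
        ref_t <- get0(kk, envir = ctxs[[t]]$dih_env)
        if (is.null(ref_t)) {
          counts["make_break"] <- counts["make_break"] + 1L
          note("make_break", s, t, tops$atoms$name[av], "dihedral removed")
          next
        }
        assign(kk, TRUE, envir = consumed)
        ps <- ff_params(tops, tops$dihedrals$ref[r]); pt <- ff_params(topt, ref_t)
        if (!identical(ps$mult, pt$mult)) {
          if (isTRUE(opts$allow_multiplicity_change)) {
            counts["multiplicity"] <- counts["multiplicity"] + 1L
            note("multiplicity", s, t, tops$atoms$name[av],
                 paste(ps$mult, "->", pt$mult))
          } else violations <- c(violations, "multiplicity")
        }
        if (!params_equal(ps, pt)) {
          counts["dihedral"] <- counts["dihedral"] + 1L
          note("dihedral", s, t, tops$atoms$name[av])
        } else if (identical(ps$mult, pt$mult)) {
          note("dihedral_matched", s, t, tops$atoms$name[av])
        }
      }
      for (r in seq_len(nrow(topt$dihedrals))) {
        av <- as.integer(topt$dihedrals[r, 1:4])
        st <- term_status(av, t, s)
        if (st != "ok") next
        kk <- key4(av[1], av[2], av[3], av[4])
        if (is.null(get0(kk, envir = consumed))) {
          counts["make_break"] <- counts["make_break"] + 1L
          note("make_break", s, t, topt$atoms$name[av], "dihedral created")
        }
      }
    } else if (!partial) {
      # middle-two-atoms procedure: group by the mapped central bond
      grp <- list()
      add_grp <- function(ck, side, p, atoms) {
        g <- grp[[ck]]
        if (is.null(g)) g <- list(s = list(), t = list())
        g[[side]][[length(g[[side]]) + 1L]] <- list(p = p, atoms = atoms)
        grp[[ck]] <<- g
      }
      for (r in seq_len(nrow(tops$dihedrals))) {
        av <- as.integer(tops$dihedrals[r, 1:4])
        if (term_status(av, s, t) != "ok") next
        add_grp(key2(m_st[av[2]], m_st[av[3]]), "s",
                ff_params(tops, tops$dihedrals$ref[r]), tops$atoms$name[av])
      }
      for (r in seq_len(nrow(topt$dihedrals))) {
        av <- as.integer(topt$dihedrals[r, 1:4])
        if (term_status(av, t, s) != "ok") next
        add_grp(key2(av[2], av[3]), "t",
                ff_params(topt, topt$dihedrals$ref[r]), topt$atoms$name[av])
      }
      for (ck in names(grp)) {
        ls <- grp[[ck]]$s; lt <- grp[[ck]]$t
        ord <- function(l) l[order(vapply(l, function(d) paste(d$p$mult, param_sig(d$p)),
                                          character(1)))]
        ls <- ord(ls); lt <- ord(lt)
        # pair equal multiplicities first
        used_t <- rep(FALSE, length(lt))
        for (ds in seq_along(ls)) {
          cand <- which(!used_t &
                          vapply(lt, function(d) identical(d$p$mult, ls[[ds]]$p$mult),
                                 logical(1)))
          if (length(cand)) {
            used_t[cand[1]] <- TRUE
            if (!params_equal(ls[[ds]]$p, lt[[cand[1]]]$p)) {
              counts["dihedral"] <- counts["dihedral"] + 1L
              note("dihedral", s, t, ls[[ds]]$atoms)
            } else {
              note("dihedral_matched", s, t, ls[[ds]]$atoms)
            }
            ls[[ds]] <- NA
          }
        }
        ls <- ls[!vapply(ls, function(x) identical(x, NA), logical(1))]
        lt <- lt[!used_t]
        if (isTRUE(opts$allow_multiplicity_change)) {
          np <- min(length(ls), length(lt))
          for (q in seq_len(np)) {
            counts["multiplicity"] <- counts["multiplicity"] + 1L
            note("multiplicity", s, t, ls[[q]]$atoms,
                 paste(ls[[q]]$p$mult, "->", lt[[q]]$p$mult))
            if (!params_equal(ls[[q]]$p, lt[[q]]$p)) {
              counts["dihedral"] <- counts["dihedral"] + 1L
              note("dihedral", s, t, ls[[q]]$atoms)
            }
          }
          ls <- ls[seq_len(length(ls)) > np]; lt <- lt[seq_len(length(lt)) > np]
        }
        for (d in c(ls, lt)) {
          counts["make_break"] <- counts["make_break"] + 1L
          note("make_break", s, t, d$atoms, "dihedral unpaired")
        }
      }
    }
  }
  if (counts["make_break"] > 0 && !isTRUE(opts$allow_make_break_bonded))
    violations <- c(violations, "make_break")
  list(counts = counts, violations = unique(violations),
       details = if (detail && length(details)) dplyr::bind_rows(details)
       else tibble::tibble(category = character(), states = character(),
                           atoms = character(), info = character()))
}

#' Score a match solution
#'
#' Recomputes the penalty breakdown of a complete (or partial) solution under
#' a weight specification: counts per category, the weighted total (infinite
#' for solutions violating a forbidden category or a hard matching rule), and
#' the comparison key.
#'
#' @param sol A `match_solution`.
#' @param spec A [score_spec()].
#' @return List with `total`, `breakdown` (named counts), `key`,
#'   `lower_bound` (equals `total` for complete solutions) and `violations`.
#' @export
evaluate_solution <- function(sol, spec = score_spec()) {
  bd <- solution_breakdown(sol$states, sol$matches, sol$options,
                           partial = !isTRUE(sol$complete), detail = TRUE)
  violated <- length(bd$violations) > 0
  total <- score_total(bd$counts, spec, violated)
  lb <- if (isTRUE(sol$complete)) total else
    lower_bound_from_partial(sol$states, sol$matches, bd, spec)$total
  list(total = total, breakdown = bd$counts, key = score_key(bd$counts, spec, violated),
       lower_bound = lb, violations = bd$violations, details = bd$details)
}

# admissible completion bound: penalties accumulated so far plus the minimal
# number of dummy matches any completion must still add (future tuples carry
# a real anchor-state atom and consume at most one atom per state; leftover
# atoms complete as single-atom dummy rows)
lower_bound_from_partial <- function(states, mat, bd, spec) {
  rem <- vapply(seq_along(states), function(s) {
    v <- mat[, s]; nrow(states[[s]]$atoms) - sum(!is.na(v))
  }, numeric(1))
  extra_dummy <- future_dummy_min(rem)
  counts <- bd$counts
  counts["dummy"] <- counts["dummy"] + extra_dummy
  violated <- length(bd$violations) > 0
  list(total = score_total(counts, spec, violated),
       key = score_key(counts, spec, violated))
}

#' Admissible lower bound on the score of any completion
#'
#' For a partial solution, returns a score that no completion can beat:
#' the penalty accumulated so far plus the minimal number of additional dummy
#' matches forced by the remaining unmatched atom counts. For a complete
#' solution it equals the evaluated total.
#'
#' @param sol A `match_solution` (partial or complete).
#' @param spec A [score_spec()].
#' @return Numeric lower bound on the total.
#' @export
lower_bound <- function(sol, spec = score_spec()) {
  if (isTRUE(sol$complete)) return(evaluate_solution(sol, spec)$total)
  bd <- solution_breakdown(sol$states, sol$matches, sol$options, partial = TRUE)
  lower_bound_from_partial(sol$states, sol$matches, bd, spec)$total
}

#' Coordinate RMSD of a match solution
#'
#' Atom-positional root-mean-square deviation over matched (real-real) atoms,
#' computed on the coordinates as provided, without least-squares fitting:
#' the intended use is ranking equal-score solutions for ligands posed in a
#' binding pocket, where superposition would destroy the pose information.
#'
#' For more than two states, `mode = "rmsd"` returns the root mean square of
#' the pairwise RMSDs and `mode = "rmsf"` the root-mean-square fluctuation
#' around the mean structure over atoms matched across all states; the two
#' are related by `<RMSD^2> = 2N/(N-1) <RMSF^2>` when computed over the same
#' atoms (N = number of states).
#'
#' @param sol A complete `match_solution`.
#' @param coords List of `coordset` objects, one per state (atom order equal
#'   to the state's topology).
#' @param mode `"rmsd"` (pairwise form, default) or `"rmsf"`.
#' @return RMSD in nm.
#' @export
rmsd_of_mapping <- function(sol, coords, mode = c("rmsd", "rmsf")) {
  mode <- match.arg(mode)
  ns <- length(sol$states)
  if (length(coords) != ns)
    rlang::abort("need one coordinate set per state", class = "perttop_validation_error")
  for (s in seq_len(ns))
    if (nrow(coords[[s]]$positions) != nrow(sol$states[[s]]$atoms))
      rlang::abort(sprintf("coordinate set %d does not match its topology", s),
                   class = "perttop_validation_error")
  mat <- sol$matches
  if (mode == "rmsd") {
    acc <- c()
    for (s in seq_len(ns - 1L)) for (t in (s + 1L):ns) {
      both <- which(!is.na(mat[, s]) & !is.na(mat[, t]))
      if (!length(both)) next
      d <- coords[[s]]$positions[mat[both, s], , drop = FALSE] -
        coords[[t]]$positions[mat[both, t], , drop = FALSE]
      acc <- c(acc, mean(rowSums(d^2)))
    }
    if (!length(acc))
      rlang::abort("no real-real matched atoms", class = "perttop_validation_error")
    sqrt(mean(acc))
  } else {
    allreal <- which(rowSums(is.na(mat)) == 0L)
    if (!length(allreal))
      rlang::abort("no atoms matched across all states", class = "perttop_validation_error")
    msf <- 0
    for (r in allreal) {
      xs <- t(vapply(seq_len(ns), function(s) coords[[s]]$positions[mat[r, s], ],
                     numeric(3)))
      xbar <- colMeans(xs)
      msf <- msf + mean(rowSums(sweep(xs, 2, xbar)^2))
    }
    sqrt(msf / length(allreal))
  }
}

solution_signature <- function(mat) {
  paste(apply(mat, 1L, function(r) paste(ifelse(is.na(r), "D", r), collapse = ":")),
        collapse = ";")
}

#' Select the best solution from a set
#'
#' Picks the minimal-score solution; among equal scores, the one with the
#' smallest coordinate RMSD when coordinates are given, otherwise the first
#' in a deterministic canonical order (so repeated runs select the same
#' solution).
#'
#' @param solutions Non-empty list of complete `match_solution` objects.
#' @param coords Optional list of `coordset` objects, one per state.
#' @param spec A [score_spec()] used to (re)compare the solutions.
#' @return A single `match_solution`.
#' @export
select_best <- function(solutions, coords = NULL, spec = score_spec()) {
  if (!length(solutions))
    rlang::abort("empty solution list", class = "perttop_validation_error")
  keys <- lapply(solutions, function(s) evaluate_solution(s, spec)$key)
  best <- keys[[1]]
  for (k in keys) if (key_less(k, best)) best <- k
  cand <- which(vapply(keys, key_equal, logical(1), best))
  sigs <- vapply(solutions[cand], function(s) solution_signature(s$matches), character(1))
  cand <- cand[order(sigs)]
  if (length(cand) > 1L && !is.null(coords)) {
    r <- vapply(solutions[cand], rmsd_of_mapping, numeric(1), coords = coords)
    cand <- cand[order(r)]
  }
  solutions[[cand[1]]]
}

#' Read score weights and search options from a config file
#'
#' Flat key-value format, one setting per line (`key value`, `#` comments).
#' Keys matching [score_spec()] weight arguments (`w_dummy`, `w_bond`, ...)
#' and `forbid` (comma-separated categories) populate the score
#' specification; keys matching [search_options()] arguments populate the
#' options.
#'
#' @param path Config file path.
#' @return List with elements `spec` and `options`.
#' @export
read_search_config <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("config file not found: %s", path), class = "perttop_io_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t=]+")[[1]]
    if (length(parts) < 2L)
      rlang::abort(sprintf("bad config line: '%s'", ln), class = "perttop_parse_error")
    kv[[parts[1]]] <- paste(parts[-1], collapse = " ")
  }
  sargs <- list(); oargs <- list()
  snames <- setdiff(names(formals(score_spec)), "custom_score")
  onames <- names(formals(search_options))
  for (k in names(kv)) {
    v <- kv[[k]]
    if (k == "forbid") sargs$forbid <- strsplit(v, ",")[[1]]
    else if (k %in% snames) {
      sargs[[k]] <- if (k == "lexicographic") as.logical(v) else as.numeric(v)
    } else if (k %in% onames) {
      oargs[[k]] <- if (startsWith(k, "allow_") || k == "enumerate_all_best")
        as.logical(v)
      else if (k %in% c("max_solutions", "node_budget")) as.integer(v)
      else v
    } else {
      rlang::abort(sprintf("unknown config key '%s'", k), class = "perttop_parse_error")
    }
  }
  list(spec = do.call(score_spec, sargs), options = do.call(search_options, oargs))
}
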