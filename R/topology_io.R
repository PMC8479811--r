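#' Read a molecular topology file
#'
#' Reads a solute molecular topology in either supported dialect into the
#' engine-neutral [ff_topology()] representation. For GROMOS11, the block
#' format (TITLE/END delimited blocks: SOLUTEATOM, BOND(H), BONDANGLE(H),
#' DIHEDRAL(H), IMPDIHEDRAL(H) plus the *TYPE parameter blocks) is parsed;
#' solvent blocks are ignored. For GROMACS, `#include` directives are inlined
#' and `#define` macros resolved textually before parsing the `[ sections ]`;
#' only the first (solute) moleculetype is read. Atom indices are 1-based in
#' both dialects and internally.
#'
#' Each GROMOS SOLUTEATOM record is
#' `nr resnr name type-code mass charge charge-group nex excl... n14 pairs...`;
#' bonded-term blocks reference the `*TYPE` parameter blocks by 1-based code.
#'
#' @param path File path.
#' @param dialect `"gromos"` or `"gromacs"`.
#' @return An `fftop` object.
#' @export
read_topology <- function(path, dialect = c("gromos", "gromacs")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    rlang::abort(sprintf("cannot read topology file: %s", path),
                 class = "perttop_io_error")
  lines <- readLines(path, warn = FALSE)
  tryCatch(
    if (dialect == "gromos") parse_gromos(lines, path) else parse_gromacs(lines, path),
    perttop_validation_error = function(e)
      rlang::abort(sprintf("%s: invalid topology: %s", path, conditionMessage(e)),
                   class = "perttop_parse_error"))
}

#' Write a molecular topology file
#'
#' Serializes an `fftop` in the requested dialect such that
#' [read_topology()] reproduces all semantic content. Parameter references
#' are resolved to numeric values on output (GROMOS type tables are rebuilt
#' from unique parameter value sets; GROMACS carries parameters inline on
#' each bonded line). The GROMOS dialect requires charge groups; a topology
#' without them raises a serialization error.
#'
#' @param top An `fftop`.
#' @param path Output file path.
#' @param dialect `"gromos"` or `"gromacs"`.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path, dialect = c("gromos", "gromacs")) {
  dialect <- match.arg(dialect)
  bad <- setdiff(c(top$bonds$ref, top$angles$ref, top$dihedrals$ref, top$impropers$ref),
                 names(top$params))
  if (length(bad))
    rlang::abort(sprintf("cannot serialize: unresolved parameter reference %s",
                         paste(bad, collapse = ", ")),
                 class = "perttop_serialization_error")
  validate_fftop(top)
  if (dialect == "gromos" && anyNA(top$atoms$charge_group))
    rlang::abort("GROMOS dialect requires charge groups for all atoms",
                 class = "perttop_serialization_error")
  lines <- if (dialect == "gromos") format_gromos(top) else format_gromacs(top)
  writeLines(lines, path)
  invisible(path)
}

num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v
}

# ---- GROMOS11 block format ---------------------------------------------

gromos_known_blocks <- c(
  "TITLE", "PHYSICALCONSTANTS", "TOPVERSION", "ATOMTYPENAME", "RESNAME",
  "SOLUTEATOM", "BONDSTRETCHTYPE", "BOND", "BONDH", "BONDANGLETYPE",
  "BONDANGLE", "BONDANGLEH", "IMPDIHEDRALTYPE", "IMPDIHEDRAL", "IMPDIHEDRALH",
  "TORSDIHEDRALTYPE", "DIHEDRAL", "DIHEDRALH", "LJPARAMETERS",
  "SOLUTEMOLECULES", "TEMPERATUREGROUPS", "PRESSUREGROUPS", "LJEXCEPTIONS",
  "SOLVENTATOM", "SOLVENTCONSTR")

split_gromos_blocks <- function(lines, path,
                                known = gromos_known_blocks) {
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
    name <- ln
    if (!name %in% known)
      rlang::abort(sprintf("%s:%d: unknown block '%s'", path, i, name),
                   class = "perttop_parse_error")
    j <- i + 1L
    body <- character()
    repeat {
      if (j > n)
        rlang::abort(sprintf("%s:%d: block '%s' not closed by END", path, i, name),
                     class = "perttop_parse_error")
      bl <- trimws(lines[j])
      if (identical(bl, "END")) break
      if (nzchar(bl) && !startsWith(bl, "#")) body <- c(body, bl)
      j <- j + 1L
    }
    blocks[[name]] <- body
    i <- j + 1L
  }
  blocks
}

gromos_tokens <- function(body) {
  toks <- unlist(strsplit(paste(body, collapse = " "), "[ \t]+"))
  toks[nzchar(toks)]
}

# counted token stream reader
token_stream <- function(tokens, path, what) {
  pos <- 0L
  list(
    take = function(k = 1L) {
      if (pos + k > length(tokens))
        rlang::abort(sprintf("%s: truncated %s block", path, what),
                     class = "perttop_parse_error")
      out <- tokens[(pos + 1L):(pos + k)]
      pos <<- pos + k
      out
    },
    done = function() pos >= length(tokens)
  )
}

parse_gromos_type_block <- function(blocks, name, nvals, kind, path,
                                    with_mult = FALSE) {
  if (is.null(blocks[[name]])) return(list())
  ts <- token_stream(gromos_tokens(blocks[[name]]), path, name)
  ntypes <- as.integer(ts$take())
  out <- vector("list", ntypes)
  for (q in seq_len(ntypes)) {
    vals <- num(ts$take(nvals + if (with_mult) 1L else 0L))
    if (anyNA(vals))
      rlang::abort(sprintf("%s: non-numeric value in %s", path, name),
                   class = "perttop_parse_error")
    out[[q]] <- if (with_mult)
      list(kind = kind, values = vals[seq_len(nvals)],
           mult = as.integer(vals[nvals + 1L]))
    else list(kind = kind, values = vals)
  }
  out
}

parse_gromos_terms <- function(blocks, names, arity, prefix, ntypes, path) {
  rows <- list()
  for (bn in names) {
    if (is.null(blocks[[bn]])) next
    ts <- token_stream(gromos_tokens(blocks[[bn]]), path, bn)
    nterms <- as.integer(ts$take())
    for (q in seq_len(nterms)) {
      v <- as.integer(ts$take(arity + 1L))
      code <- v[arity + 1L]
      if (is.na(code) || code < 1L || code > ntypes)
        rlang::abort(sprintf("%s: %s term %d references undefined type code %s",
                             path, bn, q, code),
                     class = "perttop_parse_error")
      rows[[length(rows) + 1L]] <- c(v[seq_len(arity)], paste0(prefix, code))
    }
  }
  if (!length(rows)) return(NULL)
  idx <- t(vapply(rows, function(r) as.integer(r[seq_len(arity)]), integer(arity)))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(idx),
                                           c("i", "j", "k", "l")[seq_len(arity)]))
  out$ref <- vapply(rows, function(r) r[arity + 1L], character(1))
  out
}

parse_gromos <- function(lines, path) {
  blocks <- split_gromos_blocks(lines, path)
  if (is.null(blocks$SOLUTEATOM))
    rlang::abort(sprintf("%s: missing required block 'SOLUTEATOM'", path),
                 class = "perttop_parse_error")
  title <- if (!is.null(blocks$TITLE)) paste(blocks$TITLE, collapse = " ") else "molecule"
  type_names <- character()
  if (!is.null(blocks$ATOMTYPENAME)) {
    tk <- gromos_tokens(blocks$ATOMTYPENAME)
    ntt <- as.integer(tk[1])
    if (is.na(ntt) || length(tk) != ntt + 1L)
      rlang::abort(sprintf("%s: malformed ATOMTYPENAME block", path),
                   class = "perttop_parse_error")
    type_names <- tk[-1]
  }
  ts <- token_stream(gromos_tokens(blocks$SOLUTEATOM), path, "SOLUTEATOM")
  natoms <- as.integer(ts$take())
  if (is.na(natoms) || natoms < 1L)
    rlang::abort(sprintf("%s: SOLUTEATOM atom count missing", path),
                 class = "perttop_parse_error")
  at <- vector("list", natoms)
  excl <- vector("list", natoms)
  p14 <- list()
  for (a in seq_len(natoms)) {
    rec <- ts$take(8L)  # nr resnr name iac mass charge cgrp nex
    iac <- as.integer(rec[4])
    nex <- as.integer(rec[8])
    if (is.na(nex) || nex < 0L)
      rlang::abort(sprintf("%s: SOLUTEATOM atom %d: bad exclusion count", path, a),
                   class = "perttop_parse_error")
    ex <- if (nex > 0L) as.integer(ts$take(nex)) else integer()
    n14 <- as.integer(ts$take())
    p4 <- if (n14 > 0L) as.integer(ts$take(n14)) else integer()
    tid <- if (length(type_names)) {
      if (is.na(iac) || iac < 1L || iac > length(type_names))
        rlang::abort(sprintf("%s: SOLUTEATOM atom %d: atom type code %s not in ATOMTYPENAME",
                             path, a, rec[4]),
                     class = "perttop_parse_error")
      type_names[iac]
    } else as.character(iac)
    at[[a]] <- tibble::tibble(name = rec[3], type_id = tid, mass = num(rec[5]),
                              charge = num(rec[6]),
                              charge_group = as.integer(rec[7]))
    if (any(ex > natoms) || any(p4 > natoms))
      rlang::abort(sprintf("%s: SOLUTEATOM atom %d: exclusion/1-4 index beyond atom count",
                           path, a),
                   class = "perttop_parse_error")
    excl[[a]] <- ex
    for (b in p4) p14[[length(p14) + 1L]] <- c(a, b)
  }
  atoms <- dplyr::bind_rows(at)
  bt <- parse_gromos_type_block(blocks, "BONDSTRETCHTYPE", 2L, "bond", path)
  gt <- parse_gromos_type_block(blocks, "BONDANGLETYPE", 2L, "angle", path)
  it <- parse_gromos_type_block(blocks, "IMPDIHEDRALTYPE", 2L, "improper", path)
  dt <- parse_gromos_type_block(blocks, "TORSDIHEDRALTYPE", 2L, "dihedral", path,
                                with_mult = TRUE)
  params <- c(
    stats::setNames(bt, if (length(bt)) paste0("bond:", seq_along(bt)) else character()),
    stats::setNames(gt, if (length(gt)) paste0("angle:", seq_along(gt)) else character()),
    stats::setNames(it, if (length(it)) paste0("improper:", seq_along(it)) else character()),
    stats::setNames(dt, if (length(dt)) paste0("dihedral:", seq_along(dt)) else character()))
  bonds <- parse_gromos_terms(blocks, c("BOND", "BONDH"), 2L, "bond:", length(bt), path)
  angles <- parse_gromos_terms(blocks, c("BONDANGLE", "BONDANGLEH"), 3L, "angle:",
                               length(gt), path)
  imps <- parse_gromos_terms(blocks, c("IMPDIHEDRAL", "IMPDIHEDRALH"), 4L,
                             "improper:", length(it), path)
  dihs <- parse_gromos_terms(blocks, c("DIHEDRAL", "DIHEDRALH"), 4L, "dihedral:",
                             length(dt), path)
  pairs14 <- if (length(p14)) {
    m <- do.call(rbind, p14)
    tibble::tibble(i = m[, 1], j = m[, 2])
  } else NULL
  ff_topology(atoms, bonds = bonds, angles = angles, dihedrals = dihs,
              impropers = imps, params = params, exclusions = excl,
              pairs14 = pairs14, dialect = "gromos", title = title)
}

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) sprintf("%.1f", v) else format(v, digits = 12)
  }, character(1))
}

# unique parameter codes per kind, preserving first-seen order
param_codes <- function(top, kind, refs) {
  refs_u <- unique(refs)
  sigs <- character(); entries <- list(); code_of <- character(0)
  for (rf in refs_u) {
    p <- ff_params(top, rf)
    sg <- paste(param_sig(p), if (is.null(p$mult)) "" else p$mult)
    hit <- match(sg, sigs)
    if (is.na(hit)) {
      sigs <- c(sigs, sg)
      entries[[length(entries) + 1L]] <- p
      hit <- length(sigs)
    }
    code_of[rf] <- hit
  }
  list(entries = entries, code = code_of)
}

format_gromos <- function(top) {
  out <- c("TITLE", top$title, "END")
  types <- unique(top$atoms$type_id)
  out <- c(out, "ATOMTYPENAME", "# NRATT", length(types), types, "END")
  n <- nrow(top$atoms)
  sa <- c("SOLUTEATOM", "# NRP", n,
          "#  ATNM MRES PANM IAC MASS CG CGC INE / INE14")
  p14_of <- lapply(seq_len(n), function(a) top$pairs14$j[top$pairs14$i == a])
  for (a in seq_len(n)) {
    r <- top$atoms[a, ]
    ex <- top$exclusions[[a]]
    p4 <- p14_of[[a]]
    sa <- c(sa, paste(a, 1L, r$name, match(r$type_id, types),
                      sprintf("%.5f", r$mass), sprintf("%.6f", r$charge),
                      r$charge_group, length(ex), paste(ex, collapse = " "),
                      length(p4), paste(p4, collapse = " ")))
  }
  out <- c(out, sa, "END")
  emit <- function(type_block, term_block, tb, arity, kind) {
    if (!nrow(tb)) return(character())
    pc <- param_codes(top, kind, tb$ref)
    tl <- c(type_block, "# NTY", length(pc$entries))
    for (p in pc$entries)
      tl <- c(tl, paste(c(fmt_num(p$values),
                          if (!is.null(p$mult) && !is.na(p$mult)) p$mult),
                        collapse = " "))
    tl <- c(tl, "END", term_block, "# N", nrow(tb))
    for (r in seq_len(nrow(tb)))
      tl <- c(tl, paste(c(as.integer(tb[r, seq_len(arity)]),
                          pc$code[[tb$ref[r]]]), collapse = " "))
    c(tl, "END")
  }
  out <- c(out,
           emit("BONDSTRETCHTYPE", "BOND", top$bonds, 2L, "bond"),
           emit("BONDANGLETYPE", "BONDANGLE", top$angles, 3L, "angle"),
           emit("IMPDIHEDRALTYPE", "IMPDIHEDRAL", top$impropers, 4L, "improper"),
           emit("TORSDIHEDRALTYPE", "DIHEDRAL", top$dihedrals, 4L, "dihedral"))
  out
}

# ---- GROMACS format ----------------------------------------------------

gromacs_known_sections <- c(
  "defaults", "atomtypes", "bondtypes", "angletypes", "dihedraltypes",
  "moleculetype", "atoms", "bonds", "angles", "dihedrals", "pairs",
  "exclusions", "system", "molecules", "settles", "position_restraints")

gromacs_preprocess <- function(lines, path) {
  # inline #include and resolve #define macros textually
  dir <- dirname(path)
  out <- character()
  defines <- list()
  for (ln in lines) {
    raw <- sub(";.*$", "", ln)
    t <- trimws(raw)
    if (startsWith(t, "#include")) {
      inc <- gsub('^#include[ \t]+["<]?([^">]+)[">]?.*$', "\\1", t)
      incp <- if (file.exists(inc)) inc else file.path(dir, inc)
      if (!file.exists(incp))
        rlang::abort(sprintf("%s: unresolved #include '%s'", path, inc),
                     class = "perttop_parse_error")
      out <- c(out, gromacs_preprocess(readLines(incp, warn = FALSE), incp))
    } else if (startsWith(t, "#define")) {
      parts <- strsplit(t, "[ \t]+")[[1]]
      if (length(parts) < 2L)
        rlang::abort(sprintf("%s: malformed #define", path),
                     class = "perttop_parse_error")
      defines[[parts[2]]] <- paste(parts[-(1:2)], collapse = " ")
    } else if (startsWith(t, "#")) {
      rlang::abort(sprintf("%s: unsupported preprocessor directive: %s", path, t),
                   class = "perttop_parse_error")
    } else {
      out <- c(out, raw)
    }
  }
  if (length(defines)) {
    for (nm in names(defines)) {
      pat <- paste0("(?<![A-Za-z0-9_])", nm, "(?![A-Za-z0-9_])")
      out <- vapply(out, function(l) gsub(pat, defines[[nm]], l, perl = TRUE),
                    character(1), USE.NAMES = FALSE)
    }
  }
  out
}

parse_gromacs <- function(lines, path) {
  lines <- gromacs_preprocess(lines, path)
  section <- NA_character_
  mt_seen <- 0L
  title <- "molecule"
  atoms <- list(); bonds <- list(); angles <- list(); dihs <- list()
  imps <- list(); pairs <- list(); excl_rows <- list()
  params <- list()
  pkey <- function(kind, values, mult = NULL) {
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
    if (grepl("^\\[", t)) {
      sec <- trimws(gsub("[][]", "", t))
      if (!sec %in% gromacs_known_sections)
        rlang::abort(sprintf("%s:%d: unknown section '[ %s ]'", path, li, sec),
                     class = "perttop_parse_error")
      if (sec == "moleculetype") mt_seen <- mt_seen + 1L
      section <- sec
      next
    }
    if (is.na(section) || mt_seen > 1L) next
    tok <- strsplit(t, "[ \t]+")[[1]]
    bad_line <- function(msg)
      rlang::abort(sprintf("%s:%d: %s: '%s'", path, li, msg, t),
                   class = "perttop_parse_error")
    if (section == "moleculetype") {
      title <- tok[1]
    } else if (section == "atoms") {
      if (length(tok) < 8L) bad_line("atom line needs 8 fields")
      atoms[[length(atoms) + 1L]] <-
        tibble::tibble(name = tok[5], type_id = tok[2], mass = num(tok[8]),
                       charge = num(tok[7]), charge_group = as.integer(tok[6]))
    } else if (section == "bonds") {
      if (length(tok) < 5L) bad_line("bond line needs i j funct b0 kb")
      v <- num(tok[4:5])
      if (anyNA(v)) bad_line("non-numeric bond parameters")
      bonds[[length(bonds) + 1L]] <-
        c(tok[1:2], pkey("bond", c(v[2], v[1])))  # store (kb, b0)
    } else if (section == "angles") {
      if (length(tok) < 6L) bad_line("angle line needs i j k funct th0 k")
      v <- num(tok[5:6])
      if (anyNA(v)) bad_line("non-numeric angle parameters")
      angles[[length(angles) + 1L]] <-
        c(tok[1:3], pkey("angle", c(v[2], v[1])))
    } else if (section == "dihedrals") {
      if (length(tok) < 5L) bad_line("dihedral line needs i j k l funct ...")
      funct <- as.integer(tok[5])
      if (identical(funct, 1L)) {
        if (length(tok) < 8L) bad_line("proper dihedral needs phase k mult")
        v <- num(tok[6:7]); mlt <- as.integer(tok[8])
        if (anyNA(v) || is.na(mlt)) bad_line("non-numeric dihedral parameters")
        dihs[[length(dihs) + 1L]] <-
          c(tok[1:4], pkey("dihedral", c(v[2], v[1]), mlt))  # (k, phase)
      } else if (identical(funct, 2L)) {
        if (length(tok) < 7L) bad_line("improper dihedral needs xi0 k")
        v <- num(tok[6:7])
        if (anyNA(v)) bad_line("non-numeric improper parameters")
        imps[[length(imps) + 1L]] <-
          c(tok[1:4], pkey("improper", c(v[2], v[1])))
      } else bad_line("unsupported dihedral funct")
    } else if (section == "pairs") {
      if (length(tok) < 2L) bad_line("pair line needs i j")
      pairs[[length(pairs) + 1L]] <- as.integer(tok[1:2])
    } else if (section == "exclusions") {
      excl_rows[[length(excl_rows) + 1L]] <- as.integer(tok)
    }
  }
  if (!length(atoms))
    rlang::abort(sprintf("%s: no [ atoms ] section found", path),
                 class = "perttop_parse_error")
  atoms <- dplyr::bind_rows(atoms)
  n <- nrow(atoms)
  term_tb <- function(rows, arity) {
    if (!length(rows)) return(NULL)
    idx <- t(vapply(rows, function(r) {
      v <- as.integer(r[seq_len(arity)])
      if (anyNA(v) || any(v < 1L) || any(v > n))
        rlang::abort(sprintf("%s: bonded term references atom index beyond atom count (%s)",
                             path, paste(r[seq_len(arity)], collapse = " ")),
                     class = "perttop_parse_error")
      v
    }, integer(arity)))
    out <- tibble::as_tibble(stats::setNames(as.data.frame(idx),
                                             c("i", "j", "k", "l")[seq_len(arity)]))
    out$ref <- vapply(rows, function(r) r[arity + 1L], character(1))
    out
  }
  excl <- rep(list(integer()), n)
  for (row in excl_rows) {
    if (anyNA(row) || row[1] < 1L || row[1] > n || any(row > n))
      rlang::abort(sprintf("%s: bad exclusion line", path),
                   class = "perttop_parse_error")
    excl[[row[1]]] <- sort(union(excl[[row[1]]], row[-1]))
  }
  pairs14 <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    tibble::tibble(i = m[, 1], j = m[, 2])
  } else NULL
  ff_topology(atoms, bonds = term_tb(bonds, 2L), angles = term_tb(angles, 3L),
              dihedrals = term_tb(dihs, 4L), impropers = term_tb(imps, 4L),
              params = params, exclusions = excl, pairs14 = pairs14,
              dialect = "gromacs", title = title)
}

format_gromacs <- function(top) {
  out <- c("; generated by perttop", "[ moleculetype ]",
           "; name  nrexcl", paste(gsub("[ \t]", "_", top$title), 3))
  out <- c(out, "", "[ atoms ]",
           ";   nr type resnr residue atom cgnr charge mass")
  cg <- top$atoms$charge_group
  if (anyNA(cg)) cg <- seq_len(nrow(top$atoms))
  for (a in seq_len(nrow(top$atoms))) {
    r <- top$atoms[a, ]
    out <- c(out, sprintf("%6d %-6s %5d %-6s %-6s %5d %10.6f %10.5f",
                          a, r$type_id, 1L, "MOL", r$name, cg[a], r$charge, r$mass))
  }
  line_terms <- function(header, tb, arity, funct, fmt_par) {
    if (!nrow(tb)) return(character())
    ll <- c("", sprintf("[ %s ]", header))
    for (r in seq_len(nrow(tb))) {
      p <- ff_params(top, tb$ref[r])
      ll <- c(ll, paste(c(sprintf("%5d", as.integer(tb[r, seq_len(arity)])),
                          sprintf("%3d", funct), fmt_par(p)), collapse = " "))
    }
    ll
  }
  out <- c(out,
           line_terms("bonds", top$bonds, 2L, 1L,
                      function(p) fmt_num(c(p$values[2], p$values[1]))),
           line_terms("angles", top$angles, 3L, 1L,
                      function(p) fmt_num(c(p$values[2], p$values[1]))),
           line_terms("dihedrals", top$dihedrals, 4L, 1L,
                      function(p) c(fmt_num(c(p$values[2], p$values[1])), p$mult)),
           line_terms("dihedrals", top$impropers, 4L, 2L,
                      function(p) fmt_num(c(p$values[2], p$values[1]))))
  if (nrow(top$pairs14)) {
    out <- c(out, "", "[ pairs ]")
    for (r in seq_len(nrow(top$pairs14)))
      out <- c(out, sprintf("%5d %5d %3d", top$pairs14$i[r], top$pairs14$j[r], 1L))
  }
  if (any(lengths(top$exclusions) > 0)) {
    out <- c(out, "", "[ exclusions ]")
    for (a in seq_along(top$exclusions))
      if (length(top$exclusions[[a]]))
        out <- c(out, paste(c(a, top$exclusions[[a]]), collapse = " "))
  }
  out
}

# ---- coordinates -------------------------------------------------------

#' Read a coordinate file
#'
#' Reads PDB (via bio3d) or GRO fixed-column coordinates into a `coordset`
#' in nm (PDB Angstrom values are divided by 10).
#'
#' @param path File path.
#' @param format `"gro"` or `"pdb"` (default: from the file extension).
#' @param top Optional `fftop`; the atom count must then match.
#' @return A `coordset`.
#' @export
read_coordinates <- function(path, format = NULL, top = NULL) {
  if (!file.exists(path))
    rlang::abort(sprintf("cannot read coordinate file: %s", path),
                 class = "perttop_io_error")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "pdb"))
  if (file.size(path) == 0L)
    rlang::abort(sprintf("%s: empty coordinate file", path),
                 class = "perttop_parse_error")
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e)
                      rlang::abort(sprintf("%s: PDB parse failure: %s", path,
                                           conditionMessage(e)),
                                   class = "perttop_parse_error"))
    xyz <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE) / 10
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 3L)
      rlang::abort(sprintf("%s: truncated GRO file", path),
                   class = "perttop_parse_error")
    nat <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(nat) || length(lines) < 2L + nat)
      rlang::abort(sprintf("%s: bad GRO atom count", path),
                   class = "perttop_parse_error")
    xyz <- t(vapply(seq_len(nat), function(a) {
      ln <- lines[2L + a]
      v <- num(c(substr(ln, 21, 28), substr(ln, 29, 36), substr(ln, 37, 44)))
      if (anyNA(v))
        rlang::abort(sprintf("%s: bad GRO coordinate line %d", path, 2L + a),
                     class = "perttop_parse_error")
      v
    }, numeric(3)))
  }
  coord_set(xyz, top)
}

#' Write a coordinate file
#'
#' @param coords A `coordset` (nm).
#' @param top The matching `fftop` (provides atom names).
#' @param path Output path.
#' @param format `"gro"` or `"pdb"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, top, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "pdb"))
  x <- coords$positions
  if (nrow(x) != nrow(top$atoms))
    rlang::abort("coordinate/topology atom count mismatch",
                 class = "perttop_validation_error")
  if (format == "gro") {
    lines <- c(top$title, sprintf("%5d", nrow(x)))
    for (a in seq_len(nrow(x)))
      lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                1L, "MOL", substr(top$atoms$name[a], 1, 5), a,
                                x[a, 1], x[a, 2], x[a, 3]))
    lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", 5, 5, 5))
  } else {
    lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nrow(x)), substr(top$atoms$name, 1, 4), "MOL", 1L,
                     x[, 1] * 10, x[, 2] * 10, x[, 3] * 10)
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}
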