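# Chemical-shift file I/O: NMR-STAR 2.1, NMR-STAR 3.1 and SHIFTY readers and
# writers, plus the TALOS-N prediction-table reader. Everything downstream
# works on the normalized in-memory dataset produced here, with residues
# renumbered 1..N (author numbering retained for reporting).

stop_parse <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop(errorCondition(msg, class = c("nmrsecstr_parse_error", "error")))
}

as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

#' Detect the dialect of a chemical-shift file
#'
#' Distinguishes NMR-STAR 3.1 (`_Atom_chem_shift.*` tags), NMR-STAR 2.1
#' (`_Chem_shift_value` tags) and SHIFTY (whitespace-columnar with a
#' `#NUM AA ...` header) by their structural signatures.
#'
#' @param text File content as a single string or character vector of lines.
#' @return One of `"nmrstar3"`, `"nmrstar2"`, `"shifty"`.
#' @export
detect_format <- function(text) {
  lines <- as_lines(text)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop_parse("empty input")
  body <- paste(lines, collapse = "\n")
  if (grepl("_Atom_chem_shift\\.", body)) return("nmrstar3")
  if (grepl("_Chem_shift_value", body)) return("nmrstar2")
  hdr <- grep("^\\s*#\\s*NUM\\b", lines, ignore.case = TRUE)
  if (length(hdr)) return("shifty")
  # headerless columnar fallback: integer, residue code, then numbers
  dat <- trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
  if (length(dat)) {
    toks <- strsplit(dat[1], "\\s+")[[1]]
    if (length(toks) >= 3 && grepl("^-?[0-9]+$", toks[1]) &&
        toupper(toks[2]) %in% c(AA3TO1, names(AA3TO1)))
      return("shifty")
  }
  stop_parse("unrecognized chemical-shift format")
}

# ---- STAR machinery ---------------------------------------------------------

star_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

# Extract every loop_ ... stop_ block: tags + data rows (rows may wrap lines).
star_loops <- function(lines) {
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (identical(trimws(lines[i]), "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, strsplit(trimws(lines[i]), "\\s+")[[1]][1])
        i <- i + 1L
      }
      rows <- list()
      buf <- character()
      buf_line <- NA_integer_
      while (i <= n) {
        l <- trimws(lines[i])
        if (identical(l, "stop_")) { i <- i + 1L; break }
        if (grepl("^(loop_|save_|_)", l)) break
        if (nzchar(l) && !startsWith(l, "#")) {
          if (!length(buf)) buf_line <- i
          buf <- c(buf, star_tokens(l))
          while (length(buf) >= length(tags)) {
            rows[[length(rows) + 1L]] <-
              list(line = buf_line, values = buf[seq_along(tags)])
            buf <- buf[-seq_along(tags)]
            buf_line <- i
          }
        }
        i <- i + 1L
      }
      if (length(buf))
        stop_parse("loop row does not match tag count", buf_line)
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
    } else i <- i + 1L
  }
  loops
}

star_find_loop <- function(loops, marker) {
  for (lp in loops) if (any(grepl(marker, lp$tags))) return(lp)
  NULL
}

loop_col <- function(lp, candidates, required = TRUE) {
  for (tag in candidates) {
    j <- match(tag, lp$tags)
    if (!is.na(j)) return(j)
  }
  if (required) stop_parse(paste0("missing STAR tag(s): ",
                                  paste(candidates, collapse = " / ")))
  NA_integer_
}

loop_records <- function(lp, seq_col, label_col, atom_col, val_col,
                         entity_col = NA_integer_) {
  if (!length(lp$rows)) stop_parse("shift loop contains no data rows")
  g <- function(j) vapply(lp$rows, function(r) r$values[[j]], "")
  rec <- data.frame(
    line = vapply(lp$rows, function(r) r$line, 1L),
    seq_code = g(seq_col), label = g(label_col),
    atom = g(atom_col), value = g(val_col),
    stringsAsFactors = FALSE
  )
  if (!is.na(entity_col)) {
    ent <- g(entity_col)
    ents <- unique(ent[!ent %in% c(".", "?")])
    if (length(ents) > 1L) {
      warning("multiple entities in STAR file; using entity ", ents[1])
      rec <- rec[ent == ents[1], , drop = FALSE]
    }
  }
  rec
}

parse_nmrstar3 <- function(lines) {
  lp <- star_find_loop(star_loops(lines), "^_Atom_chem_shift\\.")
  if (is.null(lp)) stop_parse("no _Atom_chem_shift loop found")
  loop_records(
    lp,
    seq_col = loop_col(lp, c("_Atom_chem_shift.Seq_ID",
                             "_Atom_chem_shift.Comp_index_ID",
                             "_Atom_chem_shift.Auth_seq_ID")),
    label_col = loop_col(lp, "_Atom_chem_shift.Comp_ID"),
    atom_col = loop_col(lp, "_Atom_chem_shift.Atom_ID"),
    val_col = loop_col(lp, "_Atom_chem_shift.Val"),
    entity_col = loop_col(lp, "_Atom_chem_shift.Entity_ID", required = FALSE)
  )
}

parse_nmrstar2 <- function(lines) {
  lp <- star_find_loop(star_loops(lines), "^_Chem_shift_value$")
  if (is.null(lp)) stop_parse("no chemical-shift loop (_Chem_shift_value) found")
  loop_records(
    lp,
    seq_col = loop_col(lp, "_Residue_seq_code"),
    label_col = loop_col(lp, "_Residue_label"),
    atom_col = loop_col(lp, "_Atom_name"),
    val_col = loop_col(lp, "_Chem_shift_value")
  )
}

parse_shifty <- function(lines) {
  hdr_i <- grep("^\\s*#\\s*NUM\\b", lines, ignore.case = TRUE)
  if (!length(hdr_i)) stop_parse("SHIFTY header (#NUM AA ...) not found")
  hdr_i <- hdr_i[1]
  cols <- toupper(strsplit(trimws(sub("^\\s*#", "", lines[hdr_i])),
                           "\\s+")[[1]])
  if (length(cols) < 3 || cols[1] != "NUM")
    stop_parse("malformed SHIFTY header", hdr_i)
  recs <- list()
  for (i in seq(hdr_i + 1L, length.out = max(0L, length(lines) - hdr_i))) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "#")) next
    toks <- strsplit(l, "\\s+")[[1]]
    if (length(toks) != length(cols))
      stop_parse(sprintf("expected %d columns, found %d",
                         length(cols), length(toks)), i)
    for (j in 3:length(cols)) {
      if (toks[j] %in% c(".", "", "?", "-")) next
      recs[[length(recs) + 1L]] <- data.frame(
        line = i, seq_code = toks[1], label = toks[2],
        atom = cols[j], value = toks[j], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(recs)) stop_parse("SHIFTY file contains no shift values")
  do.call(rbind, recs)
}

# ---- normalization ----------------------------------------------------------

normalize_residue_label <- function(label, line) {
  lab <- toupper(label)
  out <- character(length(lab))
  three <- lab %in% names(AA3TO1)
  one <- lab %in% AA3TO1
  out[three] <- AA3TO1[lab[three]]
  out[one & !three] <- lab[one & !three]
  bad <- !(three | one)
  if (any(bad))
    stop_parse(paste0("unknown residue label: ", lab[bad][1]), line[bad][1])
  out
}

build_dataset <- function(rec, source_format, chain_id = "A") {
  rec$atom <- toupper(rec$atom)
  syn <- match(rec$atom, names(ATOM_SYNONYMS))
  rec$atom[!is.na(syn)] <- ATOM_SYNONYMS[syn[!is.na(syn)]]

  rec <- rec[!(rec$value %in% c(".", "?", "")), , drop = FALSE]
  if (!nrow(rec)) stop_parse("no shift values found")
  n_records <- nrow(rec)

  known <- rec$atom %in% BACKBONE_ATOMS
  if (any(!known)) {
    warning(sprintf("ignoring %d shift(s) on non-backbone atoms (%s)",
                    sum(!known),
                    paste(unique(rec$atom[!known]), collapse = ", ")))
  }
  n_rejected <- sum(!known)
  rec <- rec[known, , drop = FALSE]

  seq_code <- suppressWarnings(as.integer(rec$seq_code))
  if (anyNA(seq_code))
    stop_parse("non-integer residue number", rec$line[which(is.na(seq_code))[1]])
  val <- suppressWarnings(as.numeric(rec$value))
  if (anyNA(val) || any(!is.finite(val)))
    stop_parse("non-numeric shift value",
               rec$line[which(is.na(val) | !is.finite(val))[1]])
  aa <- normalize_residue_label(rec$label, rec$line)

  codes <- sort(unique(seq_code))
  for (code in codes) {
    labs <- unique(aa[seq_code == code])
    if (length(labs) > 1L)
      stop_parse(sprintf(
        "residue %d has conflicting residue labels (%s); sequence cannot be reconstructed",
        code, paste(labs, collapse = ", ")))
  }
  if (any(diff(codes) != 1L))
    warning("gaps in author residue numbering; residues renumbered contiguously 1..N")
  residue <- match(seq_code, codes)
  sequence <- paste(aa[match(codes, seq_code)], collapse = "")
  sq <- seq_chars(sequence)

  # per-residue HA bookkeeping: glycine may carry HA2/HA3 (not mixed with HA);
  # any other residue at most one HA and never HA2/HA3
  for (r in unique(residue)) {
    atoms_r <- rec$atom[residue == r]
    if (sq[r] == "G") {
      if ("HA" %in% atoms_r && any(c("HA2", "HA3") %in% atoms_r))
        stop_parse(sprintf("glycine %d carries both HA and HA2/HA3", r))
    } else if (any(c("HA2", "HA3") %in% atoms_r)) {
      stop_parse(sprintf("non-glycine residue %d carries HA2/HA3", r))
    }
  }

  key <- paste(residue, rec$atom)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_parse(paste0("duplicate shift entry for residue/atom ", d))
  }

  shifts <- data.frame(residue = residue, atom = rec$atom, value = val,
                       stringsAsFactors = FALSE)
  shifts <- shifts[order(shifts$residue, shifts$atom), , drop = FALSE]
  rownames(shifts) <- NULL

  structure(
    list(chain_id = chain_id, sequence = sequence, n = length(codes),
         shifts = shifts, source_format = source_format,
         author_numbering = data.frame(residue = seq_along(codes),
                                       author_seq = codes),
         n_records = n_records, n_rejected = n_rejected),
    class = "shift_dataset"
  )
}

#' Parse an assigned chemical-shift file
#'
#' @param text File content (string or character vector of lines).
#' @param format Dialect; autodetected when omitted.
#' @return A `shift_dataset`: chain id, one-letter sequence, a long-format
#'   shift table (`residue`, `atom`, `value` in ppm) over the canonical
#'   backbone atom set, and the author-numbering map.
#' @export
parse_shifts <- function(text, format = detect_format(text)) {
  lines <- as_lines(text)
  rec <- switch(format,
    nmrstar3 = parse_nmrstar3(lines),
    nmrstar2 = parse_nmrstar2(lines),
    shifty = parse_shifty(lines),
    stop_parse(paste0("unknown format: ", format))
  )
  build_dataset(rec, format)
}

#' Read a chemical-shift file from disk
#' @param path File path.
#' @param format Dialect override; autodetected by default.
#' @return A `shift_dataset`.
#' @export
read_shifts <- function(path, format = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(format)) format <- detect_format(lines)
  parse_shifts(lines, format)
}

#' @export
print.shift_dataset <- function(x, ...) {
  cat(sprintf("shift_dataset: chain %s, %d residues, %d shifts (%s)\n",
              x$chain_id, x$n, nrow(x$shifts), x$source_format))
  cat("sequence:", x$sequence, "\n")
  invisible(x)
}

shift_lookup <- function(ds) {
  # residue x atom matrix of observed shifts (NA where absent)
  m <- matrix(NA_real_, ds$n, length(BACKBONE_ATOMS),
              dimnames = list(NULL, BACKBONE_ATOMS))
  m[cbind(ds$shifts$residue, match(ds$shifts$atom, BACKBONE_ATOMS))] <-
    ds$shifts$value
  m
}

# ---- completeness -----------------------------------------------------------

#' Backbone shift completeness report
#'
#' Expected atoms per residue are H, HA, CA, CB, C and N, minus CB for
#' glycine (HA2/HA3 jointly satisfy glycine's HA) and minus H for proline.
#'
#' @param ds A `shift_dataset`.
#' @return List with `overall_pct`, named `per_atom_pct` and a `missing`
#'   data frame of absent (residue, atom) pairs.
#' @export
completeness <- function(ds) {
  sq <- seq_chars(ds$sequence)
  obs <- shift_lookup(ds)
  expected_atoms <- c("H", "HA", "CA", "CB", "C", "N")
  exp_n <- stats::setNames(numeric(length(expected_atoms)), expected_atoms)
  got_n <- exp_n
  missing <- list()
  for (i in seq_len(ds$n)) {
    for (a in expected_atoms) {
      if (a == "CB" && sq[i] == "G") next
      if (a == "H" && sq[i] == "P") next
      exp_n[a] <- exp_n[a] + 1
      present <- if (a == "HA" && sq[i] == "G")
        any(!is.na(obs[i, c("HA", "HA2", "HA3")]))
      else !is.na(obs[i, a])
      if (present) got_n[a] <- got_n[a] + 1
      else missing[[length(missing) + 1L]] <-
        data.frame(residue = i, atom = a, stringsAsFactors = FALSE)
    }
  }
  per_atom <- ifelse(exp_n > 0, 100 * got_n / exp_n, NA_real_)
  structure(
    list(overall_pct = 100 * sum(got_n) / sum(exp_n),
         per_atom_pct = per_atom,
         missing = if (length(missing)) do.call(rbind, missing)
                   else data.frame(residue = integer(), atom = character())),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("backbone shift completeness: %.1f%%\n", x$overall_pct))
  for (a in names(x$per_atom_pct))
    cat(sprintf("  %-3s %.1f%%\n", a, x$per_atom_pct[a]))
  invisible(x)
}

# ---- torsion tables ---------------------------------------------------------

wrap_angle <- function(x) ((x + 180) %% 360) - 180

#' Parse a TALOS-N style torsion-angle prediction table
#'
#' Whitespace-columnar with optional `DATA`/`VARS`/`FORMAT` header lines.
#' Columns are located via the `VARS` line when present (RESID, PHI, PSI,
#' CLASS), else positionally (1, 3, 4, last). Rows whose class label is
#' `None`, or whose angles carry the 9999 missing sentinel, are dropped.
#' Angles are wrapped to [-180, 180).
#'
#' @param text File content.
#' @return A `torsion_table` data frame (`residue`, `phi`, `psi`, `class`)
#'   with attribute `n_dropped`.
#' @export
parse_torsion_table <- function(text) {
  lines <- as_lines(text)
  vars <- NULL
  recs <- list()
  dropped <- 0L
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "#")) next
    toks <- strsplit(l, "\\s+")[[1]]
    head1 <- toupper(toks[1])
    if (head1 == "VARS") { vars <- toupper(toks[-1]); next }
    if (head1 %in% c("DATA", "FORMAT", "REMARK")) next
    if (!grepl("^-?[0-9]+$", toks[1]))
      stop_parse("unrecognized torsion-table row", i)
    idx <- function(name, default) {
      j <- if (!is.null(vars)) match(name, vars) else NA_integer_
      if (is.na(j)) default else j
    }
    phi_j <- idx("PHI", 3L)
    psi_j <- idx("PSI", 4L)
    cls_j <- idx("CLASS", length(toks))
    if (length(toks) < max(phi_j, psi_j))
      stop_parse("torsion-table row too short", i)
    phi <- suppressWarnings(as.numeric(toks[phi_j]))
    psi <- suppressWarnings(as.numeric(toks[psi_j]))
    if (is.na(phi) || is.na(psi))
      stop_parse("non-numeric torsion angle", i)
    cls <- if (cls_j <= length(toks) &&
               !grepl("^-?[0-9.]+$", toks[cls_j])) toks[cls_j] else NA_character_
    if ((!is.na(cls) && tolower(cls) == "none") ||
        abs(phi) > 360 || abs(psi) > 360) {
      dropped <- dropped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      residue = as.integer(toks[1]), phi = wrap_angle(phi),
      psi = wrap_angle(psi), class = cls, stringsAsFactors = FALSE
    )
  }
  tt <- if (length(recs)) do.call(rbind, recs)
        else data.frame(residue = integer(), phi = numeric(),
                        psi = numeric(), class = character())
  if (anyDuplicated(tt$residue)) stop_parse("duplicate torsion-table residue")
  tt <- tt[order(tt$residue), , drop = FALSE]
  rownames(tt) <- NULL
  attr(tt, "n_dropped") <- dropped
  class(tt) <- c("torsion_table", "data.frame")
  tt
}

#' Read a torsion table from disk
#' @param path File path.
#' @return A `torsion_table`.
#' @export
read_torsion_table <- function(path) parse_torsion_table(readLines(path, warn = FALSE))

#' Fraction of residues with a torsion entry
#' @param tt A `torsion_table`.
#' @param n Number of residues in the companion dataset.
#' @return Coverage in [0, 1].
#' @export
torsion_coverage <- function(tt, n) nrow(tt) / n

# ---- writers ----------------------------------------------------------------

fmt_shift <- function(x) formatC(x, format = "f", digits = 3)

write_shifty_text <- function(ds) {
  obs <- shift_lookup(ds)
  sq <- seq_chars(ds$sequence)
  cols <- c("H", "HA", "HA2", "HA3", "CA", "CB", "C", "N")
  out <- paste("#NUM AA", paste(cols, collapse = " "))
  for (i in seq_len(ds$n)) {
    vals <- vapply(cols, function(a)
      if (is.na(obs[i, a])) "." else fmt_shift(obs[i, a]), "")
    out <- c(out, paste(i, sq[i], paste(vals, collapse = " ")))
  }
  out
}

write_nmrstar3_text <- function(ds) {
  tags <- paste0("_Atom_chem_shift.",
                 c("ID", "Entity_ID", "Seq_ID", "Comp_ID", "Atom_ID",
                   "Atom_type", "Val"))
  sq <- seq_chars(ds$sequence)
  rows <- character(nrow(ds$shifts))
  for (k in seq_len(nrow(ds$shifts))) {
    r <- ds$shifts$residue[k]
    a <- ds$shifts$atom[k]
    rows[k] <- sprintf("     %d 1 %d %s %s %s %s", k, r, AA1TO3[sq[r]], a,
                       substr(a, 1, 1), fmt_shift(ds$shifts$value[k]))
  }
  c("data_assigned_chemical_shifts", "",
    "save_assigned_chem_shift_list_1",
    "   _Assigned_chem_shift_list.Sf_category  assigned_chemical_shifts",
    "   loop_", paste0("      ", tags), "", rows, "   stop_", "save_")
}

write_nmrstar2_text <- function(ds) {
  tags <- c("_Atom_shift_assign_ID", "_Residue_seq_code", "_Residue_label",
            "_Atom_name", "_Atom_type", "_Chem_shift_value",
            "_Chem_shift_value_error")
  sq <- seq_chars(ds$sequence)
  rows <- character(nrow(ds$shifts))
  for (k in seq_len(nrow(ds$shifts))) {
    r <- ds$shifts$residue[k]
    a <- ds$shifts$atom[k]
    rows[k] <- sprintf("     %d %d %s %s %s %s 0.02", k, r, AA1TO3[sq[r]], a,
                       substr(a, 1, 1), fmt_shift(ds$shifts$value[k]))
  }
  c("data_entry", "", "save_chemical_shift_assignment_data_set_one",
    "   loop_", paste0("      ", tags), "", rows, "   stop_", "save_")
}

#' Write a shift dataset in one of the accepted dialects
#'
#' @param ds A `shift_dataset`.
#' @param path Output path, or `NULL` to return the lines invisibly.
#' @param dialect `"nmrstar2"`, `"nmrstar3"` or `"shifty"`.
#' @return The file lines, invisibly.
#' @export
write_shifts <- function(ds, path = NULL,
                         dialect = c("shifty", "nmrstar2", "nmrstar3")) {
  dialect <- match.arg(dialect)
  lines <- switch(dialect,
    shifty = write_shifty_text(ds),
    nmrstar2 = write_nmrstar2_text(ds),
    nmrstar3 = write_nmrstar3_text(ds)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a torsion table in the TALOS-N prediction-table dialect
#'
#' @param tt A `torsion_table` (columns `residue`, `phi`, `psi`, optionally
#'   `class`; missing class defaults to `Strong`).
#' @param sequence Optional one-letter sequence used for the residue-type
#'   column (falls back to `A`).
#' @param path Output path, or `NULL` to return the lines invisibly.
#' @return The file lines, invisibly.
#' @export
write_torsion_table <- function(tt, sequence = NULL, path = NULL) {
  cls <- if ("class" %in% names(tt) && !all(is.na(tt$class)))
    ifelse(is.na(tt$class), "Strong", tt$class) else rep("Strong", nrow(tt))
  sq <- if (!is.null(sequence)) seq_chars(sequence) else NULL
  rows <- vapply(seq_len(nrow(tt)), function(k) {
    aa <- if (!is.null(sq)) sq[tt$residue[k]] else "A"
    sprintf("%5d %s %9.3f %9.3f %9.3f %9.3f %9.3f %6.3f %3d %3d %s",
            tt$residue[k], aa, tt$phi[k], tt$psi[k], 10, 10, 0, 0.85,
            25L, 6L, cls[k])
  }, "")
  lines <- c("DATA FIRST_RESID 1",
             "VARS   RESID RESNAME PHI PSI DPHI DPSI DIST S2 COUNT CS_COUNT CLASS",
             "FORMAT %4d %s %9.3f %9.3f %9.3f %9.3f %9.3f %6.3f %3d %3d %s",
             "", rows)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
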