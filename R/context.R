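# Contextual assignment phase: beta-turn typing from central-residue
# torsions (30/45 degree rule, S2-gated), beta-hairpin detection (two
# sequential strands joined by a loop of at most six residues containing a
# selected reverse turn), and the seven-criterion edge/interior strand
# score. Results merge into the final 11-class annotation.

#' Minimal angular deviation on the circle
#' @param a,b Angles in degrees.
#' @return Deviation in [0, 180].
#' @export
angular_deviation <- function(a, b) abs(((a - b + 180) %% 360) - 180)

#' Classify a four-residue window as a beta-turn type
#'
#' Compares the central-pair torsions (phi, psi of residues i+1 and i+2)
#' with the canonical angles of the five turn types. A type matches when at
#' least three of the four deviations are within `tol_primary_deg` and the
#' remaining one within `tol_relaxed_deg`, all bounds inclusive. Among
#' matching types the one with the smallest total deviation wins (canonical
#' table order breaks exact ties).
#'
#' @param phi1,psi1,phi2,psi2 Central-residue torsions in degrees.
#' @param cfg An [ssa_config()].
#' @return List with `type` (one of I, II, I', II', VIII, or `NA`),
#'   `deviations` (4 values for the winning type) and `total`.
#' @export
classify_turn <- function(phi1, psi1, phi2, psi2, cfg = ssa_config()) {
  canon <- cfg$canonical_turn_angles
  best <- list(type = NA_character_, deviations = rep(NA_real_, 4),
               total = Inf)
  for (ty in rownames(canon)) {
    dev <- angular_deviation(c(phi1, psi1, phi2, psi2), canon[ty, ])
    ok <- sum(dev <= cfg$tol_primary_deg) >= 3 &&
      max(dev) <= cfg$tol_relaxed_deg
    if (ok && sum(dev) < best$total)
      best <- list(type = ty, deviations = unname(dev), total = sum(dev))
  }
  best
}

#' Locate and type beta-turns
#'
#' Scans every window i..i+3 whose two central residues are coil with
#' S2 strictly above the gate (undefined S2 fails) and carry torsion
#' entries, classifies it, then greedily selects a non-overlapping set in
#' ascending (total deviation, start) order. Two turns overlap when their
#' central pairs share a residue.
#'
#' @param ss Character state vector from [assign_sse()].
#' @param o An `order_profile`.
#' @param tt A `torsion_table` (or `NULL`: no turns are typed).
#' @param cfg An [ssa_config()].
#' @return Data frame of selected turns: `start`, `type`, `d1`..`d4`,
#'   `total`. Attribute `candidates` holds all matching windows before
#'   overlap resolution.
#' @export
find_turns <- function(ss, o, tt, cfg = ssa_config()) {
  n <- length(ss)
  empty <- data.frame(start = integer(), type = character(),
                      d1 = numeric(), d2 = numeric(), d3 = numeric(),
                      d4 = numeric(), total = numeric())
  if (is.null(tt) || !nrow(tt) || n < 4) {
    attr(empty, "candidates") <- empty
    return(empty)
  }
  phi <- psi <- rep(NA_real_, n)
  keep <- tt$residue <= n
  phi[tt$residue[keep]] <- tt$phi[keep]
  psi[tt$residue[keep]] <- tt$psi[keep]
  cand <- list()
  for (i in seq_len(n - 3L)) {
    c1 <- i + 1L; c2 <- i + 2L
    if (ss[c1] != "C" || ss[c2] != "C") next
    if (!gate_gt(o$s2[c1], cfg$s2_turn_gate) ||
        !gate_gt(o$s2[c2], cfg$s2_turn_gate)) next
    if (is.na(phi[c1]) || is.na(psi[c1]) || is.na(phi[c2]) || is.na(psi[c2]))
      next
    hit <- classify_turn(phi[c1], psi[c1], phi[c2], psi[c2], cfg)
    if (is.na(hit$type)) next
    cand[[length(cand) + 1L]] <- data.frame(
      start = i, type = hit$type, d1 = hit$deviations[1],
      d2 = hit$deviations[2], d3 = hit$deviations[3],
      d4 = hit$deviations[4], total = hit$total,
      stringsAsFactors = FALSE
    )
  }
  cand <- if (length(cand)) do.call(rbind, cand) else empty
  sel <- greedy_select_turns(cand)
  attr(sel, "candidates") <- cand
  sel
}

# stable greedy: ascending (total deviation, start); overlap = shared central
greedy_select_turns <- function(cand) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$total, cand$start), , drop = FALSE]
  taken <- logical(0)
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    centrals <- c(cand$start[k] + 1L, cand$start[k] + 2L)
    if (!any(centrals %in% used)) {
      keep[k] <- TRUE
      used <- c(used, centrals)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect beta-hairpins
#'
#' For each pair of sequentially adjacent strands whose connecting loop has
#' at most `hairpin_max_loop` residues, reports a hairpin when at least one
#' selected turn of an accepted type has both central residues inside the
#' loop; the in-loop turn with the smallest total deviation is recorded.
#'
#' @param ss State vector.
#' @param turns Selected turns from [find_turns()].
#' @param cfg An [ssa_config()].
#' @return Data frame: strand spans, loop span, and the licensing turn.
#' @export
detect_hairpins <- function(ss, turns, cfg = ssa_config()) {
  strands <- state_runs(ss, "B")
  out <- list()
  if (nrow(strands) >= 2 && nrow(turns)) {
    for (k in seq_len(nrow(strands) - 1L)) {
      loop_start <- strands$end[k] + 1L
      loop_end <- strands$start[k + 1L] - 1L
      loop_len <- loop_end - loop_start + 1L
      if (loop_len < 1L || loop_len > cfg$hairpin_max_loop) next
      inloop <- turns$type %in% cfg$hairpin_turn_types &
        (turns$start + 1L) >= loop_start & (turns$start + 2L) <= loop_end
      if (!any(inloop)) next
      cand <- turns[inloop, , drop = FALSE]
      best <- cand[order(cand$total, cand$start)[1], ]
      out[[length(out) + 1L]] <- data.frame(
        strand1_start = strands$start[k], strand1_end = strands$end[k],
        loop_start = loop_start, loop_end = loop_end,
        strand2_start = strands$start[k + 1L],
        strand2_end = strands$end[k + 1L],
        turn_start = best$start, turn_type = best$type,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(strand1_start = integer(), strand1_end = integer(),
                  loop_start = integer(), loop_end = integer(),
                  strand2_start = integer(), strand2_end = integer(),
                  turn_start = integer(), turn_type = character())
}

#' Alternating HA secondary-shift sign pattern
#'
#' Edge strands, hydrogen bonded to water on one face, show alternating
#' upfield/downfield HA secondary shifts; interior strands do not. True when
#' the sign strictly changes over at least `frac` of the consecutive residue
#' pairs with HA available on both sides.
#'
#' @param span Residue indices of the strand.
#' @param p A `secondary_shifts` object.
#' @param frac Minimum alternating fraction.
#' @return Logical.
#' @export
ha_alternation <- function(span, p, frac = 0.7) {
  stopifnot(length(span) >= 3)
  d <- p$delta[span, "HA"]
  alt <- avail <- 0L
  for (k in seq_len(length(d) - 1L)) {
    if (is.na(d[k]) || is.na(d[k + 1L])) next
    avail <- avail + 1L
    if (d[k] * d[k + 1L] < 0) alt <- alt + 1L
  }
  avail > 0L && alt / avail >= frac
}

#' Hydrophobic/hydrophilic periodicity of a sequence segment
#'
#' Residues are classed hydrophobic or hydrophilic by the bundled binary
#' hydropathy table; true when the class alternates over at least `frac`
#' of consecutive pairs.
#'
#' @param seq_segment Character vector of one-letter codes.
#' @param frac Minimum alternating fraction.
#' @return Logical.
#' @export
hydropathy_periodicity <- function(seq_segment, frac = 0.7) {
  stopifnot(length(seq_segment) >= 3)
  cls <- is_hydrophobic(seq_segment)
  mean(cls[-length(cls)] != cls[-1]) >= frac
}

#' Charged-residue pattern of a strand
#'
#' True when the fraction of charged residues (D, E, K, R, H) reaches
#' `frac`, or when at least one charged residue sits in the central third
#' of the span — charged residues sit mid-strand in edge strands and almost
#' never in interior ones.
#'
#' @param seq_segment Character vector of one-letter codes.
#' @param frac Minimum charged fraction for the proportion clause.
#' @return Logical.
#' @export
charge_pattern <- function(seq_segment, frac = 0.25) {
  stopifnot(length(seq_segment) >= 3)
  charged <- seq_segment %in% CHARGED_AA
  L <- length(seq_segment)
  lo <- floor(L / 3) + 1L
  hi <- L - floor(L / 3)
  mean(charged) >= frac || any(charged[lo:hi])
}

#' Seven-criterion edge/interior classification of one strand
#'
#' Criteria (one point each): alternating HA signs; average strand fASA
#' strictly above 0.3; strict majority (> 0.50) of exposed residues
#' (fASA > 0.25); rigid-residue fraction (S2 > 0.90) strictly below 0.40;
#' hydropathy periodicity; charged-residue pattern; short strand
#' (< 5 residues). A strand whose score exceeds 4 (i.e. >= 5 of 7) is an
#' edge strand, otherwise interior.
#'
#' @param span Residue indices of the strand (contiguous).
#' @param p A `secondary_shifts` object.
#' @param o An `order_profile`.
#' @param f A `fasa_profile`.
#' @param seq One-letter sequence of the whole chain.
#' @param cfg An [ssa_config()].
#' @return One-row data frame: span, the seven named booleans,
#'   `edge_score`, `call`.
#' @export
edge_criteria <- function(span, p, o, f, seq, cfg = ssa_config()) {
  sq <- seq_chars(seq)[span]
  fasa <- f$fasa[span]
  crit <- c(
    ha_alternation = ha_alternation(span, p, cfg$ha_alternation_frac),
    high_avg_fasa = mean(fasa) > cfg$fasa_edge_avg,
    exposed_majority =
      mean(fasa > cfg$fasa_exposed) > cfg$exposed_majority,
    low_rigid_fraction =
      mean(gate_gt(o$s2[span], cfg$s2_rigid)) < cfg$rigid_frac_max,
    hydropathy_periodicity = hydropathy_periodicity(sq, cfg$hydropathy_frac),
    charge_pattern = charge_pattern(sq, cfg$charge_frac),
    short_strand = length(span) < cfg$short_strand_len
  )
  score <- sum(crit)
  data.frame(start = span[1], end = span[length(span)],
             t(as.data.frame(crit)), edge_score = score,
             call = if (score > cfg$edge_score_threshold) "edge" else "interior",
             row.names = NULL, stringsAsFactors = FALSE)
}

strand_topologies <- function(ss, p, o, f, seq, cfg = ssa_config()) {
  strands <- state_runs(ss, "B")
  if (!nrow(strands))
    return(data.frame(start = integer(), end = integer(),
                      ha_alternation = logical(), high_avg_fasa = logical(),
                      exposed_majority = logical(),
                      low_rigid_fraction = logical(),
                      hydropathy_periodicity = logical(),
                      charge_pattern = logical(), short_strand = logical(),
                      edge_score = integer(), call = character()))
  do.call(rbind, lapply(seq_len(nrow(strands)), function(k)
    edge_criteria(strands$start[k]:strands$end[k], p, o, f, seq, cfg)))
}

#' Merge component results into the final annotation
#'
#' Enforces the class-partition invariants: turn labels only on coil
#' central residues with no overlap, exactly one topology call per strand
#' run, hairpins referencing existing strands. Any violation is an internal
#' error naming the offending residue.
#'
#' @param ss State vector.
#' @param turns Selected turns.
#' @param hairpins Detected hairpins.
#' @param topologies Per-strand topology calls.
#' @param sequence One-letter chain sequence.
#' @return An `ssa_annotation`: per-residue `state`, `turn_label`,
#'   `hairpin`, `strand_class`, plus the three feature tables.
#' @export
merge_annotation <- function(ss, turns, hairpins, topologies, sequence) {
  n <- length(ss)
  turn_label <- rep(NA_character_, n)
  if (nrow(turns)) for (k in seq_len(nrow(turns))) {
    centrals <- c(turns$start[k] + 1L, turns$start[k] + 2L)
    for (r in centrals) {
      if (ss[r] != "C")
        stop("internal inconsistency: turn label on non-coil residue ", r)
      if (!is.na(turn_label[r]))
        stop("internal inconsistency: overlapping turn labels at residue ", r)
      turn_label[r] <- turns$type[k]
    }
  }
  strands <- state_runs(ss, "B")
  if (nrow(topologies) != nrow(strands) ||
      (nrow(strands) && !all(topologies$start == strands$start &
                             topologies$end == strands$end)))
    stop("internal inconsistency: topology calls do not match strand runs")
  strand_class <- rep(NA_character_, n)
  if (nrow(topologies)) for (k in seq_len(nrow(topologies)))
    strand_class[topologies$start[k]:topologies$end[k]] <- topologies$call[k]
  hairpin <- rep(FALSE, n)
  if (nrow(hairpins)) for (k in seq_len(nrow(hairpins))) {
    ok1 <- any(strands$start == hairpins$strand1_start[k] &
               strands$end == hairpins$strand1_end[k])
    ok2 <- any(strands$start == hairpins$strand2_start[k] &
               strands$end == hairpins$strand2_end[k])
    if (!ok1 || !ok2)
      stop("internal inconsistency: hairpin references a non-strand span at residue ",
           hairpins$strand1_start[k])
    hairpin[hairpins$strand1_start[k]:hairpins$strand2_end[k]] <- TRUE
  }
  structure(
    list(sequence = sequence, n = n, state = ss, turn_label = turn_label,
         hairpin = hairpin, strand_class = strand_class,
         turns = turns, hairpins = hairpins, strands = topologies),
    class = "ssa_annotation"
  )
}

#' @export
print.ssa_annotation <- function(x, ...) {
  cat(sprintf("ssa_annotation: %d residues\n", x$n))
  cat("  states:  ", paste(x$state, collapse = ""), "\n")
  cat(sprintf("  %d turn(s), %d hairpin(s), %d strand(s) (%d edge)\n",
              nrow(x$turns), nrow(x$hairpins), nrow(x$strands),
              sum(x$strands$call == "edge")))
  invisible(x)
}
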