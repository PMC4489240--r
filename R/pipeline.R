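# End-to-end pipeline in the published stage order:
# parse -> secondary shifts -> ternary filter -> 3-state assignment ->
# S2 -> (gate) -> torsions -> turn typing -> fASA -> hairpins ->
# edge/interior -> merged annotation.

#' Annotate an in-memory shift dataset
#'
#' @param ds A `shift_dataset`.
#' @param torsions A `torsion_table`, or `NULL` (turn typing is skipped
#'   with a message; no turns or hairpins can then be reported).
#' @param cfg An [ssa_config()].
#' @param order_override,fasa_override Optional externally supplied
#'   profiles replacing the built-in estimators.
#' @param rc Random-coil reference matrix.
#' @return An `ssa_annotation` with attribute `intermediates` (secondary
#'   shifts, index profile, consensus, states, S2, fASA).
#' @export
annotate_dataset <- function(ds, torsions = NULL, cfg = ssa_config(),
                             order_override = NULL, fasa_override = NULL,
                             rc = random_coil_table()) {
  p <- secondary_shifts(ds, rc)
  ci <- csi_filter(p, cfg$csi_thresholds)
  cons <- consensus_index(ci)
  ss <- assign_sse(cons, cfg$min_helix_len, cfg$min_strand_len)
  o <- if (!is.null(order_override)) order_override else rci_s2(p, cfg$rci)
  if (is.null(torsions))
    message("no torsion table supplied: turn typing skipped")
  turns <- find_turns(ss, o, torsions, cfg)
  f <- if (!is.null(fasa_override)) fasa_override
       else fasa_estimate(p, o, cfg$fasa_coef)
  hairpins <- detect_hairpins(ss, turns, cfg)
  topologies <- strand_topologies(ss, p, o, f, ds$sequence, cfg)
  ann <- merge_annotation(ss, turns, hairpins, topologies, ds$sequence)
  attr(ann, "intermediates") <- list(profile = p, index = ci,
                                     consensus = cons, order = o, fasa = f)
  ann
}

#' Annotate a chemical-shift file
#'
#' Reads the shift file (dialect autodetected unless given), optionally a
#' TALOS-N style torsion table and/or a per-residue profile TSV, runs the
#' pipeline, and — when `out_dir` is set — writes every intermediate
#' profile plus the final per-residue table, feature summary and plot.
#'
#' @param path Shift file path.
#' @param torsion_path Optional torsion-table path.
#' @param format Dialect override.
#' @param cfg An [ssa_config()].
#' @param profile_path Optional TSV with externally computed `s2`/`fasa`.
#' @param out_dir Optional output directory (created if needed).
#' @param plot Write an SVG plot into `out_dir` (requires cairo)?
#' @return The `ssa_annotation`, invisibly when `out_dir` is set.
#' @export
annotate_shifts <- function(path, torsion_path = NULL, format = NULL,
                            cfg = ssa_config(), profile_path = NULL,
                            out_dir = NULL, plot = TRUE) {
  ds <- read_shifts(path, format)
  tt <- if (!is.null(torsion_path)) read_torsion_table(torsion_path) else NULL
  ov <- if (!is.null(profile_path)) read_profile_tsv(profile_path, ds$n)
        else list(order = NULL, fasa = NULL)
  ann <- annotate_dataset(ds, tt, cfg, ov$order, ov$fasa)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    im <- attr(ann, "intermediates")
    write_index_tsv(im$index, file.path(out_dir, "csi_index.tsv"))
    write_profile_tsv(im$order, im$fasa, file.path(out_dir, "profiles.tsv"))
    write_annotation_tsv(ann, file.path(out_dir, "annotation.tsv"))
    writeLines(annotation_summary(ann), file.path(out_dir, "features.txt"))
    if (plot && capabilities("cairo")) {
      grDevices::svg(file.path(out_dir, "csi_plot.svg"), width = 10,
                     height = 4)
      plot_annotation(ann)
      grDevices::dev.off()
    }
    return(invisible(ann))
  }
  ann
}

#' Per-residue annotation table
#'
#' Columns: residue, aa, state, turn_type, hairpin, strand_class, s2, fasa.
#'
#' @param ann An `ssa_annotation` (with intermediates attached for the
#'   profile columns).
#' @param path Output path, or `NULL` to return the data frame.
#' @return The data frame, invisibly.
#' @export
write_annotation_tsv <- function(ann, path = NULL) {
  im <- attr(ann, "intermediates")
  df <- data.frame(
    residue = seq_len(ann$n), aa = seq_chars(ann$sequence),
    state = ann$state,
    turn_type = ifelse(is.na(ann$turn_label), ".", ann$turn_label),
    hairpin = ann$hairpin,
    strand_class = ifelse(is.na(ann$strand_class), ".", ann$strand_class),
    s2 = if (!is.null(im)) round(im$order$s2, 4) else NA_real_,
    fasa = if (!is.null(im)) round(im$fasa$fasa, 4) else NA_real_
  )
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a per-residue annotation table back into an annotation
#' @param path TSV written by [write_annotation_tsv()].
#' @return An `ssa_annotation` (per-residue fields only; feature tables are
#'   reconstructed from the per-residue columns).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  n <- nrow(df)
  state <- df$state
  turn_label <- ifelse(df$turn_type == ".", NA_character_, df$turn_type)
  strand_class <- ifelse(df$strand_class == ".", NA_character_,
                         df$strand_class)
  strands <- state_runs(state, "B")
  topo <- if (nrow(strands)) {
    data.frame(strands, call = strand_class[strands$start])
  } else data.frame(start = integer(), end = integer(), call = character())
  structure(
    list(sequence = paste(df$aa, collapse = ""), n = n, state = state,
         turn_label = turn_label, hairpin = as.logical(df$hairpin),
         strand_class = strand_class,
         turns = data.frame(start = integer(), type = character()),
         hairpins = data.frame(), strands = topo),
    class = "ssa_annotation")
}

annotation_summary <- function(ann) {
  out <- c(sprintf("sequence (%d aa): %s", ann$n, ann$sequence),
           paste0("states: ", paste(ann$state, collapse = "")), "")
  hx <- state_runs(ann$state, "H")
  out <- c(out, sprintf("helices: %d", nrow(hx)),
           if (nrow(hx)) sprintf("  H %d-%d", hx$start, hx$end))
  st <- ann$strands
  out <- c(out, sprintf("beta-strands: %d", nrow(st)),
           if (nrow(st)) sprintf("  B %d-%d  %s (edge score %d/7)",
                                 st$start, st$end, st$call, st$edge_score))
  tu <- ann$turns
  out <- c(out, sprintf("beta-turns: %d", nrow(tu)),
           if (nrow(tu)) sprintf("  type %-4s %d-%d (total deviation %.1f deg)",
                                 tu$type, tu$start, tu$start + 3L, tu$total))
  hp <- ann$hairpins
  out <- c(out, sprintf("beta-hairpins: %d", nrow(hp)),
           if (nrow(hp)) sprintf("  strands %d-%d / %d-%d, loop %d-%d, turn %s",
                                 hp$strand1_start, hp$strand1_end,
                                 hp$strand2_start, hp$strand2_end,
                                 hp$loop_start, hp$loop_end, hp$turn_type))
  out
}

#' Qn agreement scores between two annotations
#'
#' `q3`: percent of residues with the same H/B/C state. `q6_turn`: percent
#' agreement of turn-type labels (five types or non-turn) over the gated
#' set, i.e. residues that are coil in the reference. `q2_hairpin`:
#' percent agreement of per-residue hairpin membership. `q3_topology`:
#' percent agreement over \{edge, interior, non-strand\}.
#'
#' @param pred,truth `ssa_annotation` objects of equal length.
#' @return List of the four scores (0-100).
#' @export
evaluate_annotation <- function(pred, truth) {
  if (pred$n != truth$n)
    stop("annotation length mismatch: ", pred$n, " vs ", truth$n)
  pc <- function(x) 100 * mean(x)
  lab <- function(a) ifelse(is.na(a$turn_label), "non-turn", a$turn_label)
  topo <- function(a) ifelse(a$state == "B",
                             ifelse(is.na(a$strand_class), "strand",
                                    a$strand_class), "non-strand")
  gated <- truth$state == "C"
  list(
    q3 = pc(pred$state == truth$state),
    q6_turn = if (any(gated)) pc(lab(pred)[gated] == lab(truth)[gated])
              else 100,
    q2_hairpin = pc(pred$hairpin == truth$hairpin),
    q3_topology = pc(topo(pred) == topo(truth))
  )
}

#' CSI bar-graph plot with feature annotations
#'
#' Per-residue consensus index bars (helix evidence down, strand evidence
#' up) colored by assigned state, with glyph tracks for turns, hairpins and
#' edge/interior strand calls. Deterministic layout; draw to any open
#' device.
#'
#' @param ann An `ssa_annotation` carrying intermediates.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_annotation <- function(ann, main = "chemical shift index") {
  im <- attr(ann, "intermediates")
  cons <- if (!is.null(im)) im$consensus else
    ifelse(ann$state == "B", 1L, ifelse(ann$state == "H", -1L, 0L))
  n <- ann$n
  cols <- c(H = "#D55E00", B = "#0072B2", C = "grey60")
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(-2.2, 1.6),
                 xlab = "residue", ylab = "consensus CSI", yaxt = "n",
                 main = main)
  graphics::axis(2, at = c(-1, 0, 1))
  graphics::abline(h = 0, col = "grey80")
  graphics::rect(seq_len(n) - 0.4, 0, seq_len(n) + 0.4, cons,
                 col = cols[ann$state], border = NA)
  # feature tracks
  hx <- state_runs(ann$state, "H")
  if (nrow(hx))
    graphics::rect(hx$start - 0.4, -1.5, hx$end + 0.4, -1.3,
                   col = cols["H"], border = NA)
  st <- ann$strands
  if (nrow(st))
    graphics::rect(st$start - 0.4, -1.5, st$end + 0.4, -1.3,
                   col = ifelse(st$call == "edge", "#56B4E9", cols["B"]),
                   border = NA)
  tu <- ann$turns
  if (nrow(tu)) {
    graphics::points(tu$start + 1.5, rep(-1.75, nrow(tu)), pch = 25,
                     bg = "#009E73", col = "#009E73")
    graphics::text(tu$start + 1.5, rep(-1.95, nrow(tu)), tu$type, cex = 0.7)
  }
  hp <- ann$hairpins
  if (nrow(hp))
    graphics::segments(hp$strand1_start, -2.1, hp$strand2_end, -2.1,
                       lwd = 2, col = "#CC79A7")
  graphics::legend("topright", bty = "n", cex = 0.7,
                   fill = c(cols, "#56B4E9"),
                   legend = c("helix", "interior/strand", "coil", "edge strand"))
  invisible(NULL)
}
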