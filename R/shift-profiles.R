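# Secondary shifts, the ternary CSI digital filter, and the consensus
# 3-state secondary-structure assignment. This is the first pipeline stage:
# everything downstream depends only on the per-residue H/B/C states.

#' Per-residue secondary chemical shifts
#'
#' Observed shift minus the residue-specific random-coil reference, per
#' backbone nucleus. Glycine's HA secondary shift uses the mean of HA2/HA3
#' when both are present.
#'
#' @param ds A `shift_dataset`.
#' @param rc Random-coil reference matrix (see [random_coil_table()]).
#' @return A `secondary_shifts` object: an N x 6 `delta` matrix (columns
#'   H, HA, CA, CB, C, N; `NA` where unobserved) plus the sequence.
#' @export
secondary_shifts <- function(ds, rc = random_coil_table()) {
  sq <- seq_chars(ds$sequence)
  if (!all(sq %in% rownames(rc)))
    stop("random-coil table lacks entries for residue type(s): ",
         paste(setdiff(sq, rownames(rc)), collapse = ", "))
  obs <- shift_lookup(ds)
  atoms <- c("H", "HA", "CA", "CB", "C", "N")
  delta <- matrix(NA_real_, ds$n, length(atoms),
                  dimnames = list(NULL, atoms))
  for (i in seq_len(ds$n)) {
    aa <- sq[i]
    ha_obs <- if (aa == "G") {
      gly <- obs[i, c("HA", "HA2", "HA3")]
      if (all(is.na(gly))) NA_real_ else mean(gly, na.rm = TRUE)
    } else obs[i, "HA"]
    for (a in atoms) {
      o <- if (a == "HA") ha_obs else obs[i, a]
      if (is.na(o)) next
      ref <- rc[aa, a]
      if (is.na(ref))
        stop("random-coil table has no ", a, " reference for residue type ", aa)
      delta[i, a] <- o - ref
    }
  }
  structure(list(delta = delta, sequence = ds$sequence, n = ds$n),
            class = "secondary_shifts")
}

#' Ternary CSI digital filter
#'
#' Per nucleus: index +1 when the secondary shift strictly exceeds the
#' cutoff, -1 when it falls strictly below minus the cutoff, else 0
#' (including wherever the shift is unobserved).
#'
#' @param p A `secondary_shifts` object.
#' @param thresholds Named positive ppm cutoffs for HA, CA, CB, C.
#' @return A `csi_index` object: N x 4 ternary `index` matrix plus the
#'   thresholds used.
#' @export
csi_filter <- function(p, thresholds = csi_thresholds()) {
  stopifnot(all(thresholds > 0), all(CSI_NUCLEI %in% names(thresholds)))
  idx <- matrix(0L, p$n, length(CSI_NUCLEI),
                dimnames = list(NULL, CSI_NUCLEI))
  for (a in CSI_NUCLEI) {
    d <- p$delta[, a]
    idx[, a] <- ifelse(is.na(d), 0L,
                ifelse(d > thresholds[[a]], 1L,
                ifelse(d < -thresholds[[a]], -1L, 0L)))
  }
  structure(list(index = idx, thresholds = thresholds[CSI_NUCLEI], n = p$n),
            class = "csi_index")
}

#' Consensus per-residue ternary index
#'
#' Harmonizes the per-nucleus indices to a common strand(+)/helix(-)
#' convention — downfield HA/CB is strand evidence, downfield CA/C is helix
#' evidence — and takes the majority of non-zero votes. Ties and all-zero
#' residues give 0.
#'
#' @param ci A `csi_index` object.
#' @return Integer vector in \{-1, 0, +1\}; +1 marks strand, -1 helix.
#' @export
consensus_index <- function(ci) {
  harmonized <- ci$index
  harmonized[, c("CA", "C")] <- -harmonized[, c("CA", "C")]
  as.integer(sign(rowSums(harmonized)))
}

#' Three-state secondary-structure assignment
#'
#' Maximal runs of helix consensus (-1) of at least `min_helix_len` become
#' H; maximal strand runs (+1) of at least `min_strand_len` become B;
#' everything else, including too-short runs (beta-bridges of two or fewer
#' residues), is coil.
#'
#' @param consensus Integer vector from [consensus_index()].
#' @param min_helix_len Minimum helix run length (default 4).
#' @param min_strand_len Minimum strand run length (default 3).
#' @return Character vector of states `"H"`, `"B"`, `"C"`.
#' @export
assign_sse <- function(consensus, min_helix_len = 4, min_strand_len = 3) {
  state <- rep("C", length(consensus))
  r <- rle(consensus)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    span <- pos[k]:(pos[k + 1L] - 1L)
    if (r$values[k] == -1L && r$lengths[k] >= min_helix_len) state[span] <- "H"
    if (r$values[k] == 1L && r$lengths[k] >= min_strand_len) state[span] <- "B"
  }
  state
}

state_runs <- function(state, which) {
  r <- rle(state)
  pos <- cumsum(c(1L, r$lengths))
  keep <- which(r$values == which)
  data.frame(start = pos[keep], end = pos[keep + 1L] - 1L)
}

#' Write the per-residue ternary index profile as TSV
#'
#' Columns: residue, HA, CA, CB, C, consensus — the data behind the classic
#' CSI bar graph.
#'
#' @param ci A `csi_index` object.
#' @param path Output path, or `NULL` to return the data frame.
#' @return The data frame, invisibly.
#' @export
write_index_tsv <- function(ci, path = NULL) {
  df <- data.frame(residue = seq_len(ci$n), ci$index,
                   consensus = consensus_index(ci))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
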