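# Backbone flexibility (RCI-style S2 order parameter) and fractional
# accessible surface area (fASA), both estimated from backbone secondary
# shifts. These are deliberately simple, fully parameterized surrogates for
# the published RCI / side-chain-RCI models: downstream logic consumes only
# thresholded values (0.7, 0.90, 0.25, 0.3), which are honored exactly.

# weighted, normalized |delta| per residue, then a centered moving average
smoothed_delta_magnitude <- function(p, params) {
  nuc <- intersect(CSI_NUCLEI, names(params$normalizers))
  w <- params$weights[nuc]
  norm <- params$normalizers[nuc]
  m_raw <- vapply(seq_len(p$n), function(i) {
    d <- abs(p$delta[i, nuc]) / norm
    ok <- !is.na(d)
    if (!any(ok)) return(NA_real_)
    sum(d[ok] * w[ok]) / sum(w[ok])
  }, 0)
  half <- (params$window - 1L) %/% 2L
  m_s <- vapply(seq_len(p$n), function(i) {
    win <- m_raw[max(1L, i - half):min(p$n, i + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, 0)
  m_s[is.na(m_raw)] <- NA_real_  # no usable nuclei -> undefined
  m_s
}

#' RCI-style backbone order parameter
#'
#' Per residue: the weighted mean of normalized secondary-shift magnitudes
#' over the available nuclei, smoothed with a centered moving average, is
#' mapped to S2 = clamp(1 - k / max(m, floor), 0, 1). Residues near the
#' random-coil baseline score near 0; well-structured residues near 1; the
#' map is monotone in the smoothed magnitude. Residues with no usable
#' nuclei get `NA`, which fails every "greater-than" gate downstream.
#'
#' @param p A `secondary_shifts` object.
#' @param params Estimator settings (see the `rci` element of
#'   [ssa_config()]): `weights`, `normalizers`, odd `window`, `k`, `floor`.
#' @return An `order_profile`: per-residue `s2` in [0, 1] (or `NA`) plus the
#'   `method_params` used.
#' @export
rci_s2 <- function(p, params = ssa_config()$rci) {
  stopifnot(params$window %% 2 == 1, all(params$weights > 0),
            all(params$normalizers > 0))
  m <- smoothed_delta_magnitude(p, params)
  s2 <- 1 - params$k / pmax(m, params$floor)
  s2 <- pmin(pmax(s2, 0), 1)
  structure(list(s2 = s2, method_params = params, n = p$n),
            class = "order_profile")
}

#' Fractional accessible surface area estimate
#'
#' Logistic model on flexibility (1 - S2), Kyte-Doolittle hydropathy
#' (scaled to [-1, 1]) and the smoothed normalized secondary-shift
#' magnitude. Exposed residues — hydrophilic, flexible, near-random-coil —
#' score high; buried ones — hydrophobic, rigid, strongly shifted — score
#' low. Undefined S2 is treated as fully flexible (conservatively exposed).
#'
#' @param p A `secondary_shifts` object.
#' @param o An `order_profile` from [rci_s2()].
#' @param coef Model coefficients (see `fasa_coef` of [ssa_config()]).
#' @param rci_params Settings used to recompute the local shift magnitude.
#' @return A `fasa_profile` with per-residue `fasa` in [0, 1].
#' @export
fasa_estimate <- function(p, o, coef = ssa_config()$fasa_coef,
                          rci_params = o$method_params) {
  stopifnot(o$n == p$n)
  d <- smoothed_delta_magnitude(p, rci_params)
  d[is.na(d)] <- 0
  flex <- ifelse(is.na(o$s2), 1, 1 - o$s2)
  h <- kd_hydropathy()[seq_chars(p$sequence)] / 4.5
  x <- coef[["intercept"]] + coef[["flex"]] * flex +
    coef[["hydro"]] * h + coef[["delta"]] * d
  structure(list(fasa = unname(stats::plogis(x)), n = p$n),
            class = "fasa_profile")
}

# strict gate helpers: NA (undefined S2) fails > gates and passes < gates
gate_gt <- function(x, cut) !is.na(x) & x > cut
gate_lt <- function(x, cut) is.na(x) | x < cut

#' Write per-residue S2/fASA profiles as TSV
#' @param o An `order_profile` (or `NULL`).
#' @param f A `fasa_profile` (or `NULL`).
#' @param path Output path, or `NULL` to return the data frame.
#' @return The data frame, invisibly.
#' @export
write_profile_tsv <- function(o, f = NULL, path = NULL) {
  n <- if (!is.null(o)) o$n else f$n
  df <- data.frame(residue = seq_len(n),
                   s2 = if (!is.null(o)) o$s2 else NA_real_,
                   fasa = if (!is.null(f)) f$fasa else NA_real_)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read per-residue S2/fASA profiles from TSV
#'
#' Lets externally computed order parameters or accessibility values be
#' plugged into the pipeline in place of the built-in estimators.
#'
#' @param path TSV with columns `residue`, `s2` and/or `fasa`.
#' @param n Expected number of residues.
#' @return List with `order` (`order_profile` or `NULL`) and `fasa`
#'   (`fasa_profile` or `NULL`).
#' @export
read_profile_tsv <- function(path, n) {
  df <- utils::read.delim(path)
  stopifnot("residue" %in% names(df))
  o <- f <- NULL
  if ("s2" %in% names(df) && !all(is.na(df$s2))) {
    s2 <- rep(NA_real_, n)
    s2[df$residue] <- df$s2
    bad <- !is.na(s2) & (s2 < 0 | s2 > 1)
    if (any(bad)) stop("s2 outside [0,1] at residue ", which(bad)[1])
    o <- structure(list(s2 = s2, method_params = list(source = path), n = n),
                   class = "order_profile")
  }
  if ("fasa" %in% names(df) && !all(is.na(df$fasa))) {
    fa <- rep(NA_real_, n)
    fa[df$residue] <- df$fasa
    bad <- !is.na(fa) & (fa < 0 | fa > 1)
    if (any(bad)) stop("fasa outside [0,1] at residue ", which(bad)[1])
    f <- structure(list(fasa = fa, n = n), class = "fasa_profile")
  }
  list(order = o, fasa = f)
}
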