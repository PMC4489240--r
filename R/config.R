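# Run configuration: one flat object carrying every tunable threshold of the
# contextual-assignment phase plus the estimator parameters, overridable from
# a key-value config file and from CLI flags.

#' Pipeline configuration
#'
#' Builds the configuration object consumed by every stage of the pipeline.
#' Defaults follow the published contextual-assignment rules: turn candidates
#' are gated at S2 strictly greater than 0.7, turn typing uses the 30/45
#' degree tolerance rule, hairpin loops may span at most 6 residues, and a
#' strand is an edge strand when at least 5 of the 7 edge criteria fire
#' (score strictly greater than 4).
#'
#' @param csi_thresholds Named ppm cutoffs for the ternary filter (HA, CA,
#'   CB, C).
#' @param min_helix_len Minimum run of helix consensus indices kept as helix.
#' @param min_strand_len Minimum strand run; beta-bridges of 2 or fewer
#'   residues are reclassified as coil.
#' @param s2_turn_gate Coil residues with S2 at or below this value are
#'   excluded from turn typing.
#' @param tol_primary_deg,tol_relaxed_deg Turn-typing tolerances: at least 3
#'   of the 4 central torsions must fall within `tol_primary_deg` of the
#'   canonical values, the remaining one within `tol_relaxed_deg` (inclusive).
#' @param hairpin_max_loop Maximum loop length between the two strands of a
#'   hairpin.
#' @param hairpin_turn_types Turn types accepted as the hairpin's reverse
#'   turn (default: all five; set to `c("I'", "II'")` for strict mode).
#' @param fasa_exposed fASA above which a residue counts as exposed.
#' @param fasa_edge_avg Strand-average fASA that must be strictly exceeded
#'   for edge evidence.
#' @param exposed_majority Fraction of exposed residues that must be strictly
#'   exceeded for edge evidence.
#' @param s2_rigid S2 above which a residue counts as rigid.
#' @param rigid_frac_max Strand rigid-residue fraction strictly below this is
#'   edge evidence.
#' @param short_strand_len Strands shorter than this are edge evidence.
#' @param edge_score_threshold A strand is called edge when its score
#'   strictly exceeds this value.
#' @param ha_alternation_frac Minimum fraction of consecutive residue pairs
#'   with alternating HA secondary-shift signs.
#' @param hydropathy_frac Minimum fraction of consecutive pairs alternating
#'   between hydrophobic and hydrophilic classes.
#' @param charge_frac Minimum fraction of charged residues (D/E/K/R/H) for
#'   the charge-pattern criterion's proportion clause.
#' @param canonical_turn_angles 5 x 4 matrix of canonical central torsions.
#' @param rci List of order-parameter estimator settings: per-nucleus
#'   `weights` and dynamic-range `normalizers`, smoothing `window` (odd),
#'   map constants `k` and `floor`.
#' @param fasa_coef Coefficients of the logistic fASA estimator
#'   (`intercept`, `flex` on 1 - S2, `hydro` on scaled hydropathy, `delta`
#'   on the smoothed normalized secondary-shift magnitude).
#' @return A list of class `ssa_config`.
#' @export
ssa_config <- function(csi_thresholds = nmrsecstr::csi_thresholds(),
                       min_helix_len = 4,
                       min_strand_len = 3,
                       s2_turn_gate = 0.7,
                       tol_primary_deg = 30,
                       tol_relaxed_deg = 45,
                       hairpin_max_loop = 6,
                       hairpin_turn_types = TURN_TYPES,
                       fasa_exposed = 0.25,
                       fasa_edge_avg = 0.3,
                       exposed_majority = 0.50,
                       s2_rigid = 0.90,
                       rigid_frac_max = 0.40,
                       short_strand_len = 5,
                       edge_score_threshold = 4,
                       ha_alternation_frac = 0.7,
                       hydropathy_frac = 0.7,
                       charge_frac = 0.25,
                       canonical_turn_angles = nmrsecstr::canonical_turn_angles(),
                       rci = list(
                         weights = c(HA = 1, CA = 1, CB = 1, C = 1),
                         normalizers = c(HA = 0.2, CA = 1.4, CB = 1.4, C = 1.0),
                         window = 3, k = 0.08, floor = 0.02
                       ),
                       fasa_coef = c(intercept = 0.5, flex = 2.0,
                                     hydro = -1.5, delta = -2.0)) {
  cfg <- list(
    csi_thresholds = csi_thresholds, min_helix_len = min_helix_len,
    min_strand_len = min_strand_len, s2_turn_gate = s2_turn_gate,
    tol_primary_deg = tol_primary_deg, tol_relaxed_deg = tol_relaxed_deg,
    hairpin_max_loop = hairpin_max_loop, hairpin_turn_types = hairpin_turn_types,
    fasa_exposed = fasa_exposed, fasa_edge_avg = fasa_edge_avg,
    exposed_majority = exposed_majority, s2_rigid = s2_rigid,
    rigid_frac_max = rigid_frac_max, short_strand_len = short_strand_len,
    edge_score_threshold = edge_score_threshold,
    ha_alternation_frac = ha_alternation_frac,
    hydropathy_frac = hydropathy_frac, charge_frac = charge_frac,
    canonical_turn_angles = canonical_turn_angles, rci = rci,
    fasa_coef = fasa_coef
  )
  stopifnot(
    all(cfg$csi_thresholds > 0),
    cfg$tol_primary_deg > 0,
    cfg$tol_relaxed_deg >= cfg$tol_primary_deg,
    cfg$hairpin_max_loop >= 1,
    cfg$fasa_exposed >= 0, cfg$fasa_exposed <= 1,
    cfg$s2_rigid >= 0, cfg$s2_rigid <= 1,
    cfg$rci$window %% 2 == 1,
    all(cfg$hairpin_turn_types %in% TURN_TYPES)
  )
  structure(cfg, class = "ssa_config")
}

#' Read a key-value configuration file
#'
#' Lines of the form `key value` or `key = value`; `#` starts a comment.
#' Values are parsed as numbers where possible; comma-separated values become
#' vectors. Keys of the form `threshold_HA` override individual CSI cutoffs,
#' `rci_k`/`rci_floor`/`rci_window` override estimator constants, and any
#' scalar `ssa_config` field name overrides that field.
#'
#' @param path Path to the config file.
#' @param base Configuration to override (default `ssa_config()`).
#' @return An `ssa_config` object.
#' @export
read_config <- function(path, base = ssa_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (l in lines) {
    l <- sub("=", " ", l, fixed = TRUE)
    toks <- strsplit(l, "[[:space:]]+")[[1]]
    if (length(toks) < 2) stop("malformed config line: ", l)
    key <- toks[1]
    val <- paste(toks[-1], collapse = " ")
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    kv[[key]] <- if (!anyNA(num)) num else parts
  }
  apply_config_overrides(base, kv)
}

apply_config_overrides <- function(cfg, kv) {
  for (key in names(kv)) {
    val <- kv[[key]]
    if (grepl("^threshold_", key)) {
      atom <- sub("^threshold_", "", key)
      cfg$csi_thresholds[[atom]] <- val
    } else if (grepl("^rci_", key)) {
      cfg$rci[[sub("^rci_", "", key)]] <- val
    } else if (grepl("^fasa_coef_", key)) {
      cfg$fasa_coef[[sub("^fasa_coef_", "", key)]] <- val
    } else if (key %in% names(cfg)) {
      cfg[[key]] <- val
    } else {
      warning("unknown config key ignored: ", key)
    }
  }
  do.call(ssa_config, unclass(cfg))
}
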