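# Forward-model generator of synthetic proteins: a declared topology is
# turned into a consistent chemical-shift dataset, torsion table, S2/fASA
# profiles and ground-truth annotation. At zero noise the emissions invert
# exactly under the pipeline's default thresholds, which makes the
# generator the central closed-loop oracle of the test suite.

element <- function(kind, ...) c(list(kind = kind), list(...))

#' Topology element constructors
#'
#' Building blocks for [topology_spec()]: `el_helix(n)` (n >= 4),
#' `el_strand(n, role)` (edge strands n >= 3, interior n >= 5),
#' `el_coil(n, disordered)`, `el_turn(type)` (a 4-residue ordered-coil
#' segment whose central pair carries the canonical turn torsions) and
#' `el_hairpin(strand1, loop, strand2, turn_type, roles)` (loop 2..6, with
#' the turn placed at the start of the loop).
#'
#' @param n Element length in residues.
#' @param role,roles `"edge"` or `"interior"`.
#' @param disordered Emit near-zero secondary shifts (intrinsically
#'   disordered segment)?
#' @param type,turn_type One of I, II, I', II', VIII.
#' @param strand1,loop,strand2 Span lengths of the hairpin parts.
#' @return An element list for `topology_spec()`.
#' @name topology-elements
NULL

#' @rdname topology-elements
#' @export
el_helix <- function(n) element("helix", len = n)

#' @rdname topology-elements
#' @export
el_strand <- function(n, role = "interior") element("strand", len = n, role = role)

#' @rdname topology-elements
#' @export
el_coil <- function(n, disordered = FALSE)
  element("coil", len = n, disordered = disordered)

#' @rdname topology-elements
#' @export
el_turn <- function(type = "I") element("turn", len = 4L, type = type)

#' @rdname topology-elements
#' @export
el_hairpin <- function(strand1 = 5, loop = 2, strand2 = 5, turn_type = "I'",
                       roles = c("edge", "edge"))
  element("hairpin", strand1 = strand1, loop = loop, strand2 = strand2,
          turn_type = turn_type, roles = roles)

#' Declare a synthetic protein topology
#'
#' @param elements List of elements built with the `el_*` constructors.
#' @param seed Integer seed; generation is fully deterministic given
#'   (spec, model, seed).
#' @return A validated `topology_spec`.
#' @export
topology_spec <- function(elements, seed = 1L) {
  stopifnot(length(elements) >= 1)
  for (e in elements) {
    switch(e$kind,
      helix = stopifnot(e$len >= 4),
      strand = {
        stopifnot(e$role %in% c("edge", "interior"))
        stopifnot(e$len >= if (e$role == "interior") 5 else 3)
      },
      coil = stopifnot(e$len >= 1),
      turn = stopifnot(e$type %in% TURN_TYPES),
      hairpin = {
        stopifnot(e$loop >= 2, e$loop <= 6,
                  e$turn_type %in% TURN_TYPES,
                  length(e$roles) == 2,
                  all(e$roles %in% c("edge", "interior")))
        stopifnot(e$strand1 >= if (e$roles[1] == "interior") 5 else 3,
                  e$strand2 >= if (e$roles[2] == "interior") 5 else 3)
      },
      stop("unknown element kind: ", e$kind)
    )
  }
  structure(list(elements = elements, seed = as.integer(seed)),
            class = "topology_spec")
}

#' Generator emission model
#'
#' Defaults come from the bundled model file: structured states emit mean
#' secondary shifts at twice the CSI cutoffs (edge strands at 1.5x, which
#' lowers their apparent rigidity below the 0.90 rigid gate while keeping
#' them above the 0.7 turn gate), ordered coil at 0.7x (sub-threshold but
#' rigid), disordered segments near zero. `noise_scale` multiplies every
#' shift and angle noise sd; 0 gives the exact closed-loop regime.
#'
#' @param noise_scale Multiplier on all noise standard deviations.
#' @param path Optional replacement model TSV.
#' @return A `generator_model` list.
#' @export
generator_model <- function(noise_scale = 1, path = NULL) {
  kv <- if (is.null(path)) generator_defaults()
        else {
          df <- read_ref_tsv(path)
          stats::setNames(as.numeric(df$value), df$key)
        }
  g <- function(k) unname(kv[[k]])
  mean_delta <- rbind(
    helix = c(HA = g("helix_HA"), CA = g("helix_CA"),
              CB = g("helix_CB"), C = g("helix_C")),
    strand = c(HA = g("strand_HA"), CA = g("strand_CA"),
               CB = g("strand_CB"), C = g("strand_C")),
    coil = c(HA = g("coil_HA"), CA = g("coil_CA"),
             CB = g("coil_CB"), C = g("coil_C")),
    disordered = c(HA = g("disordered_HA"), CA = g("disordered_CA"),
                   CB = g("disordered_CB"), C = g("disordered_C"))
  )
  structure(list(
    mean_delta = mean_delta,
    edge_scale = g("edge_scale"),
    noise_sd = noise_scale *
      c(HA = g("noise_sd_HA"), CA = g("noise_sd_CA"), CB = g("noise_sd_CB"),
        C = g("noise_sd_C"), N = g("noise_sd_N"), H = g("noise_sd_H")),
    angles = c(helix_phi = g("helix_phi"), helix_psi = g("helix_psi"),
               strand_phi = g("strand_phi"), strand_psi = g("strand_psi"),
               coil_phi = g("coil_phi"), coil_psi = g("coil_psi")),
    angle_noise_sd = noise_scale * g("angle_noise_sd"),
    noise_scale = noise_scale
  ), class = "generator_model")
}

# deterministic sequence emitters; edge strands alternate charged/hydrophobic
# starting with the charged residue so odd lengths get an exposed majority
element_sequence <- function(kind, len, role = NULL, offset = 0L) {
  cyc <- function(set, n) set[((offset + seq_len(n) - 1L) %% length(set)) + 1L]
  switch(kind,
    helix = cyc(c("A", "E", "L", "K"), len),
    strand = if (identical(role, "edge"))
      rep_len(c("K", "V"), len) else rep("V", len),
    coil = cyc(c("S", "G", "N", "T"), len),
    disordered = cyc(c("G", "S"), len)
  )
}

layout_spec <- function(spec, cfg) {
  rows <- list()
  strand_ord <- 0L
  add <- function(kind, len, role = NA_character_, turn_type = NA_character_,
                  disordered = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, len = len, role = role, turn_type = turn_type,
      disordered = disordered, stringsAsFactors = FALSE)
  }
  for (e in spec$elements) {
    switch(e$kind,
      helix = add("helix", e$len),
      strand = add("strand", e$len, role = e$role),
      coil = add("coil", e$len, disordered = e$disordered),
      turn = add("turn", 4L, turn_type = e$type),
      hairpin = {
        add("strand", e$strand1, role = e$roles[1])
        add("loopturn", 2L, turn_type = e$turn_type)
        if (e$loop > 2L) add("coil", e$loop - 2L)
        add("strand", e$strand2, role = e$roles[2])
      }
    )
  }
  lay <- do.call(rbind, rows)
  lay$start <- cumsum(c(1L, lay$len))[seq_len(nrow(lay))]
  lay$end <- lay$start + lay$len - 1L
  lay
}

#' Generate a synthetic protein
#'
#' Emits a chemical-shift dataset (observed = random-coil reference +
#' state-dependent secondary shift + Gaussian noise), a TALOS-N style
#' torsion table (disordered residues carry class `None` and are dropped,
#' as the parser would), the S2/fASA profiles the pipeline would derive,
#' and the ground-truth annotation. Ground-truth hairpins are derived from
#' the truth layout by the hairpin definition (consecutive strands, loop
#' <= 6, turn central pair inside the loop).
#'
#' @param spec A [topology_spec()].
#' @param model A [generator_model()].
#' @param cfg An [ssa_config()] (supplies canonical turn angles and the
#'   random-coil table context).
#' @param rc Random-coil reference matrix.
#' @return List: `dataset`, `torsions`, `order`, `fasa`, `truth`
#'   (an `ssa_annotation`), and the internal `layout`.
#' @export
generate_protein <- function(spec, model = generator_model(),
                             cfg = ssa_config(), rc = random_coil_table()) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  lay <- layout_spec(spec, cfg)
  n <- max(lay$end)
  sq <- character(n)
  state <- rep("C", n)
  phi <- psi <- numeric(n)
  delta_mean <- matrix(0, n, 4, dimnames = list(NULL, CSI_NUCLEI))
  disordered <- rep(FALSE, n)
  truth_turns <- list()
  truth_roles <- list()

  for (k in seq_len(nrow(lay))) {
    span <- lay$start[k]:lay$end[k]
    kind <- lay$kind[k]
    emit_kind <- switch(kind, loopturn = "coil", turn = "coil", kind)
    if (lay$disordered[k]) emit_kind <- "disordered"
    sq[span] <- element_sequence(emit_kind, lay$len[k], lay$role[k],
                                 offset = lay$start[k] - 1L)
    base <- model$mean_delta[switch(emit_kind, helix = "helix",
                                    strand = "strand", coil = "coil",
                                    disordered = "disordered"), ]
    if (kind == "strand" && identical(lay$role[k], "edge")) {
      base <- base * model$edge_scale
      dm <- matrix(rep(base, each = length(span)), ncol = 4,
                   dimnames = list(NULL, CSI_NUCLEI))
      # start downfield (+), then alternate sign along the strand
      dm[, "HA"] <- abs(dm[, "HA"]) * rep_len(c(1, -1), length(span))
      delta_mean[span, ] <- dm
    } else if (emit_kind %in% c("coil", "disordered")) {
      sgn <- outer(span, seq_len(4), function(i, j) (-1)^(i + j))
      delta_mean[span, ] <- sgn * rep(abs(base), each = length(span))
    } else {
      delta_mean[span, ] <- rep(base, each = length(span))
    }
    state[span] <- switch(kind, helix = "H", strand = "B", "C")
    ang <- switch(emit_kind,
      helix = model$angles[c("helix_phi", "helix_psi")],
      strand = model$angles[c("strand_phi", "strand_psi")],
      model$angles[c("coil_phi", "coil_psi")])
    phi[span] <- ang[1]
    psi[span] <- ang[2]
    if (kind %in% c("turn", "loopturn")) {
      canon <- cfg$canonical_turn_angles[lay$turn_type[k], ]
      if (kind == "turn") {
        centrals <- span[2:3]
        tstart <- span[1]
      } else {            # loopturn: centrals are the first two loop residues
        centrals <- span[1:2]
        tstart <- span[1] - 1L
      }
      phi[centrals] <- canon[c("phi1", "phi2")]
      psi[centrals] <- canon[c("psi1", "psi2")]
      truth_turns[[length(truth_turns) + 1L]] <- data.frame(
        start = tstart, type = lay$turn_type[k], stringsAsFactors = FALSE)
    }
    if (kind == "strand")
      truth_roles[[length(truth_roles) + 1L]] <- data.frame(
        start = span[1], end = span[length(span)], call = lay$role[k],
        stringsAsFactors = FALSE)
    if (lay$disordered[k]) disordered[span] <- TRUE
  }

  # observed shifts = reference + mean secondary shift + noise
  recs <- list()
  for (i in seq_len(n)) {
    aa <- sq[i]
    for (a in c("H", "HA", "CA", "CB", "C", "N")) {
      if (a == "CB" && aa == "G") next
      if (a == "H" && aa == "P") next
      d <- if (a %in% CSI_NUCLEI) delta_mean[i, a] else 0
      val <- rc[aa, a] + d + stats::rnorm(1, 0, model$noise_sd[[a]])
      val <- round(val, 3)
      if (a == "HA" && aa == "G") {
        recs[[length(recs) + 1L]] <- data.frame(residue = i, atom = "HA2",
                                                value = val)
        recs[[length(recs) + 1L]] <- data.frame(residue = i, atom = "HA3",
                                                value = val)
      } else {
        recs[[length(recs) + 1L]] <- data.frame(residue = i, atom = a,
                                                value = val)
      }
    }
  }
  shifts <- do.call(rbind, recs)
  shifts <- shifts[order(shifts$residue, shifts$atom), ]
  rownames(shifts) <- NULL
  sequence <- paste(sq, collapse = "")
  ds <- structure(
    list(chain_id = "SYN", sequence = sequence, n = n, shifts = shifts,
         source_format = "synthetic",
         author_numbering = data.frame(residue = seq_len(n),
                                       author_seq = seq_len(n)),
         n_records = nrow(shifts), n_rejected = 0L),
    class = "shift_dataset")

  phi <- round(wrap_angle(phi + stats::rnorm(n, 0, model$angle_noise_sd)), 3)
  psi <- round(wrap_angle(psi + stats::rnorm(n, 0, model$angle_noise_sd)), 3)
  tt_full <- data.frame(residue = seq_len(n), phi = phi, psi = psi,
                        class = ifelse(disordered, "None", "Strong"),
                        stringsAsFactors = FALSE)
  tt <- tt_full[tt_full$class != "None", , drop = FALSE]
  rownames(tt) <- NULL
  class(tt) <- c("torsion_table", "data.frame")
  attr(tt, "n_dropped") <- sum(disordered)

  prof <- secondary_shifts(ds, rc)
  o <- rci_s2(prof, cfg$rci)
  f <- fasa_estimate(prof, o, cfg$fasa_coef)

  truth_turns <- if (length(truth_turns)) do.call(rbind, truth_turns)
    else data.frame(start = integer(), type = character())
  for (nm in c("d1", "d2", "d3", "d4", "total"))
    truth_turns[[nm]] <- numeric(nrow(truth_turns))
  truth_turns <- truth_turns[, c("start", "type", "d1", "d2", "d3", "d4",
                                 "total")]
  roles <- if (length(truth_roles)) do.call(rbind, truth_roles)
    else data.frame(start = integer(), end = integer(), call = character())
  truth <- build_truth_annotation(state, truth_turns, roles, sequence, cfg)

  list(dataset = ds, torsions = tt, order = o, fasa = f, truth = truth,
       layout = lay, disordered = disordered)
}

# ground-truth hairpins follow from the truth layout by the definition:
# consecutive strands, loop of <= hairpin_max_loop residues, a declared turn
# with its central pair wholly inside the loop
build_truth_annotation <- function(state, turns, roles, sequence, cfg) {
  n <- nchar(sequence)
  strands <- state_runs(state, "B")
  hp <- list()
  if (nrow(strands) >= 2 && nrow(turns)) {
    for (k in seq_len(nrow(strands) - 1L)) {
      loop_start <- strands$end[k] + 1L
      loop_end <- strands$start[k + 1L] - 1L
      len <- loop_end - loop_start + 1L
      if (len < 1L || len > cfg$hairpin_max_loop) next
      inloop <- turns$type %in% cfg$hairpin_turn_types &
        (turns$start + 1L) >= loop_start & (turns$start + 2L) <= loop_end
      if (!any(inloop)) next
      best <- turns[which(inloop)[1], ]
      hp[[length(hp) + 1L]] <- data.frame(
        strand1_start = strands$start[k], strand1_end = strands$end[k],
        loop_start = loop_start, loop_end = loop_end,
        strand2_start = strands$start[k + 1L],
        strand2_end = strands$end[k + 1L],
        turn_start = best$start, turn_type = best$type,
        stringsAsFactors = FALSE)
    }
  }
  hairpins <- if (length(hp)) do.call(rbind, hp)
    else data.frame(strand1_start = integer(), strand1_end = integer(),
                    loop_start = integer(), loop_end = integer(),
                    strand2_start = integer(), strand2_end = integer(),
                    turn_start = integer(), turn_type = character())
  topo <- roles
  if (nrow(topo)) {
    topo$edge_score <- ifelse(topo$call == "edge", 7L, 0L)
    for (nm in c("ha_alternation", "high_avg_fasa", "exposed_majority",
                 "low_rigid_fraction", "hydropathy_periodicity",
                 "charge_pattern", "short_strand"))
      topo[[nm]] <- topo$call == "edge"
    topo <- topo[, c("start", "end", "ha_alternation", "high_avg_fasa",
                     "exposed_majority", "low_rigid_fraction",
                     "hydropathy_periodicity", "charge_pattern",
                     "short_strand", "edge_score", "call")]
  } else {
    topo <- data.frame(start = integer(), end = integer(),
                       ha_alternation = logical(), high_avg_fasa = logical(),
                       exposed_majority = logical(),
                       low_rigid_fraction = logical(),
                       hydropathy_periodicity = logical(),
                       charge_pattern = logical(), short_strand = logical(),
                       edge_score = integer(), call = character())
  }
  merge_annotation(state, turns, hairpins, topo, sequence)
}

#' Recovery rates under increasing noise
#'
#' Re-generates the declared topology at each noise scale, runs the full
#' pipeline and scores the result against the ground truth. Recovery is the
#' Qn score / 100 for the 3-state, turn, hairpin and strand-topology
#' classes.
#'
#' @param spec A [topology_spec()].
#' @param model Base [generator_model()] (its sds are multiplied by each
#'   value of `sds`).
#' @param sds Numeric vector of noise scale multipliers.
#' @param reps Replicates per noise level.
#' @param seed Integer seed for the replicate streams.
#' @param cfg An [ssa_config()].
#' @return Data frame: `noise_scale`, mean recovery per class over reps.
#' @export
noise_sweep <- function(spec, model = generator_model(), sds = c(0, 1, 3, 10),
                        reps = 10, seed = 1L, cfg = ssa_config()) {
  stopifnot(reps >= 1)
  out <- list()
  for (li in seq_along(sds)) {
    m <- generator_model(noise_scale = sds[li] * model$noise_scale)
    acc <- matrix(0, reps, 4,
                  dimnames = list(NULL, c("three_state", "turn", "hairpin",
                                          "topology")))
    for (r in seq_len(reps)) {
      rep_seed <- (spec$seed + 7919L * li + r) %% .Machine$integer.max
      sp <- topology_spec(spec$elements, seed = rep_seed)
      sim <- generate_protein(sp, m, cfg)
      ann <- annotate_dataset(sim$dataset, sim$torsions, cfg)
      q <- evaluate_annotation(ann, sim$truth)
      acc[r, ] <- c(q$q3, q$q6_turn, q$q2_hairpin, q$q3_topology) / 100
    }
    out[[li]] <- data.frame(noise_scale = sds[li],
                            t(colMeans(acc)))
  }
  do.call(rbind, out)
}
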