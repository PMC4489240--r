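# Fixture builders and independent oracles. Oracles are deliberately
# written as plain loops, independent of the package's code paths.

TURN_TYPES_ALL <- c("I", "II", "I'", "II'", "VIII")

make_profile <- function(delta, sequence) {
  atoms <- c("H", "HA", "CA", "CB", "C", "N")
  m <- matrix(NA_real_, nrow(delta), length(atoms),
              dimnames = list(NULL, atoms))
  m[, colnames(delta)] <- delta
  structure(list(delta = m, sequence = sequence, n = nrow(delta)),
            class = "secondary_shifts")
}

make_order <- function(s2) {
  structure(list(s2 = s2, method_params = ssa_config()$rci, n = length(s2)),
            class = "order_profile")
}

make_fasa <- function(fa) {
  structure(list(fasa = fa, n = length(fa)), class = "fasa_profile")
}

# shift_dataset with every expected backbone shift at its random-coil value,
# minus an optional list of (residue, atom) omissions
full_obs_dataset <- function(sequence, drop = list()) {
  rc <- random_coil_table()
  sq <- strsplit(sequence, "")[[1]]
  recs <- list()
  for (i in seq_along(sq)) {
    aa <- sq[i]
    for (a in c("H", "HA", "CA", "CB", "C", "N")) {
      if (a == "CB" && aa == "G") next
      if (a == "H" && aa == "P") next
      dropped <- any(vapply(drop, function(d)
        d[[1]] == i && d[[2]] == a, TRUE))
      if (dropped) next
      if (a == "HA" && aa == "G") {
        recs[[length(recs) + 1L]] <- data.frame(residue = i, atom = "HA2",
                                                value = rc[aa, "HA"])
        recs[[length(recs) + 1L]] <- data.frame(residue = i, atom = "HA3",
                                                value = rc[aa, "HA"])
      } else {
        recs[[length(recs) + 1L]] <- data.frame(residue = i, atom = a,
                                                value = rc[aa, a])
      }
    }
  }
  shifts <- do.call(rbind, recs)
  shifts <- shifts[order(shifts$residue, shifts$atom), ]
  rownames(shifts) <- NULL
  structure(
    list(chain_id = "A", sequence = sequence, n = length(sq),
         shifts = shifts, source_format = "synthetic",
         author_numbering = data.frame(residue = seq_along(sq),
                                       author_seq = seq_along(sq)),
         n_records = nrow(shifts), n_rejected = 0L),
    class = "shift_dataset")
}

# randomized topology for closed-loop tests: structured elements always
# separated by short ordered coil
rand_spec <- function(seed) {
  set.seed(seed)
  els <- list(el_coil(sample(2:4, 1)))
  for (k in seq_len(sample(2:5, 1))) {
    kind <- sample(c("helix", "strand_i", "strand_e", "turn", "hairpin"), 1)
    els[[length(els) + 1L]] <- switch(kind,
      helix = el_helix(sample(4:9, 1)),
      strand_i = el_strand(sample(5:8, 1), "interior"),
      strand_e = el_strand(sample(3:6, 1), "edge"),
      turn = el_turn(sample(TURN_TYPES_ALL, 1)),
      hairpin = {
        roles <- sample(c("edge", "interior"), 2, replace = TRUE)
        len <- function(role) if (role == "interior") sample(5:7, 1)
                              else sample(3:6, 1)
        el_hairpin(len(roles[1]), sample(2:6, 1), len(roles[2]),
                   sample(TURN_TYPES_ALL, 1), roles)
      })
    els[[length(els) + 1L]] <- el_coil(sample(2:4, 1))
  }
  topology_spec(els, seed = seed)
}

# --- independent oracles -----------------------------------------------------

# run-length 3-state assignment by direct scan
oracle_sse <- function(cons, min_h = 4, min_b = 3) {
  n <- length(cons)
  out <- rep("C", n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && cons[j + 1L] == cons[i]) j <- j + 1L
    len <- j - i + 1L
    if (cons[i] == -1L && len >= min_h) out[i:j] <- "H"
    if (cons[i] == 1L && len >= min_b) out[i:j] <- "B"
    i <- j + 1L
  }
  out
}

# brute-force edge score from raw per-residue vectors
oracle_edge_score <- function(dha, fasa, s2, sq, cfg = ssa_config()) {
  L <- length(sq)
  alt <- avail <- 0
  for (k in 1:(L - 1)) {
    if (!is.na(dha[k]) && !is.na(dha[k + 1])) {
      avail <- avail + 1
      if (sign(dha[k]) * sign(dha[k + 1]) == -1) alt <- alt + 1
    }
  }
  c1 <- avail > 0 && alt / avail >= cfg$ha_alternation_frac
  c2 <- mean(fasa) > cfg$fasa_edge_avg
  c3 <- sum(fasa > cfg$fasa_exposed) / L > cfg$exposed_majority
  rigid <- 0
  for (k in 1:L) if (!is.na(s2[k]) && s2[k] > cfg$s2_rigid) rigid <- rigid + 1
  c4 <- rigid / L < cfg$rigid_frac_max
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  phob <- kd[sq] > 0
  flips <- 0
  for (k in 1:(L - 1)) if (phob[k] != phob[k + 1]) flips <- flips + 1
  c5 <- flips / (L - 1) >= cfg$hydropathy_frac
  chg <- sq %in% c("D", "E", "K", "R", "H")
  lo <- floor(L / 3) + 1
  hi <- L - floor(L / 3)
  c6 <- sum(chg) / L >= cfg$charge_frac || any(chg[lo:hi])
  c7 <- L < cfg$short_strand_len
  sum(c(c1, c2, c3, c4, c5, c6, c7))
}

# exhaustive turn selection: among all maximal non-overlapping candidate
# subsets, the one whose sorted (total, start) key is lexicographically least
oracle_select_turns <- function(cand) {
  n <- nrow(cand)
  if (!n) return(cand)
  overlap <- function(a, b)
    length(intersect(cand$start[a] + 1:2, cand$start[b] + 1:2)) > 0
  subsets <- list()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(idx) > 1)
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b && overlap(idx[a], idx[b])) ok <- FALSE
    if (!ok) next
    maximal <- TRUE
    for (extra in setdiff(seq_len(n), idx))
      if (!any(vapply(idx, function(a) overlap(a, extra), TRUE)))
        maximal <- FALSE
    if (maximal) subsets[[length(subsets) + 1L]] <- idx
  }
  key <- function(idx) {
    o <- idx[order(cand$total[idx], cand$start[idx])]
    as.vector(rbind(cand$total[o], cand$start[o]))
  }
  best <- subsets[[1]]
  for (s in subsets[-1]) {
    ka <- key(s); kb <- key(best)
    len <- min(length(ka), length(kb))
    cmp <- 0
    for (j in seq_len(len)) {
      if (ka[j] < kb[j]) { cmp <- -1; break }
      if (ka[j] > kb[j]) { cmp <- 1; break }
    }
    if (cmp == -1) best <- s
  }
  out <- cand[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

shifty_3res <- c(
  "#NUM AA HA CA CB CO N HN",
  "1 A 4.12 54.20 18.80 179.40 122.00 8.10",
  "2 G 3.95 46.10 . 175.00 109.00 8.35",
  "3 V 4.00 64.10 31.00 177.10 120.00 8.20"
)

star3_gly <- c(
  "data_test", "save_shifts", "   loop_",
  "      _Atom_chem_shift.ID",
  "      _Atom_chem_shift.Seq_ID",
  "      _Atom_chem_shift.Comp_ID",
  "      _Atom_chem_shift.Atom_ID",
  "      _Atom_chem_shift.Val",
  "      1 1 ALA HA 4.20",
  "      2 1 ALA CA 52.80",
  "      3 2 GLY HA2 3.80",
  "      4 2 GLY HA3 4.00",
  "      5 2 GLY CA 45.20",
  "      6 3 VAL HA 4.05",
  "      7 3 VAL CA 62.00",
  "   stop_", "save_"
)
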