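# Contextual assignment: turn typing, turn selection, hairpins, edge
# criteria and the annotation merge invariants.

cfg0 <- ssa_config()
canon <- canonical_turn_angles()

test_that("angular deviation is the minimal circle distance", {
  expect_equal(angular_deviation(-170, 175), 15)
  expect_equal(angular_deviation(42, 42), 0)
  expect_equal(angular_deviation(-60, 60), 120)
  expect_equal(angular_deviation(179, -179), 2)
})

test_that("turn classification applies the 30/45 rule inclusively", {
  ti <- canon["I", ]
  exact <- classify_turn(ti[1], ti[2], ti[3], ti[4], cfg0)
  expect_identical(exact$type, "I")
  expect_equal(exact$deviations, c(0, 0, 0, 0))
  # one angle off by 44 (<= 45): still type I
  off44 <- classify_turn(ti[1], ti[2], ti[3], ti[4] + 44, cfg0)
  expect_identical(off44$type, "I")
  # two angles off by 31: only 2 of 4 within 30, no match anywhere
  off31 <- classify_turn(ti[1] + 31, ti[2] + 31, ti[3], ti[4], cfg0)
  expect_true(is.na(off31$type))
})

test_that("turn windows are gated by coil state, S2 and torsion presence", {
  ss <- rep("C", 6)
  tt <- data.frame(residue = 1:6, phi = c(-120, canon["I", "phi1"],
                                          canon["I", "phi2"], -120, -120, -120),
                   psi = c(140, canon["I", "psi1"], canon["I", "psi2"],
                           140, 140, 140))
  # S2 exactly at the 0.7 gate: excluded (strictly-greater rule)
  o_gate <- make_order(c(1, 0.7, 0.7, 1, 1, 1))
  expect_identical(nrow(find_turns(ss, o_gate, tt, cfg0)), 0L)
  o_ok <- make_order(rep(0.85, 6))
  found <- find_turns(ss, o_ok, tt, cfg0)
  expect_identical(found$start, 1L)
  expect_identical(found$type, "I")
  # single-coil region: no window has two consecutive coil centrals
  ss2 <- c("H", "H", "C", "H", "H", "H")
  expect_identical(nrow(find_turns(ss2, o_ok, tt, cfg0)), 0L)
  # missing torsions skip the window (drop both canonical centrals)
  expect_identical(nrow(find_turns(ss, o_ok, tt[-c(2, 3), ], cfg0)), 0L)
})

test_that("overlapping candidates resolve to the smaller total deviation", {
  ss <- rep("C", 6)
  o <- make_order(rep(0.9, 6))
  # window 1 (centrals 2,3): type I, total deviation 20; window 2 (centrals
  # 3,4): type I, total 60; they share residue 3, so only the better window
  # survives the greedy selection
  tt <- data.frame(
    residue = 1:6,
    phi = c(-120, canon["I", "phi1"] + 5, canon["I", "phi2"] + 5,
            canon["I", "phi2"], 60, -120),
    psi = c(140, canon["I", "psi1"] + 5, canon["I", "psi2"] + 5,
            canon["I", "psi2"], 60, 140))
  found <- find_turns(ss, o, tt, cfg0)
  cand <- attr(found, "candidates")
  expect_identical(sort(cand$start), c(1L, 2L))
  expect_identical(nrow(found), 1L)
  expect_identical(found$start, 1L)
  expect_equal(found$total, 20)
})

test_that("greedy turn selection equals the exhaustive-subset oracle", {
  set.seed(901)
  for (rep in 1:40) {
    k <- sample(1:8, 1)
    cand <- data.frame(start = sample(1:15, k),
                       type = sample(TURN_TYPES_ALL, k, replace = TRUE),
                       total = round(stats::runif(k, 0, 90), 1))
    cand$d1 <- cand$d2 <- cand$d3 <- cand$d4 <- cand$total / 4
    cand <- cand[, c("start", "type", "d1", "d2", "d3", "d4", "total")]
    got <- nmrsecstr:::greedy_select_turns(cand)
    want <- oracle_select_turns(cand)
    want <- want[order(want$start), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got$start, want$start)
    expect_equal(got$total, want$total)
  }
})

test_that("turn mirror symmetry: negation swaps I<->I' and II<->II'", {
  set.seed(902)
  mirror <- c(I = "I'", "I'" = "I", II = "II'", "II'" = "II")
  for (ty in c("I", "I'", "II", "II'")) {
    for (rep in 1:25) {
      a <- canon[ty, ] + stats::runif(4, -28, 28)
      r1 <- classify_turn(a[1], a[2], a[3], a[4], cfg0)
      r2 <- classify_turn(-a[1], -a[2], -a[3], -a[4], cfg0)
      expect_identical(r1$type, ty)
      expect_identical(r2$type, unname(mirror[ty]))
      expect_equal(r1$total, r2$total)
    }
  }
})

test_that("hairpins require a short loop containing a selected turn", {
  turns <- data.frame(start = 7L, type = "I'", d1 = 0, d2 = 0, d3 = 0,
                      d4 = 0, total = 0)
  ss_ok <- c(rep("B", 6), rep("C", 4), rep("B", 5))  # strands 1-6 / 11-15
  hp <- detect_hairpins(ss_ok, turns, cfg0)          # centrals 8,9 in loop 7-10
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$turn_type, "I'")
  expect_identical(hp$loop_start, 7L)
  # loop of length 7: rejected even with a valid turn inside
  ss_long <- c(rep("B", 6), rep("C", 7), rep("B", 5))
  expect_identical(nrow(detect_hairpins(ss_long, turns, cfg0)), 0L)
  # loop without any selected turn: no hairpin
  no_turns <- turns[0, ]
  expect_identical(nrow(detect_hairpins(ss_ok, no_turns, cfg0)), 0L)
})

test_that("HA alternation requires sign flips over enough pairs", {
  mk <- function(dha) {
    delta <- matrix(NA_real_, length(dha), 4,
                    dimnames = list(NULL, c("HA", "CA", "CB", "C")))
    delta[, "HA"] <- dha
    make_profile(delta, paste(rep("V", length(dha)), collapse = ""))
  }
  expect_true(ha_alternation(1:4, mk(c(0.3, -0.2, 0.4, -0.1))))
  expect_false(ha_alternation(1:4, mk(c(0.3, 0.2, 0.4, 0.1))))
  # 2 of 3 pairs alternate: below the 0.7 cutoff
  expect_false(ha_alternation(1:4, mk(c(0.3, -0.2, 0.4, 0.1))))
  # missing HA makes pairs unavailable rather than broken
  expect_true(ha_alternation(1:4, mk(c(0.3, -0.2, NA, NA))))
})

test_that("hydropathy periodicity and charge pattern follow their rules", {
  expect_true(hydropathy_periodicity(c("V", "K", "L", "E", "I")))
  expect_false(hydropathy_periodicity(c("V", "L", "I", "A", "F")))
  expect_false(hydropathy_periodicity(c("V", "K", "L", "L", "I")))  # 2/4
  expect_true(charge_pattern(c("A", "A", "K", "A", "A", "A")))  # central K
  expect_false(charge_pattern(c("A", "V", "L", "I", "A", "V")))
  # 8 residues, D/E at the termini only: proportion clause (2/8 = 0.25)
  expect_true(charge_pattern(c("D", "A", "V", "L", "I", "A", "V", "E")))
})

test_that("edge criteria threshold boundaries are strict as printed", {
  mkp <- function(n) make_profile(
    matrix(0.2, n, 4, dimnames = list(NULL, c("HA", "CA", "CB", "C"))),
    paste(rep("V", n), collapse = ""))
  n <- 5
  p <- mkp(n)
  o <- make_order(rep(0.5, n))
  sq <- paste(rep("V", n), collapse = "")
  tp <- function(fasa) edge_criteria(1:n, p, o, make_fasa(rep(fasa, n)),
                                     sq, cfg0)
  expect_false(tp(0.30)$high_avg_fasa)   # average 0.30 is not > 0.3
  expect_true(tp(0.31)$high_avg_fasa)
  # strand length boundary: < 5 residues is short
  p4 <- mkp(4)
  short <- edge_criteria(1:4, p4, make_order(rep(0.5, 4)),
                         make_fasa(rep(0.1, 4)), "VVVV", cfg0)
  expect_true(short$short_strand)
  expect_false(tp(0.1)$short_strand)
})

test_that("edge call fires at score 5, not 4", {
  # alternating HA, exposed, flexible, short: 5 criteria -> edge
  delta <- matrix(0, 4, 4, dimnames = list(NULL, c("HA", "CA", "CB", "C")))
  delta[, "HA"] <- c(0.3, -0.3, 0.3, -0.3)
  p <- make_profile(delta, "VVVV")
  o_flex <- make_order(rep(0.5, 4))
  f_exp <- make_fasa(rep(0.5, 4))
  five <- edge_criteria(1:4, p, o_flex, f_exp, "VVVV", cfg0)
  expect_identical(five$edge_score, 5L)
  expect_identical(five$call, "edge")
  # same strand but rigid: 4 criteria -> interior
  o_rigid <- make_order(rep(0.95, 4))
  four <- edge_criteria(1:4, p, o_rigid, f_exp, "VVVV", cfg0)
  expect_identical(four$edge_score, 4L)
  expect_identical(four$call, "interior")
})

test_that("merge_annotation enforces the class partition", {
  ss <- c("H", "H", "H", "H", "C", "C")
  no_turns <- data.frame(start = integer(), type = character(),
                         d1 = numeric(), d2 = numeric(), d3 = numeric(),
                         d4 = numeric(), total = numeric())
  no_hp <- detect_hairpins(ss, no_turns, cfg0)
  topo <- nmrsecstr:::strand_topologies(
    ss, make_profile(matrix(0, 6, 4,
                            dimnames = list(NULL, c("HA", "CA", "CB", "C"))),
                     "AAAAAA"),
    make_order(rep(0.8, 6)), make_fasa(rep(0.2, 6)), "AAAAAA", cfg0)
  ann <- merge_annotation(ss, no_turns, no_hp, topo, "AAAAAA")
  expect_identical(nrow(ann$strands), 0L)
  # a turn whose central residues sit in a helix is an internal error
  bad_turn <- data.frame(start = 1L, type = "I", d1 = 0, d2 = 0, d3 = 0,
                         d4 = 0, total = 0)
  expect_error(merge_annotation(ss, bad_turn, no_hp, topo, "AAAAAA"),
               "internal inconsistency")
})
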