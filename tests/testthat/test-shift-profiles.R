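# CSI stage: secondary shifts, ternary filter, consensus vote, 3-state
# assignment.

test_that("secondary shifts subtract the residue-specific reference", {
  rc <- random_coil_table()
  ds <- full_obs_dataset("AG")
  # overwrite alanine CA and glycine HA2/HA3 with chosen observations
  ds$shifts$value[ds$shifts$residue == 1 & ds$shifts$atom == "CA"] <- 58.2
  ds$shifts$value[ds$shifts$residue == 2 & ds$shifts$atom == "HA2"] <- 3.8
  ds$shifts$value[ds$shifts$residue == 2 & ds$shifts$atom == "HA3"] <- 4.0
  p <- secondary_shifts(ds)
  expect_equal(unname(p$delta[1, "CA"]), 58.2 - 52.5)  # rc(A, CA) = 52.5
  expect_equal(unname(p$delta[1, "C"]), 0)             # observed == reference
  # glycine HA = mean(HA2, HA3) = 3.90; rc(G, HA) = 3.96
  expect_equal(unname(p$delta[2, "HA"]), -0.06)
})

test_that("ternary filter thresholds are strict and missing gives 0", {
  delta <- cbind(HA = c(0.25, 0, NA, -0.15), CA = c(0.3, 0, -0.69, -0.71),
                 CB = c(NA, 0, 0.2, 0.9), C = c(0.6, 0, 0.1, -0.51))
  ci <- csi_filter(make_profile(delta, "AAAA"))
  expect_identical(unname(ci$index[1, ]), c(1L, 0L, 0L, 1L))
  expect_identical(unname(ci$index[2, ]), c(0L, 0L, 0L, 0L))
  # CA delta -0.69 vs cutoff 0.7: inside the band, index 0
  expect_identical(unname(ci$index[3, ]), c(0L, 0L, 0L, 0L))
  expect_identical(unname(ci$index[4, ]), c(-1L, -1L, 1L, -1L))
})

test_that("ternary filter is odd under delta negation", {
  set.seed(402)
  for (rep in 1:20) {
    delta <- matrix(stats::rnorm(40, 0, 1), 10, 4,
                    dimnames = list(NULL, c("HA", "CA", "CB", "C")))
    delta[sample(40, 5)] <- NA
    sq <- paste(rep("A", 10), collapse = "")
    a <- csi_filter(make_profile(delta, sq))$index
    b <- csi_filter(make_profile(-delta, sq))$index
    expect_identical(b, -a)
  }
})

test_that("consensus harmonizes nucleus signs and breaks ties to 0", {
  mk <- function(ha, ca, cb, co) {
    structure(list(index = cbind(HA = ha, CA = ca, CB = cb, C = co),
                   thresholds = csi_thresholds(), n = length(ha)),
              class = "csi_index")
  }
  # HA +1, CB +1 and CA -1 are all strand-consistent after harmonization
  expect_identical(consensus_index(mk(1L, -1L, 1L, 0L)), 1L)
  # single nucleus, index 0
  expect_identical(consensus_index(mk(0L, 0L, 0L, 0L)), 0L)
  # HA +1 (strand) vs CA +1 (helix after harmonization): tie
  expect_identical(consensus_index(mk(1L, 1L, 0L, 0L)), 0L)
  # downfield CA/C vote helix
  expect_identical(consensus_index(mk(0L, 1L, 0L, 1L)), -1L)
})

test_that("3-state assignment enforces minimum run lengths", {
  # beta-bridges of two or fewer residues become coil
  expect_identical(assign_sse(c(1L, 1L)), c("C", "C"))
  expect_identical(assign_sse(rep(0L, 5)), rep("C", 5))
  expect_identical(assign_sse(rep(-1L, 5)), rep("H", 5))
  expect_identical(assign_sse(c(0L, -1L, -1L, -1L, 0L)), rep("C", 5))
})

test_that("3-state assignment matches the run-length oracle", {
  set.seed(77)
  for (rep in 1:50) {
    cons <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
    got <- assign_sse(cons)
    expect_identical(got, oracle_sse(cons))
    r <- rle(got)
    expect_true(all(r$lengths[r$values == "B"] >= 3))
    expect_true(all(r$lengths[r$values == "H"] >= 4))
  }
})

test_that("index TSV writer emits the bar-graph columns", {
  sim <- generate_protein(topology_spec(list(el_helix(6)), seed = 2),
                          generator_model(noise_scale = 0))
  ci <- csi_filter(secondary_shifts(sim$dataset))
  df <- write_index_tsv(ci)
  expect_named(df, c("residue", "HA", "CA", "CB", "C", "consensus"))
  expect_identical(df$consensus, rep(-1L, 6))
})
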