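# I/O module: dialect detection, parsing, writers, torsion tables,
# completeness accounting.

test_that("detect_format recognizes the three dialects by signature", {
  expect_identical(detect_format(star3_gly), "nmrstar3")
  star2 <- c("data_x", "   loop_", "      _Residue_seq_code",
             "      _Residue_label", "      _Atom_name",
             "      _Chem_shift_value", "      1 ALA HA 4.2", "   stop_")
  expect_identical(detect_format(star2), "nmrstar2")
  expect_identical(detect_format(shifty_3res), "shifty")
  expect_error(detect_format("random prose, no shifts"),
               class = "nmrsecstr_parse_error")
})

test_that("SHIFTY parsing maps synonym columns and counts entries", {
  ds <- parse_shifts(shifty_3res, "shifty")
  expect_identical(ds$sequence, "AGV")
  # 3 residues x 6 columns, one "." missing (G CB) => 17 stored shifts
  expect_identical(nrow(ds$shifts), 17L)
  # CO -> C and HN -> H synonym mapping
  expect_setdiff <- setdiff(unique(ds$shifts$atom),
                            c("H", "HA", "CA", "CB", "C", "N"))
  expect_length(expect_setdiff, 0)
  expect_equal(ds$shifts$value[ds$shifts$residue == 1 &
                               ds$shifts$atom == "C"], 179.40)
})

test_that("NMR-STAR 3.1 glycine keeps HA2/HA3 separate, never HA", {
  ds <- parse_shifts(star3_gly, "nmrstar3")
  g_atoms <- ds$shifts$atom[ds$shifts$residue == 2]
  expect_true(all(c("HA2", "HA3") %in% g_atoms))
  expect_false("HA" %in% g_atoms)
  expect_identical(ds$sequence, "AGV")
})

test_that("the same protein round-trips identically through all dialects", {
  sim <- generate_protein(rand_spec(11), generator_model(noise_scale = 0))
  for (dialect in c("shifty", "nmrstar2", "nmrstar3")) {
    ds2 <- parse_shifts(write_shifts(sim$dataset, dialect = dialect))
    expect_identical(ds2$sequence, sim$dataset$sequence)
    expect_equal(ds2$shifts, sim$dataset$shifts, tolerance = 1e-9)
    expect_identical(ds2$source_format, dialect)
    # conservation: every in-file record is stored or reported rejected
    expect_identical(ds2$n_records, nrow(ds2$shifts) + ds2$n_rejected)
  }
})

test_that("malformed records are rejected with parse errors", {
  dup <- c("#NUM AA HA CA", "1 A 4.2 52.0", "1 A 4.3 52.1")
  expect_error(parse_shifts(dup, "shifty"), class = "nmrsecstr_parse_error")
  ha2_non_gly <- c("#NUM AA HA2 CA", "1 A 4.2 52.0")
  expect_error(parse_shifts(ha2_non_gly, "shifty"),
               regexp = "HA2", class = "nmrsecstr_parse_error")
  badval <- c("#NUM AA HA", "1 A fourpointtwo")
  expect_error(parse_shifts(badval, "shifty"),
               class = "nmrsecstr_parse_error")
  conflict <- c("#NUM AA HA", "1 A 4.2", "1 V 4.1")
  expect_error(parse_shifts(conflict, "shifty"),
               regexp = "conflicting", class = "nmrsecstr_parse_error")
})

test_that("unknown atoms are dropped with a warning, never silently", {
  txt <- c("#NUM AA HA CG2", "1 T 4.35 21.0", "2 A 4.32 .")
  expect_warning(ds <- parse_shifts(txt, "shifty"), "CG2")
  expect_identical(nrow(ds$shifts), 2L)
  expect_identical(ds$n_rejected, 1L)
  expect_identical(ds$n_records, 3L)
})

test_that("torsion tables parse, drop None rows, and wrap angles", {
  txt <- c("DATA FIRST_RESID 1",
           "VARS RESID RESNAME PHI PSI DPHI DPSI DIST S2 COUNT CS_COUNT CLASS",
           "FORMAT %4d %s %9.3f %9.3f %9.3f %9.3f %9.3f %6.3f %3d %3d %s",
           "  5 A  -63.000  -42.000 10 10 0 0.85 25 6 Strong",
           "  6 A  181.000  150.000 10 10 0 0.85 25 6 Strong",
           "  7 A 9999.000 9999.000 10 10 0 0.00 25 6 None")
  tt <- parse_torsion_table(txt)
  expect_identical(tt$residue, c(5L, 6L))
  expect_equal(tt$phi, c(-63, -179))
  expect_identical(attr(tt, "n_dropped"), 1L)
  expect_equal(torsion_coverage(tt, 10), 0.2)
  expect_error(parse_torsion_table("5 A abc -42.0 x"),
               class = "nmrsecstr_parse_error")
})

test_that("torsion tables round-trip through the writer", {
  tt <- parse_torsion_table(
    c("VARS RESID RESNAME PHI PSI CLASS",
      "1 V -120.000 135.000 Strong", "2 K -60.000 -30.000 Strong"))
  tt2 <- parse_torsion_table(write_torsion_table(tt, "VK"))
  expect_equal(tt2$residue, tt$residue)
  expect_equal(tt2$phi, tt$phi)
  expect_equal(tt2$psi, tt$psi)
})

test_that("completeness counts the expected backbone set", {
  ds <- full_obs_dataset("AVKLEIMFST")
  cr <- completeness(ds)
  expect_equal(cr$overall_pct, 100)

  ds_no_n <- full_obs_dataset("AVKLEIMFST",
                              drop = lapply(1:10, function(i) list(i, "N")))
  cr2 <- completeness(ds_no_n)
  expect_equal(unname(cr2$per_atom_pct["N"]), 0)
  expect_equal(unname(cr2$per_atom_pct["CA"]), 100)

  # 60 expected shifts (no G/P in sequence), 3 dropped => 95%
  ds95 <- full_obs_dataset("AVKLEIMFST",
                           drop = list(list(2, "N"), list(5, "CB"),
                                       list(9, "H")))
  expect_equal(completeness(ds95)$overall_pct, 95)

  # glycine: HA2/HA3 jointly satisfy HA, CB not expected; proline: no H
  ds_gp <- full_obs_dataset("AGPV")
  expect_equal(completeness(ds_gp)$overall_pct, 100)
})
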