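test_that("desalt keeps the largest fragment and records the rest", {
  r <- desalt("CC(=O)[O-].[Na+]")
  expect_equal(r$canonical_smiles, canonical_smiles_of("CC(=O)[O-]"))
  expect_true(r$was_desalted)
  expect_equal(r$removed_fragments, "[Na+]")

  r2 <- desalt("c1ccccc1")
  expect_false(r2$was_desalted)
  expect_length(r2$removed_fragments, 0)

  # equal-size tie: lexicographically smallest canonical SMILES wins
  r3 <- desalt("CCO.CCN")
  expect_equal(r3$canonical_smiles, "CCN")
  r4 <- desalt("CCO.OCC")
  expect_equal(r4$canonical_smiles, "CCO")

  expect_error(desalt(""), "empty")
})

test_that("neutralization removes protonation charges but not structural ones", {
  expect_equal(neutralize("CC(=O)[O-]")$canonical_smiles, "CC(=O)O")
  expect_equal(neutralize("CC[NH3+]")$canonical_smiles, "CCN")
  expect_equal(neutralize("[O-]c1ccccc1")$canonical_smiles, "Oc1ccccc1")
  expect_equal(neutralize("[S-]CC")$canonical_smiles, "CCS")
  # sulfonate and phosphate oxyanions
  expect_false(grepl("-", neutralize("CS(=O)(=O)[O-]")$canonical_smiles, fixed = TRUE))
  expect_false(grepl("-", neutralize("CCOP(=O)([O-])[O-]")$canonical_smiles, fixed = TRUE))
  # quaternary ammonium: charge is structural, must survive
  q <- neutralize("C[N+](C)(C)C")
  expect_false(q$was_neutralized)
  expect_true(grepl("N+", q$canonical_smiles, fixed = TRUE))
  # neutral input is identity
  b <- neutralize("c1ccccc1")
  expect_false(b$was_neutralized)
})

test_that("standardize_record composes desalt and neutralize and is idempotent", {
  r <- standardize_record("CC(=O)[O-].[Na+]")
  expect_equal(r$canonical_smiles, "CC(=O)O")
  expect_true(r$was_desalted)
  expect_true(r$was_neutralized)

  plain <- standardize_record("c1ccccc1")
  expect_false(plain$was_desalted || plain$was_neutralized)

  for (smi in c("CC(=O)[O-].[Na+]", "CC[NH3+].[Cl-]", "Cc1ccccc1",
                "C[N+](C)(C)C", "OCC.CCO.[Na+]")) {
    once <- standardize_record(smi)
    twice <- standardize_record(once$canonical_smiles)
    expect_equal(twice$canonical_smiles, once$canonical_smiles, label = smi)
    expect_false(twice$was_desalted)
  }
})

test_that("standardization never grows the structure and neutral outputs carry no charge", {
  set.seed(41)
  lib <- generate_library(synthetic_library_spec(n_molecules = 120,
                                                 salt_fraction = 0.5, seed = 11))
  std <- standardize_library(lib)
  expect_false(any(std$flag_parse_failed))
  hin <- scaffchron:::smiles_heavy_atoms(lib$smiles)
  hout <- scaffchron:::smiles_heavy_atoms(std$canonical_smiles)
  expect_true(all(hout <= hin))
  expect_true(all((hout == hin) == !std$was_desalted))
  # protonation-state charges are all removable for this generator
  expect_false(any(grepl("\\[[^]]*[+-]", std$canonical_smiles)))
})

test_that("vectorized standardization agrees with the per-record operation", {
  smi <- c("CC(=O)[O-].[Na+]", "c1ccccc1", "CC[NH3+]", "CCO.CCN")
  lib <- data.frame(id = paste0("m", seq_along(smi)), smiles = smi)
  std <- standardize_library(lib)
  for (i in seq_along(smi)) {
    expect_equal(std$canonical_smiles[i],
                 standardize_record(smi[i])$canonical_smiles)
  }
  # parse failures pass through flagged, others still standardized
  lib2 <- data.frame(id = c("a", "b"), smiles = c("xxx_bad", "CC(=O)[O-]"))
  std2 <- standardize_library(lib2)
  expect_true(std2$flag_parse_failed[1])
  expect_equal(std2$canonical_smiles[2], "CC(=O)O")
})
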