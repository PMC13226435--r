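test_that("decoration always round-trips to the parent scaffold", {
  set.seed(12)
  pool <- privileged_scaffolds()$smiles
  pool_can <- canonical_smiles_of(pool)
  draws <- 1000L
  idx <- sample(seq_along(pool), draws, replace = TRUE)
  mols <- vapply(idx, function(i) decorate_scaffold(pool[i]), "")
  sc <- extract_scaffolds(mols)$scaffold_smiles
  expect_equal(sc, pool_can[idx])
})

test_that("library generation is seed-deterministic and exactly sized", {
  spec <- synthetic_library_spec(n_molecules = 150, seed = 42)
  a <- generate_library(spec)
  b <- generate_library(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 150L)
  expect_false(any(duplicated(a$id)))
  expect_true(all(a$origin_year >= 1976 & a$origin_year <= 2024))
  c <- generate_library(synthetic_library_spec(n_molecules = 150, seed = 43))
  expect_false(identical(a$smiles, c$smiles))
  # caller RNG state untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_library(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(synthetic_library_spec(scaffold_pool = character(0)), "pool")
  expect_error(synthetic_library_spec(year_range = c(2020L, 2000L)), "year")
  expect_error(synthetic_library_spec(zipf_exponent = -1), "zipf")
})

test_that("zipf skew controls scaffold evenness in the expected direction", {
  # flat pool: SEE near 1
  flat <- generate_library(synthetic_library_spec(n_molecules = 5000,
                                                  zipf_exponent = 0, seed = 8))
  see_flat <- equitability(scaffold_counts(flat$scaffold_key))
  expect_gt(see_flat, 0.98)
  # rank-frequency order follows the pool order under strong skew
  skew <- generate_library(synthetic_library_spec(n_molecules = 10000,
                                                  zipf_exponent = 1.2, seed = 8))
  cnt <- scaffold_counts(skew$scaffold_key)$counts
  pool_can <- canonical_smiles_of(privileged_scaffolds()$smiles)
  expect_equal(names(cnt), pool_can)
  # paired seeds: stronger skew always lowers evenness at this separation
  for (s in 1:20) {
    z0 <- generate_library(synthetic_library_spec(2000, zipf_exponent = 0,
                                                  seed = s, max_substituents = 0L))
    z2 <- generate_library(synthetic_library_spec(2000, zipf_exponent = 2,
                                                  seed = s, max_substituents = 0L))
    expect_lt(equitability(scaffold_counts(z2$scaffold_key)),
              equitability(scaffold_counts(z0$scaffold_key)))
  }
})

test_that("salted records standardize back to their unsalted twin", {
  lib <- generate_library(synthetic_library_spec(n_molecules = 200,
                                                 salt_fraction = 1, seed = 3))
  std <- standardize_library(lib)
  expect_false(any(std$flag_parse_failed))
  expect_equal(std$canonical_smiles, canonical_smiles_of(lib$clean_smiles))
  expect_true(all(std$was_desalted))
})

test_that("origin years follow the geometric growth curve", {
  lib <- generate_library(synthetic_library_spec(n_molecules = 30000,
                                                 annual_growth = 0.1,
                                                 year_range = c(1990L, 2019L),
                                                 seed = 14, max_substituents = 0L))
  tab <- table(factor(lib$origin_year, levels = 1990:2019))
  # late-decade counts dwarf the first decade under g = 0.1
  expect_gt(sum(tab[21:30]), 5 * sum(tab[1:10]))
  g <- yoy_growth(as.integer(tab), series_is_cumulative = FALSE,
                  min_base = 50)
  expect_equal(g$mean, 10, tolerance = 2)
})
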