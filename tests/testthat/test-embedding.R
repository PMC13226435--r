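test_that("fingerprints are canonical-structure invariants with set bits", {
  spellings <- list(
    c("c1ccccc1", "C1=CC=CC=C1", "c1ccccc1"),
    c("O=C(Nc1ccccc1)c1ccccc1", "c1ccccc1NC(=O)c1ccccc1"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
    c("c1ccc2[nH]ccc2c1", "c1cc2cc[nH]c2cc1")
  )
  for (sp in spellings) {
    can <- canonical_smiles_of(sp)
    fps <- lapply(can, circular_fingerprint)
    for (i in seq_along(fps)[-1]) expect_identical(fps[[i]], fps[[1]])
    expect_gte(sum(fps[[1]]), 1)
  }
  # frameworks of benzene and cyclohexane coincide, hence identical bits
  f1 <- generic_framework("c1ccccc1")$canonical_smiles
  f2 <- generic_framework("C1CCCCC1")$canonical_smiles
  expect_identical(circular_fingerprint(f1), circular_fingerprint(f2))
})

test_that("fingerprints separate distinct local environments", {
  # unsubstituted rings larger than the fingerprint diameter are locally
  # indistinguishable (every atom sees the same circular environment) --
  # a known property of circular fingerprints
  bare <- fingerprint_matrix(c("C1CCCCC1", "C1CCCC1"))
  expect_identical(bare$bits[1, ], bare$bits[2, ])
  # a single substituent breaks the symmetry and ring sizes separate
  fp <- fingerprint_matrix(c("CC1CCCCC1", "CC1CCCC1", "C1CCC2CCCCC2C1",
                             "CCCCCC"))
  for (i in 1:3) for (j in seq_len(4)[-seq_len(i)]) {
    expect_false(identical(fp$bits[i, ], fp$bits[j, ]))
  }
  expect_equal(fp$n_bits, 2048L)
  expect_true(all(rowSums(fp$bits) >= 1))
})

test_that("the linear reduction is a well-behaved PCA", {
  fp <- fingerprint_matrix(rep(c("C1CCCCC1", "C1CCCC1", "C1CCCCCC1",
                                 "C1CCC2CCCCC2C1", "C1CC1"), each = 2))
  red <- suppressWarnings(reduce_dimensions(fp, n_components = 4))
  # duplicate inputs land on identical coordinates
  expect_equal(red$coords[1, ], red$coords[2, ])
  expect_true(all(diff(red$sdev) <= 1e-12))
  expect_warning(reduce_dimensions(fp, n_components = 50), "reducing")
  expect_error(reduce_dimensions(fp$bits[c(1, 1), ]), "distinct")
})

test_that("2D embedding is seeded, shape-preserving and size-preserving", {
  set.seed(1)
  x <- matrix(rnorm(40 * 5), 40)
  a <- embed_2d(x, perplexity = 5, seed = 42)
  b <- embed_2d(x, perplexity = 5, seed = 42)
  expect_identical(a, b)
  expect_equal(dim(a), c(40L, 2L))
  expect_false(identical(a, embed_2d(x, perplexity = 5, seed = 43)))
  expect_error(embed_2d(x, perplexity = 30, seed = 1), "perplexity")
  expect_error(embed_2d(x[1:2, ], perplexity = 1, seed = 1), "at least 3")
})

test_that("constructed framework families separate in the 2D map", {
  # three families with distinct local motifs: spiro bicyclics (a ring atom
  # of degree 4), fused bicyclics (adjacent ring atoms of degree 3) and
  # branched chains (no ring atoms at all, zero bit overlap with the others)
  fams <- list(
    c("C1CCC2(C1)CCCC2", "C1CCC2(C1)CCCCC2", "C1CCCC2(C1)CCCCC2",
      "C1CCC2(C1)CCCCCC2", "C1CCCC2(C1)CCCCCC2", "C1CCCCC2(C1)CCCCCC2",
      "C1CC2(C1)CCCC2"),
    c("C1CCC2CCCCC2C1", "C1CCC2CCCC2C1", "C1CC2CCCC2C1",
      "C1CCC2CCCCCC2C1", "C1CCCC2CCCCC2CC1", "C1CC2CCCCC2C1",
      "C1CCC2CCCCC2CC1"),
    c("CCCCCCCC", "CCC(C)CCCC", "CCCC(CC)CCC", "CC(C)CCCCC",
      "CCCCC(C)CC", "CCCCCCCCC", "CCC(CC)CCCC"))
  keys <- canonical_smiles_of(unlist(fams))
  labels <- rep(seq_along(fams), lengths(fams))
  fp <- fingerprint_matrix(keys)
  red <- suppressWarnings(reduce_dimensions(fp, n_components = 10))
  xy <- embed_2d(red$coords, perplexity = 5, seed = 17)
  expect_gt(mean_silhouette(xy, labels), 0)
  # majority of each point's 3 nearest neighbors share its family
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  agree <- vapply(seq_len(nrow(xy)), function(i) {
    nn <- order(d[i, ])[1:3]
    sum(labels[nn] == labels[i]) >= 2
  }, TRUE)
  expect_gt(mean(agree), 0.5)
})

test_that("era snapshots compose the pipeline, conserve weights and respect time", {
  set.seed(3)
  lib <- generate_library(synthetic_library_spec(n_molecules = 250, seed = 21,
                                                 year_range = c(1990L, 2020L)))
  fw <- generic_frameworks(lib$scaffold_key)
  rec <- data.frame(framework_key = fw$framework_smiles,
                    origin_year = lib$origin_year)
  snaps <- snapshot_series(rec, eras = c(2000L, 2020L), n_components = 5,
                           perplexity = 2, seed = 9, max_iter = 250)
  expect_named(snaps, c("2000", "2020"))
  for (era in names(snaps)) {
    s <- snaps[[era]]
    in_era <- rec$origin_year <= as.integer(era) & !is.na(rec$framework_key)
    expect_equal(sum(s$weights), sum(in_era))          # weight conservation
    expect_setequal(s$keys, unique(rec$framework_key[in_era]))
    expect_equal(nrow(s$coords), length(s$keys))
  }
  # frameworks absent before an era's end never appear in that era
  only_late <- setdiff(snaps[["2020"]]$keys, snaps[["2000"]]$keys)
  first_seen <- vapply(only_late, function(k) {
    min(rec$origin_year[rec$framework_key == k])
  }, 1)
  expect_true(all(first_seen > 2000))

  # single-era call equals the manual three-step pipeline
  s <- snaps[["2000"]]
  fpm <- fingerprint_matrix(s$keys)
  redm <- suppressWarnings(reduce_dimensions(fpm, n_components = 5))
  manual <- embed_2d(redm$coords, perplexity = s$params$perplexity, seed = 9,
                     max_iter = 250)
  expect_equal(unname(s$coords), unname(manual))

  # eras with too few frameworks are skipped with a warning
  expect_warning(
    none <- snapshot_series(rec[1:2, ], eras = 2020L, perplexity = 2, seed = 1),
    "skipped")
  expect_length(none, 0)
})
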