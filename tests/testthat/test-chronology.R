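test_that("origin year is the earliest citation year", {
  expect_equal(assign_origin_year(c(2007, 2004, 2010)), 2004L)
  expect_equal(assign_origin_year(numeric(0)), NA_integer_)
  expect_equal(assign_origin_year(1998), 1998L)
  expect_equal(assign_origin_year(c(NA, 2003)), 2003L)
  expect_error(assign_origin_year(c(2000.5)), "whole")
})

test_that("the chronicle tallies first appearances, gap years and diversity", {
  rec <- data.frame(origin_year = c(2000L, 2000L, 2002L),
                    scaffold_key = c("A", "B", "A"))
  ch <- build_chronicle(rec, window = c(2000L, 2002L))
  r <- ch$records
  expect_equal(r$year, 2000:2002)
  expect_equal(r$n_new_molecules, c(2L, 0L, 1L))     # 2001 materialized, zero
  expect_equal(r$cumulative_molecules, c(2L, 2L, 3L))
  expect_equal(r$n_new_scaffolds, c(2L, 0L, 0L))
  expect_equal(r$cumulative_scaffolds, c(2L, 2L, 2L))
  # SE at 2002 on cumulative table {A:2, B:1}
  expect_equal(r$se[3], shannon_entropy(c(A = 2, B = 1)))
  expect_equal(r$se[3], 0.9182958, tolerance = 1e-6)

  # single shared scaffold across two years
  one <- build_chronicle(data.frame(origin_year = c(2000L, 2001L),
                                    scaffold_key = c("S", "S")),
                         window = c(2000L, 2001L))
  expect_equal(one$records$cumulative_scaffolds, c(1L, 1L))
  expect_equal(one$records$n_new_scaffolds, c(1L, 0L))
  expect_equal(one$records$see, c(0, 0))      # single-scaffold convention
})

test_that("undated molecules are excluded but conserved in the bookkeeping", {
  rec <- data.frame(origin_year = c(2001L, NA, 2003L, NA),
                    scaffold_key = c("A", "B", "", "C"))
  ch <- build_chronicle(rec, window = c(2001L, 2003L))
  expect_equal(ch$n_undated, 2L)
  expect_equal(sum(ch$records$n_new_molecules) + ch$n_undated, nrow(rec))
  expect_equal(ch$records$cumulative_molecules,
               cumsum(ch$records$n_new_molecules))

  # fully undated input: zero-count series, no growth rate
  empty <- build_chronicle(data.frame(origin_year = rep(NA_integer_, 3),
                                      scaffold_key = c("A", "B", "C")),
                           window = c(2000L, 2002L))
  expect_equal(empty$n_undated, 3L)
  expect_true(all(empty$records$n_new_molecules == 0L))
  expect_true(is.na(empty$mean_growth_pct))
  expect_error(build_chronicle(rec, window = c(2005L, 2000L)), "window")
})

test_that("chronicle SE equals the diversity module evaluated on the same table", {
  set.seed(31)
  lib <- generate_library(synthetic_library_spec(n_molecules = 400, seed = 5))
  ch <- build_chronicle(data.frame(origin_year = lib$origin_year,
                                   scaffold_key = lib$scaffold_key))
  last <- nrow(ch$records)
  tab <- scaffold_counts(lib$scaffold_key)
  expect_equal(ch$records$se[last], shannon_entropy(tab))
  expect_equal(ch$records$see[last], equitability(tab))
  expect_equal(ch$records$cumulative_scaffolds[last], tab$n_scaffolds)
})

test_that("year-over-year growth handles geometric, flat and degenerate series", {
  g <- yoy_growth(c(100, 110, 121))
  expect_equal(g$pct, c(10, 10))
  expect_equal(g$mean, 10)
  expect_equal(yoy_growth(c(50, 50, 50))$mean, 0)
  expect_error(yoy_growth(c(0, 0, 0)), "all-zero")
  expect_error(yoy_growth(5), "at least 2")
  expect_error(yoy_growth(c(10, 5), series_is_cumulative = TRUE), "non-decreasing")
  # leading zeros are excluded from the defined percentages
  g2 <- yoy_growth(c(0, 0, 10, 20), series_is_cumulative = TRUE)
  expect_equal(g2$pct, 100)
  # a base-count floor drops shot-noise ratios from the mean
  g3 <- yoy_growth(c(2, 6, 600, 660), series_is_cumulative = FALSE,
                   min_base = 50)
  expect_equal(g3$mean, 10)
})
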