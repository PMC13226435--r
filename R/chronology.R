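# Time-resolving a library: origin years, per-year chronicles of new
# molecules and scaffolds, diversity over time, and growth rates.

#' Earliest-citation origin year
#'
#' The origin of a compound is its earliest recorded year of appearance in
#' the literature; given all citation years for one compound this is their
#' minimum, or `NA` when no dated citation exists.
#'
#' @param citation_years numeric vector of years (may be empty or contain
#'   `NA`s, which are dropped).
#' @return integer year or `NA_integer_`.
#' @examples
#' assign_origin_year(c(2007, 2004, 2010))   # 2004
#' @export
assign_origin_year <- function(citation_years) {
  citation_years <- citation_years[!is.na(citation_years)]
  if (!length(citation_years)) return(NA_integer_)
  if (!is.numeric(citation_years) || any(citation_years %% 1 != 0)) {
    stop("citation years must be whole numbers")
  }
  as.integer(min(citation_years))
}

#' Build a per-year chronicle of a scaffolded library
#'
#' Tallies, for every calendar year in the window, the molecules and
#' scaffolds appearing for the first time, the cumulative totals, and the
#' diversity (Shannon entropy and equitability) of the scaffold distribution.
#' Gap years are materialized with zero new counts so year-over-year growth
#' is well defined. Records without an origin year are excluded and counted
#' in `n_undated`; records before the window start are folded into the first
#' year's cumulative base.
#'
#' @param records data frame with columns `origin_year` and `scaffold_key`
#'   (canonical scaffold SMILES; `""`/`NA` = no scaffold, excluded from
#'   scaffold statistics but still counted as molecules).
#' @param window integer `c(start, end)`; default spans 1976 to the last
#'   dated year.
#' @param diversity_on `"cumulative"` (default) evaluates SE/SEE each year on
#'   the cumulative-to-date scaffold table; `"annual"` on that year's new
#'   molecules only.
#' @param growth_on `"cumulative"` (default) or `"annual"`: series on which
#'   year-over-year growth percentages are computed.
#' @param min_base see [yoy_growth()]; floor on the base count for ratios
#'   entering the mean growth rate.
#' @return an object of class `chronicle`: list with `records` (one row per
#'   year: `year`, `n_new_molecules`, `cumulative_molecules`,
#'   `n_new_scaffolds`, `cumulative_scaffolds`, `se`, `see`,
#'   `yoy_growth_pct`), `year_span`, `n_undated`, `mean_growth_pct`,
#'   `growth_on`, `diversity_on`.
#' @export
build_chronicle <- function(records,
                            window = NULL,
                            diversity_on = c("cumulative", "annual"),
                            growth_on = c("cumulative", "annual"),
                            min_base = 0) {
  diversity_on <- match.arg(diversity_on)
  growth_on <- match.arg(growth_on)
  stopifnot(is.data.frame(records),
            all(c("origin_year", "scaffold_key") %in% names(records)))
  yr <- records$origin_year
  n_undated <- sum(is.na(yr))
  dated <- records[!is.na(yr), , drop = FALSE]
  if (is.null(window)) {
    window <- c(1976L, if (nrow(dated)) max(dated$origin_year) else 1976L)
  }
  if (window[1] > window[2]) stop("window start exceeds window end")
  years <- seq.int(window[1], window[2])
  # records dated before the window enter the first year's base
  dated$eff_year <- pmax(dated$origin_year, window[1])
  dated <- dated[dated$eff_year <= window[2], , drop = FALSE]

  n_new <- integer(length(years))
  n_new_sc <- integer(length(years))
  cum_sc <- integer(length(years))
  se <- rep(NA_real_, length(years))
  see <- rep(NA_real_, length(years))

  tab <- table(factor(dated$eff_year, levels = years))
  n_new <- as.integer(tab)
  cum_mol <- cumsum(n_new)

  keys <- dated$scaffold_key
  has_key <- !is.na(keys) & nzchar(keys)
  seen <- new.env(parent = emptyenv())
  cum_counts <- integer(0)
  for (t in seq_along(years)) {
    sel <- dated$eff_year == years[t] & has_key
    yk <- keys[sel]
    if (length(yk)) {
      new_tab <- table(yk)
      prev <- names(new_tab) %in% names(cum_counts)
      n_new_sc[t] <- sum(!prev)
      merged <- c(cum_counts, stats::setNames(integer(sum(!prev)), names(new_tab)[!prev]))
      merged[names(new_tab)] <- merged[names(new_tab)] + as.integer(new_tab)
      cum_counts <- merged
    }
    cum_sc[t] <- length(cum_counts)
    dtab <- if (diversity_on == "cumulative") {
      cum_counts
    } else {
      if (length(yk)) as.integer(table(yk)) else integer(0)
    }
    if (length(dtab) && sum(dtab) > 0) {
      se[t] <- shannon_entropy(dtab)
      see[t] <- equitability(dtab)
    }
  }

  gsrc <- if (growth_on == "cumulative") cum_mol else n_new
  gr <- if (length(gsrc) >= 2 && any(gsrc > 0)) {
    yoy_growth(gsrc, series_is_cumulative = (growth_on == "cumulative"),
               min_base = min_base, .quiet = TRUE)
  } else {
    list(pct_by_index = rep(NA_real_, length(gsrc)), mean = NA_real_)
  }
  rec <- data.frame(year = years,
                    n_new_molecules = n_new,
                    cumulative_molecules = cum_mol,
                    n_new_scaffolds = n_new_sc,
                    cumulative_scaffolds = cum_sc,
                    se = se, see = see,
                    yoy_growth_pct = gr$pct_by_index)
  structure(list(records = rec,
                 year_span = c(years[1], years[length(years)]),
                 n_undated = n_undated,
                 mean_growth_pct = gr$mean,
                 growth_on = growth_on,
                 diversity_on = diversity_on),
            class = "chronicle")
}

#' @export
print.chronicle <- function(x, ...) {
  cat("Library chronicle ", x$year_span[1], "-", x$year_span[2],
      " (", x$n_undated, " undated molecules excluded)\n", sep = "")
  cat("  mean YoY growth (", x$growth_on, " basis): ",
      round(x$mean_growth_pct, 2), "%\n", sep = "")
  print(utils::tail(x$records, 5), row.names = FALSE)
  invisible(x)
}

#' Year-over-year growth of a count series
#'
#' `growth_t = 100 * (C_t - C_(t-1)) / C_(t-1)` for a positive series, with
#' the mean taken as the arithmetic mean of the defined percentages. Leading
#' zero-count entries are excluded (growth from a zero base is undefined).
#'
#' For a cumulative series the input must be non-decreasing. For an annual
#' (new-count) series interior zeros also leave gaps: a percentage is only
#' defined where the previous year's count is positive.
#'
#' @param counts numeric series ordered by year.
#' @param series_is_cumulative `TRUE` if `counts` is a running total.
#' @param min_base ratios are only included in the mean when the base
#'   (previous-year) count is at least this large. The default 0 keeps every
#'   defined ratio; a positive floor (e.g. 50) excludes the shot-noise-
#'   dominated ratios of very small early counts when estimating an
#'   underlying growth rate.
#' @param .quiet internal.
#' @return list with `pct` (growth percentages for consecutive defined
#'   years), `pct_by_index` (aligned with the input, `NA` where undefined)
#'   and `mean`.
#' @examples
#' yoy_growth(c(100, 110, 121))$mean   # 10
#' @export
yoy_growth <- function(counts, series_is_cumulative = TRUE, min_base = 0,
                       .quiet = FALSE) {
  if (length(counts) < 2) stop("need a series of at least 2 entries")
  if (all(counts == 0)) stop("all-zero series has no growth rate")
  if (series_is_cumulative && any(diff(counts) < 0)) {
    stop("cumulative series must be non-decreasing")
  }
  prev <- counts[-length(counts)]
  curr <- counts[-1]
  pct <- ifelse(prev > 0, 100 * (curr - prev) / prev, NA_real_)
  pct_by_index <- c(NA_real_, pct)
  first_pos <- which(counts > 0)[1]
  pct_by_index[seq_len(first_pos)] <- NA_real_   # leading zero base years
  in_mean <- !is.na(pct_by_index) & c(0, prev) >= min_base
  defined <- pct_by_index[in_mean]
  list(pct = pct_by_index[!is.na(pct_by_index)],
       pct_by_index = pct_by_index,
       mean = if (length(defined)) mean(defined) else NA_real_)
}
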