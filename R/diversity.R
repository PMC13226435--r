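# Scaffold frequency tables and diversity statistics.
#
# Treating each unique scaffold as a "species", the Shannon entropy
#   SE = -sum_i p_i log2(p_i),  p_i = count_i / n_molecules
# measures the structural variety of a library, and the Shannon equitability
# (evenness)
#   SEE = SE / log2(n_scaffolds)
# normalizes it to [0, 1]: 1 is a perfectly even spread of molecules over the
# available scaffolds, values near 0 mean a few scaffolds dominate. Both logs
# share base 2, which is what pins SEE to the unit interval.

#' Tally scaffold keys into a frequency table
#'
#' @param keys character vector of canonical scaffold keys; empty strings or
#'   `NA`s mark molecules without a scaffold (acyclic or unparseable).
#' @param include_empty count the empty scaffold as a key of its own
#'   (default `FALSE`: such molecules are excluded).
#' @return an object of class `scaffold_counts`: list with `counts` (named
#'   integer vector, decreasing), `n_molecules`, `n_scaffolds` and
#'   `n_excluded` (molecules dropped by the empty-scaffold rule).
#' @examples
#' scaffold_counts(c("A", "A", "B"))
#' @export
scaffold_counts <- function(keys, include_empty = FALSE) {
  stopifnot(is.character(keys) || length(keys) == 0)
  empty <- is.na(keys) | !nzchar(keys)
  if (include_empty) {
    keys[empty] <- "<no scaffold>"
    excluded <- 0L
  } else {
    keys <- keys[!empty]
    excluded <- sum(empty)
  }
  tab <- table(keys)
  cnt <- sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
  structure(list(counts = cnt,
                 n_molecules = sum(cnt),
                 n_scaffolds = length(cnt),
                 n_excluded = excluded),
            class = "scaffold_counts")
}

#' @export
print.scaffold_counts <- function(x, ...) {
  cat("Scaffold counts:", x$n_scaffolds, "scaffolds over", x$n_molecules,
      "molecules\n")
  if (x$n_excluded) cat("  (", x$n_excluded, " molecules without scaffold excluded)\n", sep = "")
  utils::str(utils::head(x$counts, 5))
  invisible(x)
}

.as_counts <- function(table) {
  if (inherits(table, "scaffold_counts")) return(table$counts)
  if (is.numeric(table)) {
    stopifnot(all(table >= 0))
    return(table[table > 0])
  }
  stop("expected a scaffold_counts object or a numeric count vector")
}

#' Shannon entropy of a scaffold frequency table
#'
#' @param table a [scaffold_counts()] object or a positive count vector.
#' @return entropy in bits; 0 for a single scaffold.
#' @examples
#' shannon_entropy(c(A = 2, B = 1, C = 1))   # 1.5 bits
#' @export
shannon_entropy <- function(table) {
  cnt <- .as_counts(table)
  if (!length(cnt) || sum(cnt) == 0) stop("empty scaffold table")
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

#' Shannon equitability (evenness) of a scaffold frequency table
#'
#' `SE / log2(n_scaffolds)`, in `[0, 1]`. Defined as 0 when only one scaffold
#' is present (maximally restricted library; the ratio itself is 0/0).
#'
#' @param table a [scaffold_counts()] object or a positive count vector.
#' @param base logarithm base used for both entropy and its maximum
#'   (default 2; the value of SEE is base-independent up to this consistency,
#'   and base 2 keeps SEE equal to 1 at perfect evenness).
#' @return evenness in `[0, 1]`.
#' @examples
#' equitability(c(A = 5, B = 5, C = 5))   # 1
#' @export
equitability <- function(table, base = 2) {
  cnt <- .as_counts(table)
  if (!length(cnt) || sum(cnt) == 0) stop("empty scaffold table")
  k <- length(cnt)
  if (k == 1L) return(0)
  p <- cnt / sum(cnt)
  se <- -sum(p * log(p, base = base))
  se / log(k, base = base)
}

#' Diversity metrics of a scaffold table
#'
#' Convenience wrapper returning entropy, equitability and the table sizes in
#' one list.
#'
#' @inheritParams shannon_entropy
#' @return list with `se` (bits), `see`, `n_scaffolds`, `n_molecules`.
#' @export
diversity_metrics <- function(table) {
  cnt <- .as_counts(table)
  list(se = shannon_entropy(cnt), see = equitability(cnt),
       n_scaffolds = length(cnt), n_molecules = sum(cnt))
}

#' Most frequent scaffolds
#'
#' Ranks scaffolds by molecule count (descending; ties broken by the
#' lexicographically smaller key) and reports each count as a percentage of
#' the library. The percentage denominator defaults to all molecules in the
#' table but can be widened to the full library size (e.g. to include
#' molecules without a scaffold, the convention used when quoting shares of a
#' whole database).
#'
#' @param table a [scaffold_counts()] object or named count vector.
#' @param k how many scaffolds to report; the full ranking is returned when
#'   `k` exceeds the number of scaffolds.
#' @param total percentage denominator; default `NULL` uses
#'   `n_molecules + n_excluded` of a `scaffold_counts` object (i.e. the full
#'   library including scaffold-less molecules), or the count sum otherwise.
#' @return data frame with `scaffold`, `count`, `percent`.
#' @export
top_k_scaffolds <- function(table, k = 10, total = NULL) {
  if (k < 1) stop("k must be >= 1")
  cnt <- .as_counts(table)
  if (!length(cnt)) stop("empty scaffold table")
  if (is.null(total)) {
    total <- if (inherits(table, "scaffold_counts")) {
      table$n_molecules + table$n_excluded
    } else {
      sum(cnt)
    }
  }
  ord <- order(-cnt, names(cnt))
  cnt <- cnt[ord]
  k <- min(k, length(cnt))
  data.frame(scaffold = names(cnt)[seq_len(k)],
             count = as.integer(cnt[seq_len(k)]),
             percent = 100 * as.numeric(cnt[seq_len(k)]) / total,
             row.names = NULL)
}

#' Part-of-whole coverage percentage
#'
#' `100 * part / whole`, optionally rounded to a number of significant
#' figures (used for order-of-magnitude statements such as the share of
#' known proteins with a solved structure).
#'
#' @param part_count non-negative numerator.
#' @param whole_count positive denominator.
#' @param sig_figs if not `NULL`, round the percentage to this many
#'   significant figures.
#' @return percentage (numeric).
#' @examples
#' coverage_percent(251806, 203130941, sig_figs = 1)   # 0.1
#' @export
coverage_percent <- function(part_count, whole_count, sig_figs = NULL) {
  stopifnot(length(part_count) == 1L, length(whole_count) == 1L)
  if (is.na(whole_count) || whole_count <= 0) stop("whole_count must be > 0")
  if (part_count < 0) stop("part_count must be >= 0")
  pct <- 100 * part_count / whole_count
  if (!is.null(sig_figs)) pct <- signif(pct, sig_figs)
  pct
}
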