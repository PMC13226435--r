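# Chemical-space mapping: circular (Morgan) fingerprints of generic
# frameworks, linear reduction by PCA, then 2D t-SNE, with node weights equal
# to framework frequencies and era slicing along origin years.

# Deterministic integer hash for invariant tuples; arithmetic kept in doubles
# below 2^53 so it is exact, reduced mod a Mersenne prime.
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                    Cl = 17, Br = 35, I = 53)

#' Circular (Morgan) fingerprint of one molecule
#'
#' Iteratively hashes each atom's neighborhood out to the given radius
#' (radius 2 = diameter 4, the ECFP4 convention) and folds the resulting
#' substructure identifiers onto a fixed-length bit vector. Deterministic and
#' invariant to the input atom ordering (structures are canonicalized before
#' fingerprinting). Bit positions are NOT compatible with other toolkits'
#' ECFP implementations — hashing schemes differ — but similarity ranks on
#' common structures agree.
#'
#' @param smiles single-fragment SMILES.
#' @param radius neighborhood radius (default 2).
#' @param n_bits vector length (default 2048).
#' @return integer vector of 0/1 of length `n_bits`.
#' @export
circular_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(smiles) == 1L)
  fp <- fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
  if (anyNA(fp$bits)) stop("unparseable or empty molecule: ", smiles)
  fp$bits[1, ]
}

#' Fingerprint matrix for a set of structures
#'
#' @param keys character vector of SMILES (typically generic frameworks).
#' @param radius,n_bits see [circular_fingerprint()].
#' @return object of class `fingerprint_matrix`: list with `keys`, `bits`
#'   (matrix keys x n_bits; `NA` rows for unparseable input), `n_bits`,
#'   `radius`.
#' @export
fingerprint_matrix <- function(keys, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0L, n_bits >= 16L)
  uniq <- unique(keys)
  mols <- smiles_to_mols(uniq, gen2d = FALSE)
  bits <- matrix(NA_integer_, nrow = length(uniq), ncol = n_bits)
  for (i in seq_along(uniq)) {
    m <- mols[[i]]
    if (is.null(m) || nrow(m$atoms) == 0) next
    bits[i, ] <- .morgan_bits(m, radius, n_bits)
  }
  rows <- match(keys, uniq)
  structure(list(keys = keys,
                 bits = bits[rows, , drop = FALSE],
                 n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint_matrix")
}

.morgan_bits <- function(mol, radius, n_bits) {
  na <- nrow(mol$atoms)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = na)
  hs <- .implicit_h(mol)
  inring <- as.integer(.ring_atoms(mol))
  z <- .atomic_number[mol$atoms$elem]
  z[is.na(z)] <- 0
  # initial invariant: element, degree, implicit H, charge, ring membership
  ids <- vapply(seq_len(na), function(i) {
    .hash_ints(c(z[i], deg[i], hs[i], mol$atoms$chg[i] + 8, inring[i]))
  }, 0)
  all_ids <- ids
  nbrs <- lapply(seq_len(na), function(i) {
    j <- c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
    o <- c(mol$bonds$order[mol$bonds$a1 == i], mol$bonds$order[mol$bonds$a2 == i])
    list(j = j, o = o)
  })
  r <- 0L
  while (r < radius) {
    new_ids <- vapply(seq_len(na), function(i) {
      nb <- nbrs[[i]]
      ord <- order(nb$o, ids[nb$j])
      .hash_ints(c(r + 1, ids[i], rbind(nb$o[ord], ids[nb$j][ord])))
    }, 0)
    ids <- new_ids
    all_ids <- c(all_ids, ids)
    r <- r + 1L
  }
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1L] <- 1L
  bits
}

#' Linear reduction of a fingerprint matrix
#'
#' Mean-centered principal component analysis of the bit matrix. When fewer
#' informative dimensions exist than components requested, the component
#' count is reduced with a warning.
#'
#' @param matrix a [fingerprint_matrix()] (or a plain numeric matrix).
#' @param n_components target dimensionality (default 50).
#' @return list with `coords` (rows x components), `sdev` (component
#'   standard deviations, non-increasing) and `n_components`.
#' @export
reduce_dimensions <- function(matrix, n_components = 50L) {
  x <- if (inherits(matrix, "fingerprint_matrix")) matrix$bits else matrix
  if (anyNA(x)) stop("fingerprint matrix has NA rows; drop unparseable keys first")
  n_distinct <- nrow(unique(x))
  if (n_distinct < 2) stop("need at least 2 distinct vectors")
  maxc <- min(n_distinct - 1L, ncol(x), nrow(x))
  if (n_components > maxc) {
    warning("reducing n_components from ", n_components, " to ", maxc)
    n_components <- maxc
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  list(coords = p$x[, seq_len(n_components), drop = FALSE],
       sdev = p$sdev[seq_len(n_components)],
       n_components = as.integer(n_components))
}

#' 2D embedding by t-SNE
#'
#' Projects reduced coordinates to two dimensions with exact t-distributed
#' stochastic neighbor embedding. Bit-reproducible for a fixed seed and
#' input.
#'
#' @param coords numeric matrix (rows = structures), e.g.
#'   `reduce_dimensions(...)$coords`.
#' @param perplexity t-SNE perplexity (default 30; reduced automatically is
#'   an error — it must satisfy `3 * perplexity < n - 1`).
#' @param seed integer RNG seed.
#' @param max_iter gradient-descent iterations (default 500).
#' @return matrix with columns `x`, `y`.
#' @export
embed_2d <- function(coords, perplexity = 30, seed = 1L, max_iter = 500L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points to embed")
  if (3 * perplexity > n - 1) {
    stop("perplexity ", perplexity, " too large for ", n,
         " points; choose perplexity <= (n - 1) / 3")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(coords, dims = 2, perplexity = perplexity,
                      theta = 0, max_iter = as.integer(max_iter),
                      check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
  out <- fit$Y
  colnames(out) <- c("x", "y")
  out
}

#' Era-sliced chemical-space snapshots
#'
#' For each era (a year), takes the generic frameworks of all molecules
#' dated up to that year (cumulative mode, the default) or within the era's
#' window, deduplicates them with frequency weights, fingerprints and embeds
#' them. All eras share one seed so maps are comparable.
#'
#' @param records data frame with columns `framework_key` and `origin_year`.
#' @param eras integer vector of era end years.
#' @param cumulative if `TRUE` (default) era `y` covers all years `<= y`;
#'   otherwise the window since the previous era.
#' @param radius,n_bits fingerprint parameters.
#' @param n_components PCA components before t-SNE.
#' @param perplexity,seed,max_iter embedding parameters; perplexity is capped
#'   at `(n - 2) / 3` per era.
#' @return named list (one element per era) of `embedding_result` objects:
#'   `keys`, `coords`, `weights`, `params`. Eras with fewer than 3 distinct
#'   frameworks are skipped with a warning.
#' @export
snapshot_series <- function(records, eras, cumulative = TRUE,
                            radius = 2L, n_bits = 2048L, n_components = 50L,
                            perplexity = 30, seed = 1L, max_iter = 500L) {
  stopifnot(is.data.frame(records),
            all(c("framework_key", "origin_year") %in% names(records)))
  eras <- sort(unique(as.integer(eras)))
  out <- list()
  prev <- -Inf
  for (e in eras) {
    lo <- if (cumulative) -Inf else prev + 1
    sel <- !is.na(records$origin_year) & records$origin_year <= e &
      records$origin_year >= lo &
      !is.na(records$framework_key) & nzchar(records$framework_key)
    prev <- e
    keys <- records$framework_key[sel]
    if (length(unique(keys)) < 3) {
      warning("era ", e, " has fewer than 3 distinct frameworks; skipped")
      next
    }
    wt <- table(keys)
    ukeys <- names(wt)
    fp <- fingerprint_matrix(ukeys, radius = radius, n_bits = n_bits)
    ok <- !apply(is.na(fp$bits), 1, any)
    if (sum(ok) < 3) {
      warning("era ", e, " has fewer than 3 fingerprintable frameworks; skipped")
      next
    }
    bits <- fp$bits[ok, , drop = FALSE]
    ukeys <- ukeys[ok]
    per <- max(0.5, min(perplexity, (nrow(bits) - 1) / 3))
    red <- suppressWarnings(reduce_dimensions(
      structure(list(bits = bits), class = "fingerprint_matrix"),
      n_components = n_components))
    xy <- embed_2d(red$coords, perplexity = per, seed = seed,
                   max_iter = max_iter)
    out[[as.character(e)]] <- structure(
      list(keys = ukeys,
           coords = xy,
           weights = as.integer(wt[ukeys]),
           params = list(era = e, cumulative = cumulative, radius = radius,
                         n_bits = n_bits, n_components = red$n_components,
                         perplexity = per, seed = seed,
                         max_iter = max_iter)),
      class = "embedding_result")
  }
  out
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("Chemical-space snapshot (era ", x$params$era, "): ",
      length(x$keys), " frameworks, ", sum(x$weights), " molecules\n", sep = "")
  invisible(x)
}
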