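# Shared test fixtures and independent oracles.

# all compositions of n molecules into at most k scaffold classes
# (unordered positive parts), enumerated recursively
compositions_upto <- function(n, k) {
  parts <- function(n, k, maxpart) {
    if (n == 0) return(list(integer(0)))
    if (k == 0) return(list())
    out <- list()
    for (p in seq_len(min(n, maxpart))) {
      for (rest in parts(n - p, k - 1, p)) out <- c(out, list(c(p, rest)))
    }
    out
  }
  parts(n, k, n)
}

# independent entropy evaluation: expand counts to one row per molecule and
# accumulate -p log2 p term by term over the distinct classes
brute_entropy_bits <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (c_i in counts) acc <- acc - (c_i / total) * log(c_i / total) / log(2)
  acc
}

# mean silhouette width over a 2D embedding with known family labels
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l) mean(d[i, labels == l]), 1))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

canonical_smiles_of <- function(s) scaffchron:::canonical_smiles(s)

# small mixed-structure SMILES set used across modules
test_molecules <- function() {
  c("Cc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2[nH]ccc2c1",
    "O=C(Nc1ccc(F)cc1)c1ccccc1", "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    "C1CCNC1", "O=C1CCCCC1", "CCCCO", "c1ccc(-c2ccccc2)cc1",
    "O=C(/C=C/c1ccccc1)c1ccccc1")
}

write_smi_fixture <- function(lines, ext = ".smi") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
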