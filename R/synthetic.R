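# Synthetic compound-library generator.
#
# Emulates the structure of a public bioactivity library at desk scale:
# a small pool of privileged scaffolds used with Zipf-skewed frequencies
# (a handful of scaffolds dominate, the rest form a long tail), random
# small-substituent decoration, a fraction of records emitted as salts or
# protonated forms, and origin years drawn from a geometric growth curve so
# expected new-molecule counts increase by a fixed factor per year.
#
# Decoration works by validated branch insertion into the scaffold's
# canonical SMILES: for each scaffold, every atom-token position is probed
# once with a methyl branch and kept only if the decorated string parses and
# its extracted Bemis-Murcko scaffold equals the scaffold itself. Drawing
# substituents is then pure string assembly, which keeps generation fast and
# guarantees the round-trip property extract_scaffold(decorated) == scaffold.

#' Ten privileged ring scaffolds
#'
#' A reference pool of ten scaffolds recurrent among bioactive molecules
#' (benzene, biphenyl, pyridine, indole, benzanilide, pyrrolidine, quinoline,
#' chalcone, isoflavone, naphthalene), used as the default scaffold pool of
#' the synthetic-library generator.
#'
#' @return data frame with columns `name` and `smiles`.
#' @export
privileged_scaffolds <- function() {
  data.frame(
    name = c("benzene", "biphenyl", "pyridine", "indole", "benzanilide",
             "pyrrolidine", "quinoline", "chalcone", "isoflavone",
             "naphthalene"),
    smiles = c("c1ccccc1",
               "c1ccc(-c2ccccc2)cc1",
               "c1ccncc1",
               "c1ccc2[nH]ccc2c1",
               "O=C(Nc1ccccc1)c1ccccc1",
               "C1CCNC1",
               "c1ccc2ncccc2c1",
               "O=C(/C=C/c1ccccc1)c1ccccc1",
               "O=c1cc(-c2ccccc2)oc2ccccc12",
               "c1ccc2ccccc2c1")
  )
}

#' Synthetic-library generation parameters
#'
#' @param n_molecules library size (emitted exactly).
#' @param scaffold_pool character vector of scaffold SMILES; default the
#'   [privileged_scaffolds()] pool.
#' @param zipf_exponent skew of scaffold frequencies: scaffold at rank `r` is
#'   drawn with probability proportional to `r^-zipf_exponent`; 0 gives
#'   uniform usage. Default 1.2, which reproduces the roughly 17-fold spread
#'   between the most and the tenth most frequent scaffold seen in large
#'   bioactivity libraries.
#' @param year_range `c(first, last)` calendar years.
#' @param annual_growth g >= 0: expected new-molecule counts grow as
#'   `(1+g)^(year-first)`, normalized so the library size is exactly
#'   `n_molecules`. Default 0.116.
#' @param salt_fraction probability a record is emitted as a salt or
#'   protonated form (default 0.1).
#' @param max_substituents 0..k substituents drawn per molecule (default 3).
#' @param substituents substituent alphabet as SMILES branches
#'   (default methyl, ethyl, hydroxyl, fluoro, chloro, amino).
#' @param seed integer seed; one pseudo-random stream per generation call.
#' @return object of class `synthetic_library_spec` (a validated list).
#' @export
synthetic_library_spec <- function(n_molecules = 1000L,
                                   scaffold_pool = privileged_scaffolds()$smiles,
                                   zipf_exponent = 1.2,
                                   year_range = c(1976L, 2024L),
                                   annual_growth = 0.116,
                                   salt_fraction = 0.1,
                                   max_substituents = 3L,
                                   substituents = c("C", "CC", "O", "F", "Cl", "N"),
                                   seed = 1L) {
  if (!length(scaffold_pool)) stop("scaffold pool must not be empty")
  if (length(year_range) != 2L || year_range[1] > year_range[2]) {
    stop("invalid year range")
  }
  stopifnot(n_molecules >= 1, zipf_exponent >= 0, annual_growth >= 0,
            salt_fraction >= 0, salt_fraction <= 1, max_substituents >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 scaffold_pool = scaffold_pool,
                 zipf_exponent = zipf_exponent,
                 year_range = as.integer(year_range),
                 annual_growth = annual_growth,
                 salt_fraction = salt_fraction,
                 max_substituents = as.integer(max_substituents),
                 substituents = substituents,
                 seed = as.integer(seed)),
            class = "synthetic_library_spec")
}

# cache of validated insertion positions per scaffold SMILES
.decor_cache <- new.env(parent = emptyenv())

# Offsets (character positions) in a scaffold SMILES after which a
# parenthesized branch may be inserted, validated by the round-trip property.
.substitutable_positions <- function(scaffold) {
  hit <- get0(scaffold, envir = .decor_cache)
  if (!is.null(hit)) return(hit)
  can <- canonical_smiles(scaffold)
  if (is.na(can)) stop("unparseable scaffold: ", scaffold)
  # atom tokens: bracket atoms, two-letter halogens, organic-subset symbols
  m <- gregexpr("\\[[^]]*\\]|Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", scaffold)[[1]]
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  # a branch must come after any ring-bond digits that follow the atom
  ends <- vapply(ends, function(e) {
    while (e < nchar(scaffold) &&
           grepl("^[0-9]$", substr(scaffold, e + 1L, e + 1L))) e <- e + 1L
    e
  }, 1L)
  ok <- vapply(ends, function(e) {
    probe <- paste0(substr(scaffold, 1, e), "(C)",
                    substr(scaffold, e + 1L, nchar(scaffold)))
    sc <- tryCatch(extract_scaffolds(probe)$scaffold_smiles,
                   error = function(e2) NA_character_)
    identical(sc, can)
  }, TRUE)
  pos <- ends[ok]
  assign(scaffold, pos, envir = .decor_cache)
  pos
}

#' Decorate a scaffold with random substituents
#'
#' Attaches 0 to `max_substituents` substituents from the alphabet at random
#' substitutable ring/linker positions, each by a single bond, so that the
#' Bemis-Murcko scaffold of the product is the input scaffold. Uses the
#' current RNG state. A scaffold with no substitutable position is emitted
#' undecorated.
#'
#' @param scaffold scaffold SMILES.
#' @param max_substituents maximum substituent count.
#' @param substituents substituent alphabet (SMILES fragments).
#' @return a single molecule SMILES.
#' @export
decorate_scaffold <- function(scaffold, max_substituents = 3L,
                              substituents = c("C", "CC", "O", "F", "Cl", "N")) {
  pos <- .substitutable_positions(scaffold)
  k <- if (length(pos) && max_substituents > 0) {
    sample.int(max_substituents + 1L, 1L) - 1L
  } else 0L
  k <- min(k, length(pos))
  if (k == 0L) return(scaffold)
  at <- sort(sample(pos, k), decreasing = TRUE)
  subs <- sample(substituents, k, replace = TRUE)
  out <- scaffold
  for (i in seq_len(k)) {
    out <- paste0(substr(out, 1, at[i]), "(", subs[i], ")",
                  substr(out, at[i] + 1L, nchar(out)))
  }
  out
}

#' Generate a synthetic compound library
#'
#' Draws `n_molecules` records according to a [synthetic_library_spec()]:
#' Zipf-distributed scaffold choice, random decoration, geometric-growth
#' origin years, and a `salt_fraction` of records emitted as salts (appended
#' counter-fragment) or protonated amines (when an amino substituent is
#' present). Fully reproducible per seed; the RNG state of the caller is
#' left untouched.
#'
#' @param spec a [synthetic_library_spec()].
#' @return data frame of compound records: `id`, `smiles`, `origin_year`,
#'   `mol_type_label`, `flag_parse_failed`, plus generator ground truth
#'   columns `scaffold_key` (canonical scaffold SMILES) and `clean_smiles`
#'   (the unsalted, neutral form of the emitted structure).
#' @examples
#' \donttest{
#' lib <- generate_library(synthetic_library_spec(n_molecules = 50, seed = 7))
#' head(lib)
#' }
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_library_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)

  pool <- spec$scaffold_pool
  pool_can <- canonical_smiles(pool)
  if (anyNA(pool_can)) stop("unparseable scaffold in pool: ",
                            paste(pool[is.na(pool_can)], collapse = ", "))
  n <- spec$n_molecules
  ranks <- seq_along(pool)
  pz <- ranks^(-spec$zipf_exponent)
  scaf_idx <- sample.int(length(pool), n, replace = TRUE, prob = pz / sum(pz))

  years <- seq.int(spec$year_range[1], spec$year_range[2])
  wy <- (1 + spec$annual_growth)^(years - years[1])
  origin <- sample(years, n, replace = TRUE, prob = wy / sum(wy))

  smiles <- character(n)
  clean <- character(n)
  salted <- stats::runif(n) < spec$salt_fraction
  counter <- c("[Na+]", "Cl", "O")
  for (i in seq_len(n)) {
    mol <- decorate_scaffold(pool[scaf_idx[i]], spec$max_substituents,
                             spec$substituents)
    clean[i] <- mol
    if (salted[i]) {
      if (grepl("(N)", mol, fixed = TRUE)) {
        # protonated primary amine + chloride counter-ion
        mol <- paste0(sub("(N)", "([NH3+])", mol, fixed = TRUE), ".[Cl-]")
      } else {
        mol <- paste0(mol, ".", sample(counter, 1L))
      }
    }
    smiles[i] <- mol
  }
  data.frame(id = sprintf("SYN%06d", seq_len(n)),
             smiles = smiles,
             origin_year = origin,
             mol_type_label = NA_character_,
             flag_parse_failed = FALSE,
             scaffold_key = pool_can[scaf_idx],
             clean_smiles = clean)
}
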