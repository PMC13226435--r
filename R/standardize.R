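# Structure standardization: desalting (largest organic fragment) followed by
# charge neutralization, then canonicalization. Applied before any scaffold
# work so that counter-ions and protonation states never split scaffold keys.

#' Desalt a SMILES string
#'
#' Keeps the fragment with the most heavy atoms of a (possibly multi-fragment)
#' SMILES; ties are broken by the lexicographically smallest canonical SMILES
#' so the choice is deterministic. Single-fragment input is returned
#' canonicalized and unchanged otherwise.
#'
#' @param smiles a single SMILES string.
#' @return list with `canonical_smiles` (kept fragment, canonical),
#'   `was_desalted` and `removed_fragments` (canonical SMILES of dropped
#'   fragments).
#' @examples
#' desalt("CC(=O)[O-].[Na+]")
#' @export
desalt <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles))) stop("empty molecule")
  frags <- strsplit(trimws(smiles), ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) stop("empty molecule")
  can <- canonical_smiles(frags)
  if (anyNA(can)) stop("unparseable fragment in '", smiles, "'")
  if (length(frags) == 1L) {
    return(list(canonical_smiles = can, was_desalted = FALSE,
                removed_fragments = character(0)))
  }
  heavy <- smiles_heavy_atoms(can)
  # max heavy atoms; tie -> lexicographically smallest canonical SMILES
  best <- which(heavy == max(heavy))
  keep <- best[order(can[best])][1]
  list(canonical_smiles = can[keep], was_desalted = TRUE,
       removed_fragments = can[-keep])
}

# Neutralization rule list, applied exhaustively at the graph level:
#   * O(-) or S(-) carrying exactly one single bond (carboxylate, sulfonate /
#     phosphate oxygens, alkoxide, thiolate) -> charge 0, implicit H restored;
#   * N(+) or P(+) whose explicit bond orders sum to <= 3 (protonated amines,
#     anilinium, etc.) -> charge 0, one proton removed implicitly.
# Charges that cannot be removed by hydrogen adjustment (quaternary N,
# N-oxides written as [N+][O-] keep the N; the O- side is still cleared only
# when singly bonded to a *neutral* frame -- see below) are left intact.
.neutralize_mol <- function(mol) {
  changed <- FALSE
  bsum <- .bond_order_sums(mol)
  chg <- mol$atoms$chg
  elem <- mol$atoms$elem
  # count single bonds per atom to detect e.g. [O-] with one connection
  nb <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = nrow(mol$atoms))
  for (i in seq_len(nrow(mol$atoms))) {
    if (chg[i] == -1L && elem[i] %in% c("O", "S") && bsum[i] == 1 && nb[i] == 1) {
      # skip when the anion balances an adjacent cationic center (N-oxide,
      # nitro written in charged form): removing only one side breaks valence
      j <- c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
      if (any(chg[j] > 0L)) next
      chg[i] <- 0L; changed <- TRUE
    } else if (chg[i] == 1L && elem[i] %in% c("N", "P") && bsum[i] <= 3) {
      chg[i] <- 0L; changed <- TRUE
    }
  }
  mol$atoms$chg <- chg
  list(mol = mol, changed = changed)
}

#' Neutralize protonation-state charges
#'
#' Removes formal charges that exist only as protonation states (carboxylate
#' to acid, alkoxide/thiolate to alcohol/thiol, sulfonate and phosphate
#' oxyanions, protonated amines) by implicit hydrogen adjustment. Charges that
#' cannot be removed without breaking bonds (quaternary ammonium, balanced
#' ylide/N-oxide pairs) are left intact.
#'
#' @param smiles a single-fragment SMILES string.
#' @return list with `canonical_smiles` and `was_neutralized`.
#' @examples
#' neutralize("CC(=O)[O-]")
#' @export
neutralize <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  if (is.na(smiles) || grepl(".", smiles, fixed = TRUE)) {
    stop("neutralize() expects a single-fragment molecule; desalt first")
  }
  if (!grepl("\\[[^]]*[+-]", smiles)) {   # formal charges live inside brackets
    can <- canonical_smiles(smiles)
    if (is.na(can)) stop("unparseable SMILES: ", smiles)
    return(list(canonical_smiles = can, was_neutralized = FALSE))
  }
  mol <- smiles_to_mols(smiles)[[1]]
  if (is.null(mol)) stop("unparseable SMILES: ", smiles)
  res <- .neutralize_mol(mol)
  if (!res$changed) {
    return(list(canonical_smiles = canonical_smiles(smiles), was_neutralized = FALSE))
  }
  out <- mols_to_smiles(list(res$mol))
  if (is.na(out)) stop("neutralization produced an unreadable structure for ", smiles)
  list(canonical_smiles = out, was_neutralized = TRUE)
}

#' Standardize one compound record
#'
#' Desalts, neutralizes and canonicalizes a structure. The operation is
#' idempotent: standardizing its own output reproduces it.
#'
#' @param smiles SMILES string (or a one-row record data frame with a
#'   `smiles` column).
#' @param id identifier used in error messages.
#' @return list with `canonical_smiles`, `was_desalted`, `was_neutralized`
#'   and `removed_fragments`.
#' @examples
#' standardize_record("CC(=O)[O-].[Na+]")
#' @export
standardize_record <- function(smiles, id = NULL) {
  if (is.data.frame(smiles)) {
    stopifnot(nrow(smiles) == 1L)
    if (isTRUE(smiles$flag_parse_failed)) {
      stop("record '", smiles$id, "' is flagged parse-failed; cannot standardize")
    }
    id <- smiles$id
    smiles <- smiles$smiles
  }
  d <- tryCatch(desalt(smiles), error = function(e) {
    stop("standardization failed for record '", if (is.null(id)) smiles else id,
         "': ", conditionMessage(e))
  })
  n <- neutralize(d$canonical_smiles)
  list(canonical_smiles = n$canonical_smiles,
       was_desalted = d$was_desalted,
       was_neutralized = n$was_neutralized,
       removed_fragments = d$removed_fragments)
}

#' Standardize a compound table
#'
#' Vectorized [standardize_record()] over a compound table from
#' [read_compound_table()]. Parse-failed records pass through untouched with
#' `canonical_smiles = NA`. Batches toolkit calls, so this is the form to use
#' on whole libraries.
#'
#' @param records data frame with at least `id` and `smiles`
#'   (and optionally `flag_parse_failed`).
#' @return the input with columns `canonical_smiles`, `was_desalted`,
#'   `was_neutralized` and `removed_fragments` (`;`-joined) appended.
#' @export
standardize_library <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  n <- nrow(records)
  failed <- if ("flag_parse_failed" %in% names(records)) records$flag_parse_failed else rep(FALSE, n)
  out_smi <- rep(NA_character_, n)
  desalted <- rep(FALSE, n); neutralized <- rep(FALSE, n)
  removed <- rep("", n)

  todo <- which(!failed)
  smi <- trimws(records$smiles[todo])
  multi <- grepl(".", smi, fixed = TRUE)
  charged <- grepl("\\[[^]]*[+-]", smi)

  # fast path: single fragment, no charges -> plain canonicalization
  fast <- todo[!multi & !charged]
  if (length(fast)) {
    can <- canonical_smiles(records$smiles[fast])
    out_smi[fast] <- can
    failed[fast][is.na(can)] <- TRUE
  }
  # slow path: per-record desalt + neutralize (still batched underneath per call)
  slow <- todo[multi | charged]
  for (i in slow) {
    res <- tryCatch(standardize_record(records$smiles[i], id = records$id[i]),
                    error = function(e) NULL)
    if (is.null(res)) { failed[i] <- TRUE; next }
    out_smi[i] <- res$canonical_smiles
    desalted[i] <- res$was_desalted
    neutralized[i] <- res$was_neutralized
    removed[i] <- paste(res$removed_fragments, collapse = ";")
  }
  records$canonical_smiles <- out_smi
  records$was_desalted <- desalted
  records$was_neutralized <- neutralized
  records$removed_fragments <- removed
  records$flag_parse_failed <- failed
  records
}
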