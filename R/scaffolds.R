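# Bemis-Murcko scaffolds and generic frameworks.
#
# The scaffold of a molecule is its ring systems plus the linker atoms
# connecting them, with all side chains pruned; atoms attached to a retained
# atom by a double or triple bond (exocyclic =O, =N, =C) are retained. On the
# molecular graph this is exactly:
#
#   scaffold atoms = 2-core of the graph (iteratively strip atoms of degree
#                    < 2)  UNION  atoms bonded to a 2-core atom with order >= 2
#
# The 2-core of a connected molecular graph is the set of ring atoms plus the
# atoms on paths between rings; terminal multiply-bonded decorations are then
# restored in one pass, never recursively, which reproduces the reference
# Murcko implementations (an aldehyde at the end of a side chain is pruned, a
# carbonyl on a ring or linker survives).

#' Extract the Bemis-Murcko scaffold of one molecule
#'
#' @param smiles a single-fragment, standardized SMILES string.
#' @return list with `canonical_smiles` (empty string for acyclic input),
#'   `n_rings` (smallest-set ring count) and `is_empty`.
#' @examples
#' extract_scaffold("Cc1ccccc1")   # toluene -> benzene
#' extract_scaffold("CCCC")        # acyclic -> empty scaffold
#' @export
extract_scaffold <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  res <- extract_scaffolds(smiles)
  if (is.na(res$scaffold_smiles)) stop("unparseable SMILES: ", smiles)
  list(canonical_smiles = res$scaffold_smiles, n_rings = res$n_rings,
       is_empty = res$is_empty)
}

#' Extract scaffolds for a vector of molecules
#'
#' Vectorized scaffold extraction with batched toolkit calls; the form to use
#' on whole libraries.
#'
#' @param smiles character vector of single-fragment SMILES.
#' @return data frame with columns `smiles`, `scaffold_smiles` (`""` for
#'   acyclic molecules, `NA` for unparseable ones), `n_rings`, `is_empty`.
#' @export
extract_scaffolds <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(smiles = smiles,
                    scaffold_smiles = rep(NA_character_, n),
                    n_rings = rep(NA_integer_, n),
                    is_empty = rep(NA, n))
  if (!n) return(out)
  if (any(grepl(".", smiles, fixed = TRUE), na.rm = TRUE)) {
    stop("multi-fragment SMILES in input; desalt first")
  }
  mols <- smiles_to_mols(smiles)
  scaf <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mols[[i]]
    if (is.null(m)) next
    na <- nrow(m$atoms); nb <- nrow(m$bonds)
    if (nb < na) {                       # connected & acyclic: tree
      out$scaffold_smiles[i] <- ""
      out$n_rings[i] <- 0L
      out$is_empty[i] <- TRUE
      next
    }
    core <- .two_core(m)
    incore <- logical(na); incore[core] <- TRUE
    multi <- m$bonds$order >= 2L
    restore <- unique(c(
      m$bonds$a2[multi & incore[m$bonds$a1] & !incore[m$bonds$a2]],
      m$bonds$a1[multi & incore[m$bonds$a2] & !incore[m$bonds$a1]]
    ))
    keep <- sort(c(core, restore))
    sm <- .subset_mol(m, keep)
    out$n_rings[i] <- nrow(sm$bonds) - nrow(sm$atoms) + 1L
    out$is_empty[i] <- FALSE
    scaf[[i]] <- sm
  }
  todo <- which(!vapply(scaf, is.null, TRUE))
  if (length(todo)) {
    out$scaffold_smiles[todo] <- mols_to_smiles(scaf[todo])
  }
  out
}

#' Generic (carbon-skeleton) framework of a scaffold
#'
#' Converts every heavy atom of a scaffold to an uncharged carbon and every
#' bond to a single bond, dropping aromaticity and stereochemistry, so only
#' the molecular shape remains. Heavy-atom count is preserved; benzene and
#' cyclohexane collapse to the same framework.
#'
#' @param scaffold_smiles a single non-empty scaffold SMILES.
#' @return list with `canonical_smiles` and `heavy_atom_count`.
#' @examples
#' generic_framework("c1ccncc1")   # pyridine -> C1CCCCC1
#' @export
generic_framework <- function(scaffold_smiles) {
  stopifnot(length(scaffold_smiles) == 1L)
  if (is.na(scaffold_smiles) || !nzchar(scaffold_smiles)) {
    stop("empty scaffold has no generic framework")
  }
  res <- generic_frameworks(scaffold_smiles)
  if (is.na(res$framework_smiles)) stop("unparseable scaffold: ", scaffold_smiles)
  list(canonical_smiles = res$framework_smiles,
       heavy_atom_count = res$heavy_atom_count)
}

#' Generic frameworks for a vector of scaffolds
#'
#' @param scaffold_smiles character vector of scaffold SMILES; empty strings
#'   and `NA`s map to `NA`.
#' @return data frame with `scaffold_smiles`, `framework_smiles`,
#'   `heavy_atom_count`.
#' @export
generic_frameworks <- function(scaffold_smiles) {
  n <- length(scaffold_smiles)
  out <- data.frame(scaffold_smiles = scaffold_smiles,
                    framework_smiles = rep(NA_character_, n),
                    heavy_atom_count = rep(NA_integer_, n))
  ok <- which(!is.na(scaffold_smiles) & nzchar(scaffold_smiles))
  if (!length(ok)) return(out)
  # the same framework never needs converting twice
  uniq <- unique(scaffold_smiles[ok])
  mols <- smiles_to_mols(uniq, gen2d = FALSE)
  gen <- lapply(mols, function(m) {
    if (is.null(m)) return(NULL)
    m$atoms$elem <- "C"
    m$atoms$chg <- 0L
    if (nrow(m$bonds)) { m$bonds$order <- 1L; m$bonds$flag <- 0L }
    m
  })
  fw <- rep(NA_character_, length(uniq))
  todo <- which(!vapply(gen, is.null, TRUE))
  if (length(todo)) fw[todo] <- mols_to_smiles(gen[todo])
  hv <- vapply(mols, function(m) if (is.null(m)) NA_integer_ else nrow(m$atoms), 1L)
  idx <- match(scaffold_smiles[ok], uniq)
  out$framework_smiles[ok] <- fw[idx]
  out$heavy_atom_count[ok] <- hv[idx]
  out
}
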