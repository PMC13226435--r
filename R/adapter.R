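# Molecular-graph adapter over OpenBabel (via ChemmineOB).
#
# All SMILES parsing, aromaticity perception and canonicalization are delegated
# to OpenBabel; this file only moves structures between three representations:
#   SMILES text  <->  SDF (V2000) text  <->  a light R graph ("mol")
# A mol is list(title, atoms = data.frame(elem, x, y, chg),
#               bonds = data.frame(a1, a2, order, flag)).
# V2000 records are parsed and rendered here by fixed-width column, because the
# higher-level SDF container in ChemmineR does not round-trip formal charges.

.ob_opts <- function(..., continue_on_error = TRUE) {
  names <- c(...)
  if (continue_on_error) names <- c(names, "e")
  data.frame(names = names, args = rep("", length(names)))
}

.ob_convert <- function(text, from, to, gen2d = FALSE) {
  opts <- if (gen2d) .ob_opts("gen2D") else .ob_opts()
  suppressWarnings(ChemmineOB::convertFormat(from, to, text, options = opts))
}

# Canonicalize a vector of SMILES. Returns a character vector aligned with the
# input; entries OpenBabel cannot parse come back NA.
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[[:space:]]", trimws(smiles))
  if (!any(ok)) return(out)
  tags <- paste0("x", seq_len(n))
  inp <- paste0(paste(trimws(smiles[ok]), tags[ok]), collapse = "\n")
  res <- .ob_convert(paste0(inp, "\n"), "SMI", "CAN")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got_tag <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, "")
  got_smi <- vapply(parts, `[[`, "", 1L)
  idx <- match(got_tag, tags)
  keep <- !is.na(idx)
  out[idx[keep]] <- got_smi[keep]
  out
}

# SMILES -> list of mol graphs (NA entries for parse failures), aligned with
# input. 2D coordinates are generated so that double-bond and tetrahedral
# stereochemistry survives the SDF leg.
smiles_to_mols <- function(smiles, gen2d = TRUE) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[[:space:]]", trimws(smiles))
  if (!any(ok)) return(out)
  tags <- paste0("x", seq_len(n))
  inp <- paste0(paste(trimws(smiles[ok]), tags[ok]), collapse = "\n")
  sdf <- .ob_convert(paste0(inp, "\n"), "SMI", "SDF", gen2d = gen2d)
  mols <- parse_sdf_text(sdf)
  idx <- match(vapply(mols, `[[`, "", "title"), tags)
  keep <- !is.na(idx)
  out[idx[keep]] <- mols[keep]
  out
}

# Split multi-record SDF text into mol graphs.
parse_sdf_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) .parse_v2000(lines[s:(e - 1L)]),
         starts, ends, SIMPLIFY = FALSE)
}

.parse_v2000 <- function(rec) {
  title <- trimws(rec[1])
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  at <- rec[seq.int(5L, length.out = na)]
  atoms <- data.frame(
    elem = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    chg = .legacy_charge(as.integer(substr(at, 37, 39)))
  )
  bonds <- if (nb > 0L) {
    bl <- rec[seq.int(5L + na, length.out = nb)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)),
      flag = as.integer(substr(bl, 10, 12))
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0), flag = integer(0))
  }
  bonds$flag[is.na(bonds$flag)] <- 0L
  # "M  CHG" property lines override the legacy atom-block charge column
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    atoms$chg <- 0L
    for (ln in chg_lines) {
      v <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "[[:space:]]+")[[1]])
      k <- v[1]
      pairs <- matrix(v[-1], ncol = 2, byrow = TRUE)
      atoms$chg[pairs[, 1]] <- pairs[, 2]
    }
  }
  list(title = title, atoms = atoms, bonds = bonds)
}

.legacy_charge <- function(code) {
  code[is.na(code)] <- 0L
  chg <- integer(length(code))
  known <- code %in% c(1L, 2L, 3L, 5L, 6L, 7L)
  chg[known] <- 4L - code[known]
  chg
}

# Render one mol as a V2000 record (without the "$$$$" terminator). Charges go
# into "M  CHG" lines; bond stereo flags (wedge/hash) are preserved.
mol_to_sdf <- function(mol, title = mol$title) {
  a <- mol$atoms
  b <- mol$bonds
  hdr <- c(title, " scaffchron          2D", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                a$x, a$y, 0, a$elem)
  bl <- if (nrow(b)) sprintf("%3d%3d%3d%3d  0  0  0", b$a1, b$a2, b$order, b$flag) else character(0)
  props <- character(0)
  charged <- which(a$chg != 0L)
  if (length(charged)) {
    # at most 8 atom/charge pairs per M CHG line
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      props <- c(props, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, a$chg[grp]), collapse = "")
      ))
    }
  }
  paste(c(hdr, counts, at, bl, props, "M  END"), collapse = "\n")
}

# list of mols -> canonical SMILES vector (aligned; NA where conversion fails
# or the mol slot is NULL/NA).
mols_to_smiles <- function(mols) {
  n <- length(mols)
  out <- rep(NA_character_, n)
  ok <- vapply(mols, function(m) is.list(m) && nrow(m$atoms) > 0, TRUE)
  if (!any(ok)) return(out)
  tags <- paste0("x", seq_len(n))
  recs <- vapply(which(ok), function(i) mol_to_sdf(mols[[i]], title = tags[i]), "")
  text <- paste0(paste(recs, collapse = "\n$$$$\n"), "\n$$$$\n")
  res <- .ob_convert(text, "SDF", "CAN")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got_tag <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, "")
  got_smi <- vapply(parts, `[[`, "", 1L)
  idx <- match(got_tag, tags)
  keep <- !is.na(idx)
  out[idx[keep]] <- got_smi[keep]
  out
}

# Heavy atoms in a SMILES string, by tokenization (bracket atoms count one;
# two-letter organic-subset symbols matched before one-letter ones).
smiles_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_integer_)
    s <- gsub("\\[[^]]*\\]", "Q", s)           # any bracket atom -> one token
    toks <- gregexpr("Cl|Br|Q|B|C|N|O|P|S|F|I|b|c|n|o|p|s", s)[[1]]
    if (toks[1] == -1L) 0L else length(toks)
  }, 1L, USE.NAMES = FALSE)
}

# Sum of explicit bond orders per atom.
.bond_order_sums <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  b <- mol$bonds
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      s[b$a1[i]] <- s[b$a1[i]] + b$order[i]
      s[b$a2[i]] <- s[b$a2[i]] + b$order[i]
    }
  }
  s
}

.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

# Implicit hydrogen count per atom under standard valences (charge-adjusted).
.implicit_h <- function(mol) {
  v <- .default_valence[mol$atoms$elem]
  v[is.na(v)] <- 0
  pmax(0, v + mol$atoms$chg - .bond_order_sums(mol))
}

# Indices of atoms in the 2-core: iteratively strip degree-<2 atoms.
.two_core <- function(mol) {
  keep <- rep(TRUE, nrow(mol$atoms))
  b <- mol$bonds
  repeat {
    deg <- tabulate(c(b$a1[keep[b$a1] & keep[b$a2]], b$a2[keep[b$a1] & keep[b$a2]]),
                    nbins = nrow(mol$atoms))
    drop <- keep & deg < 2L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  which(keep)
}

# Subset a mol to the given atom indices (bonds renumbered).
.subset_mol <- function(mol, atom_idx) {
  map <- integer(nrow(mol$atoms))
  map[atom_idx] <- seq_along(atom_idx)
  b <- mol$bonds
  keep_b <- b$a1 %in% atom_idx & b$a2 %in% atom_idx
  b <- b[keep_b, , drop = FALSE]
  b$a1 <- map[b$a1]
  b$a2 <- map[b$a2]
  list(title = mol$title, atoms = mol$atoms[atom_idx, , drop = FALSE], bonds = b)
}

# Per-atom ring membership: an atom is in a ring iff it is incident to a bond
# that lies on a cycle (i.e. a non-bridge edge).
.ring_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b) == 0L) return(logical(n))
  g <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  ring_edge <- setdiff(seq_len(nrow(b)), as.integer(br))
  inring <- logical(n)
  inring[c(b$a1[ring_edge], b$a2[ring_edge])] <- TRUE
  inring
}
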