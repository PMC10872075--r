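# SMILES -> molecular graph featurization, ECFP fingerprints, Bemis-Murcko
# scaffolds, and a graph-attention drug encoder producing a drug latent.
#
# Chemistry parsing goes through OpenBabel (ChemmineR/ChemmineOB).  OpenBabel
# silently repairs malformed SMILES, so a syntactic validator runs first and
# rejects inputs with unbalanced brackets or ring-bond digits.

ATOM_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "other")
HYB_LEVELS <- c("sp", "sp2", "sp3", "aromatic", "other")
BOND_LEVELS <- c("single", "double", "triple", "aromatic")

#' Atom and bond feature layout of molecular graphs
#'
#' The layout is fixed and stable across runs: attribution scores are keyed
#' by these names.
#'
#' @return A list with `atom` and `bond` feature name vectors.
#' @export
graph_feature_names <- function() {
  list(
    atom = c(paste0("elem_", ATOM_VOCAB), "degree", "formal_charge",
             paste0("hyb_", HYB_LEVELS), "aromatic", "n_H"),
    bond = c(paste0("bond_", BOND_LEVELS), "conjugated", "in_ring")
  )
}

#' Validate a SMILES string syntactically
#'
#' Checks for an empty string, unbalanced parentheses or brackets, and
#' unmatched ring-closure digits.  The downstream parser is lenient and
#' would otherwise silently truncate malformed input.
#'
#' @param smiles a single SMILES string.
#' @return `smiles`, invisibly; errors on malformed input.
#' @export
validate_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("invalid SMILES: empty input", call. = FALSE)
  }
  s <- trimws(smiles)
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) stop("invalid SMILES '", smiles, "': unbalanced parentheses",
                         call. = FALSE)
  }
  if (depth != 0L) stop("invalid SMILES '", smiles, "': unbalanced parentheses",
                        call. = FALSE)
  nb <- sum(chars == "[") - sum(chars == "]")
  if (nb != 0L) stop("invalid SMILES '", smiles, "': unbalanced brackets",
                     call. = FALSE)
  # ring-closure digits (outside brackets, not %-escaped two-digit labels)
  s_nobr <- gsub("\\[[^]]*\\]", "A", s)
  labels <- c(regmatches(s_nobr, gregexpr("%[0-9]{2}", s_nobr))[[1L]],
              regmatches(gsub("%[0-9]{2}", "", s_nobr),
                         gregexpr("[0-9]", gsub("%[0-9]{2}", "", s_nobr)))[[1L]])
  if (length(labels)) {
    tab <- table(labels)
    if (any(tab %% 2L != 0L)) {
      stop("invalid SMILES '", smiles, "': unmatched ring-closure digit",
           call. = FALSE)
    }
  }
  if (!grepl("[A-Za-z]", s)) {
    stop("invalid SMILES '", smiles, "': no atoms", call. = FALSE)
  }
  invisible(smiles)
}

ob_convert <- function(from, to, source, add_h = FALSE) {
  opts <- if (add_h) data.frame(names = "h", args = "") else NULL
  out <- if (is.null(opts)) ChemmineOB::convertFormat(from, to, source)
         else ChemmineOB::convertFormat(from, to, source, options = opts)
  if (!nzchar(out)) stop("conversion failed for input: ", source, call. = FALSE)
  out
}

#' Canonical SMILES via OpenBabel
#' @param smiles a SMILES string.
#' @return The canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  validate_smiles(smiles)
  out <- ob_convert("SMI", "CAN", smiles)
  trimws(strsplit(out, "[\t\n]")[[1L]][1L])
}

parse_molblock <- function(sdftxt) {
  lines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1L]]
  counts <- lines[4L]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  atom_lines <- lines[seq_len(n_atoms) + 4L]
  elements <- vapply(atom_lines, function(l) trimws(substr(l, 32L, 34L)), "")
  names(elements) <- NULL
  bonds <- if (n_bonds > 0L) {
    bl <- lines[seq_len(n_bonds) + 4L + n_atoms]
    data.frame(i = as.integer(substr(bl, 1L, 3L)),
               j = as.integer(substr(bl, 4L, 6L)),
               order = as.integer(substr(bl, 7L, 9L)))
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  charges <- rep(0L, n_atoms)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1L]])
    n <- f[1L]
    for (k in seq_len(n)) charges[f[2L * k]] <- f[2L * k + 1L]
  }
  list(n_atoms = n_atoms, elements = elements, bonds = bonds, charges = charges)
}

parse_mol2 <- function(mol2txt) {
  lines <- strsplit(mol2txt, "\n", fixed = TRUE)[[1L]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  sect_end <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    if (length(nxt)) min(nxt) - 1L else length(lines)
  }
  atom_lines <- lines[(a0 + 1L):sect_end(a0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "\\s+")
  types <- vapply(af, `[`, "", 6L)
  bond_lines <- if (length(b0) && sect_end(b0) > b0) {
    bl <- lines[(b0 + 1L):sect_end(b0)]
    bl[nzchar(trimws(bl))]
  } else character(0)
  bf <- strsplit(trimws(bond_lines), "\\s+")
  bonds <- if (length(bf)) {
    data.frame(i = as.integer(vapply(bf, `[`, "", 2L)),
               j = as.integer(vapply(bf, `[`, "", 3L)),
               type = vapply(bf, `[`, "", 4L))
  } else data.frame(i = integer(0), j = integer(0), type = character(0))
  list(types = types, bonds = bonds)
}

#' Featurize a SMILES string into a molecular graph
#'
#' Heavy atoms only (hydrogens implicit, counted per atom).  Atom features:
#' element one-hot over a fixed vocabulary (out-of-vocabulary elements map to
#' "other" with a warning), heavy-atom degree, formal charge, hybridization
#' one-hot, aromatic flag, total hydrogen count.  Bond features: bond-type
#' one-hot, conjugation flag, ring-membership flag.  Each bond is stored
#' once; consumers expand it symmetrically.
#'
#' @param smiles a SMILES string.
#' @return An object of class `molecular_graph`.
#' @export
featurize_smiles <- function(smiles) {
  validate_smiles(smiles)
  sdf <- parse_molblock(ob_convert("SMI", "SDF", smiles))
  if (sdf$n_atoms == 0L) stop("invalid SMILES '", smiles, "': no atoms",
                              call. = FALSE)
  m2 <- parse_mol2(ob_convert("SMI", "MOL2", smiles))
  m2h <- parse_mol2(ob_convert("SMI", "MOL2", smiles, add_h = TRUE))
  n <- sdf$n_atoms
  stopifnot(length(m2$types) == n)

  elems <- sdf$elements
  vocab_idx <- match(elems, ATOM_VOCAB)
  if (anyNA(vocab_idx)) {
    warning("out-of-vocabulary element(s) mapped to 'other': ",
            paste(unique(elems[is.na(vocab_idx)]), collapse = ", "))
    vocab_idx[is.na(vocab_idx)] <- length(ATOM_VOCAB)
  }

  # hydrogen counts from the explicit-H conversion (H atoms appended last)
  n_H <- rep(0L, n)
  if (nrow(m2h$bonds)) {
    h_atoms <- which(m2h$types == "H")
    for (r in seq_len(nrow(m2h$bonds))) {
      i <- m2h$bonds$i[r]; j <- m2h$bonds$j[r]
      if (i <= n && j %in% h_atoms) n_H[i] <- n_H[i] + 1L
      if (j <= n && i %in% h_atoms) n_H[j] <- n_H[j] + 1L
    }
  }

  suffix <- sub("^[^.]*\\.?", "", m2$types)   # "" when untyped (e.g. halogens)
  hyb <- ifelse(suffix == "1", "sp",
         ifelse(suffix %in% c("2", "am", "pl3", "cat"), "sp2",
         ifelse(suffix == "3", "sp3",
         ifelse(suffix == "ar", "aromatic", "other"))))
  aromatic_atom <- hyb == "aromatic"

  degree <- tabulate(c(sdf$bonds$i, sdf$bonds$j), nbins = n)

  # ring bonds = non-bridge edges of the heavy-atom graph
  in_ring <- rep(FALSE, nrow(sdf$bonds))
  if (nrow(sdf$bonds)) {
    g <- igraph::graph_from_data_frame(sdf$bonds[, c("i", "j")],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    br <- igraph::bridges(g)
    in_ring <- !(seq_len(nrow(sdf$bonds)) %in% as.integer(br))
  }

  fn <- graph_feature_names()
  A <- matrix(0, n, length(fn$atom), dimnames = list(NULL, fn$atom))
  A[cbind(seq_len(n), vocab_idx)] <- 1
  A[, "degree"] <- degree
  A[, "formal_charge"] <- sdf$charges
  A[cbind(seq_len(n), length(ATOM_VOCAB) + 2L + match(hyb, HYB_LEVELS))] <- 1
  A[, "aromatic"] <- as.numeric(aromatic_atom)
  A[, "n_H"] <- n_H

  bonds <- sdf$bonds
  B <- matrix(0, nrow(bonds), length(fn$bond), dimnames = list(NULL, fn$bond))
  if (nrow(bonds)) {
    m2b <- m2$bonds
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    m2type <- m2b$type[match(key(bonds$i, bonds$j), key(m2b$i, m2b$j))]
    btype <- ifelse(!is.na(m2type) & m2type == "ar", "aromatic",
             ifelse(bonds$order == 2L, "double",
             ifelse(bonds$order == 3L, "triple", "single")))
    B[cbind(seq_len(nrow(bonds)), match(btype, BOND_LEVELS))] <- 1
    sp2ish <- hyb %in% c("sp", "sp2", "aromatic")
    B[, "conjugated"] <- as.numeric(btype == "aromatic" |
                                      (sp2ish[bonds$i] & sp2ish[bonds$j]))
    B[, "in_ring"] <- as.numeric(in_ring)
  }

  structure(list(n_atoms = n, elements = elems,
                 atom_features = A,
                 bonds = bonds[, c("i", "j")],
                 bond_order = bonds$order,
                 bond_features = B,
                 smiles = smiles,
                 canonical = canonical_smiles(smiles)),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d atoms, %d bonds, '%s'>\n",
              x$n_atoms, nrow(x$bonds), x$canonical))
  invisible(x)
}

#' Extended-connectivity fingerprint
#'
#' Circular substructure fingerprint of the given radius, folded to
#' `n_bits` by OR-ing congruent positions.  Deterministic and invariant to
#' the SMILES spelling of a molecule.
#'
#' @param smiles a SMILES string.
#' @param radius circular neighborhood radius (default 2, i.e. ECFP4).
#' @param n_bits folded fingerprint length (default 2048).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
ecfp <- function(smiles, radius = 2, n_bits = 2048) {
  validate_smiles(smiles)
  stopifnot(radius %in% 0:5, n_bits >= 16)
  mol <- ChemmineOB::forEachMol("SMILES", canonical_smiles(smiles), identity)
  bits <- as.numeric(ChemmineOB::fingerprint_OB(mol, sprintf("ECFP%d", 2L * radius)))
  folded <- integer(n_bits)
  idx <- ((seq_along(bits) - 1L) %% n_bits) + 1L
  folded[unique(idx[bits > 0])] <- 1L
  folded
}

#' Count SMARTS substructure matches in a molecule
#'
#' @param smiles a SMILES string.
#' @param pattern a SMARTS pattern.
#' @return Number of unique matches (integer).
#' @export
smarts_matches <- function(smiles, pattern) {
  validate_smiles(smiles)
  mol <- ChemmineOB::forEachMol("SMILES", canonical_smiles(smiles), identity)
  as.integer(ChemmineOB::smartsSearch_OB(mol, pattern, uniqueMatches = TRUE))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively prunes terminal atoms attached by single bonds, leaving ring
#' systems, linkers, and exocyclic multiply-bonded atoms; the remaining
#' substructure is canonicalized.  Acyclic molecules have no scaffold and
#' map to the sentinel `"ACYCLIC:<canonical smiles>"` so each forms its own
#' group under scaffold-based splitting.
#'
#' @param smiles a SMILES string.
#' @return Canonical scaffold identifier string.
#' @export
murcko_scaffold <- function(smiles) {
  g <- featurize_smiles(smiles)
  if (!nrow(g$bonds) || !any(g$bond_features[, "in_ring"] > 0)) {
    return(paste0("ACYCLIC:", g$canonical))
  }
  keep <- rep(TRUE, g$n_atoms)
  bonds <- cbind(g$bonds$i, g$bonds$j)
  order <- g$bond_order
  repeat {
    alive <- which(keep)
    deg <- tabulate(c(bonds[, 1L][keep[bonds[, 1L]] & keep[bonds[, 2L]]],
                      bonds[, 2L][keep[bonds[, 1L]] & keep[bonds[, 2L]]]),
                    nbins = g$n_atoms)
    drop <- integer(0)
    for (a in alive) {
      if (deg[a] != 1L) next
      b <- which((bonds[, 1L] == a | bonds[, 2L] == a) &
                   keep[bonds[, 1L]] & keep[bonds[, 2L]])
      if (length(b) == 1L && order[b] == 1L) drop <- c(drop, a)
    }
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  sub_atoms <- which(keep)
  remap <- match(seq_len(g$n_atoms), sub_atoms)
  bkeep <- keep[bonds[, 1L]] & keep[bonds[, 2L]]
  block <- build_molblock(g$elements[sub_atoms],
                          cbind(remap[bonds[bkeep, 1L]],
                                remap[bonds[bkeep, 2L]]),
                          order[bkeep],
                          g$atom_features[sub_atoms, "formal_charge"])
  out <- ob_convert("SDF", "CAN", block)
  trimws(strsplit(out, "[\t\n]")[[1L]][1L])
}

# Minimal V2000 molblock writer (dummy coordinates; connectivity only).
build_molblock <- function(elements, bonds, orders, charges) {
  n <- length(elements)
  nb <- nrow(bonds)
  lines <- c("", " drpfuse scaffold", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, elements[a]))
  }
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds[b, 1L], bonds[b, 2L], orders[b]))
  }
  chg <- which(charges != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, charges[chg]),
                                    collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

#' Write a drug -> scaffold audit table
#' @param catalog drug catalog data frame (`name`, `smiles`).
#' @param path output TSV path.
#' @return The scaffold table, invisibly.
#' @export
write_scaffold_table <- function(catalog, path) {
  tab <- data.frame(drug = catalog$name,
                    scaffold = vapply(catalog$smiles, murcko_scaffold, ""),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
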