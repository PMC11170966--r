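# Internal molecule model used by the substructure matcher.
#
# Perception is delegated to OpenBabel: a molecule enters as its OpenBabel
# canonical SMILES, is converted to an SDF block (kekulized bond orders,
# old-style charge codes), and aromaticity is read back from the canonical
# SMILES atom tokens (lowercase = aromatic), whose order OpenBabel preserves
# in the SDF atom block.  Implicit hydrogens are recomputed from standard
# valences, bond-order sums, and formal charges.

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                     Cl = 1, Br = 1, I = 1, Se = 2, As = 3, Si = 4)

# tokenize a SMILES string into its atom symbols, in writing order
smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elem <- character(0)
  arom <- logical(0)
  i <- 1L
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec("^[0-9]*([A-Za-z][a-z]?)", body))[[1]]
      sym <- m[2]
      # bracket atoms: "nH" parses as element n + H; two-letter aromatic
      # elements (se, as) and genuine two-letter elements kept as written
      if (nchar(sym) == 2 && !(sym %in% names(DEFAULT_VALENCE)) &&
          !(sym %in% c("se", "as"))) {
        sym <- substr(sym, 1, 1)
      }
      is_arom <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      base <- if (is_arom) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      elem <- c(elem, base)
      arom <- c(arom, is_arom)
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      nxt <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (nxt %in% two_letter) {
        elem <- c(elem, nxt)
        arom <- c(arom, FALSE)
        i <- i + 2L
      } else {
        elem <- c(elem, ch)
        arom <- c(arom, FALSE)
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elem <- c(elem, toupper(ch))
      arom <- c(arom, TRUE)
      i <- i + 1L
    } else if (ch == "*") {
      elem <- c(elem, "*")
      arom <- c(arom, FALSE)
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L                       # two-digit ring-bond label
    } else {
      i <- i + 1L                       # bonds, digits, parens, stereo marks
    }
  }
  data.frame(elem = elem, arom = arom, stringsAsFactors = FALSE)
}

# MDL charge codes (atom-block column 6)
.mdl_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

# parse one SDF block (character lines) into atoms/bonds with formal charges
parse_sdf_block <- function(lines) {
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n_atoms)]
  fields <- strsplit(trimws(atom_lines), "\\s+")
  elem <- vapply(fields, function(f) f[4], character(1))
  chg <- vapply(fields, function(f) .mdl_charge[f[6]], numeric(1))
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    a <- as.integer(substr(bond_lines, 1, 3))
    b <- as.integer(substr(bond_lines, 4, 6))
    o <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a <- b <- o <- integer(0)
  }
  # "M  CHG" property lines override the atom-block charge column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines) > 0) {
    chg[] <- 0
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
      k <- f[1]
      for (p in seq_len(k)) chg[f[2 * p]] <- f[2 * p + 1]
    }
  }
  list(elem = elem, charge = chg, bonds = data.frame(a = a, b = b, order = o))
}

#' @noRd
mol_graph <- function(smiles_canonical) {
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                       paste0(smiles_canonical, "\tm\n"))
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  blk <- parse_sdf_block(lines)
  toks <- smiles_atom_tokens(smiles_canonical)
  if (nrow(toks) != length(blk$elem)) {
    stop("internal atom-order mismatch between SMILES tokens and SDF block for: ",
         smiles_canonical)
  }
  n <- length(blk$elem)
  arom_atom <- toks$arom
  bonds <- blk$bonds

  # ring bonds = non-bridge edges; aromatic bonds = ring bonds joining two
  # aromatic atoms
  ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a, bonds$b), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_bond[-as.integer(br)] <- TRUE
    if (length(br) == 0) ring_bond[] <- TRUE
  }
  bond_arom <- ring_bond & arom_atom[bonds$a] & arom_atom[bonds$b]

  heavy <- tabulate(c(bonds$a, bonds$b), nbins = n)
  order_sum <- rep(0L, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      order_sum[bonds$a[k]] <- order_sum[bonds$a[k]] + bonds$order[k]
      order_sum[bonds$b[k]] <- order_sum[bonds$b[k]] + bonds$order[k]
    }
  }
  val <- DEFAULT_VALENCE[blk$elem]
  val[is.na(val)] <- 0
  nH <- pmax(0L, as.integer(val + blk$charge - order_sum))
  ring_atom <- rep(FALSE, n)
  ring_atom[unique(c(bonds$a[ring_bond], bonds$b[ring_bond]))] <- TRUE

  adj <- vector("list", n)
  badj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], bonds$b[k])
      adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], bonds$a[k])
      badj[[bonds$a[k]]] <- c(badj[[bonds$a[k]]], k)
      badj[[bonds$b[k]]] <- c(badj[[bonds$b[k]]], k)
    }
  }
  structure(list(
    atoms = data.frame(elem = blk$elem, arom = arom_atom, charge = blk$charge,
                       nH = nH, heavy = heavy, ring = ring_atom,
                       stringsAsFactors = FALSE),
    bonds = cbind(bonds, arom = bond_arom),
    adj = adj, badj = badj,
    smiles = smiles_canonical
  ), class = "mol_graph")
}

# count non-hydrogen atoms in a SMILES fragment (used for salt stripping)
count_heavy_atoms <- function(smiles) {
  toks <- smiles_atom_tokens(smiles)
  sum(toks$elem != "H")
}

# permute atom numbering of a mol_graph (testing aid: matching must be
# invariant to input atom order)
permute_mol_graph <- function(mg, perm) {
  n <- nrow(mg$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)
  atoms <- mg$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mg$bonds
  bonds$a <- inv[bonds$a]
  bonds$b <- inv[bonds$b]
  adj <- vector("list", n)
  badj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], bonds$b[k])
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], bonds$a[k])
    badj[[bonds$a[k]]] <- c(badj[[bonds$a[k]]], k)
    badj[[bonds$b[k]]] <- c(badj[[bonds$b[k]]], k)
  }
  structure(list(atoms = atoms, bonds = bonds, adj = adj, badj = badj,
                 smiles = mg$smiles), class = "mol_graph")
}
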