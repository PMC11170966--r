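# Substructure match engine.
#
# Patterns are small labelled graphs (atom predicates + typed bonds), the
# in-code equivalents of the registry's SMARTS strings.  Matching is
# subgraph monomorphism by backtracking: pattern atoms are visited in a
# connectivity-preserving order starting from the most selective atom, and
# automorphic matches covering the same molecule atom set are collapsed to
# one (non-redundant counting).

# atom predicate constructor; NA means "unconstrained"
p_atom <- function(elem = NULL, arom = NA, hmin = 0L, hmax = Inf,
                   heavy = NA, xtot = NA, ring = NA, charge = 0,
                   not_acyl = FALSE) {
  list(elem = elem, arom = arom, hmin = hmin, hmax = hmax, heavy = heavy,
       xtot = xtot, ring = ring, charge = charge, not_acyl = not_acyl)
}

# bond types: "-" single (non-aromatic), "=" double, "#" triple,
# ":" aromatic, "~" any
p_bonds <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(a = as.integer(m[, 1]), b = as.integer(m[, 2]), type = m[, 3],
             stringsAsFactors = FALSE)
}

pattern_graph <- function(atoms, bonds) {
  stopifnot(max(bonds$a, bonds$b) <= length(atoms))
  list(atoms = atoms, bonds = bonds)
}

atom_matches <- function(mg, i, spec) {
  at <- mg$atoms
  if (!is.null(spec$elem) && !(at$elem[i] %in% spec$elem)) return(FALSE)
  if (!is.na(spec$arom) && at$arom[i] != spec$arom) return(FALSE)
  if (!is.na(spec$charge) && at$charge[i] != spec$charge) return(FALSE)
  if (at$nH[i] < spec$hmin || at$nH[i] > spec$hmax) return(FALSE)
  if (!is.na(spec$heavy) && at$heavy[i] != spec$heavy) return(FALSE)
  if (!is.na(spec$xtot) && (at$heavy[i] + at$nH[i]) != spec$xtot) return(FALSE)
  if (!is.na(spec$ring) && at$ring[i] != spec$ring) return(FALSE)
  if (isTRUE(spec$not_acyl)) {
    for (j in mg$adj[[i]]) {
      if (at$elem[j] == "C") {
        ks <- mg$badj[[j]]
        for (k in ks) {
          other <- if (mg$bonds$a[k] == j) mg$bonds$b[k] else mg$bonds$a[k]
          if (mg$bonds$order[k] == 2 && at$elem[other] == "O") return(FALSE)
        }
      }
    }
  }
  TRUE
}

bond_matches <- function(mg, k, type) {
  switch(type,
    "-" = mg$bonds$order[k] == 1 && !mg$bonds$arom[k],
    "=" = mg$bonds$order[k] == 2 && !mg$bonds$arom[k],
    "#" = mg$bonds$order[k] == 3 && !mg$bonds$arom[k],
    ":" = mg$bonds$arom[k],
    "~" = TRUE,
    stop("unknown bond type: ", type))
}

# find molecule bond index between atoms i and j (0 if none)
find_bond <- function(mg, i, j) {
  for (k in mg$badj[[i]]) {
    if (mg$bonds$a[k] == j || mg$bonds$b[k] == j) return(k)
  }
  0L
}

#' @noRd
match_pattern <- function(mg, pg, unique_sets = TRUE) {
  np <- length(pg$atoms)
  nm <- nrow(mg$atoms)
  if (np == 0L || nm < np) return(list())

  cand <- lapply(seq_len(np), function(p) {
    which(vapply(seq_len(nm), function(i) atom_matches(mg, i, pg$atoms[[p]]),
                 logical(1)))
  })
  if (any(vapply(cand, length, integer(1)) == 0L)) return(list())

  # pattern adjacency
  padj <- vector("list", np)
  for (r in seq_len(nrow(pg$bonds))) {
    a <- pg$bonds$a[r]; b <- pg$bonds$b[r]
    padj[[a]] <- rbind(padj[[a]], c(b, r))
    padj[[b]] <- rbind(padj[[b]], c(a, r))
  }

  # visit order: most selective anchor, then breadth-first over the pattern
  start <- which.min(vapply(cand, length, integer(1)))
  order_p <- start
  seen <- rep(FALSE, np); seen[start] <- TRUE
  repeat {
    frontier <- integer(0)
    for (p in order_p) {
      if (!is.null(padj[[p]])) {
        nb <- padj[[p]][, 1]
        frontier <- c(frontier, nb[!seen[nb]])
      }
    }
    frontier <- unique(frontier)
    if (length(frontier) == 0L) break
    seen[frontier] <- TRUE
    order_p <- c(order_p, frontier)
  }
  if (length(order_p) < np) {
    stop("pattern graph is disconnected")      # registry invariant
  }

  results <- list()
  assign_vec <- rep(NA_integer_, np)
  used <- rep(FALSE, nm)

  recurse <- function(step) {
    if (step > np) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    p <- order_p[step]
    # molecule candidates: constrain through already-assigned neighbours
    pool <- cand[[p]]
    anchored <- FALSE
    if (!is.null(padj[[p]])) {
      for (r in seq_len(nrow(padj[[p]]))) {
        q <- padj[[p]][r, 1]
        if (!is.na(assign_vec[q])) {
          anchored <- TRUE
          mi <- assign_vec[q]
          pool <- pool[pool %in% mg$adj[[mi]]]
        }
      }
    }
    if (step > 1L && !anchored) pool <- integer(0)  # unreachable by order
    for (m in pool) {
      if (used[m]) next
      ok <- TRUE
      if (!is.null(padj[[p]])) {
        for (r in seq_len(nrow(padj[[p]]))) {
          q <- padj[[p]][r, 1]; br <- padj[[p]][r, 2]
          if (!is.na(assign_vec[q])) {
            k <- find_bond(mg, m, assign_vec[q])
            if (k == 0L || !bond_matches(mg, k, pg$bonds$type[br])) {
              ok <- FALSE; break
            }
          }
        }
      }
      if (!ok) next
      assign_vec[p] <<- m
      used[m] <<- TRUE
      recurse(step + 1L)
      assign_vec[p] <<- NA_integer_
      used[m] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)

  if (unique_sets && length(results) > 1L) {
    keys <- vapply(results, function(v) paste(sort(v), collapse = ","),
                   character(1))
    results <- results[!duplicated(keys)]
  }
  results
}
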