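# Matching molecules against the functional-group registry.

#' Match one molecule against the pattern registry
#'
#' Evaluates every pattern on a molecule and returns non-redundant match
#' counts together with the matched atom-index sets.  Matches that cover the
#' same atom set through a symmetry of the pattern are counted once.
#'
#' @param record A single-row `mol_records` table, or a canonical SMILES
#'   string (optionally named with the record id).
#' @param patterns A `pattern_registry` from [load_default_patterns()].
#' @return A `match_profile`: list with `record_id`, `counts` (named integer
#'   vector over all group names) and `matched_atoms` (named list of lists
#'   of integer atom-index vectors; `NULL` for override patterns matched via
#'   the SMARTS engine, which does not report atom maps).
#' @examples
#' prof <- match_groups("CC(=O)NO", load_default_patterns())
#' prof$counts[["hydroxamate"]]   # 1
#' @export
match_groups <- function(record, patterns = load_default_patterns()) {
  if (is.character(record)) {
    id <- names(record) %||% record
    # raw strings are canonicalized so aromaticity perception and atom
    # indices always refer to the canonical form
    smi <- unname(canonicalize(record))
  } else {
    stopifnot(nrow(record) == 1L)
    id <- record$record_id
    smi <- record$smiles_canonical
  }
  mg <- mol_graph(smi)
  nm <- pattern_names(patterns)
  counts <- setNames(integer(length(patterns)), nm)
  matched <- setNames(vector("list", length(patterns)), nm)
  need_ob <- which(vapply(patterns, function(p) is.null(p$graph), logical(1)))
  for (i in seq_along(patterns)) {
    if (i %in% need_ob) next
    hits <- match_pattern(mg, patterns[[i]]$graph, unique_sets = TRUE)
    counts[i] <- length(hits)
    matched[[i]] <- lapply(hits, function(v) sort(unname(v)))
  }
  if (length(need_ob) > 0) {
    sdf <- ChemmineR::smiles2sdf(setNames(smi, "m"))
    for (i in need_ob) {
      counts[i] <- as.integer(
        ChemmineR::smartsSearchOB(sdf, patterns[[i]]$smarts,
                                  uniqueMatches = TRUE))
      matched[i] <- list(NULL)
    }
  }
  structure(list(record_id = id, counts = counts, matched_atoms = matched),
            class = "match_profile")
}

#' @export
print.match_profile <- function(x, ...) {
  cat("<match_profile>", x$record_id, "\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz) == 0) cat("  no pattern matches\n")
  else for (g in names(nz)) cat(sprintf("  %-36s %d\n", g, nz[g]))
  invisible(x)
}

#' Functional-group count matrix for a library
#'
#' @param records A `mol_records` table.
#' @param patterns A `pattern_registry`.
#' @return Integer matrix, one row per record (rownames = `record_id`), one
#'   column per group name.
#' @export
count_matrix <- function(records, patterns = load_default_patterns()) {
  nm <- pattern_names(patterns)
  if (nrow(records) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = length(nm),
                  dimnames = list(NULL, nm)))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    match_groups(records[i, , drop = FALSE], patterns)$counts
  })
  m <- do.call(rbind, rows)
  rownames(m) <- records$record_id
  m
}
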