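# Reproduction helpers for deposit-scale analyses.
#
# The published reference corpus (the curated siderophore record table and
# its cluster assignments, deposited alongside the original study) and a
# COCONUT-scale background library are inputs the user supplies locally;
# this package ships only download-free fixtures.  These helpers run the
# package's own pipeline over such files.  By default they look for files
# under the directory named by `options(sideroscreen.deposit_dir=)`
# ("data-external" relative to the working directory if unset).

#' Directory searched for locally supplied reference data
#' @return Path (not required to exist).
#' @export
deposit_dir <- function() {
  getOption("sideroscreen.deposit_dir", "data-external")
}

#' Deduplicate a deposited record table
#'
#' Reads a record table (e.g. the 872-record curated siderophore deposit),
#' canonicalizes, deduplicates, and reports the unique-structure count.
#'
#' @param path CSV/TSV with at least an id, a name, and a SMILES column.
#' @param id_col,name_col,smiles_col Column names in the file.
#' @param ... Passed to [canonicalize()] (e.g. `keep_stereo`).
#' @return List with `n_records`, `n_unique`, and the merged `records`.
#' @export
reproduce_dedup <- function(path, id_col = "id", name_col = "name",
                            smiles_col = "smiles", ...) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", fileEncoding = "UTF-8")
  assert_cols(tab, c(id_col, name_col, smiles_col), basename(path))
  recs <- mol_records(record_id = as.character(tab[[id_col]]),
                      smiles = tab[[smiles_col]],
                      name = tab[[name_col]], source_tag = "knownset", ...)
  uniq <- deduplicate(recs)
  list(n_records = nrow(recs), n_unique = nrow(uniq), records = uniq)
}

#' Functional-group prevalence per deposited cluster
#'
#' Given a table of structures with published cluster assignments, computes
#' for each cluster the percentage of member structures containing each
#' functional group at least once (isolating the matcher from the
#' clustering).
#'
#' @param path CSV/TSV with a SMILES column and a cluster column.
#' @param smiles_col,cluster_col Column names in the file.
#' @param patterns A `pattern_registry`.
#' @return List with `prevalence` (matrix cluster x group, percent of
#'   members matching) and `counts` (matrix cluster x group, number of
#'   members matching) and `cluster_sizes`.
#' @export
cluster_group_prevalence <- function(path, smiles_col = "smiles",
                                     cluster_col = "cluster",
                                     patterns = load_default_patterns()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", fileEncoding = "UTF-8")
  assert_cols(tab, c(smiles_col, cluster_col), basename(path))
  recs <- mol_records(record_id = sprintf("s%04d", seq_len(nrow(tab))),
                      smiles = tab[[smiles_col]], source_tag = "knownset")
  cm <- count_matrix(recs, patterns)
  cl <- tab[[cluster_col]]
  sizes <- table(cl)
  has <- cm > 0
  counts <- rowsum(has + 0L, group = cl)
  prevalence <- sweep(counts, 1, as.numeric(sizes[rownames(counts)]),
                      "/") * 100
  list(prevalence = prevalence, counts = counts,
       cluster_sizes = as.integer(sizes[rownames(counts)]))
}
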