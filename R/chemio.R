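# Library I/O, canonical-SMILES identity, record merging, atom statistics.
#
# Structure identity is defined as equality of OpenBabel canonical SMILES
# after (1) stripping salts/solvents to the largest covalent fragment and
# (2) neutralizing simple protonation states, so that carboxylate and
# carboxylic-acid spellings collapse.  Stereochemistry is retained by
# default: stereoisomeric siderophores are distinct structures.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES.  Multi-fragment inputs
#' (salts, solvates) are stripped to the largest covalent fragment, and
#' simple protonation states are neutralized, before canonicalization.
#' Canonicalization is idempotent: applying it to its own output returns
#' the same string.
#'
#' @param smiles Character vector of SMILES.  Names, if present, are used to
#'   identify offending records in error messages.
#' @param strip_salts Keep only the largest covalent fragment (by heavy-atom
#'   count) of multi-fragment inputs.  Every stripped fragment is reported
#'   via [message()].
#' @param neutralize Neutralize simple protonation states (e.g. carboxylate
#'   to carboxylic acid) before canonicalization.
#' @param keep_stereo Retain stereochemistry (default).  When `FALSE`,
#'   stereo marks are removed first, collapsing stereoisomers -- useful for
#'   sensitivity analysis of deduplication counts.
#' @return Character vector of canonical SMILES, same length and names.
#' @examples
#' canonicalize(c("OCC", "C(C)O"))   # both spellings of ethanol agree
#' @export
canonicalize <- function(smiles, strip_salts = TRUE, neutralize = TRUE,
                         keep_stereo = TRUE) {
  if (length(smiles) == 0L) return(character(0))
  ids <- names(smiles) %||% as.character(seq_along(smiles))
  x <- as.character(smiles)
  if (!keep_stereo) {
    x <- gsub("@", "", x, fixed = TRUE)
    x <- gsub("[/\\\\]", "", x)
  }
  if (strip_salts) {
    multi <- grepl(".", x, fixed = TRUE)
    for (i in which(multi)) {
      frags <- strsplit(x[i], ".", fixed = TRUE)[[1]]
      sizes <- vapply(frags, count_heavy_atoms, numeric(1))
      keep <- which.max(sizes)
      message(sprintf("record '%s': stripped %d fragment(s) [%s]", ids[i],
                      length(frags) - 1L,
                      paste(frags[-keep], collapse = ", ")))
      x[i] <- frags[keep]
    }
  }
  opts <- if (neutralize) {
    data.frame(names = "neutralize", args = "", stringsAsFactors = FALSE)
  } else {
    data.frame(names = character(0), args = character(0))
  }
  src <- paste0(x, "\t", seq_along(x), "\n", collapse = "")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", src, options = opts))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[2] %||% NA_character_, character(1))
  can <- vapply(parts, `[[`, "", 1)
  res <- rep(NA_character_, length(x))
  idx <- match(as.character(seq_along(x)), got)
  res <- can[idx]
  if (anyNA(res)) {
    bad <- ids[is.na(res)]
    stop("unparsable SMILES for record(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  names(res) <- names(smiles)
  res
}

#' Construct a molecule record table
#'
#' The record table is the package's library container: a `data.frame` with
#' columns `record_id`, `name`, `other_names` (pipe-separated),
#' `smiles_raw`, `smiles_canonical`, `biosynthetic_type` (one of `NRPS`,
#' `NIS`, `NRPS+NIS`, `PKS-hybrid`, `unknown`) and `source_tag` (one of
#' `knownset`, `background`, `query`).
#'
#' @param record_id Unique identifiers.
#' @param smiles Raw SMILES strings.
#' @param name Display names (defaults to `record_id`).
#' @param other_names Pipe-separated alternative names.
#' @param biosynthetic_type,source_tag Enumerated annotations.
#' @param canonicalize Compute `smiles_canonical` (default); set to `FALSE`
#'   only when a canonical column is supplied separately.
#' @param ... Passed on to [canonicalize()].
#' @return A `data.frame` of class `mol_records`.
#' @export
mol_records <- function(record_id, smiles, name = record_id,
                        other_names = "", biosynthetic_type = "unknown",
                        source_tag = "query", canonicalize = TRUE, ...) {
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id)) {
    stop("duplicate record_id: ",
         paste(unique(record_id[duplicated(record_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(biosynthetic_type), BIOSYNTHETIC_TYPES)
  if (length(bad) > 0) stop("unknown biosynthetic_type: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(source_tag), SOURCE_TAGS)
  if (length(bad) > 0) stop("unknown source_tag: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(
    record_id = record_id,
    name = rep_len(as.character(name), length(record_id)),
    other_names = rep_len(as.character(other_names), length(record_id)),
    smiles_raw = as.character(smiles),
    smiles_canonical = NA_character_,
    biosynthetic_type = rep_len(biosynthetic_type, length(record_id)),
    source_tag = rep_len(source_tag, length(record_id)),
    stringsAsFactors = FALSE)
  if (canonicalize) {
    df$smiles_canonical <- canonicalize(setNames(df$smiles_raw,
                                                 df$record_id), ...)
  }
  class(df) <- c("mol_records", "data.frame")
  df
}

#' Deduplicate a record table by canonical SMILES
#'
#' Records sharing a canonical SMILES are merged into one: the
#' representative's name becomes the official `name` and all other names are
#' appended to `other_names`.
#'
#' @param records A `mol_records` table with `smiles_canonical` filled in.
#' @param prefer `"first"` keeps the first-seen record as representative
#'   (deterministic given input order); `"lexicographic"` keeps the record
#'   whose `record_id` sorts first, for inputs whose order carries no
#'   meaning.
#' @return A merged `mol_records` table, one row per unique structure, in
#'   order of first appearance of each structure.
#' @examples
#' recs <- mol_records(c("a", "b", "c"), c("CCO", "OCC", "CC=O"))
#' deduplicate(recs)   # 2 unique structures; "b" merged into "a"
#' @export
deduplicate <- function(records, prefer = c("first", "lexicographic")) {
  prefer <- match.arg(prefer)
  assert_cols(records, c("record_id", "name", "other_names",
                         "smiles_canonical"), "record table")
  if (nrow(records) == 0L) return(records)
  if (anyNA(records$smiles_canonical)) {
    stop("records must be canonicalized before deduplication")
  }
  groups <- split(seq_len(nrow(records)), records$smiles_canonical)
  # preserve first-appearance order of structures
  first_pos <- vapply(groups, min, numeric(1))
  groups <- groups[order(first_pos)]
  rows <- lapply(groups, function(ix) {
    sub <- records[ix, , drop = FALSE]
    rep_i <- if (prefer == "first") 1L else order(sub$record_id)[1L]
    others <- unique(c(
      unlist(lapply(sub$other_names, split_pipes), use.names = FALSE),
      sub$name[-rep_i]))
    others <- setdiff(others, sub$name[rep_i])
    out <- sub[rep_i, , drop = FALSE]
    out$other_names <- join_pipes(others)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("mol_records", "data.frame")
  res
}

#' Read a molecule library
#'
#' @param path File path.
#' @param format `"smiles-table"` (CSV/TSV with required columns
#'   `id`, `name`, `smiles` and optional `other_names`, `biosynthetic_type`,
#'   `source_tag`), `"sdf"` (MDL SD file), or `"auto"` to infer from the
#'   extension.
#' @param canonicalize Compute canonical SMILES on read (default).
#' @param ... Passed on to [canonicalize()].
#' @return A `mol_records` table.
#' @export
read_library <- function(path, format = c("auto", "smiles-table", "sdf"),
                         canonicalize = TRUE, ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles-table"
  }
  if (format == "smiles-table") {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      comment.char = "#", fileEncoding = "UTF-8")
    assert_cols(tab, c("id", "name", "smiles"), basename(path))
    if (anyDuplicated(tab$id)) {
      stop(sprintf("%s: duplicate record id(s): %s", basename(path),
                   paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")),
           call. = FALSE)
    }
    mol_records(
      record_id = tab$id, smiles = tab$smiles, name = tab$name,
      other_names = if ("other_names" %in% names(tab)) {
        ifelse(is.na(tab$other_names), "", tab$other_names)
      } else "",
      biosynthetic_type = if ("biosynthetic_type" %in% names(tab)) {
        ifelse(is.na(tab$biosynthetic_type) | !nzchar(tab$biosynthetic_type),
               "unknown", tab$biosynthetic_type)
      } else "unknown",
      source_tag = if ("source_tag" %in% names(tab)) tab$source_tag
                   else "query",
      canonicalize = canonicalize, ...)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    if (!all(valid)) {
      stop(sprintf("%s: malformed SDF block at index/indices: %s",
                   basename(path),
                   paste(which(!valid), collapse = ", ")), call. = FALSE)
    }
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    nms <- vapply(seq_along(sdf), function(i) {
      h <- ChemmineR::header(sdf[[i]])[1]
      if (is.na(h) || !nzchar(h)) sprintf("mol%04d", i) else h
    }, character(1))
    ids <- make.unique(nms, sep = "_")
    mol_records(record_id = ids, smiles = smi, name = nms,
                canonicalize = canonicalize, ...)
  }
}

#' Write a molecule library
#'
#' @param records A `mol_records` table.
#' @param path Output path.
#' @param format `"smiles-table"` (CSV or TSV by extension), `"sdf"`, or
#'   `"auto"`.
#' @param header Optional named character vector serialized as
#'   `# key=value` comment lines above a smiles-table (run metadata).
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path,
                          format = c("auto", "smiles-table", "sdf"),
                          header = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles-table"
  }
  if (format == "smiles-table") {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- data.frame(id = records$record_id, name = records$name,
                     smiles = records$smiles_canonical,
                     other_names = records$other_names,
                     biosynthetic_type = records$biosynthetic_type,
                     source_tag = records$source_tag,
                     stringsAsFactors = FALSE)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) {
      writeLines(sprintf("# %s=%s", names(header), header), con)
    }
    write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    sdf <- ChemmineR::smiles2sdf(setNames(records$smiles_canonical,
                                          records$record_id))
    ChemmineR::write.SDF(sdf, path, cid = TRUE)
  }
  invisible(path)
}

#' Per-molecule element statistics
#'
#' Counts carbon, nitrogen, and oxygen atoms (implicit hydrogens are not
#' counted) and the C/N and C/O ratios used to characterise siderophore
#' composition.  Ratios are `NA` (undefined), not zero, when the denominator
#' is zero.
#'
#' @param records A `mol_records` table (or a character vector of canonical
#'   SMILES).
#' @return A `data.frame` with columns `record_id`, `n_C`, `n_N`, `n_O`,
#'   `ratio_CN`, `ratio_CO`.
#' @examples
#' element_stats(mol_records("gly", "NCC(=O)O"))  # 2 C, 1 N, 2 O
#' @export
element_stats <- function(records) {
  if (is.character(records)) {
    records <- mol_records(names(records) %||%
                             as.character(seq_along(records)), records)
  }
  counts <- t(vapply(records$smiles_canonical, function(s) {
    mg <- mol_graph(s)
    c(C = sum(mg$atoms$elem == "C"),
      N = sum(mg$atoms$elem == "N"),
      O = sum(mg$atoms$elem == "O"))
  }, numeric(3)))
  data.frame(
    record_id = records$record_id,
    n_C = as.integer(counts[, "C"]),
    n_N = as.integer(counts[, "N"]),
    n_O = as.integer(counts[, "O"]),
    ratio_CN = ifelse(counts[, "N"] == 0, NA_real_,
                      counts[, "C"] / counts[, "N"]),
    ratio_CO = ifelse(counts[, "O"] == 0, NA_real_,
                      counts[, "C"] / counts[, "O"]),
    row.names = NULL, stringsAsFactors = FALSE)
}
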