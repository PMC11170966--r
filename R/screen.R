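# The candidate rule.
#
# A molecule is a siderophore candidate iff it carries at least one
# searchable iron-coordinating group, none of the modified-veto groups, and
# is not already a known structure.  The common_excluded groups
# (alpha-hydroxycarboxylate, carboxylate) never trigger candidacy.  The
# default veto is global: one blocked group anywhere rejects the whole
# molecule.  A per-site alternative (veto only the overlapping site; the
# molecule survives if an intact searchable match shares no atom with any
# veto match) is available behind `veto_mode = "per_site"`.

#' Screening decision for one molecule
#'
#' @param profile A `match_profile` from [match_groups()] computed against
#'   the same registry.
#' @param known_set Character vector of canonical SMILES of known
#'   structures (exact-identity exclusion), or `character(0)`.
#' @param patterns The `pattern_registry` the profile was computed with.
#' @param smiles_canonical Canonical SMILES of the molecule (needed for the
#'   known-set identity test; may be omitted when `known_set` is empty).
#' @param veto_mode `"global"` (default) or `"per_site"`.
#' @return A `screen_decision`: list with `record_id`, `is_candidate`,
#'   `triggering_groups`, `vetoing_groups`, `excluded_known`.
#' @examples
#' pats <- load_default_patterns()
#' decide(match_groups("CC(=O)NO", pats), character(0), pats)$is_candidate
#' @export
decide <- function(profile, known_set, patterns = load_default_patterns(),
                   smiles_canonical = NULL,
                   veto_mode = c("global", "per_site")) {
  veto_mode <- match.arg(veto_mode)
  searchable <- pattern_names(patterns, "searchable")
  vetoes <- pattern_names(patterns, "modified_veto")
  trig <- names(profile$counts[searchable][profile$counts[searchable] > 0])
  veto <- names(profile$counts[vetoes][profile$counts[vetoes] > 0])
  excluded <- FALSE
  if (length(known_set) > 0) {
    if (is.null(smiles_canonical)) {
      stop("smiles_canonical is required when known_set is non-empty")
    }
    excluded <- smiles_canonical %in% known_set
  }
  vetoed <- length(veto) > 0
  if (vetoed && veto_mode == "per_site" && length(trig) > 0) {
    veto_atoms <- unique(unlist(profile$matched_atoms[veto]))
    intact <- FALSE
    for (g in trig) {
      sets <- profile$matched_atoms[[g]]
      if (is.null(sets)) next
      if (any(vapply(sets, function(s) length(intersect(s, veto_atoms)) == 0,
                     logical(1)))) {
        intact <- TRUE
        break
      }
    }
    vetoed <- !intact
  }
  structure(list(
    record_id = profile$record_id,
    is_candidate = length(trig) > 0 && !vetoed && !excluded,
    triggering_groups = trig,
    vetoing_groups = veto,
    excluded_known = excluded), class = "screen_decision")
}

#' Screen a library for siderophore candidates
#'
#' @param records A deduplicated `mol_records` table.
#' @param known_set Character vector of canonical SMILES to exclude as
#'   already-known structures.
#' @param patterns A `pattern_registry`.
#' @param veto_mode See [decide()].
#' @return A `screen_result`: list with `decisions` (a `data.frame` of one
#'   decision per record: `record_id`, `is_candidate`, `triggering`,
#'   `vetoing`, `excluded_known`), and `summary` (named counts:
#'   `n_records`, `n_candidates`, `n_vetoed`, `n_known_excluded`,
#'   `n_no_trigger`).
#' @export
screen_library <- function(records, known_set = character(0),
                           patterns = load_default_patterns(),
                           veto_mode = c("global", "per_site")) {
  veto_mode <- match.arg(veto_mode)
  n <- nrow(records)
  decisions <- vector("list", n)
  # summary accumulated incrementally; decisions are made row by row so the
  # screen streams over arbitrarily large libraries
  acc <- c(n_records = 0L, n_candidates = 0L, n_vetoed = 0L,
           n_known_excluded = 0L, n_no_trigger = 0L)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    prof <- match_groups(rec, patterns)
    d <- decide(prof, known_set, patterns,
                smiles_canonical = rec$smiles_canonical,
                veto_mode = veto_mode)
    decisions[[i]] <- data.frame(
      record_id = d$record_id,
      is_candidate = d$is_candidate,
      triggering = join_pipes(d$triggering_groups),
      vetoing = join_pipes(d$vetoing_groups),
      excluded_known = d$excluded_known,
      stringsAsFactors = FALSE)
    acc["n_records"] <- acc["n_records"] + 1L
    acc["n_candidates"] <- acc["n_candidates"] + d$is_candidate
    acc["n_vetoed"] <- acc["n_vetoed"] + (length(d$vetoing_groups) > 0)
    acc["n_known_excluded"] <- acc["n_known_excluded"] + d$excluded_known
    acc["n_no_trigger"] <- acc["n_no_trigger"] +
      (length(d$triggering_groups) == 0)
  }
  df <- if (n > 0) do.call(rbind, decisions) else data.frame(
    record_id = character(0), is_candidate = logical(0),
    triggering = character(0), vetoing = character(0),
    excluded_known = logical(0), stringsAsFactors = FALSE)
  structure(list(decisions = df, summary = as.list(acc)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<screen_result> %d records: %d candidates, ",
                     "%d vetoed, %d known-excluded, %d without any ",
                     "searchable group\n"),
              s$n_records, s$n_candidates, s$n_vetoed, s$n_known_excluded,
              s$n_no_trigger))
  invisible(x)
}
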