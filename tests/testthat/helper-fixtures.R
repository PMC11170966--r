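# Shared fixture objects, computed once per test run.

PATS <- load_default_patterns()
REFS <- suppressMessages(reference_set())
DECOYS <- decoy_set()
VETOS <- veto_constructs()

fixture_bed <- function() {
  v <- VETOS
  v$parent_id <- NULL
  r <- REFS
  attr(r, "expected_counts") <- NULL
  out <- rbind(r, DECOYS, v)
  class(out) <- c("mol_records", "data.frame")
  out
}

ALL_RECORDS <- fixture_bed()

# count matrix over the whole bed (the expensive shared computation)
CMAT <- count_matrix(ALL_RECORDS, PATS)

REF_FPS <- fingerprints(REFS)
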