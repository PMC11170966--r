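test_that("canonicalization collapses SMILES spellings and is idempotent", {
  spellings <- canonicalize(c("OCC", "CCO", "C(C)O"))
  expect_length(unique(spellings), 1L)

  # idempotence on a structurally varied set
  smis <- ALL_RECORDS$smiles_canonical
  expect_identical(unname(canonicalize(smis)), unname(smis))
})

test_that("canonicalization neutralizes charges and strips salts", {
  expect_identical(unname(canonicalize("CC(=O)[O-]")),
                   unname(canonicalize("CC(=O)O")))
  # sodium acetate collapses to acetic acid, with a report of the stripping
  expect_message(
    salt <- canonicalize(c(na_oac = "CC(=O)[O-].[Na+]")),
    "stripped")
  expect_identical(unname(salt), unname(canonicalize("CC(=O)O")))
})

test_that("stereoisomers stay distinct by default, collapse on request", {
  l_ala <- "C[C@H](N)C(=O)O"
  d_ala <- "C[C@@H](N)C(=O)O"
  expect_false(canonicalize(l_ala) == canonicalize(d_ala))
  expect_identical(
    unname(canonicalize(l_ala, keep_stereo = FALSE)),
    unname(canonicalize(d_ala, keep_stereo = FALSE)))
})

test_that("unparsable SMILES raise an error naming the offending record", {
  expect_error(canonicalize(c(good = "CCO", broken = "XY(Z")), "broken")
})

test_that("deduplication merges names and preserves unique structures", {
  recs <- mol_records(c("a", "b", "c"), c("CCO", "OCC", "CC=O"))
  merged <- deduplicate(recs)
  expect_equal(nrow(merged), 2L)
  eth <- merged[merged$record_id == "a", ]
  expect_identical(eth$name, "a")
  expect_identical(eth$other_names, "b")

  # empty library passes through
  expect_equal(nrow(deduplicate(recs[0, ])), 0L)

  # the curated fixture bed is already unique: dedup is the identity
  expect_equal(nrow(deduplicate(ALL_RECORDS)), nrow(ALL_RECORDS))
})

test_that("deduplication is order-insensitive up to representative choice", {
  recs <- mol_records(paste0("r", 1:6),
                      c("CCO", "OCC", "CC=O", "C(C)O", "c1ccccc1", "CCO"))
  base <- sort(deduplicate(recs)$smiles_canonical)
  for (seed in 1:5) {
    perm <- with_seed(seed, sample(nrow(recs)))
    shuffled <- recs[perm, ]
    class(shuffled) <- class(recs)
    expect_identical(sort(deduplicate(shuffled)$smiles_canonical), base)
  }
  # lexicographic tie-break picks the alphabetically first record id
  rev_recs <- recs[6:1, ]
  class(rev_recs) <- class(recs)
  lex <- deduplicate(rev_recs, prefer = "lexicographic")
  expect_identical(lex$record_id[lex$smiles_canonical ==
                                   canonicalize("CCO")], "r1")
})

test_that("element statistics match the OpenBabel formula oracle", {
  st <- element_stats(ALL_RECORDS)
  for (i in seq_len(nrow(ALL_RECORDS))) {
    oracle <- formula_counts(ALL_RECORDS$smiles_canonical[i])
    expect_equal(unlist(st[i, c("n_C", "n_N", "n_O")]),
                 oracle[c("C", "N", "O")],
                 ignore_attr = TRUE,
                 info = ALL_RECORDS$record_id[i])
  }
})

test_that("element ratios are undefined, not zero, for zero denominators", {
  st <- element_stats(mol_records(c("eth", "gly"), c("CCO", "NCC(=O)O")))
  expect_equal(st$n_C, c(2L, 2L))
  expect_equal(st$n_N, c(0L, 1L))
  expect_equal(st$n_O, c(1L, 2L))
  expect_true(is.na(st$ratio_CN[1]))     # ethanol has no nitrogen
  expect_equal(st$ratio_CN[2], 2)
  expect_equal(st$ratio_CO[2], 1)
})

test_that("smiles-table round trip preserves records", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(REFS, path)
  back <- read_library(path)
  expect_identical(back$record_id, REFS$record_id)
  expect_identical(back$name, REFS$name)
  expect_identical(back$smiles_canonical, REFS$smiles_canonical)
  expect_identical(back$biosynthetic_type, REFS$biosynthetic_type)

  # TSV dialect too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_library(REFS, path2)
  expect_identical(read_library(path2)$smiles_canonical,
                   REFS$smiles_canonical)
})

test_that("sdf round trip preserves structures", {
  path <- withr::local_tempfile(fileext = ".sdf")
  sub <- REFS[1:3, ]
  class(sub) <- class(REFS)
  write_library(sub, path)
  back <- read_library(path)
  expect_identical(back$smiles_canonical, sub$smiles_canonical)
  expect_identical(back$record_id, sub$record_id)
})

test_that("malformed library files are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "a,CCO"), p)      # missing the name column
  expect_error(read_library(p), "name")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,smiles", "a,x,CCO", "a,y,CCC"), p2)
  expect_error(read_library(p2), "duplicate")

  p3 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("junk", "not an sdf"), p3)
  expect_error(read_library(p3))
})
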