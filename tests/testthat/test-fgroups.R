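test_that("default registry satisfies the category invariants", {
  cats <- vapply(PATS, `[[`, "", "category")
  expect_equal(sum(cats == "searchable"), 15L)
  expect_equal(sum(cats == "modified_veto"), 8L)
  expect_true("alpha-hydroxycarboxylate" %in%
                pattern_names(PATS, "common_excluded"))
  expect_false(anyDuplicated(pattern_names(PATS)) > 0)
})

test_that("pattern overrides extend the registry and bad patterns fail", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group_name\tcategory\tsmarts\trarity",
               "thiohydroxamate\tsearchable\t[CX3](=S)[NX3][OX2H1]\trare"),
             p)
  reg <- load_default_patterns(p)
  expect_equal(sum(vapply(reg, `[[`, "", "category") == "searchable"), 16L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group_name\tcategory\tsmarts\trarity",
               "broken\tsearchable\t[[[\trare"), bad)
  expect_error(load_default_patterns(bad), "broken")
})

test_that("registry dump round-trips through the TSV interface", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(PATS, p)
  tab <- read.delim(p, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(tab), length(PATS))
  expect_identical(tab$group_name, pattern_names(PATS))
  expect_identical(tab$smarts, vapply(PATS, `[[`, "", "smarts"))
})

test_that("reference molecules show their expected group counts", {
  expected <- attr(REFS, "expected_counts")
  for (id in names(expected)) {
    e <- expected[[id]]
    expect_equal(unname(CMAT[id, names(e)]), unname(e), info = id)
    # no veto pattern fires on an intact reference siderophore
    vet <- pattern_names(PATS, "modified_veto")
    expect_true(all(CMAT[id, vet] == 0), info = id)
  }
})

test_that("worked single-molecule examples match manual identification", {
  aha <- match_groups("CC(=O)NO", PATS)      # acetohydroxamic acid
  expect_equal(aha$counts[["hydroxamate"]], 1L)
  expect_equal(length(aha$matched_atoms[["hydroxamate"]]), 1L)

  dhb <- match_groups("OC(=O)c1cccc(O)c1O", PATS)  # 2,3-dihydroxybenzoate
  expect_equal(dhb$counts[["catecholate"]], 1L)
  expect_equal(dhb$counts[["carboxylate"]], 1L)

  meoh <- match_groups("CO", PATS)
  expect_true(all(meoh$counts == 0L))
})

test_that("matcher counts equal the OpenBabel SMARTS engine on the bed", {
  ob <- ob_count_matrix(ALL_RECORDS, PATS)
  expect_equal(unname(CMAT), unname(ob))
})

test_that("counts equal the number of distinct matched atom sets", {
  for (id in c("aerobactin", "enterobactin", "veto_schizokinen_o_dimethyl")) {
    rec <- ALL_RECORDS[ALL_RECORDS$record_id == id, ]
    prof <- match_groups(rec, PATS)
    for (g in names(prof$counts)) {
      sets <- prof$matched_atoms[[g]]
      expect_equal(prof$counts[[g]], length(sets), info = paste(id, g))
      if (length(sets) > 1) {
        keys <- vapply(sets, paste, "", collapse = ",")
        expect_false(anyDuplicated(keys) > 0, info = paste(id, g))
      }
    }
  }
})

test_that("matching is invariant to atom renumbering", {
  mols <- c("aerobactin", "vibriobactin", "cepabactin", "quinolobactin")
  for (id in mols) {
    smi <- ALL_RECORDS$smiles_canonical[ALL_RECORDS$record_id == id]
    mg <- sideroscreen:::mol_graph(smi)
    n <- nrow(mg$atoms)
    for (seed in 1:3) {
      perm <- with_seed(seed * 7 + nchar(id), sample(n))
      mg2 <- sideroscreen:::permute_mol_graph(mg, perm)
      for (p in PATS) {
        if (is.null(p$graph)) next
        expect_equal(
          length(sideroscreen:::match_pattern(mg2, p$graph)),
          length(sideroscreen:::match_pattern(mg, p$graph)),
          info = paste(id, p$group_name, seed))
      }
    }
  }
})

test_that("a vetoed site never co-counts as its intact parent group", {
  # one of three hydroxamates O-methylated: two intact sites remain and
  # the blocked site's atoms are disjoint from the intact matches
  mono <- paste0("NCCCCCN(OC)C(=O)CCC(=O)NCCCCCN(O)C(=O)CCC(=O)",
                 "NCCCCCN(O)C(C)=O")
  prof <- match_groups(c(dfoB_1Me = mono), PATS)
  expect_equal(prof$counts[["hydroxamate"]], 2L)
  expect_equal(prof$counts[["O-alkyl-hydroxamate"]], 1L)
  veto_atoms <- unlist(prof$matched_atoms[["O-alkyl-hydroxamate"]])
  for (s in prof$matched_atoms[["hydroxamate"]]) {
    expect_length(intersect(s, veto_atoms), 0)
  }

  # fully blocked molecules lose the parent match entirely
  for (i in seq_len(nrow(VETOS))) {
    prof <- match_groups(VETOS[i, ], PATS)
    vet <- pattern_names(PATS, "modified_veto")
    expect_true(any(prof$counts[vet] > 0), info = VETOS$record_id[i])
  }
})

test_that("count matrix rows equal single-molecule profiles", {
  expect_equal(nrow(count_matrix(REFS[0, ], PATS)), 0L)
  one <- count_matrix(REFS[3, ], PATS)
  expect_equal(one[1, ], match_groups(REFS[3, ], PATS)$counts)
})
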