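test_that("tanimoto identities hold", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  # FPset route: self-similarity 1, symmetry
  expect_equal(tanimoto(REF_FPS[1], REF_FPS[1]), 1)
  expect_equal(tanimoto(REF_FPS[1], REF_FPS[2]),
               tanimoto(REF_FPS[2], REF_FPS[1]))
})

test_that("fingerprints are deterministic and chemically sensible", {
  fp1 <- fingerprints(REFS[1:3, ])
  fp2 <- fingerprints(REFS[1:3, ])
  expect_identical(ChemmineR::as.matrix(fp1), ChemmineR::as.matrix(fp2))

  trio <- fingerprints(c(ethanol = "CCO", propanol = "CCCO",
                         octane = "CCCCCCCC"))
  s_prop <- tanimoto(trio[1], trio[2])
  s_oct <- tanimoto(trio[1], trio[3])
  expect_gt(s_prop, s_oct)   # ethanol closer to propanol than to octane
})

test_that("1 - tanimoto behaves as a distance on fingerprint triples", {
  fps <- fingerprints(ALL_RECORDS)
  m <- ChemmineR::as.matrix(fps)
  idx <- with_seed(5, replicate(60, sample(nrow(m), 3), simplify = FALSE))
  for (tr in idx) {
    d_ab <- 1 - tanimoto(m[tr[1], ], m[tr[2], ])
    d_bc <- 1 - tanimoto(m[tr[2], ], m[tr[3], ])
    d_ac <- 1 - tanimoto(m[tr[1], ], m[tr[3], ])
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
    expect_gte(d_ab, 0)
    expect_lte(d_ab, 1)
  }
})

test_that("novelty assessment against a known set", {
  # a member of the known set is never novel
  r <- max_similarity_to_known(REF_FPS[4], REF_FPS)
  expect_equal(r$max_tanimoto, 1)
  expect_false(r$novel)

  # methanol shares almost nothing with large siderophores
  r <- max_similarity_to_known(fingerprints(c(m = "CO")), REF_FPS)
  expect_lt(r$max_tanimoto, 0.1)
  expect_true(r$novel)

  # a one-methyl analogue of desferrioxamine B stays recognisable
  ana <- fingerprints(c(a = paste0("NCCCCCN(OC)C(=O)CCC(=O)NCCCCCN(O)",
                                   "C(=O)CCC(=O)NCCCCCN(O)C(C)=O")))
  r <- max_similarity_to_known(ana, REF_FPS)
  expect_identical(r$best_known_id, "desferrioxamine_b")
  expect_gt(r$max_tanimoto, 0.60)
  expect_false(r$novel)

  expect_error(max_similarity_to_known(REF_FPS[1], REF_FPS[0]), "non-empty")
})

test_that("every veto construct stays similar (>0.60) to its parent", {
  fp_v <- fingerprints(VETOS)
  for (i in seq_len(nrow(VETOS))) {
    s <- tanimoto(fp_v[i], REF_FPS[match(VETOS$parent_id[i],
                                         REFS$record_id)])
    expect_gt(s, 0.60)
    # and is a different structure than its parent
    expect_false(VETOS$smiles_canonical[i] %in% REFS$smiles_canonical)
  }
})

test_that("minimum spanning tree on a 3-node toy uses the two short edges", {
  dist <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.9, 0.2, 0.9, 0), 3, 3)
  expect_equal(igraph_mst_weight(dist), 0.3)
})

test_that("MST weights agree with an independent Kruskal implementation", {
  # (the exhaustive 100-seed enumeration check lives in the acceptance
  # suite; this guards the oracle plumbing itself)
  for (i in 1:20) {
    d <- with_seed(2000 + i, {
      m <- matrix(stats::runif(64), 8, 8)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    })
    expect_equal(igraph_mst_weight(d), kruskal_mst_weight(d),
                 tolerance = 1e-12)
  }
})

test_that("joint graph MST invariants hold on the fixture bed", {
  sg <- build_joint_graph(REFS, DECOYS, k = 5)
  n <- nrow(sg$nodes)
  expect_equal(nrow(sg$mst_edges), n - 1)
  expect_false(igraph::any_loop(sg$mst))
  expect_true(igraph::is_connected(sg$mst))
  # total MST weight matches an independent Kruskal on the same edge set
  el <- igraph::as_edgelist(sg$graph, names = FALSE)
  full <- matrix(Inf, n, n)
  w <- igraph::E(sg$graph)$weight
  full[el] <- w; full[el[, c(2, 1)]] <- w
  diag(full) <- 0
  expect_equal(sum(sg$mst_edges$weight), kruskal_mst_weight(full),
               tolerance = 1e-12)
})

test_that("adding a duplicate molecule contributes a zero-weight edge", {
  dup <- rbind(REFS, transform(REFS[1, ], record_id = "dup"))
  class(dup) <- class(REFS)
  sg <- build_joint_graph(dup, k = 5)
  inc <- sg$mst_edges[sg$mst_edges$a %in% c("enterobactin", "dup") &
                        sg$mst_edges$b %in% c("enterobactin", "dup"), ]
  expect_equal(nrow(inc), 1L)
  expect_equal(inc$weight, 0)
})

test_that("cluster extraction cuts the tree at background nodes", {
  # chain known-known-background-known -> clusters sized 2 and 1
  sg <- synthetic_sim_graph(
    ids = c("k1", "k2", "bg", "k3"),
    tags = c("knownset", "knownset", "background", "knownset"),
    edges = matrix(c("k1", "k2", "k2", "bg", "bg", "k3"), ncol = 2,
                   byrow = TRUE))
  cl <- extract_clusters(sg)
  expect_equal(cl$cluster_size[match(c("k1", "k2", "k3"), cl$record_id)],
               c(2L, 2L, 1L))
  expect_equal(cl$cluster[match("k3", cl$record_id)], 2L)

  # no background molecules: a spanning tree is one cluster
  sg2 <- build_joint_graph(REFS[1:5, ], k = 3)
  cl2 <- extract_clusters(sg2)
  expect_equal(unique(cl2$cluster), 1L)
})

test_that("cluster indexes are size-ranked with deterministic ties", {
  sg <- synthetic_sim_graph(
    ids = c("z1", "bg1", "a1", "bg2", "m1", "m2"),
    tags = c("knownset", "background", "knownset", "background",
             "knownset", "knownset"),
    edges = matrix(c("z1", "bg1", "bg1", "a1", "a1", "bg2",
                     "bg2", "m1", "m1", "m2"), ncol = 2, byrow = TRUE))
  cl <- extract_clusters(sg)
  # sizes 2 ("m1","m2"), 1, 1; the singletons tie and sort by record id
  expect_equal(cl$cluster[match("m1", cl$record_id)], 1L)
  expect_equal(cl$cluster[match("a1", cl$record_id)], 2L)
  expect_equal(cl$cluster[match("z1", cl$record_id)], 3L)
})

test_that("cluster extraction is invariant to node insertion order and to
           duplicated background molecules", {
  base <- build_joint_graph(REFS, DECOYS, k = 5)
  cl_base <- extract_clusters(base)
  key <- function(cl) {
    lapply(split(cl$record_id, cl$cluster), sort)
  }
  perm <- with_seed(3, sample(nrow(REFS)))
  refs2 <- REFS[perm, ]
  class(refs2) <- class(REFS)
  cl_perm <- extract_clusters(build_joint_graph(refs2, DECOYS, k = 5))
  expect_identical(key(cl_base), key(cl_perm))

  dup_bg <- rbind(DECOYS, transform(DECOYS[1:3, ],
                                    record_id = paste0("dup_", 1:3)))
  class(dup_bg) <- class(DECOYS)
  cl_dup <- extract_clusters(build_joint_graph(REFS, dup_bg, k = 5))
  expect_identical(key(cl_base), key(cl_dup))
})

test_that("group definition follows the similarity threshold", {
  sg <- build_joint_graph(REFS, k = 5)
  cl <- extract_clusters(sg)
  # threshold 0: every cluster is a single group
  g0 <- define_groups(cl, sg$fps, threshold = 0)
  expect_equal(unique(g0$group[g0$cluster == 1]), 1L)
  # threshold above 1: all singleton groups
  g1 <- define_groups(cl, sg$fps, threshold = 1 + 1e-9)
  expect_true(all(g1$group_size == 1L))
})

test_that("two similarity blocks split into two groups at threshold 0.6", {
  m <- matrix(0, 4, 256)
  m[1, 1:100] <- 1; m[2, 1:90] <- 1          # block A: similarity 0.9
  m[3, 101:200] <- 1; m[4, 101:190] <- 1     # block B: similarity 0.9
  m[, 201:210] <- 1                          # weak cross-talk
  rownames(m) <- c("a1", "a2", "b1", "b2")
  fps <- methods::as(m, "FPset")
  ChemmineR::cid(fps) <- rownames(m)
  cl <- data.frame(record_id = rownames(m), cluster = 1L,
                   cluster_size = 4L, stringsAsFactors = FALSE)
  gr <- define_groups(cl, fps, threshold = 0.6)
  expect_equal(length(unique(gr$group)), 2L)
  expect_equal(gr$group[gr$record_id == "a1"],
               gr$group[gr$record_id == "a2"])
  expect_false(gr$group[gr$record_id == "a1"] ==
                 gr$group[gr$record_id == "b1"])
})

test_that("chemical-space IDs are unique and append-stable", {
  sg <- build_joint_graph(REFS, DECOYS, k = 5)
  cl <- extract_clusters(sg)
  gr <- define_groups(cl, sg$fps)
  ids <- assign_ids(gr)
  expect_false(anyDuplicated(ids$id) > 0)
  expect_setequal(ids$record_id, REFS$record_id)

  # append a new analogue: existing records keep their IDs, the newcomer
  # gets a fresh z in its group
  ana <- mol_records("dfoB_analog",
                     paste0("NCCCCCN(OC)C(=O)CCC(=O)NCCCCCN(O)C(=O)CCC",
                            "(=O)NCCCCCN(O)C(C)=O"),
                     source_tag = "knownset")
  refs2 <- rbind(REFS, ana)
  class(refs2) <- class(REFS)
  attr(refs2, "expected_counts") <- NULL
  sg2 <- build_joint_graph(refs2, DECOYS, k = 5)
  cl2 <- extract_clusters(sg2)
  gr2 <- define_groups(cl2, sg2$fps)
  ids2 <- assign_ids(gr2, previous = ids)
  old <- ids2[match(ids$record_id, ids2$record_id), c("x", "y", "z")]
  rownames(old) <- NULL
  expect_equal(old, ids[, c("x", "y", "z")])
  expect_false(anyDuplicated(ids2$id) > 0)
})

test_that("group biosynthetic types are inferred by majority vote", {
  expect_identical(
    infer_biosynthetic_type(c("NRPS", "NRPS", "unknown"))$inferred_type,
    "NRPS")
  expect_false(
    infer_biosynthetic_type(c("NRPS", "NRPS", "unknown"))$is_mixed)
  mix <- infer_biosynthetic_type(c("NRPS", "NIS"))
  expect_true(mix$is_mixed)
  expect_identical(mix$inferred_type, "NIS")   # deterministic tie-break
  expect_identical(infer_biosynthetic_type(c("unknown",
                                             "unknown"))$inferred_type,
                   "unknown")
})
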