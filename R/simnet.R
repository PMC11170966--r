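# Fingerprint similarity, novelty, and chemical-space clustering.
#
# Chemical space is modelled the way large natural-product libraries are
# visualised: molecules become circular-substructure fingerprints, a
# k-nearest-neighbour graph is built under the Tanimoto distance
# (1 - similarity), and its minimum spanning tree gives the topology.
# Known siderophores are placed jointly with a background library;
# clusters are the connected components of the known molecules that remain
# after background molecules are removed from the tree, indexed in
# decreasing size order.  Within a cluster, groups are components of the
# similarity graph at a fixed Tanimoto threshold, and every structure gets
# a chemical-space ID x.y.z (cluster.group.record).

#' Compute fingerprints for a record table
#'
#' @param records A `mol_records` table (or named character vector of
#'   canonical SMILES).
#' @param scheme `"ecfp4"` (circular substructure fingerprint, radius 2,
#'   4096 bits; default) or `"fp2"` (path-based, 1024 bits).  Both are
#'   computed by OpenBabel and are bit-identical across repeated calls.
#' @return A [ChemmineR::FPset-class] with compound ids set to record ids.
#' @export
fingerprints <- function(records, scheme = c("ecfp4", "fp2")) {
  scheme <- match.arg(scheme)
  if (is.character(records)) {
    smi <- records
    ids <- names(records) %||% as.character(seq_along(records))
  } else {
    smi <- records$smiles_canonical
    ids <- records$record_id
  }
  sdf <- ChemmineR::smiles2sdf(setNames(smi, ids))
  fp <- ChemmineR::fingerprintOB(sdf, toupper(scheme))
  ChemmineR::cid(fp) <- ids
  fp
}

#' Tanimoto similarity
#'
#' `|A intersect B| / |A union B|` over fingerprint features.  Accepts two
#' single-molecule `FPset`/`FP` objects, two binary (0/1 or logical)
#' vectors, or two positive-integer index sets of "on" bits.
#'
#' @param a,b Fingerprints in one of the accepted forms (both the same
#'   form and, for vectors, the same length).
#' @return Similarity in `[0, 1]`; `1` for identical fingerprints, `0`
#'   when no features are shared.  Two empty fingerprints compare as `1`.
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 2 shared / 4 union = 0.5
#' @export
tanimoto <- function(a, b) {
  if (methods::is(a, "FPset") || methods::is(a, "FP")) {
    a <- as.numeric(ChemmineR::as.matrix(a)[1, ])
    b <- as.numeric(ChemmineR::as.matrix(b)[1, ])
  }
  is_bits <- function(x) is.logical(x) || all(x %in% c(0, 1))
  if (is_bits(a) && is_bits(b)) {
    if (length(a) != length(b)) stop("bit vectors must have equal length")
    a <- which(as.logical(a))
    b <- which(as.logical(b))
  } else {
    if (any(a <= 0) || any(b <= 0) || any(a != floor(a)) ||
        any(b != floor(b))) {
      stop("index sets must contain positive integers")
    }
  }
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fp_a An `FPset` (rows of the result).
#' @param fp_b An `FPset` (columns); defaults to `fp_a`.
#' @return Numeric matrix of Tanimoto similarities with record ids as
#'   dimnames (mirrors the reference similarity-table layout).
#' @export
similarity_matrix <- function(fp_a, fp_b = fp_a) {
  m <- t(vapply(seq_along(ChemmineR::cid(fp_a)), function(i) {
    ChemmineR::fpSim(fp_a[i], fp_b, sorted = FALSE, addone = 0)
  }, numeric(length(ChemmineR::cid(fp_b)))))
  dimnames(m) <- list(ChemmineR::cid(fp_a), ChemmineR::cid(fp_b))
  m
}

#' Maximum similarity of a candidate to a known set, and novelty
#'
#' A candidate is *novel* when its maximum Tanimoto similarity to every
#' known structure is at or below the novelty threshold (default 0.60,
#' i.e. only candidates with similarity above 60% to some known structure
#' are considered already-explored chemistry).
#'
#' @param candidate A single-molecule `FPset` (or an `FPset` row id to use
#'   from `knownset`).
#' @param knownset A non-empty `FPset` of known structures.
#' @param threshold Novelty threshold on the maximum similarity.
#' @return List with `best_known_id`, `max_tanimoto`, `novel`.
#' @export
max_similarity_to_known <- function(candidate, knownset, threshold = 0.60) {
  if (length(ChemmineR::cid(knownset)) == 0) {
    stop("knownset must be non-empty", call. = FALSE)
  }
  sims <- ChemmineR::fpSim(candidate, knownset, sorted = FALSE, addone = 0)
  best <- which.max(sims)
  list(best_known_id = ChemmineR::cid(knownset)[best],
       max_tanimoto = unname(sims[best]),
       novel = unname(sims[best]) <= threshold)
}

#' Joint k-nearest-neighbour graph and minimum spanning tree
#'
#' Places known structures and a background library in one similarity
#' graph: every molecule is linked to its `k` nearest neighbours under the
#' Tanimoto distance `1 - similarity`, disconnected components (possible at
#' small `k`) are bridged by the smallest inter-component edges (the number
#' of added bridges is reported), and the minimum spanning tree is
#' computed.
#'
#' @param knownset,background `mol_records` tables (the `source_tag` of the
#'   output nodes records which side each came from).  `background` may be
#'   empty.
#' @param k Neighbours per node for the kNN graph.
#' @param scheme Fingerprint scheme, see [fingerprints()].
#' @param fps Optional precomputed `FPset` for `rbind(knownset,
#'   background)` record ids (avoids recomputation).
#' @return A `sim_graph`: list with `nodes` (`record_id`, `source_tag`),
#'   `edges` (kNN edge list with `weight`), `mst_edges`, and the
#'   corresponding \pkg{igraph} objects `graph` and `mst`.
#' @export
build_joint_graph <- function(knownset, background = NULL, k = 20,
                              scheme = c("ecfp4", "fp2"), fps = NULL) {
  scheme <- match.arg(scheme)
  nodes <- data.frame(
    record_id = c(knownset$record_id,
                  if (!is.null(background)) background$record_id),
    source_tag = c(rep("knownset", nrow(knownset)),
                   if (!is.null(background))
                     rep("background", nrow(background))),
    stringsAsFactors = FALSE)
  n <- nrow(nodes)
  if (n < 2) stop("need at least 2 molecules to build a graph")
  if (anyDuplicated(nodes$record_id)) {
    stop("record ids must be unique across knownset and background")
  }
  smi <- c(knownset$smiles_canonical,
           if (!is.null(background)) background$smiles_canonical)
  # canonical node order: results depend only on the molecule *set*, never
  # on input insertion order (ties in kNN selection and MST construction
  # are broken by this order)
  ord <- order(nodes$record_id)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  smi <- smi[ord]
  if (is.null(fps)) {
    fps <- fingerprints(setNames(smi, nodes$record_id), scheme)
  } else {
    fps <- fps[match(nodes$record_id, ChemmineR::cid(fps))]
  }
  sim <- similarity_matrix(fps)
  dist <- 1 - sim
  kk <- min(k, n - 1)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    ord <- order(dist[i, -i])
    nb <- setdiff(seq_len(n), i)[ord][seq_len(kk)]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  w <- dist[pairs]

  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  n_bridges <- 0L
  while (comp$no > 1) {
    # connect the first component to its nearest outside neighbour
    in1 <- which(comp$membership == 1)
    out1 <- which(comp$membership != 1)
    sub <- dist[in1, out1, drop = FALSE]
    at <- arrayInd(which.min(sub), dim(sub))
    a <- in1[at[1]]; b <- out1[at[2]]
    g <- igraph::add_edges(g, c(a, b), weight = dist[a, b])
    pairs <- rbind(pairs, c(min(a, b), max(a, b)))
    w <- c(w, dist[a, b])
    n_bridges <- n_bridges + 1L
    comp <- igraph::components(g)
  }
  if (n_bridges > 0) {
    message(sprintf("kNN graph disconnected; added %d bridging edge(s)",
                    n_bridges))
  }
  igraph::V(g)$name <- nodes$record_id
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mst, names = TRUE)
  structure(list(
    nodes = nodes,
    edges = data.frame(a = nodes$record_id[pairs[, 1]],
                       b = nodes$record_id[pairs[, 2]], weight = w,
                       stringsAsFactors = FALSE),
    mst_edges = data.frame(a = el[, 1], b = el[, 2],
                           weight = igraph::E(mst)$weight,
                           stringsAsFactors = FALSE),
    graph = g, mst = mst, n_bridges = n_bridges, fps = fps,
    scheme = scheme, k = k), class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("<sim_graph> %d nodes (%d known, %d background), %d kNN edges, MST weight %.3f\n",
              nrow(x$nodes), sum(x$nodes$source_tag == "knownset"),
              sum(x$nodes$source_tag == "background"), nrow(x$edges),
              sum(x$mst_edges$weight)))
  invisible(x)
}

#' Extract size-ranked clusters of known structures
#'
#' Background molecules (and their incident edges) are deleted from the
#' minimum spanning tree; the connected components of the remaining known
#' molecules are the clusters.  Cluster indexes are 1-based and sorted by
#' decreasing member count; ties go to the cluster whose smallest
#' `record_id` sorts first.
#'
#' @param sg A `sim_graph` from [build_joint_graph()].
#' @return A `data.frame` with `record_id`, `cluster`, `cluster_size`, in
#'   cluster order then input node order.
#' @export
extract_clusters <- function(sg) {
  known_ids <- sg$nodes$record_id[sg$nodes$source_tag == "knownset"]
  sub <- igraph::induced_subgraph(sg$mst,
                                  igraph::V(sg$mst)$name %in% known_ids)
  comp <- igraph::components(sub)
  members <- split(igraph::V(sub)$name, comp$membership)
  sizes <- vapply(members, length, integer(1))
  min_id <- vapply(members, function(m) sort(m)[1], character(1))
  ord <- order(-sizes, min_id)
  members <- members[ord]
  out <- do.call(rbind, lapply(seq_along(members), function(ci) {
    ids <- members[[ci]]
    ids <- ids[order(match(ids, sg$nodes$record_id))]
    data.frame(record_id = ids, cluster = ci,
               cluster_size = length(ids), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Define groups within clusters by a similarity threshold
#'
#' Groups are the connected components of the within-cluster similarity
#' graph containing the edges with Tanimoto similarity `>= threshold`.
#' Group indexes are size-ranked within their cluster (ties to the group
#' whose smallest `record_id` sorts first).
#'
#' @param clusters Cluster assignment from [extract_clusters()].
#' @param fps `FPset` covering all clustered records.
#' @param threshold Structure-similarity coefficient in `[0, 1]`; pairs at
#'   or above it fall in one group.  The default mirrors the 0.60 novelty
#'   threshold.
#' @return A `data.frame` with `record_id`, `cluster`, `cluster_size`,
#'   `group`, `group_size`.
#' @export
define_groups <- function(clusters, fps, threshold = 0.60) {
  stopifnot(threshold >= 0)
  out <- do.call(rbind, lapply(split(clusters, clusters$cluster),
                               function(cl) {
    ids <- cl$record_id
    sub_fp <- fps[match(ids, ChemmineR::cid(fps))]
    sim <- similarity_matrix(sub_fp)
    adjm <- sim >= threshold
    diag(adjm) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adjm, mode = "undirected")
    comp <- igraph::components(g)
    members <- split(ids, comp$membership)
    sizes <- vapply(members, length, integer(1))
    min_id <- vapply(members, function(m) sort(m)[1], character(1))
    ordg <- order(-sizes, min_id)
    members <- members[ordg]
    do.call(rbind, lapply(seq_along(members), function(gi) {
      mids <- members[[gi]]
      mids <- mids[order(match(mids, ids))]
      data.frame(record_id = mids, cluster = cl$cluster[1],
                 cluster_size = cl$cluster_size[1], group = gi,
                 group_size = length(mids), stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(out$cluster, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign chemical-space IDs x.y.z
#'
#' Every structure gets a unique ID `x.y.z`: cluster `x`, group `y` within
#' the cluster, record `z` within the group (by record order).  When a
#' `previous` assignment is given, existing records keep their IDs and new
#' records in an existing group receive the next free `z` (append-stable
#' growth); new groups/clusters get the next free `y`/`x`.
#'
#' @param partition Output of [define_groups()].
#' @param previous Optional earlier assignment (`data.frame` with
#'   `record_id`, `x`, `y`, `z`) to extend.
#' @return A `data.frame` with `record_id`, `x`, `y`, `z`, `id`
#'   (`"x.y.z"`), `cluster_size`, `group_size`.
#' @export
assign_ids <- function(partition, previous = NULL) {
  out <- partition
  out$x <- out$cluster
  out$y <- out$group
  out$z <- stats::ave(seq_len(nrow(out)),
                      paste(out$cluster, out$group, sep = "."),
                      FUN = seq_along)
  if (!is.null(previous)) {
    assert_cols(previous, c("record_id", "x", "y", "z"), "previous IDs")
    keep <- match(out$record_id, previous$record_id)
    # existing records keep their published IDs
    out$x <- ifelse(is.na(keep), out$x, previous$x[keep])
    out$y <- ifelse(is.na(keep), out$y, previous$y[keep])
    out$z <- ifelse(is.na(keep), out$z, previous$z[keep])
    # new records appended to a group holding previous members adopt that
    # group's published (x, y) and continue its z sequence
    for (i in which(is.na(keep))) {
      mates <- out$record_id[out$cluster == out$cluster[i] &
                               out$group == out$group[i]]
      pm <- previous[previous$record_id %in% mates, , drop = FALSE]
      if (nrow(pm) > 0) {
        out$x[i] <- pm$x[1]
        out$y[i] <- pm$y[1]
        prior_max <- max(pm$z)
        new_here <- which(is.na(keep) & out$cluster == out$cluster[i] &
                            out$group == out$group[i])
        out$z[i] <- prior_max + match(i, new_here)
      }
    }
  }
  out$id <- paste(out$x, out$y, out$z, sep = ".")
  if (anyDuplicated(out$id)) stop("internal error: chemical-space IDs not unique")
  out[, c("record_id", "x", "y", "z", "id", "cluster_size", "group_size")]
}

#' Infer the biosynthetic type of one group by majority vote
#'
#' Members with unknown type do not vote.  A group is *mixed* when at least
#' two distinct known types occur among its members; ties are resolved to
#' the alphabetically first type for determinism.  All-unknown groups stay
#' `unknown`.
#'
#' @param member_types Character vector of member biosynthetic types.
#' @param group Group label (`"x.y"`), carried through to the output.
#' @return A `biosynthetic_call`: list with `group`, `inferred_type`,
#'   `is_mixed`, `member_vote_counts`.
#' @examples
#' infer_biosynthetic_type(c("NRPS", "NRPS", "unknown"))$inferred_type
#' @export
infer_biosynthetic_type <- function(member_types, group = NA_character_) {
  stopifnot(length(member_types) > 0)
  known <- member_types[member_types != "unknown" & !is.na(member_types)]
  votes <- sort(table(known), decreasing = TRUE)
  inferred <- if (length(votes) == 0) "unknown" else {
    top <- votes[votes == max(votes)]
    sort(names(top))[1]
  }
  structure(list(group = group,
                 inferred_type = inferred,
                 is_mixed = length(unique(known)) >= 2,
                 member_vote_counts = as.list(votes)),
            class = "biosynthetic_call")
}

#' Biosynthetic-type calls for every group of an assignment
#'
#' @param ids Assignment from [assign_ids()].
#' @param records `mol_records` carrying `biosynthetic_type` per record.
#' @return `data.frame` with `group` (`"x.y"`), `inferred_type`,
#'   `is_mixed`, `n_members`.
#' @export
biosynthetic_calls <- function(ids, records) {
  types <- records$biosynthetic_type[match(ids$record_id,
                                           records$record_id)]
  key <- paste(ids$x, ids$y, sep = ".")
  rows <- lapply(split(seq_along(key), key), function(ix) {
    call <- infer_biosynthetic_type(types[ix], group = key[ix[1]])
    data.frame(group = call$group, inferred_type = call$inferred_type,
               is_mixed = call$is_mixed, n_members = length(ix),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(as.numeric(sub("\\..*", "", out$group)),
            as.numeric(sub(".*\\.", "", out$group))), , drop = FALSE]
}
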