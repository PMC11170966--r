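# Independent oracles used by the tests.
#
# These deliberately take different routes from the implementation:
# substructure counts come from OpenBabel's SMARTS engine (the package's
# own matcher never calls it), element counts from OpenBabel's molecular
# formula, and minimum-spanning-tree weights from exhaustive enumeration
# of all labelled trees via Pruefer sequences (or an independent Kruskal
# implementation for larger graphs).

# per-pattern match counts via the OpenBabel SMARTS engine
ob_count_matrix <- function(records, patterns) {
  sdf <- ChemmineR::smiles2sdf(setNames(records$smiles_canonical,
                                        records$record_id))
  m <- sapply(patterns, function(p)
    ChemmineR::smartsSearchOB(sdf, p$smarts, uniqueMatches = TRUE))
  colnames(m) <- vapply(patterns, `[[`, "", "group_name")
  m
}

# element counts parsed from the OpenBabel molecular formula
formula_counts <- function(smiles) {
  obm <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm"), identity)
  f <- ChemmineOB::prop_OB(obm)$formula
  one <- function(el) {
    m <- regmatches(f, regexec(paste0(el, "(?![a-z])([0-9]*)"), f,
                               perl = TRUE))[[1]]
    if (length(m) == 0) return(0L)
    if (m[2] == "") 1L else as.integer(m[2])
  }
  c(C = one("C"), N = one("N"), O = one("O"))
}

# decode a Pruefer sequence into the edge list of a labelled tree
prufer_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, nrow = n - 1, ncol = 2)
  ptr <- 1L
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    edges[ptr, ] <- c(leaf, s)
    ptr <- ptr + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[ptr, ] <- last
  edges
}

# exhaustive minimum spanning tree weight over all n^(n-2) labelled trees
bruteforce_mst_weight <- function(dist) {
  n <- nrow(dist)
  stopifnot(n >= 2)
  if (n == 2) return(dist[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_edges(seqs[r, ], n)
    w <- sum(dist[e])
    if (w < best) best <- w
  }
  best
}

# independent Kruskal MST (union-find), for graphs too large to enumerate
kruskal_mst_weight <- function(dist) {
  n <- nrow(dist)
  pairs <- which(upper.tri(dist), arr.ind = TRUE)
  ord <- order(dist[pairs])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  total <- 0
  used <- 0L
  for (e in ord) {
    a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + dist[pairs[e, 1], pairs[e, 2]]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  total
}

# igraph MST weight of a complete graph with the given distance matrix
igraph_mst_weight <- function(dist) {
  g <- igraph::graph_from_adjacency_matrix(dist, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# synthetic sim_graph for cluster-extraction tests: an MST given directly
# as an edge list with node source tags
synthetic_sim_graph <- function(ids, tags, edges, weights = NULL) {
  idx <- matrix(match(edges, ids), ncol = 2)   # edges: 2-column id matrix
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(idx)))
  igraph::V(g)$name <- ids
  igraph::E(g)$weight <- weights %||% rep(0.5, igraph::ecount(g))
  structure(list(nodes = data.frame(record_id = ids, source_tag = tags,
                                    stringsAsFactors = FALSE),
                 mst = g, graph = g), class = "sim_graph")
}
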