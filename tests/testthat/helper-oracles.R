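# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately avoid every fast path the package
# uses: plain set algebra, exhaustive sums, dense eigendecomposition, and
# igraph for components.

# Exact hypergeometric upper tail P(X >= k) by summing over the support.
# All binomial coefficients are exact in doubles for N <= 25.
oracle_hyper <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Bipartite weights by direct set enumeration: Jaccard times the median DE
# magnitude of the shared genes.
oracle_bipartite <- function(P, G, mags) {
  rows <- list()
  for (g in names(G$sets)) {
    for (p in names(P$sets)) {
      inter <- intersect(G$sets[[g]], P$sets[[p]])
      if (!length(inter)) next
      uni <- union(G$sets[[g]], P$sets[[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        go_id = g, pathway_id = p,
        weight = length(inter) / length(uni) * stats::median(mags[inter]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(go_id = character(0),
                                       pathway_id = character(0),
                                       weight = numeric(0)))
  do.call(rbind, rows)
}

# One-mode projection by an explicit triple loop over pathway pairs and GO
# terms.
oracle_project <- function(edges, pathway_ids, go_ids) {
  A <- matrix(0, length(pathway_ids), length(pathway_ids),
              dimnames = list(pathway_ids, pathway_ids))
  for (i in seq_along(pathway_ids)) {
    for (j in seq_along(pathway_ids)) {
      if (i == j) next
      s <- 0
      for (g in go_ids) {
        wi <- edges$weight[edges$go_id == g &
                             edges$pathway_id == pathway_ids[i]]
        wj <- edges$weight[edges$go_id == g &
                             edges$pathway_id == pathway_ids[j]]
        if (length(wi) && length(wj)) s <- s + wi * wj
      }
      A[i, j] <- s
    }
  }
  A
}

# Eigenvector centrality by dense eigendecomposition on the largest
# connected component (components via igraph), nonnegative orientation,
# zeros elsewhere.
oracle_centrality <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  wt <- vapply(seq_along(comp$csize), function(cc)
    sum(A[comp$membership == cc, comp$membership == cc]), 0)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) best <- best[which.max(wt[best])]
  members <- which(comp$membership == best[1L])
  v <- eigen(A[members, members, drop = FALSE], symmetric = TRUE)$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  out <- numeric(nrow(A))
  out[members] <- v
  out
}

# Random small instance: gene universe, two overlapping collections, and a
# DEG table covering every gene.
rand_instance <- function(seed, max_pathways = 10, max_go = 10,
                          max_genes = 30) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(sample(6:max_genes, 1)))
  rand_sets <- function(n, prefix) {
    sets <- lapply(seq_len(n), function(i)
      sample(genes, sample(seq_len(min(6L, length(genes))), 1)))
    names(sets) <- sprintf("%s%02d", prefix, seq_len(n))
    sets
  }
  P <- gene_set_collection(rand_sets(sample(2:max_pathways, 1), "P"),
                           category = "KEGG")
  G <- gene_set_collection(rand_sets(sample(2:max_go, 1), "G"),
                           category = "GO_BP")
  lfc <- stats::rnorm(length(genes)) +
    sign(stats::rnorm(length(genes))) * 0.1
  degs <- deg_table(gene_id = genes, log2fc = lfc,
                    pvalue = stats::runif(length(genes), 0, 1e-4),
                    qvalue = stats::runif(length(genes), 0, 1e-3))
  list(P = P, G = G, degs = degs,
       mags = stats::setNames(abs(lfc), genes))
}

# The exhaustively enumerable toy used for bootstrap validation: 4 genes
# with distinct magnitudes, chained pathways and GO terms.
toy_bootstrap_instance <- function() {
  genes <- c("g1", "g2", "g3", "g4")
  P <- gene_set_collection(list(P1 = c("g1", "g2"), P2 = c("g2", "g3"),
                                P3 = c("g3", "g4")), category = "KEGG")
  G <- gene_set_collection(list(`GO:1` = c("g1", "g2", "g3"),
                                `GO:2` = c("g2", "g3", "g4")),
                           category = "GO_BP")
  degs <- deg_table(gene_id = genes, log2fc = c(1, -2, 3, -4),
                    pvalue = rep(1e-6, 4), qvalue = rep(1e-4, 4))
  list(P = P, G = G, degs = degs,
       mags = stats::setNames(c(1, 2, 3, 4), genes))
}

# Exact per-pathway bootstrap null by enumerating every with-replacement
# reassignment of the magnitude multiset (m^m equally likely tuples),
# scoring each through the oracle pipeline.
oracle_enumerated_pvalues <- function(P, G, mags) {
  genes <- names(mags)
  m <- length(genes)
  score_of <- function(vals) {
    mg <- stats::setNames(vals, genes)
    edges <- oracle_bipartite(P, G, mg)
    A <- oracle_project(edges, names(P$sets), names(G$sets))
    s <- oracle_centrality(A)
    stats::setNames(s, names(P$sets))
  }
  obs <- score_of(unname(mags))
  grid <- expand.grid(rep(list(unname(mags)), m))
  hits <- matrix(0, nrow(grid), length(obs))
  for (r in seq_len(nrow(grid)))
    hits[r, ] <- score_of(as.numeric(grid[r, ])) >= obs
  list(observed = obs, exact_p = colMeans(hits))
}

expect_no_warning_ <- function(expr) testthat::expect_warning(expr, NA)

# Drop the diagnostic attributes (component_flag, iterations) from a
# centrality vector, keeping names.
strip_scores <- function(s) {
  attributes(s) <- list(names = names(s))
  s
}
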