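#' LPIA configuration
#'
#' Bundles the tunable parameters of the latent-pathway analysis.
#'
#' @param n_boot number of bootstrap replicates `B` (default 1000).
#' @param edge_threshold strictly-greater-than cut on projected
#'   pathway-pathway weights when exporting the network (default 0.1).
#' @param alpha significance level on the adjusted p-value for calling a
#'   pathway latent (default 0.05).
#' @param power_tol L2 residual tolerance of the power iteration.
#' @param power_max_iter iteration cap of the power iteration.
#' @param seed integer seed governing all resampling.
#' @param de_value which per-gene statistic feeds the bipartite weight:
#'   `"abs_log2fc"` (default; magnitude of the log2 fold change),
#'   `"log2fc"` (signed; non-positive weights are dropped), or
#'   `"neglog10_q"`.
#' @param resample bootstrap null construction: `"magnitudes"` (default;
#'   the DE-magnitude multiset is resampled with replacement and reassigned
#'   to the gene ids, annotation topology fixed) or `"genes"` (the gene
#'   universe itself is bootstrap-resampled).
#' @param adjust multiplicity adjustment: `"maxT"` (default; step-down
#'   max-statistic over the joint bootstrap replicates) or `"BH"`.
#' @return A list of class `LPIAConfig`.
#' @export
lpia_config <- function(n_boot = 1000, edge_threshold = 0.1, alpha = 0.05,
                        power_tol = 1e-10, power_max_iter = 10000,
                        seed = 20210505,
                        de_value = c("abs_log2fc", "log2fc", "neglog10_q"),
                        resample = c("magnitudes", "genes"),
                        adjust = c("maxT", "BH")) {
  if (!is.numeric(n_boot) || n_boot < 1) stop("n_boot must be >= 1")
  if (!is.numeric(edge_threshold) || edge_threshold < 0)
    stop("edge_threshold must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  structure(list(n_boot = as.integer(n_boot),
                 edge_threshold = edge_threshold, alpha = alpha,
                 power_tol = power_tol,
                 power_max_iter = as.integer(power_max_iter),
                 seed = as.integer(seed),
                 de_value = match.arg(de_value),
                 resample = match.arg(resample),
                 adjust = match.arg(adjust)),
            class = "LPIAConfig")
}

# Per-gene DE statistic used as DE_x in the bipartite weight.
de_magnitudes <- function(degs, de_value = "abs_log2fc") {
  stopifnot(inherits(degs, "DEGTable"))
  v <- switch(de_value,
              abs_log2fc = abs(degs$log2fc),
              log2fc = degs$log2fc,
              neglog10_q = -log10(pmax(degs$qvalue, 1e-300)),
              stop("unknown de_value: ", de_value))
  stats::setNames(v, degs$gene_id)
}

# Topology of the pathway-GO bipartite graph: which (GO, pathway) pairs
# share genes, their Jaccard index over the DEG universe, and the member
# indices needed to recompute medians under resampling. Built once per
# analysis; the bootstrap reuses it for every replicate.
bipartite_structure <- function(P, G, degs) {
  stopifnot(inherits(P, "GeneSetCollection"), inherits(G, "GeneSetCollection"))
  if (!length(P$sets) || !length(G$sets))
    stop("empty gene-set collection after restriction")
  genes <- unique(c(unlist(P$sets, use.names = FALSE),
                    unlist(G$sets, use.names = FALSE)))
  missing <- setdiff(genes, degs$gene_id)
  if (length(missing))
    stop("gene(s) without a DE record (restrict the collections to the ",
         "DEG universe first): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  gidx <- stats::setNames(seq_along(genes), genes)
  MP <- matrix(0, nrow = length(P$sets), ncol = length(genes))
  for (i in seq_along(P$sets)) MP[i, gidx[P$sets[[i]]]] <- 1
  MG <- matrix(0, nrow = length(G$sets), ncol = length(genes))
  for (i in seq_along(G$sets)) MG[i, gidx[G$sets[[i]]]] <- 1
  inter_count <- MG %*% t(MP)
  hit <- which(inter_count > 0, arr.ind = TRUE)
  sizes_g <- rowSums(MG)
  sizes_p <- rowSums(MP)
  m <- nrow(hit)
  inter_idx <- vector("list", m)
  union_idx <- vector("list", m)
  for (e in seq_len(m)) {
    g <- hit[e, 1L]; p <- hit[e, 2L]
    inter_idx[[e]] <- which(MG[g, ] > 0 & MP[p, ] > 0)
    union_idx[[e]] <- which(MG[g, ] > 0 | MP[p, ] > 0)
  }
  jaccard <- inter_count[hit] /
    (sizes_g[hit[, 1L]] + sizes_p[hit[, 2L]] - inter_count[hit])
  list(genes = genes,
       go_ids = names(G$sets), pathway_ids = names(P$sets),
       go = hit[, 1L], pathway = hit[, 2L],
       jaccard = jaccard, inter_idx = inter_idx, union_idx = union_idx,
       size_groups = .size_groups(inter_idx))
}

# Edges grouped by intersection size so per-replicate medians vectorize.
.size_groups <- function(inter_idx) {
  sizes <- lengths(inter_idx)
  lapply(split(seq_along(inter_idx), sizes), function(cols) {
    s <- length(inter_idx[[cols[1L]]])
    list(cols = cols, size = s,
         idx = matrix(unlist(inter_idx[cols], use.names = FALSE), nrow = s))
  })
}

# Median DE magnitude per edge, vectorized over the common small sizes.
.edge_medians <- function(size_groups, mags, n_edges) {
  out <- numeric(n_edges)
  for (grp in size_groups) {
    s <- grp$size
    M <- grp$idx
    out[grp$cols] <- if (s == 1L) {
      mags[M[1L, ]]
    } else if (s == 2L) {
      (mags[M[1L, ]] + mags[M[2L, ]]) / 2
    } else if (s == 3L) {
      a <- mags[M[1L, ]]; b <- mags[M[2L, ]]; c <- mags[M[3L, ]]
      a + b + c - pmax(a, b, c) - pmin(a, b, c)
    } else {
      apply(matrix(mags[M], nrow = s), 2L, stats::median)
    }
  }
  out
}

#' Build the DE-weighted pathway-GO bipartite graph
#'
#' For every GO term `G` and pathway `P` sharing at least one gene, the edge
#' weight is the Jaccard index of the two sets times the median DE magnitude
#' of the shared genes:
#' `W = (|G n P| / |G u P|) * median{ DE_x : x in G n P }`.
#' Both collections must already be restricted to the DEG universe (see
#' [restrict_to_universe()]); a set member without a DE record is an error.
#' The median of an even-sized multiset is the mean of the two middle
#' values. Pairs with empty intersection carry no edge; edges with
#' non-positive weight (possible only for signed `de_value`) are dropped.
#'
#' @param P pathway `GeneSetCollection`, restricted to the DEG universe.
#' @param G GO-term `GeneSetCollection`, restricted likewise.
#' @param degs a `DEGTable` covering every member gene.
#' @param de_value per-gene statistic, see [lpia_config()].
#' @return A `BipartiteWeightMatrix`: list with `go_ids`, `pathway_ids` and
#'   an `edges` data.frame (`go_id`, `pathway_id`, `weight`).
#' @export
build_bipartite <- function(P, G, degs, de_value = "abs_log2fc") {
  struct <- bipartite_structure(P, G, degs)
  mags <- de_magnitudes(degs, de_value)[struct$genes]
  w <- struct$jaccard *
    .edge_medians(struct$size_groups, mags, length(struct$jaccard))
  keep <- w > 0
  structure(list(go_ids = struct$go_ids,
                 pathway_ids = struct$pathway_ids,
                 edges = data.frame(go_id = struct$go_ids[struct$go[keep]],
                                    pathway_id =
                                      struct$pathway_ids[struct$pathway[keep]],
                                    weight = w[keep],
                                    stringsAsFactors = FALSE)),
            class = "BipartiteWeightMatrix")
}

# Dense GO x pathway weight matrix -> projected pathway adjacency.
.project_weights <- function(w, go, pathway, n_go, n_p) {
  W <- matrix(0, nrow = n_go, ncol = n_p)
  W[cbind(go, pathway)] <- w
  A <- crossprod(W)
  diag(A) <- 0
  A
}

#' Project the bipartite graph to the pathway-pathway network
#'
#' One-mode projection: `A_ij = sum_k W(Gk, Pi) * W(Gk, Pj)` over GO terms
#' `k`, for `i != j`; the diagonal is zero and `A` is exactly symmetric.
#' Pathways with no surviving edge are retained as isolated nodes.
#'
#' @param W a `BipartiteWeightMatrix` from [build_bipartite()].
#' @return A `PathwayNetwork`: list with `pathway_ids` and the symmetric
#'   weight matrix `A` (dimnames = pathway ids).
#' @export
project <- function(W) {
  stopifnot(inherits(W, "BipartiteWeightMatrix"))
  if (!nrow(W$edges)) stop("bipartite graph has no edges")
  gi <- match(W$edges$go_id, W$go_ids)
  pi_ <- match(W$edges$pathway_id, W$pathway_ids)
  A <- .project_weights(W$edges$weight, gi, pi_,
                        length(W$go_ids), length(W$pathway_ids))
  dimnames(A) <- list(W$pathway_ids, W$pathway_ids)
  structure(list(pathway_ids = W$pathway_ids, A = A),
            class = "PathwayNetwork")
}

# Connected components of a nonnegative symmetric adjacency matrix (BFS).
# Returns the integer component label per node.
.components <- function(A) {
  n <- nrow(A)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      new <- nbr[[v]][comp[nbr[[v]]] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# Principal component of the network: largest component, ties broken by
# total edge weight.
.principal_component <- function(A) {
  comp <- .components(A)
  sizes <- tabulate(comp)
  weight <- vapply(seq_along(sizes), function(cc) {
    sum(A[comp == cc, comp == cc])
  }, 0)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) best <- best[which.max(weight[best])]
  list(members = which(comp == best[1L]), comp = comp)
}

# Power iteration on (A + I): the shift leaves eigenvectors unchanged but
# guarantees convergence for symmetric nonnegative A (breaks +/-lambda
# oscillation). Uniform positive start; L2-normalized each step.
.power_iteration <- function(A, tol, max_iter) {
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    res <- sqrt(sum((y - x)^2))
    x <- y
    if (res < tol)
      return(list(vector = x, iterations = it, residual = res))
  }
  stop(sprintf("power iteration did not converge in %d iterations (final residual %.3e)",
               max_iter, res))
}

#' Eigenvector centrality of the pathway network
#'
#' Principal-eigenvector scores of the weighted adjacency matrix, computed
#' by power iteration restricted to the largest connected component (ties
#' between equal-sized components broken by total edge weight). Scores are
#' nonnegative and L2-normalized over that component; pathways outside it
#' score 0 and are flagged `"off_component"` in
#' `attr(scores, "component_flag")`. Deterministic for fixed input, and
#' invariant to positive rescaling of `A`.
#'
#' @param net a `PathwayNetwork` with at least one edge.
#' @param tol L2 residual tolerance (default `1e-10`).
#' @param max_iter iteration cap (default `10000`).
#' @return Named numeric vector of centrality scores with attributes
#'   `component_flag` (named character) and `iterations`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(net, "PathwayNetwork"))
  A <- net$A
  if (!any(A > 0)) stop("network has no edges")
  pc <- .principal_component(A)
  off <- setdiff(seq_len(nrow(A)), pc$members)
  if (length(off))
    warning(length(off), " pathway(s) outside the principal component ",
            "scored 0")
  pw <- .power_iteration(A[pc$members, pc$members, drop = FALSE],
                         tol, max_iter)
  scores <- stats::setNames(numeric(nrow(A)), net$pathway_ids)
  scores[pc$members] <- pw$vector
  flag <- stats::setNames(rep("off_component", nrow(A)), net$pathway_ids)
  flag[pc$members] <- "principal"
  attr(scores, "component_flag") <- flag
  attr(scores, "iterations") <- pw$iterations
  scores
}

# Centrality for a bootstrap replicate: a replicate whose network lost all
# edges scores everyone 0 instead of erroring.
.replicate_scores <- function(A, tol, max_iter) {
  if (!any(A > 0)) return(numeric(nrow(A)))
  pc <- .principal_component(A)
  s <- numeric(nrow(A))
  s[pc$members] <- .power_iteration(A[pc$members, pc$members, drop = FALSE],
                                    tol, max_iter)$vector
  s
}

#' Bootstrap significance of pathway centralities
#'
#' Computes the observed centrality of every pathway, then generates `B`
#' null replicates and attaches per-pathway bootstrap p-values. Under the
#' default null, the multiset of DE magnitudes is resampled with
#' replacement and reassigned to the gene ids while all gene-set
#' memberships stay fixed — the null keeps the annotation topology and asks
#' whether the placement of strong DE responses on the bipartite graph
#' drives a pathway's centrality. Each replicate reruns the full
#' weight-projection-centrality pipeline.
#'
#' Raw p-values use the add-one estimator
#' `(1 + #\{b : e_b >= e_obs\}) / (B + 1)`, so 0 is never reported.
#' Adjusted p-values use step-down max-statistic adjustment over the joint
#' replicates (the familywise-error-controlling resampling scheme of the
#' Westfall-Young / Dudoit-van der Laan family): hypotheses are ordered by
#' decreasing observed score, each is compared against the running maximum
#' of the null scores over itself and all lower-ranked hypotheses, and
#' monotonicity is enforced down the ranking. `adjust = "BH"` substitutes
#' Benjamini-Hochberg on the raw p-values.
#'
#' @param P,G gene-set collections restricted to the DEG universe.
#' @param degs a `DEGTable` covering every member gene.
#' @param cfg an [lpia_config()].
#' @return A `CentralityResult`: list with `pathway_ids`, `scores`,
#'   `raw_p`, `adjusted_p` (all named), `component_flag`, `n_boot`, `seed`,
#'   `adjust`, `resample`.
#' @export
bootstrap_significance <- function(P, G, degs, cfg = lpia_config()) {
  stopifnot(inherits(cfg, "LPIAConfig"))
  struct <- bipartite_structure(P, G, degs)
  n_p <- length(struct$pathway_ids)
  n_g <- length(struct$go_ids)
  if (length(unique(struct$pathway[struct$jaccard > 0])) < 2L)
    stop("degenerate universe: fewer than 2 pathways carry bipartite edges")
  mags <- de_magnitudes(degs, cfg$de_value)[struct$genes]
  n_e <- length(struct$jaccard)

  weights_for <- function(m) {
    struct$jaccard * .edge_medians(struct$size_groups, m, n_e)
  }
  scores_for <- function(w) {
    w <- pmax(w, 0)
    A <- .project_weights(w, struct$go, struct$pathway, n_g, n_p)
    .replicate_scores(A, cfg$power_tol, cfg$power_max_iter)
  }
  obs <- scores_for(weights_for(mags))
  if (!any(obs > 0)) stop("observed network has no edges")

  old_seed <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  B <- cfg$n_boot
  E <- matrix(0, nrow = B, ncol = n_p)
  if (cfg$resample == "magnitudes") {
    for (b in seq_len(B))
      E[b, ] <- scores_for(weights_for(sample(mags, replace = TRUE)))
  } else {
    n_genes <- length(struct$genes)
    for (b in seq_len(B)) {
      in_s <- logical(n_genes)
      in_s[unique(sample.int(n_genes, replace = TRUE))] <- TRUE
      w <- vapply(seq_len(n_e), function(e) {
        ii <- struct$inter_idx[[e]][in_s[struct$inter_idx[[e]]]]
        if (!length(ii)) return(0)
        uu <- sum(in_s[struct$union_idx[[e]]])
        (length(ii) / uu) * stats::median(mags[ii])
      }, 0)
      E[b, ] <- scores_for(w)
    }
  }

  raw_p <- (1 + colSums(E >= rep(obs, each = B))) / (B + 1)
  if (cfg$adjust == "maxT") {
    ord <- order(-obs, struct$pathway_ids)
    Eord <- E[, ord, drop = FALSE]
    # running max of null scores over each hypothesis and all below it
    U <- Eord
    for (j in rev(seq_len(n_p - 1L))) U[, j] <- pmax(U[, j], U[, j + 1L])
    adj <- (1 + colSums(U >= rep(obs[ord], each = B))) / (B + 1)
    adj <- cummax(adj)               # step-down monotonicity
    adjusted_p <- numeric(n_p)
    adjusted_p[ord] <- adj
  } else {
    adjusted_p <- bh_adjust(raw_p)
  }
  adjusted_p <- pmax(adjusted_p, raw_p)

  flag <- rep("off_component", n_p)
  flag[obs > 0] <- "principal"
  nm <- struct$pathway_ids
  structure(list(pathway_ids = nm,
                 scores = stats::setNames(obs, nm),
                 raw_p = stats::setNames(raw_p, nm),
                 adjusted_p = stats::setNames(adjusted_p, nm),
                 component_flag = stats::setNames(flag, nm),
                 n_boot = B, seed = cfg$seed,
                 adjust = cfg$adjust, resample = cfg$resample),
            class = "CentralityResult")
}

#' @export
print.CentralityResult <- function(x, ...) {
  cat(sprintf("CentralityResult: %d pathways, B = %d, seed = %d (%s null, %s adjustment)\n",
              length(x$pathway_ids), x$n_boot, x$seed, x$resample, x$adjust))
  top <- order(-x$scores)[seq_len(min(5L, length(x$scores)))]
  for (i in top)
    cat(sprintf("  %-14s score %.4f  raw p %s  adj p %s\n",
                x$pathway_ids[i], x$scores[i],
                format_pvalue(x$raw_p[i], x$n_boot),
                format_pvalue(x$adjusted_p[i], x$n_boot)))
  invisible(x)
}

#' Display formatting for bootstrap p-values
#'
#' A bootstrap p-value can never be below `1/(B+1)`; values at the
#' resolution floor are rendered `"<..."` so a printed `0.00` is never
#' mistaken for a literal zero.
#'
#' @param p numeric p-value(s).
#' @param n_boot the number of replicates behind them.
#' @return Character vector.
#' @export
format_pvalue <- function(p, n_boot) {
  floor_ <- 1 / (n_boot + 1)
  ifelse(p < 2 * floor_, sprintf("<%.3g", 2 * floor_), sprintf("%.4f", p))
}

#' Tabulate a centrality result
#'
#' @param x a `CentralityResult`.
#' @param ... unused.
#' @return data.frame with columns `pathway_id`, `score`, `raw_p`,
#'   `adjusted_p`, `component_flag`, ordered by descending score.
#' @export
as.data.frame.CentralityResult <- function(x, ...) {
  df <- data.frame(pathway_id = x$pathway_ids,
                   score = unname(x$scores),
                   raw_p = unname(x$raw_p),
                   adjusted_p = unname(x$adjusted_p),
                   component_flag = unname(x$component_flag),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select latent pathways
#'
#' Pathways whose adjusted p-value is at or below `alpha`, ordered by
#' descending centrality score, ties broken by ascending pathway id. An
#' `alpha` below the bootstrap resolution `1/(B+1)` legitimately yields an
#' empty selection.
#'
#' @param result a `CentralityResult`.
#' @param alpha significance level in (0, 1).
#' @return Character vector of pathway ids (possibly empty).
#' @export
select_latent <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "CentralityResult"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  hit <- result$pathway_ids[result$adjusted_p <= alpha]
  hit[order(-result$scores[hit], hit)]
}

# Attach a stage name to errors propagated out of a pipeline step.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' In-memory LPIA pipeline
#'
#' Restricts both collections to the DEG universe, builds the bipartite
#' graph and pathway network, and runs [bootstrap_significance()] and
#' [select_latent()].
#'
#' @param P,G gene-set collections (unrestricted is fine).
#' @param degs a filtered `DEGTable`.
#' @param cfg an [lpia_config()].
#' @return List with `result` (`CentralityResult`), `network`
#'   (`PathwayNetwork`), `bipartite`, `latent` (character vector), and
#'   `counts` (stage counts).
#' @export
lpia_analysis <- function(P, G, degs, cfg = lpia_config()) {
  stopifnot(inherits(degs, "DEGTable"))
  Pr <- .stage("restrict", restrict_to_universe(P, degs$gene_id))
  Gr <- .stage("restrict", restrict_to_universe(G, degs$gene_id))
  W <- .stage("build_bipartite", build_bipartite(Pr, Gr, degs, cfg$de_value))
  net <- .stage("project", project(W))
  result <- .stage("bootstrap", bootstrap_significance(Pr, Gr, degs, cfg))
  latent <- select_latent(result, cfg$alpha)
  list(result = result, network = net, bipartite = W, latent = latent,
       counts = list(n_deg = nrow(degs),
                     n_pathways_in = length(P$sets),
                     n_go_in = length(G$sets),
                     n_pathways_network = length(Pr$sets),
                     n_go_network = length(Gr$sets),
                     n_bipartite_edges = nrow(W$edges),
                     n_latent = length(latent)))
}

#' Run the full LPIA pipeline from files
#'
#' Reads the pathway and GO-term collections and the DEG table, filters
#' DEGs at `deg_q_threshold`, restricts the collections to the DEG
#' universe, and runs the bipartite build, projection and bootstrap
#' centrality analysis. A run manifest (inputs with MD5 hashes, thresholds,
#' seed, stage counts) is returned and, when `output_dir` is given, written
#' as YAML alongside the centrality table and the thresholded network
#' (edge/node TSV, SIF, GraphML, and the full weight matrix).
#'
#' @param p_path,g_path gene-set files readable by [read_gmt()].
#' @param deg_path DEG TSV readable by [read_deg_table()].
#' @param cfg an [lpia_config()].
#' @param column_map column mapping for the DEG table.
#' @param deg_q_threshold FDR cut for calling DEGs (default 0.001).
#' @param enrichment_rows optional [enrich()] table used to annotate
#'   exported nodes.
#' @param output_dir optional directory for result files.
#' @return As [lpia_analysis()], plus `manifest`.
#' @export
run_lpia <- function(p_path, g_path, deg_path, cfg = lpia_config(),
                     column_map = c(gene_id = "gene_id", log2fc = "log2fc",
                                    pvalue = "pvalue", qvalue = "qvalue"),
                     deg_q_threshold = 0.001, enrichment_rows = NULL,
                     output_dir = NULL) {
  P <- .stage("read_pathways", read_gmt(p_path, "KEGG"))
  G <- .stage("read_go_terms", read_gmt(g_path, "GO_BP"))
  degs <- .stage("read_degs", read_deg_table(deg_path, column_map))
  filtered <- .stage("filter_degs", filter_degs(degs, deg_q_threshold))
  if (!nrow(filtered))
    stop("stage 'restrict': no DEGs pass q <= ", deg_q_threshold)
  ana <- lpia_analysis(P, G, filtered, cfg)
  manifest <- list(
    inputs = list(pathways = unname(p_path), go_terms = unname(g_path),
                  degs = unname(deg_path)),
    input_md5 = as.list(tools::md5sum(c(p_path, g_path, deg_path))),
    config = unclass(cfg),
    deg_q_threshold = deg_q_threshold,
    counts = c(list(n_deg_input = nrow(degs)), ana$counts),
    latent = as.list(ana$latent))
  ana$manifest <- manifest
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    ct <- as.data.frame(ana$result)
    utils::write.table(ct, file.path(output_dir, "centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
    edges <- edge_list(ana$network, cfg$edge_threshold)
    nodes <- assemble_node_attributes(enrichment_rows, ana$result, cfg$alpha)
    for (fmt in c("tsv", "sif", "graphml"))
      write_network(edges, nodes,
                    file.path(output_dir, paste0("network.", fmt)),
                    format = fmt)
    write_pathway_network(ana$network,
                          file.path(output_dir, "network_weights.tsv"))
  }
  ana
}

#' Write / read the full pathway-pathway weight matrix
#'
#' TSV with pathway ids as row and column names; exact values, no
#' thresholding. `read_pathway_network()` is its inverse.
#'
#' @param net a `PathwayNetwork`.
#' @param path file path.
#' @return `path` invisibly / a `PathwayNetwork`.
#' @export
write_pathway_network <- function(net, path) {
  stopifnot(inherits(net, "PathwayNetwork"))
  df <- data.frame(pathway_id = net$pathway_ids,
                   as.data.frame(net$A, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathway_network
#' @export
read_pathway_network <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$pathway_id)
  A <- as.matrix(df[, -1, drop = FALSE])
  dimnames(A) <- list(ids, ids)
  structure(list(pathway_ids = ids, A = A), class = "PathwayNetwork")
}
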