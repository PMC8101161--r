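test_that("bipartite weights follow Jaccard x median of shared DE magnitudes", {
  degs <- deg_table(gene_id = c("g1", "g2", "g3", "g4"),
                    log2fc = c(1, 2, -4, 0.5),
                    pvalue = rep(1e-6, 4), qvalue = rep(1e-4, 4))
  P <- gene_set_collection(list(P1 = c("g2", "g3", "g4")), "KEGG")
  G <- gene_set_collection(list(G1 = c("g1", "g2", "g3")), "GO_BP")
  W <- build_bipartite(P, G, degs)
  # |G n P| = 2, |G u P| = 4, median{2, 4} = 3
  expect_equal(W$edges$weight, 0.5 * 3)

  # identical sets with unit magnitudes: Jaccard 1 x median 1
  unit <- deg_table(gene_id = c("a", "b"), log2fc = c(1, -1),
                    pvalue = c(0, 0), qvalue = c(0, 0))
  S <- gene_set_collection(list(X = c("a", "b")), "KEGG")
  Sg <- gene_set_collection(list(Y = c("a", "b")), "GO_BP")
  expect_equal(build_bipartite(S, Sg, unit)$edges$weight, 1.0)

  # disjoint sets carry no edge
  D <- gene_set_collection(list(P1 = "a"), "KEGG")
  Dg <- gene_set_collection(list(G1 = "b"), "GO_BP")
  expect_equal(nrow(build_bipartite(D, Dg, unit)$edges), 0L)

  # a member without a DE record signals a skipped restriction step
  Pbad <- gene_set_collection(list(P1 = c("g1", "gX")), "KEGG")
  expect_error(build_bipartite(Pbad, G, degs), "gX")
})

test_that("projection sums products of shared-GO weights symmetrically", {
  # W(G1,P1)=0.5, W(G1,P2)=0.2, W(G2,P1)=0.3, W(G2,P2)=0.4 -> A_12 = 0.22
  W <- structure(list(go_ids = c("G1", "G2"), pathway_ids = c("P1", "P2"),
                      edges = data.frame(
                        go_id = c("G1", "G1", "G2", "G2"),
                        pathway_id = c("P1", "P2", "P1", "P2"),
                        weight = c(0.5, 0.2, 0.3, 0.4),
                        stringsAsFactors = FALSE)),
                 class = "BipartiteWeightMatrix")
  net <- project(W)
  expect_equal(net$A["P1", "P2"], 0.5 * 0.2 + 0.3 * 0.4)
  expect_identical(net$A, t(net$A))
  expect_equal(diag(net$A), c(P1 = 0, P2 = 0))

  W$edges <- W$edges[1:2, ]   # single shared GO term with weights w1, w2
  expect_equal(project(W)$A["P1", "P2"], 0.5 * 0.2)

  W$edges <- W$edges[1, , drop = FALSE]  # no shared GO term
  expect_equal(project(W)$A["P1", "P2"], 0)
})

test_that("bipartite and projection match brute-force set oracles", {
  for (seed in 1:20) {
    inst <- rand_instance(seed)
    W <- build_bipartite(inst$P, inst$G, inst$degs)
    ref <- oracle_bipartite(inst$P, inst$G, inst$mags)
    key <- function(d) paste(d$go_id, d$pathway_id)
    expect_setequal(key(W$edges), key(ref))
    m <- match(key(W$edges), key(ref))
    expect_equal(W$edges$weight, ref$weight[m], tolerance = 1e-12)

    if (!nrow(W$edges)) next   # fully disjoint draw: nothing to project
    net <- project(W)
    refA <- oracle_project(ref, names(inst$P$sets), names(inst$G$sets))
    expect_equal(net$A, refA[net$pathway_ids, net$pathway_ids],
                 tolerance = 1e-12)
  }
})

test_that("a GO term disjoint from every pathway changes nothing", {
  inst <- rand_instance(42)
  extra_gene <- "zz_orphan"
  degs2 <- deg_table(gene_id = c(inst$degs$gene_id, extra_gene),
                     log2fc = c(inst$degs$log2fc, 5),
                     pvalue = c(inst$degs$pvalue, 1e-9),
                     qvalue = c(inst$degs$qvalue, 1e-6))
  G2 <- gene_set_collection(c(inst$G$sets, list(`GO:orphan` = extra_gene)),
                            category = "GO_BP")
  W1 <- build_bipartite(inst$P, inst$G, inst$degs)
  W2 <- build_bipartite(inst$P, G2, degs2)
  expect_equal(W1$edges[, c("go_id", "pathway_id", "weight")],
               W2$edges[, c("go_id", "pathway_id", "weight")])
  expect_equal(project(W1)$A, project(W2)$A)
})

test_that("centrality solves the closed forms and the dense eigen oracle", {
  two <- structure(list(pathway_ids = c("P1", "P2"),
                        A = matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("P1", "P2"),
                                                   c("P1", "P2")))),
                   class = "PathwayNetwork")
  expect_equal(as.numeric(eigenvector_centrality(two)),
               c(1, 1) / sqrt(2), tolerance = 1e-8)

  # path graph 1-2-3: principal eigenvector (1, sqrt(2), 1)/2
  A <- matrix(0, 3, 3, dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  path_net <- structure(list(pathway_ids = paste0("P", 1:3), A = A),
                        class = "PathwayNetwork")
  expect_equal(as.numeric(eigenvector_centrality(path_net)),
               c(1, sqrt(2), 1) / 2, tolerance = 1e-8)

  # scale invariance
  scaled <- path_net
  scaled$A <- 17.3 * A
  expect_equal(strip_scores(eigenvector_centrality(scaled)),
               strip_scores(eigenvector_centrality(path_net)),
               tolerance = 1e-10)

  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:50, 1)
    M <- matrix(stats::runif(n * n), n)
    M[M < 0.5] <- 0
    M <- (M + t(M)) / 2
    diag(M) <- 0
    if (!any(M > 0)) next
    dimnames(M) <- list(paste0("P", 1:n), paste0("P", 1:n))
    net <- structure(list(pathway_ids = rownames(M), A = M),
                     class = "PathwayNetwork")
    got <- suppressWarnings(eigenvector_centrality(net))
    expect_equal(as.numeric(got), oracle_centrality(M), tolerance = 1e-8)
  }
})

test_that("off-component pathways score zero and are flagged", {
  # two 2-node components; the heavier one is principal
  A <- matrix(0, 5, 5, dimnames = list(paste0("P", 1:5), paste0("P", 1:5)))
  A[1, 2] <- A[2, 1] <- 3
  A[3, 4] <- A[4, 3] <- 1
  net <- structure(list(pathway_ids = paste0("P", 1:5), A = A),
                   class = "PathwayNetwork")
  expect_warning(s <- eigenvector_centrality(net), "outside")
  flag <- attr(s, "component_flag")
  expect_equal(unname(flag), c("principal", "principal", "off_component",
                               "off_component", "off_component"))
  expect_equal(as.numeric(s), c(1, 1, 0, 0, 0) / sqrt(2), tolerance = 1e-8)
  expect_equal(sum(s^2), 1, tolerance = 1e-10)

  empty <- net
  empty$A[] <- 0
  expect_error(eigenvector_centrality(empty), "no edges")

  path3 <- matrix(0, 3, 3, dimnames = list(paste0("P", 1:3),
                                           paste0("P", 1:3)))
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  path_net <- structure(list(pathway_ids = rownames(path3), A = path3),
                        class = "PathwayNetwork")
  expect_error(eigenvector_centrality(path_net, max_iter = 1),
               "did not converge")
})

test_that("identical DE magnitudes give bootstrap p = 1 everywhere", {
  degs <- deg_table(gene_id = paste0("g", 1:6),
                    log2fc = rep(2, 6), pvalue = rep(0, 6),
                    qvalue = rep(0, 6))
  P <- gene_set_collection(list(P1 = paste0("g", 1:3),
                                P2 = paste0("g", 3:5),
                                P3 = paste0("g", 4:6)), "KEGG")
  G <- gene_set_collection(list(A = paste0("g", 2:4),
                                B = paste0("g", 3:6)), "GO_BP")
  res <- bootstrap_significance(P, G, degs, lpia_config(n_boot = 50,
                                                        seed = 7))
  expect_equal(unname(res$raw_p), rep(1, 3))
  expect_equal(unname(res$adjusted_p), rep(1, 3))
})

test_that("rescaling all DE magnitudes leaves scores and p-values unchanged", {
  inst <- rand_instance(11)
  cfg <- lpia_config(n_boot = 60, seed = 99)
  r1 <- bootstrap_significance(inst$P, inst$G, inst$degs, cfg)
  scaled <- inst$degs
  scaled$log2fc <- scaled$log2fc * 3.7
  class(scaled) <- class(inst$degs)
  r2 <- bootstrap_significance(inst$P, inst$G, scaled, cfg)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-8)
  expect_equal(r1$raw_p, r2$raw_p)
  expect_equal(r1$adjusted_p, r2$adjusted_p)

  W1 <- build_bipartite(inst$P, inst$G, inst$degs)
  W2 <- build_bipartite(inst$P, inst$G, scaled)
  expect_equal(W2$edges$weight, 3.7 * W1$edges$weight, tolerance = 1e-12)
  expect_equal(project(W2)$A, 3.7^2 * project(W1)$A, tolerance = 1e-10)
})

test_that("bootstrap p-values respect bounds and step-down monotonicity", {
  inst <- rand_instance(13)
  cfg <- lpia_config(n_boot = 80, seed = 5)
  res <- bootstrap_significance(inst$P, inst$G, inst$degs, cfg)
  B <- cfg$n_boot
  expect_true(all(res$raw_p >= 1 / (B + 1) - 1e-12))
  expect_true(all(res$raw_p <= 1))
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-12))
  expect_true(all(res$adjusted_p <= 1))
  ord <- order(-res$scores, res$pathway_ids)
  expect_true(all(diff(res$adjusted_p[ord]) >= -1e-12))
})

test_that("degenerate universes are rejected", {
  degs <- deg_table(gene_id = c("a", "b"), log2fc = c(1, 2),
                    pvalue = c(0, 0), qvalue = c(0, 0))
  P1 <- gene_set_collection(list(only = c("a", "b")), "KEGG")
  G1 <- gene_set_collection(list(g = c("a", "b")), "GO_BP")
  expect_error(bootstrap_significance(P1, G1, degs, lpia_config(n_boot = 5)),
               "degenerate")
  expect_error(lpia_config(n_boot = 0), "n_boot")
})

test_that("latent selection thresholds, orders and validates", {
  res <- structure(list(pathway_ids = c("pA", "pB", "pC"),
                        scores = c(pA = 0.3, pB = 0.9, pC = 0.6),
                        raw_p = c(pA = 0.001, pB = 0.2, pC = 0.01),
                        adjusted_p = c(pA = 0.001, pB = 0.2, pC = 0.04),
                        component_flag = c(pA = "principal",
                                           pB = "principal",
                                           pC = "principal"),
                        n_boot = 999L, seed = 1L, adjust = "maxT",
                        resample = "magnitudes"),
                   class = "CentralityResult")
  expect_equal(select_latent(res, 0.05), c("pC", "pA"))  # by score desc
  expect_equal(select_latent(res, 0.0005), character(0))
  expect_error(select_latent(res, 0), "alpha")
  expect_error(select_latent(res, 1), "alpha")

  tied <- res
  tied$scores[] <- 0.5
  expect_equal(select_latent(tied, 0.05), c("pA", "pC"))  # id tie-break
})

test_that("file-level pipeline reproduces itself and names failing stages", {
  dir <- withr::local_tempdir()
  generate_scenario(synthetic_scenario(n_genes = 300, n_deg = 80,
                                       n_pathways = 10, n_go = 25,
                                       pathway_size_range = c(6, 12),
                                       go_size_range = c(5, 10),
                                       seed = 4),
                    dir = dir)
  cfg <- lpia_config(n_boot = 40, seed = 21)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  ana <- run_lpia(file.path(dir, "pathways.gmt"),
                  file.path(dir, "go_terms.gmt"),
                  file.path(dir, "degs.tsv"), cfg, output_dir = out1)
  run_lpia(file.path(dir, "pathways.gmt"), file.path(dir, "go_terms.gmt"),
           file.path(dir, "degs.tsv"), cfg, output_dir = out2)
  expect_equal(ana$counts$n_pathways_in, 10L)
  expect_equal(ana$manifest$counts$n_deg_input, 88L)  # 80 DEGs + 10% margin
  expect_equal(ana$counts$n_deg, 80L)
  for (f in c("centrality.tsv", "network.tsv", "network_nodes.tsv",
              "network.sif", "network.graphml", "network_weights.tsv",
              "manifest.yaml"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))

  # an empty DEG table fails at the restriction stage, by name
  deg_path <- file.path(dir, "no_degs.tsv")
  writeLines(c("gene_id\tlog2fc\tpvalue\tqvalue", "g1\t2\t0.5\t0.9"),
             deg_path)
  expect_error(run_lpia(file.path(dir, "pathways.gmt"),
                        file.path(dir, "go_terms.gmt"), deg_path, cfg),
               "stage 'restrict'")
})
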