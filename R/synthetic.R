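#' Define a synthetic LPIA scenario
#'
#' Describes a simulated study: a gene universe with a DE subset, randomly
#' overlapping pathway and GO-term annotations, and one planted "latent"
#' pathway whose GO-mediated connectivity — not its raw enrichment — is
#' elevated. Each pathway draws its members uniformly from the DEG pool;
#' each GO term, with probability `base_overlap`, adopts a random parent
#' pathway and takes a fraction of its members from it, otherwise draws
#' from the global pool. The planted pathway is additionally adopted as
#' parent by `planted_go_links` GO terms, and the DE magnitudes of the
#' genes it shares with them are multiplied by `planted_lfc_boost`. With
#' `planted_lfc_boost = 1` and `planted_go_links = 0` the scenario is an
#' exchangeable null.
#'
#' @param n_genes size of the measured-gene universe.
#' @param n_deg number of differentially expressed genes.
#' @param n_pathways,n_go number of pathway / GO-term gene sets.
#' @param pathway_size_range,go_size_range inclusive integer ranges of set
#'   sizes (drawn uniformly), within the DEG pool.
#' @param base_overlap probability that a GO term adopts a parent pathway.
#' @param lfc_null_sd DE magnitudes are `|Normal(0, lfc_null_sd)|`.
#' @param planted_id id of the planted pathway.
#' @param planted_go_links number of GO terms forced to overlap it.
#' @param planted_lfc_boost multiplier on the shared genes' magnitudes.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `SyntheticScenario`.
#' @export
synthetic_scenario <- function(n_genes = 2000, n_deg = 400,
                               n_pathways = 40, n_go = 120,
                               pathway_size_range = c(10, 30),
                               go_size_range = c(8, 25),
                               base_overlap = 0.6, lfc_null_sd = 2,
                               planted_id = "P001", planted_go_links = 10,
                               planted_lfc_boost = 3, seed = 1) {
  if (n_deg > n_genes) stop("n_deg must be <= n_genes")
  for (r in list(pathway_size_range, go_size_range)) {
    if (length(r) != 2L || any(r < 1) || r[1] > r[2])
      stop("size ranges must be positive increasing pairs")
    if (r[2] > n_deg) stop("set sizes cannot exceed n_deg")
  }
  if (planted_go_links > n_go) stop("planted_go_links must be <= n_go")
  if (planted_lfc_boost <= 0) stop("planted_lfc_boost must be > 0")
  if (base_overlap < 0 || base_overlap > 1)
    stop("base_overlap must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes), n_deg = as.integer(n_deg),
                 n_pathways = as.integer(n_pathways),
                 n_go = as.integer(n_go),
                 pathway_size_range = as.integer(pathway_size_range),
                 go_size_range = as.integer(go_size_range),
                 base_overlap = base_overlap, lfc_null_sd = lfc_null_sd,
                 planted_id = planted_id,
                 planted_go_links = as.integer(planted_go_links),
                 planted_lfc_boost = planted_lfc_boost,
                 seed = as.integer(seed)),
            class = "SyntheticScenario")
}

#' Generate a synthetic dataset
#'
#' Realizes a [synthetic_scenario()]: pathway and GO-term collections, a
#' DEG table (true DEGs with q-values below 0.001 plus a 10% margin of
#' near-threshold non-DEG rows, so DEG filtering has something to do), and
#' the ground truth of the planted signal. Bit-reproducible for a fixed
#' seed; q-values are paired to DE magnitudes by rank so that stronger
#' responses get stochastically smaller q-values. When `dir` is given the
#' dataset is also written as `pathways.gmt`, `go_terms.gmt`, `degs.tsv`
#' and `truth.yaml` — the exact formats [read_gmt()] and [read_deg_table()]
#' consume.
#'
#' @param scn a `SyntheticScenario`.
#' @param dir optional output directory.
#' @return List with `P`, `G` (`GeneSetCollection`s), `degs` (`DEGTable`)
#'   and `truth` (list: `planted_id`, `realized_go_links`,
#'   `overlap_genes`).
#' @export
generate_scenario <- function(scn, dir = NULL) {
  stopifnot(inherits(scn, "SyntheticScenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(scn$seed)

  genes <- sprintf("g%05d", seq_len(scn$n_genes))
  deg_pool <- sort(sample(genes, scn$n_deg))
  mags <- abs(stats::rnorm(scn$n_deg, 0, scn$lfc_null_sd))
  names(mags) <- deg_pool

  path_ids <- sprintf("P%03d", seq_len(scn$n_pathways))
  if (!scn$planted_id %in% path_ids)
    stop("planted_id ", scn$planted_id, " not among generated pathway ids")
  psz <- sample(seq(scn$pathway_size_range[1], scn$pathway_size_range[2]),
                scn$n_pathways, replace = TRUE)
  psz[path_ids == scn$planted_id] <-
    round(mean(scn$pathway_size_range))   # planted: unexceptional size
  P_sets <- lapply(psz, function(s) sample(deg_pool, s))
  names(P_sets) <- path_ids
  planted_members <- P_sets[[scn$planted_id]]

  go_ids <- sprintf("GO:%07d", seq_len(scn$n_go))
  linked <- if (scn$planted_go_links > 0)
    sample(scn$n_go, scn$planted_go_links) else integer(0)
  G_sets <- vector("list", scn$n_go)
  for (i in seq_len(scn$n_go)) {
    s <- sample(seq(scn$go_size_range[1], scn$go_size_range[2]), 1L)
    parent <- NULL
    frac <- 0
    if (i %in% linked) {
      parent <- planted_members
      frac <- stats::runif(1, 0.4, 0.7)
    } else if (stats::runif(1) < scn$base_overlap) {
      parent <- P_sets[[sample(scn$n_pathways, 1L)]]
      frac <- stats::runif(1, 0.3, 0.7)
    }
    take <- if (is.null(parent)) character(0) else
      sample(parent, min(length(parent), max(1L, round(frac * s))))
    rest <- sample(setdiff(deg_pool, take), s - length(take))
    G_sets[[i]] <- sample(c(take, rest))
  }
  names(G_sets) <- go_ids

  overlap_genes <- lapply(linked, function(i)
    intersect(G_sets[[i]], planted_members))
  names(overlap_genes) <- go_ids[linked]
  boosted <- unique(unlist(overlap_genes, use.names = FALSE))
  mags[boosted] <- mags[boosted] * scn$planted_lfc_boost

  # q-values paired to magnitudes by rank: strongest response, smallest q
  q_deg <- sort(stats::runif(scn$n_deg, 0, 0.001))
  q_deg <- q_deg[rank(-mags, ties.method = "first")]
  n_null <- round(0.1 * scn$n_deg)
  null_genes <- sample(setdiff(genes, deg_pool), n_null)
  null_mags <- abs(stats::rnorm(n_null, 0, scn$lfc_null_sd / 2))
  q_null <- sort(stats::runif(n_null, 0.0012, 1))
  q_null <- q_null[rank(-null_mags, ties.method = "first")]

  gene_id <- c(deg_pool, null_genes)
  mag_all <- c(unname(mags), null_mags)
  q_all <- c(q_deg, q_null)
  sign_ <- sample(c(-1, 1), length(gene_id), replace = TRUE)
  degs <- deg_table(gene_id = gene_id,
                    log2fc = sign_ * mag_all,
                    pvalue = q_all * stats::runif(length(q_all)),
                    qvalue = q_all,
                    background = genes)

  P <- gene_set_collection(P_sets, category = "KEGG")
  G <- gene_set_collection(G_sets, category = "GO_BP")
  truth <- list(planted_id = scn$planted_id,
                realized_go_links =
                  sum(vapply(overlap_genes, length, 0L) > 0L),
                overlap_genes = overlap_genes)
  out <- list(P = P, G = G, degs = degs, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gmt(P, file.path(dir, "pathways.gmt"))
    write_gmt(G, file.path(dir, "go_terms.gmt"))
    write_deg_table(degs, file.path(dir, "degs.tsv"))
    yaml::write_yaml(list(planted_id = truth$planted_id,
                          realized_go_links = truth$realized_go_links,
                          overlap_genes = lapply(truth$overlap_genes,
                                                 as.list),
                          scenario = unclass(scn)),
                     file.path(dir, "truth.yaml"))
  }
  out
}

#' Generate the matched null scenario
#'
#' Same generator with the planted effect switched off
#' (`planted_lfc_boost = 1`, `planted_go_links = 0`): DE magnitudes are
#' exchangeable across genes, so no pathway is truly latent.
#'
#' @param scn a `SyntheticScenario`.
#' @param dir optional output directory.
#' @return As [generate_scenario()].
#' @export
null_scenario <- function(scn, dir = NULL) {
  stopifnot(inherits(scn, "SyntheticScenario"))
  scn$planted_go_links <- 0L
  scn$planted_lfc_boost <- 1
  generate_scenario(scn, dir = dir)
}

#' Generate and analyze one scenario
#'
#' Convenience composition: [generate_scenario()], DEG filtering, and
#' [lpia_analysis()], returning the analysis plus the ground truth and the
#' planted pathway's rank by observed centrality.
#'
#' @param scn a `SyntheticScenario`.
#' @param cfg an [lpia_config()]; its seed drives the bootstrap (the
#'   scenario seed drives the data).
#' @param deg_q_threshold DEG filter cut.
#' @return List: `analysis`, `truth`, `planted_rank`, `planted_selected`.
#' @export
analyze_scenario <- function(scn, cfg = lpia_config(),
                             deg_q_threshold = 0.001) {
  dat <- generate_scenario(scn)
  degs <- filter_degs(dat$degs, deg_q_threshold)
  ana <- lpia_analysis(dat$P, dat$G, degs, cfg)
  ord <- as.data.frame(ana$result)$pathway_id
  list(analysis = ana, truth = dat$truth,
       planted_rank = match(dat$truth$planted_id, ord),
       planted_selected = dat$truth$planted_id %in% ana$latent)
}

#' Recovery sweep over scenario parameters
#'
#' Runs the full pipeline across a grid of planted-signal parameters and
#' seeds and tabulates how often the planted pathway is recovered
#' (adjusted p at or below the configured alpha) and where it ranks.
#'
#' @param scn base `SyntheticScenario`.
#' @param boosts numeric vector of `planted_lfc_boost` values (default:
#'   the scenario's own).
#' @param go_links integer vector of `planted_go_links` values (default:
#'   the scenario's own).
#' @param seeds integer vector of scenario seeds.
#' @param cfg an [lpia_config()] used for every run (its seed is offset by
#'   the scenario seed so replicate runs differ).
#' @param path optional TSV output path.
#' @return data.frame with one row per (boost, links) cell: `boost`,
#'   `links`, `n_runs`, `recovery`, `first_rank`, `mean_rank`.
#' @export
sweep_recovery <- function(scn, boosts = NULL, go_links = NULL,
                           seeds = 1:5, cfg = lpia_config(n_boot = 200),
                           path = NULL) {
  stopifnot(inherits(scn, "SyntheticScenario"))
  if (is.null(boosts)) boosts <- scn$planted_lfc_boost
  if (is.null(go_links)) go_links <- scn$planted_go_links
  grid <- expand.grid(boost = boosts, links = go_links)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    runs <- lapply(seeds, function(s) {
      scn_i <- scn
      scn_i$planted_lfc_boost <- grid$boost[i]
      scn_i$planted_go_links <- as.integer(grid$links[i])
      scn_i$seed <- as.integer(s)
      cfg_i <- cfg
      cfg_i$seed <- as.integer((cfg$seed + s) %% .Machine$integer.max)
      analyze_scenario(scn_i, cfg_i)
    })
    data.frame(boost = grid$boost[i], links = grid$links[i],
               n_runs = length(seeds),
               recovery = mean(vapply(runs, `[[`, TRUE,
                                      "planted_selected")),
               first_rank = mean(vapply(runs, function(r)
                 isTRUE(r$planted_rank == 1L), TRUE)),
               mean_rank = mean(vapply(runs, `[[`, 1,
                                       "planted_rank")))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
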