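#' Upper-tail hypergeometric p-value for gene-set overrepresentation
#'
#' Probability of observing `k` or more candidate genes in a set of size `K`
#' when `n` candidates are drawn without replacement from a background of
#' `N` genes: `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. The observed
#' count is included in the tail, the conventional overrepresentation call.
#'
#' @param k observed candidate genes in the set.
#' @param K genes in the set (within the background).
#' @param n candidate genes in the background.
#' @param N background size.
#' @return The one-sided p-value in \[0, 1\]. Vectorized over `k, K, n, N`.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  v <- data.frame(k = k, K = K, n = n, N = N)
  with(v, {
    if (any(k < 0)) stop("violated: k >= 0")
    if (any(k > pmin(K, n))) stop("violated: k <= min(K, n)")
    if (any(K > N)) stop("violated: K <= N")
    if (any(n > N)) stop("violated: n <= N")
  })
  stats::phyper(v$k - 1, v$K, v$N - v$K, v$n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate q-values, returned in input order,
#' monotonicity enforced and capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set overrepresentation of a DEG list
#'
#' For every set in the collection, counts the candidate DEGs it contains
#' (`k`), its background-annotated size (`K`), the candidate total (`n`) and
#' the background size (`N`); computes the rich ratio `k/K`, the upper-tail
#' hypergeometric p-value and BH q-values across the whole collection. Sets
#' containing no candidate DEG are kept (with `p = 1`) so the multiplicity
#' correction covers every tested set.
#'
#' By default the background is the union of all genes annotated to at least
#' one set in the collection; pass `background` explicitly to use the full
#' measured-gene universe instead. The background actually used is recorded
#' in `attr(, "background_size")` and `attr(, "background_source")`.
#'
#' @param coll a `GeneSetCollection`.
#' @param degs a `DEGTable` (typically already filtered) or a character
#'   vector of candidate gene ids.
#' @param background optional character vector of background gene ids.
#' @return A `data.frame` with columns `set_id`, `name`, `k`, `K`, `n`, `N`,
#'   `rich_ratio`, `pvalue`, `qvalue`, one row per set, in collection order.
#' @export
enrich <- function(coll, degs, background = NULL) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  if (!length(coll$sets)) stop("empty gene-set collection")
  cand <- if (inherits(degs, "DEGTable")) degs$gene_id else
    unique(as.character(degs))
  bg_source <- "user-supplied"
  if (is.null(background)) {
    background <- unique(unlist(coll$sets, use.names = FALSE))
    bg_source <- "union of annotated genes"
  }
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  cand <- intersect(cand, background)
  n <- length(cand)
  N <- length(background)
  K <- vapply(coll$sets, function(m) length(intersect(m, background)), 0L)
  k <- vapply(coll$sets, function(m) length(intersect(m, cand)), 0L)
  if (any(K == 0L))
    warning("set(s) with no background-annotated genes: ",
            paste(names(coll$sets)[K == 0L], collapse = ", "))
  p <- ifelse(K == 0L, 1, hypergeom_pvalue(k, K, n, N))
  out <- data.frame(set_id = names(coll$sets),
                    name = unname(coll$set_names[names(coll$sets)]),
                    k = k, K = K, n = n, N = N,
                    rich_ratio = ifelse(K == 0L, NA_real_, k / K),
                    pvalue = p,
                    qvalue = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "background_size") <- N
  attr(out, "background_source") <- bg_source
  out
}

#' Significantly enriched sets
#'
#' Rows with `qvalue <= q_threshold` (inclusive), ordered by ascending
#' q-value then set id.
#'
#' @param rows an enrichment table from [enrich()].
#' @param q_threshold significance cut-off in (0, 1]; default `0.05`.
#' @return The filtered, reordered enrichment table.
#' @export
significant_sets <- function(rows, q_threshold = 0.05) {
  if (!is.numeric(q_threshold) || length(q_threshold) != 1L ||
      is.na(q_threshold) || q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must be a single value in (0, 1]")
  if (!"qvalue" %in% names(rows)) stop("rows carry no qvalue column")
  out <- rows[rows$qvalue <= q_threshold, , drop = FALSE]
  out <- out[order(out$qvalue, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' Fixed column order: `set_id, name, k, K, n, N, rich_ratio, pvalue,
#' qvalue, significant`, where `significant` flags `qvalue <= q_threshold`.
#'
#' @param rows an enrichment table from [enrich()].
#' @param path output path.
#' @param q_threshold threshold behind the `significant` flag.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path, q_threshold = 0.05) {
  out <- rows[, c("set_id", "name", "k", "K", "n", "N", "rich_ratio",
                  "pvalue", "qvalue")]
  out$significant <- rows$qvalue <= q_threshold
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
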