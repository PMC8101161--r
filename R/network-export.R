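#' Thresholded edge list of a pathway network
#'
#' Keeps undirected edges whose projected weight is strictly greater than
#' `threshold` (the network-drawing rule "weight scores > 0.1"). Each edge
#' is emitted once with `source < target` lexicographically, sorted by
#' `(source, target)`.
#'
#' @param net a `PathwayNetwork`.
#' @param threshold nonnegative cut; default `0.1`.
#' @return data.frame with columns `source`, `target`, `weight`.
#' @export
edge_list <- function(net, threshold = 0.1) {
  stopifnot(inherits(net, "PathwayNetwork"))
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be >= 0")
  A <- net$A
  ids <- net$pathway_ids
  hit <- which(upper.tri(A) & A > threshold, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  a <- ids[hit[, 1L]]
  b <- ids[hit[, 2L]]
  src <- ifelse(a < b, a, b)
  tgt <- ifelse(a < b, b, a)
  out <- data.frame(source = src, target = tgt, weight = A[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join centrality and enrichment annotations per pathway
#'
#' Left-joins the enrichment table onto the centrality result by pathway
#' id. Pathways absent from the enrichment table carry `NA` markers (never
#' fabricated zeros). `latent` is `TRUE` exactly when the adjusted p-value
#' is at or below `alpha`.
#'
#' @param enrich_rows an [enrich()] table, or `NULL` for no annotation.
#' @param result a `CentralityResult`.
#' @param alpha significance level for the `latent` flag.
#' @return data.frame with columns `pathway_id`, `name`, `rich_ratio`,
#'   `enrichment_q`, `latent`, `centrality`.
#' @export
assemble_node_attributes <- function(enrich_rows, result, alpha = 0.05) {
  stopifnot(inherits(result, "CentralityResult"))
  ids <- result$pathway_ids
  if (anyDuplicated(ids))
    stop("duplicate pathway ids in centrality result")
  out <- data.frame(pathway_id = ids,
                    name = NA_character_,
                    rich_ratio = NA_real_,
                    enrichment_q = NA_real_,
                    latent = unname(result$adjusted_p[ids] <= alpha),
                    centrality = unname(result$scores[ids]),
                    stringsAsFactors = FALSE)
  if (!is.null(enrich_rows)) {
    if (anyDuplicated(enrich_rows$set_id))
      stop("duplicate set_id in enrichment table")
    m <- match(ids, enrich_rows$set_id)
    out$name <- ifelse(is.na(m), NA_character_, enrich_rows$name[m])
    out$rich_ratio <- enrich_rows$rich_ratio[m]
    out$enrichment_q <- enrich_rows$qvalue[m]
  }
  out
}

# 6 significant digits, fixed across platforms; NA -> literal "NA".
.fmt6 <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = 6, format = "g")))
}

#' Write a pathway network for graph viewers
#'
#' Emits the thresholded network in one of three formats: `"tsv"` (a
#' two-file bundle `<path>` = edges and `<path_without_ext>_nodes.tsv` =
#' node attributes), `"sif"` (Cytoscape simple interaction format,
#' interaction type `pp`, isolated nodes on singleton lines), or
#' `"graphml"` with node and edge attributes. Output is byte-deterministic
#' for fixed input: stable ordering, floats at 6 significant digits,
#' missing attributes as literal `NA`.
#'
#' @param edges data.frame from [edge_list()].
#' @param nodes data.frame from [assemble_node_attributes()].
#' @param path output path (edge file for `"tsv"`).
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return Character vector of files written, invisibly.
#' @export
write_network <- function(edges, nodes, path, format = c("tsv", "sif",
                                                         "graphml")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("tsv", "sif", "graphml"))
    stop("unknown format: ", format)
  format <- match.arg(format)
  missing_nodes <- setdiff(unique(c(edges$source, edges$target)),
                           nodes$pathway_id)
  if (length(missing_nodes))
    stop("edge endpoint(s) missing from the node table: ",
         paste(missing_nodes, collapse = ", "))
  nodes <- nodes[order(nodes$pathway_id), , drop = FALSE]
  files <- switch(format,
                  tsv = .write_tsv_bundle(edges, nodes, path),
                  sif = .write_sif(edges, nodes, path),
                  graphml = .write_graphml(edges, nodes, path))
  invisible(files)
}

.write_tsv_bundle <- function(edges, nodes, path) {
  e <- data.frame(source = edges$source, target = edges$target,
                  weight = .fmt6(edges$weight), stringsAsFactors = FALSE)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  node_path <- paste0(sub("\\.[^.]*$", "", path), "_nodes.tsv")
  n <- data.frame(pathway_id = nodes$pathway_id,
                  name = ifelse(is.na(nodes$name), "NA", nodes$name),
                  rich_ratio = .fmt6(nodes$rich_ratio),
                  enrichment_q = .fmt6(nodes$enrichment_q),
                  latent = ifelse(nodes$latent, "true", "false"),
                  centrality = .fmt6(nodes$centrality),
                  stringsAsFactors = FALSE)
  utils::write.table(n, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(path, node_path)
}

.write_sif <- function(edges, nodes, path) {
  lines <- sprintf("%s pp %s", edges$source, edges$target)
  isolated <- setdiff(nodes$pathway_id,
                      unique(c(edges$source, edges$target)))
  writeLines(c(lines, isolated), path)
  path
}

.write_graphml <- function(edges, nodes, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  keys <- c(
    '<key id="name" for="node" attr.name="name" attr.type="string"/>',
    '<key id="rich_ratio" for="node" attr.name="rich_ratio" attr.type="double"/>',
    '<key id="enrichment_q" for="node" attr.name="enrichment_q" attr.type="double"/>',
    '<key id="latent" for="node" attr.name="latent" attr.type="boolean"/>',
    '<key id="centrality" for="node" attr.name="centrality" attr.type="double"/>',
    '<key id="weight" for="edge" attr.name="weight" attr.type="double"/>')
  node_data <- function(i) {
    d <- character(0)
    if (!is.na(nodes$name[i]))
      d <- c(d, sprintf('      <data key="name">%s</data>',
                        esc(nodes$name[i])))
    if (!is.na(nodes$rich_ratio[i]))
      d <- c(d, sprintf('      <data key="rich_ratio">%s</data>',
                        .fmt6(nodes$rich_ratio[i])))
    if (!is.na(nodes$enrichment_q[i]))
      d <- c(d, sprintf('      <data key="enrichment_q">%s</data>',
                        .fmt6(nodes$enrichment_q[i])))
    c(sprintf('    <node id="%s">', esc(nodes$pathway_id[i])), d,
      sprintf('      <data key="latent">%s</data>',
              ifelse(nodes$latent[i], "true", "false")),
      sprintf('      <data key="centrality">%s</data>',
              .fmt6(nodes$centrality[i])),
      "    </node>")
  }
  edge_lines <- if (nrow(edges)) unlist(lapply(seq_len(nrow(edges)),
    function(i) {
      c(sprintf('    <edge source="%s" target="%s">',
                esc(edges$source[i]), esc(edges$target[i])),
        sprintf('      <data key="weight">%s</data>',
                .fmt6(edges$weight[i])),
        "    </edge>")
    })) else character(0)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             paste0("  ", keys),
             '  <graph id="pathway_network" edgedefault="undirected">',
             unlist(lapply(seq_len(nrow(nodes)), node_data)),
             edge_lines,
             "  </graph>",
             "</graphml>")
  writeLines(lines, path)
  path
}

#' Read back an edge TSV written by [write_network()]
#'
#' @param path the edge file.
#' @return data.frame with columns `source`, `target`, `weight`.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
}
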