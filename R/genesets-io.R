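#' Construct a gene-set collection
#'
#' A `GeneSetCollection` stores named gene sets (KEGG pathways or GO
#' biological-process terms) as character vectors of gene identifiers,
#' together with optional human-readable term names. Gene identifiers are
#' matched by exact, case-sensitive string equality throughout the package.
#'
#' @param sets named list; each element is a character vector of member gene
#'   ids, the element name is the term accession (e.g. `"ko04216"`,
#'   `"GO:0006631"`).
#' @param set_names optional named character vector of free-text term names,
#'   indexed by accession. Missing names default to the accession itself.
#' @param category either `"KEGG"` or `"GO_BP"`.
#' @return An object of class `GeneSetCollection`: a list with elements
#'   `sets`, `set_names`, `category`.
#' @export
gene_set_collection <- function(sets, set_names = NULL,
                                category = c("KEGG", "GO_BP")) {
  category <- match.arg(category)
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop("every gene set must have a nonempty set_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate set_id: ", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty))
    stop("gene sets with no members: ", paste(ids[empty], collapse = ", "))
  if (is.null(set_names)) set_names <- stats::setNames(ids, ids)
  nm <- stats::setNames(ids, ids)
  nm[intersect(ids, names(set_names))] <-
    set_names[intersect(ids, names(set_names))]
  structure(list(sets = sets, set_names = nm, category = category),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection [%s]: %d sets, %d distinct genes\n",
              x$category, length(x$sets),
              length(unique(unlist(x$sets, use.names = FALSE)))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read gene sets from a GMT or two-column file
#'
#' Reads the standard tab-separated GMT dialect (set id, description, then
#' member gene ids, one set per line). Files whose first line has exactly two
#' fields are auto-detected as the long two-column layout
#' (`set_id<TAB>gene_id`, one membership per line), a common supplementary
#' format. Duplicate member ids within a set are collapsed; sets left with no
#' members are dropped with a warning.
#'
#' @param path path to the file.
#' @param category collection category, `"KEGG"` or `"GO_BP"`.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, category = c("KEGG", "GO_BP")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields[[1]]) == 2L)
    return(.read_long_pairs(fields, path, category))
  n_fields <- vapply(fields, length, 0L)
  bad <- which(n_fields < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         ": expected >= 3 tab-separated fields, got ", n_fields[bad[1]])
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate set_id in ", path, ": ", paste(dup, collapse = ", "))
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- ids
  descr <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  empty <- vapply(members, length, 0L) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " gene set(s) with no members: ",
            paste(ids[empty], collapse = ", "))
    members <- members[!empty]
    descr <- descr[!empty]
  }
  if (!length(members)) stop("no non-empty gene sets in ", path)
  gene_set_collection(members, set_names = descr, category = category)
}

.read_long_pairs <- function(fields, path, category) {
  n_fields <- vapply(fields, length, 0L)
  bad <- which(n_fields != 2L)
  if (length(bad))
    stop("malformed two-column line ", bad[1], " in ", path,
         ": expected 2 tab-separated fields, got ", n_fields[bad[1]])
  set_id <- vapply(fields, `[[`, "", 1L)
  gene_id <- vapply(fields, `[[`, "", 2L)
  keep <- nzchar(gene_id)
  members <- lapply(split(gene_id[keep], set_id[keep]), unique)
  gene_set_collection(members, category = category)
}

#' Write a collection to a GMT file
#'
#' Inverse of [read_gmt()] on the `(set_id, members)` pair: reading the file
#' back reproduces the collection (the description column carries the term
#' name). Sets are written in their stored order.
#'
#' @param coll a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  lines <- vapply(names(coll$sets), function(id) {
    paste(c(id, coll$set_names[[id]], coll$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Reads a TSV with a header and one row per gene, carrying a signed log2
#' fold change and raw/adjusted p-values. Column names are resolved through
#' `column_map`, so any column layout can be consumed. Rows whose statistics
#' are non-numeric, out of range (p or q outside \[0, 1\]) or non-finite are
#' rejected with a warning rather than silently kept. The regulation
#' direction (`"up"`/`"down"`) is derived from the sign of the fold change.
#'
#' @param path path to the TSV file.
#' @param column_map named character vector mapping the roles `gene_id`,
#'   `log2fc`, `pvalue`, `qvalue` to column names in the file.
#' @param background optional character vector of all measured gene ids; must
#'   be a superset of the table's gene ids.
#' @return A `DEGTable`: a `data.frame` with columns `gene_id`, `log2fc`,
#'   `pvalue`, `qvalue`, `direction`, with the background (if any) stored in
#'   `attr(, "background")`.
#' @export
read_deg_table <- function(path,
                           column_map = c(gene_id = "gene_id",
                                          log2fc = "log2fc",
                                          pvalue = "pvalue",
                                          qvalue = "qvalue"),
                           background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  roles <- c("gene_id", "log2fc", "pvalue", "qvalue")
  missing_roles <- setdiff(roles, names(column_map))
  if (length(missing_roles))
    stop("column_map lacks role(s): ", paste(missing_roles, collapse = ", "))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unname(column_map[roles]), names(raw))
  if (length(absent))
    stop("mapped column(s) not in ", path, ": ",
         paste(absent, collapse = ", "))
  deg_table(gene_id = as.character(raw[[column_map[["gene_id"]]]]),
            log2fc = raw[[column_map[["log2fc"]]]],
            pvalue = raw[[column_map[["pvalue"]]]],
            qvalue = raw[[column_map[["qvalue"]]]],
            background = background)
}

#' Construct a DEG table from vectors
#'
#' @param gene_id character vector of gene ids (unique).
#' @param log2fc,pvalue,qvalue numeric vectors parallel to `gene_id`.
#' @param background optional superset of measured gene ids.
#' @return A `DEGTable` data.frame; see [read_deg_table()].
#' @export
deg_table <- function(gene_id, log2fc, pvalue, qvalue, background = NULL) {
  suppress_num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  log2fc <- suppress_num(log2fc)
  pvalue <- suppress_num(pvalue)
  qvalue <- suppress_num(qvalue)
  gene_id <- as.character(gene_id)
  ok <- is.finite(log2fc) &
    is.finite(pvalue) & pvalue >= 0 & pvalue <= 1 &
    is.finite(qvalue) & qvalue >= 0 & qvalue <= 1
  if (any(!ok)) {
    warning("rejecting ", sum(!ok),
            " row(s) with non-numeric or out-of-range statistics: ",
            paste(utils::head(gene_id[!ok], 5L), collapse = ", "),
            if (sum(!ok) > 5L) ", ..." else "")
    gene_id <- gene_id[ok]
    log2fc <- log2fc[ok]
    pvalue <- pvalue[ok]
    qvalue <- qvalue[ok]
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  if (!is.null(background)) {
    background <- unique(as.character(background))
    out <- setdiff(gene_id, background)
    if (length(out))
      stop("gene ids absent from the background: ",
           paste(utils::head(out, 5L), collapse = ", "))
  }
  df <- data.frame(gene_id = gene_id, log2fc = log2fc, pvalue = pvalue,
                   qvalue = qvalue,
                   direction = ifelse(log2fc >= 0, "up", "down"),
                   stringsAsFactors = FALSE)
  attr(df, "background") <- background
  class(df) <- c("DEGTable", "data.frame")
  df
}

#' Filter a DEG table on the adjusted p-value
#'
#' Retains records with `qvalue <= q_threshold` (inclusive comparison). The
#' background is unchanged. Filtering is monotone in the threshold: the kept
#' set at a smaller threshold is a subset of the kept set at a larger one.
#'
#' @param degs a `DEGTable`.
#' @param q_threshold FDR cut-off in (0, 1]; default `0.001`, the
#'   conventional stringent cut for calling DEGs from deep bulk RNA-seq.
#' @return The filtered `DEGTable`.
#' @export
filter_degs <- function(degs, q_threshold = 0.001) {
  stopifnot(inherits(degs, "DEGTable"))
  if (!is.numeric(q_threshold) || length(q_threshold) != 1L ||
      is.na(q_threshold) || q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must be a single value in (0, 1]")
  out <- degs[degs$qvalue <= q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background") <- attr(degs, "background")
  class(out) <- c("DEGTable", "data.frame")
  out
}

#' Restrict gene sets to a gene universe
#'
#' Intersects every set's members with `genes` and drops sets whose
#' intersection is empty. Used to restrict annotation collections to the DEG
#' universe before building the bipartite graph, so that only sets sharing at
#' least one DEG enter the network. An empty result is legal.
#'
#' @param coll a `GeneSetCollection`.
#' @param genes character vector of gene ids (nonempty).
#' @return The restricted `GeneSetCollection` (possibly with zero sets).
#' @export
restrict_to_universe <- function(coll, genes) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene universe is empty")
  sets <- lapply(coll$sets, function(m) m[m %in% genes])
  keep <- vapply(sets, length, 0L) > 0L
  structure(list(sets = sets[keep],
                 set_names = coll$set_names[names(sets)[keep]],
                 category = coll$category),
            class = "GeneSetCollection")
}

#' Write a DEG table as TSV
#'
#' @param degs a `DEGTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  stopifnot(inherits(degs, "DEGTable"))
  utils::write.table(as.data.frame(degs)[, c("gene_id", "log2fc", "pvalue",
                                             "qvalue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
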