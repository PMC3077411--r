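# GCAT-style outputs: the cohesion network graph, the common log-entropy
# terms of a gene set, and the gene annotation table.

#' Build the cohesion graph for a gene set
#'
#' Nodes are all resolved genes (isolated nodes included); edges are
#' unordered pairs with cosine strictly above `threshold`, weighted by the
#' cosine.  The threshold is recorded as a graph attribute.
#'
#' @param genes resolved gene ids (>= 1).
#' @param similarity a `similarity_matrix` containing them.
#' @param threshold cosine edge threshold.
#' @param abstract_counts optional named vector (or `documents` data.frame)
#'   supplying the `abstract_count` node attribute.
#' @return an `igraph` graph with node attribute `abstract_count` (if
#'   supplied), edge attribute `cosine`, graph attribute `threshold`.
#' @export
build_graph <- function(genes, similarity, threshold,
                        abstract_counts = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) < 1) stop_litcohesion("empty gene set")
  s <- unclass(similarity)[genes, genes, drop = FALSE]
  idx <- which(upper.tri(s) & s > threshold, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      cosine = s[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  if (!is.null(abstract_counts)) {
    if (is.data.frame(abstract_counts))
      abstract_counts <- structure(abstract_counts$abstract_count,
                                   names = abstract_counts$gene_id)
    igraph::V(g)$abstract_count <-
      as.integer(abstract_counts[igraph::V(g)$name])
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Write a graph as GraphML
#' @param graph an igraph graph ([build_graph()]).
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML graph back
#' @param path a GraphML file written by [write_graphml()].
#' @return an igraph graph.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write a graph in Cytoscape SIF format
#'
#' One line per edge `a<TAB>sim<TAB>b`; isolated nodes are written as bare
#' node lines, as Cytoscape expects.
#'
#' @param graph an igraph graph.
#' @param path output path.
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el)) paste(el[, 1], "sim", el[, 2], sep = "\t")
           else character(0)
  isolated <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, isolated), con, sep = "\n")
  invisible(path)
}

#' Common log-entropy terms of a gene set
#'
#' "Common" terms are terms with nonzero log-entropy weight in at least two
#' genes of the set.  They are ranked either by the sum of weights across
#' the set's genes (default) or by the minimum weight, ties broken
#' lexicographically.
#'
#' @param genes resolved gene ids.
#' @param tgm a weighted `term_gene_matrix`.
#' @param top_n maximum number of terms to return.
#' @param ranking `"sum"` (default) or `"min"`.
#' @return `data.frame` of `term`, `score`, `n_genes` (set genes with
#'   nonzero weight); possibly fewer than `top_n` rows.
#' @export
common_terms <- function(genes, tgm, top_n = 20, ranking = c("sum", "min")) {
  ranking <- match.arg(ranking)
  stopifnot(inherits(tgm, "term_gene_matrix"))
  if (is.null(tgm$weights))
    stop_litcohesion("apply_log_entropy() before common_terms()")
  if (top_n < 1) stop_litcohesion("top_n must be >= 1")
  genes <- unique(as.character(genes))
  genes <- intersect(genes, tgm$genes)
  if (length(genes) < 2)
    return(data.frame(term = character(), score = numeric(),
                      n_genes = integer()))
  w <- tgm$weights[, genes, drop = FALSE]
  nz <- Matrix::rowSums(w > 0)
  keep <- nz >= 2
  if (!any(keep))
    return(data.frame(term = character(), score = numeric(),
                      n_genes = integer()))
  w <- w[keep, , drop = FALSE]
  score <- if (ranking == "sum") Matrix::rowSums(w)
           else apply(as.matrix(w), 1, function(r) min(r[r > 0]))
  df <- data.frame(term = rownames(w), score = as.numeric(score),
                   n_genes = as.integer(nz[keep]), stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$term), , drop = FALSE]
  rownames(df) <- NULL
  head(df, top_n)
}

#' Gene annotation table
#'
#' One row per requested gene, resolved or not, in input order (duplicates
#' collapsed to their first occurrence), with abstract counts and hyperlink
#' fields built from URL templates.  No network access is performed.
#'
#' @param requested_ids requested gene ids and/or symbols.
#' @param documents `data.frame` from [build_gene_documents()] (provides
#'   `abstract_count`); may be `NULL`.
#' @param symbols optional symbol table ([read_gene_info()]).
#' @param gene_url,pubmed_url URL templates with `%s` substituted by the
#'   gene id.
#' @return `data.frame` with columns `requested`, `gene_id`, `symbol`,
#'   `status`, `abstract_count`, `gene_link`, `pubmed_link`.
#' @export
annotation_table <- function(requested_ids, documents = NULL,
                             symbols = NULL,
                             gene_url = "https://www.ncbi.nlm.nih.gov/gene/%s",
                             pubmed_url = "https://pubmed.ncbi.nlm.nih.gov/?term=%s") {
  requested_ids <- as.character(requested_ids)
  requested_ids <- requested_ids[!duplicated(requested_ids)]
  known <- if (!is.null(documents)) documents$gene_id else character(0)
  res <- resolve_genes(requested_ids, known, symbols)
  rep_df <- res$report
  counts <- if (!is.null(documents))
    structure(documents$abstract_count, names = documents$gene_id)
  else structure(integer(0), names = character(0))
  sym <- if (!is.null(symbols))
    structure(symbols$symbol, names = symbols$gene_id)
  else structure(character(0), names = character(0))
  resolved <- rep_df$status == "resolved"
  data.frame(
    requested = rep_df$requested,
    gene_id = ifelse(resolved, rep_df$gene_id, NA_character_),
    symbol = ifelse(resolved & rep_df$gene_id %in% names(sym),
                    sym[rep_df$gene_id], NA_character_),
    status = rep_df$status,
    abstract_count = ifelse(resolved, counts[rep_df$gene_id], NA_integer_),
    gene_link = ifelse(resolved, sprintf(gene_url, rep_df$gene_id),
                       NA_character_),
    pubmed_link = ifelse(resolved, sprintf(pubmed_url, rep_df$gene_id),
                         NA_character_),
    stringsAsFactors = FALSE)
}

#' Write a table as UTF-8, LF-terminated TSV with header
#' @param df a data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) write_tsv_file(df, path)
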