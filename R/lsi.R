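# Latent semantic indexing of the weighted term-by-gene matrix.
#
# A truncated SVD W ~= U_k S_k V_k' places each gene in a k-dimensional
# concept space.  The gene vector is the gene-side factor row scaled by the
# singular values (rows of V_k S_k), the standard LSI document
# representation; the unscaled V_k rows are available via
# `scale_gene_vectors = FALSE` (cosines differ between the two conventions
# except at full rank).  Gene-gene similarity is the cosine between gene
# vectors; at k = rank it equals the cosine between the raw weighted
# columns.

#' Fit a rank-k LSI model
#'
#' @param x a weighted `term_gene_matrix` (weights applied), or a plain
#'   term x gene weight matrix with dimnames.
#' @param k number of factors (rank); the default 300 follows common
#'   practice for large document collections and is capped at
#'   `min(#terms, #genes)` for small corpora.
#' @param scale_gene_vectors if `TRUE` (default) gene vectors are V_k
#'   scaled by the singular values; if `FALSE`, unscaled V_k.
#' @return An object of class `lsi_model`: `k`, `term_factors` (term x k,
#'   orthonormal columns), `singular_values` (non-increasing),
#'   `gene_vectors` (gene x k), `genes`, `terms`, `scaled`, `fingerprint`.
#' @export
fit_lsi <- function(x, k = 300, scale_gene_vectors = TRUE) {
  if (inherits(x, "term_gene_matrix")) {
    if (is.null(x$weights))
      stop_litcohesion("apply_log_entropy() before fit_lsi()")
    w <- x$weights
  } else w <- x
  w <- as.matrix(w)
  if (is.null(rownames(w)) || is.null(colnames(w)))
    stop_litcohesion("weight matrix needs term and gene dimnames")
  max_k <- min(dim(w))
  if (k < 1) stop_litcohesion("k must be >= 1")
  requested_k <- k
  if (missing(k)) {
    k <- min(k, max_k)  # default gracefully degrades on small corpora
  } else if (k > max_k) {
    stop_litcohesion("k = ", k, " exceeds min(#terms, #genes) = ", max_k)
  }
  sv <- svd(w, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  gene_vectors <- if (scale_gene_vectors) sv$v %*% diag(d, k, k) else sv$v
  rownames(gene_vectors) <- colnames(w)
  term_factors <- sv$u
  rownames(term_factors) <- rownames(w)
  structure(list(k = k, requested_k = requested_k,
                 term_factors = term_factors,
                 singular_values = d,
                 gene_vectors = gene_vectors,
                 genes = colnames(w), terms = rownames(w),
                 scaled = scale_gene_vectors,
                 fingerprint = content_fingerprint(colnames(w), d)),
            class = "lsi_model")
}

#' @export
print.lsi_model <- function(x, ...) {
  cat("lsi_model: rank ", x$k, ", ", length(x$terms), " terms, ",
      length(x$genes), " genes (gene vectors ",
      if (x$scaled) "scaled by singular values" else "unscaled", ")\n",
      sep = "")
  invisible(x)
}

gene_vector <- function(model, gene) {
  idx <- match(gene, model$genes)
  if (is.na(idx))
    stop_litcohesion("gene '", gene, "' is not in the model")
  model$gene_vectors[idx, ]
}

#' Cosine similarity between two modeled genes
#'
#' Genes whose vectors are numerically zero (possible at small k) get
#' cosine 0 with a warning, so they simply contribute no edges;
#' `cosine(g, g)` is 1 for nonzero vectors.
#'
#' @param model an `lsi_model`.
#' @param gene_a,gene_b gene identifiers present in the model.
#' @return cosine in \[-1, 1\].
#' @export
cosine <- function(model, gene_a, gene_b) {
  va <- gene_vector(model, gene_a)
  vb <- gene_vector(model, gene_b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    warning("zero gene vector; cosine defined as 0")
    return(0)
  }
  min(1, max(-1, sum(va * vb) / (na * nb)))
}

#' Gene-by-gene cosine similarity matrix
#'
#' @param model an `lsi_model`.
#' @return An object of class `similarity_matrix`: a symmetric gene x gene
#'   matrix of cosines with unit diagonal, carrying the model fingerprint
#'   as attribute `fingerprint`.
#' @export
similarity_matrix <- function(model) {
  v <- model$gene_vectors
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero vectors; their cosines set to 0")
    nrm[zero] <- 1
  }
  u <- v / nrm
  s <- tcrossprod(u)
  s[zero, ] <- 0
  s[, zero] <- 0
  s <- (s + t(s)) / 2
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 1
  structure(s, class = c("similarity_matrix", class(s)),
            fingerprint = model$fingerprint)
}

sim_genes <- function(similarity) rownames(similarity)

#' Top-n literature neighbors of a gene
#'
#' Self is excluded; descending cosine, ties broken by gene id ascending.
#'
#' @param similarity a `similarity_matrix`.
#' @param gene gene identifier.
#' @param n maximum number of neighbors (default 10, the diagnostic used
#'   for well-studied genes).
#' @return list with `neighbors` (`data.frame` of `gene_id`, `cosine`) and
#'   `mean_cosine` (mean over the returned, possibly fewer than `n`,
#'   values).
#' @export
top_neighbors <- function(similarity, gene, n = 10) {
  genes <- sim_genes(similarity)
  if (!(gene %in% genes))
    stop_litcohesion("gene '", gene, "' is not in the similarity matrix")
  if (n < 1) stop_litcohesion("n must be >= 1")
  others <- setdiff(genes, gene)
  cos <- unclass(similarity)[gene, others]
  ord <- order(-cos, others)
  take <- head(ord, n)
  data_out <- data.frame(gene_id = others[take],
                         cosine = unname(cos[take]),
                         stringsAsFactors = FALSE)
  list(neighbors = data_out, mean_cosine = mean(data_out$cosine))
}

#' Export similarity pairs above a floor as TSV
#'
#' Writes columns `gene_a`, `gene_b`, `cosine` for unordered pairs with
#' cosine >= `floor`, gene_a < gene_b, sorted.
#'
#' @param similarity a `similarity_matrix`.
#' @param path output path.
#' @param floor minimum cosine to emit (default 0).
#' @export
write_similarity_pairs <- function(similarity, path, floor = 0) {
  s <- unclass(similarity)
  genes <- rownames(s)
  idx <- which(upper.tri(s) & s >= floor, arr.ind = TRUE)
  df <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                   cosine = s[idx], stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  write_tsv_file(df, path)
}

# Versioned on-disk model artifact.  Format v1: a plain list serialized
# with saveRDS; the version field guards future layout changes.
#' Save / load an LSI model artifact
#' @param model an `lsi_model`.
#' @param path file path (conventionally `.rds`).
#' @export
write_lsi_model <- function(model, path) {
  stopifnot(inherits(model, "lsi_model"))
  saveRDS(c(list(format = "litcohesion/lsi_model", format_version = 1L),
            unclass(model)), path)
  invisible(path)
}

#' @rdname write_lsi_model
#' @export
read_lsi_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "litcohesion/lsi_model"))
    stop_litcohesion("not an lsi_model artifact: ", path)
  if (!identical(obj$format_version, 1L))
    stop_litcohesion("unsupported lsi_model artifact version")
  obj$format <- NULL; obj$format_version <- NULL
  structure(obj, class = "lsi_model")
}
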