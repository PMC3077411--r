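# The term-by-gene matrix and log-entropy weighting.
#
# Raw counts f_ij (term i in gene document j) get the classic log-entropy
# weight: local part l_ij = log2(1 + f_ij); global part
#   g_i = 1 + sum_j p_ij log2(p_ij) / log2(n),   p_ij = f_ij / sum_j f_ij,
# over the n gene documents; w_ij = g_i * l_ij.  g_i is 1 minus the
# normalized entropy of the term's distribution across genes: a term
# concentrated in one gene gets g = 1 (maximally discriminative), a term
# spread evenly over all genes gets g = 0.  The log base cancels in g and
# only rescales l uniformly, so cosines are base-invariant; base 2 is used
# throughout.

#' Build a term-by-gene count matrix from gene documents
#'
#' Tokenizes each gene document and assembles a sparse term-by-gene matrix.
#' All-zero term rows and gene columns cannot occur by construction (every
#' emitted token has count >= 1); genes whose documents tokenize to nothing
#' are dropped with a warning.
#'
#' @param documents `data.frame` with columns `gene_id` and `text`
#'   (see [build_gene_documents()]).
#' @param rules a [tokenize_rules()] object.
#' @return An object of class `term_gene_matrix`: a list with `counts`
#'   (sparse term x gene `Matrix`), `weights` and `global_weights` (`NULL`
#'   until [apply_log_entropy()] is called), `terms`, `genes`, and `rules`.
#' @export
term_gene_matrix <- function(documents, rules = tokenize_rules()) {
  stopifnot(is.data.frame(documents),
            all(c("gene_id", "text") %in% names(documents)))
  bags <- lapply(documents$text, tokenize, rules = rules)
  names(bags) <- documents$gene_id
  empty <- lengths(bags) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " gene(s) with empty token bags: ",
            paste(head(names(bags)[empty], 5), collapse = ", "))
    bags <- bags[!empty]
  }
  if (length(bags) == 0) stop_litcohesion("no non-empty gene documents")
  genes <- names(bags)
  terms <- sort(unique(unlist(lapply(bags, names), use.names = FALSE)))
  i <- unlist(lapply(bags, function(b) match(names(b), terms)),
              use.names = FALSE)
  j <- rep(seq_along(bags), lengths(bags))
  x <- unlist(bags, use.names = FALSE)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                                 dims = c(length(terms), length(genes)),
                                 dimnames = list(terms, genes))
  structure(list(counts = counts, weights = NULL, global_weights = NULL,
                 terms = terms, genes = genes, rules = rules),
            class = "term_gene_matrix")
}

#' @export
print.term_gene_matrix <- function(x, ...) {
  cat("term_gene_matrix: ", length(x$terms), " terms x ", length(x$genes),
      " genes; weights ", if (is.null(x$weights)) "not yet applied"
      else "applied", "\n", sep = "")
  invisible(x)
}

# Shared worker: returns list(weights, global) for any matrix-like input.
log_entropy_weights <- function(f) {
  n <- ncol(f)
  if (is.null(n) || n < 2)
    stop_litcohesion("log-entropy weighting needs at least 2 gene documents")
  if (any(f < 0)) stop_litcohesion("negative counts")
  row_tot <- Matrix::rowSums(f)
  if (any(row_tot == 0)) stop_litcohesion("all-zero term row")
  fs <- methods::as(methods::as(Matrix::Matrix(f, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  p <- fs@x / row_tot[fs@i + 1L]
  ent <- rep(0, nrow(f))
  acc <- tapply(p * log2(p), fs@i + 1L, sum)  # 0 log 0 := 0 by omission
  ent[as.integer(names(acc))] <- acc
  g <- 1 + ent / log2(n)
  g <- pmin(pmax(g, 0), 1)  # clamp tiny negative rounding
  g[g < 1e-12] <- 0         # uniform terms are analytically exactly 0
  w <- fs
  w@x <- g[w@i + 1L] * log2(1 + w@x)
  w <- methods::as(Matrix::drop0(w), "CsparseMatrix")
  dimnames(w) <- dimnames(f)
  list(weights = w, global = structure(g, names = rownames(f)))
}

#' Apply log-entropy weighting
#'
#' @param x a `term_gene_matrix` or a plain non-negative term x gene matrix
#'   with at least two columns.
#' @return For a `term_gene_matrix`, the same object with `weights` and
#'   `global_weights` filled in; for a plain matrix, the dense weight
#'   matrix.
#' @export
apply_log_entropy <- function(x) {
  if (inherits(x, "term_gene_matrix")) {
    le <- log_entropy_weights(x$counts)
    x$weights <- le$weights
    x$global_weights <- le$global
    return(x)
  }
  as.matrix(log_entropy_weights(x)$weights)
}

#' Per-term global (entropy) weights
#'
#' @param x a weighted `term_gene_matrix` or a plain count matrix.
#' @return named numeric vector of g_i in \[0, 1\].
#' @export
global_weights <- function(x) {
  if (inherits(x, "term_gene_matrix")) {
    if (is.null(x$global_weights))
      x <- apply_log_entropy(x)
    return(x$global_weights)
  }
  log_entropy_weights(x)$global
}
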