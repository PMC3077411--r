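# Literature cohesion of a gene set.
#
# The edge threshold is calibrated empirically: many random gene sets are
# drawn from the similarity matrix, all within-set pairwise cosines are
# pooled, and the threshold is the nearest-rank percentile (95th by
# default, so that roughly the top 5% of pairwise similarities count as
# edges).  A gene set's cohesion is then the count k of its pairs strictly
# above the threshold, compared against the calibration background (K
# above-threshold pairs out of M) by a one-sided Fisher's exact test on
#   [[k, m - k], [K, M - K]]
# whose p-value is the literature p-value (LPv): small LPv means the set
# shares far more literature similarity than random sets do.

#' Calibrate the cosine edge threshold from random gene sets
#'
#' Draws `n_sets` random gene sets with sizes uniform over `size_range`
#' (inclusive), pools all within-set pairwise cosines, and returns the
#' nearest-rank `percentile` of the pooled scores together with the
#' background counts used by the Fisher test.
#'
#' @param similarity a `similarity_matrix`.
#' @param n_sets number of random sets (default 1000).
#' @param size_range inclusive integer pair, default c(50, 400); capped
#'   (with a warning) at one less than the number of genes.
#' @param percentile percentile in (0, 100), default 95.
#' @param seed integer seed; recorded in the result. Defaults to 1 with a
#'   message if not supplied.
#' @return An object of class `calibration_result`: `threshold`,
#'   `percentile`, `n_sets`, `size_range`, `pooled_count` (= `M`),
#'   `fraction_above`, `K`, `M`, `per_set_fraction_above` (diagnostic
#'   vector, computed at the returned threshold), `seed`, `fingerprint`.
#' @export
calibrate_threshold <- function(similarity, n_sets = 1000,
                                size_range = c(50, 400), percentile = 95,
                                seed = NULL) {
  s <- unclass(similarity)
  genes <- rownames(s)
  n_genes <- length(genes)
  if (n_genes < 2) stop_litcohesion("need at least 2 genes to calibrate")
  if (percentile <= 0 || percentile >= 100)
    stop_litcohesion("percentile must be in (0, 100)")
  size_range <- as.integer(round(sort(size_range)))
  if (size_range[1] < 2) stop_litcohesion("minimum set size is 2")
  if (size_range[2] > n_genes - 1) {
    warning("size_range capped at ", n_genes - 1, " (matrix has ",
            n_genes, " genes)")
    size_range <- pmin(size_range, n_genes - 1L)
  }
  if (is.null(seed)) {
    seed <- 1L
    message("no seed supplied; using seed = 1")
  }
  draws <- with_seed(seed, {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
    lapply(sizes, function(sz) sample(genes, sz, replace = FALSE))
  })
  pooled <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    sub <- s[draws[[i]], draws[[i]]]
    pooled[[i]] <- sub[upper.tri(sub)]
  }
  scores <- unlist(pooled, use.names = FALSE)
  M <- length(scores)
  threshold <- nearest_rank_percentile(scores, percentile)
  K <- sum(scores > threshold)
  structure(list(threshold = threshold, percentile = percentile,
                 n_sets = n_sets, size_range = size_range,
                 pooled_count = M, fraction_above = K / M,
                 K = K, M = M,
                 per_set_fraction_above =
                   vapply(pooled, function(x) mean(x > threshold), 0),
                 seed = as.integer(seed),
                 fingerprint = attr(similarity, "fingerprint")),
            class = "calibration_result")
}

#' Nearest-rank percentile
#'
#' The `p`-th percentile of `x` as an observed order statistic: the value
#' at rank `ceiling(p/100 * length(x))` of the ascending sort.
#'
#' @param x numeric vector (non-empty).
#' @param p percentile in (0, 100\].
#' @return an element of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  if (length(x) == 0) stop_litcohesion("empty score vector")
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: threshold %.4f (%gth percentile of %d pooled scores)\n",
    x$threshold, x$percentile, x$M))
  cat(sprintf("  %d sets of %d-%d genes, seed %d; background K/M = %d/%d (%.2f%%)\n",
              x$n_sets, x$size_range[1], x$size_range[2], x$seed,
              x$K, x$M, 100 * x$fraction_above))
  invisible(x)
}

#' Count above-threshold pairs within a gene set
#'
#' @param genes resolved gene ids (>= 2, deduplicated internally).
#' @param similarity a `similarity_matrix` containing them.
#' @param threshold cosine threshold; edges are pairs strictly above it.
#' @return list with `m` (= n(n-1)/2 unordered pairs) and `k_above`.
#' @export
count_edges <- function(genes, similarity, threshold) {
  genes <- unique(as.character(genes))
  n <- length(genes)
  if (n < 2)
    stop_litcohesion("cohesion undefined for fewer than two genes with abstracts")
  missing_genes <- setdiff(genes, sim_genes(similarity))
  if (length(missing_genes) > 0)
    stop_litcohesion("genes not in similarity matrix: ",
                     paste(head(missing_genes, 5), collapse = ", "))
  sub <- unclass(similarity)[genes, genes]
  vals <- sub[upper.tri(sub)]
  list(m = n * (n - 1) / 2, k_above = sum(vals > threshold))
}

#' One-sided Fisher's exact test p-value (LPv) for edge enrichment
#'
#' Exact hypergeometric tail probability of observing at least `k_above`
#' above-threshold pairs in the 2x2 table
#' `[[k_above, m - k_above], [K, M - K]]`; equal to
#' `fisher.test(..., alternative = "greater")`.
#'
#' @param k_above observed above-threshold pairs in the set.
#' @param m total pairs in the set.
#' @param K background above-threshold pairs (from calibration).
#' @param M background total pairs.
#' @param alternative `"greater"` (enrichment, the LPv; default) or
#'   `"two.sided"`.
#' @return p-value in (0, 1\].
#' @export
fisher_lpv <- function(k_above, m, K, M,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  k_above <- as.numeric(k_above); m <- as.numeric(m)
  K <- as.numeric(K); M <- as.numeric(M)
  if (any(c(k_above, m, K, M) < 0) || k_above > m || K > M || m < 1 || M < 1)
    stop_litcohesion("inconsistent contingency counts")
  if (alternative == "two.sided") {
    return(stats::fisher.test(matrix(c(k_above, m - k_above, K, M - K),
                                     nrow = 2, byrow = TRUE))$p.value)
  }
  # P(X >= k), X ~ Hypergeometric(white = m, black = M, drawn = k + K)
  min(1, stats::phyper(k_above - 1, m, M, k_above + K, lower.tail = FALSE))
}

# Resolve requested identifiers (ids or symbols, mixed) against the model.
resolve_genes <- function(requested, genes, symbols = NULL) {
  requested <- as.character(requested)
  map <- character(0)
  if (!is.null(symbols))
    map <- structure(symbols$gene_id, names = symbols$symbol)
  resolved <- ifelse(requested %in% genes, requested,
                     ifelse(requested %in% names(map),
                            unname(map[requested]), NA_character_))
  status <- ifelse(!is.na(resolved) & resolved %in% genes, "resolved",
                   ifelse(is.na(resolved), "unknown", "no_abstracts"))
  resolved[status != "resolved"] <- NA_character_
  report <- data.frame(requested = requested, gene_id = resolved,
                       status = status, stringsAsFactors = FALSE)
  dup <- duplicated(report$gene_id) & !is.na(report$gene_id)
  report$status[dup] <- "duplicate"
  list(resolved = unique(resolved[!is.na(resolved)]), report = report)
}

#' Literature p-value for a gene set
#'
#' Resolves identifiers (dropping duplicates and genes without modeled
#' abstracts), counts above-threshold pairs at the calibrated threshold and
#' computes the LPv against the calibration background.
#'
#' @param requested_ids character vector of gene ids and/or symbols.
#' @param similarity a `similarity_matrix`.
#' @param calibration a `calibration_result` from the same model (checked
#'   via the stored fingerprint), or `NULL` when `threshold` and a
#'   background are given explicitly.
#' @param symbols optional symbol table ([read_gene_info()]).
#' @param threshold optional override of the calibrated threshold; requires
#'   a background: either `background = c(K, M)` or `background_proportion`
#'   with `background_total`.
#' @param background optional integer pair c(K, M).
#' @param background_proportion,background_total fixed-proportion
#'   background: K = round(proportion * total), M = total.
#' @param alternative passed to [fisher_lpv()].
#' @return An object of class `cohesion_result`: `gene_set` (bookkeeping:
#'   `requested_ids`, `resolved_ids`, `n_input`, `n_with_abstracts`,
#'   `report`), `threshold`, `m`, `k_above`, `contingency` (2x2 integer
#'   matrix), `K`, `M`, `lpv`, `alternative`, `seed` (from calibration, if
#'   any).
#' @export
lpv_for_gene_set <- function(requested_ids, similarity, calibration = NULL,
                             symbols = NULL, threshold = NULL,
                             background = NULL,
                             background_proportion = NULL,
                             background_total = NULL,
                             alternative = "greater") {
  if (!is.null(calibration)) {
    if (!inherits(calibration, "calibration_result"))
      stop_litcohesion("calibration must be a calibration_result")
    fp <- attr(similarity, "fingerprint")
    if (!is.null(fp) && !is.null(calibration$fingerprint) &&
        !identical(fp, calibration$fingerprint))
      stop_litcohesion("calibration and similarity matrix come from ",
                       "different models (fingerprint mismatch)")
    if (is.null(threshold)) threshold <- calibration$threshold
    K <- calibration$K; M <- calibration$M
  }
  if (!is.null(background)) {
    K <- background[1]; M <- background[2]
  } else if (!is.null(background_proportion)) {
    if (is.null(background_total))
      stop_litcohesion("background_proportion needs background_total")
    M <- as.integer(background_total)
    K <- as.integer(round(background_proportion * M))
  }
  if (is.null(threshold))
    stop_litcohesion("no threshold: supply a calibration or threshold=")
  if (!exists("K", inherits = FALSE))
    stop_litcohesion("no background: supply a calibration, background=, ",
                     "or background_proportion= with background_total=")
  res <- resolve_genes(requested_ids, sim_genes(similarity), symbols)
  if (length(res$resolved) < 2)
    stop_litcohesion("fewer than two genes with abstracts resolved (",
                     length(res$resolved), "); statuses: ",
                     paste(sprintf("%s=%s", res$report$requested,
                                   res$report$status), collapse = ", "))
  ce <- count_edges(res$resolved, similarity, threshold)
  lpv <- fisher_lpv(ce$k_above, ce$m, K, M, alternative = alternative)
  contingency <- matrix(as.integer(c(ce$k_above, ce$m - ce$k_above,
                                     K, M - K)),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("gene_set", "background"),
                                        c("above", "not_above")))
  structure(list(gene_set = list(requested_ids = requested_ids,
                                 resolved_ids = res$resolved,
                                 n_input = length(requested_ids),
                                 n_with_abstracts = length(res$resolved),
                                 report = res$report),
                 threshold = threshold, m = ce$m, k_above = ce$k_above,
                 contingency = contingency, K = K, M = M, lpv = lpv,
                 alternative = alternative,
                 seed = if (!is.null(calibration)) calibration$seed else NA),
            class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf("cohesion_result: LPv = %.4g\n", x$lpv))
  cat(sprintf("  %d input genes, %d with abstracts; threshold %.4f\n",
              x$gene_set$n_input, x$gene_set$n_with_abstracts, x$threshold))
  cat(sprintf("  edges %d / %d pairs vs background %d / %d (%.2f%%)\n",
              x$k_above, x$m, x$K, x$M, 100 * x$K / x$M))
  invisible(x)
}

#' Serialize a cohesion result as JSON
#'
#' Writes the full contingency table, threshold, seed lineage, and
#' per-gene resolution status.
#'
#' @param result a `cohesion_result`.
#' @param path output path.
#' @export
write_cohesion_json <- function(result, path) {
  stopifnot(inherits(result, "cohesion_result"))
  obj <- list(
    lpv = result$lpv,
    threshold = result$threshold,
    alternative = result$alternative,
    m = result$m, k_above = result$k_above,
    contingency = unclass(result$contingency),
    background = list(K = result$K, M = result$M),
    calibration_seed = result$seed,
    n_input = result$gene_set$n_input,
    n_with_abstracts = result$gene_set$n_with_abstracts,
    resolution = result$gene_set$report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
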