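#' @keywords internal
"_PACKAGE"

#' @importFrom methods as
#' @importFrom stats cor rlnorm rpois
#' @importFrom utils head read.delim write.table
NULL

# Lightweight content fingerprint used to check that a calibration and a
# similarity matrix came from the same model artifact.  Not cryptographic:
# it only needs to catch accidental mix-ups between runs.
content_fingerprint <- function(genes, values) {
  genes <- sort(as.character(genes))
  h <- sum(vapply(genes, function(g) sum(utf8ToInt(g)), numeric(1))) %% 1e9
  sprintf("v1:%d:%.0f:%.8g", length(genes), h, sum(as.numeric(values)^2))
}

# Per-stage substream seeds derived from one master seed, so that adding a
# generator stage never perturbs the draws of earlier stages.  Kept below
# 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + 7919 * stage) %% 2147483629
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_litcohesion <- function(...) stop(..., call. = FALSE)

write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
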