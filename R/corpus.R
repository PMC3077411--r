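# Corpus construction: abstract records, gene-citation links, per-gene
# documents.  A "gene document" is the concatenation of the titles and
# abstracts of every citation cross-referenced to the gene, after two
# filters: citations linked to too many genes are dropped (they are usually
# genome-scale experiments carrying no functional signal), and citation sets
# of orthologous genes are merged.

#' Construct a validated collection of abstract records
#'
#' @param citation_id character vector of unique citation identifiers
#'   (PMID-like, treated as opaque strings).
#' @param title character vector of citation titles (may be empty strings).
#' @param abstract character vector of abstract bodies (may be empty
#'   strings, but a record may not have both title and abstract empty).
#' @return A `data.frame` with columns `citation_id`, `title`, `abstract`.
#' @export
abstract_records <- function(citation_id, title = "", abstract = "") {
  citation_id <- as.character(citation_id)
  df <- data.frame(citation_id = citation_id,
                   title = as.character(rep_len(title, length(citation_id))),
                   abstract = as.character(rep_len(abstract, length(citation_id))),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$citation_id))
    stop_litcohesion("duplicate citation_id in abstract records: ",
                     paste(unique(df$citation_id[duplicated(df$citation_id)]),
                           collapse = ", "))
  both_empty <- !nzchar(df$title) & !nzchar(df$abstract)
  if (any(both_empty))
    stop_litcohesion("abstract records with both title and abstract empty: ",
                     paste(df$citation_id[both_empty], collapse = ", "))
  df
}

#' Read abstract records from a JSON Lines file
#'
#' One JSON object per line with keys `id`, `title`, `abstract`.
#'
#' @param path path to a JSONL file.
#' @return A `data.frame` as returned by [abstract_records()].
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  get_chr <- function(r, k) {
    v <- r[[k]]
    if (is.null(v)) "" else as.character(v)
  }
  abstract_records(citation_id = vapply(recs, get_chr, "", k = "id"),
                   title = vapply(recs, get_chr, "", k = "title"),
                   abstract = vapply(recs, get_chr, "", k = "abstract"))
}

#' Construct gene-citation links
#'
#' Duplicate (gene, citation) pairs are collapsed.
#'
#' @param gene_id,citation_id character vectors of equal length.
#' @return A `data.frame` with columns `gene_id`, `citation_id`, one row per
#'   distinct pair.
#' @export
gene_links <- function(gene_id, citation_id) {
  df <- data.frame(gene_id = as.character(gene_id),
                   citation_id = as.character(citation_id),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df[order(df$gene_id, df$citation_id), , drop = FALSE]
}

#' Read gene-citation links from a gene2pubmed-style TSV
#'
#' Expects a header with columns `tax_id`, `GeneID`, `PubMed_ID` (a leading
#' `#` on the header, as NCBI writes it, is tolerated).
#'
#' @param path path to the TSV file.
#' @param tax_id optional taxon filter; rows with other taxa are dropped.
#' @return A `data.frame` as returned by [gene_links()].
#' @export
read_gene_links <- function(path, tax_id = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "")
  names(df) <- sub("^X\\.", "", names(df))
  names(df)[1] <- sub("^#", "", names(df)[1])
  need <- c("tax_id", "GeneID", "PubMed_ID")
  if (!all(need %in% names(df)))
    stop_litcohesion("link file must have columns tax_id, GeneID, PubMed_ID")
  if (!is.null(tax_id)) df <- df[df$tax_id %in% as.character(tax_id), ]
  gene_links(df$GeneID, df$PubMed_ID)
}

#' Remove promiscuous citations
#'
#' Citations linked to more than `max_genes_per_citation` distinct genes are
#' removed entirely (strictly-more-than semantics: a citation linked to
#' exactly the cutoff is kept).  Such citations typically describe
#' genome-scale experiments and carry no gene-specific functional signal.
#'
#' @param links a `data.frame` of gene-citation links ([gene_links()]).
#' @param max_genes_per_citation integer cutoff, default 10.
#' @return A list with `links` (the retained rows) and `removed`, a
#'   `data.frame` of dropped `citation_id`s and their distinct gene counts.
#' @export
filter_promiscuous_citations <- function(links, max_genes_per_citation = 10) {
  if (max_genes_per_citation < 1)
    stop_litcohesion("max_genes_per_citation must be >= 1")
  links <- gene_links(links$gene_id, links$citation_id)
  if (nrow(links) == 0) {
    return(list(links = links,
                removed = data.frame(citation_id = character(),
                                     n_genes = integer())))
  }
  counts <- tapply(links$gene_id, links$citation_id,
                   function(g) length(unique(g)))
  bad <- names(counts)[counts > max_genes_per_citation]
  removed <- data.frame(citation_id = bad,
                        n_genes = as.integer(counts[bad]),
                        row.names = NULL, stringsAsFactors = FALSE)
  removed <- removed[order(removed$citation_id), , drop = FALSE]
  list(links = links[!(links$citation_id %in% bad), , drop = FALSE],
       removed = removed)
}

# Normalise an ortholog specification into a disjoint list of groups.
# Accepts a two-column data.frame of gene pairs (groups = connected
# components) or a list of character vectors (checked for disjointness).
ortholog_groups <- function(orthologs) {
  if (is.data.frame(orthologs)) {
    if (ncol(orthologs) < 2)
      stop_litcohesion("ortholog pairs need two columns")
    g <- igraph::graph_from_data_frame(
      data.frame(a = as.character(orthologs[[1]]),
                 b = as.character(orthologs[[2]])),
      directed = FALSE)
    comp <- igraph::components(g)
    groups <- split(names(comp$membership), comp$membership)
    names(groups) <- NULL
  } else if (is.list(orthologs)) {
    groups <- lapply(orthologs, as.character)
    all_members <- unlist(groups)
    if (anyDuplicated(all_members))
      stop_litcohesion("ortholog groups overlap: gene(s) ",
                       paste(unique(all_members[duplicated(all_members)]),
                             collapse = ", "),
                       " appear in more than one group")
  } else stop_litcohesion("orthologs must be a pair data.frame or a list")
  groups[lengths(groups) >= 2]
}

#' Merge citation sets of orthologous genes
#'
#' Within each ortholog group every member gene receives the union of the
#' group's citation sets, so each organism's gene keeps a per-gene document
#' while sharing the group's literature.  Genes absent from the map pass
#' through unchanged.
#'
#' @param links a `data.frame` of gene-citation links.
#' @param orthologs either a two-column `data.frame` of gene-id pairs
#'   (groups are the connected components) or a list of character vectors
#'   (must be disjoint).
#' @return A `data.frame` of links with merged citation sets.
#' @export
merge_ortholog_citations <- function(links, orthologs) {
  groups <- ortholog_groups(orthologs)
  if (length(groups) == 0 || nrow(links) == 0)
    return(gene_links(links$gene_id, links$citation_id))
  extra <- lapply(groups, function(members) {
    cits <- unique(links$citation_id[links$gene_id %in% members])
    if (length(cits) == 0) return(NULL)
    data.frame(gene_id = rep(members, each = length(cits)),
               citation_id = rep(cits, times = length(members)),
               stringsAsFactors = FALSE)
  })
  merged <- rbind(links, do.call(rbind, extra))
  gene_links(merged$gene_id, merged$citation_id)
}

#' Build one document per gene
#'
#' Concatenates title and abstract of every retained citation of a gene, in
#' ascending `citation_id` order (a documented, byte-stable order; the
#' bag-of-words model downstream is order-invariant).  Links whose citation
#' has no abstract record are skipped and reported.  Genes with zero
#' resolved citations are omitted.
#'
#' @param abstracts a `data.frame` from [abstract_records()] /
#'   [read_abstracts()].
#' @param links a `data.frame` of (filtered, merged) gene-citation links.
#' @return A list with `documents` (`data.frame` of `gene_id`, `text`,
#'   `abstract_count`, sorted by `gene_id`) and `dangling` (skipped links).
#' @export
build_gene_documents <- function(abstracts, links) {
  links <- gene_links(links$gene_id, links$citation_id)
  ok <- links$citation_id %in% abstracts$citation_id
  dangling <- links[!ok, , drop = FALSE]
  if (nrow(dangling) > 0)
    message(nrow(dangling), " link(s) reference unknown citations; skipped")
  links <- links[ok, , drop = FALSE]
  txt <- paste(abstracts$title, abstracts$abstract)
  names(txt) <- abstracts$citation_id
  docs <- lapply(split(links$citation_id, links$gene_id), function(cits) {
    cits <- sort(unique(cits))
    list(text = paste(txt[cits], collapse = " "), n = length(cits))
  })
  documents <- data.frame(
    gene_id = names(docs),
    text = vapply(docs, `[[`, "", "text"),
    abstract_count = vapply(docs, function(d) as.integer(d$n), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  documents <- documents[order(documents$gene_id), , drop = FALSE]
  rownames(documents) <- NULL
  list(documents = documents, dangling = dangling)
}

#' Tokenization rules
#'
#' Defaults: lowercase, purely alphabetic tokens, minimum length 3, a small
#' fixed English stop-list, no stemming.  Deliberately simple and fully
#' reproducible; all pieces are configurable.
#'
#' @param lowercase lowercase the text before matching.
#' @param pattern regular expression matched to extract tokens.
#' @param min_length minimum token length in characters.
#' @param stopwords character vector of tokens to drop (compared after
#'   lowercasing).
#' @return An object of class `tokenize_rules`.
#' @export
tokenize_rules <- function(lowercase = TRUE, pattern = "[a-z]+",
                           min_length = 3, stopwords = default_stopwords()) {
  structure(list(lowercase = lowercase, pattern = pattern,
                 min_length = as.integer(min_length),
                 stopwords = as.character(stopwords)),
            class = "tokenize_rules")
}

#' Default stop-list
#'
#' A small fixed English stop-list shipped with the package.
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "litcohesion")
  readLines(path, warn = FALSE)
}

#' Tokenize document text into term counts
#'
#' @param text a character scalar (or vector, concatenated).
#' @param rules a [tokenize_rules()] object.
#' @return A named integer vector of term counts, names sorted.
#' @export
tokenize <- function(text, rules = tokenize_rules()) {
  text <- paste(text, collapse = " ")
  if (rules$lowercase) text <- tolower(text)
  toks <- regmatches(text, gregexpr(rules$pattern, text))[[1]]
  toks <- toks[nchar(toks) >= rules$min_length]
  toks <- toks[!(toks %in% rules$stopwords)]
  if (length(toks) == 0) return(structure(integer(0), names = character(0)))
  tab <- table(toks)
  structure(as.integer(tab), names = names(tab))
}

#' Read a two-column ortholog pair TSV
#' @param path path to a headerless or headered two-column TSV of gene-id
#'   pairs; a header is detected by the literal first field `gene_a`.
#' @return two-column `data.frame` of pairs.
#' @export
read_orthologs <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("^gene_a\\b", first)
  df <- read.delim(path, header = header, sep = "\t",
                   colClasses = "character")
  names(df)[1:2] <- c("gene_a", "gene_b")
  df[, 1:2]
}

#' Read a gene_info-style symbol table
#' @param path TSV with columns `GeneID` and `Symbol` (extra columns
#'   ignored; leading `#` on the header tolerated).
#' @return `data.frame` with columns `gene_id`, `symbol`.
#' @export
read_gene_info <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "")
  names(df)[1] <- sub("^X\\.", "", sub("^#", "", names(df)[1]))
  if (!all(c("GeneID", "Symbol") %in% names(df)))
    stop_litcohesion("gene info file must have columns GeneID and Symbol")
  data.frame(gene_id = df$GeneID, symbol = df$Symbol,
             stringsAsFactors = FALSE)
}
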