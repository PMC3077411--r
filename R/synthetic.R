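# Synthetic literature corpora with known topic structure.
#
# The generator emulates the statistical shape of a real gene-document
# collection: a heavy-tailed abstracts-per-gene distribution (median around
# 3-5, a large mass of single-abstract genes, a long right tail), latent
# topic structure so that designated cohesive gene sets share vocabulary, a
# shared background vocabulary mixed into every abstract, promiscuous
# citations linked to more than ten genes (genome-scale papers), and
# "well-studied" genes whose many abstracts are spread across topics.  It
# makes no attempt at realistic English text, MeSH structure, or citation
# dates.

#' Specification of a synthetic literature corpus
#'
#' Defaults describe a desk-scale corpus with the qualitative shape of a
#' mammalian gene-document collection: 200 genes over 5 topics,
#' abstracts-per-gene from a discretized lognormal (median about 3, ~25%
#' of genes with a single abstract, long right tail), 30% background
#' vocabulary per abstract, 5% well-studied genes, and 5 promiscuous
#' citations each linked to 12 genes.
#'
#' @param n_genes number of genes.
#' @param n_topics number of latent topics (genes assigned round-robin).
#' @param topic_vocab words in each topic's vocabulary.
#' @param background_vocab words in the shared background vocabulary.
#' @param background_mix fraction of each abstract's words drawn from the
#'   background vocabulary, in \[0, 1\].
#' @param abstracts_meanlog,abstracts_sdlog parameters of the discretized
#'   lognormal for abstracts per gene.
#' @param abstracts_min truncation point of the abstracts-per-gene
#'   distribution (default 1: every gene has at least one abstract).
#' @param words_per_abstract mean words per abstract (Poisson, floor 8).
#' @param wellstudied_fraction fraction of genes with a multi-topic
#'   literature: each abstract's topic is drawn uniformly at random from
#'   the gene's own random set of `wellstudied_topics` topics (well-studied
#'   genes span multiple pathways, but different genes span *different*
#'   pathways).
#' @param wellstudied_topics number of topics a well-studied gene's
#'   literature spans (capped at `n_topics`).
#' @param wellstudied_boost multiplier on the abstract count of
#'   well-studied genes (they are well-studied *because* they have many
#'   abstracts).
#' @param cocitation_rate probability that an abstract also cites other
#'   genes of its topic (functional papers describe several related genes;
#'   genes sharing all their abstracts have cosine 1).  Co-cited genes
#'   spend one of their own abstract "slots" on the shared citation, so
#'   the abstracts-per-gene marginal distribution is unchanged.
#' @param cocitation_max maximum number of extra same-topic genes cited by
#'   a co-citing abstract (uniform on 1..max).
#' @param promiscuous_citations number of extra citations linked to more
#'   than ten genes each.
#' @param promiscuous_genes_per_citation genes linked to each promiscuous
#'   citation (> 10 so the default filter removes them).
#' @param seed master seed; expanded into per-stage substreams so adding a
#'   stage never perturbs earlier draws.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_genes = 200, n_topics = 5, topic_vocab = 60,
                        background_vocab = 120, background_mix = 0.3,
                        abstracts_meanlog = log(3),
                        abstracts_sdlog = 1.1,
                        abstracts_min = 1,
                        words_per_abstract = 40,
                        wellstudied_fraction = 0.05,
                        wellstudied_boost = 8,
                        wellstudied_topics = 3,
                        cocitation_rate = 0.3,
                        cocitation_max = 3,
                        promiscuous_citations = 5,
                        promiscuous_genes_per_citation = 12,
                        seed = 1) {
  spec <- list(n_genes = as.integer(n_genes), n_topics = as.integer(n_topics),
               topic_vocab = as.integer(topic_vocab),
               background_vocab = as.integer(background_vocab),
               background_mix = background_mix,
               abstracts_meanlog = abstracts_meanlog,
               abstracts_sdlog = abstracts_sdlog,
               abstracts_min = as.integer(abstracts_min),
               words_per_abstract = words_per_abstract,
               wellstudied_fraction = wellstudied_fraction,
               wellstudied_boost = wellstudied_boost,
               wellstudied_topics = as.integer(wellstudied_topics),
               cocitation_rate = cocitation_rate,
               cocitation_max = as.integer(cocitation_max),
               promiscuous_citations = as.integer(promiscuous_citations),
               promiscuous_genes_per_citation =
                 as.integer(promiscuous_genes_per_citation),
               seed = as.integer(seed))
  if (spec$n_genes < 2 || spec$n_topics < 1)
    stop_litcohesion("need at least 2 genes and 1 topic")
  if (spec$topic_vocab < 1) stop_litcohesion("topic vocabulary is empty")
  if (spec$abstracts_min < 1) stop_litcohesion("abstracts_min must be >= 1")
  if (spec$background_mix < 0 || spec$background_mix > 1 ||
      spec$wellstudied_fraction < 0 || spec$wellstudied_fraction > 1 ||
      spec$cocitation_rate < 0 || spec$cocitation_rate > 1)
    stop_litcohesion("fractions must be in [0, 1]")
  if (spec$background_mix > 0 && spec$background_vocab < 1)
    stop_litcohesion("background_mix > 0 needs background vocabulary")
  structure(spec, class = "corpus_spec")
}

#' Read a corpus spec from a JSON config file
#' @param path JSON file whose keys are [corpus_spec()] arguments.
#' @return a `corpus_spec`.
#' @export
corpus_spec_from_json <- function(path) {
  args <- jsonlite::fromJSON(path)
  do.call(corpus_spec, args)
}

# Purely alphabetic synthetic words (so the default tokenizer keeps them):
# base-26 codes of fixed width appended to an alphabetic prefix.
make_words <- function(prefix, n) {
  width <- max(3, ceiling(log(max(n, 2)) / log(26)))
  code <- function(i) {
    out <- character(width)
    i <- i - 1
    for (p in width:1) { out[p] <- letters[i %% 26 + 1]; i <- i %/% 26 }
    paste(out, collapse = "")
  }
  paste0(prefix, vapply(seq_len(n), code, ""))
}

#' Generate a synthetic corpus
#'
#' @param spec a [corpus_spec()].
#' @return list with `abstracts` (JSONL-compatible `data.frame`), `links`
#'   (gene-citation `data.frame`), and `labels`: a list with `genes`
#'   (`data.frame` of `gene_id`, `topic`, `wellstudied`, `n_abstracts`),
#'   `promiscuous_citation_ids`, and the `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  topic_of <- rep_len(seq_len(spec$n_topics), spec$n_genes)
  topic_words <- lapply(seq_len(spec$n_topics), function(t)
    make_words(paste0("top", letters[(t - 1) %% 26 + 1]), spec$topic_vocab))
  bg_words <- make_words("bg", max(spec$background_vocab, 1))

  n_abs <- with_seed(substream_seed(spec$seed, 1), {
    x <- pmax(spec$abstracts_min,
              round(rlnorm(spec$n_genes, spec$abstracts_meanlog,
                           spec$abstracts_sdlog)))
    as.integer(x)
  })
  ws_draw <- with_seed(substream_seed(spec$seed, 2), {
    ws <- rep(FALSE, spec$n_genes)
    n_ws <- round(spec$wellstudied_fraction * spec$n_genes)
    if (n_ws > 0) ws[sample(spec$n_genes, n_ws)] <- TRUE
    span <- min(spec$wellstudied_topics, spec$n_topics)
    # each well-studied gene's literature spans its own topic subset,
    # always including the gene's home topic
    mix <- lapply(seq_len(spec$n_genes), function(gi) {
      if (!ws[gi]) return(topic_of[gi])
      extra <- setdiff(seq_len(spec$n_topics), topic_of[gi])
      if (span - 1 >= length(extra)) c(topic_of[gi], extra)
      else c(topic_of[gi], extra[sample.int(length(extra), span - 1)])
    })
    list(ws = ws, mix = mix)
  })
  wellstudied <- ws_draw$ws
  topic_mix <- ws_draw$mix
  n_abs[wellstudied] <- n_abs[wellstudied] * spec$wellstudied_boost

  genes_by_topic <- split(seq_len(spec$n_genes), topic_of)
  gen <- with_seed(substream_seed(spec$seed, 3), {
    # every gene has exactly n_abs citation slots; a co-citing paper
    # consumes one slot from each gene it cites, so the abstracts-per-gene
    # marginal equals the drawn target counts exactly
    slots <- n_abs
    cit <- 0L
    texts <- list()
    link_gene <- list()
    link_cit <- list()
    for (gi in seq_len(spec$n_genes)) {
      while (slots[gi] > 0) {
        cit <- cit + 1L
        id <- sprintf("c%06d", cit)
        mix <- topic_mix[[gi]]
        t <- mix[sample.int(length(mix), 1)]
        nw <- max(8, rpois(1, spec$words_per_abstract))
        n_bg <- round(spec$background_mix * nw)
        words <- c(sample(bg_words, n_bg, replace = TRUE),
                   sample(topic_words[[t]], nw - n_bg, replace = TRUE))
        cited <- gi
        # functional papers often describe several genes of the same topic
        mates <- setdiff(genes_by_topic[[t]], gi)
        mates <- mates[slots[mates] > 0]
        if (spec$cocitation_rate > 0 && length(mates) > 0 &&
            runif(1) < spec$cocitation_rate) {
          n_extra <- min(sample.int(spec$cocitation_max, 1), length(mates))
          cited <- c(gi, mates[sample.int(length(mates), n_extra)])
        }
        slots[cited] <- slots[cited] - 1L
        texts[[cit]] <- paste(sample(words), collapse = " ")
        link_gene[[cit]] <- gene_ids[cited]
        link_cit[[cit]] <- rep(id, length(cited))
      }
    }
    list(abstracts = data.frame(citation_id = sprintf("c%06d", seq_len(cit)),
                                text = unlist(texts),
                                stringsAsFactors = FALSE),
         links = data.frame(gene_id = unlist(link_gene),
                            citation_id = unlist(link_cit),
                            stringsAsFactors = FALSE),
         n_citations = cit)
  })

  prom <- with_seed(substream_seed(spec$seed, 4), {
    if (spec$promiscuous_citations == 0) {
      list(abstracts = NULL, links = NULL, ids = character(0))
    } else {
      ids <- sprintf("c%06d",
                     gen$n_citations + seq_len(spec$promiscuous_citations))
      texts <- vapply(ids, function(id) {
        nw <- max(8, rpois(1, spec$words_per_abstract))
        paste(sample(bg_words, nw, replace = TRUE), collapse = " ")
      }, "")
      links <- do.call(rbind, lapply(seq_along(ids), function(i) {
        data.frame(gene_id = sample(gene_ids,
                                    spec$promiscuous_genes_per_citation),
                   citation_id = ids[i], stringsAsFactors = FALSE)
      }))
      list(abstracts = data.frame(citation_id = ids, text = unname(texts),
                                  stringsAsFactors = FALSE),
           links = links, ids = ids)
    }
  })

  all_abs <- rbind(gen$abstracts, prom$abstracts)
  nwords_title <- 5
  title <- vapply(strsplit(all_abs$text, " ", fixed = TRUE), function(w)
    paste(head(w, nwords_title), collapse = " "), "")
  body <- vapply(strsplit(all_abs$text, " ", fixed = TRUE), function(w)
    paste(w[-seq_len(min(nwords_title, length(w)))], collapse = " "), "")
  abstracts <- abstract_records(all_abs$citation_id, title, body)
  links <- gene_links(rbind(gen$links, prom$links)$gene_id,
                      rbind(gen$links, prom$links)$citation_id)
  # abstract count per gene = distinct non-promiscuous citations, i.e.
  # authored plus co-cited literature
  own <- links[!(links$citation_id %in% prom$ids), , drop = FALSE]
  n_final <- table(factor(own$gene_id, levels = gene_ids))
  labels <- list(genes = data.frame(gene_id = gene_ids, topic = topic_of,
                                    wellstudied = wellstudied,
                                    n_abstracts = as.integer(n_final),
                                    stringsAsFactors = FALSE),
                 promiscuous_citation_ids = prom$ids,
                 spec = spec)
  list(abstracts = abstracts, links = links, labels = labels)
}

#' Draw cohesive (within-topic) and null (uniform) gene sets
#'
#' @param labels the `labels` element of [generate_corpus()] output.
#' @param n_cohesive,n_null number of sets of each kind.
#' @param size genes per set (null sets are size-matched).
#' @param seed seed for the draws.
#' @return list with `cohesive` and `null`, each a list of character
#'   vectors without duplicates; each cohesive set carries its topic as
#'   attribute `topic`.
#' @export
make_gene_sets <- function(labels, n_cohesive, n_null, size, seed = 1) {
  genes <- labels$genes
  by_topic <- split(genes$gene_id, genes$topic)
  with_seed(substream_seed(seed, 11), {
    cohesive <- lapply(seq_len(n_cohesive), function(i) {
      t <- ((i - 1) %% length(by_topic)) + 1
      pop <- by_topic[[t]]
      if (size > length(pop))
        stop_litcohesion("set size ", size, " exceeds topic population ",
                         length(pop))
      structure(sample(pop, size), topic = as.integer(names(by_topic)[t]))
    })
    null <- lapply(seq_len(n_null), function(i)
      sample(genes$gene_id, size))
    list(cohesive = cohesive, null = null)
  })
}

#' Write a synthetic corpus in the pipeline's input formats
#'
#' Emits `abstracts.jsonl` (keys id, title, abstract), `links.tsv`
#' (gene2pubmed dialect: tax_id, GeneID, PubMed_ID, with a synthetic
#' tax_id of 0), and `labels.tsv` (truth labels).
#'
#' @param corpus output of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab_path <- file.path(dir, "abstracts.jsonl")
  con <- file(ab_path, open = "wb")
  for (i in seq_len(nrow(corpus$abstracts))) {
    writeLines(jsonlite::toJSON(list(id = corpus$abstracts$citation_id[i],
                                     title = corpus$abstracts$title[i],
                                     abstract = corpus$abstracts$abstract[i]),
                                auto_unbox = TRUE), con, sep = "\n")
  }
  close(con)
  links_path <- file.path(dir, "links.tsv")
  write_tsv_file(data.frame(tax_id = 0L,
                            GeneID = corpus$links$gene_id,
                            PubMed_ID = corpus$links$citation_id),
                 links_path)
  labels_path <- file.path(dir, "labels.tsv")
  write_tsv_file(corpus$labels$genes, labels_path)
  invisible(c(abstracts = ab_path, links = links_path, labels = labels_path))
}
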