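# Small in-code fixtures shared across test files.

tiny_abstracts <- function() {
  abstract_records(
    citation_id = c("c1", "c2", "c3", "c4", "c5"),
    title = c("Kinase signaling cascade", "Receptor kinase binding",
              "Lipid transport pathway", "Membrane lipid dynamics",
              "Genome wide association screen"),
    abstract = c("phosphorylation kinase substrate activation",
                 "kinase receptor phosphorylation signaling",
                 "cholesterol lipid transport membrane",
                 "lipid bilayer membrane cholesterol",
                 "thousands loci screening genotype"))
}

tiny_links <- function() {
  gene_links(gene_id = c("gA", "gA", "gB", "gC", "gC", "gD"),
             citation_id = c("c1", "c2", "c2", "c3", "c4", "c4"))
}

# a fitted pipeline on a small seeded synthetic corpus
fit_synthetic <- function(spec) {
  corpus <- generate_corpus(spec)
  filt <- filter_promiscuous_citations(corpus$links)
  docs <- build_gene_documents(corpus$abstracts, filt$links)
  tgm <- apply_log_entropy(term_gene_matrix(docs$documents))
  model <- fit_lsi(tgm)
  list(corpus = corpus, documents = docs$documents, tgm = tgm,
       model = model, sim = similarity_matrix(model))
}
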