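# Trigger pre-screening, inverted indexes, triple queries and the gene
# co-occurrence graph.

make_trigger <- function(text, type, start = 0L) {
  mention(paste0("TR", start), "EVENT_TRIGGER", start, start + 1L, text,
          event_type = type)
}

test_that("trigger pre-screening removes blacklisted and band-notation triggers", {
  lex <- load_lexicons()
  trigs <- list(make_trigger("described", "Transcription", 0L),
                make_trigger("transcription", "Transcription", 1L),
                make_trigger("17q21", "Localization", 2L),
                make_trigger("membrane", "Localization", 3L),
                make_trigger("described", "Binding", 4L))
  out <- prescreen_triggers(trigs, lex$trigger_blacklist)
  texts <- vapply(out, function(m) m$text, character(1))
  # "described" is only blacklisted for transcription, not binding
  expect_setequal(texts, c("transcription", "membrane", "described"))
  expect_true(all(vapply(out, function(m)
    !(m$text == "described" && m$event_type == "transcription"),
    logical(1))))
  # band notation variants
  for (band in c("17q21", "8p11.2", "xq28")) {
    got <- prescreen_triggers(list(make_trigger(band, "Localization", 0L)),
                              lex$trigger_blacklist)
    expect_length(got, 0L)
  }
})

# Shared fixture: two abstracts, ranked synthetic candidates.
index_fixture <- function() {
  lex <- load_lexicons()
  corp <- generate_corpus(synth_params(n_pos = 12, n_neg = 12, seed = 19))
  feats <- corpus_features(corp$docs, lex)
  model <- fit_evidence_model(feats)
  ranked <- rank_evidence(model, feats)
  idx <- build_evidence_index(corp$docs, ranked, lex)
  list(lex = lex, corp = corp, ranked = ranked, idx = idx)
}

test_that("index construction resolves every candidate and is deterministic", {
  fx <- index_fixture()
  # every evidence row is indexed under at least the abstract-level key
  expect_equal(nrow(fx$idx$evidence), nrow(fx$ranked))
  expect_true(all(lengths(fx$idx$cancer_keys) >= 1))
  idx2 <- build_evidence_index(fx$corp$docs, fx$ranked, fx$lex)
  expect_equal(idx2$evidence, fx$idx$evidence)
  expect_equal(idx2$cancer_keys, fx$idx$cancer_keys)
  # duplicate sentence ids across abstracts are rejected
  dup <- fx$corp$docs
  dup[[2]] <- abstract_doc("DUP",
                           list(dup[[1]]$sentences[[1]]), "cancer")
  expect_error(build_evidence_index(dup, fx$ranked, fx$lex),
               "duplicate sentence ids")
  # empty corpus -> empty index
  empty <- build_evidence_index(list(), fx$ranked[0, ], fx$lex)
  expect_equal(nrow(empty$evidence), 0L)
})

test_that("triple queries respect wildcards, max-sentence rule and ordering", {
  fx <- index_fixture()
  res_all <- query_evidence(fx$idx, "cancer")
  # results are a subset of the corpus; re-querying is idempotent
  expect_true(all(res_all$hits$sentence_id %in%
                    fx$ranked$sentence_id))
  expect_equal(query_evidence(fx$idx, "cancer")$hits, res_all$hits)
  # abstracts sorted by max score, each shown with its best sentence
  expect_true(all(diff(res_all$abstracts$max_score) <= 0))
  for (i in seq_len(min(4, nrow(res_all$abstracts)))) {
    aid <- res_all$abstracts$abstract_id[i]
    hits_a <- res_all$hits[res_all$hits$abstract_id == aid, ]
    expect_equal(res_all$abstracts$max_score[i], max(hits_a$score))
    expect_equal(res_all$abstracts$best_sentence_id[i],
                 hits_a$sentence_id[which.max(hits_a$score)])
  }
  # wildcard gene query equals the union over all per-gene queries
  genes <- unique(res_all$hits$gene_id)
  per_gene <- lapply(genes, function(g)
    query_evidence(fx$idx, "cancer", genes = g)$hits)
  union_keys <- sort(unique(unlist(lapply(per_gene, function(h)
    paste(h$sentence_id, h$gene_mid, h$trigger_mid)))))
  all_keys <- sort(paste(res_all$hits$sentence_id, res_all$hits$gene_mid,
                         res_all$hits$trigger_mid))
  expect_equal(all_keys, union_keys)
  # event filter restricts event types; unknown cancer yields empty result
  et <- unique(res_all$hits$event_type)[1]
  res_et <- query_evidence(fx$idx, "cancer", events = et)
  expect_true(all(res_et$hits$event_type == et))
  expect_equal(nrow(query_evidence(fx$idx, "no such disease")$hits), 0L)
  # returned sentences all contain a matching gene and event type
  for (j in seq_len(min(5, nrow(res_et$hits)))) {
    doc <- fx$idx$docs[[res_et$hits$abstract_id[j]]]
    sent <- Filter(function(s) s$sentence_id == res_et$hits$sentence_id[j],
                   doc$sentences)[[1]]
    kinds <- vapply(sent$mentions, function(m) m$kind, character(1))
    expect_true("GENE" %in% kinds)
    ets <- vapply(Filter(function(m) m$kind == "EVENT_TRIGGER",
                         sent$mentions),
                  function(m) m$event_type, character(1))
    expect_true(et %in% ets)
  }
})

test_that("cancer synonyms map queries onto canonical keys", {
  syn <- load_cancer_synonyms()
  expect_equal(unname(syn["glioblastoma"]), "brain cancer")
  fx <- build_fixtures()
  lex <- load_lexicons()
  feats <- corpus_features(list(fx$sentence1, fx$sentence2), lex)
  model <- fit_evidence_model(toy_features(20, 20, seed = 1))
  ranked <- rank_evidence(model, feats)
  idx <- build_evidence_index(list(fx$sentence1, fx$sentence2), ranked, lex)
  direct <- query_evidence(idx, "prostate cancer")
  via_syn <- query_evidence(idx, "Prostatic Carcinoma")
  expect_gt(nrow(direct$hits), 0L)
  expect_equal(via_syn$hits, direct$hits)
})

test_that("the co-occurrence graph matches a brute-force pairwise oracle", {
  # two genes sharing one abstract -> one edge
  hits <- data.frame(abstract_id = c("A1", "A1"), gene_id = c("g1", "g2"),
                     score = c(0.9, 0.8), stringsAsFactors = FALSE)
  g <- cooccurrence_graph(list(hits = hits))
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$n_shared, 1L)
  # disjoint abstracts -> no edges
  hits2 <- data.frame(abstract_id = c("A1", "A2"), gene_id = c("g1", "g2"),
                      score = c(0.9, 0.8), stringsAsFactors = FALSE)
  expect_equal(igraph::ecount(cooccurrence_graph(list(hits = hits2))), 0L)
  # 10-gene random instance vs O(n^2) abstract-intersection oracle
  set.seed(20)
  hits3 <- data.frame(abstract_id = sample(sprintf("A%d", 1:6), 40,
                                           replace = TRUE),
                      gene_id = sample(sprintf("g%d", 1:10), 40,
                                       replace = TRUE),
                      score = runif(40), stringsAsFactors = FALSE)
  g3 <- cooccurrence_graph(list(hits = hits3), top_n = 10)
  expect_true(all(igraph::E(g3)$n_shared >= 1))       # no empty edges
  expect_equal(sum(igraph::which_loop(g3)), 0L)       # no self-edges
  present <- igraph::V(g3)$name
  for (i in seq_along(present)) for (j in seq_along(present)) {
    if (i >= j) next
    shared <- intersect(
      unique(hits3$abstract_id[hits3$gene_id == present[i]]),
      unique(hits3$abstract_id[hits3$gene_id == present[j]]))
    connected <- igraph::are_adjacent(g3, present[i], present[j])
    expect_equal(connected, length(shared) > 0)
    if (connected) {
      eid <- igraph::get_edge_ids(g3, c(present[i], present[j]))
      expect_equal(igraph::E(g3)$n_shared[eid], length(shared))
    }
  }
  # top_n limits nodes to the best-scoring genes
  g1 <- cooccurrence_graph(list(hits = hits3), top_n = 3)
  expect_equal(igraph::vcount(g1), 3L)
  gene_max <- tapply(hits3$score, hits3$gene_id, max)
  expect_setequal(igraph::V(g1)$name,
                  names(sort(gene_max, decreasing = TRUE))[1:3])
})

test_that("graph export writes edge-list TSV and GraphML", {
  hits <- data.frame(abstract_id = c("A1", "A1", "A2"),
                     gene_id = c("g1", "g2", "g1"),
                     score = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  g <- cooccurrence_graph(list(hits = hits))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_cooc_graph(g, tsv, gml)
  el <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(el), 1L)
  expect_setequal(c(el$gene_a, el$gene_b), c("g1", "g2"))
  expect_true(file.size(gml) > 0)
})
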