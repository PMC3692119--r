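# Domain types, readers and candidate assembly.

test_that("parse_dependencies hand-parses small CoNLL blocks", {
  toks <- parse_dependencies(
    "1 reduced 0 root\n2 SOX9 1 nsubj\n3 levels 1 dobj")[[1]]
  expect_equal(nrow(toks), 3L)
  expect_equal(toks$head, c(-1L, 0L, 0L))
  expect_equal(toks$surface[toks$head == -1L], "reduced")
  expect_equal(toks$deplabel, c("root", "nsubj", "dobj"))

  single <- parse_dependencies("1 alone 0 root")[[1]]
  expect_equal(single$head, -1L)

  # CoNLL-X style rows (10 columns) use FORM/LEMMA/HEAD/DEPREL columns
  cx <- paste("1\tLevels\tlevel\tN\tNN\t_\t2\tnsubj\t_\t_",
              "2\trose\trise\tV\tVBD\t_\t0\troot\t_\t_", sep = "\n")
  toks <- parse_dependencies(cx)[[1]]
  expect_equal(toks$lemma, c("level", "rise"))
  expect_equal(toks$head, c(1L, -1L))

  # blank lines split sentence blocks
  blocks <- parse_dependencies("1 a 0 root\n\n1 b 0 root\n2 c 1 dep")
  expect_length(blocks, 2L)
})

test_that("parse_dependencies rejects malformed trees", {
  expect_error(parse_dependencies("1 a 0 root\n2 b 0 root")[[1]],
               "root")
  expect_error(parse_dependencies("1 a 2 dep\n2 b 1 dep")[[1]],
               "root|cycle")
  expect_error(parse_dependencies("1 a 5 dep")[[1]], "range")
  expect_error(token_frame(c("a", "b", "c"), c(-1L, 2L, 1L)), "cycle")
})

test_that("parse_standoff maps character spans onto tokens", {
  fx <- build_fixtures()
  s1 <- fx$sentence1$sentences[[1]]
  s1$mentions <- list()
  # "SOX9" first occurs at characters 31-35 of the sentence text
  off <- regexpr("SOX9", s1$text, fixed = TRUE)
  ents <- sprintf("T1\tProtein %d %d\tSOX9", off - 1L, off + 3L)
  out <- parse_standoff(ents, character(), s1)
  expect_length(out$mentions, 1L)
  m <- out$mentions[[1]]
  expect_equal(m$kind, "GENE")
  expect_equal(m$text, "SOX9")
  expect_equal(out$tokens$surface[(m$start + 1):m$end], "SOX9")

  # empty annotation text -> no mentions
  expect_length(parse_standoff("", "", s1)$mentions, 0L)

  # scores travel through attribute lines
  ev <- paste(sprintf("T2\tNegative_regulation 15 30\tdown-regulation"),
              "E1\tNegative_regulation:T2 Theme:T1",
              "A1\tScore T2 1.25", "A2\tEdgeScore E1 T1 0.75", sep = "\n")
  out2 <- parse_standoff(ents, ev, s1)
  trig <- Filter(function(m) m$kind == "EVENT_TRIGGER", out2$mentions)[[1]]
  expect_equal(trig$event_type, "regulation")
  expect_equal(trig$trigger_score, 1.25)
  expect_equal(trig$edge_scores$T1, 0.75)
})

test_that("parse_standoff rejects malformed annotations", {
  fx <- build_fixtures()
  s1 <- fx$sentence1$sentences[[1]]
  s1$mentions <- list()
  expect_error(parse_standoff("T2\tBanana 0 3\txxx", "", s1),
               "unknown kind")
  expect_error(parse_standoff("T1\tProtein 0 9999\tSOX9", "", s1),
               "line 1")
  expect_error(
    mention("T9", "EVENT_TRIGGER", 0L, 1L, "x", event_type = "Banana_event"),
    "Positive_regulation")
})

test_that("merge_event_types combines the regulation polarity types", {
  expect_equal(merge_event_types("Positive_regulation"), "regulation")
  expect_equal(merge_event_types("Negative_regulation"), "regulation")
  expect_equal(merge_event_types("Phosphorylation"), "phosphorylation")
  expect_equal(merge_event_types("Gene_expression"), "gene expression")
  expect_error(merge_event_types("Methylation"), "unknown event type")
})

test_that("default lexicons have the documented sizes and are deduplicated", {
  lex <- load_lexicons()
  expect_length(lex$hallmark_terms, 6L)
  expect_length(lex$cancer_terms, 12L)
  expect_true(all(c("cancer", "tumor", "carcinoma") %in% lex$cancer_terms))
  expect_setequal(lex$hallmark_terms,
                  c("apoptosis", "angiogenesis", "growth", "invasion",
                    "metastasis", "proliferation"))
  expect_equal(lex$trigger_blacklist$transcription,
               c("described", "derived", "prescribed", "transition"))

  tmp <- withr::local_tempfile(lines = c("Growth", "growth", "# comment",
                                         "growth  "))
  lex2 <- load_lexicons(hallmark = tmp)
  expect_equal(lex2$hallmark_terms, "growth")
  expect_error(load_lexicons(cancer = "/nonexistent/file.txt"), "cancer")
})

test_that("candidate assembly enumerates gene x trigger pairs of eligible sentences", {
  lex <- load_lexicons()
  tok <- token_frame(c("cancer", "binding", "of", "ABC1", "and", "XYZ2"),
                     c(1L, -1L, 1L, 2L, 3L, 4L))
  ms <- list(mention("T1", "GENE", 3L, 4L, "ABC1", gene_id = "1"),
             mention("T2", "GENE", 5L, 6L, "XYZ2", gene_id = "2"),
             mention("T3", "EVENT_TRIGGER", 1L, 2L, "binding",
                     event_type = "Binding"))
  s <- annotated_sentence("X1", "AB", "cancer binding of ABC1 and XYZ2",
                          tok, ms)
  ab <- abstract_doc("AB", list(s))
  cands <- assemble_candidates(ab, lex)
  expect_length(cands, 2L)      # 2 genes x 1 trigger
  expect_setequal(vapply(cands, function(cd) cd$gene$id, character(1)),
                  c("T1", "T2"))

  # no trigger -> no candidates
  s2 <- s; s2$mentions <- ms[1:2]
  expect_length(assemble_candidates(abstract_doc("AB", list(s2)), lex), 0L)

  # no cancer term anywhere -> no candidates
  tok3 <- token_frame(c("data", "binding", "of", "ABC1"),
                      c(1L, -1L, 1L, 2L))
  s3 <- annotated_sentence("X3", "AB", "data binding of ABC1", tok3,
                           list(ms[[1]], ms[[3]]))
  expect_length(assemble_candidates(abstract_doc("AB", list(s3)), lex), 0L)
  # ...but an abstract-level cancer term restores eligibility
  expect_length(assemble_candidates(
    abstract_doc("AB", list(s3), cancer_terms = "melanoma"), lex), 1L)
})

test_that("candidate counts match brute-force pair enumeration on synthetic corpora", {
  lex <- load_lexicons()
  corp <- generate_corpus(synth_params(n_pos = 15, n_neg = 15, seed = 5))
  for (d in corp$docs) {
    got <- length(assemble_candidates(d, lex))
    want <- 0L
    for (s in d$sentences) {
      genes <- sum(vapply(s$mentions, function(m) m$kind == "GENE",
                          logical(1)))
      trigs <- Filter(function(m) m$kind == "EVENT_TRIGGER", s$mentions)
      trigs <- prescreen_triggers(trigs, lex$trigger_blacklist)
      want <- want + genes * length(trigs)
    }
    expect_equal(got, want)
  }
})

test_that("the document format round-trips all fields", {
  fx <- build_fixtures()
  corp <- generate_corpus(synth_params(n_pos = 4, n_neg = 4, seed = 2))
  docs <- c(list(fx$sentence1, fx$sentence2), corp$docs)
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(docs, tmp)
  back <- read_corpus(tmp)
  expect_length(back, length(docs))
  for (i in seq_along(docs)) {
    expect_equal(back[[i]]$abstract_id, docs[[i]]$abstract_id)
    expect_equal(back[[i]]$cancer_terms, docs[[i]]$cancer_terms)
    for (j in seq_along(docs[[i]]$sentences)) {
      a <- docs[[i]]$sentences[[j]]; b <- back[[i]]$sentences[[j]]
      expect_equal(b$text, a$text)
      expect_equal(b$label, a$label)
      expect_equal(b$tokens, a$tokens)
      expect_equal(b$mentions, a$mentions)
    }
  }
})

test_that("gold label files are read and applied", {
  tmp <- withr::local_tempfile(lines = c("sentence_id\tlabel",
                                         "SENT1\tPOSITIVE",
                                         "SENT2\tnegative"))
  gold <- read_gold_labels(tmp)
  expect_equal(gold$label, c("POSITIVE", "NEGATIVE"))
  fx <- build_fixtures()
  docs <- lapply(list(fx$sentence1, fx$sentence2), function(d) {
    d$sentences[[1]]$label <- NA_character_; d
  })
  docs <- apply_gold_labels(docs, gold)
  expect_equal(docs[[1]]$sentences[[1]]$label, "POSITIVE")
  expect_equal(docs[[2]]$sentences[[1]]$label, "NEGATIVE")

  bad <- withr::local_tempfile(lines = "SENT1\tMAYBE")
  expect_error(read_gold_labels(bad), "unknown labels")
})
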