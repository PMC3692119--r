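# The ten ranking features.

test_that("dep_path_length matches a BFS oracle and is a metric", {
  tok <- random_tree(3, seed = 1)
  expect_equal(dep_path_length(tok, 0L, 0L), 0L)
  root <- tok$index[tok$head == -1L]
  child <- tok$index[tok$head == root][1]
  expect_equal(dep_path_length(tok, root, child), 1L)
  expect_error(dep_path_length(tok, 0L, 99L), "range")

  set.seed(42)
  for (rep in 1:40) {
    tok <- random_tree(12)
    a <- sample(0:11, 1); b <- sample(0:11, 1); c <- sample(0:11, 1)
    dab <- dep_path_length(tok, a, b)
    expect_equal(dab, bfs_dist(tok, a, b))
    # symmetry and triangle inequality
    expect_equal(dab, dep_path_length(tok, b, a))
    expect_lte(dab, dep_path_length(tok, a, c) + dep_path_length(tok, c, b))
  }
})

test_that("event_depth equals BFS distance from the root", {
  set.seed(7)
  for (rep in 1:20) {
    tok <- random_tree(10)
    root <- tok$index[tok$head == -1L]
    i <- sample(0:9, 1)
    expect_equal(event_depth(tok, i), bfs_dist(tok, root, i))
  }
  tok <- random_tree(5, seed = 3)
  expect_equal(event_depth(tok, tok$index[tok$head == -1L]), 0L)
})

test_that("term distances fall back to the penalty for absent terms", {
  lex <- load_lexicons()
  fx <- build_fixtures()
  cands <- assemble_candidates(fx$sentence1, lex)
  cd <- Filter(function(x) x$gene$id == "T1" && x$trigger$id == "T6",
               cands)[[1]]
  d <- term_distances(cd, lex, penalty = 10)
  expect_equal(unname(d["event_regulation_dist"]), 10)  # no regulation term
  expect_equal(unname(d["gene_event_dist"]), 2)         # SOX9 <- of <- down-regulation
  expect_equal(unname(d["event_cancer_dist"]), 3)

  # trigger compared with a term anchored on its own token -> distance 0
  cd2 <- chain_candidate()
  cd2$sentence$mentions <- c(cd2$sentence$mentions,
                             list(mention("T3", "CANCER", 1L, 2L,
                                          "expression")))
  d2 <- term_distances(cd2, lex, penalty = 10)
  expect_equal(unname(d2["event_cancer_dist"]), 0)

  # hand-placed gene three edges from the trigger
  tok <- token_frame(c("r", "t", "a", "b", "G"), c(-1L, 0L, 1L, 2L, 3L))
  g <- mention("T1", "GENE", 4L, 5L, "G", gene_id = "1")
  tr <- mention("T2", "EVENT_TRIGGER", 1L, 2L, "t",
                event_type = "Binding")
  s <- annotated_sentence("D1", "DA", "r t a b G", tok, list(g, tr))
  cd3 <- list(abstract_id = "DA", sentence_id = "D1", sentence = s,
              gene = g, trigger = tr)
  expect_equal(unname(term_distances(cd3, lex)["gene_event_dist"]), 3)
})

test_that("score normalization is min-max with the constant and missing rules", {
  expect_equal(normalize_scores(c(2, -1, 0.5)), c(1, 0, 0.5))
  expect_equal(normalize_scores(3.3), 0.5)
  expect_equal(normalize_scores(c(1, NA, 3)), c(0, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  y <- normalize_scores(x)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(order(x), order(y))                 # order-preserving
  expect_equal(normalize_scores(y), y, tolerance = 1e-12)  # idempotent
})

test_that("keyword counting counts every occurrence, case-insensitively", {
  lex <- load_lexicons()
  fx <- build_fixtures()
  s1 <- fx$sentence1$sentences[[1]]
  expect_equal(keyword_count(s1, lex$cancer_terms), 1L)
  expect_equal(keyword_count(s1, lex$hallmark_terms), 2L)
  tok <- token_frame(c("Tumor", "and", "tumor", "growth"),
                     c(-1L, 0L, 1L, 2L))
  expect_equal(keyword_count(tok, lex$cancer_terms), 2L)
  expect_equal(keyword_count(token_frame(character(0), integer(0)),
                             lex$cancer_terms), 0L)
  # multi-word terms match consecutive tokens, longest first
  expect_equal(keyword_count(token_frame(c("endoplasmic", "reticulum"),
                                         c(-1L, 0L)),
                             lex$subcellular_terms), 1L)
})

test_that("negative cues count purpose phrases and negations per occurrence", {
  lex <- load_lexicons()
  fx <- build_fixtures()
  expect_gte(negative_cue_score(fx$sentence2$sentences[[1]], lex), 1L)
  expect_equal(negative_cue_score(fx$sentence1$sentences[[1]], lex), 0L)
  tok <- token_frame(c("this", "was", "not", "not", "observed"),
                     c(1L, -1L, 4L, 4L, 1L))
  s <- annotated_sentence("N1", "NA1", "this was not not observed", tok)
  expect_equal(negative_cue_score(s, lex), 2L)
})

test_that("agent detection finds genes in the other branch of the event", {
  lex <- load_lexicons()
  fx <- build_fixtures()
  cands <- assemble_candidates(fx$sentence1, lex)
  # query gene AR (first mention), event "reduced"
  cd <- Filter(function(x) x$gene$id == "T2" && x$trigger$id == "T7",
               cands)[[1]]
  agents <- detect_agents(cd)
  expect_equal(vapply(agents, function(m) m$text, character(1)), "SOX9")
  expect_equal(vapply(agents, function(m) m$id, character(1)), "T1")

  # a single-gene sentence has no agent
  expect_length(detect_agents(chain_candidate()), 0L)

  # a second gene hanging below the query gene is in the same branch
  tok <- token_frame(c("r", "t", "G1", "of", "G2"), c(-1L, 0L, 1L, 2L, 3L))
  g1 <- mention("T1", "GENE", 2L, 3L, "G1", gene_id = "1")
  g2 <- mention("T2", "GENE", 4L, 5L, "G2", gene_id = "2")
  tr <- mention("T3", "EVENT_TRIGGER", 1L, 2L, "t", event_type = "Binding")
  s <- annotated_sentence("A1", "AA", "r t G1 of G2", tok, list(g1, g2, tr))
  cd2 <- list(abstract_id = "AA", sentence_id = "A1", sentence = s,
              gene = g1, trigger = tr)
  expect_length(detect_agents(cd2), 0L)
  # ...but from G2's viewpoint G1 is on the path, not another branch
  cd3 <- cd2; cd3$gene <- g2
  expect_length(detect_agents(cd3), 0L)
})

test_that("extract_features populates all ten features deterministically", {
  lex <- load_lexicons()
  fx <- build_fixtures()
  cands <- c(assemble_candidates(fx$sentence1, lex),
             assemble_candidates(fx$sentence2, lex))
  f1 <- extract_features(cands, lex)
  f2 <- extract_features(cands, lex)
  expect_identical(f1, f2)
  expect_true(all(feature_names() %in% names(f1)))
  s1 <- f1[f1$sentence_id == "SENT1" & f1$gene_mid == "T1" &
             f1$trigger_mid == "T6", ]
  expect_equal(s1$cancer_count, 1)
  expect_equal(s1$hallmark_count, 2)
  expect_equal(s1$event_depth, 2)
  expect_equal(s1$event_regulation_dist, 10)

  # minimal chain candidate: all distances finite
  fc <- extract_features(list(chain_candidate()), lex)
  expect_equal(fc$cancer_count, 1)
  expect_equal(fc$hallmark_count, 0)
  expect_lt(fc$gene_event_dist, 10)
  expect_lt(fc$event_cancer_dist, 10)
  expect_equal(nrow(extract_features(list(), lex)), 0L)
})
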