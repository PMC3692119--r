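# Synthetic labeled corpora with controllable class-conditional feature
# structure, plus the two packaged worked-example sentences.

#' Parameters for the synthetic corpus generator
#'
#' Class-conditional probabilities and distributions that drive the
#' generator. The `"paper-like"` preset emulates a manually labeled
#' gold-standard corpus of 207 positive and 356 negative candidate
#' sentences with well-separated classes: positives more often name the
#' cancer near the event, carry hallmark keywords and high classifier
#' scores; negatives more often carry purpose/negation cues and agent
#' genes. The `"uninformative"` preset makes both classes identical
#' (a null corpus).
#'
#' @param preset `"paper-like"` or `"uninformative"`.
#' @param n_pos,n_neg Class sizes.
#' @param seed Integer seed; fixes the corpus exactly.
#' @param ... Named overrides for individual parameter fields.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(preset = c("paper-like", "uninformative"),
                         n_pos = 207, n_neg = 356, seed = 7, ...) {
  preset <- match.arg(preset)
  two <- function(p, n) c(POSITIVE = p, NEGATIVE = n)
  norm1 <- function(x) x / sum(x)
  p <- list(
    preset = preset, n_pos = n_pos, n_neg = n_neg, seed = seed,
    p_cancer_sentence = two(0.88, 0.35),
    p_second_cancer = two(0.35, 0.15),
    p_hallmark = two(0.50, 0.18),
    p_second_hallmark = two(0.35, 0.25),
    p_negcue = two(0.08, 0.48),
    p_agent = two(0.12, 0.32),
    p_regulation = two(0.60, 0.30),
    p_subcellular = two(0.70, 0.30),
    dist_gene_event = list(POSITIVE = norm1(c(2.5, 2.2, 2, 1.5, 1, 0.8,
                                              0.5, 0.3)),
                           NEGATIVE = norm1(c(2, 2, 2, 1.8, 1.4, 1, 0.7,
                                              0.5))),
    dist_event_cancer = list(POSITIVE = norm1(c(3, 3, 2, 1, 0.5, 0.25,
                                                0.15, 0.1)),
                             NEGATIVE = norm1(c(0.6, 1, 1.6, 2, 2, 1.4, 0.8,
                                                0.6))),
    dist_event_regulation = list(POSITIVE = norm1(c(3, 2.5, 2, 1, 0.5,
                                                    0.25, 0.15, 0.1)),
                                 NEGATIVE = norm1(c(1.2, 1.6, 2, 2, 1.5, 1,
                                                    0.6, 0.4))),
    depth_probs = list(POSITIVE = c(0.28, 0.30, 0.25, 0.17),
                       NEGATIVE = c(0.22, 0.28, 0.28, 0.22)),
    trigger_score_range = list(POSITIVE = c(-0.5, 3.0),
                               NEGATIVE = c(-1.0, 2.5)),
    edge_score_range = list(POSITIVE = c(-0.5, 3.0),
                            NEGATIVE = c(-1.0, 2.5)),
    event_mixture = c("gene expression" = 0.25, "transcription" = 0.14,
                      "phosphorylation" = 0.17, "localization" = 0.17,
                      "regulation" = 0.05, "binding" = 0.14,
                      "protein catabolism" = 0.08),
    sentences_per_abstract = 3L)
  if (preset == "uninformative") {
    flat <- function(x) { x[] <- mean(x); x }
    for (f in c("p_cancer_sentence", "p_second_cancer", "p_hallmark",
                "p_second_hallmark", "p_negcue", "p_agent", "p_regulation",
                "p_subcellular")) p[[f]] <- flat(p[[f]])
    mid <- list(POSITIVE = norm1(rep(1, 8)), NEGATIVE = norm1(rep(1, 8)))
    p$dist_gene_event <- mid
    p$dist_event_cancer <- mid
    p$dist_event_regulation <- mid
    p$depth_probs <- list(POSITIVE = rep(0.25, 4), NEGATIVE = rep(0.25, 4))
    p$trigger_score_range <- list(POSITIVE = c(-1, 3), NEGATIVE = c(-1, 3))
    p$edge_score_range <- p$trigger_score_range
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("unknown generator parameter: ", nm)
    p[[nm]] <- over[[nm]]
  }
  stopifnot(p$n_pos + p$n_neg >= 2)
  if (length(p$event_mixture) == 0 || any(p$event_mixture < 0) ||
      sum(p$event_mixture) <= 0)
    stop("event_mixture must be a nonempty nonnegative mixture")
  p$event_mixture <- p$event_mixture / sum(p$event_mixture)
  structure(p, class = "synth_params")
}

SYNTH_GENES <- c("TP53", "EGFR", "MYC", "KRAS", "PTEN", "BRCA1", "AKT1",
                 "STAT3", "VEGFA", "CDKN2A", "RB1", "NOTCH1", "CTNNB1",
                 "SMAD4", "ERBB2", "JUN", "FOS", "MDM2", "BCL2", "CCND1")
SYNTH_FILLERS <- c("of", "the", "in", "for", "with", "cells", "protein",
                   "levels", "effect", "pathway", "samples", "lines")
SYNTH_TRIGGER_WORDS <- c("gene expression" = "expression",
                         "transcription" = "transcription",
                         "phosphorylation" = "phosphorylation",
                         "localization" = "localization",
                         "regulation" = "down-regulation",
                         "binding" = "binding",
                         "protein catabolism" = "degradation")
SYNTH_CANCER_WORDS <- c("cancer", "carcinoma", "tumor")
SYNTH_HALLMARK_WORDS <- c("growth", "proliferation", "apoptosis",
                          "invasion", "metastasis", "angiogenesis")
SYNTH_REG_WORDS <- c("induces", "inhibits", "promotes", "suppresses",
                     "mediates")
SYNTH_ROOT_VERBS <- c("showed", "revealed", "demonstrated", "suggested")

#' Generate a labeled synthetic corpus
#'
#' Builds template sentences (valid single-rooted dependency trees with
#' gene/trigger mentions, classifier scores and token-level lexicon terms)
#' whose class-conditional feature distributions follow `params`. Each
#' sentence carries one query gene and one event trigger (plus an agent
#' gene when drawn); sentences are grouped into abstracts, and every
#' abstract carries an abstract-level cancer term so that all sentences
#' are candidate evidence. Deterministic given `params$seed`.
#'
#' @param params A [synth_params()] object.
#' @return An object of class `synthetic_corpus`: a list with `docs`
#'   (list of [abstract_doc()]), `gold` (data.frame `sentence_id`,
#'   `label`), `query` (data.frame `sentence_id`, `gene_mid`,
#'   `trigger_mid` naming the intended query pair) and `params`.
#' @export
generate_corpus <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  labels <- c(rep("POSITIVE", params$n_pos), rep("NEGATIVE", params$n_neg))
  labels <- sample(labels)
  n <- length(labels)
  sents <- vector("list", n)
  gold <- data.frame(sentence_id = character(n), label = character(n),
                     stringsAsFactors = FALSE)
  query <- data.frame(sentence_id = character(n), gene_mid = character(n),
                      trigger_mid = character(n), stringsAsFactors = FALSE)
  per_ab <- max(1L, params$sentences_per_abstract)
  for (i in seq_len(n)) {
    sid <- sprintf("S%05d", i)
    aid <- sprintf("A%04d", (i - 1L) %/% per_ab + 1L)
    s <- synth_sentence(sid, aid, labels[i], params)
    sents[[i]] <- s$sentence
    gold$sentence_id[i] <- sid
    gold$label[i] <- labels[i]
    query$sentence_id[i] <- sid
    query$gene_mid[i] <- s$gene_mid
    query$trigger_mid[i] <- s$trigger_mid
  }
  ab_ids <- vapply(sents, function(s) s$abstract_id, character(1))
  docs <- lapply(split(sents, ab_ids), function(group) {
    abstract_doc(group[[1]]$abstract_id, group, cancer_terms = "cancer")
  })
  docs <- docs[order(names(docs))]
  structure(list(docs = unname(docs), gold = gold, query = query,
                 params = params),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$gold), "sentence(s) (",
      sum(x$gold$label == "POSITIVE"), "pos /",
      sum(x$gold$label == "NEGATIVE"), "neg ) in", length(x$docs),
      "abstract(s); preset", x$params$preset, "\n")
  invisible(x)
}

# One template sentence. The tree is built root-first; every chain hangs
# off the trigger or the root, so sampled path lengths are realized
# exactly.
synth_sentence <- function(sid, aid, class, p) {
  surface <- character(0); head1 <- integer(0); dep <- character(0)
  add <- function(word, parent, label = "dep") {
    surface <<- c(surface, word)
    head1 <<- c(head1, parent)        # 1-based; 0 = root
    dep <<- c(dep, label)
    length(surface)
  }
  root <- add(sample(SYNTH_ROOT_VERBS, 1), 0L, "root")

  if (stats::runif(1) < p$p_negcue[[class]]) {
    # "to determine" prefix: consecutive tokens, clause under the root
    det <- add("determine", root, "advcl")
    surface <- c(surface[seq_len(det - 1L)], "to", surface[det])
    head1 <- c(head1[seq_len(det - 1L)], det + 1L, head1[det])
    dep <- c(dep[seq_len(det - 1L)], "aux", dep[det])
    # inserting before 'determine' shifted nothing else (it was last)
  }

  event_type <- sample(names(p$event_mixture), 1, prob = p$event_mixture)
  depth <- sample(1:4, 1, prob = p$depth_probs[[class]])
  parent <- length(surface)  # placeholder; chain starts at root
  parent <- root
  if (depth > 1) for (j in seq_len(depth - 1L)) {
    parent <- add(sample(SYNTH_FILLERS, 1), parent, "prep")
  }
  trig <- add(SYNTH_TRIGGER_WORDS[[event_type]], parent, "pobj")

  d_ge <- sample(1:8, 1, prob = p$dist_gene_event[[class]])
  parent <- trig
  if (d_ge > 1) for (j in seq_len(d_ge - 1L)) {
    parent <- add(sample(SYNTH_FILLERS, 1), parent, "prep")
  }
  gene_word <- sample(SYNTH_GENES, 1)
  gene <- add(gene_word, parent, "pobj")

  cancer_tok <- NA_integer_
  if (stats::runif(1) < p$p_cancer_sentence[[class]]) {
    d_ec <- sample(1:8, 1, prob = p$dist_event_cancer[[class]])
    parent <- trig
    if (d_ec > 1) for (j in seq_len(d_ec - 1L)) {
      parent <- add(sample(SYNTH_FILLERS, 1), parent, "prep")
    }
    cancer_tok <- add(sample(SYNTH_CANCER_WORDS, 1), parent, "pobj")
    if (stats::runif(1) < p$p_second_cancer[[class]]) {
      add(sample(SYNTH_CANCER_WORDS, 1), root, "dep")
    }
  }

  if (stats::runif(1) < p$p_regulation[[class]]) {
    d_er <- sample(1:8, 1, prob = p$dist_event_regulation[[class]])
    parent <- trig
    if (d_er > 1) for (j in seq_len(d_er - 1L)) {
      parent <- add(sample(SYNTH_FILLERS, 1), parent, "prep")
    }
    add(sample(SYNTH_REG_WORDS, 1), parent, "rcmod")
  }

  if (stats::runif(1) < p$p_hallmark[[class]]) {
    add(sample(SYNTH_HALLMARK_WORDS, 1), root, "dobj")
    if (stats::runif(1) < p$p_second_hallmark[[class]]) {
      add(sample(SYNTH_HALLMARK_WORDS, 1), root, "conj")
    }
  }

  agent_tok <- NA_integer_
  if (stats::runif(1) < p$p_agent[[class]]) {
    agent_word <- sample(setdiff(SYNTH_GENES, gene_word), 1)
    agent_tok <- add(agent_word, trig, "nsubj")
  }

  if (event_type == "localization" &&
      stats::runif(1) < p$p_subcellular[[class]]) {
    add("nucleus", root, "dep")
  }
  add(".", root, "punct")

  tok <- token_frame(surface,
                     as.integer(ifelse(head1 == 0L, ROOT_SENTINEL,
                                       head1 - 1L)),
                     dep)
  tr_range <- p$trigger_score_range[[class]]
  ed_range <- p$edge_score_range[[class]]
  gene_mid <- "T1"; trig_mid <- "T2"
  mentions <- list(
    mention("T1", "GENE", gene - 1L, gene, gene_word,
            gene_id = as.character(match(gene_word, SYNTH_GENES) + 1000L)),
    mention("T2", "EVENT_TRIGGER", trig - 1L, trig,
            SYNTH_TRIGGER_WORDS[[event_type]], event_type = event_type,
            trigger_score = stats::runif(1, tr_range[1], tr_range[2]),
            edge_scores = stats::setNames(
              list(stats::runif(1, ed_range[1], ed_range[2])), "T1")))
  if (!is.na(agent_tok)) {
    aw <- surface[agent_tok]
    mentions[[3]] <- mention("T3", "GENE", agent_tok - 1L, agent_tok, aw,
                             gene_id = as.character(match(aw, SYNTH_GENES) +
                                                      1000L))
  }
  sent <- annotated_sentence(sid, aid, paste(surface, collapse = " "), tok,
                             mentions, label = class)
  list(sentence = sent, gene_mid = gene_mid, trigger_mid = trig_mid)
}

#' Extract features for a whole corpus
#'
#' Assembles candidates over all abstracts (pooled as one normalization
#' batch) and computes the feature table.
#'
#' @param docs List of [abstract_doc()]s.
#' @param lexicons A [load_lexicons()] object.
#' @param penalty Absent-term penalty (default 10).
#' @return Feature data.frame (see [extract_features()]).
#' @export
corpus_features <- function(docs, lexicons, penalty = 10) {
  cands <- unlist(lapply(docs, assemble_candidates, lexicons = lexicons),
                  recursive = FALSE)
  extract_features(cands, lexicons, penalty)
}

#' Feature table restricted to the generator's query pairs
#'
#' One row per generated sentence: the candidate formed by the intended
#' query gene and trigger (agent genes also form candidates of their own,
#' which this view excludes so that realized rates can be compared with
#' the generator parameters).
#'
#' @param corpus A [generate_corpus()] result.
#' @param lexicons A [load_lexicons()] object.
#' @param penalty Absent-term penalty (default 10).
#' @return Feature data.frame with one row per sentence.
#' @export
query_candidate_features <- function(corpus, lexicons, penalty = 10) {
  feats <- corpus_features(corpus$docs, lexicons, penalty)
  key <- paste(feats$sentence_id, feats$gene_mid, feats$trigger_mid)
  qkey <- paste(corpus$query$sentence_id, corpus$query$gene_mid,
                corpus$query$trigger_mid)
  out <- feats[key %in% qkey, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged worked-example sentences
#'
#' Two fully annotated single-sentence abstracts used throughout the
#' documentation and tests: a positive evidence sentence (SOX9
#' down-regulation reducing AR levels and growth in prostate cancer
#' cells) and a negative purpose-statement sentence (an experiment
#' down-regulating CD147). The dependency trees are hand-built,
#' linguistically plausible parses constructed to realize the documented
#' feature values of the positive example: cancer keyword count 1,
#' hallmark keyword count 2, trigger depth 2, absent regulation term
#' (penalty), and SOX9 detected as agent of the event "reduced" for query
#' gene AR.
#'
#' @return List with elements `sentence1` and `sentence2`, each an
#'   [abstract_doc()] with one labeled sentence.
#' @export
build_fixtures <- function() {
  s1_text <- paste0(
    "Significantly, down-regulation of SOX9 by siRNA in prostate cancer ",
    "cells reduced endogenous AR protein levels, and cell growth ",
    "indicating that SOX9 contributes to AR regulation and decreased ",
    "cellular proliferation.")
  s1_surface <- c("Significantly", ",", "down-regulation", "of", "SOX9",
                  "by", "siRNA", "in", "prostate", "cancer", "cells",
                  "reduced", "endogenous", "AR", "protein", "levels", ",",
                  "and", "cell", "growth", "indicating", "that", "SOX9",
                  "contributes", "to", "AR", "regulation", "and",
                  "decreased", "cellular", "proliferation", ".")
  s1_head1 <- c(12, 12, 12, 3, 4, 3, 6, 3, 11, 11, 8, 21, 16, 16, 16, 12,
                12, 16, 20, 16, 0, 24, 24, 21, 24, 27, 25, 27, 31, 31, 27,
                21)
  s1_dep <- c("advmod", "punct", "nsubj", "prep", "pobj", "prep", "pobj",
              "prep", "nn", "nn", "pobj", "advcl", "amod", "nn", "nn",
              "dobj", "punct", "cc", "nn", "conj", "root", "mark", "nsubj",
              "ccomp", "prep", "nn", "pobj", "cc", "amod", "amod", "conj",
              "punct")
  tok1 <- token_frame(s1_surface,
                      as.integer(ifelse(s1_head1 == 0, ROOT_SENTINEL,
                                        s1_head1 - 1L)), s1_dep)
  m1 <- list(
    mention("T1", "GENE", 4L, 5L, "SOX9", gene_id = "6662"),
    mention("T2", "GENE", 13L, 14L, "AR", gene_id = "367"),
    mention("T3", "GENE", 22L, 23L, "SOX9", gene_id = "6662"),
    mention("T4", "GENE", 25L, 26L, "AR", gene_id = "367"),
    mention("T5", "CANCER", 8L, 10L, "prostate cancer"),
    mention("T6", "EVENT_TRIGGER", 2L, 3L, "down-regulation",
            event_type = "Negative_regulation", trigger_score = 1.9,
            edge_scores = list(T1 = 1.4)),
    mention("T7", "EVENT_TRIGGER", 11L, 12L, "reduced",
            event_type = "Negative_regulation", trigger_score = 1.2,
            edge_scores = list(T2 = 1.1)))
  s1 <- annotated_sentence("SENT1", "FIX1", s1_text, tok1, m1,
                           label = "POSITIVE")

  s2_text <- paste0(
    "To determine the role of CD147 in the invasiveness properties of ",
    "prostate cancer, we successfully down-regulated CD147 by RNA ",
    "interference (RNAi) technology, in PC-3 cell line at high level of ",
    "CD147 expression.")
  s2_surface <- c("To", "determine", "the", "role", "of", "CD147", "in",
                  "the", "invasiveness", "properties", "of", "prostate",
                  "cancer", ",", "we", "successfully", "down-regulated",
                  "CD147", "by", "RNA", "interference", "(", "RNAi", ")",
                  "technology", ",", "in", "PC-3", "cell", "line", "at",
                  "high", "level", "of", "CD147", "expression", ".")
  s2_head1 <- c(2, 17, 4, 2, 4, 5, 4, 10, 10, 7, 10, 13, 11, 17, 17, 17, 0,
                17, 17, 21, 25, 23, 21, 23, 19, 17, 17, 30, 30, 27, 30, 33,
                31, 33, 36, 34, 17)
  s2_dep <- c("aux", "advcl", "det", "dobj", "prep", "pobj", "prep", "det",
              "nn", "pobj", "prep", "nn", "pobj", "punct", "nsubj",
              "advmod", "root", "dobj", "prep", "nn", "nn", "punct",
              "appos", "punct", "pobj", "punct", "prep", "nn", "nn",
              "pobj", "prep", "amod", "pobj", "prep", "nn", "pobj",
              "punct")
  tok2 <- token_frame(s2_surface,
                      as.integer(ifelse(s2_head1 == 0, ROOT_SENTINEL,
                                        s2_head1 - 1L)), s2_dep)
  m2 <- list(
    mention("T1", "GENE", 5L, 6L, "CD147", gene_id = "682"),
    mention("T2", "GENE", 17L, 18L, "CD147", gene_id = "682"),
    mention("T3", "GENE", 34L, 35L, "CD147", gene_id = "682"),
    mention("T4", "CANCER", 11L, 13L, "prostate cancer"),
    mention("T5", "EVENT_TRIGGER", 16L, 17L, "down-regulated",
            event_type = "Negative_regulation", trigger_score = 0.8,
            edge_scores = list(T2 = 0.9)),
    mention("T6", "EVENT_TRIGGER", 35L, 36L, "expression",
            event_type = "Gene_expression", trigger_score = 0.6,
            edge_scores = list(T3 = 0.5)))
  s2 <- annotated_sentence("SENT2", "FIX2", s2_text, tok2, m2,
                           label = "NEGATIVE")

  list(sentence1 = abstract_doc("FIX1", list(s1)),
       sentence2 = abstract_doc("FIX2", list(s2)))
}
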