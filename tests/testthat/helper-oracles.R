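# Independent oracles and small fixture builders used across the suite.

# Random single-rooted dependency tree over n tokens (0-based heads).
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  head <- integer(n)
  head[1] <- -1L
  if (n > 1) for (i in 2:n) head[i] <- sample.int(i - 1L, 1L) - 1L
  token_frame(sprintf("w%d", seq_len(n)), head)
}

# Breadth-first-search distance between two tokens on the undirected tree.
bfs_dist <- function(tokens, a, b) {
  n <- nrow(tokens)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- tokens$head[i]
    if (h >= 0) {
      adj[[i]] <- c(adj[[i]], h + 1L)
      adj[[h + 1L]] <- c(adj[[h + 1L]], i)
    }
  }
  dist <- rep(NA_integer_, n)
  dist[a + 1L] <- 0L
  frontier <- a + 1L
  while (length(frontier) > 0 && is.na(dist[b + 1L])) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  dist[b + 1L]
}

# Confusion-matrix precision/recall/F oracle (percent).
prf_oracle <- function(ranked_pos, k) {
  pred <- c(rep(TRUE, k), rep(FALSE, length(ranked_pos) - k))
  tp <- sum(pred & ranked_pos)
  fp <- sum(pred & !ranked_pos)
  fn <- sum(!pred & ranked_pos)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = 100 * p, recall = 100 * r, f_measure = 100 * f)
}

# O(n^2) pairwise AUC oracle (percent).
auc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  100 * tot / (length(sp) * length(sn))
}

# Exhaustive best-average-F sweep oracle over all attained fractions.
best_cutoff_oracle <- function(fold_pos) {
  fracs <- sort(unique(unlist(lapply(fold_pos, function(v)
    seq_along(v) / length(v)))))
  bestF <- -1; bestfrac <- NA
  for (fr in fracs) {
    fs <- vapply(fold_pos, function(v) {
      k <- min(length(v), max(1L, round(fr * length(v))))
      prf_oracle(v, k)["f_measure"]
    }, numeric(1))
    if (mean(fs) > bestF + 1e-12) { bestF <- mean(fs); bestfrac <- fr }
  }
  list(fraction = bestfrac, f_measure = bestF)
}

# A minimal hand-built candidate: chain tree GENE <- TRIGGER <- root-ish.
chain_candidate <- function() {
  # tokens: 0 showed(root) 1 expression 2 of 3 TP53 4 cancer
  tok <- token_frame(c("showed", "expression", "of", "TP53", "cancer"),
                     c(-1L, 0L, 1L, 2L, 1L))
  g <- mention("T1", "GENE", 3L, 4L, "TP53", gene_id = "7157")
  tr <- mention("T2", "EVENT_TRIGGER", 1L, 2L, "expression",
                event_type = "Gene_expression", trigger_score = 1,
                edge_scores = list(T1 = 0.5))
  s <- annotated_sentence("CH1", "CHA", "showed expression of TP53 cancer",
                          tok, list(g, tr), label = "POSITIVE")
  list(abstract_id = "CHA", sentence_id = "CH1", sentence = s, gene = g,
       trigger = tr)
}

# Small labeled feature frame with controllable separation, for model tests.
toy_features <- function(n_pos, n_neg, seed = 1, informative = TRUE) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- c(rep("POSITIVE", n_pos), rep("NEGATIVE", n_neg))
  pos <- lab == "POSITIVE"
  df <- data.frame(
    abstract_id = sprintf("A%03d", seq_len(n)),
    sentence_id = sprintf("S%03d", seq_len(n)),
    gene_mid = "T1", gene_id = as.character(seq_len(n)),
    gene_text = "G", trigger_mid = "T2", event_type = "binding",
    norm_event_score = runif(n), norm_edge_score = runif(n),
    gene_event_dist = sample(1:6, n, replace = TRUE),
    event_regulation_dist = sample(c(1:5, 10), n, replace = TRUE),
    event_cancer_dist = sample(c(1:6, 10), n, replace = TRUE),
    cancer_count = rpois(n, 1), hallmark_count = rpois(n, 0.6),
    event_depth = sample(0:4, n, replace = TRUE),
    negative_score = rpois(n, 0.4),
    agent_present = runif(n) < 0.3,
    subcellular_present = runif(n) < 0.5,
    label = lab, stringsAsFactors = FALSE)
  if (informative) {
    df$event_cancer_dist[pos] <- sample(c(1:3, 10), n_pos, replace = TRUE,
                                        prob = c(0.4, 0.3, 0.2, 0.1))
    df$event_cancer_dist[!pos] <- sample(c(3:6, 10), n_neg, replace = TRUE)
    df$negative_score[pos] <- rpois(n_pos, 0.1)
    df$negative_score[!pos] <- rpois(n_neg, 1.2)
  }
  df
}
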