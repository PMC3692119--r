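# The ten ranking features: classifier scores, dependency-tree distances,
# keyword counts, event depth, negative cues and agent detection.

#' Names of the ten ranking features
#'
#' @return Character vector with the canonical feature order.
#' @export
feature_names <- function() {
  c("norm_event_score", "norm_edge_score", "gene_event_dist",
    "event_regulation_dist", "event_cancer_dist", "cancer_count",
    "hallmark_count", "event_depth", "negative_score", "agent_present")
}

#' Dependency-path length between two tokens
#'
#' Number of edges on the unique path between tokens `a` and `b` in the
#' undirected dependency tree.
#'
#' @param tokens Token table (see [token_frame()]).
#' @param a,b 0-based token indices.
#' @return Non-negative integer path length.
#' @export
dep_path_length <- function(tokens, a, b) {
  n <- nrow(tokens)
  if (a < 0L || a >= n || b < 0L || b >= n)
    stop("token index out of range")
  if (a == b) return(0L)
  pa <- path_to_root(tokens, a)
  pb <- path_to_root(tokens, b)
  # distance = depth(a) + depth(b) - 2 * depth(lowest common ancestor)
  da <- stats::setNames(seq_along(pa) - 1L, pa)
  for (j in seq_along(pb)) {
    hit <- da[as.character(pb[j])]
    if (!is.na(hit)) return(as.integer(hit + j - 1L))
  }
  stop("tokens are not connected; invalid tree")   # unreachable on valid trees
}

# 0-based indices from token (inclusive) up to the root (inclusive).
path_to_root <- function(tokens, i) {
  path <- i
  while (tokens$head[i + 1L] != ROOT_SENTINEL) {
    i <- tokens$head[i + 1L]
    path <- c(path, i)
  }
  path
}

#' Anchor token of a mention
#'
#' The representative token of a (possibly multi-token) mention span: the
#' rightmost token in the span whose head lies outside the span (the
#' syntactic head of the span; English noun compounds are head-final).
#'
#' @param tokens Token table.
#' @param m A [mention()].
#' @return 0-based index of the anchor token.
#' @export
mention_anchor <- function(tokens, m) {
  span <- seq.int(m$start, m$end - 1L)
  heads <- tokens$head[span + 1L]
  outside <- span[heads == ROOT_SENTINEL | !(heads %in% span)]
  if (length(outside) == 0L) span[1L] else max(outside)
}

#' Depth of a trigger token below the root
#'
#' Number of edges from the dependency-tree root down to the trigger's
#' anchor token; 0 when the trigger is the root. Events governed near the
#' root tend to be the main assertion of the sentence.
#'
#' @param tokens Token table.
#' @param trigger Trigger [mention()] or a 0-based token index.
#' @return Non-negative integer depth.
#' @export
event_depth <- function(tokens, trigger) {
  idx <- if (is.list(trigger)) mention_anchor(tokens, trigger)
         else as.integer(trigger)
  length(path_to_root(tokens, idx)) - 1L
}

#' Min-max normalize a batch of raw classifier scores
#'
#' Raw trigger/edge SVM scores are comparable only within one result batch,
#' so they are rescaled to `[0, 1]` against the batch extremes. A constant
#' batch maps to 0.5 everywhere; missing scores (`NA`) map to 0.
#'
#' @param x Numeric vector of raw scores (may contain `NA`).
#' @return Numeric vector in `[0, 1]`, same order as the input.
#' @export
normalize_scores <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  out <- rep(0, length(x))
  obs <- !is.na(x)
  if (any(obs)) {
    lo <- min(x[obs]); hi <- max(x[obs])
    out[obs] <- if (hi > lo) (x[obs] - lo) / (hi - lo) else 0.5
  }
  out
}

# Token positions (0-based) whose lemma matches a single-word term, plus
# start positions of consecutive-token matches for multi-word terms.
# Returns a list of match spans (each c(start, end) half-open).
match_term_spans <- function(tokens, terms) {
  lem <- tokens$lemma
  srf <- tolower(tokens$surface)
  spans <- list()
  nw <- vapply(strsplit(terms, " ", fixed = TRUE), length, integer(1))
  singles <- terms[nw == 1L]
  multis <- terms[nw > 1L]
  multis <- multis[order(-nw[nw > 1L])]   # longest-match-first
  taken <- rep(FALSE, length(lem))
  for (term in multis) {
    words <- strsplit(term, " ", fixed = TRUE)[[1]]
    k <- length(words)
    if (length(srf) < k) next
    for (s in seq_len(length(srf) - k + 1L)) {
      span <- s:(s + k - 1L)
      if (any(taken[span])) next
      if (all(srf[span] == words)) {
        taken[span] <- TRUE
        spans[[length(spans) + 1L]] <- c(s - 1L, s + k - 1L)
      }
    }
  }
  if (length(singles) > 0) {
    for (i in which(!taken & (lem %in% singles | srf %in% singles))) {
      spans[[length(spans) + 1L]] <- c(i - 1L, i)
    }
  }
  spans
}

#' Count lexicon-term occurrences in a sentence
#'
#' Case-insensitive occurrence count: single-word terms are matched on
#' token lemmas (falling back to lowercase surface forms), multi-word terms
#' on consecutive lowercase tokens with longest-match-first, non-overlapping
#' consumption. Every occurrence counts, not just distinct terms.
#'
#' @param sentence An [annotated_sentence()] (or a bare token table).
#' @param term_set Character vector of lowercase terms.
#' @return Non-negative integer count.
#' @export
keyword_count <- function(sentence, term_set) {
  tokens <- if (is.data.frame(sentence)) sentence else sentence$tokens
  if (nrow(tokens) == 0L || length(term_set) == 0L) return(0L)
  length(match_term_spans(tokens, term_set))
}

#' Count negative cues in a sentence
#'
#' Counts occurrences of purpose/method and negation cues (e.g.
#' "to determine", "not"); multi-word cues are matched on consecutive
#' lowercase tokens. High counts mark sentences describing study aims
#' rather than results.
#'
#' @param sentence An [annotated_sentence()].
#' @param lexicons A [load_lexicons()] object.
#' @return Non-negative integer count.
#' @export
negative_cue_score <- function(sentence, lexicons) {
  keyword_count(sentence, lexicons$negative_cues)
}

#' Dependency distances among candidate terms
#'
#' Three path lengths in the dependency tree: gene-event (between the
#' candidate's gene and trigger anchors), event-regulation and event-cancer
#' (minimum over anchor positions of regulation / cancer terms in the
#' sentence). When a term kind is absent from the sentence the configured
#' penalty constant is returned instead of a distance.
#'
#' @param candidate A candidate from [assemble_candidates()].
#' @param lexicons A [load_lexicons()] object.
#' @param penalty Penalty constant used for absent terms (default 10).
#' @return Named numeric vector `gene_event_dist`, `event_regulation_dist`,
#'   `event_cancer_dist`.
#' @export
term_distances <- function(candidate, lexicons, penalty = 10) {
  s <- candidate$sentence
  tokens <- s$tokens
  ga <- mention_anchor(tokens, candidate$gene)
  ta <- mention_anchor(tokens, candidate$trigger)
  ge <- dep_path_length(tokens, ga, ta)

  min_dist_to <- function(anchors) {
    if (length(anchors) == 0L) return(penalty)
    min(vapply(anchors, function(a) dep_path_length(tokens, ta, a),
               numeric(1)))
  }
  reg_anchors <- term_anchors(s, "REGULATION_TERM", lexicons$regulation_terms)
  can_anchors <- term_anchors(s, "CANCER", lexicons$cancer_terms)
  c(gene_event_dist = ge,
    event_regulation_dist = min_dist_to(reg_anchors),
    event_cancer_dist = min_dist_to(can_anchors))
}

# Anchor positions of mentions of a given kind plus lexicon matches.
term_anchors <- function(sentence, kind, terms) {
  tokens <- sentence$tokens
  anchors <- integer(0)
  for (m in sentence$mentions) {
    if (m$kind == kind) anchors <- c(anchors, mention_anchor(tokens, m))
  }
  for (sp in match_term_spans(tokens, terms)) {
    fake <- list(start = sp[1], end = sp[2])
    anchors <- c(anchors, mention_anchor(tokens, fake))
  }
  unique(anchors)
}

#' Detect agent genes for a candidate
#'
#' An agent is a gene other than the query gene that hangs in a different
#' branch below the same event: when the trigger's anchor token is an
#' ancestor of the query gene's anchor, every other gene whose anchor lies
#' in the trigger's subtree but is reached through a different child of the
#' trigger is an agent. Agents signal gene-gene rather than gene-disease
#' assertions.
#'
#' @param candidate A candidate from [assemble_candidates()].
#' @return List of agent gene [mention()]s (possibly empty).
#' @export
detect_agents <- function(candidate) {
  s <- candidate$sentence
  tokens <- s$tokens
  ta <- mention_anchor(tokens, candidate$trigger)
  ga <- mention_anchor(tokens, candidate$gene)
  qpath <- path_to_root(tokens, ga)           # gene .. root
  pos <- match(ta, qpath)
  if (is.na(pos) || pos == 1L) return(list()) # trigger not a proper ancestor
  query_branch <- qpath[pos - 1L]             # trigger child leading to query
  agents <- list()
  for (m in s$mentions) {
    if (m$kind != "GENE" || m$id == candidate$gene$id) next
    oa <- mention_anchor(tokens, m)
    opath <- path_to_root(tokens, oa)
    opos <- match(ta, opath)
    if (is.na(opos) || opos == 1L) next       # not below the trigger
    if (opath[opos - 1L] != query_branch)
      agents[[length(agents) + 1L]] <- m
  }
  agents
}

#' Extract the ten-feature table for a candidate batch
#'
#' Computes all ten ranking features for every candidate, normalizing
#' trigger and edge scores within the batch (the batch plays the role of
#' one search-result set). The result also carries identifier columns, the
#' sentence label when present, and `subcellular_present`, used by the
#' localization post-processing step at ranking time.
#'
#' @param candidates List of candidates from [assemble_candidates()]
#'   (pooled over abstracts).
#' @param lexicons A [load_lexicons()] object.
#' @param penalty Penalty constant for absent-term distances (default 10).
#' @return data.frame with one row per candidate: id columns
#'   (`abstract_id`, `sentence_id`, `gene_mid`, `gene_id`, `gene_text`,
#'   `trigger_mid`, `event_type`), the ten feature columns of
#'   [feature_names()], `subcellular_present` and `label`.
#' @export
extract_features <- function(candidates, lexicons, penalty = 10) {
  n <- length(candidates)
  if (n == 0L) {
    return(empty_feature_frame())
  }
  raw_trig <- vapply(candidates, function(cd) cd$trigger$trigger_score,
                     numeric(1))
  raw_edge <- vapply(candidates, function(cd) {
    es <- cd$trigger$edge_scores[[cd$gene$id]]
    if (is.null(es)) NA_real_ else es
  }, numeric(1))
  nes <- normalize_scores(raw_trig)
  ned <- normalize_scores(raw_edge)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cd <- candidates[[i]]
    s <- cd$sentence
    d <- term_distances(cd, lexicons, penalty)
    rows[[i]] <- data.frame(
      abstract_id = cd$abstract_id, sentence_id = cd$sentence_id,
      gene_mid = cd$gene$id, gene_id = cd$gene$gene_id,
      gene_text = cd$gene$text, trigger_mid = cd$trigger$id,
      event_type = cd$trigger$event_type,
      norm_event_score = nes[i], norm_edge_score = ned[i],
      gene_event_dist = unname(d["gene_event_dist"]),
      event_regulation_dist = unname(d["event_regulation_dist"]),
      event_cancer_dist = unname(d["event_cancer_dist"]),
      cancer_count = keyword_count(s, lexicons$cancer_terms),
      hallmark_count = keyword_count(s, lexicons$hallmark_terms),
      event_depth = event_depth(s$tokens, cd$trigger),
      negative_score = negative_cue_score(s, lexicons),
      agent_present = length(detect_agents(cd)) > 0,
      subcellular_present =
        keyword_count(s, lexicons$subcellular_terms) > 0,
      label = s$label, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_feature_frame <- function() {
  out <- data.frame(abstract_id = character(), sentence_id = character(),
                    gene_mid = character(), gene_id = character(),
                    gene_text = character(), trigger_mid = character(),
                    event_type = character(), stringsAsFactors = FALSE)
  for (f in feature_names()) out[[f]] <- numeric()
  out$agent_present <- logical()
  out$subcellular_present <- logical()
  out$label <- character()
  out
}

#' Write a feature table to TSV
#'
#' @param features data.frame from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
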