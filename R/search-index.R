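# Miniature retrieval layer: trigger pre-screening, the two inverted
# indexes (abstract index, evidence-sentence index), triple-query
# answering and the gene co-occurrence graph.

#' Pre-screen event triggers
#'
#' Removes triggers whose lowercased text is blacklisted for their event
#' type (words that almost never signal a genuine event of that type, e.g.
#' "described" for transcription), and localization triggers anchored on
#' cytogenetic band notation (e.g. "17q21"), which name chromosomal
#' locations rather than sub-cellular localization.
#'
#' @param triggers List of EVENT_TRIGGER [mention()]s.
#' @param blacklist Named list, event type -> character vector of
#'   blacklisted lowercase words.
#' @return The surviving triggers.
#' @export
prescreen_triggers <- function(triggers, blacklist = list()) {
  keep <- vapply(triggers, function(tr) {
    txt <- tolower(tr$text)
    bl <- blacklist[[tr$event_type]]
    if (!is.null(bl) && txt %in% bl) return(FALSE)
    if (tr$event_type == "localization" && is_cytogenetic_band(txt))
      return(FALSE)
    TRUE
  }, logical(1))
  triggers[keep]
}

# Cytogenetic band notation: chromosome 1-22/X/Y, arm p/q, band digits
# with optional sub-band (e.g. 17q21, 8p11.2, Xq28).
is_cytogenetic_band <- function(x) {
  grepl("^([0-9]{1,2}|[xy])[pq][0-9]+(\\.[0-9]+)?$", x)
}

#' Load a cancer synonym table
#'
#' @param path Two-column TSV (`synonym`, `canonical`); defaults to the
#'   small packaged demo table.
#' @return Named character vector mapping lowercase synonym -> canonical
#'   cancer key.
#' @export
load_cancer_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cancer_synonyms.tsv",
                                package = "evisent", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) stop("malformed synonym line ", bad[1])
  stats::setNames(tolower(vapply(parts, `[`, character(1), 2)),
                  tolower(vapply(parts, `[`, character(1), 1)))
}

canonical_cancer_key <- function(term, synonyms) {
  term <- tolower(term)
  out <- unname(synonyms[term])
  ifelse(is.na(out), term, out)
}

# Cancer keys a candidate satisfies: canonicalized cancer mentions and
# lexicon matches in its sentence plus abstract-level terms.
candidate_cancer_keys <- function(doc, sentence, lexicons, synonyms) {
  terms <- doc$cancer_terms
  for (m in sentence$mentions) {
    if (m$kind == "CANCER") terms <- c(terms, tolower(m$text))
  }
  for (s in doc$sentences) {
    for (sp in match_term_spans(s$tokens, lexicons$cancer_terms)) {
      terms <- c(terms,
                 tolower(paste(s$tokens$surface[(sp[1] + 1L):sp[2]],
                               collapse = " ")))
    }
    for (m in s$mentions) {
      if (m$kind == "CANCER") terms <- c(terms, tolower(m$text))
    }
  }
  unique(canonical_cancer_key(terms, synonyms))
}

#' Build the inverted evidence indexes
#'
#' Constructs the two indexes used for triple queries: the evidence
#' sentence index, mapping (canonical cancer key, gene id, event type) to
#' scored candidates, and the abstract index, mapping abstract ids to
#' their candidates and maximum sentence score.
#'
#' @param docs List of [abstract_doc()]s (sentence ids must be unique
#'   across abstracts).
#' @param ranked Ranked evidence data.frame from [rank_evidence()].
#' @param lexicons A [load_lexicons()] object.
#' @param synonyms Synonym map from [load_cancer_synonyms()].
#' @return An object of class `evidence_index`.
#' @export
build_evidence_index <- function(docs, ranked, lexicons,
                                 synonyms = load_cancer_synonyms()) {
  sent_ids <- unlist(lapply(docs, function(d)
    vapply(d$sentences, function(s) s$sentence_id, character(1))))
  if (anyDuplicated(sent_ids))
    stop("duplicate sentence ids across abstracts")
  doc_by_id <- stats::setNames(docs,
                               vapply(docs, function(d) d$abstract_id,
                                      character(1)))
  sent_by_id <- list()
  for (d in docs) for (s in d$sentences) sent_by_id[[s$sentence_id]] <- s

  sentence_index <- new.env(parent = emptyenv())
  abstract_index <- new.env(parent = emptyenv())
  keys_by_row <- vector("list", nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    row <- ranked[i, ]
    doc <- doc_by_id[[row$abstract_id]]
    sent <- sent_by_id[[row$sentence_id]]
    if (is.null(doc) || is.null(sent))
      stop("ranked row ", i, " does not resolve to a stored sentence")
    ckeys <- candidate_cancer_keys(doc, sent, lexicons, synonyms)
    keys_by_row[[i]] <- ckeys
    for (ck in ckeys) {
      key <- paste(ck, row$gene_id, row$event_type, sep = "\r")
      sentence_index[[key]] <- c(sentence_index[[key]], i)
    }
    abstract_index[[row$abstract_id]] <-
      c(abstract_index[[row$abstract_id]], i)
  }
  structure(list(evidence = ranked, cancer_keys = keys_by_row,
                 sentence_index = sentence_index,
                 abstract_index = abstract_index, synonyms = synonyms,
                 docs = doc_by_id),
            class = "evidence_index")
}

#' @export
print.evidence_index <- function(x, ...) {
  cat("<evidence_index>", nrow(x$evidence), "candidate(s),",
      length(ls(x$abstract_index)), "abstract(s),",
      length(ls(x$sentence_index)), "triple key(s)\n")
  invisible(x)
}

#' Answer a (cancer, genes, events) triple query
#'
#' Returns all indexed evidence matching the canonical cancer key, any of
#' the requested gene ids (empty = all genes) and any of the requested
#' event types (empty = all seven). Abstracts are ordered by their maximum
#' sentence score (descending, ties by abstract id) and each is paired
#' with its best-scoring sentence; the full per-candidate detail is also
#' returned. An unknown cancer name yields an empty result.
#'
#' @param index An [build_evidence_index()] object.
#' @param cancer Cancer name (matched through the synonym table).
#' @param genes Optional character vector of gene ids.
#' @param events Optional character vector of event types.
#' @return List with `abstracts` (data.frame: `abstract_id`, `max_score`,
#'   `best_sentence_id`, `best_text`) and `hits` (ranked candidate
#'   data.frame).
#' @export
query_evidence <- function(index, cancer, genes = character(),
                           events = character()) {
  ck <- canonical_cancer_key(cancer, index$synonyms)
  if (length(events) == 0) events <- event_types()
  events <- vapply(events, merge_event_types, character(1))
  if (length(genes) == 0) {
    match_rows <- which(vapply(index$cancer_keys, function(k) ck %in% k,
                               logical(1)))
    match_rows <- match_rows[index$evidence$event_type[match_rows] %in%
                               events]
  } else {
    match_rows <- integer(0)
    for (g in genes) for (et in events) {
      key <- paste(ck, g, et, sep = "\r")
      match_rows <- c(match_rows, index$sentence_index[[key]])
    }
    match_rows <- sort(unique(match_rows))
  }
  hits <- index$evidence[match_rows, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(abstracts = data.frame(abstract_id = character(),
                                       max_score = numeric(),
                                       best_sentence_id = character(),
                                       best_text = character(),
                                       stringsAsFactors = FALSE),
                hits = hits))
  }
  hits <- hits[order(-hits$score, hits$abstract_id, hits$sentence_id,
                     hits$gene_id, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  first <- !duplicated(hits$abstract_id)
  abstracts <- data.frame(abstract_id = hits$abstract_id[first],
                          max_score = hits$score[first],
                          best_sentence_id = hits$sentence_id[first],
                          stringsAsFactors = FALSE)
  abstracts$best_text <- vapply(seq_len(nrow(abstracts)), function(i) {
    d <- index$docs[[abstracts$abstract_id[i]]]
    for (s in d$sentences) {
      if (s$sentence_id == abstracts$best_sentence_id[i]) return(s$text)
    }
    NA_character_
  }, character(1))
  abstracts <- abstracts[order(-abstracts$max_score, abstracts$abstract_id,
                               method = "radix"), , drop = FALSE]
  rownames(abstracts) <- NULL
  list(abstracts = abstracts, hits = hits)
}

#' Gene co-occurrence graph of a query result
#'
#' Nodes are the `top_n` genes by maximum evidence score in the result;
#' two genes are connected when they share at least one abstract, and each
#' edge records the shared abstracts.
#'
#' @param result A [query_evidence()] result.
#' @param top_n Maximum number of gene nodes (default 25).
#' @return An `igraph` graph with vertex attribute `max_score` and edge
#'   attributes `n_shared` and `abstracts` (comma-separated ids).
#' @export
cooccurrence_graph <- function(result, top_n = 25) {
  stopifnot(top_n >= 1)
  hits <- result$hits
  if (nrow(hits) == 0) return(igraph::make_empty_graph(directed = FALSE))
  gene_max <- tapply(hits$score, hits$gene_id, max)
  genes <- names(sort(gene_max, decreasing = TRUE))
  genes <- genes[seq_len(min(top_n, length(genes)))]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(genes, max_score = as.numeric(gene_max[genes]))
  abst_by_gene <- lapply(genes, function(gid)
    unique(hits$abstract_id[hits$gene_id == gid]))
  names(abst_by_gene) <- genes
  if (length(genes) >= 2) {
    for (i in seq_len(length(genes) - 1L)) for (j in (i + 1L):length(genes)) {
      shared <- intersect(abst_by_gene[[i]], abst_by_gene[[j]])
      if (length(shared) > 0) {
        g <- igraph::add_edges(g, c(genes[i], genes[j]),
                               n_shared = length(shared),
                               abstracts = paste(shared, collapse = ","))
      }
    }
  }
  g
}

#' Export a co-occurrence graph
#'
#' Writes the edge list as TSV and, optionally, the full graph as GraphML.
#'
#' @param graph Graph from [cooccurrence_graph()].
#' @param edge_tsv Path for the edge-list TSV.
#' @param graphml Optional path for a GraphML export.
#' @return `edge_tsv`, invisibly.
#' @export
export_cooc_graph <- function(graph, edge_tsv, graphml = NULL) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   n_shared = igraph::E(graph)$n_shared %||% integer(0),
                   abstracts = igraph::E(graph)$abstracts %||% character(0),
                   stringsAsFactors = FALSE)
  utils::write.table(df, edge_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(graph, graphml, format = "graphml")
  invisible(edge_tsv)
}
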