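# Domain types and readers: annotated sentences, abstracts, lexicons,
# standoff/CoNLL parsing, and candidate assembly.

ROOT_SENTINEL <- -1L

#' Supported biological event types
#'
#' The seven event types served by the ranker. Positive and negative
#' regulation from upstream event extraction are merged into a single
#' `regulation` type because event polarity does not determine the polarity
#' of the gene-disease relation.
#'
#' @return Character vector of the seven canonical event types.
#' @export
event_types <- function() {
  c("gene expression", "transcription", "phosphorylation", "localization",
    "regulation", "binding", "protein catabolism")
}

# Raw trigger labels accepted from upstream event extraction (nine types).
raw_event_types <- function() {
  c("Gene_expression", "Transcription", "Phosphorylation", "Localization",
    "Regulation", "Binding", "Protein_catabolism",
    "Positive_regulation", "Negative_regulation")
}

#' Map a raw event-extraction type to a canonical event type
#'
#' `Positive_regulation` and `Negative_regulation` are both mapped to
#' `regulation`; the remaining seven types map to their lowercase,
#' space-separated canonical names. Canonical names are accepted and
#' returned unchanged.
#'
#' @param raw_type Character scalar, one of the nine raw types (or an
#'   already-canonical type).
#' @return One of [event_types()].
#' @export
merge_event_types <- function(raw_type) {
  stopifnot(is.character(raw_type), length(raw_type) == 1L)
  if (raw_type %in% event_types()) return(raw_type)
  canon <- tolower(gsub("_", " ", raw_type))
  canon <- sub("^(positive|negative) regulation$", "regulation", canon)
  if (!canon %in% event_types()) {
    stop("unknown event type '", raw_type, "'; allowed raw types: ",
         paste(raw_event_types(), collapse = ", "))
  }
  canon
}

#' Construct a token table
#'
#' Tokens of one sentence with their dependency heads. Heads are 0-based
#' token indices; the single root token has head `-1`.
#'
#' @param surface Character vector of token surface forms.
#' @param head Integer vector of 0-based head indices (`-1` for the root).
#' @param deplabel Character vector of dependency labels.
#' @param lemma Optional character vector of lemmas; defaults to the
#'   lowercased surface forms.
#' @return A `data.frame` with columns `index`, `surface`, `lemma`, `head`,
#'   `deplabel`, validated to form a single-rooted tree.
#' @export
token_frame <- function(surface, head, deplabel = rep("dep", length(surface)),
                        lemma = tolower(surface)) {
  n <- length(surface)
  stopifnot(length(head) == n, length(deplabel) == n, length(lemma) == n)
  tok <- data.frame(index = seq_len(n) - 1L, surface = as.character(surface),
                    lemma = as.character(lemma), head = as.integer(head),
                    deplabel = as.character(deplabel),
                    stringsAsFactors = FALSE)
  validate_tree(tok)
  tok
}

validate_tree <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0L) return(invisible(tokens))   # empty sentence: nothing to check
  h <- tokens$head
  roots <- which(h == ROOT_SENTINEL)
  if (length(roots) != 1L)
    stop("invalid dependency tree: expected exactly one root, found ",
         length(roots))
  if (any(h[-roots] < 0L | h[-roots] >= n))
    stop("invalid dependency tree: head index out of range")
  # walk to root from every token; a cycle never reaches the sentinel
  for (i in seq_len(n)) {
    cur <- i
    steps <- 0L
    while (tokens$head[cur] != ROOT_SENTINEL) {
      cur <- tokens$head[cur] + 1L
      steps <- steps + 1L
      if (steps > n) stop("invalid dependency tree: head cycle detected")
    }
  }
  invisible(tokens)
}

#' Construct an annotated sentence
#'
#' @param sentence_id Unique sentence identifier.
#' @param abstract_id Identifier of the containing abstract.
#' @param text Sentence text.
#' @param tokens Token table from [token_frame()] or [parse_dependencies()].
#' @param mentions List of mentions (see [mention()]).
#' @param label Optional gold label, `"POSITIVE"` or `"NEGATIVE"`.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(sentence_id, abstract_id, text, tokens,
                               mentions = list(), label = NA_character_) {
  if (!is.na(label) && !label %in% c("POSITIVE", "NEGATIVE"))
    stop("label must be POSITIVE, NEGATIVE or NA")
  n <- nrow(tokens)
  for (m in mentions) {
    if (m$start < 0L || m$end > n || m$start >= m$end)
      stop("mention span [", m$start, ",", m$end, ") outside token range")
  }
  structure(list(sentence_id = as.character(sentence_id),
                 abstract_id = as.character(abstract_id),
                 text = as.character(text), tokens = tokens,
                 mentions = mentions, label = label),
            class = "annotated_sentence")
}

#' Construct a mention
#'
#' A typed span over sentence tokens: a gene, an event trigger, a cancer
#' term or a regulation term. Event triggers carry an event type, an
#' optional raw classifier (trigger) score and optional per-theme edge
#' scores keyed by gene mention id.
#'
#' @param id Mention identifier, unique within the sentence (e.g. `"T1"`).
#' @param kind One of `GENE`, `EVENT_TRIGGER`, `CANCER`, `REGULATION_TERM`.
#' @param start,end Half-open 0-based token span.
#' @param text Mention surface text.
#' @param gene_id Optional Entrez gene identifier (genes only).
#' @param event_type Canonical event type (triggers only).
#' @param trigger_score Optional raw trigger classifier score.
#' @param edge_scores Optional named list, gene mention id -> raw edge score.
#' @return A `mention` list object.
#' @export
mention <- function(id, kind, start, end, text, gene_id = NA_character_,
                    event_type = NA_character_, trigger_score = NA_real_,
                    edge_scores = list()) {
  kinds <- c("GENE", "EVENT_TRIGGER", "CANCER", "REGULATION_TERM")
  if (!kind %in% kinds)
    stop("unknown mention kind '", kind, "'")
  if (kind == "EVENT_TRIGGER") {
    if (is.na(event_type)) stop("event triggers require an event_type")
    event_type <- merge_event_types(event_type)
  } else if (!is.na(event_type)) {
    stop("event_type is only valid for EVENT_TRIGGER mentions")
  }
  structure(list(id = as.character(id), kind = kind,
                 start = as.integer(start), end = as.integer(end),
                 text = as.character(text), gene_id = as.character(gene_id),
                 event_type = event_type,
                 trigger_score = as.numeric(trigger_score),
                 edge_scores = edge_scores),
            class = "mention")
}

#' Construct an abstract document
#'
#' @param abstract_id PMID-like identifier.
#' @param sentences List of [annotated_sentence()] objects; sentence ids
#'   must be unique within the abstract.
#' @param cancer_terms Character vector of cancer lexicon terms matched
#'   anywhere in the abstract (sentence-external evidence of disease
#'   context).
#' @return An object of class `abstract_doc`.
#' @export
abstract_doc <- function(abstract_id, sentences, cancer_terms = character()) {
  ids <- vapply(sentences, function(s) s$sentence_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sentence ids within abstract")
  structure(list(abstract_id = as.character(abstract_id),
                 sentences = sentences,
                 cancer_terms = unique(tolower(cancer_terms))),
            class = "abstract_doc")
}

#' @export
print.abstract_doc <- function(x, ...) {
  cat("<abstract_doc>", x$abstract_id, "-", length(x$sentences),
      "sentence(s)\n")
  invisible(x)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence>", x$sentence_id, "[", x$label, "]\n  ",
      substr(x$text, 1, 70), "\n  ", nrow(x$tokens), "tokens,",
      length(x$mentions), "mention(s)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Lexicons

#' Load scoring lexicons
#'
#' Reads the plain-text lexicons used by the feature extractors (one entry
#' per line, `#` comments allowed; entries are lowercased and
#' deduplicated). Any lexicon without an override path falls back to the
#' packaged default: 12 cancer terms, the 6 hallmark keywords, negation and
#' purpose-phrase cues, regulation connectives, sub-cellular compartments
#' and the per-event trigger blacklist.
#'
#' @param cancer,hallmark,negative,regulation,subcellular Optional file
#'   paths overriding the packaged term lists.
#' @param trigger_blacklist Optional path to a two-column TSV
#'   (`event_type`, `word`).
#' @return An object of class `lexicons` with fields `cancer_terms`,
#'   `hallmark_terms`, `negative_cues`, `regulation_terms`,
#'   `subcellular_terms` and `trigger_blacklist` (named list by event type).
#' @export
load_lexicons <- function(cancer = NULL, hallmark = NULL, negative = NULL,
                          regulation = NULL, subcellular = NULL,
                          trigger_blacklist = NULL) {
  pkg_lex <- function(name) {
    system.file("extdata", "lexicons", name, package = "evisent",
                mustWork = TRUE)
  }
  read_terms <- function(path, what) {
    if (!file.exists(path)) stop("cannot read ", what, " lexicon: ", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    unique(tolower(lines[nzchar(lines)]))
  }
  bl_path <- if (is.null(trigger_blacklist)) pkg_lex("trigger_blacklist.tsv")
             else trigger_blacklist
  if (!file.exists(bl_path))
    stop("cannot read trigger_blacklist lexicon: ", bl_path)
  bl_lines <- readLines(bl_path, encoding = "UTF-8", warn = FALSE)
  bl_lines <- trimws(sub("#.*$", "", bl_lines))
  bl_lines <- bl_lines[nzchar(bl_lines)]
  bl <- list()
  for (ln in bl_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed trigger blacklist line: ", ln)
    et <- merge_event_types(trimws(parts[1]))
    bl[[et]] <- unique(c(bl[[et]], tolower(trimws(parts[2]))))
  }
  structure(list(
    cancer_terms = read_terms(cancer %||% pkg_lex("cancer_terms.txt"),
                              "cancer"),
    hallmark_terms = read_terms(hallmark %||% pkg_lex("hallmark_terms.txt"),
                                "hallmark"),
    negative_cues = read_terms(negative %||% pkg_lex("negative_cues.txt"),
                               "negative"),
    regulation_terms = read_terms(regulation %||%
                                    pkg_lex("regulation_terms.txt"),
                                  "regulation"),
    subcellular_terms = read_terms(subcellular %||%
                                     pkg_lex("subcellular_terms.txt"),
                                   "subcellular"),
    trigger_blacklist = bl), class = "lexicons")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# CoNLL dependency parsing

#' Parse CoNLL dependency columns into token tables
#'
#' Accepts CoNLL-X / CoNLL-U style rows (ID FORM LEMMA ... HEAD DEPREL in
#' columns 1, 2, 3, 7, 8) or a minimal four-column dialect
#' (ID FORM HEAD DEPREL). Sentence blocks are separated by blank lines;
#' 1-based heads are converted to 0-based with `-1` marking the root.
#'
#' @param conll_text Character scalar (possibly multi-line) or character
#'   vector of lines.
#' @return A list of token tables (one per sentence block), each satisfying
#'   the single-root acyclic tree invariants.
#' @export
parse_dependencies <- function(conll_text) {
  lines <- if (length(conll_text) == 1L)
    strsplit(conll_text, "\n", fixed = TRUE)[[1]] else conll_text
  lines <- sub("\r$", "", lines)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- blocks[lengths(blocks) > 0]
  lapply(unname(blocks), parse_conll_block)
}

parse_conll_block <- function(block) {
  rows <- lapply(block, function(ln) strsplit(trimws(ln), "[ \t]+")[[1]])
  nc <- vapply(rows, length, integer(1))
  if (any(nc < 4L)) stop("CoNLL row with fewer than 4 columns")
  surface <- character(0); lemma <- character(0)
  head1 <- integer(0); dep <- character(0)
  for (r in rows) {
    if (length(r) >= 8L) {         # CoNLL-X / CoNLL-U
      surface <- c(surface, r[2]); lemma <- c(lemma, tolower(r[3]))
      head1 <- c(head1, suppressWarnings(as.integer(r[7])))
      dep <- c(dep, r[8])
    } else {                       # minimal: ID FORM HEAD DEPREL
      surface <- c(surface, r[2]); lemma <- c(lemma, tolower(r[2]))
      head1 <- c(head1, suppressWarnings(as.integer(r[3])))
      dep <- c(dep, r[4])
    }
  }
  if (anyNA(head1)) stop("non-integer head in CoNLL block")
  n <- length(surface)
  if (any(head1 < 0L | head1 > n)) stop("head index out of range in CoNLL block")
  head0 <- ifelse(head1 == 0L, ROOT_SENTINEL, head1 - 1L)
  token_frame(surface, as.integer(head0), dep, lemma)
}

# ---------------------------------------------------------------------------
# Standoff annotation parsing

#' Attach standoff annotations to a sentence
#'
#' Parses BioNLP shared-task style standoff lines with sentence-local,
#' 0-based, half-open character offsets. Entity lines
#' (`T1<TAB>Protein 24 28<TAB>SOX9`) accept the kinds `Protein`/`Gene`
#' (gene), `Cancer`/`Disease` (cancer term), `Regulation_term`, or a raw
#' event-trigger type (e.g. `Negative_regulation`). Event lines
#' (`E1<TAB>Negative_regulation:T2 Theme:T1`) bind a trigger to its theme
#' genes. Optional attribute lines carry classifier confidences:
#' `A1<TAB>Score T2 1.3` (trigger score) and
#' `A2<TAB>EdgeScore E1 T1 0.7` (edge score for one theme).
#'
#' A mention's token span covers every token its character span overlaps.
#'
#' @param entity_lines Character scalar/vector of `T` lines (may be empty).
#' @param event_lines Character scalar/vector of `E`/`A` lines (may be
#'   empty).
#' @param sentence An [annotated_sentence()] with tokens populated.
#' @return The sentence with `mentions` attached.
#' @export
parse_standoff <- function(entity_lines, event_lines = character(),
                           sentence) {
  split_lines <- function(x) {
    if (length(x) == 1L) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
    x[nzchar(trimws(x))]
  }
  raw_evs <- split_lines(event_lines)
  # trigger T lines live in the .a2 file alongside E lines
  ents <- c(split_lines(entity_lines),
            raw_evs[startsWith(raw_evs, "T")])
  evs <- raw_evs[!startsWith(raw_evs, "T")]
  char_starts <- token_char_offsets(sentence)

  mentions <- list()
  for (i in seq_along(ents)) {
    parts <- strsplit(ents[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed annotation at entity line ", i, ": ", ents[i])
    mid <- parts[1]
    mid_fields <- strsplit(trimws(parts[2]), " +")[[1]]
    if (length(mid_fields) != 3L)
      stop("malformed annotation at entity line ", i, ": ", ents[i])
    kind_raw <- mid_fields[1]
    cs <- suppressWarnings(as.integer(mid_fields[2]))
    ce <- suppressWarnings(as.integer(mid_fields[3]))
    if (is.na(cs) || is.na(ce) || cs < 0L || ce > nchar(sentence$text) ||
        cs >= ce)
      stop("malformed annotation at entity line ", i,
           ": character offsets outside sentence")
    span <- char_span_to_token_span(char_starts, sentence$tokens$surface,
                                    cs, ce)
    if (is.null(span))
      stop("malformed annotation at entity line ", i,
           ": span covers no token")
    m <- if (kind_raw %in% c("Protein", "Gene")) {
      mention(mid, "GENE", span[1], span[2], parts[3])
    } else if (kind_raw %in% c("Cancer", "Disease")) {
      mention(mid, "CANCER", span[1], span[2], parts[3])
    } else if (kind_raw == "Regulation_term") {
      mention(mid, "REGULATION_TERM", span[1], span[2], parts[3])
    } else if (kind_raw %in% c(raw_event_types(), event_types())) {
      mention(mid, "EVENT_TRIGGER", span[1], span[2], parts[3],
              event_type = merge_event_types(kind_raw))
    } else {
      stop("malformed annotation at entity line ", i, ": unknown kind '",
           kind_raw, "' (allowed: Protein, Gene, Cancer, Disease, ",
           "Regulation_term, or an event type among ",
           paste(raw_event_types(), collapse = ", "), ")")
    }
    mentions[[mid]] <- m
  }

  # E lines bind triggers to themes; A lines attach scores.
  event_theme <- list()   # event id -> list(trigger = Tid, themes = Tids)
  for (i in seq_along(evs)) {
    parts <- strsplit(evs[i], "\t", fixed = TRUE)[[1]]
    tag <- parts[1]
    if (startsWith(tag, "E")) {
      if (length(parts) < 2L)
        stop("malformed annotation at event line ", i, ": ", evs[i])
      fields <- strsplit(trimws(parts[2]), " +")[[1]]
      tr <- strsplit(fields[1], ":", fixed = TRUE)[[1]]
      if (length(tr) != 2L || is.null(mentions[[tr[2]]]))
        stop("malformed annotation at event line ", i,
             ": unresolved trigger reference")
      themes <- character(0)
      for (f in fields[-1]) {
        kv <- strsplit(f, ":", fixed = TRUE)[[1]]
        if (length(kv) == 2L && grepl("^Theme", kv[1])) {
          if (is.null(mentions[[kv[2]]]))
            stop("malformed annotation at event line ", i,
                 ": unresolved theme reference ", kv[2])
          themes <- c(themes, kv[2])
        }
      }
      event_theme[[tag]] <- list(trigger = tr[2], themes = themes)
    } else if (startsWith(tag, "A")) {
      fields <- strsplit(trimws(parts[2]), " +")[[1]]
      if (fields[1] == "Score" && length(fields) == 3L) {
        tid <- fields[2]
        if (is.null(mentions[[tid]]))
          stop("malformed annotation at attribute line ", i,
               ": unknown mention ", tid)
        mentions[[tid]]$trigger_score <- as.numeric(fields[3])
      } else if (fields[1] == "EdgeScore" && length(fields) == 4L) {
        eid <- fields[2]
        ev <- event_theme[[eid]]
        if (is.null(ev))
          stop("malformed annotation at attribute line ", i,
               ": unknown event ", eid)
        mentions[[ev$trigger]]$edge_scores[[fields[3]]] <-
          as.numeric(fields[4])
      } else if (fields[1] == "GeneId" && length(fields) == 3L) {
        mentions[[fields[2]]]$gene_id <- fields[3]
      } else {
        stop("malformed annotation at attribute line ", i, ": ", evs[i])
      }
    }
  }
  sentence$mentions <- unname(mentions)
  validate_sentence_mentions(sentence)
  sentence
}

# Character start offset of each token within the sentence text, located by
# sequential search so repeated tokens resolve left to right.
token_char_offsets <- function(sentence) {
  text <- sentence$text
  toks <- sentence$tokens$surface
  starts <- integer(length(toks))
  pos <- 1L
  for (i in seq_along(toks)) {
    hit <- regexpr(toks[i], substr(text, pos, nchar(text)), fixed = TRUE)
    if (hit == -1L)
      stop("token '", toks[i], "' not found in sentence text")
    starts[i] <- pos + as.integer(hit) - 2L   # 0-based
    pos <- starts[i] + nchar(toks[i]) + 1L
  }
  starts
}

char_span_to_token_span <- function(starts, surfaces, cs, ce) {
  ends <- starts + nchar(surfaces)   # half-open char ends
  overlap <- which(starts < ce & ends > cs)
  if (length(overlap) == 0L) return(NULL)
  c(min(overlap) - 1L, max(overlap))   # 0-based half-open token span
}

validate_sentence_mentions <- function(sentence) {
  gene_ids <- vapply(Filter(function(m) m$kind == "GENE", sentence$mentions),
                     function(m) m$id, character(1))
  for (m in sentence$mentions) {
    if (m$kind == "EVENT_TRIGGER" && length(m$edge_scores) > 0) {
      bad <- setdiff(names(m$edge_scores), gene_ids)
      if (length(bad) > 0)
        stop("edge score refers to non-gene mention(s): ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(sentence)
}

# ---------------------------------------------------------------------------
# Candidate assembly

#' Assemble candidate evidence sentences
#'
#' A candidate is one (gene mention, event trigger) pair from a sentence
#' containing at least one gene and at least one surviving event trigger,
#' in an abstract where a cancer term occurs in the sentence itself or
#' anywhere else in the abstract. Blacklisted triggers and cytogenetic-band
#' localization triggers are removed first (see [prescreen_triggers()]).
#'
#' @param abstract An [abstract_doc()].
#' @param lexicons A [load_lexicons()] object.
#' @return A list of candidates; each candidate is a list with fields
#'   `abstract_id`, `sentence_id`, `sentence`, `gene`, `trigger`.
#' @export
assemble_candidates <- function(abstract, lexicons) {
  cancer_in_abstract <- length(abstract$cancer_terms) > 0 ||
    any(vapply(abstract$sentences, sentence_has_cancer_term,
               logical(1), lexicons = lexicons))
  out <- list()
  for (s in abstract$sentences) {
    if (!cancer_in_abstract && !sentence_has_cancer_term(s, lexicons)) next
    genes <- Filter(function(m) m$kind == "GENE", s$mentions)
    trigs <- Filter(function(m) m$kind == "EVENT_TRIGGER", s$mentions)
    trigs <- prescreen_triggers(trigs, lexicons$trigger_blacklist)
    if (length(genes) == 0 || length(trigs) == 0) next
    for (g in genes) for (tr in trigs) {
      out[[length(out) + 1L]] <- list(abstract_id = abstract$abstract_id,
                                      sentence_id = s$sentence_id,
                                      sentence = s, gene = g, trigger = tr)
    }
  }
  out
}

sentence_has_cancer_term <- function(sentence, lexicons) {
  any(vapply(sentence$mentions, function(m) m$kind == "CANCER",
             logical(1))) ||
    keyword_count(sentence, lexicons$cancer_terms) > 0
}

# ---------------------------------------------------------------------------
# Document format (JSON lines, one abstract per line) and gold labels

#' Write a corpus to the package document format
#'
#' One abstract per line as JSON, bundling text, tokens, parses, mentions,
#' classifier scores and labels, so a corpus round-trips without external
#' NLP tools.
#'
#' @param docs List of [abstract_doc()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in docs) {
    writeLines(jsonlite::toJSON(doc_to_list(d), auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null"),
               con)
  }
  invisible(path)
}

#' Read a corpus from the package document format
#'
#' @param path File written by [write_corpus()].
#' @return List of [abstract_doc()] objects.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln)
    doc_from_list(jsonlite::fromJSON(ln, simplifyVector = FALSE)))
}

doc_to_list <- function(d) {
  list(abstract_id = d$abstract_id, cancer_terms = as.list(d$cancer_terms),
       sentences = lapply(d$sentences, function(s) {
         list(sentence_id = s$sentence_id, text = s$text,
              label = if (is.na(s$label)) NULL else s$label,
              tokens = list(surface = as.list(s$tokens$surface),
                            lemma = as.list(s$tokens$lemma),
                            head = as.list(s$tokens$head),
                            deplabel = as.list(s$tokens$deplabel)),
              mentions = lapply(s$mentions, function(m) {
                out <- list(id = m$id, kind = m$kind, start = m$start,
                            end = m$end, text = m$text)
                if (!is.na(m$gene_id)) out$gene_id <- m$gene_id
                if (!is.na(m$event_type)) out$event_type <- m$event_type
                if (!is.na(m$trigger_score))
                  out$trigger_score <- m$trigger_score
                if (length(m$edge_scores) > 0)
                  out$edge_scores <- m$edge_scores
                out
              }))
       }))
}

doc_from_list <- function(x) {
  sentences <- lapply(x$sentences, function(s) {
    tok <- token_frame(unlist(s$tokens$surface),
                       as.integer(unlist(s$tokens$head)),
                       unlist(s$tokens$deplabel), unlist(s$tokens$lemma))
    mentions <- lapply(s$mentions, function(m) {
      mention(m$id, m$kind, m$start, m$end, m$text,
              gene_id = m$gene_id %||% NA_character_,
              event_type = m$event_type %||% NA_character_,
              trigger_score = m$trigger_score %||% NA_real_,
              edge_scores = lapply(m$edge_scores %||% list(), as.numeric))
    })
    annotated_sentence(s$sentence_id, x$abstract_id, s$text, tok, mentions,
                       label = s$label %||% NA_character_)
  })
  abstract_doc(x$abstract_id, sentences,
               unlist(x$cancer_terms) %||% character())
}

#' Read a gold-standard label file
#'
#' @param path TSV with columns `sentence_id` and `label`
#'   (POSITIVE/NEGATIVE); a header row is detected and skipped.
#' @return data.frame with columns `sentence_id`, `label`.
#' @export
read_gold_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("gold label file needs two columns")
  tab <- tab[, 1:2]
  names(tab) <- c("sentence_id", "label")
  if (tolower(tab$label[1]) == "label") tab <- tab[-1, , drop = FALSE]
  tab$label <- toupper(tab$label)
  bad <- setdiff(unique(tab$label), c("POSITIVE", "NEGATIVE"))
  if (length(bad) > 0)
    stop("unknown labels in gold file: ", paste(bad, collapse = ", "))
  tab$sentence_id <- as.character(tab$sentence_id)
  rownames(tab) <- NULL
  tab
}

#' Apply gold labels to a corpus
#'
#' @param docs List of [abstract_doc()] objects.
#' @param gold data.frame from [read_gold_labels()].
#' @return The corpus with sentence labels set where a gold row matches.
#' @export
apply_gold_labels <- function(docs, gold) {
  lab <- stats::setNames(gold$label, gold$sentence_id)
  lapply(docs, function(d) {
    d$sentences <- lapply(d$sentences, function(s) {
      if (!is.na(lab[s$sentence_id])) s$label <- unname(lab[s$sentence_id])
      s
    })
    d
  })
}
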