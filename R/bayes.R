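# Semi-naive Bayes likelihood-ratio ranker: binned class-conditional
# tables for the ten features, two explicit feature dependencies
# (cancer-keyword count | event-cancer distance; agent | hallmark
# presence), sigmoid score conversion and localization post-processing.

CLASSES <- c("POSITIVE", "NEGATIVE")

# Feature typing drives the binning scheme.
feature_types <- function() {
  c(norm_event_score = "score", norm_edge_score = "score",
    gene_event_dist = "distance", event_regulation_dist = "distance",
    event_cancer_dist = "distance", cancer_count = "count",
    hallmark_count = "count", event_depth = "count",
    negative_score = "count", agent_present = "bool")
}

# Equal-frequency quartile cut points over the "ordinary" values of a
# feature; penalty and zero values are kept out and get dedicated bins.
fit_bin_spec <- function(x, type, penalty) {
  if (type == "bool") {
    return(list(type = type, edges = numeric(0),
                labels = c("FALSE", "TRUE")))
  }
  ordinary <- x[!is.na(x) & x != 0]
  has_pen <- FALSE
  if (type == "distance") {
    has_pen <- TRUE
    ordinary <- ordinary[ordinary != penalty]
  }
  edges <- numeric(0)
  if (length(ordinary) > 0) {
    edges <- unique(unname(stats::quantile(ordinary, c(0.25, 0.5, 0.75),
                                           type = 7)))
  }
  labels <- c(if (has_pen) "PEN", "Z",
              paste0("B", seq_len(length(edges) + 1L)))
  list(type = type, edges = edges, labels = labels)
}

assign_bins <- function(x, spec, penalty) {
  if (spec$type == "bool") return(ifelse(as.logical(x), "TRUE", "FALSE"))
  out <- character(length(x))
  is_pen <- spec$type == "distance" & x == penalty
  out[is_pen] <- "PEN"
  out[!is_pen & x == 0] <- "Z"
  ord <- !is_pen & x != 0
  if (any(ord)) {
    idx <- findInterval(x[ord], spec$edges, rightmost.closed = FALSE) + 1L
    out[ord] <- paste0("B", idx)
  }
  out
}

smoothed_table <- function(bins, labels, classes, alpha) {
  # P(bin | class) with add-alpha smoothing over the fixed label set
  tab <- matrix(alpha, nrow = length(labels), ncol = 2,
                dimnames = list(labels, CLASSES))
  counts <- table(factor(bins, levels = labels),
                  factor(classes, levels = CLASSES))
  tab <- tab + counts
  sweep(tab, 2, colSums(tab), "/")
}

# Coarse conditioning bins for the event-cancer distance: the dependency
# is motivated by whether the cancer name co-occurs near the event.
cancer_dist_zone <- function(x, penalty) {
  ifelse(x == penalty, "absent", ifelse(x < 4, "near", "far"))
}

#' Fit the evidence-sentence likelihood-ratio model
#'
#' Bins every feature (equal-frequency quartiles over pooled values, with
#' dedicated bins for zero and for the absent-term penalty), then estimates
#' add-alpha-smoothed class-conditional probability tables per feature.
#' Two dependencies replace the corresponding marginals when
#' `use_dependencies = TRUE`: the cancer-keyword count is conditioned on a
#' coarse event-cancer-distance zone (near < 4 edges, far, absent), and
#' agent presence is conditioned on hallmark presence. Class priors are
#' taken equal, so the ranking score is a pure likelihood ratio.
#'
#' @param features data.frame from [extract_features()] with a `label`
#'   column (or labels supplied separately).
#' @param labels Optional character vector of POSITIVE/NEGATIVE labels.
#' @param alpha Additive smoothing pseudo-count (default 1).
#' @param use_dependencies Use the two feature dependencies (default TRUE);
#'   with FALSE the model is plain naive Bayes over the ten features.
#' @param penalty Penalty constant matching the extraction step.
#' @param sigmoid_slope Slope of the score sigmoid (default 1).
#' @param localization_factor Multiplicative demotion in (0, 1] applied to
#'   localization evidence lacking sub-cellular terms (default 0.5).
#' @param feature_subset Optional subset of [feature_names()] to model
#'   (used for ablation studies); dependent features keep their
#'   conditioning variable.
#' @return An object of class `evidence_model`.
#' @export
fit_evidence_model <- function(features, labels = features$label, alpha = 1,
                               use_dependencies = TRUE, penalty = 10,
                               sigmoid_slope = 1, localization_factor = 0.5,
                               feature_subset = NULL) {
  if (nrow(features) == 0L) stop("cannot fit on an empty feature table")
  labels <- as.character(labels)
  if (anyNA(labels)) stop("all training rows must be labeled")
  if (!all(CLASSES %in% labels))
    stop("training data must contain both POSITIVE and NEGATIVE examples")
  subset <- feature_subset %||% feature_names()
  bad <- setdiff(subset, feature_names())
  if (length(bad) > 0) stop("unknown features: ", paste(bad, collapse = ", "))
  if (localization_factor <= 0 || localization_factor > 1)
    stop("localization_factor must be in (0, 1]")
  stopifnot(alpha > 0, sigmoid_slope > 0)

  types <- feature_types()
  bin_specs <- list(); tables <- list()
  for (f in feature_names()) {
    spec <- fit_bin_spec(features[[f]], types[[f]], penalty)
    bins <- assign_bins(features[[f]], spec, penalty)
    bin_specs[[f]] <- spec
    tables[[f]] <- smoothed_table(bins, spec$labels, labels, alpha)
  }

  # dependency tables over the marginal bins of the dependent feature
  cbins <- assign_bins(features$cancer_count, bin_specs$cancer_count,
                       penalty)
  zone <- cancer_dist_zone(features$event_cancer_dist, penalty)
  dep_cancer <- list()
  for (z in c("near", "far", "absent")) {
    sel <- zone == z
    dep_cancer[[z]] <- smoothed_table(cbins[sel],
                                      bin_specs$cancer_count$labels,
                                      labels[sel], alpha)
  }
  hp <- ifelse(features$hallmark_count > 0, "TRUE", "FALSE")
  abins <- assign_bins(features$agent_present, bin_specs$agent_present,
                       penalty)
  dep_agent <- list()
  for (h in c("FALSE", "TRUE")) {
    sel <- hp == h
    dep_agent[[h]] <- smoothed_table(abins[sel], c("FALSE", "TRUE"),
                                     labels[sel], alpha)
  }

  structure(list(bin_specs = bin_specs, tables = tables,
                 dep_table_cancer = dep_cancer, dep_table_agent = dep_agent,
                 smoothing_alpha = alpha,
                 use_dependencies = use_dependencies, penalty = penalty,
                 sigmoid_slope = sigmoid_slope,
                 localization_factor = localization_factor,
                 feature_subset = subset,
                 n_pos = sum(labels == "POSITIVE"),
                 n_neg = sum(labels == "NEGATIVE"),
                 version = 1L),
            class = "evidence_model")
}

#' @export
print.evidence_model <- function(x, ...) {
  cat("<evidence_model>", length(x$feature_subset), "feature(s),",
      x$n_pos, "pos /", x$n_neg, "neg training rows;",
      if (x$use_dependencies) "with" else "without",
      "feature dependencies\n")
  invisible(x)
}

table_log_ratio <- function(tab, bins, model) {
  # log P(bin|pos) - log P(bin|neg); unseen bins get the smoothed floor
  lp <- log(tab[, "POSITIVE"])[bins]
  ln <- log(tab[, "NEGATIVE"])[bins]
  nb <- nrow(tab)
  floor_p <- log(model$smoothing_alpha /
                   (model$n_pos + model$smoothing_alpha * nb))
  floor_n <- log(model$smoothing_alpha /
                   (model$n_neg + model$smoothing_alpha * nb))
  lp[is.na(lp)] <- floor_p
  ln[is.na(ln)] <- floor_n
  unname(lp - ln)
}

#' Log likelihood ratio of candidates under a fitted model
#'
#' Sums, over the modeled independent features, the log ratio of binned
#' class-conditional probabilities, plus the two dependency terms
#' (cancer-count given event-cancer-distance zone; agent given hallmark
#' presence) when dependencies are enabled. Equal class priors contribute
#' nothing.
#'
#' @param model An [fit_evidence_model()] object.
#' @param features Feature data.frame (one or more rows).
#' @return Numeric vector of log likelihood ratios.
#' @export
log_likelihood_ratio <- function(model, features) {
  if (!inherits(model, "evidence_model")) stop("model is not fitted")
  n <- nrow(features)
  llr <- numeric(n)
  dep_feats <- if (model$use_dependencies) c("cancer_count", "agent_present")
               else character(0)
  for (f in intersect(model$feature_subset, feature_names())) {
    bins <- assign_bins(features[[f]], model$bin_specs[[f]], model$penalty)
    if (f %in% dep_feats) next
    llr <- llr + table_log_ratio(model$tables[[f]], bins, model)
  }
  if ("cancer_count" %in% model$feature_subset &&
      "cancer_count" %in% dep_feats) {
    bins <- assign_bins(features$cancer_count, model$bin_specs$cancer_count,
                        model$penalty)
    zone <- cancer_dist_zone(features$event_cancer_dist, model$penalty)
    for (z in unique(zone)) {
      sel <- zone == z
      llr[sel] <- llr[sel] +
        table_log_ratio(model$dep_table_cancer[[z]], bins[sel], model)
    }
  }
  if ("agent_present" %in% model$feature_subset &&
      "agent_present" %in% dep_feats) {
    bins <- assign_bins(features$agent_present,
                        model$bin_specs$agent_present, model$penalty)
    hp <- ifelse(features$hallmark_count > 0, "TRUE", "FALSE")
    for (h in unique(hp)) {
      sel <- hp == h
      llr[sel] <- llr[sel] +
        table_log_ratio(model$dep_table_agent[[h]], bins[sel], model)
    }
  }
  llr
}

#' Sigmoid conversion of a log likelihood ratio
#'
#' `1 / (1 + exp(-slope * log_lr))`: a strictly increasing map of the
#' ranking statistic into (0, 1) for display.
#'
#' @param log_lr Numeric vector.
#' @param slope Positive slope (default 1).
#' @return Numeric vector in (0, 1).
#' @export
sigmoid_score <- function(log_lr, slope = 1) {
  stopifnot(slope > 0)
  1 / (1 + exp(-slope * log_lr))
}

#' Localization post-processing
#'
#' Localization events are only useful disease evidence when they describe
#' sub-cellular localization; candidates of event type `localization`
#' whose sentence mentions no sub-cellular compartment have their score
#' multiplied by `factor`. All other candidates pass through unchanged.
#'
#' @param score Numeric score vector.
#' @param event_type Character vector of event types.
#' @param subcellular_present Logical vector.
#' @param factor Demotion factor in (0, 1].
#' @return Adjusted score vector.
#' @export
localization_adjust <- function(score, event_type, subcellular_present,
                                factor = 0.5) {
  stopifnot(factor > 0, factor <= 1)
  demote <- event_type == "localization" & !subcellular_present
  score[demote] <- score[demote] * factor
  score
}

#' Score and rank candidate evidence
#'
#' Computes the log likelihood ratio of every feature row, converts it to a
#' (0, 1) score through the sigmoid, applies the localization demotion,
#' and returns the rows sorted by adjusted score (descending) with the
#' deterministic tie-break (abstract_id, sentence_id, gene_id).
#'
#' @param model An [fit_evidence_model()] object.
#' @param features data.frame from [extract_features()].
#' @return data.frame of ranked evidence: id columns plus `log_lr`,
#'   `score`, `label`; attribute `abstract_scores` holds the per-abstract
#'   maximum score.
#' @export
rank_evidence <- function(model, features) {
  llr <- log_likelihood_ratio(model, features)
  score <- sigmoid_score(llr, model$sigmoid_slope)
  if (!is.null(features$subcellular_present)) {
    score <- localization_adjust(score, features$event_type,
                                 features$subcellular_present,
                                 model$localization_factor)
  }
  out <- features
  out$log_lr <- llr
  out$score <- score
  ord <- order(-score, out$abstract_id, out$sentence_id, out$gene_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  ab <- tapply(out$score, out$abstract_id, max)
  attr(out, "abstract_scores") <-
    data.frame(abstract_id = names(ab), max_score = as.numeric(ab),
               stringsAsFactors = FALSE)
  out
}

#' Persist a fitted model as versioned JSON
#'
#' @param model An `evidence_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ser <- unclass(model)
  ser$tables <- lapply(ser$tables, mat_to_list)
  ser$dep_table_cancer <- lapply(ser$dep_table_cancer, mat_to_list)
  ser$dep_table_agent <- lapply(ser$dep_table_agent, mat_to_list)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path Model JSON path.
#' @return An `evidence_model`.
#' @export
read_model <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ser$tables <- lapply(ser$tables, list_to_mat)
  ser$dep_table_cancer <- lapply(ser$dep_table_cancer, list_to_mat)
  ser$dep_table_agent <- lapply(ser$dep_table_agent, list_to_mat)
  ser$bin_specs <- lapply(ser$bin_specs, function(sp) {
    list(type = sp$type, edges = as.numeric(sp$edges),
         labels = as.character(sp$labels))
  })
  structure(ser, class = "evidence_model")
}

mat_to_list <- function(m) {
  list(bins = rownames(m), POSITIVE = unname(m[, "POSITIVE"]),
       NEGATIVE = unname(m[, "NEGATIVE"]))
}

list_to_mat <- function(l) {
  m <- cbind(POSITIVE = as.numeric(l$POSITIVE),
             NEGATIVE = as.numeric(l$NEGATIVE))
  rownames(m) <- as.character(l$bins)
  m
}
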