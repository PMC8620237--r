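# Evidence-level and article-level scoring, Shannon-entropy uncertainty
# sampling, the linguistic test suite and Pearson correlation analysis.

#' Shannon entropy of a class-probability vector
#'
#' Base-2 entropy with the 0 log 0 := 0 convention: the prediction
#' uncertainty. Bounded by log2(k) — 2 bits for the 4-class term task, 1 bit
#' for the binary code task.
#'
#' @param p Non-negative vector summing to 1 (within 1e-8).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("shannon_entropy: input must be a probability simplex")
  }
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Confusion matrix of predictions
#'
#' Rows are true labels, columns predicted labels, both in task class order.
#'
#' @param preds List of `prediction_record`.
#' @param task A `task_spec`.
#' @return Integer matrix.
#' @export
confusion_matrix <- function(preds, task) {
  truth <- pred_field(preds, "true_label")
  predicted <- pred_field(preds, "predicted_label")
  if (!all(c(truth, predicted) %in% task$classes)) {
    stop("confusion_matrix: label outside task classes")
  }
  m <- table(factor(truth, levels = task$classes),
             factor(predicted, levels = task$classes))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = task$classes, predicted = task$classes)
  m
}

#' Per-class and micro precision/recall/F1
#'
#' Evidence-level scores from a confusion matrix; 0/0 is defined as 0 and the
#' per-class support is recorded so empty classes can be masked. For
#' single-label multi-class prediction over a fixed set, micro precision,
#' recall and F1 coincide.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Object of class `class_metrics`: data.frame `per_class` plus
#'   `micro_precision`, `micro_recall`, `micro_f1`.
#' @export
class_metrics <- function(cm) {
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  tp <- diag(cm)
  precision <- safe_div(tp, colSums(cm))
  recall <- safe_div(tp, rowSums(cm))
  f1 <- safe_div(2 * precision * recall, precision + recall)
  micro <- safe_div(sum(tp), sum(cm))
  structure(list(
    per_class = data.frame(class = rownames(cm), precision = precision,
                           recall = recall, f1 = f1, support = rowSums(cm),
                           row.names = NULL, stringsAsFactors = FALSE),
    micro_precision = micro, micro_recall = micro, micro_f1 = micro
  ), class = "class_metrics")
}

#' Article-level inconsistency flags
#'
#' An article is flagged when at least one of its predictions is any
#' inconsistent class; detecting a single inconsistency in an article sends
#' all of its annotations to a curator, so one detection yields perfect
#' recall at article level. Article recall is computed against articles
#' containing at least one truly inconsistent instance.
#'
#' @param preds List of `prediction_record`.
#' @param instances The matching instances (supply the article mapping).
#' @return List with `table` (per-article flags) and `article_recall`.
#' @export
article_flag <- function(preds, instances) {
  aid <- stats::setNames(vapply(instances, function(x) x$article_id, ""),
                         vapply(instances, function(x) x$instance_id, ""))
  ids <- pred_field(preds, "instance_id")
  art <- unname(aid[ids])
  if (anyNA(art)) stop("article_flag: prediction without matching instance")
  predicted_bad <- pred_field(preds, "predicted_label") != "consistent"
  true_bad <- pred_field(preds, "true_label") != "consistent"
  tab <- data.frame(
    article_id = sort(unique(art)),
    stringsAsFactors = FALSE
  )
  tab$flagged <- vapply(tab$article_id, function(a)
    any(predicted_bad[art == a]), TRUE)
  tab$has_true_inconsistency <- vapply(tab$article_id, function(a)
    any(true_bad[art == a]), TRUE)
  pos <- tab$has_true_inconsistency
  recall <- if (any(pos)) mean(tab$flagged[pos]) else NA_real_
  list(table = tab, article_recall = recall)
}

#' Write / read prediction records as JSONL
#'
#' One record per line with the class-probability vector; entropy is
#' recomputed on read from the probabilities.
#'
#' @param preds List of `prediction_record`.
#' @param path File path.
#' @export
write_predictions <- function(preds, path) {
  lines <- vapply(preds, function(r) {
    jsonlite::toJSON(list(
      instance_id = r$instance_id, true_label = r$true_label,
      predicted_label = r$predicted_label,
      classes = names(r$probabilities),
      probabilities = unname(r$probabilities)
    ), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    prediction_record(x$instance_id, x$true_label, x$predicted_label,
                      x$probabilities, x$classes)
  })
}

# ---- uncertainty sampling ----------------------------------------------------

#' Cluster predictions into entropy-window collections
#'
#' One collection per tau on the inclusive arithmetic grid; a prediction
#' belongs to the collection when its entropy lies in the closed interval
#' [tau - alpha, tau]. With alpha equal to the step, an instance whose
#' entropy falls exactly on a boundary is shared by two consecutive
#' collections. Per-collection sizes and per-class precision are computed
#' over the members (sizes count predicted labels, the denominator of
#' precision).
#'
#' @param preds List of `prediction_record`.
#' @param task A `task_spec`.
#' @param tau_min,tau_max,step Grid of aggregated-uncertainty bounds
#'   (defaults 0.2, 1.7, 0.1).
#' @param alpha Window width (default 0.1).
#' @return List of collections: `tau`, `alpha`, `member_ids`, `size`,
#'   `size_by_class`, `precision_by_class`.
#' @export
uncertainty_collections <- function(preds, task, tau_min = 0.2,
                                    tau_max = 1.7, step = 0.1, alpha = 0.1) {
  if (step <= 0 || alpha <= 0) stop("uncertainty_collections: step and alpha ",
                                    "must be positive")
  n_tau <- floor((tau_max - tau_min) / step + 1e-9) + 1L
  if (n_tau < 1L) stop("uncertainty_collections: empty tau grid")
  taus <- tau_min + step * (seq_len(n_tau) - 1L)
  h <- pred_field(preds, "entropy")
  truth <- pred_field(preds, "true_label")
  predicted <- pred_field(preds, "predicted_label")
  ids <- pred_field(preds, "instance_id")
  eps <- 1e-9
  lapply(taus, function(tau) {
    member <- which(h >= tau - alpha - eps & h <= tau + eps)
    size_by_class <- table(factor(predicted[member], levels = task$classes))
    correct <- table(factor(predicted[member][predicted[member] ==
                                                truth[member]],
                            levels = task$classes))
    precision <- ifelse(size_by_class == 0, NA_real_,
                        as.numeric(correct) / as.numeric(size_by_class))
    names(precision) <- task$classes
    list(tau = tau, alpha = alpha, member_ids = ids[member],
         size = length(member),
         size_by_class = stats::setNames(as.integer(size_by_class),
                                         task$classes),
         precision_by_class = precision)
  })
}

# ---- linguistic test suite ---------------------------------------------------

#' Linguistic test-suite metrics
#'
#' Per-instance scores: `go_len` is the whitespace token count of the GO
#' term; `align_ratio` the evidence token count divided by the definition
#' token count; `geo_ratio` the count of distinct tokens shared by term and
#' evidence divided by `go_len`. Tokenisation is the shared convention of
#' [go_tokens()].
#'
#' @param term GO term string.
#' @return `go_len()`: positive integer.
#' @export
go_len <- function(term) length(go_tokens(term))

#' @rdname go_len
#' @param evidence Evidence text.
#' @param definition GO definition text (non-empty for `align_ratio`).
#' @export
align_ratio <- function(evidence, definition) {
  if (!nzchar(trimws(definition))) {
    stop("align_ratio: empty GO definition")
  }
  length(go_tokens(evidence)) / length(go_tokens(definition))
}

#' @rdname go_len
#' @export
geo_ratio <- function(term, evidence) {
  word_overlap(term, evidence) / go_len(term)
}

strip_punct_tokens <- function(term) {
  toks <- strsplit(trimws(term), "\\s+")[[1]]
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
}

#' Surface-form indicators on GO terms
#'
#' `contains_roman`: some whitespace token of the term (surrounding
#' punctuation ignored) is composed entirely of uppercase Roman-numeral
#' letters, so "photosystem II" matches while a lone lowercase "i" does not.
#' `contains_digit`: any character 0-9 anywhere in the term.
#' `contains_stop_of`: case-insensitive whole-token match of "of".
#'
#' @param term GO term string.
#' @return Logical scalar.
#' @export
contains_roman <- function(term) {
  any(grepl("^[IVXLCDM]+$", strip_punct_tokens(term)))
}

#' @rdname contains_roman
#' @export
contains_digit <- function(term) grepl("[0-9]", term)

#' @rdname contains_roman
#' @export
contains_stop_of <- function(term) {
  any(tolower(strip_punct_tokens(term)) == "of")
}

#' Test-suite scores for an instance
#'
#' @param instance A `goa_instance`.
#' @return List with `go_len`, `align_ratio`, `geo_ratio` and the three
#'   surface indicators.
#' @export
test_suite_instance <- function(instance) {
  list(
    go_len = go_len(instance$go_term),
    align_ratio = align_ratio(instance$evidence_text,
                              instance$go_definition),
    geo_ratio = geo_ratio(instance$go_term, instance$evidence_text),
    contains_roman = contains_roman(instance$go_term),
    contains_digit = contains_digit(instance$go_term),
    contains_stop_of = contains_stop_of(instance$go_term)
  )
}

#' Test-suite scores aggregated over a collection
#'
#' Per-instance metrics are averaged; the percentage metrics are the
#' fraction of members whose GO term contains a Roman-numeral token, any
#' digit, or the stopword "of".
#'
#' @param instances Collection members (`goa_instance` list).
#' @return List of aggregated scores.
#' @export
test_suite_collection <- function(instances) {
  if (!length(instances)) {
    stop("test_suite_collection: empty collection")
  }
  scores <- lapply(instances, test_suite_instance)
  get <- function(f) vapply(scores, function(s) as.numeric(s[[f]]), 1)
  list(
    mean_go_len = mean(get("go_len")),
    mean_align_ratio = mean(get("align_ratio")),
    mean_geo_ratio = mean(get("geo_ratio")),
    pct_contain_roman = mean(get("contains_roman")),
    pct_contain_digit = mean(get("contains_digit")),
    pct_contain_stop_of = mean(get("contains_stop_of"))
  )
}

#' Pearson correlation with two-sided p value
#'
#' Used in two modes: per-instance (a test-suite metric against per-instance
#' prediction entropy) and per-collection (an aggregated collection metric
#' against the collection's tau).
#'
#' @param values_x,values_y Paired finite numeric vectors, length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_analysis <- function(values_x, values_y) {
  if (length(values_x) != length(values_y) || length(values_x) < 3L) {
    stop("pearson_analysis: need paired vectors of length >= 3")
  }
  if (!all(is.finite(values_x)) || !all(is.finite(values_y))) {
    stop("pearson_analysis: inputs must be finite")
  }
  if (stats::sd(values_x) == 0 || stats::sd(values_y) == 0) {
    stop("pearson_analysis: undefined correlation (zero variance)")
  }
  ct <- stats::cor.test(values_x, values_y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
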