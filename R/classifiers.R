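# Consistency prediction: prior-biased and section-rule baselines, the
# sequence-pair input contract for transformer backends, and a
# feature-transparent lexical classifier (multinomial logistic regression)
# as the in-core learned model.

#' Task specification
#'
#' Two tasks: `term` is multi-class (consistent vs term inconsistencies A, B,
#' C); `code` is binary (consistent vs evidence-code inconsistency D). The
#' class order is fixed so probability index i is unambiguous in entropy
#' computations.
#'
#' @param name `"term"` or `"code"`.
#' @return Object of class `task_spec` with `name` and ordered `classes`.
#' @export
task_spec <- function(name = c("term", "code")) {
  name <- match.arg(name)
  classes <- if (name == "term") c("consistent", "A", "B", "C") else
    c("consistent", "D")
  structure(list(name = name, classes = classes), class = "task_spec")
}

#' Render an instance as a sequence pair
#'
#' Term task pairs the evidence text with "GO term: GO definition"; code task
#' pairs it with the evidence code. The rendered form is
#' `"[CLS] text_a [SEP] text_b [SEP]"`. With `section_mode` the 1-based index
#' of the section category in the fixed 10-category order is attached as an
#' extra feature for backends that concatenate a section encoding.
#'
#' @param instance A `goa_instance`.
#' @param task A `task_spec`.
#' @param section_mode Attach the section feature?
#' @return List with `text_a`, `text_b`, `section_feature`, `rendered`.
#' @export
format_pair <- function(instance, task, section_mode = FALSE) {
  if (task$name == "code" && identical(instance$evidence_code, "NONE")) {
    stop("format_pair: code task undefined for summary instances (code NONE)")
  }
  text_b <- if (task$name == "term") {
    paste0(instance$go_term, ": ", instance$go_definition)
  } else {
    instance$evidence_code
  }
  list(
    text_a = instance$evidence_text,
    text_b = text_b,
    section_feature = if (section_mode) {
      match(instance$section_category, SECTION_CATEGORIES)
    },
    rendered = paste0("[CLS] ", instance$evidence_text, " [SEP] ",
                      text_b, " [SEP]")
  )
}

# ---- prediction records ------------------------------------------------------

prediction_record <- function(instance_id, true_label, predicted_label,
                              probabilities, classes) {
  p <- as.numeric(probabilities)
  if (length(p) != length(classes) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stop("prediction_record: probabilities must be a simplex over the task ",
         "classes")
  }
  names(p) <- classes
  structure(list(instance_id = instance_id, true_label = true_label,
                 predicted_label = predicted_label, probabilities = p,
                 entropy = shannon_entropy(p)),
            class = "prediction_record")
}

argmax_label <- function(p, classes) classes[which.max(p)]

pred_field <- function(preds, field) {
  vapply(preds, function(r) r[[field]], if (field == "entropy") 1 else "")
}

# ---- prior-biased baseline ---------------------------------------------------

#' Fit the prior-biased baseline
#'
#' The class-probability vector is the empirical label distribution of the
#' training set, with no smoothing.
#'
#' @param train Labelled `goa_instance` list.
#' @param task A `task_spec`.
#' @return Named probability vector over `task$classes`.
#' @export
prior_classifier_fit <- function(train, task) {
  if (!length(train)) stop("prior_classifier_fit: empty training set")
  labels <- vapply(train, function(x) x$label, "")
  if (!all(labels %in% task$classes)) {
    stop("prior_classifier_fit: label outside task classes")
  }
  counts <- table(factor(labels, levels = task$classes))
  as.numeric(counts) / length(labels) -> p
  names(p) <- task$classes
  p
}

#' Predict with the prior-biased baseline
#'
#' Each instance receives a seeded categorical draw from the prior as its
#' predicted label (sampling interpretation); `mode = "argmax"` instead
#' always predicts the majority class. The probability vector of every
#' record is the prior itself.
#'
#' @param prior Named probability vector from [prior_classifier_fit()].
#' @param instances Instances to predict.
#' @param task A `task_spec`.
#' @param seed Seed for the draws.
#' @param mode `"sample"` or `"argmax"`.
#' @return List of `prediction_record`.
#' @export
prior_classifier_predict <- function(prior, instances, task, seed = 1L,
                                     mode = c("sample", "argmax")) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(prior) - 1) < 1e-8)
  n <- length(instances)
  drawn <- if (mode == "sample") {
    with_seed(seed, sample(task$classes, n, replace = TRUE, prob = prior))
  } else {
    rep(argmax_label(prior, task$classes), n)
  }
  lapply(seq_len(n), function(i) {
    prediction_record(instances[[i]]$instance_id, instances[[i]]$label,
                      drawn[i], prior, task$classes)
  })
}

#' Predict with the section-information rule
#'
#' Instances whose evidence section is Background, Supporting information,
#' Supplementary or Other are predicted as unsupportive (C); all other
#' sections are consistent-side and are then redistributed by a seeded draw
#' from `fallback_prior` (a prior-biased classifier over the non-C classes).
#' For the code task the rule has no C class and degenerates to a pure prior
#' draw.
#'
#' @param instances Instances to predict.
#' @param task A `task_spec`.
#' @param fallback_prior Named probability vector over a subset of
#'   `task$classes` excluding `"C"`.
#' @param seed Seed for the redistribution draws.
#' @return List of `prediction_record`.
#' @export
section_rule_predict <- function(instances, task, fallback_prior, seed = 1L) {
  unsupportive_sections <- c("Background", "Supporting information",
                             "Supplementary", "Other")
  if (!all(names(fallback_prior) %in% setdiff(task$classes, "C")) ||
      abs(sum(fallback_prior) - 1) > 1e-8) {
    stop("section_rule_predict: fallback_prior must be a probability vector ",
         "over the non-C task classes")
  }
  full_prior <- stats::setNames(numeric(length(task$classes)), task$classes)
  full_prior[names(fallback_prior)] <- fallback_prior
  one_hot_c <- stats::setNames(as.numeric(task$classes == "C"), task$classes)

  n <- length(instances)
  draws <- with_seed(seed, sample(names(fallback_prior), n, replace = TRUE,
                                  prob = fallback_prior))
  lapply(seq_len(n), function(i) {
    inst <- instances[[i]]
    rule_c <- task$name == "term" &&
      inst$section_category %in% unsupportive_sections
    if (rule_c) {
      prediction_record(inst$instance_id, inst$label, "C", one_hot_c,
                        task$classes)
    } else {
      prediction_record(inst$instance_id, inst$label, draws[i], full_prior,
                        task$classes)
    }
  })
}

# ---- lexical classifier ------------------------------------------------------

POLARITY_POS <- c("increase", "increases", "increased", "activate",
                  "activates", "activated", "promote", "promotes", "promoted",
                  "enhance", "enhances", "enhanced", "stimulate", "stimulates",
                  "stimulated", "accelerates", "upregulates", "up-regulates")
POLARITY_NEG <- c("decrease", "decreases", "decreased", "inhibit", "inhibits",
                  "inhibited", "prevent", "prevents", "prevented", "suppress",
                  "suppresses", "suppressed", "repress", "represses",
                  "repressed", "reduce", "reduces", "reduced", "block",
                  "blocks", "blocked", "deactivates", "downregulates",
                  "down-regulates")
FRAMING_LEXICON <- c("demonstrate", "demonstrates", "demonstrated", "show",
                     "shows", "showed", "shown", "indicate", "indicates",
                     "indicated", "reveal", "reveals", "revealed", "found",
                     "observed", "confirm", "confirms", "confirmed")
# keyword vocabulary of the evidence-code decision tree
CODE_CUES <- list(
  IDA = c("direct", "assay", "assays", "assayed"),
  IMP = c("mutant", "mutants", "mutation", "phenotype", "knock-out",
          "knockout"),
  IPI = c("interaction", "interacts", "binds", "binding", "two-hybrid",
          "coimmunoprecipitation"),
  IGI = c("genetic", "allele", "alleles", "epistasis", "double-mutant"),
  IEP = c("expression", "expressed", "transcript", "transcripts", "pattern")
)

clean_tokens <- function(x) {
  toks <- gsub("[^a-z0-9-]", "", go_tokens(x))
  toks[nzchar(toks)]
}

term_polarity <- function(name) {
  s <- tolower(name)
  if (grepl("positive regulation", s)) 1L
  else if (grepl("negative regulation", s)) -1L
  else 0L
}

text_polarity <- function(tokens) {
  pos <- sum(tokens %in% POLARITY_POS)
  neg <- sum(tokens %in% POLARITY_NEG)
  sign(pos - neg)
}

lexical_features <- function(instance, task, section_mode = TRUE) {
  ev <- clean_tokens(instance$evidence_text)
  term <- clean_tokens(instance$go_term)
  def <- clean_tokens(instance$go_definition)
  tp <- term_polarity(instance$go_term)
  ep <- text_polarity(ev)
  feats <- c(
    geo_ratio = length(intersect(term, ev)) / max(length(term), 1L),
    def_overlap = length(intersect(def, ev)) / max(length(def), 1L),
    align_ratio = length(ev) / max(length(def), 1L),
    go_len = length(go_tokens(instance$go_term)),
    term_pol = tp,
    pol_mismatch = as.numeric(tp != 0L && ep != 0L && tp != ep),
    framing = as.numeric(any(ev %in% FRAMING_LEXICON))
  )
  if (section_mode) {
    sec <- as.numeric(SECTION_CATEGORIES == instance$section_category)
    names(sec) <- paste0("sec_", gsub("[^A-Za-z]", "_", SECTION_CATEGORIES))
    feats <- c(feats, sec[-1])  # drop one level
  }
  if (task$name == "code") {
    cues <- vapply(names(CODE_CUES), function(code)
      length(intersect(CODE_CUES[[code]], ev)), 1L)
    own <- if (instance$evidence_code %in% names(CODE_CUES)) {
      cues[[instance$evidence_code]]
    } else 0L
    other <- if (length(cues)) max(cues[names(cues) !=
                                          instance$evidence_code], 0L) else 0L
    onehot <- as.numeric(names(CODE_CUES) == instance$evidence_code)
    names(onehot) <- paste0("code_", names(CODE_CUES))
    feats <- c(feats, own_code_cue = own, other_code_cue = other, onehot)
  }
  feats
}

feature_frame <- function(instances, task, section_mode) {
  m <- t(vapply(instances, lexical_features,
                lexical_features(instances[[1]], task, section_mode),
                task = task, section_mode = section_mode))
  as.data.frame(m)
}

#' Fit the lexical consistency classifier
#'
#' Multinomial logistic regression over transparent, inspectable features:
#' token-overlap ratios between evidence and the GO term/definition, evidence
#' vs definition length ratio, term token count, regulation-polarity mismatch
#' between the term and the evidence lexicon, a result-framing indicator,
#' section one-hots, and (for the code task) evidence-code one-hots plus
#' overlap with a small evidence-code keyword vocabulary. Training rows are
#' canonically ordered by instance id, so permuting the input leaves the fit
#' unchanged; the optimiser is seeded and deterministic.
#'
#' @param train Labelled instances (at least two classes).
#' @param task A `task_spec`.
#' @param section_mode Include section one-hot features?
#' @param seed Seed for weight initialisation.
#' @return Object of class `lexical_model`.
#' @export
lexical_classifier_fit <- function(train, task, section_mode = TRUE,
                                   seed = 1L) {
  labels <- vapply(train, function(x) x$label, "")
  if (length(unique(labels)) < 2L) {
    stop("lexical_classifier_fit: training set must contain >= 2 classes")
  }
  ord <- order(vapply(train, function(x) x$instance_id, ""))
  train <- train[ord]
  labels <- labels[ord]
  df <- feature_frame(train, task, section_mode)
  df$.label <- factor(labels, levels = task$classes)
  fit <- with_seed(seed, nnet::multinom(
    .label ~ ., data = df, trace = FALSE, maxit = 500, MaxNWts = 5000))
  structure(list(fit = fit, task = task, section_mode = section_mode,
                 seed = as.integer(seed)),
            class = "lexical_model")
}

#' Predict with the lexical classifier
#'
#' @param model A `lexical_model`.
#' @param instances Instances to predict.
#' @return List of `prediction_record` (predicted label = argmax probability,
#'   ties to the lower class index).
#' @export
lexical_classifier_predict <- function(model, instances) {
  df <- feature_frame(instances, model$task, model$section_mode)
  probs <- stats::predict(model$fit, newdata = df, type = "probs")
  classes <- model$task$classes
  if (is.null(dim(probs))) {
    # binary multinom returns P(second level); single row returns a vector
    probs <- if (length(classes) == 2L && length(probs) == nrow(df)) {
      cbind(1 - probs, probs)
    } else {
      matrix(probs, nrow = 1L)
    }
  }
  colnames(probs) <- classes
  lapply(seq_along(instances), function(i) {
    p <- pmax(probs[i, ], 0)
    p <- p / sum(p)
    prediction_record(instances[[i]]$instance_id, instances[[i]]$label,
                      argmax_label(p, classes), p, classes)
  })
}

# ---- transformer backend contract -------------------------------------------

#' Emit input files and hyperparameters for a transformer backend
#'
#' Writes the rendered sequence pairs, numeric label ids and section indices
#' as TSV, plus a manifest recording the fine-tuning hyperparameters
#' (AdamW, 0.01 weight decay, 300 warmup steps, 3 epochs, train batch 16,
#' dev batch 64, 768 hidden units, 769 with the concatenated section
#' encoding). No training happens in-core; the files are the input contract
#' for an external fine-tuning run.
#'
#' @param instances Instances to render.
#' @param task A `task_spec`.
#' @param out_dir Output directory (created if missing).
#' @param section_mode Attach section indices?
#' @return The manifest, invisibly.
#' @export
transformer_backend_contract <- function(instances, task, out_dir,
                                         section_mode = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(instances, function(inst) {
    pair <- format_pair(inst, task, section_mode)
    paste(inst$instance_id, pair$rendered,
          match(inst$label, task$classes) - 1L,
          if (section_mode) pair$section_feature else "",
          sep = "\t")
  }, "")
  writeLines(c(paste("instance_id", "rendered", "label_id", "section_index",
                     sep = "\t"), rows),
             file.path(out_dir, paste0(task$name, "_pairs.tsv")),
             useBytes = TRUE)
  manifest <- list(
    task = task$name,
    classes = task$classes,
    model = "biomedical BERT-base uncased",
    optimizer = "AdamW",
    weight_decay = 0.01,
    warmup_steps = 300L,
    epochs = 3L,
    train_batch_size = 16L,
    dev_batch_size = 64L,
    hidden_size = 768L,
    section_concat_dim = if (section_mode) 769L else 768L,
    n_instances = length(instances)
  )
  jsonlite::write_json(manifest, file.path(out_dir,
                                           paste0(task$name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
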