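fake_pred <- function(id, true_label, p, classes, predicted = NULL) {
  if (is.null(predicted)) predicted <- classes[which.max(p)]
  structure(list(instance_id = id, true_label = true_label,
                 predicted_label = predicted,
                 probabilities = stats::setNames(p, classes),
                 entropy = shannon_entropy(p)),
            class = "prediction_record")
}

test_that("entropy matches closed forms and rejects non-simplex input", {
  expect_equal(shannon_entropy(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), 1)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.9, 0.1)),
               -(0.9 * log2(0.9) + 0.1 * log2(0.1)))
  expect_error(shannon_entropy(c(0.5, 0.6)), "simplex")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "simplex")
})

test_that("confusion matrix and derived metrics follow the arithmetic", {
  code <- task_spec("code")
  labels <- c(rep("consistent", 10), rep("D", 10))
  predicted <- c(rep("consistent", 8), "D", "D",
                 rep("consistent", 3), rep("D", 7))
  preds <- lapply(seq_along(labels), function(i)
    fake_pred(paste0("i", i), labels[i],
              if (predicted[i] == "consistent") c(1, 0) else c(0, 1),
              code$classes))
  cm <- confusion_matrix(preds, code)
  expect_equal(unname(cm), matrix(c(8L, 3L, 2L, 7L), 2))

  m <- class_metrics(cm)
  expect_equal(m$per_class$precision, c(8 / 11, 7 / 9))
  expect_equal(m$per_class$recall, c(0.8, 0.7))
  expect_equal(m$per_class$support, c(10, 10))
  expect_equal(m$micro_precision, 15 / 20)
  expect_identical(m$micro_precision, m$micro_recall)

  # perfect predictions give an identity-supported matrix
  perfect <- lapply(seq_along(labels), function(i)
    fake_pred(paste0("i", i), labels[i],
              if (labels[i] == "consistent") c(1, 0) else c(0, 1),
              code$classes))
  mp <- class_metrics(confusion_matrix(perfect, code))
  expect_true(all(mp$per_class$precision == 1, mp$per_class$recall == 1,
                  mp$per_class$f1 == 1))

  # 0/0 cells are defined as 0, support recorded
  never_d <- lapply(1:4, function(i)
    fake_pred(paste0("i", i), "consistent", c(1, 0), code$classes))
  m0 <- class_metrics(confusion_matrix(never_d, code))
  expect_equal(m0$per_class$precision[2], 0)
  expect_equal(m0$per_class$support[2], 0)
})

test_that("evidence-level grounding: one of two sentences wrong gives 0.5", {
  term <- task_spec("term")
  preds <- list(
    fake_pred("e1", "consistent", c(1, 0, 0, 0), term$classes),
    fake_pred("e2", "B", c(1, 0, 0, 0), term$classes)
  )
  m <- class_metrics(confusion_matrix(preds, term))
  expect_equal(m$per_class$precision[1], 0.5)
})

test_that("article flags achieve recall from a single detection", {
  term <- task_spec("term")
  instances <- list(
    list(instance_id = "a1", article_id = "ART1"),
    list(instance_id = "a2", article_id = "ART1"),
    list(instance_id = "b1", article_id = "ART2"),
    list(instance_id = "c1", article_id = "ART3"),
    list(instance_id = "c2", article_id = "ART3")
  )
  preds <- list(
    # ART1: 1 of 2 true inconsistencies detected -> flagged
    fake_pred("a1", "B", c(0, 0, 1, 0), term$classes),
    fake_pred("a2", "C", c(1, 0, 0, 0), term$classes),
    # ART2: all consistent, predicted consistent -> not flagged
    fake_pred("b1", "consistent", c(1, 0, 0, 0), term$classes),
    # ART3: true inconsistency fully missed -> not flagged
    fake_pred("c1", "A", c(1, 0, 0, 0), term$classes),
    fake_pred("c2", "consistent", c(1, 0, 0, 0), term$classes)
  )
  af <- article_flag(preds, instances)
  expect_equal(af$table$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(af$table$has_true_inconsistency, c(TRUE, FALSE, TRUE))
  expect_equal(af$article_recall, 0.5)

  # brute-force agreement over every article
  for (i in seq_len(nrow(af$table))) {
    aid <- af$table$article_id[i]
    members <- vapply(instances, function(x) x$article_id, "") == aid
    expect_equal(af$table$flagged[i],
                 any(pred_field(preds[members],
                                "predicted_label") != "consistent"))
  }
})

test_that("uncertainty collections use closed boundaries on the tau grid", {
  term <- task_spec("term")
  # entropy exactly 1 bit sits on the boundary of tau=1.0 and tau=1.1
  p_h1 <- c(0.5, 0.5, 0, 0)
  preds <- list(fake_pred("x", "consistent", p_h1, term$classes))
  cols <- uncertainty_collections(preds, term, 0.2, 1.7, 0.1, 0.1)
  expect_length(cols, 16L)
  member <- vapply(cols, function(cl) "x" %in% cl$member_ids, TRUE)
  taus <- vapply(cols, function(cl) cl$tau, 1)
  expect_equal(taus[member], c(1.0, 1.1), tolerance = 1e-9)

  # fully certain predictions fall below every collection
  certain <- list(fake_pred("y", "A", c(0, 1, 0, 0), term$classes))
  cols0 <- uncertainty_collections(certain, term)
  expect_true(all(vapply(cols0, function(cl) cl$size, 1L) == 0L))

  expect_error(uncertainty_collections(preds, term, 1, 0.5, 0.1, 0.1),
               "grid")
})

test_that("collection membership matches a brute-force interval scan", {
  term <- task_spec("term")
  set.seed(77)
  entropies <- round(runif(100, 0, 2), 3)
  mk_p <- function(h) {
    # two-point distribution over 4 classes achieving entropy h via search
    f <- function(q) shannon_entropy(c(q, 1 - q, 0, 0)) - h
    if (h <= 1) {
      q <- uniroot(f, c(0.5, 1 - 1e-12))$root
      c(q, 1 - q, 0, 0)
    } else {
      g <- function(q) shannon_entropy(c(q, rep((1 - q) / 3, 3))) - h
      q <- uniroot(g, c(0.25, 1 - 1e-9))$root
      c(q, rep((1 - q) / 3, 3))
    }
  }
  preds <- lapply(seq_along(entropies), function(i)
    fake_pred(paste0("p", i), "consistent", mk_p(entropies[i]),
              term$classes))
  h <- pred_field(preds, "entropy")
  cols <- uncertainty_collections(preds, term)
  for (cl in cols) {
    brute <- which(h >= cl$tau - cl$alpha - 1e-9 & h <= cl$tau + 1e-9)
    expect_identical(sort(cl$member_ids), sort(paste0("p", brute)))
    expect_true(all(h[brute] >= cl$tau - cl$alpha - 1e-9))
  }
  # coverage: the union over the grid captures everything in range
  covered <- unique(unlist(lapply(cols, `[[`, "member_ids")))
  in_range <- paste0("p", which(h >= 0.1 - 1e-9 & h <= 1.7 + 1e-9))
  expect_true(all(in_range %in% covered))
})

test_that("test-suite scores reproduce the worked examples", {
  expect_equal(go_len("feeding behavior"), 2L)
  evidence <- "CeCDC-14 and ZEN-4 are interdependent in their localization"
  definition <- paste(
    "Any process that modulates the frequency, rate or extent of any",
    "process in which a protein is transported to, or maintained in, a",
    "specific location.")
  expect_equal(align_ratio(evidence, definition), 0.32)
  expect_equal(geo_ratio("regulation of protein localization", evidence),
               0.25)
  expect_error(align_ratio(evidence, "  "), "empty")
})

test_that("surface indicators follow the token rules", {
  expect_true(contains_roman(
    "photosynthesis, light harvesting in photosystem II"))
  expect_false(contains_roman("feeding behavior"))
  expect_false(contains_roman("i feeding"))  # lone lowercase i is not Roman
  expect_false(contains_roman("VIral process"))

  expect_true(contains_digit("cellular response to interleukin-1"))
  expect_false(contains_digit("cellular response to peptide"))

  expect_true(contains_stop_of("regulation of feeding behavior"))
  expect_false(contains_stop_of("offal processing"))
})

test_that("pearson analysis matches the textbook formula", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2, 9.9, 10.1, 11.4, 12.8,
         13.3, 14.7, 15.2)
  y <- c(2.1, 1.9, 3.8, 4.1, 6.2, 5.9, 7.5, 9.1, 9.8, 11.2, 11.9, 12.1,
         14.4, 14.1, 16.3)
  res <- pearson_analysis(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(13 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_oracle), 13), tolerance = 1e-12)

  expect_equal(pearson_analysis(1:10, 2 * (1:10) + 1)$r, 1)
  # balanced antisymmetric fixture has exactly zero correlation
  x0 <- c(-2, -1, 0, 1, 2)
  y0 <- c(4, 1, 0, 1, 4)
  expect_equal(pearson_analysis(x0, y0)$r, 0)
  expect_error(pearson_analysis(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_analysis(1:2, 1:2), "length")
})

test_that("predictions round-trip through JSONL", {
  term <- task_spec("term")
  preds <- list(
    fake_pred("p1", "consistent", c(0.7, 0.1, 0.1, 0.1), term$classes),
    fake_pred("p2", "B", c(0.25, 0.25, 0.25, 0.25), term$classes)
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(back, preds)
})
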