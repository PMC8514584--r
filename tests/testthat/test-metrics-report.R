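test_that("metrics follow their defining formulas", {
  m <- compute_metrics(confusion_matrix(tn = 96, fp = 12, fn = 15, tp = 199))
  expect_equal(m$sensitivity, 199 / 214)
  expect_equal(m$specificity, 96 / 108)
  expect_equal(m$accuracy, 295 / 322)
  expect_equal(m$balanced_accuracy, (199 / 214 + 96 / 108) / 2)
  perfect <- compute_metrics(confusion_matrix(tn = 10, fp = 0, fn = 0, tp = 20))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "balanced_accuracy")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 balanced_accuracy = 1))
})

test_that("an all-positive predictor scores balanced accuracy 0.5", {
  m <- compute_metrics(confusion_matrix(tn = 0, fp = 108, fn = 0, tp = 214))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$balanced_accuracy, 0.5)
  expect_equal(round(m$accuracy, 3), 0.665)
})

test_that("accuracy decomposes by prevalence on random matrices", {
  set.seed(8)
  for (i in 1:50) {
    cm <- confusion_matrix(tn = sample(1:200, 1), fp = sample(0:200, 1),
                           fn = sample(0:200, 1), tp = sample(1:200, 1))
    m <- compute_metrics(cm)
    total <- cm$tn + cm$fp + cm$fn + cm$tp
    prev <- (cm$tp + cm$fn) / total
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
    if (cm$tp + cm$fn == cm$tn + cm$fp) {
      expect_equal(m$balanced_accuracy, m$accuracy)
    }
  }
})

test_that("degenerate classes raise undefined-metric errors", {
  expect_error(compute_metrics(confusion_matrix(tn = 5, fp = 5, fn = 0, tp = 0)),
               "no positive")
  expect_error(compute_metrics(confusion_matrix(tn = 0, fp = 0, fn = 5, tp = 5)),
               "no negative")
  expect_error(confusion_matrix(tn = 0, fp = 0, fn = 0, tp = 0), "empty")
  expect_error(confusion_matrix(tn = -1, fp = 1, fn = 1, tp = 1),
               "non-negative")
})

test_that("case results tabulate with benign as the negative class", {
  res <- data.frame(
    true_label = c("malignant", "malignant", "malignant", "benign"),
    probability = c(0.9, 0.8, 0.7, 0.6))
  cm <- results_to_confusion(res)
  expect_equal(unlist(cm[c("tn", "fp", "fn", "tp")]),
               c(tn = 0, fp = 1, fn = 0, tp = 3))
  cm0 <- results_to_confusion(res, threshold = 0)
  expect_equal(cm0$fn + cm0$tn, 0)
  expect_error(results_to_confusion(res[0, ]), "empty")
  # predicted_label used when no probability column present
  res2 <- data.frame(true_label = c("benign", "malignant"),
                     predicted_label = c("benign", "benign"))
  cm2 <- results_to_confusion(res2)
  expect_equal(unlist(cm2[c("tn", "fp", "fn", "tp")]),
               c(tn = 1, fp = 0, fn = 1, tp = 0))
})

test_that("display rounding is half-up at three decimals", {
  expect_equal(admil:::round_half_up(0.5685, 3), 0.569)
  expect_equal(admil:::round_half_up(0.9095, 3), 0.910)
  expect_equal(admil:::round_half_up(0.8925, 3), 0.893)
})

test_that("the published metric table follows from the published matrices", {
  cms <- reference_confusions()
  ref <- reference_metrics()
  merged <- merge(cms, ref, by = c("regime", "backbone", "evaluation"))
  expect_equal(nrow(merged), 7)
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    flagged <- strsplit(ifelse(is.na(r$known_inconsistencies), "",
                               r$known_inconsistencies), ";")[[1]]
    m <- compute_metrics(confusion_matrix(r$tn, r$fp, r$fn, r$tp),
                         rounded_inputs = TRUE)
    for (metric in c("sensitivity", "specificity", "accuracy",
                     "balanced_accuracy")) {
      if (metric %in% flagged) next
      expect_equal(admil:::round_half_up(m[[metric]], 3), r[[metric]],
                   label = paste(r$regime, r$backbone, r$evaluation, metric))
    }
  }
})

test_that("the flagged published entries are genuinely irreproducible", {
  # residual-backbone balanced accuracy: published 0.900, matrix gives 0.895
  m <- compute_metrics(confusion_matrix(tn = 99, fp = 9, fn = 27, tp = 187))
  expect_equal(admil:::round_half_up(m$balanced_accuracy, 3), 0.895)
  mr <- compute_metrics(confusion_matrix(tn = 99, fp = 9, fn = 27, tp = 187),
                        rounded_inputs = TRUE)
  expect_false(admil:::round_half_up(mr$balanced_accuracy, 3) == 0.900)
  # supervised case-level: published sensitivity 0.985 / accuracy 0.849,
  # matrix gives 0.986 (0.98598 truncated) and 0.894
  m2 <- compute_metrics(confusion_matrix(tn = 77, fp = 31, fn = 3, tp = 211))
  expect_equal(admil:::round_half_up(m2$sensitivity, 3), 0.986)
  expect_equal(floor(m2$sensitivity * 1000) / 1000, 0.985)
  expect_equal(admil:::round_half_up(m2$accuracy, 3), 0.894)
  expect_equal(admil:::round_half_up(m2$balanced_accuracy, 3), 0.849)
})
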