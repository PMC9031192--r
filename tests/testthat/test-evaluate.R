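# Brute-force transcription of the one-vs-all macro-metric formulas,
# independent of the package implementation.
oracle_macro <- function(m) {
  c_n <- nrow(m); total <- sum(m)
  acc <- sens <- spec <- prec <- numeric(c_n)
  for (i in seq_len(c_n)) {
    tp <- m[i, i]; fn <- sum(m[i, ]) - tp; fp <- sum(m[, i]) - tp
    tn <- total - tp - fn - fp
    acc[i] <- (tp + tn) / (tp + fn + fp + tn)
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  p <- mean(prec); r <- mean(sens)
  c(accuracy = mean(acc), sensitivity = r, specificity = mean(spec),
    precision = p, f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

test_that("confusion matrices match a pair-counting oracle", {
  cls <- c("normal", "com", "ome", "earwax")
  truth <- rep(cls, each = 10)
  cm <- confusion(truth, truth, cls)
  expect_equal(diag(unclass(cm)), setNames(rep(10L, 4), cls))
  expect_equal(sum(cm), 40)

  all_com <- confusion(truth, rep("com", 40), cls)
  expect_equal(unname(unclass(all_com)[, "com"]), rep(10L, 4))
  expect_equal(sum(unclass(all_com)[, -2]), 0)

  set.seed(77)
  t2 <- sample(cls, 200, replace = TRUE)
  p2 <- sample(cls, 200, replace = TRUE)
  cm2 <- unclass(confusion(t2, p2, cls))
  for (i in seq_along(cls)) for (j in seq_along(cls))
    expect_equal(cm2[i, j], sum(t2 == cls[i] & p2 == cls[j]))

  expect_error(confusion(c("normal", "aom"), c("normal", "normal"), cls),
               "outside")
})

test_that("one-vs-all reduction follows the definition arithmetic", {
  m <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  bo <- one_vs_all(m)
  expect_equal(bo[1, c("TP", "FN", "FP", "TN")],
               data.frame(TP = 8L, FN = 2L, FP = 3L, TN = 7L),
               ignore_attr = TRUE)
  # diagonal matrix: no errors of either kind
  bo_d <- one_vs_all(diag(c(5L, 6L, 7L)))
  expect_true(all(bo_d$FP == 0) && all(bo_d$FN == 0))
  # partition identity holds for every class of random matrices
  set.seed(5)
  for (r in 1:20) {
    bo_r <- one_vs_all(random_cm())
    expect_true(all(bo_r$TP + bo_r$TN + bo_r$FP + bo_r$FN ==
                      sum(bo_r[1, -1])))
  }
})

test_that("macro metrics equal the brute-force formula evaluation", {
  # perfect classifier: every metric 1
  perfect <- macro_metrics(diag(c(10L, 10L, 10L, 10L)))
  expect_equal(unname(perfect$macro), rep(1, 5))

  # harmonic mean of equal precision and recall is that value
  p <- 0.85; r <- 0.85
  expect_equal(2 * p * r / (p + r), 0.85)

  # 1,000 random confusion matrices vs the independent transcription
  set.seed(123)
  for (i in 1:1000) {
    m <- random_cm(4, 120)
    got <- suppressWarnings(macro_metrics(m))
    expect_equal(got$macro, oracle_macro(m), tolerance = 1e-12)
  }

  # zero-denominator terms are defined as 0 and flagged
  never_pred <- matrix(c(10L, 0L, 10L, 0L), 2, 2)
  expect_warning(macro_metrics(never_pred), "zero-denominator")
})

test_that("macro sensitivity equals the mean of per-class recalls", {
  set.seed(9)
  for (i in 1:50) {
    rep_ <- suppressWarnings(macro_metrics(random_cm()))
    expect_equal(unname(rep_$macro["sensitivity"]),
                 mean(rep_$per_class$sensitivity))
    expect_true(all(unlist(rep_$per_class[-1]) >= 0 &
                      unlist(rep_$per_class[-1]) <= 1))
  }
})

test_that("ROC curves are monotone, symmetric and match pROC", {
  cls <- c("neg", "pos")
  # perfectly separating scores
  truth <- rep(cls, each = 20)
  probs <- cbind(c(runif(20, 0.6, 1), runif(20, 0, 0.4)))
  probs <- cbind(probs, 1 - probs)
  rc <- roc(truth, probs, 2, cls)
  expect_equal(rc$auc, 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_true(all(rc$fpr >= 0 & rc$fpr <= 1 & rc$tpr >= 0 & rc$tpr <= 1))

  # label-independent scores: AUC near 1/2 (n = 2,000 permutation draw)
  set.seed(31)
  t2 <- sample(cls, 2000, replace = TRUE)
  s2 <- runif(2000)
  rc2 <- roc(t2, cbind(1 - s2, s2), 2, cls)
  expect_lt(abs(rc2$auc - 0.5), 0.05)

  # complement symmetry: AUC(s) + AUC(1 - s as positive score) = 1
  rc_flip <- roc(t2, cbind(s2, 1 - s2), 2, cls)
  expect_equal(rc2$auc + rc_flip$auc, 1, tolerance = 1e-12)

  # AUC invariant under strictly monotone score transforms
  rc3 <- roc(t2, cbind(1 - s2, exp(3 * s2)), 2, cls)
  expect_equal(rc3$auc, rc2$auc, tolerance = 1e-12)

  # independent oracle: pROC on the same data
  p_auc <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(t2 == "pos"), predictor = s2, quiet = TRUE,
    direction = "<")))
  expect_equal(rc2$auc, p_auc, tolerance = 1e-10)

  expect_error(roc(rep("pos", 10), cbind(runif(10), runif(10)), 2, cls),
               "single class")
})

test_that("model comparison flags the per-metric maxima", {
  mk <- function(v) structure(list(
    macro = setNames(v, c("accuracy", "sensitivity", "specificity",
                          "precision", "f1")),
    per_class = data.frame(), n_classes = 4), class = "metrics_report")
  tab <- compare_models(list(a = mk(rep(0.9, 5)), b = mk(rep(0.6, 5))))
  expect_true(all(unlist(tab[1, startsWith(names(tab), "best_")])))
  expect_false(any(unlist(tab[2, startsWith(names(tab), "best_")])))

  # seven-report table with an exhaustive argmax scan
  set.seed(6)
  reports <- lapply(1:7, function(i) mk(runif(5)))
  names(reports) <- channel_modes()
  tab7 <- compare_models(reports)
  expect_equal(nrow(tab7), 7)
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1"))
    expect_equal(tab7[[paste0("best_", m)]], tab7[[m]] == max(tab7[[m]]))
  expect_error(compare_models(reports[1]), "at least 2")
})
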