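#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred equal-length label vectors; every label must appear in
#'   `class_names`.
#' @param class_names ordered class names; fixes row/column order. Default
#'   class order for the ear study is normal, COM, OME, earwax.
#' @return object of class `"confusion_matrix"`: integer `c x c` matrix,
#'   rows = true class, columns = predicted class.
#' @export
confusion <- function(truth, pred, class_names) {
  stopifnot(length(truth) == length(pred))
  t_i <- match(as.character(truth), class_names)
  p_i <- match(as.character(pred), class_names)
  if (anyNA(t_i) || anyNA(p_i))
    stopf("labels outside class_names: %s",
          paste(unique(c(truth[is.na(t_i)], pred[is.na(p_i)])), collapse = ", "))
  c_n <- length(class_names)
  m <- matrix(0L, c_n, c_n, dimnames = list(truth = class_names,
                                            predicted = class_names))
  for (k in seq_along(t_i)) m[t_i[k], p_i[k]] <- m[t_i[k], p_i[k]] + 1L
  structure(m, class = c("confusion_matrix", class(m)))
}

#' One-vs-all binary outcomes per class
#'
#' Reduces a `c`-class confusion matrix to `c` binary problems: for class i,
#' `TP = m[i,i]`, `FN = rowSums(m)[i] - TP`, `FP = colSums(m)[i] - TP`,
#' `TN = total - TP - FN - FP`.
#'
#' @param cm a [confusion()] result (or plain square count matrix).
#' @return data.frame with columns `class`, `TP`, `TN`, `FP`, `FN`; every row
#'   sums to the total sample count.
#' @export
one_vs_all <- function(cm) {
  m <- unclass(cm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  total <- sum(m)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  data.frame(class = if (!is.null(rownames(m))) rownames(m)
             else as.character(seq_len(nrow(m))),
             TP = as.integer(tp), TN = as.integer(tn),
             FP = as.integer(fp), FN = as.integer(fn),
             row.names = NULL)
}

# One binary-metric block; zero denominators yield 0 with a warning flag.
binary_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  data.frame(
    accuracy = safe(tp + tn, total),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    f1 = {
      p <- safe(tp, tp + fp); r <- safe(tp, tp + fn)
      ifelse(p + r == 0, 0, 2 * p * r / (p + r))
    })
}

#' Macro-averaged one-vs-all metrics
#'
#' Macro accuracy, sensitivity (recall), specificity and precision are the
#' unweighted means over classes of the per-class binary formulas; the
#' headline F1 is the harmonic mean of macro precision and macro recall
#' (`2 p r / (p + r)`), with per-class F1 also reported. Per-class terms with
#' a zero denominator (class never predicted / never present) are defined as
#' 0 and flagged with a warning.
#'
#' @param bo a [one_vs_all()] data.frame (or a [confusion()] matrix, reduced
#'   internally).
#' @return object of class `"metrics_report"`: list with `macro` (named
#'   vector: accuracy, sensitivity, specificity, precision, f1),
#'   `per_class` (data.frame incl. per-class F1), `n_classes`.
#' @export
macro_metrics <- function(bo) {
  if (inherits(bo, "confusion_matrix") || is.matrix(bo)) bo <- one_vs_all(bo)
  if (any(bo$TP + bo$FP == 0) || any(bo$TP + bo$FN == 0))
    warning("zero-denominator per-class term(s) defined as 0", call. = FALSE)
  pc <- cbind(class = bo$class, binary_metrics(bo$TP, bo$TN, bo$FP, bo$FN))
  macro_p <- mean(pc$precision); macro_r <- mean(pc$sensitivity)
  macro <- c(accuracy = mean(pc$accuracy), sensitivity = macro_r,
             specificity = mean(pc$specificity), precision = macro_p,
             f1 = if (macro_p + macro_r == 0) 0
                  else 2 * macro_p * macro_r / (macro_p + macro_r))
  structure(list(macro = macro, per_class = pc, n_classes = nrow(bo)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Macro one-vs-all metrics (%):\n")
  print(round(100 * x$macro, 1))
  cat("Per class:\n")
  pc <- x$per_class
  pc[-1] <- round(100 * pc[-1], 1)
  print(pc)
  invisible(x)
}

#' One-vs-all ROC curve for one class
#'
#' Threshold sweep on the class-i predicted probability against the binarized
#' truth; AUC by the trapezoidal rule.
#'
#' @param truth label vector.
#' @param probs `n x c` probability matrix (rows sum to 1), columns ordered
#'   like `class_names`.
#' @param class_index positive class column.
#' @param class_names ordered class names.
#' @return object of class `"roc_curve"`: list with `fpr`, `tpr`,
#'   `thresholds` (all nondecreasing in sweep order), `auc`, `class`.
#' @export
roc <- function(truth, probs, class_index, class_names) {
  y <- as.integer(as.character(truth) == class_names[class_index])
  if (length(unique(y)) < 2)
    stopf("ROC undefined: truth contains a single class for '%s'",
          class_names[class_index])
  s <- probs[, class_index]
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # collapse tied scores: keep the last cumulative point of each tie group
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc,
                 class = class_names[class_index]), class = "roc_curve")
}

#' Evaluate a trained model on a labeled test set
#'
#' @param model a trained `cnn_model`.
#' @param images list of test images.
#' @param labels true labels.
#' @param class_names class order; defaults to the model's classes.
#' @return list with `confusion`, `metrics` (a [macro_metrics()] report) and
#'   `roc` (one [roc()] curve per class, skipped with NA AUC when a class is
#'   absent from the truth).
#' @export
evaluate_model <- function(model, images, labels, class_names = model$classes) {
  probs <- predict_proba(model, images)
  pred <- class_names[max.col(probs, ties.method = "first")]
  cm <- confusion(labels, pred, class_names)
  rocs <- lapply(seq_along(class_names), function(i) {
    if (length(unique(as.character(labels) == class_names[i])) < 2)
      return(list(auc = NA_real_, class = class_names[i]))
    roc(labels, probs, i, class_names)
  })
  list(confusion = cm, metrics = macro_metrics(cm), roc = rocs)
}

#' Compare metric reports across models
#'
#' @param reports named list of [macro_metrics()] reports (names = model /
#'   channel-mode identifiers).
#' @return data.frame: one row per model, macro metric columns, plus logical
#'   `best_*` flags marking the per-metric maxima.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) stopf("need at least 2 reports to compare")
  if (is.null(names(reports)))
    names(reports) <- paste0("model_", seq_along(reports))
  tab <- do.call(rbind, lapply(reports, function(r) as.data.frame(t(r$macro))))
  tab <- cbind(model = names(reports), tab, row.names = NULL)
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1"))
    tab[[paste0("best_", m)]] <- tab[[m]] == max(tab[[m]])
  tab
}
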