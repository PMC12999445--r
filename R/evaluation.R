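# Clinical evaluation layer: confusion-matrix metrics, ROC/AUC, stratified
# cross-validation folds, one-way ANOVA with Tukey HSD (delegated to the
# standard stats routines), and decision-curve analysis. Malignant is the
# positive class throughout.

#' Build a confusion matrix
#'
#' @param tp,fp,fn,tn nonnegative counts; `tp`/`fn` refer to the malignant
#'   (positive) class.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = as.numeric(tp), fp = as.numeric(fp),
              fn = as.numeric(fn), tn = as.numeric(tn))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("confusion counts must be nonnegative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from per-class correct counts
#'
#' Convenience constructor for the worked two-class example: given how many
#' benign and malignant lesions were classified correctly.
#'
#' @param n_benign,benign_correct benign totals and correct calls.
#' @param n_malignant,malignant_correct malignant totals and correct calls.
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' cm <- confusion_from_counts(160, 155, 40, 35)
#' cm$fn  # 5
confusion_from_counts <- function(n_benign, benign_correct,
                                  n_malignant, malignant_correct) {
  confusion_matrix(tp = malignant_correct,
                   fp = n_benign - benign_correct,
                   fn = n_malignant - malignant_correct,
                   tn = benign_correct)
}

#' Scalar metrics from a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return List with `accuracy`, `precision`, `recall`, `specificity` and
#'   `f1`. Metrics whose denominator is zero are returned as `NA` rather
#'   than raising an error.
#' @export
#' @examples
#' confusion_metrics(confusion_from_counts(160, 155, 40, 35))$recall  # 0.875
confusion_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop_domain("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(cm$tp, cm$tp + cm$fp)
  recall <- safe_div(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (cm$tp + cm$tn) / total,
       precision = precision,
       recall = recall,
       specificity = safe_div(cm$tn, cm$tn + cm$fp),
       f1 = f1)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; ties receive rank-average
#' (midpoint) handling, so the trapezoidal AUC equals the concordance
#' probability with half credit for tied scores.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (0/1 or logical), 1 = positive.
#' @return List with `roc_points` (data frame of fpr, tpr, ordered from
#'   (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_domain("length mismatch")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop_domain("both classes must be present to compute a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels == 1 & scores >= t) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0 & scores >= t) / nneg,
                numeric(1))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Net benefit at a threshold probability
#'
#' `sens * prev - (1 - spec) * (1 - prev) * thr / (1 - thr)`: the expected
#' clinical gain of acting on the model at threshold probability `thr`. The
#' treat-all reference is `net_benefit(1, 0, prev, thr)`; treat-none is 0.
#'
#' @param sens sensitivity in \[0,1\].
#' @param spec specificity in \[0,1\].
#' @param prevalence disease prevalence in (0,1).
#' @param threshold threshold probability in (0,1).
#' @return Scalar net benefit.
#' @export
#' @examples
#' net_benefit(1, 1, 0.2, 0.1)  # 0.2
net_benefit <- function(sens, spec, prevalence, threshold) {
  if (threshold >= 1 || threshold <= 0) {
    stop_domain("threshold must be in (0,1)")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop_domain("prevalence must be in (0,1)")
  }
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1) {
    stop_domain("sens/spec must be in [0,1]")
  }
  sens * prevalence -
    (1 - spec) * (1 - prevalence) * threshold / (1 - threshold)
}

#' Decision-curve analysis
#'
#' Sweeps threshold probabilities (default 0.01 to 0.30, step 0.01, the
#' clinically relevant screening range), classifies positive when the score
#' reaches the threshold, and reports the model net benefit against the
#' treat-all and treat-none references at the assumed prevalence.
#'
#' @param scores positive-class probabilities per sample.
#' @param labels binary labels, 1 = positive.
#' @param thresholds threshold-probability grid.
#' @param prevalence assumed disease prevalence (default 0.20).
#' @return A `dca_curve` data frame with threshold, net_benefit, treat_all
#'   and treat_none columns.
#' @export
dca_curve <- function(scores, labels, thresholds = seq(0.01, 0.30, by = 0.01),
                      prevalence = 0.2) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  rows <- lapply(thresholds, function(thr) {
    pred <- as.integer(scores >= thr)
    sens <- if (npos) sum(pred == 1 & labels == 1) / npos else 0
    spec <- if (nneg) sum(pred == 0 & labels == 0) / nneg else 0
    data.frame(threshold = thr,
               net_benefit = net_benefit(sens, spec, prevalence, thr),
               treat_all = net_benefit(1, 0, prevalence, thr),
               treat_none = 0)
  })
  structure(do.call(rbind, rows), class = c("dca_curve", "data.frame"))
}

#' Stratified k-fold index partition
#'
#' Shuffles each class independently (seeded) and deals indices round-robin,
#' so per-fold class counts differ from exact proportionality by at most 1
#' and the folds partition the index set.
#'
#' @param labels integer class labels.
#' @param k number of folds (>= 2).
#' @param seed shuffling seed.
#' @return List of `k` disjoint index vectors.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (k < 2) stop_domain("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    stop_domain("every class must have at least k members")
  }
  folds <- vector("list", k)
  with_seed(derive_seed(seed, 131L), {
    for (cls in names(counts)) {
      idx <- sample(which(labels == cls))
      for (j in seq_along(idx)) {
        f <- ((j - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[j])
      }
    }
  })
  lapply(folds, sort)
}

#' One-way ANOVA
#'
#' Classic between/within mean-square F ratio with p-value from the F
#' distribution (equal-variance one-way ANOVA via [stats::oneway.test()]).
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `p`, `df1`, `df2`; `F`/`p` are `NA` when the
#'   within-group variance is degenerate.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F  # 3
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop_domain("need >= 2 groups with >= 2 values each")
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0) {
    return(list(F = 0, p = 1,
                df1 = length(groups) - 1L,
                df2 = length(values) - length(groups)))
  }
  res <- tryCatch(stats::oneway.test(values ~ g, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    return(list(F = NA_real_, p = NA_real_,
                df1 = length(groups) - 1L,
                df2 = length(values) - length(groups)))
  }
  list(F = unname(res$statistic), p = unname(res$p.value),
       df1 = unname(res$parameter[1]), df2 = unname(res$parameter[2]))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based post-hoc comparisons after one-way ANOVA
#' (via [stats::TukeyHSD()]).
#'
#' @param groups list of numeric vectors; names label the groups.
#' @param alpha significance level for the `significant` flag.
#' @return Data frame with pair, diff, p_adj and significant columns.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop_domain("need >= 2 groups with >= 2 values each")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(values) == 0) {
    pairs <- utils::combn(names(groups), 2)
    return(data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                      diff = 0, p_adj = 1, significant = FALSE))
  }
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' Evaluate a trained model on a labelled test set
#'
#' Runs the greedy policy on every test item, aggregates the confusion
#' matrix (positive class = malignant), computes scalar metrics, the ROC
#' curve/AUC and the decision curve from the temperature-softmax
#' positive-class probabilities.
#'
#' @param model trained model.
#' @param test_set list of labelled items.
#' @param grid patch grid.
#' @param positive_class label treated as malignant/positive.
#' @param t_max navigation horizon.
#' @param tau softmax temperature.
#' @param dca_thresholds,dca_prevalence decision-curve settings.
#' @return List with `metrics`, `confusion`, `roc` (points + auc), `dca`,
#'   `predictions` data frame.
#' @export
evaluate_model <- function(model, test_set, grid = build_grid(),
                           positive_class = 2L, t_max = 16L, tau = 1.0,
                           dca_thresholds = seq(0.01, 0.30, by = 0.01),
                           dca_prevalence = 0.2) {
  if (length(test_set) == 0) stop("empty test set", call. = FALSE)
  n <- length(test_set)
  pred <- integer(n)
  score <- numeric(n)
  truth <- integer(n)
  steps <- integer(n)
  for (i in seq_len(n)) {
    out <- predict_lesion(model, test_set[[i]], grid = grid, t_max = t_max,
                          tau = tau)
    pred[i] <- out$class
    score[i] <- out$probs[positive_class]
    truth[i] <- item_label(test_set[[i]])
    steps[i] <- nrow(out$trajectory)
  }
  pos <- truth == positive_class
  cm <- confusion_matrix(tp = sum(pred == positive_class & pos),
                         fp = sum(pred == positive_class & !pos),
                         fn = sum(pred != positive_class & pos),
                         tn = sum(pred != positive_class & !pos))
  metrics <- confusion_metrics(cm)
  roc <- if (any(pos) && any(!pos)) roc_auc(score, pos) else NULL
  dca <- dca_curve(score, pos, thresholds = dca_thresholds,
                   prevalence = dca_prevalence)
  list(metrics = metrics, confusion = cm, roc = roc, dca = dca,
       predictions = data.frame(truth = truth, predicted = pred,
                                score = score, steps = steps))
}
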