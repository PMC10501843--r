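#' Confusion counts for binary labels
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels (positive = 1).
#' @return object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  stopifnot(length(pred) == length(truth),
            all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classification metrics in percent
#'
#' Accuracy, precision, recall and F1 from confusion counts, each on the
#' 0--100 scale.  A metric whose denominator is zero is returned as `NA`
#' (undefined) rather than raising an error.
#'
#' The benchmark's printed recall formula divides by TN + FN instead of
#' the standard TP + FN; `recall_literal = TRUE` reproduces that variant
#' for comparison, the default uses the standard definition.
#'
#' @param cc a [confusion_counts()].
#' @param recall_literal use TN + FN as the recall denominator.
#' @return named list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(cc, recall_literal = FALSE) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  if (total == 0) stop("no evaluated samples")
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  acc <- frac(cc$tp + cc$tn, total)
  prec <- frac(cc$tp, cc$tp + cc$fp)
  rec <- if (recall_literal) frac(cc$tp, cc$tn + cc$fn)
         else frac(cc$tp, cc$tp + cc$fn)
  f1 <- if (anyNA(c(prec, rec)) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Binary cross-entropy loss
#'
#' \eqn{-\frac{1}{m}\sum_i [t_i \log \hat o_i + (1 - t_i)\log(1 - \hat
#' o_i)]} with the raw outputs clipped into `[clip, 1 - clip]` first;
#' ELM outputs are unbounded and the logarithm is otherwise undefined.
#'
#' @param outputs numeric vector of raw model outputs.
#' @param targets 0/1 vector of the same length.
#' @param clip clipping margin (default `1e-7`).
#' @return scalar loss.
#' @export
bce_loss <- function(outputs, targets, clip = 1e-7) {
  stopifnot(length(outputs) == length(targets))
  o <- pmin(pmax(outputs, clip), 1 - clip)
  t <- as.numeric(targets)
  -mean(t * log(o) + (1 - t) * log(1 - o))
}

#' Stratified k-fold plan
#'
#' Seeded partition of the samples into k folds with per-class counts
#' differing by at most one from proportionality (each class is
#' shuffled, then dealt round-robin).
#'
#' @param targets 0/1 label vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return object of class `fold_plan`: list with `k`, `assignments`
#'   (integer fold index per sample) and `seed`.
#' @export
kfold <- function(targets, k = 5L, seed = 1L) {
  targets <- as.numeric(targets)
  stopifnot(k >= 2)
  counts <- table(targets)
  if (any(counts < k))
    stop("every class needs at least k members (smallest has ",
         min(counts), ")")
  assignments <- integer(length(targets))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(targets == as.numeric(cl)))
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Cross-validated ELM training and evaluation
#'
#' Stratified k-fold cross-validation of the SFP-trained ELM: for each
#' fold an ELM is trained on the remaining folds and evaluated on the
#' held-out one.  When `curves = TRUE`, the solver's iterate trace is
#' replayed against both splits to give per-iteration training and
#' validation loss (binary cross-entropy) and accuracy curves.
#'
#' @param data a [training_set()].
#' @param k number of folds.
#' @param seed seed controlling both the fold plan and the hidden-layer
#'   draw.
#' @param n_hidden hidden nodes of each fold's ELM.
#' @param constraint,gamma,method,config,standardize passed to
#'   [elm_train()].
#' @param threshold decision threshold.
#' @param curves record per-iteration learning curves.
#' @return object of class `cv_result`: per-fold metrics (`folds` data
#'   frame), unweighted `mean` metrics, metrics on `pooled` confusion
#'   counts, total confusion `counts`, mean iteration count and training
#'   time, and (optionally) a list of per-fold `curves` data frames
#'   (iteration, train_loss, val_loss, train_acc, val_acc).
#' @export
cross_validate <- function(data, k = 5L, seed = 1L, n_hidden = 160L,
                           constraint = "l2_ball", gamma = 17,
                           method = "imrcqm", config = solver_config(),
                           standardize = TRUE, threshold = 0.5,
                           curves = FALSE) {
  stopifnot(inherits(data, "training_set"))
  plan <- kfold(data$targets, k = k, seed = seed)
  fold_rows <- vector("list", k)
  curve_list <- if (curves) vector("list", k) else NULL
  agg <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  per_fold_cc <- vector("list", k)

  for (fold in seq_len(k)) {
    te <- plan$assignments == fold
    Xtr <- data$features[!te, , drop = FALSE]
    ytr <- data$targets[!te]
    Xte <- data$features[te, , drop = FALSE]
    yte <- data$targets[te]

    t0 <- proc.time()[["elapsed"]]
    model <- elm_model(ncol(Xtr), n_hidden = n_hidden, seed = seed + fold)
    model <- elm_train(model, Xtr, ytr, constraint = constraint,
                       gamma = gamma, method = method, config = config,
                       standardize = standardize, store_iterates = curves)
    elapsed <- proc.time()[["elapsed"]] - t0

    pred <- predict(model, Xte, threshold = threshold)
    cc <- confusion_counts(pred, yte)
    per_fold_cc[[fold]] <- cc
    for (f in names(agg)) agg[[f]] <- agg[[f]] + cc[[f]]
    met <- classification_metrics(cc)
    fold_rows[[fold]] <- data.frame(
      fold = fold, iterations = model$run$n_iter, time = elapsed,
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1)

    if (curves) {
      sc <- model$scaling
      scale_mat <- function(X) {
        if (is.null(sc)) X
        else sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
      }
      Htr <- hidden_matrix_raw(model, scale_mat(Xtr))
      Hte <- hidden_matrix_raw(model, scale_mat(Xte))
      W <- model$run$iterates               # n_iter x M
      Otr <- Htr %*% t(W)                   # N_tr x n_iter
      Ote <- Hte %*% t(W)
      curve_list[[fold]] <- data.frame(
        iteration = seq_len(nrow(W)),
        train_loss = apply(Otr, 2L, bce_loss, targets = ytr),
        val_loss = apply(Ote, 2L, bce_loss, targets = yte),
        train_acc = colMeans((Otr >= threshold) == (ytr == 1)) * 100,
        val_acc = colMeans((Ote >= threshold) == (yte == 1)) * 100)
    }
  }

  folds <- do.call(rbind, fold_rows)
  pooled_cc <- structure(agg, class = "confusion_counts")
  structure(
    list(folds = folds,
         mean = lapply(folds[c("accuracy", "precision", "recall", "f1")],
                       mean),
         pooled = classification_metrics(pooled_cc),
         counts = pooled_cc,
         per_fold_counts = per_fold_cc,
         mean_iterations = mean(folds$iterations),
         mean_time = mean(folds$time),
         plan = plan, curves = curve_list),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds, mean %.0f iterations\n", nrow(x$folds),
    x$mean_iterations))
  cat(sprintf(
    "  mean accuracy %.2f  precision %.2f  recall %.2f  F1 %.2f\n",
    x$mean$accuracy, x$mean$precision, x$mean$recall, x$mean$f1))
  invisible(x)
}
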