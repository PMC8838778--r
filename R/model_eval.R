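## Age binning, the eight classifiers, cross-validated evaluation with
## accuracy / sensitivity / specificity, and Bonferroni-corrected paired
## t-tests between classifiers.

#' Age-group binning scheme
#'
#' Ages are grouped into contiguous half-open bins of `width` years anchored
#' at `start`: the label of age `a` is `floor((a - start) / width)`.
#'
#' @param start,end Age range in years covered by the corpus.
#' @param width Bin width in years (the study grid is 1, 2, 3, 4, 5, 10).
#' @return An `age_binning` list.
#' @export
age_binning <- function(start = 17, end = 67, width = 5) {
  if (start >= end) stop("`start` must be below `end`")
  if (width <= 0) stop("`width` must be positive")
  structure(list(start = start, end = end, width = width),
            class = "age_binning")
}

#' Bin ages into group labels
#'
#' @param ages Numeric ages in years, all within `[start, end]`.
#' @param binning An [age_binning()].
#' @return Integer labels starting at 0.
#' @export
bin_ages <- function(ages, binning = age_binning()) {
  bad <- ages < binning$start | ages > binning$end
  if (any(bad))
    stop("age(s) outside [", binning$start, ", ", binning$end, "]: ",
         paste(ages[bad], collapse = ", "))
  as.integer(floor((ages - binning$start) / binning$width))
}

#' Confusion matrix of true vs predicted labels
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Optional common level set.
#' @return Square counts matrix, rows = truth, columns = predictions.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(truth, pred)))
  unclass(base::table(factor(truth, levels = levels),
                      factor(pred, levels = levels)))
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Accuracy is the trace over the total. For two classes the first class is
#' taken as positive and the literal binary definitions apply
#' (`TP/(TP+FN)`, `TN/(TN+FP)`). For more classes, sensitivity and
#' specificity are computed one-vs-rest per class and macro-averaged over
#' classes present in the truth.
#'
#' @param cm Square confusion matrix (rows = truth).
#' @return Named vector `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  if (nrow(cm) == 2L) {
    sens <- cm[1, 1] / sum(cm[1, ])
    spec <- cm[2, 2] / sum(cm[2, ])
  } else {
    rs <- rowSums(cm); cs <- colSums(cm); d <- diag(cm)
    present <- rs > 0
    sens <- mean(d[present] / rs[present])
    spec <- mean(((total - rs - cs + d) / (total - rs))[present])
  }
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Names of the eight supported classifiers
#' @return Character vector.
#' @export
classifier_names <- function() {
  c("knn", "csvc", "rf", "dt", "nb", "lr", "lda", "qda")
}

## Shrinkage-regularised Gaussian quadratic discriminant analysis.
## Each class covariance is shrunk toward a scaled identity,
## (1 - reg) * S_k + reg * mean(diag(S_k)) * I, so classes with fewer
## samples than features still yield a proper density.
qda_shrink <- function(x, y, reg = 0.1) {
  y <- factor(y)
  p <- ncol(x)
  fits <- lapply(levels(y), function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    S <- if (nrow(xi) > 1) cov(xi) else matrix(0, p, p)
    tbar <- mean(diag(S))
    if (!is.finite(tbar) || tbar <= 0) tbar <- 1
    Sk <- (1 - reg) * S + reg * tbar * diag(p)
    R <- chol(Sk)
    list(mu = mu, R = R, logdet = 2 * sum(log(diag(R))),
         logprior = log(mean(y == cl)))
  })
  structure(list(fits = fits, levels = levels(y)), class = "qda_shrink")
}

#' @export
predict.qda_shrink <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- vapply(object$fits, function(f) {
    d <- sweep(newdata, 2, f$mu)
    z <- backsolve(f$R, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * f$logdet + f$logprior
  }, numeric(nrow(newdata)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

## Fit one classifier on (xtr, ytr) and predict labels for xte.
## Features are already standardised; hyperparameters are the canonical
## defaults (RF uses 300 trees).
fit_predict <- function(name, xtr, ytr, xte) {
  ytr <- factor(ytr)
  dtr <- data.frame(xtr); dte <- data.frame(xte)
  names(dte) <- names(dtr)
  pred <- switch(name,
    knn = class::knn(xtr, xte, ytr, k = 5),
    csvc = predict(e1071::svm(xtr, ytr, type = "C-classification",
                              kernel = "radial", cost = 1, scale = FALSE),
                   xte),
    rf = predict(randomForest::randomForest(xtr, ytr, ntree = 300), xte),
    dt = {
      dtr$.y <- ytr
      m <- rpart::rpart(.y ~ ., dtr, method = "class")
      cl <- predict(m, dte, type = "class")
      factor(as.character(cl), levels = levels(ytr))
    },
    nb = predict(e1071::naiveBayes(xtr, ytr), dte),
    lr = {
      dtr$.y <- ytr
      m <- nnet::multinom(.y ~ ., dtr, trace = FALSE, MaxNWts = 20000,
                          decay = 1e-4, maxit = 200)
      factor(as.character(predict(m, dte)), levels = levels(ytr))
    },
    lda = predict(suppressWarnings(MASS::lda(xtr, ytr)), xte)$class,
    qda = predict(qda_shrink(xtr, ytr), xte),
    stop("unknown classifier: ", name, " (supported: ",
         paste(classifier_names(), collapse = ", "), ")")
  )
  factor(as.character(pred), levels = levels(ytr))
}

## Stratified fold assignment: within each class, shuffled indices are
## dealt round-robin over k folds. Depends only on (labels, k, seed), so
## different classifiers evaluated at the same seed share folds (paired).
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(as.character(labels)))) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## Standardise by train-fold statistics, dropping zero-variance columns.
standardize_pair <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sds <- apply(xtr, 2, sd)
  keep <- sds > 0
  list(tr = scale(xtr[, keep, drop = FALSE], mu[keep], sds[keep]),
       te = scale(xte[, keep, drop = FALSE], mu[keep], sds[keep]))
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation (k reduced to the smallest class size
#' when needed) with per-fold feature standardisation. By default SMOTE is
#' applied inside each training fold only, so no synthetic sample ever
#' derives from a test row; with `paper_mode = TRUE` the whole table is
#' balanced before splitting (corpus-level balancing, which leaks
#' neighbourhood information into the test folds and inflates metrics —
#' both modes are first-class and recorded in the result).
#'
#' @param table A `feature_table` (or data frame of feature columns).
#' @param labels Class label per row (e.g. from [bin_ages()]).
#' @param classifier One of [classifier_names()].
#' @param k Number of folds (default 10).
#' @param seed Experiment seed driving fold shuffling, SMOTE and the
#'   stochastic classifiers.
#' @param paper_mode Logical; `TRUE` balances the corpus before splitting.
#' @param smote Logical; apply SMOTE at all.
#' @param smote_k SMOTE neighbour count.
#' @return An `eval_result`: `classifier`, pooled `accuracy`,
#'   `sensitivity`, `specificity`, `per_fold` data frame, `folds`
#'   assignment and `config`.
#' @export
train_eval <- function(table, labels, classifier, k = 10L, seed = 1L,
                       paper_mode = FALSE, smote = TRUE, smote_k = 5L) {
  classifier <- match.arg(classifier, classifier_names())
  labels <- as.character(labels)
  counts <- base::table(labels)
  if (length(counts) < 2) stop("need at least 2 classes")
  if (any(counts < 2))
    stop("class(es) with a single member: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         "; consider a wider age-bin width")
  if (smote && paper_mode) {
    sm <- smote_balance(table, labels, k = smote_k, seed = seed)
    table <- sm$table
    labels <- sm$labels
    counts <- base::table(labels)
  }
  k_eff <- min(k, min(counts))
  folds <- stratified_folds(labels, k_eff, seed)
  cols <- feature_columns(table)
  X <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  levs <- sort(unique(labels))
  cm_total <- matrix(0, length(levs), length(levs),
                     dimnames = list(levs, levs))
  per_fold <- vector("list", k_eff)
  for (f in seq_len(k_eff)) {
    tr <- folds != f; te <- !tr
    xtr <- X[tr, , drop = FALSE]; ytr <- labels[tr]
    if (smote && !paper_mode) {
      dtr <- as.data.frame(xtr)
      sm <- smote_balance(dtr, ytr, k = smote_k, seed = seed + f)
      xtr <- as.matrix(sm$table); ytr <- sm$labels
    }
    sp <- standardize_pair(xtr, X[te, , drop = FALSE])
    pred <- with_seed(seed + 1000L * f,
                      fit_predict(classifier, sp$tr, factor(ytr, levs),
                                  sp$te))
    cm <- confusion_matrix(labels[te], as.character(pred), levels = levs)
    cm_total <- cm_total + cm
    per_fold[[f]] <- data.frame(fold = f, t(confusion_metrics(cm)))
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(classifier = classifier,
                 accuracy = unname(confusion_metrics(cm_total)["accuracy"]),
                 sensitivity = unname(confusion_metrics(cm_total)["sensitivity"]),
                 specificity = unname(confusion_metrics(cm_total)["specificity"]),
                 per_fold = per_fold, folds = folds,
                 confusion = cm_total,
                 config = list(k = k_eff, seed = seed,
                               paper_mode = paper_mode, smote = smote,
                               smote_k = smote_k)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval: %s | acc %.3f sens %.3f spec %.3f | %d folds%s>\n",
              x$classifier, x$accuracy, x$sensitivity, x$specificity,
              x$config$k,
              if (isTRUE(x$config$paper_mode)) ", corpus-level SMOTE" else ""))
  invisible(x)
}

#' Pairwise significance of classifier differences
#'
#' Two-sided paired Student t-tests on fold-wise accuracies for every pair
#' of results, with Bonferroni correction: a pair is flagged significant
#' when `p < alpha / n_pairs`. All results must share the same fold
#' partition. Zero-variance differences are handled exactly: identical
#' fold accuracies give `p = 1`, a constant non-zero difference `p = 0`.
#'
#' @param results List of `eval_result` objects (or lists carrying
#'   `classifier`, `per_fold$accuracy` and `folds`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `p_values` (symmetric matrix), `significant` (logical
#'   matrix) and `alpha_corrected`.
#' @export
compare_classifiers <- function(results, alpha = 0.05) {
  n <- length(results)
  if (n < 2) stop("need at least two results to compare")
  accs <- lapply(results, function(r) r$per_fold$accuracy)
  if (length(unique(vapply(accs, length, 0L))) != 1)
    stop("results have mismatched fold counts; pairing impossible")
  folds0 <- results[[1]]$folds
  for (r in results[-1])
    if (!is.null(r$folds) && !identical(r$folds, folds0))
      stop("results were evaluated on different fold partitions")
  nms <- vapply(results, function(r) r$classifier, "")
  p <- matrix(1, n, n, dimnames = list(nms, nms))
  n_pairs <- n * (n - 1) / 2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- accs[[i]] - accs[[j]]
      pv <- if (all(d == 0)) 1
            else if (sd(d) == 0) 0
            else t.test(accs[[i]], accs[[j]], paired = TRUE)$p.value
      p[i, j] <- p[j, i] <- pv
    }
  }
  list(p_values = p, significant = p < alpha / n_pairs,
       alpha_corrected = alpha / n_pairs)
}

#' Full evaluation grid over bin widths and classifiers
#'
#' Prescreens the feature table once (correlation filter then PCA
#' selection — both age-blind), then for every bin width bins the ages and
#' cross-validates every classifier, and finally compares the classifiers
#' within each width with Bonferroni-corrected paired t-tests.
#'
#' @param table A `feature_table` with an `age` column.
#' @param widths Bin widths in years (default the study grid
#'   `c(1, 2, 3, 4, 5, 10)`).
#' @param classifiers Subset of [classifier_names()].
#' @param binning_start,binning_end Age range of the binning.
#' @param k,seed,paper_mode,smote,smote_k Passed to [train_eval()].
#' @param cor_threshold,evr_target Passed to [prescreen()].
#' @return An `experiment_report`: `report` data frame (one row per width x
#'   classifier), `significance` (per-width output of
#'   [compare_classifiers()]), `prescreen` report and `config`.
#' @export
run_experiment <- function(table, widths = c(1, 2, 3, 4, 5, 10),
                           classifiers = classifier_names(),
                           binning_start = 17, binning_end = 67,
                           k = 10L, seed = 1L, paper_mode = FALSE,
                           smote = TRUE, smote_k = 5L,
                           cor_threshold = 0.9, evr_target = 0.999) {
  if (!"age" %in% names(table)) stop("feature table lacks an `age` column")
  ps <- prescreen(table, cor_threshold, evr_target)
  rows <- list(); sig <- list()
  for (w in widths) {
    labels <- bin_ages(table$age, age_binning(binning_start, binning_end, w))
    res <- lapply(classifiers, function(cl)
      train_eval(ps$table, labels, cl, k = k, seed = seed,
                 paper_mode = paper_mode, smote = smote, smote_k = smote_k))
    for (r in res)
      rows[[length(rows) + 1L]] <-
        data.frame(width = w, classifier = r$classifier,
                   accuracy = r$accuracy, sensitivity = r$sensitivity,
                   specificity = r$specificity, n_folds = r$config$k,
                   seed = seed,
                   smote_mode = if (!smote) "none"
                                else if (paper_mode) "corpus" else "fold")
    if (length(res) >= 2)
      sig[[as.character(w)]] <- compare_classifiers(res)
  }
  structure(list(report = do.call(rbind, rows), significance = sig,
                 prescreen = ps$report,
                 config = list(widths = widths, classifiers = classifiers,
                               k = k, seed = seed, paper_mode = paper_mode,
                               smote = smote, smote_k = smote_k)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report (", nrow(x$report), " width x classifier cells)\n",
      sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}
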