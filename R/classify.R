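# LPR detection (SVM, balanced 10-fold CV) and severity grading (BPNN,
# stratified 10-fold CV against RSI-derived classes).
#
# No SVM implementation ships with the supported environment, so a compact
# sequential-minimal-optimization (SMO) solver is included: soft-margin
# C-SVM with an RBF kernel whose bandwidth defaults to the median pairwise
# distance heuristic. The second multiplier is chosen by the maximal
# |E_i - E_j| heuristic rather than at random, which makes training fully
# deterministic. The severity classifier is a 5-4-3 sigmoid network trained
# by batch gradient descent with momentum, matching the published
# hyperparameters (1000 cycles, learning rate 0.65, momentum 0.5).
#
# Note on conventions: the positive class is "non-LPR" (the clinical study
# defines non-LPR samples as positives), so sensitivity here is the
# non-LPR detection rate. This is the opposite of the usual disease-
# positive convention; see compute_metrics().

#' Balance a two-class sample 1:1
#'
#' Randomly downsamples the majority class (without replacement) to the
#' minority class size; recommended before K = 10 cross-validation on
#' unbalanced cohorts.
#'
#' @param features data.frame/matrix of features.
#' @param labels two-class labels.
#' @param seed RNG seed.
#' @return list with `features`, `labels` and the kept `indices`.
#' @export
balanced_subsample <- function(features, labels, seed = 1) {
  labels <- as.factor(labels)
  tab <- table(droplevels(labels))
  if (length(tab) != 2 || any(tab == 0))
    lq_stop("balanced_subsample needs two non-empty classes")
  m <- min(tab)
  idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      i <- which(labels == cl)
      if (length(i) > m) sort(sample(i, m)) else i
    }))
  })
  idx <- sort(idx)
  list(features = features[idx, , drop = FALSE], labels = labels[idx],
       indices = idx)
}

#' Confusion counts and derived classification metrics
#'
#' Accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN), false positive rate
#' = FP/(FP+TN), all as percentages. The positive class defaults to
#' "non-LPR" following the clinical convention that non-LPR samples are
#' positives; pass `positive` explicitly for other label schemes.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive the label treated as positive.
#' @return object of class `lq_metrics`: list with TP, TN, FP, FN,
#'   accuracy, sensitivity, false_positive_rate.
#' @export
compute_metrics <- function(predicted, truth, positive = "non-LPR") {
  if (length(predicted) != length(truth))
    lq_stop("predicted and truth must have equal length")
  p_pos <- predicted == positive
  t_pos <- truth == positive
  tp <- sum(p_pos & t_pos); tn <- sum(!p_pos & !t_pos)
  fp <- sum(p_pos & !t_pos); fn <- sum(!p_pos & t_pos)
  structure(list(
    TP = tp, TN = tn, FP = fp, FN = fn,
    accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    false_positive_rate = if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_
  ), class = "lq_metrics")
}

#' @export
print.lq_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  FPR %.2f%%  (TP %d TN %d FP %d FN %d)\n",
              x$accuracy, x$sensitivity, x$false_positive_rate,
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

rbf_kernel <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Train a soft-margin RBF SVM by SMO
#'
#' @param x numeric matrix (n x d); standardized internally.
#' @param y two-class labels.
#' @param positive label mapped to +1.
#' @param C box constraint (default 1).
#' @param sigma RBF bandwidth; NULL uses the median pairwise distance.
#' @param tol KKT violation tolerance.
#' @param max_passes sweeps without changes before stopping.
#' @return object of class `lq_svm`.
#' @export
svm_train <- function(x, y, positive = "non-LPR", C = 1, sigma = NULL,
                      tol = 1e-3, max_passes = 10L) {
  x <- as.matrix(x)
  yv <- ifelse(y == positive, 1, -1)
  if (length(unique(yv)) != 2) lq_stop("svm_train needs both classes present")
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center, scale_)
  if (is.null(sigma)) {
    d <- as.vector(stats::dist(xs))
    d <- d[d > 0]
    sigma <- if (length(d)) stats::median(d) else 1
  }
  n <- nrow(xs)
  K <- rbf_kernel(xs, xs, sigma)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  sweeps <- 0L
  fcache <- function() as.vector(K %*% (alpha * yv)) + b
  while (passes < max_passes && sweeps < 200L) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- sum(K[, i] * alpha * yv) + b - yv[i]
      if ((yv[i] * Ei < -tol && alpha[i] < C) ||
          (yv[i] * Ei > tol && alpha[i] > 0)) {
        # second-choice heuristic with fallback: walk candidate j's in
        # decreasing |E_i - E_j| until one admits a productive step
        E <- fcache() - yv
        for (j in setdiff(order(-abs(E - Ei)), i)) {
          Ej <- E[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (yv[i] != yv[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- clamp(aj_old - yv[j] * (Ei - Ej) / eta, L, H)
          if (abs(aj - aj_old) < 1e-5) next
          ai <- ai_old + yv[i] * yv[j] * (aj_old - aj)
          alpha[i] <- ai; alpha[j] <- aj
          b1 <- b - Ei - yv[i] * (ai - ai_old) * K[i, i] -
            yv[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - yv[i] * (ai - ai_old) * K[i, j] -
            yv[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
          changed <- changed + 1L
          break
        }
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    sweeps <- sweeps + 1L
  }
  sv <- alpha > 1e-8
  structure(list(x = xs[sv, , drop = FALSE], coef = (alpha * yv)[sv], b = b,
                 sigma = sigma, C = C, center = center, scale = scale_,
                 positive = positive,
                 negative = setdiff(unique(as.character(y)), positive)[1]),
            class = "lq_svm")
}

#' @export
predict.lq_svm <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  f <- as.vector(rbf_kernel(xs, object$x, object$sigma) %*% object$coef) + object$b
  ifelse(f > 0, object$positive, object$negative)
}

#' K-fold cross-validated SVM metrics
#'
#' Seeded shuffled k-fold split; each fold is evaluated with a model
#' trained on the remaining folds (features standardized with training-fold
#' statistics only) and the per-fold metrics are averaged.
#'
#' @param features data.frame/matrix (use the five selected features for
#'   the canonical pipeline).
#' @param labels two-class labels.
#' @param k fold count (default 10).
#' @param seed RNG seed for the split.
#' @param positive positive label (see [compute_metrics()]).
#' @param ... passed to [svm_train()].
#' @return list with `accuracy`, `sensitivity`, `false_positive_rate`
#'   (means over folds, %), `per_fold` data.frame and summed `confusion`.
#' @export
svm_cv <- function(features, labels, k = 10L, seed = 1, positive = "non-LPR", ...) {
  x <- as.matrix(features)
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    lq_stop(sprintf("each class needs at least k = %d samples", k))
  n <- nrow(x)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  rows <- vector("list", k)
  conf <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2) next
    fit <- svm_train(x[tr, , drop = FALSE], labels[tr], positive = positive, ...)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    m <- compute_metrics(pred, as.character(labels[!tr]), positive = positive)
    conf <- conf + c(TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN)
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            sensitivity = m$sensitivity,
                            false_positive_rate = m$false_positive_rate)
  }
  per_fold <- do.call(rbind, rows)
  list(accuracy = mean(per_fold$accuracy, na.rm = TRUE),
       sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
       false_positive_rate = mean(per_fold$false_positive_rate, na.rm = TRUE),
       per_fold = per_fold, confusion = conf)
}

#' Severity classifier configuration
#'
#' RSI bins: 13-20 primary, 21-30 intermediate, 31-45 severe. Network:
#' 5 input units, one hidden layer of 4 sigmoid units, 3 output units;
#' 1000 training cycles, learning rate 0.65, momentum 0.5.
#'
#' @param epochs training cycles.
#' @param learning_rate gradient step size.
#' @param momentum momentum factor in \[0, 1).
#' @param hidden hidden unit count.
#' @param seed RNG seed for the uniform \[-0.5, 0.5\] weight init.
#' @return object of class `lq_severity_config`.
#' @export
severity_config <- function(epochs = 1000L, learning_rate = 0.65,
                            momentum = 0.5, hidden = 4L, seed = 1) {
  if (epochs < 1) lq_stop("epochs must be >= 1")
  if (learning_rate <= 0) lq_stop("learning_rate must be > 0")
  if (momentum < 0 || momentum >= 1) lq_stop("momentum must be in [0, 1)")
  structure(list(
    bins = list(primary = c(13L, 20L), intermediate = c(21L, 30L),
                severe = c(31L, 45L)),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    momentum = momentum, hidden = as.integer(hidden), seed = seed
  ), class = "lq_severity_config")
}

#' Map an RSI score to its severity grade
#'
#' 13-20 primary, 21-30 intermediate, 31-45 severe. Scores outside
#' \[13, 45\] (i.e. below the LPR inclusion rule) raise an out-of-range
#' error.
#'
#' @param rsi integer vector of reflux symptom index scores.
#' @return factor with levels primary/intermediate/severe.
#' @export
rsi_to_severity <- function(rsi) {
  if (any(rsi < 13 | rsi > 45))
    lq_stop("RSI out of range [13, 45]", "lq_out_of_range")
  lv <- c("primary", "intermediate", "severe")
  factor(lv[findInterval(rsi, c(13, 21, 31))], levels = lv, ordered = TRUE)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the severity back-propagation network
#'
#' Fully connected 5-`hidden`-3 network with sigmoid activations and
#' one-hot targets, trained for exactly `epochs` cycles of batch gradient
#' descent with momentum on the mean squared error. Inputs are
#' standardized with training statistics; weights initialize uniformly in
#' \[-0.5, 0.5\] from the configured seed, so training is deterministic.
#'
#' @param features data.frame/matrix (n x 5 for the canonical pipeline).
#' @param severity factor of class labels (each class present).
#' @param config [severity_config()].
#' @return object of class `lq_bpnn` with a `loss` trace.
#' @export
bpnn_train <- function(features, severity, config = severity_config()) {
  x <- as.matrix(features)
  severity <- as.factor(severity)
  if (any(table(severity) == 0) || nlevels(severity) < 2)
    lq_stop("every severity class needs at least one sample")
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center, scale_)
  n <- nrow(xs); d <- ncol(xs)
  L <- nlevels(severity)
  tgt <- matrix(0, n, L)
  tgt[cbind(seq_len(n), as.integer(severity))] <- 1
  h <- config$hidden
  init <- with_seed(config$seed, stats::runif((d + 1) * h + (h + 1) * L, -0.5, 0.5))
  W1 <- matrix(init[seq_len(d * h)], h, d)
  b1 <- init[d * h + seq_len(h)]
  W2 <- matrix(init[(d + 1) * h + seq_len(h * L)], L, h)
  b2 <- init[(d + 1) * h + h * L + seq_len(L)]
  vW1 <- matrix(0, h, d); vb1 <- numeric(h)
  vW2 <- matrix(0, L, h); vb2 <- numeric(L)
  lr <- config$learning_rate; mom <- config$momentum
  loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    H <- sigmoid(sweep(xs %*% t(W1), 2, b1, "+"))
    O <- sigmoid(sweep(H %*% t(W2), 2, b2, "+"))
    E <- O - tgt
    loss[ep] <- 0.5 * mean(rowSums(E^2))
    d2 <- E * O * (1 - O)
    d1 <- (d2 %*% W2) * H * (1 - H)
    vW2 <- mom * vW2 - lr * crossprod(d2, H) / n
    vb2 <- mom * vb2 - lr * colMeans(d2)
    vW1 <- mom * vW1 - lr * crossprod(d1, xs) / n
    vb1 <- mom * vb1 - lr * colMeans(d1)
    W2 <- W2 + vW2; b2 <- b2 + vb2
    W1 <- W1 + vW1; b1 <- b1 + vb1
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = center, scale = scale_,
                 levels = levels(severity), loss = loss, config = config),
            class = "lq_bpnn")
}

#' @export
predict.lq_bpnn <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  H <- sigmoid(sweep(xs %*% t(object$W1), 2, object$b1, "+"))
  O <- sigmoid(sweep(H %*% t(object$W2), 2, object$b2, "+"))
  factor(object$levels[max.col(O, ties.method = "first")],
         levels = object$levels, ordered = TRUE)
}

#' Stratified k-fold cross-validation of the severity network
#'
#' Folds preserve class proportions (per-class shuffled round-robin
#' assignment); classes smaller than k simply appear in fewer folds.
#' Returns the per-fold accuracies and their mean, in percent.
#'
#' @param features data.frame/matrix.
#' @param severity factor of class labels (each class >= 2 samples).
#' @param config [severity_config()]; its seed drives the fold split.
#' @param k fold count.
#' @return list with `per_fold` (numeric vector, %) and `accuracy` (mean %).
#' @export
stratified_cv <- function(features, severity, config = severity_config(), k = 10L) {
  x <- as.matrix(features)
  severity <- as.factor(severity)
  if (any(table(severity) < 2))
    lq_stop("each severity class needs at least 2 samples")
  fold <- integer(nrow(x))
  fold <- with_seed(config$seed, {
    for (cl in levels(severity)) {
      i <- which(severity == cl)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    fold
  })
  acc <- numeric(0)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (all(tr) || !any(tr)) next
    fit <- bpnn_train(x[tr, , drop = FALSE], droplevels(severity[tr]), config)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    acc <- c(acc, 100 * mean(as.character(pred) == as.character(severity[!tr])))
  }
  list(per_fold = acc, accuracy = mean(acc))
}
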