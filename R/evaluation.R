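#' Train a linear support vector machine
#'
#' Soft-margin C-SVC with a linear kernel, solved in the dual by sequential
#' minimal optimisation with maximal-violating-pair working-set selection.
#' The solver is deterministic for a given input and tolerance.  The
#' default regularization constant is `10^-3.5`, a deliberately small value
#' that trades margin violations for a large margin to avoid overfitting.
#'
#' @param table a scaled feature table ([scale_features()]) or a plain
#'   numeric matrix.
#' @param labels two-class label vector (default: the table's `condition`
#'   column).
#' @param C regularization constant (> 0).
#' @param positive_class label mapped to +1 (default `"Target"`; decision
#'   scores are positive on this side).
#' @param tol KKT violation tolerance (default 1e-6).
#' @return An object of class `bna_svm`: feature `weights`, `bias`, `C`,
#'   `alpha`, support-vector indices and label mapping.
#' @export
train_svm <- function(table, labels = NULL, C = 10^-3.5,
                      positive_class = "Target", tol = 1e-6) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$condition
    X <- as.matrix(table[feature_columns(table)])
  } else {
    X <- as.matrix(table)
    if (is.null(labels)) bna_stop("bna_missing_labels", "labels are required")
  }
  stopifnot(C > 0)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    bna_stop("bna_single_class",
             sprintf("need exactly 2 classes, got %d", length(lev)))
  if (!positive_class %in% lev) positive_class <- lev[1]
  negative_class <- setdiff(lev, positive_class)
  y <- ifelse(labels == positive_class, 1, -1)
  n <- nrow(X)
  K <- X %*% t(X)
  alpha <- numeric(n)
  Fv <- -y                                    # F_i = sum_j a_j y_j K_ij - y_i
  max_pass <- 100000L
  for (it in seq_len(max_pass)) {
    i_up_set <- (y > 0 & alpha < C - 1e-15) | (y < 0 & alpha > 1e-15)
    i_lo_set <- (y > 0 & alpha > 1e-15) | (y < 0 & alpha < C - 1e-15)
    if (!any(i_up_set) || !any(i_lo_set)) break
    iu <- which(i_up_set)[which.min(Fv[i_up_set])]
    il <- which(i_lo_set)[which.max(Fv[i_lo_set])]
    if (Fv[il] - Fv[iu] < 2 * tol) break
    i1 <- iu; i2 <- il
    eta <- K[i1, i1] + K[i2, i2] - 2 * K[i1, i2]
    eta <- max(eta, 1e-12)
    a2_old <- alpha[i2]; a1_old <- alpha[i1]
    a2 <- a2_old + y[i2] * (Fv[i1] - Fv[i2]) / eta
    if (y[i1] != y[i2]) {
      L <- max(0, a2_old - a1_old); H <- min(C, C + a2_old - a1_old)
    } else {
      L <- max(0, a1_old + a2_old - C); H <- min(C, a1_old + a2_old)
    }
    a2 <- min(max(a2, L), H)
    a1 <- a1_old + y[i1] * y[i2] * (a2_old - a2)
    if (abs(a2 - a2_old) < 1e-16) break
    alpha[i1] <- a1; alpha[i2] <- a2
    Fv <- Fv + y[i1] * (a1 - a1_old) * K[, i1] +
      y[i2] * (a2 - a2_old) * K[, i2]
  }
  i_up_set <- (y > 0 & alpha < C - 1e-15) | (y < 0 & alpha > 1e-15)
  i_lo_set <- (y > 0 & alpha > 1e-15) | (y < 0 & alpha < C - 1e-15)
  b_up <- if (any(i_up_set)) min(Fv[i_up_set]) else 0
  b_lo <- if (any(i_lo_set)) max(Fv[i_lo_set]) else 0
  bias <- -(b_up + b_lo) / 2
  w <- drop(t(X) %*% (alpha * y))
  names(w) <- colnames(X)
  structure(list(weights = w, bias = bias, C = C, alpha = alpha,
                 support = which(alpha > 1e-12),
                 positive_class = positive_class,
                 negative_class = negative_class,
                 n_train = n),
            class = "bna_svm")
}

#' @export
print.bna_svm <- function(x, ...) {
  cat(sprintf("<bna_svm> %d features, C = %.4g, %d support vectors (+: %s)\n",
              length(x$weights), x$C, length(x$support), x$positive_class))
  invisible(x)
}

#' Signed distances to the separating plane
#'
#' @param model a [train_svm()] result.
#' @param table feature table or numeric matrix; columns are aligned to the
#'   training features by name.
#' @return numeric vector, positive on the `positive_class` side.
#' @export
decision_scores <- function(model, table) {
  X <- if (is.data.frame(table)) as.matrix(table[feature_columns(table)])
  else as.matrix(table)
  need <- names(model$weights)
  if (!is.null(colnames(X))) {
    if (!all(need %in% colnames(X)))
      bna_stop("bna_missing_columns",
               sprintf("feature columns missing: %s",
                       paste(setdiff(need, colnames(X)), collapse = ", ")))
    X <- X[, need, drop = FALSE]
  } else if (ncol(X) != length(need)) {
    bna_stop("bna_missing_columns", "feature count does not match training")
  }
  drop(X %*% model$weights) + model$bias
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outranks a random
#' negative, with ties counted one half (midrank estimator).  The curve
#' lists every threshold operating point.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels two-class labels.
#' @param positive_class label treated as positive (default `"Target"`).
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class = "Target") {
  labels <- as.character(labels)
  if (!positive_class %in% labels) positive_class <- unique(labels)[1]
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    bna_stop("bna_single_class", "need both classes for ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), 0),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 0))
  list(curve = curve, auc = auc)
}

#' Intraclass correlation from a subject x visit matrix
#'
#' One-way random-effects ANOVA with subject as the grouping factor:
#' `ICC = (MSb - MSw) / (MSb + (k - 1) MSw)` with `MSb`, `MSw` the between-
#' and within-subject mean squares and `k` the number of visits.  Negative
#' values are returned as computed.  A fully degenerate table (all values
#' equal) returns 0 with attribute `degenerate = TRUE`.
#'
#' @param values numeric matrix, subjects x visits, no missing cells.
#' @return scalar ICC with attributes `MSb`, `MSw`, `k`, `degenerate`.
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    bna_stop("bna_icc_shape", "need >= 2 subjects and >= 2 visits")
  if (anyNA(values))
    bna_stop("bna_missing_cells", "missing cells are not allowed (no imputation)")
  m_i <- rowMeans(values)
  m <- mean(values)
  msb <- k * sum((m_i - m)^2) / (n - 1)
  msw <- sum((values - m_i)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
  } else {
    out <- (msb - msw) / (msb + (k - 1) * msw)
    attr(out, "degenerate") <- FALSE
  }
  attr(out, "MSb") <- msb
  attr(out, "MSw") <- msw
  attr(out, "k") <- k
  out
}

#' Per-feature test-retest repeatability
#'
#' Computes the ICC of every feature column across visits.  All tables must
#' cover the same subjects; rows are matched by subject id (after an
#' optional condition filter when tables carry one row per subject and
#' condition).
#'
#' @param tables list of feature tables, one per visit, identical columns.
#' @param condition optional condition filter applied to every table.
#' @return data.frame: `feature`, `MSb`, `MSw`, `k`, `icc`, `degenerate`,
#'   `negative`.
#' @export
repeatability_report <- function(tables, condition = NULL) {
  stopifnot(length(tables) >= 2)
  if (!is.null(condition))
    tables <- lapply(tables, function(tb) tb[tb$condition %in% condition, ,
                                             drop = FALSE])
  subj <- lapply(tables, function(tb) sort(tb$subject_id))
  for (s in subj[-1])
    if (!identical(subj[[1]], s))
      bna_stop("bna_subject_mismatch", "visits cover different subjects")
  if (anyDuplicated(subj[[1]]))
    bna_stop("bna_subject_mismatch",
             "multiple rows per subject; filter by condition first")
  cols <- feature_columns(tables[[1]])
  for (tb in tables[-1])
    if (!identical(feature_columns(tb), cols))
      bna_stop("bna_column_mismatch", "feature columns differ across visits")
  k <- length(tables)
  ordered <- lapply(tables, function(tb) tb[order(tb$subject_id), ,
                                            drop = FALSE])
  out <- lapply(cols, function(cl) {
    m <- sapply(ordered, function(tb) tb[[cl]])
    v <- icc(m)
    data.frame(feature = cl, MSb = attr(v, "MSb"), MSw = attr(v, "MSw"),
               k = k, icc = as.numeric(v),
               degenerate = attr(v, "degenerate"),
               negative = as.numeric(v) < 0)
  })
  do.call(rbind, out)
}
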