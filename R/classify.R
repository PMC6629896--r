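#' Kernel specification
#'
#' Supported kernels on feature vectors x, y:
#' * `gaussian`: `exp(-||x-y||^2 / (2 sigma^2))`
#' * `laplace`: `exp(-||x-y|| / sigma)` (standard Laplacian)
#' * `laplace_printed`: `exp(-||x-y||^2 / (2 sigma))` — a Gaussian-shaped
#'   variant sometimes printed under the Laplace name; provided for
#'   completeness.
#' * `anova`: `sum_k exp(-sigma (x_k - y_k)^2)^d`
#'
#' @param kind kernel family.
#' @param sigma positive scale parameter.
#' @param d positive integer degree (ANOVA kernel only).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("gaussian", "laplace", "laplace_printed",
                                 "anova"), sigma = 1, d = 1L) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (kind == "anova" && (d < 1 || d != round(d)))
    stop("anova kernel requires integer d >= 1", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, d = as.integer(d)),
            class = "kernel_spec")
}

#' Evaluate a kernel on two feature vectors
#' @param spec a [kernel_spec].
#' @param x,y numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
#' @examples
#' kernel_eval(kernel_spec("gaussian", sigma = 1), c(0, 0), c(2, 0))
kernel_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y))
    stop("kernel arguments must have equal dimension", call. = FALSE)
  switch(spec$kind,
    gaussian = exp(-sum((x - y)^2) / (2 * spec$sigma^2)),
    laplace = exp(-sqrt(sum((x - y)^2)) / spec$sigma),
    laplace_printed = exp(-sum((x - y)^2) / (2 * spec$sigma)),
    anova = sum(exp(-spec$sigma * (x - y)^2)^spec$d))
}

#' Kernel matrix between two sets of feature vectors
#' @param spec a [kernel_spec].
#' @param X,Y numeric matrices (rows = observations); `Y` defaults to `X`.
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  K <- matrix(0, nrow(X), nrow(Y))
  if (spec$kind %in% c("gaussian", "laplace", "laplace_printed")) {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    d2[d2 < 0] <- 0
    K <- switch(spec$kind,
      gaussian = exp(-d2 / (2 * spec$sigma^2)),
      laplace = exp(-sqrt(d2) / spec$sigma),
      laplace_printed = exp(-d2 / (2 * spec$sigma)))
  } else {
    for (k in seq_len(ncol(X))) {
      dk <- outer(X[, k], Y[, k], "-")
      K <- K + exp(-spec$sigma * dk^2)^spec$d
    }
  }
  K
}

#' Train a soft-margin SVM with a custom kernel
#'
#' Features are standardized with training-set statistics (stored on the
#' model and reapplied at prediction), then the C-SVC dual is solved
#' (sequential minimal optimization, KKT tolerance 1e-6). The decision
#' function is `f(x) = sum_i alpha_i y_i K(x_i, x) + b` with
#' `0 <= alpha_i <= C`.
#'
#' @param X numeric matrix or data.frame of features (typically an index
#'   pair), no missing values.
#' @param y labels with exactly two levels.
#' @param C soft-margin penalty.
#' @param kernel a [kernel_spec].
#' @param positive label treated as the positive class (+1); defaults to the
#'   second factor level.
#' @return An object of class `cvc_svm` with support vectors, dual
#'   coefficients, bias, scaler and kernel.
#' @export
train_svm <- function(X, y, C = 1, kernel = kernel_spec("gaussian"),
                      positive = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("training labels must contain exactly two classes", call. = FALSE)
  y <- droplevels(y)
  if (anyNA(X)) stop("features must not contain missing values",
                     call. = FALSE)
  if (is.null(positive)) positive <- levels(y)[2]
  ysign <- ifelse(y == positive, 1, -1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  K <- kernel_matrix(kernel, Xs)
  fit <- smo_solve(K, ysign, C = C, tol = 1e-6)
  sv <- which(fit$alpha > 1e-8)
  if (length(sv) == 0L) sv <- seq_along(ysign)  # degenerate: keep all
  structure(list(sv_x = Xs[sv, , drop = FALSE], sv_index = sv,
                 coef = (fit$alpha * ysign)[sv], b = fit$b,
                 C = C, kernel = kernel, positive = positive,
                 levels = levels(y), center = ctr, scale = scl,
                 feature_names = colnames(X), n_train = nrow(X),
                 ysign = ysign, alpha = fit$alpha, K_train = K),
            class = "cvc_svm")
}

#' Decision values and class predictions
#'
#' @param object a [train_svm()] model.
#' @param newdata matrix/data.frame with the model's features.
#' @param type `"class"` (default) or `"decision"`.
#' @param ... unused.
#' @return Factor of predicted labels, or numeric decision values (positive
#'   values predict the positive class).
#' @method predict cvc_svm
#' @export
predict.cvc_svm <- function(object, newdata, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing) > 0L)
      stop(sprintf("missing feature(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  Xs <- scale(newdata, center = object$center, scale = object$scale)
  K <- kernel_matrix(object$kernel, Xs, object$sv_x)
  dec <- as.numeric(K %*% object$coef + object$b)
  if (type == "decision") return(dec)
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(dec > 0, object$positive, neg), levels = object$levels)
}

#' Classification report from labels and decision values
#'
#' Accuracy, sensitivity and specificity in percent (positive class
#' convention supplied by the caller), AUC as the rank statistic of the
#' decision values, and the 2 x 2 confusion counts.
#'
#' @param truth true labels.
#' @param decision numeric decision values (higher = more positive).
#' @param positive positive class label.
#' @return An object of class `classification_report`.
#' @export
classification_report <- function(truth, decision, positive) {
  truth_pos <- truth == positive
  pred_pos <- decision > 0
  tp <- sum(truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos); fp <- sum(!truth_pos & pred_pos)
  npos <- sum(truth_pos); nneg <- sum(!truth_pos)
  auc <- if (npos > 0 && nneg > 0) {
    r <- rank(decision)
    (sum(r[truth_pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  } else NA_real_
  structure(list(acc = 100 * (tp + tn) / length(truth),
                 sn = if (npos > 0) 100 * tp / npos else NA_real_,
                 sp = if (nneg > 0) 100 * tn / nneg else NA_real_,
                 auc = auc,
                 confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                   dimnames = list(truth = c("pos", "neg"),
                                   pred = c("pos", "neg")))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Acc %.1f%%  Sn %.1f%%  Sp %.1f%%  AUC %.3f\n",
              x$acc, x$sn, x$sp, x$auc))
  invisible(x)
}

#' Leave-one-out cross-validation of an SVM configuration
#'
#' For each subject: the scaler and the SVM are refit on the remaining
#' subjects (no leakage), and the held-out decision value recorded. The
#' report pools all held-out decisions.
#'
#' @inheritParams train_svm
#' @return A [classification_report()]; held-out decision values attached as
#'   attribute `"decisions"`.
#' @export
svm_loocv <- function(X, y, C = 1, kernel = kernel_spec("gaussian"),
                      positive = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (is.null(positive)) positive <- levels(y)[2]
  if (min(table(y)) < 3L)
    stop("at least 3 subjects per class required for LOOCV", call. = FALSE)
  n <- nrow(X)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    fit <- train_svm(X[-i, , drop = FALSE], y[-i], C = C, kernel = kernel,
                     positive = positive)
    dec[i] <- predict(fit, X[i, , drop = FALSE], type = "decision")
  }
  rep <- classification_report(y, dec, positive)
  attr(rep, "decisions") <- dec
  rep
}

#' Grid search over index pairs, kernels and C by LOOCV accuracy
#'
#' Evaluates every combination of candidate feature pair, kernel
#' specification and penalty C by [svm_loocv()]; the best configuration is
#' the one with maximal accuracy, ties broken by higher AUC and then by
#' lexical order of the configuration id.
#'
#' @param table feature table (`subject_id`, `group`, indices).
#' @param group_a,group_b the two groups; `group_b` is the positive class.
#' @param candidate_pairs list of character 2-vectors of index names.
#' @param kernels list of [kernel_spec] objects.
#' @param C_grid numeric vector of penalties.
#' @return List with `best` (pair, kernel, C, id), `report` (LOOCV
#'   [classification_report()] of the best config) and `grid` (data.frame of
#'   all configurations with acc and auc).
#' @export
loocv_grid_search <- function(table, group_a, group_b, candidate_pairs,
                              kernels, C_grid) {
  if (length(candidate_pairs) == 0L || length(kernels) == 0L ||
      length(C_grid) == 0L)
    stop("empty search grid", call. = FALSE)
  sel <- table$group %in% c(group_a, group_b)
  y <- factor(table$group[sel], levels = c(group_a, group_b))
  configs <- list()
  for (pi in seq_along(candidate_pairs))
    for (ki in seq_along(kernels))
      for (C in C_grid) {
        k <- kernels[[ki]]
        id <- sprintf("%s+%s|%s s=%g d=%d C=%g",
                      candidate_pairs[[pi]][1], candidate_pairs[[pi]][2],
                      k$kind, k$sigma, k$d, C)
        configs[[id]] <- list(pair = candidate_pairs[[pi]], kernel = k,
                              C = C, id = id)
      }
  configs <- configs[order(names(configs))]
  best <- NULL; best_rep <- NULL
  grid <- data.frame(id = names(configs), acc = NA_real_, auc = NA_real_,
                     stringsAsFactors = FALSE)
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    X <- as.matrix(table[sel, cfg$pair, drop = FALSE])
    if (anyNA(X)) next
    rep <- svm_loocv(X, y, C = cfg$C, kernel = cfg$kernel,
                     positive = group_b)
    grid$acc[ci] <- rep$acc; grid$auc[ci] <- rep$auc
    if (is.null(best) || rep$acc > best_rep$acc ||
        (rep$acc == best_rep$acc && rep$auc > best_rep$auc)) {
      best <- cfg; best_rep <- rep
    }
  }
  if (is.null(best)) stop("no configuration could be evaluated",
                          call. = FALSE)
  list(best = best, report = best_rep, grid = grid)
}

#' Two-stage cascade prediction
#'
#' Stage 1 separates controls from patients; subjects predicted as patients
#' are passed to stage 2, which assigns the risk level. A stage-1 control
#' verdict is terminal.
#'
#' @param stage1 [train_svm()] model with `positive` = the patient side
#'   (e.g. IDC) and the other level = `"CON"`.
#' @param stage2 [train_svm()] model separating `IDC_LR` (negative) from
#'   `IDC_HR` (positive).
#' @param newdata data.frame containing the features of both models.
#' @return Factor with levels `CON`, `IDC_LR`, `IDC_HR`.
#' @export
cascade_predict <- function(stage1, stage2, newdata) {
  p1 <- predict(stage1, newdata[, stage1$feature_names, drop = FALSE])
  out <- character(nrow(newdata))
  con_label <- setdiff(stage1$levels, stage1$positive)
  is_con <- p1 == con_label
  out[is_con] <- "CON"
  if (any(!is_con)) {
    p2 <- predict(stage2,
                  newdata[!is_con, stage2$feature_names, drop = FALSE])
    out[!is_con] <- as.character(p2)
  }
  factor(out, levels = c("CON", "IDC_LR", "IDC_HR"))
}

#' Leave-one-out evaluation of the full cascade
#'
#' For each subject both stage models are refit on the remaining subjects
#' (stage 1 on all of them with IDC = LR + HR pooled against CON, stage 2 on
#' the remaining patients only), and the held-out subject is passed through
#' the cascade. Reports the 3-class accuracy and one-vs-all
#' sensitivity/specificity per class.
#'
#' @param table feature table containing groups `CON`, `IDC_LR`, `IDC_HR`.
#' @param pair1,pair2 feature pairs for stage 1 and stage 2.
#' @param kernel1,kernel2 [kernel_spec] per stage.
#' @param C1,C2 penalties per stage.
#' @return List with `acc` (percent), `per_class` (data.frame of one-vs-all
#'   sn/sp), `predicted`, `truth`.
#' @export
cascade_loocv <- function(table, pair1, kernel1, C1, pair2, kernel2, C2) {
  truth <- factor(table$group, levels = c("CON", "IDC_LR", "IDC_HR"))
  n <- nrow(table)
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    y1 <- factor(ifelse(train$group == "CON", "CON", "IDC"),
                 levels = c("CON", "IDC"))
    m1 <- train_svm(train[, pair1, drop = FALSE], y1, C = C1,
                    kernel = kernel1, positive = "IDC")
    pat <- train$group %in% c("IDC_LR", "IDC_HR")
    y2 <- factor(train$group[pat], levels = c("IDC_LR", "IDC_HR"))
    m2 <- train_svm(train[pat, pair2, drop = FALSE], y2, C = C2,
                    kernel = kernel2, positive = "IDC_HR")
    pred[i] <- as.character(
      cascade_predict(m1, m2, table[i, , drop = FALSE]))
  }
  pred <- factor(pred, levels = levels(truth))
  per_class <- do.call(rbind, lapply(levels(truth), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    data.frame(class = cl, sn = 100 * tp / (tp + fn),
               sp = 100 * tn / (tn + fp), stringsAsFactors = FALSE)
  }))
  list(acc = 100 * mean(pred == truth), per_class = per_class,
       predicted = pred, truth = truth)
}
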