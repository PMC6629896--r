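#' Solve the soft-margin SVM dual by sequential minimal optimization
#'
#' Maximal-violating-pair SMO for the C-SVC dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'   y_i y_j K_{ij}, \quad 0 \le \alpha_i \le C, \; \sum_i \alpha_i y_i = 0.}
#' Iterates two-variable analytic updates on the pair that most violates the
#' KKT conditions until the duality gap measure drops below `tol`. Intended
#' for the small problems arising in subject-level classification (hundreds
#' of points at most); fully deterministic.
#'
#' @param K symmetric positive semi-definite kernel matrix.
#' @param y numeric labels in \{-1, +1\}.
#' @param C box constraint.
#' @param tol KKT violation tolerance (default 1e-6).
#' @param max_passes iteration safety cap.
#' @return List with `alpha`, `b` (decision function
#'   `f(x) = sum_i alpha_i y_i K(x_i, x) + b`), `iterations`, and
#'   `converged`.
#' @export
smo_solve <- function(K, y, C, tol = 1e-6, max_passes = 100000L) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, all(y %in% c(-1, 1)), C > 0)
  alpha <- numeric(n)
  f <- numeric(n)          # f_i = sum_k alpha_k y_k K_ik (bias-free)
  eps <- 1e-12
  it <- 0L
  converged <- FALSE
  while (it < max_passes) {
    it <- it + 1L
    grad <- y - f          # -y_i G_i in the usual dual notation
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(grad[up])]
    j <- which(lo)[which.min(grad[lo])]
    if (grad[i] - grad[j] < tol) { converged <- TRUE; break }
    s <- y[i] * y[j]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta < eps) eta <- eps
    aj_old <- alpha[j]; ai_old <- alpha[i]
    # unconstrained optimum along the pair direction
    aj_new <- aj_old - y[j] * (grad[i] - grad[j]) / eta
    if (s > 0) {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    } else {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    }
    aj_new <- min(max(aj_new, L), H)
    ai_new <- ai_old + s * (aj_old - aj_new)
    dai <- ai_new - ai_old; daj <- aj_new - aj_old
    if (abs(dai) < eps && abs(daj) < eps) { converged <- TRUE; break }
    alpha[i] <- ai_new; alpha[j] <- aj_new
    f <- f + dai * y[i] * K[, i] + daj * y[j] * K[, j]
  }
  grad <- y - f
  up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
  lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
  b <- if (any(up) && any(lo)) (max(grad[up]) + min(grad[lo])) / 2
       else if (any(alpha > eps & alpha < C - eps))
         mean(grad[alpha > eps & alpha < C - eps])
       else mean(grad)
  list(alpha = alpha, b = b, iterations = it, converged = converged)
}
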