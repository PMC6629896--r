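test_that("kernel evaluations match their closed forms", {
  x <- c(0, 0); y <- c(2, 0)
  expect_equal(kernel_eval(kernel_spec("gaussian", 1), x, y), exp(-2))
  expect_equal(kernel_eval(kernel_spec("laplace", 1), x, y), exp(-2))
  expect_equal(kernel_eval(kernel_spec("laplace_printed", 1), x, y),
               exp(-2))
  # zero distance: gaussian/laplace 1; anova = number of dimensions
  expect_equal(kernel_eval(kernel_spec("gaussian", 0.5), x, x), 1)
  expect_equal(kernel_eval(kernel_spec("laplace", 2), x, x), 1)
  expect_equal(kernel_eval(kernel_spec("anova", 1, 2), c(1, 2), c(1, 2)), 2)
  # anova in one dimension with d = 1 reduces to a gaussian form
  expect_equal(kernel_eval(kernel_spec("anova", 0.7, 1), 1.2, 0.3),
               exp(-0.7 * 0.81))
  expect_error(kernel_eval(kernel_spec("gaussian"), 1:2, 1:3), "dimension")
  expect_error(kernel_spec("gaussian", -1), "sigma")
  expect_error(kernel_spec("anova", 1, 0.5), "integer d")
  # matrix form agrees with pairwise evaluation
  set.seed(61)
  A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(6), 3, 2)
  for (ks in list(kernel_spec("gaussian", 1.3), kernel_spec("laplace", 0.8),
                  kernel_spec("anova", 0.5, 2))) {
    K <- kernel_matrix(ks, A, B)
    for (i in 1:5) for (j in 1:3)
      expect_equal(K[i, j], kernel_eval(ks, A[i, ], B[j, ]),
                   tolerance = 1e-12)
  }
})

test_that("separable data are fit perfectly and deterministically", {
  d <- blob_data(n = 15, gap = 4)
  m <- train_svm(d$X, d$y, C = 100, kernel = kernel_spec("gaussian", 1),
                 positive = "B")
  expect_equal(mean(predict(m, d$X) == d$y), 1)
  expect_true(all(abs(m$coef) <= 100 + 1e-6))
  m2 <- train_svm(d$X, d$y, C = 100, kernel = kernel_spec("gaussian", 1),
                  positive = "B")
  expect_identical(predict(m, d$X, type = "decision"),
                   predict(m2, d$X, type = "decision"))
  expect_error(train_svm(d$X, rep("A", 30), C = 1), "two classes")
})

test_that("contradictory duplicated points drive alpha to the box bound", {
  X <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1.01))
  y <- factor(c("A", "B", "A", "B"))
  m <- train_svm(X, y, C = 2, kernel = kernel_spec("gaussian", 1),
                 positive = "B")
  expect_true(any(abs(abs(m$coef) - 2) < 1e-4))
})

test_that("the SMO dual matches a brute-force QP solve on small instances", {
  set.seed(62)
  for (rep in 1:3) {
    n <- 16
    X <- rbind(matrix(rnorm(n), n / 2, 2),
               matrix(rnorm(n, mean = 1.5), n / 2, 2))
    y <- rep(c(-1, 1), each = n / 2)
    C <- 2
    m <- train_svm(X, factor(y), C = C, kernel = kernel_spec("gaussian", 1),
                   positive = "1")
    Xs <- scale(X, m$center, m$scale)
    K <- kernel_matrix(kernel_spec("gaussian", 1), Xs)
    H <- (y %o% y) * K
    qp <- kernlab::ipop(c = matrix(-1, n), H = H, A = matrix(y, 1), b = 0,
                        l = matrix(0, n), u = matrix(C, n), r = 0)
    a_qp <- kernlab::primal(qp)
    dual_obj <- function(a) sum(a) - 0.5 * as.numeric(t(a) %*% H %*% a)
    a_pkg <- rep(0, n); a_pkg[m$sv_index] <- abs(m$coef)
    expect_lt(abs(dual_obj(a_qp) - dual_obj(a_pkg)), 1e-4)
    # KKT feasibility of the package solution
    expect_lt(abs(sum(a_pkg * y)), 1e-6)
    expect_true(all(a_pkg >= -1e-8 & a_pkg <= C + 1e-8))
  }
})

test_that("LOOCV reports chance on shuffled labels and 1.0 AUC when perfect", {
  d <- blob_data(n = 12, gap = 4, seed = 63)
  set.seed(64)
  rep_sh <- svm_loocv(d$X, sample(d$y), C = 1,
                      kernel = kernel_spec("gaussian", 1), positive = "B")
  expect_lt(abs(rep_sh$acc - 50), 16)
  # perfect ordering of decision values
  r <- classification_report(factor(rep(c("A", "B"), each = 5)),
                             c(-(5:1), 1:5), positive = "B")
  expect_equal(r$auc, 1)
  expect_equal(r$acc, 100)
})

test_that("noise features stay at chance under LOOCV (no leakage)", {
  set.seed(65)
  X <- matrix(rnorm(60), 30, 2)
  colnames(X) <- c("n1", "n2")
  y <- factor(rep(c("A", "B"), 15))
  rep <- svm_loocv(X, y, C = 5, kernel = kernel_spec("gaussian", 1),
                   positive = "B")
  expect_lt(abs(rep$acc - 50), 25)
})

test_that("grid search selects a separating configuration", {
  d <- blob_data(n = 10, gap = 4, seed = 66)
  tab <- data.frame(subject_id = paste0("S", 1:20),
                    group = as.character(d$y), check.names = FALSE)
  tab <- cbind(tab, as.data.frame(d$X))
  gs <- loocv_grid_search(tab, "A", "B",
                          candidate_pairs = list(c("f1", "f2")),
                          kernels = list(kernel_spec("gaussian", 1),
                                         kernel_spec("laplace", 1)),
                          C_grid = c(1, 10))
  expect_gte(gs$report$acc, 95)
  expect_true(all(c("acc", "auc") %in% names(gs$grid)))
  expect_error(loocv_grid_search(tab, "A", "B", list(), list(), numeric(0)),
               "empty")
})

test_that("the cascade short-circuits on stage-1 controls", {
  set.seed(67)
  n <- 12
  f1 <- c(rnorm(n, 0), rnorm(n, 5), rnorm(n, 5.5))    # CON low
  f2 <- c(rnorm(n, 0), rnorm(n, -4), rnorm(n, 4))     # separates LR/HR
  tab <- data.frame(subject_id = paste0("S", 1:(3 * n)),
                    group = rep(c("CON", "IDC_LR", "IDC_HR"), each = n),
                    s1f = f1, s2f = f2, aux = rnorm(3 * n),
                    check.names = FALSE, stringsAsFactors = FALSE)
  y1 <- factor(ifelse(tab$group == "CON", "CON", "IDC"),
               levels = c("CON", "IDC"))
  m1 <- train_svm(tab[, c("s1f", "aux")], y1, C = 10,
                  kernel = kernel_spec("gaussian", 1), positive = "IDC")
  pat <- tab$group != "CON"
  m2 <- train_svm(tab[pat, c("s2f", "aux")],
                  factor(tab$group[pat], levels = c("IDC_LR", "IDC_HR")),
                  C = 10, kernel = kernel_spec("gaussian", 1),
                  positive = "IDC_HR")
  deep_con <- data.frame(s1f = -3, s2f = 0, aux = 0)
  expect_identical(as.character(cascade_predict(m1, m2, deep_con)), "CON")
  # missing feature is reported by name
  expect_error(predict(m2, as.matrix(data.frame(s1f = 1, aux = 0))),
               "s2f")
  # full cascade on the separable construction
  cv <- cascade_loocv(tab, c("s1f", "aux"), kernel_spec("gaussian", 1), 10,
                      c("s2f", "aux"), kernel_spec("gaussian", 1), 10)
  expect_gte(cv$acc, 85)
  # composition bound: 3-class accuracy cannot beat stage-1 CON-vs-rest
  stage1_acc <- 100 * mean((cv$predicted == "CON") == (cv$truth == "CON"))
  expect_lte(cv$acc, stage1_acc + 1e-9)
})
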