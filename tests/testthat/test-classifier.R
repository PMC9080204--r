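test_that("AUC: tie and perfect-ranking edge cases", {
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_equal(roc_auc(1:10, rep(c(FALSE, TRUE), each = 5))$auc, 1)
  expect_equal(roc_auc(10:1, rep(c(FALSE, TRUE), each = 5))$auc, 0)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals brute-force concordant-pair counting on random toys", {
  set.seed(99)
  for (i in 1:100) {
    n <- 30L
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    labels <- runif(n) < 0.4
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels)$auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC and is antisymmetric under score negation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- runif(40) < 0.5
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-12)
    expect_equal(roc_auc(scores, labels)$auc +
                   roc_auc(-scores, labels)$auc, 1, tolerance = 1e-12)
  }
})

test_that("ROC curve runs from (0,0) to (1,1) with monotone coordinates", {
  set.seed(12)
  r <- roc_auc(rnorm(50), runif(50) < 0.5)$roc
  expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

sep_gaussians <- function(n = 60, d = 6) {
  # two well-separated classes in 2D
  X <- rbind(matrix(rnorm(n, 0, 1), n / 2, 2),
             matrix(rnorm(n, d, 1), n / 2, 2))
  y <- rep(c("a", "b"), each = n / 2)
  list(X = scale(X), y = y)
}

test_that("separable Gaussian classes are fit to 100% training accuracy", {
  set.seed(21)
  g <- sep_gaussians()
  fit <- fit_multinomial(g$X, g$y, ridge_lambda = 0.1)
  pred <- colnames(predict(fit, g$X))[max.col(predict(fit, g$X))]
  expect_equal(pred, g$y)
})

test_that("labels independent of features predict the class priors", {
  set.seed(31)
  n <- 500
  X <- matrix(rnorm(n * 3), n, 3)
  y <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  fit <- fit_multinomial(X, y, ridge_lambda = 1)
  mean_prob <- colMeans(predict(fit, X))
  priors <- table(y)[names(mean_prob)] / n
  expect_true(all(abs(mean_prob - priors) < 0.05))
})

test_that("returned coefficients beat random perturbations on the penalized objective", {
  set.seed(41)
  n <- 80
  X <- scale(matrix(rnorm(n * 4), n, 4))
  y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  lam <- 0.5
  fit <- fit_multinomial(X, y, ridge_lambda = lam)
  pen_ll <- function(coef) {
    P <- cbind(1, X) %*% t(coef)
    P <- exp(P - apply(P, 1, max)); P <- P / rowSums(P)
    sum(log(P[cbind(1:n, as.integer(y))])) -
      lam / 2 * sum(coef[, -1]^2)
  }
  base <- pen_ll(fit$coefficients)
  for (i in 1:100) {
    pert <- fit$coefficients +
      matrix(rnorm(length(fit$coefficients), 0, 0.05), nrow(fit$coefficients))
    pert[1, ] <- 0    # keep the reference-class parametrization
    expect_lt(pen_ll(pert), base + 1e-10)
  }
})

test_that("two-class fit with tiny penalty matches logistic regression", {
  set.seed(51)
  n <- 200
  X <- scale(matrix(rnorm(n * 2), n, 2))
  y <- factor(ifelse(runif(n) < plogis(X[, 1] - 0.5 * X[, 2]), "pos", "neg"),
              levels = c("neg", "pos"))
  fit <- fit_multinomial(X, y, ridge_lambda = 1e-8)
  glm_fit <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients["pos", ]),
               unname(coef(glm_fit)), tolerance = 1e-4)
})

test_that("lambda = 0 on separable data errors with guidance", {
  set.seed(61)
  g <- sep_gaussians(d = 10)
  expect_error(fit_multinomial(g$X, g$y, ridge_lambda = 0, maxit = 200),
               "ridge_lambda > 0")
})

test_that("training log-likelihood never increases with stronger regularization", {
  set.seed(71)
  n <- 90
  X <- scale(matrix(rnorm(n * 3), n, 3))
  y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  ll <- vapply(c(0.1, 1, 10),
               function(l) fit_multinomial(X, y, ridge_lambda = l)$loglik,
               numeric(1))
  expect_true(all(diff(ll) <= 1e-8))
})

test_that("cross_validate is bit-reproducible and partitions samples into folds", {
  set.seed(81)
  n <- 45
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("s%02d", 1:n), NULL))
  y <- rep(c("a", "b", "c"), each = 15)
  r1 <- cross_validate(X, y, cv_folds = 5, ridge_lambda = 1, seed = 3)
  r2 <- cross_validate(X, y, cv_folds = 5, ridge_lambda = 1, seed = 3)
  expect_identical(r1$auc_ovr, r2$auc_ovr)
  expect_identical(r1$fold_assignments, r2$fold_assignments)
  expect_identical(r1$oof_prob, r2$oof_prob)
  expect_equal(sort(unique(r1$fold_assignments)), 1:5)
  expect_equal(length(r1$fold_assignments), n)
  # stratification: every fold sees every class
  expect_true(all(table(y, r1$fold_assignments) >= 1))
  expect_error(cross_validate(X[1:16, ], c(rep("a", 15), "b"), 5, 1, 1),
               ">= 2 samples")
})

test_that("a planted separable cohort reaches one-vs-rest AUC >= 0.95 everywhere", {
  co <- default_cohort(seed = 1L)
  r12 <- de_test(co$protein, co$samples, "TYPE_I", "TYPE_II")
  r13 <- de_test(co$protein, co$samples, "TYPE_I", "TYPE_III")
  r23 <- de_test(co$protein, co$samples, "TYPE_II", "TYPE_III")
  panel <- select_markers(r12, r13, r23)
  tum <- co$samples[co$samples$subtype != "NORMAL", ]
  X <- t(unclass(co$protein)[unique(panel$feature_id), tum$sample_id])
  rep <- cross_validate(X, tum$subtype, cv_folds = 10, ridge_lambda = 1,
                        seed = 2)
  expect_true(all(rep$auc_ovr >= 0.95))
  expect_equal(nrow(rep$auc_pairwise), 3L)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(91)
  co <- simulate_cohort(small_params(seed = 25L))
  tum <- co$samples[co$samples$subtype != "NORMAL", ]
  feats <- unlist(lapply(co$truth$planted_markers, `[[`, "feature_id"))
  X <- t(unclass(co$protein)[feats[1:10], tum$sample_id])
  aucs <- replicate(20, {
    yp <- sample(tum$subtype)
    mean(cross_validate(X, yp, cv_folds = 5, ridge_lambda = 1,
                        seed = 1)$auc_ovr)
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
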