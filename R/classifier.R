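#' Fit a ridge-penalized multinomial logistic model
#'
#' Softmax regression maximizing the L2-penalized multinomial log-likelihood
#' `loglik - lambda/2 * sum(beta^2)` (intercepts unpenalized), parametrized
#' against the first class as reference and optimized with BFGS to gradient
#' tolerance 1e-6. The problem is convex, so the fit is deterministic given
#' the data. Features are expected to be standardized by the caller (as
#' [cross_validate()] does per training split).
#'
#' With `ridge_lambda = 0` on perfectly separable data the likelihood has no
#' maximizer; this is detected and reported as an error instructing a
#' positive lambda.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels (coerced to factor; >= 2 levels present).
#' @param ridge_lambda non-negative L2 penalty.
#' @param maxit BFGS iteration cap.
#' @return a `multinomial_fit`: list with `coefficients` (classes x
#'   (intercept + features), reference class row all zero), `levels`,
#'   `ridge_lambda`, `loglik` (unpenalized, at the optimum), `grad_max`.
#' @export
fit_multinomial <- function(X, y, ridge_lambda = 1.0, maxit = 1000L) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L) stop(">= 2 classes required", call. = FALSE)
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  pen_mask <- c(0, rep(1, p))   # intercept unpenalized

  unpack <- function(theta) matrix(theta, p + 1L, K - 1L)
  neg_obj <- function(theta) {
    B <- unpack(theta)
    eta <- cbind(0, Xd %*% B)
    mx <- apply(eta, 1L, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    ll <- sum(eta[cbind(seq_len(n), as.integer(y))] - lse)
    -(ll - ridge_lambda / 2 * sum((pen_mask * B)^2))
  }
  neg_grad <- function(theta) {
    B <- unpack(theta)
    eta <- cbind(0, Xd %*% B)
    mx <- apply(eta, 1L, max)
    P <- exp(eta - mx)
    P <- P / rowSums(P)
    G <- crossprod(Xd, P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE]) +
      ridge_lambda * (pen_mask * B)
    as.vector(G)
  }
  theta <- rep(0, (p + 1L) * (K - 1L))
  grad_max <- Inf
  for (restart in 1:6) {                    # BFGS restarts rebuild the Hessian
    opt <- stats::optim(theta, neg_obj, neg_grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    theta <- opt$par
    grad_max <- max(abs(neg_grad(theta)))
    if (grad_max <= 1e-6) break
  }
  if (ridge_lambda == 0) {
    # with separation the unpenalized likelihood has no maximizer: fitted
    # probabilities saturate (and the gradient vanishes) while the
    # coefficients diverge, so saturation is the reliable symptom
    Pfit <- softmax_prob(t(cbind(0, unpack(theta))), X)
    if (min(Pfit[cbind(seq_len(n), as.integer(y))]) > 0.99) {
      stop("no finite optimum (data look perfectly separable); ",
           "use ridge_lambda > 0", call. = FALSE)
    }
  }
  if (grad_max > 1e-6) {
    stop(sprintf(paste0("multinomial fit did not converge: max|gradient| = %.3g ",
                        "after %d iterations (convergence code %d)"),
                 grad_max, maxit, opt$convergence), call. = FALSE)
  }
  B <- cbind(0, unpack(opt$par))            # reference class first
  coef <- t(B)
  dimnames(coef) <- list(lev, colnames(Xd))
  structure(list(coefficients = coef, levels = lev,
                 ridge_lambda = ridge_lambda,
                 loglik = multinomial_loglik(coef, X, y),
                 grad_max = grad_max),
            class = "multinomial_fit")
}

# unpenalized multinomial log-likelihood of a coefficient matrix
multinomial_loglik <- function(coef, X, y) {
  P <- softmax_prob(coef, as.matrix(X))
  sum(log(P[cbind(seq_len(nrow(P)), as.integer(factor(y, rownames(coef))))]))
}

softmax_prob <- function(coef, X) {
  eta <- cbind(1, X) %*% t(coef)
  mx <- apply(eta, 1L, max)
  P <- exp(eta - mx)
  P / rowSums(P)
}

#' Predict class probabilities from a multinomial fit
#'
#' @param object a [fit_multinomial()] model.
#' @param newdata samples x features matrix on the same feature scale the
#'   model was fitted on.
#' @param ... unused.
#' @return matrix samples x classes of softmax probabilities.
#' @export
predict.multinomial_fit <- function(object, newdata, ...) {
  P <- softmax_prob(object$coefficients, as.matrix(newdata))
  colnames(P) <- object$levels
  P
}

#' ROC curve and AUC by midranks
#'
#' AUC via the Mann-Whitney midrank formulation (the fraction of
#' positive/negative pairs ranked concordantly, ties counted half); ROC
#' points by sweeping thresholds over the unique scores, from (0,0) to (1,1).
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels binary labels (logical, 0/1, or 2-level factor whose second
#'   level is positive); both classes must be present.
#' @return list with `auc` and `roc`, a tibble of `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)            # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n0, numeric(1))
  list(auc = auc, roc = tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr)))
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) != 2L) {
      stop("labels must have exactly 2 levels", call. = FALSE)
    }
    return(labels == levels(droplevels(labels))[2L])
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be logical, 0/1 or a 2-level factor", call. = FALSE)
}

#' Cross-validated multinomial subtype classification
#'
#' Stratified k-fold cross-validation of [fit_multinomial()]: per fold,
#' features are standardized on the training split (train mean/SD applied to
#' the held-out split), the model is fitted, and held-out class probabilities
#' are collected. Pooled out-of-fold probabilities yield one one-vs-rest ROC
#' and AUC per class, plus one-vs-one AUCs per class pair computed on the
#' two classes' samples only (score: the renormalized probability of the
#' first class). The whole procedure is deterministic given
#' `(X, y, cv_folds, ridge_lambda, seed)`.
#'
#' @param X samples x features matrix (rownames = sample IDs, optional).
#' @param y class labels; every class needs >= 2 samples.
#' @param cv_folds number of folds (>= 2).
#' @param ridge_lambda L2 penalty passed to [fit_multinomial()].
#' @param seed integer seed for the fold split.
#' @return a `classifier_report`: list with `auc_ovr` (named vector),
#'   `roc_ovr` (list of tibbles), `auc_pairwise` (tibble `class_a`,
#'   `class_b`, `auc`), `oof_prob`, `fold_assignments`, `coefficients`
#'   (refit on the full standardized data), and the config echo.
#' @export
cross_validate <- function(X, y, cv_folds = 10L, ridge_lambda = 1.0,
                           seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  lev <- levels(y)
  if (any(table(y) < 2L)) stop("every class needs >= 2 samples", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)

  set.seed(seed)
  fold <- integer(n)
  for (cl in lev) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(cv_folds),
                                                  length(idx))
  }

  oof <- matrix(NA_real_, n, length(lev), dimnames = list(rownames(X), lev))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    if (all(tr) || !any(tr)) next
    if (nlevels(droplevels(y[tr])) < length(lev)) {
      stop("fold ", f, " training split lost a class; reduce cv_folds",
           call. = FALSE)
    }
    std <- standardizer(X[tr, , drop = FALSE])
    fit <- fit_multinomial(std$apply(X[tr, , drop = FALSE]), y[tr],
                           ridge_lambda)
    oof[!tr, ] <- predict(fit, std$apply(X[!tr, , drop = FALSE]))
  }

  auc_ovr <- numeric(0); roc_ovr <- list()
  for (cl in lev) {
    ra <- roc_auc(oof[, cl], y == cl)
    auc_ovr[cl] <- ra$auc
    roc_ovr[[cl]] <- ra$roc
  }
  pairs <- utils::combn(lev, 2L)
  auc_pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    sel <- y %in% c(a, b)
    score <- oof[sel, a] / (oof[sel, a] + oof[sel, b])
    tibble::tibble(class_a = a, class_b = b,
                   auc = roc_auc(score, (y == a)[sel])$auc)
  })

  std_all <- standardizer(X)
  full_fit <- fit_multinomial(std_all$apply(X), y, ridge_lambda)
  structure(list(auc_ovr = auc_ovr, roc_ovr = roc_ovr,
                 auc_pairwise = dplyr::bind_rows(auc_pw),
                 oof_prob = oof,
                 fold_assignments = stats::setNames(fold, rownames(X)),
                 coefficients = full_fit$coefficients,
                 config = list(cv_folds = cv_folds,
                               ridge_lambda = ridge_lambda, seed = seed)),
            class = "classifier_report")
}

standardizer <- function(Xtrain) {
  mu <- colMeans(Xtrain)
  sd <- apply(Xtrain, 2L, stats::sd)
  sd[sd < 1e-8] <- 1
  list(apply = function(X) sweep(sweep(X, 2L, mu), 2L, sd, "/"))
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", x$config$cv_folds, "fold CV, lambda =",
      x$config$ridge_lambda, "\n one-vs-rest AUC:",
      paste(sprintf("%s=%.3f", names(x$auc_ovr), x$auc_ovr), collapse = " "),
      "\n")
  invisible(x)
}
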