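#' Canonical correlation of a loading pair
#'
#' Pearson correlation between the canonical scores \code{Xu} and
#' \code{Yv}. Scores are mean-centered before applying the cosine
#' formula \eqn{(Xu)^\top Yv / (\|Xu\|\,\|Yv\|)}, so the cosine and
#' Pearson readings coincide.
#'
#' @param X,Y data matrices sharing rows.
#' @param u,v loading vectors for the two views.
#' @return correlation in \eqn{[-1, 1]}.
#' @export
canonical_correlation <- function(X, Y, u, v) {
  xu <- drop(X %*% u); yv <- drop(Y %*% v)
  xu <- xu - mean(xu); yv <- yv - mean(yv)
  nx <- sqrt(sum(xu^2)); ny <- sqrt(sum(yv^2))
  if (nx == 0 || ny == 0)
    stop("zero-variance canonical score: correlation undefined")
  sum(xu * yv) / (nx * ny)
}

#' Support-recovery AUC of an estimated loading vector
#'
#' Area under the ROC curve when features are ranked by absolute
#' estimated weight against a binary ground-truth support: the
#' probability that a randomly chosen true-signal feature outranks a
#' randomly chosen null feature, with ties counted half (mid-rank
#' Mann-Whitney statistic).
#'
#' @param weights numeric vector of estimated loadings (signed).
#' @param true_support binary (0/1 or logical) vector of the same
#'   length, with at least one 0 and one 1.
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_support <- function(weights, true_support) {
  if (length(weights) != length(true_support))
    stop("'weights' and 'true_support' must have the same length")
  lab <- as.integer(as.logical(true_support))
  if (anyNA(lab) || anyNA(weights))
    stop("missing values in AUC inputs")
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("'true_support' must contain both classes")
  r <- rank(abs(weights))  # mid-ranks on ties
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Seeded partition into k near-equal folds (sizes differ by <= 1).
make_folds <- function(n, k, seed) {
  if (n < k) stop("n = ", n, " is smaller than the number of folds k = ", k)
  rs <- local_seed(seed); on.exit(restore_seed(rs))
  sample(rep_len(seq_len(k), n))
}

#' k-fold cross-validation of a non-convex sparse CCA model
#'
#' Shuffles rows into k near-equal folds (seeded, so the identical
#' partition can be reused across penalty families), fits on each
#' training set, and records training and held-out canonical
#' correlations. Standardization parameters are learned on the training
#' folds and applied to the test fold. When ground-truth loadings are
#' supplied, per-fold support-recovery AUCs are recorded as well.
#'
#' @param X,Y data matrices sharing rows.
#' @param penalty_u,penalty_v [penalty_spec()]s for the two views.
#' @param control a [nscca_control()].
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition.
#' @param true_u,true_v optional ground-truth loading vectors; their
#'   nonzero pattern defines the support for the AUCs.
#' @param folds optional explicit fold assignment (integer vector in
#'   \code{1:k} of length \code{nrow(X)}), overriding \code{seed}.
#' @return object of class \code{"nscca_cv"}: per-fold fits, fold
#'   assignment, and a \code{summary} data frame with one row per fold
#'   (train_corr, test_corr, and auc_u / auc_v when truth is known).
#' @export
cv_nscca <- function(X, Y, penalty_u, penalty_v = penalty_u,
                     control = nscca_control(), k = 5L, seed = 1L,
                     true_u = NULL, true_v = NULL, folds = NULL) {
  n <- nrow(X)
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  stopifnot(length(folds) == n, all(folds %in% seq_len(k)))
  has_truth <- !is.null(true_u) && !is.null(true_v)
  fits <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- nscca(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                 penalty_u, penalty_v, control)
    pr <- predict(fit, X[test, , drop = FALSE], Y[test, , drop = FALSE])
    row <- data.frame(fold = f, train_corr = fit$corr,
                      test_corr = pr$corr,
                      n_iter = fit$n_iter, converged = fit$converged)
    if (has_truth) {
      row$auc_u <- auc_support(fit$u, true_u != 0)
      row$auc_v <- auc_support(fit$v, true_v != 0)
    }
    fits[[f]] <- fit
    rows[[f]] <- row
  }
  structure(list(fits = fits, folds = folds, k = k, seed = seed,
                 penalty_u = penalty_u, penalty_v = penalty_v,
                 control = control,
                 summary = do.call(rbind, rows)),
            class = "nscca_cv")
}

#' @export
print.nscca_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d-fold CV, penalty %s (lambda = %g%s)\n", x$k,
              x$penalty_u$family, x$penalty_u$lam,
              if (x$penalty_u$family == "l1") "" else
                sprintf(", gamma = %g", x$penalty_u$gamma)))
  cat(sprintf("  train corr: %.3f +/- %.3f   test corr: %.3f +/- %.3f\n",
              mean(s$train_corr), stats::sd(s$train_corr),
              mean(s$test_corr), stats::sd(s$test_corr)))
  if (!is.null(s$auc_u))
    cat(sprintf("  AUC(u): %.3f +/- %.3f   AUC(v): %.3f +/- %.3f\n",
                mean(s$auc_u), stats::sd(s$auc_u),
                mean(s$auc_v), stats::sd(s$auc_v)))
  invisible(x)
}

#' Grid search over the penalty shape parameter gamma
#'
#' Runs [cv_nscca()] for every candidate \eqn{\gamma} in
#' [gamma_grid()] for the family, on the identical fold partition, and
#' selects the \eqn{\gamma} with the highest mean held-out canonical
#' correlation. \eqn{\lambda} and the \eqn{\alpha}'s stay fixed (default
#' 1): with a suitably concave penalty the fit is insensitive to them,
#' so only the concavity parameter is tuned. For the l1 family there is
#' nothing to tune and a single CV run is returned.
#'
#' @inheritParams cv_nscca
#' @param family penalty family name.
#' @param lam penalty strength (default 1).
#' @return list of class \code{"nscca_grid"}: \code{best_gamma},
#'   \code{best_cv} (the selected [cv_nscca()] report), \code{results}
#'   (data frame, one row per candidate), and all CV reports.
#' @export
grid_search_gamma <- function(X, Y, family, lam = 1,
                              control = nscca_control(), k = 5L,
                              seed = 1L, true_u = NULL, true_v = NULL) {
  grid <- gamma_grid(family)
  folds <- make_folds(nrow(X), k, seed)
  if (length(grid) == 0L) grid <- NA_real_  # l1: single untuned run
  reports <- lapply(grid, function(g) {
    spec <- if (is.na(g)) penalty_spec(family, lam = lam)
            else penalty_spec(family, lam = lam, gamma = g)
    cv_nscca(X, Y, spec, spec, control, k = k, folds = folds,
             true_u = true_u, true_v = true_v)
  })
  mean_test <- vapply(reports, function(r) mean(r$summary$test_corr), 0)
  best <- which.max(mean_test)
  results <- data.frame(gamma = grid, mean_test_corr = mean_test,
                        mean_train_corr = vapply(reports, function(r)
                          mean(r$summary$train_corr), 0))
  structure(list(family = family, best_gamma = grid[best],
                 best_cv = reports[[best]], results = results,
                 reports = reports, folds = folds),
            class = "nscca_grid")
}

#' @export
print.nscca_grid <- function(x, ...) {
  cat(sprintf("Gamma grid search, family %s\n", x$family))
  print(x$results, digits = 3, row.names = FALSE)
  cat(sprintf("selected gamma = %g\n", x$best_gamma))
  invisible(x)
}

#' Remove covariate effects by least-squares residualization
#'
#' Replaces each column of \code{M} by its residual from an ordinary
#' least-squares regression on the covariate matrix \code{C} (which
#' must include an intercept column), the standard adjustment for
#' nuisance variables such as age, sex, education or handedness before
#' an association analysis.
#'
#' @param M numeric matrix to be adjusted (rows = subjects).
#' @param C covariate matrix with the same number of rows, full column
#'   rank, including an intercept column.
#' @return matrix of residuals, orthogonal to every column of \code{C}.
#' @export
residualize_covariates <- function(M, C) {
  stopifnot(is.matrix(M) || is.data.frame(M))
  M <- as.matrix(M); C <- as.matrix(C)
  if (nrow(M) != nrow(C))
    stop("M and C must have the same number of rows")
  qrC <- qr(C)
  if (qrC$rank < ncol(C))
    stop("covariate matrix is rank deficient (rank ", qrC$rank,
         " < ", ncol(C), " columns)")
  has_intercept <- any(apply(C, 2L, function(col)
    max(abs(col - col[1L])) == 0 && col[1L] != 0))
  if (!has_intercept)
    stop("covariate matrix must include an intercept column")
  qr.resid(qrC, M)
}
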