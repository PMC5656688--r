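#' Solver configuration for non-convex sparse CCA
#'
#' @param alpha1,alpha2 positive ridge multipliers on the scale terms
#'   \eqn{\|Xu\|^2/2} and \eqn{\|Yv\|^2/2}. Default 1; with a suitably
#'   concave penalty the solution is insensitive to them, which is why
#'   only gamma is tuned.
#' @param zeta tiny positive perturbation used in the LQA reweighting
#'   (default \code{1e-6}).
#' @param epsilon convergence threshold on the max absolute change of
#'   both canonical vectors between iterations (default \code{1e-5}).
#' @param max_iter iteration cap (default 100). Hitting it yields a
#'   result flagged \code{converged = FALSE} with a warning, not an
#'   error.
#' @param init \code{"l1"} (default: warm start at the converged l1
#'   fit, the one-step/LLA convention for folded-concave estimation —
#'   deterministic, and a no-op when the penalty is itself l1),
#'   \code{"ones"} (all-ones start rescaled to the unit-score
#'   constraint) or \code{"random"} (standard normal start; requires
#'   \code{seed}).
#' @param seed integer seed for random initialization; ignored
#'   otherwise.
#' @return an object of class \code{"nscca_control"}.
#' @export
nscca_control <- function(alpha1 = 1, alpha2 = 1, zeta = 1e-6,
                          epsilon = 1e-5, max_iter = 100L,
                          init = c("l1", "ones", "random"), seed = NULL) {
  init <- match.arg(init)
  stopifnot(is.numeric(alpha1), length(alpha1) == 1L, alpha1 > 0,
            is.numeric(alpha2), length(alpha2) == 1L, alpha2 > 0,
            is.numeric(zeta), length(zeta) == 1L, zeta > 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1)
  if (init == "random" && is.null(seed))
    stop("random initialization requires a 'seed'")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, zeta = zeta,
                 epsilon = epsilon, max_iter = as.integer(max_iter),
                 init = init, seed = seed),
            class = "nscca_control")
}

# Lagrangian objective: -u'X'Yv + Omega(u) + Omega(v)
#   + alpha1/2 ||Xu||^2 + alpha2/2 ||Yv||^2
scca_objective <- function(u, v, X, Y, spec_u, spec_v,
                           alpha1 = 1, alpha2 = 1) {
  if (length(u) != ncol(X))
    stop("length(u) = ", length(u), " does not match ncol(X) = ", ncol(X))
  if (length(v) != ncol(Y))
    stop("length(v) = ", length(v), " does not match ncol(Y) = ", ncol(Y))
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows")
  xu <- drop(X %*% u); yv <- drop(Y %*% v)
  -sum(xu * yv) + penalty_sum(u, spec_u) + penalty_sum(v, spec_v) +
    alpha1 / 2 * sum(xu^2) + alpha2 / 2 * sum(yv^2)
}

# Ridge-type update: solve (diag(d) + alpha * G) w = b with G = M'M via
# Cholesky. Never forms an explicit inverse.
ridge_update <- function(d, G, alpha, b) {
  A <- alpha * G
  diag(A) <- diag(A) + d
  R <- tryCatch(chol(A), error = function(e)
    stop("update system is not positive definite: ", conditionMessage(e)))
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

update_u <- function(X, Y, v, d1, alpha1, XtX = crossprod(X),
                     XtY = crossprod(X, Y)) {
  if (length(v) != ncol(Y)) stop("length(v) does not match ncol(Y)")
  if (length(d1) != ncol(X)) stop("length(d1) does not match ncol(X)")
  if (any(d1 <= 0)) stop("diagonal weights d1 must be positive")
  drop(ridge_update(d1, XtX, alpha1, XtY %*% v))
}

update_v <- function(X, Y, u, d2, alpha2, YtY = crossprod(Y),
                     YtX = crossprod(Y, X)) {
  if (length(u) != ncol(X)) stop("length(u) does not match ncol(X)")
  if (length(d2) != ncol(Y)) stop("length(d2) does not match ncol(Y)")
  if (any(d2 <= 0)) stop("diagonal weights d2 must be positive")
  drop(ridge_update(d2, YtY, alpha2, YtX %*% u))
}

# Rescale w so that ||Mw|| = 1.
rescale <- function(w, M) {
  nrm <- sqrt(sum(drop(M %*% w)^2))
  if (nrm == 0)
    stop("degenerate direction: Mw = 0, cannot rescale to unit score norm")
  w / nrm
}

converged <- function(u_new, u_old, v_new, v_old, epsilon) {
  if (length(u_new) != length(u_old) || length(v_new) != length(v_old))
    stop("iterate length mismatch in convergence check")
  max(abs(u_new - u_old)) <= epsilon && max(abs(v_new - v_old)) <= epsilon
}

standardize_cols <- function(M, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(M)
  M <- sweep(M, 2L, center, "-")
  if (is.null(scale)) {
    scale <- sqrt(colSums(M^2) / (nrow(M) - 1L))
    if (any(scale == 0))
      stop("constant column(s) at position ",
           paste(which(scale == 0), collapse = ", "),
           ": cannot standardize")
  }
  list(M = sweep(M, 2L, scale, "/"), center = center, scale = scale)
}

#' Fit a sparse CCA model with a non-convex penalty
#'
#' Estimates a single pair of sparse canonical vectors \eqn{(u, v)}
#' maximizing the association between \code{Xu} and \code{Yv} under
#' separable penalties \eqn{\Omega(u)}, \eqn{\Omega(v)} and unit
#' score-norm constraints \eqn{\|Xu\| = \|Yv\| = 1}. The objective is
#' the Lagrangian
#' \deqn{-u^\top X^\top Y v + \Omega(u) + \Omega(v)
#'   + \tfrac{\alpha_1}{2}\|Xu\|^2 + \tfrac{\alpha_2}{2}\|Yv\|^2.}
#'
#' Each penalty term is majorized by a local quadratic approximation at
#' the current iterate, so each half-step reduces to a ridge-type linear
#' solve with diagonal reweighting (see [lqa_weights()]); the two blocks
#' are visited alternately (alternate convex search), each followed by
#' rescaling onto the unit-score constraint. Iteration stops when the
#' max absolute change of both vectors falls below
#' \code{control$epsilon}.
#'
#' Columns of \code{X} and \code{Y} are standardized to zero mean and
#' unit variance before fitting; the standardization parameters are
#' stored for use by [predict.nscca()].
#'
#' @param X numeric matrix, n rows (subjects) by p columns (e.g. SNP
#'   dosages).
#' @param Y numeric matrix, n rows by q columns (e.g. imaging
#'   quantitative traits).
#' @param penalty_u,penalty_v [penalty_spec()] objects for the two
#'   views. \code{penalty_v} defaults to \code{penalty_u}.
#' @param control a [nscca_control()] object.
#' @return an object of class \code{"nscca"}: a list with elements
#'   \code{u}, \code{v} (canonical vectors on the standardized scale,
#'   satisfying the unit score-norm constraints on the training data),
#'   \code{corr} (training canonical correlation, sign-fixed to be
#'   nonnegative), \code{objective_trace}, \code{n_iter},
#'   \code{converged}, \code{norm_dev} (largest deviation of the score
#'   norms from 1 over post-rescale iterates), the penalty specs,
#'   control, and the
#'   column standardization parameters.
#' @examples
#' set.seed(1)
#' d <- sim_scca_data(sim_design(n = 40, p = 15, q = 20, seed = 1))
#' fit <- nscca(d$X, d$Y, penalty_spec("mcp", gamma = 0.1))
#' fit
#' @export
nscca <- function(X, Y, penalty_u, penalty_v = penalty_u,
                  control = nscca_control()) {
  stopifnot(is.matrix(X), is.matrix(Y), is.numeric(X), is.numeric(Y),
            inherits(penalty_u, "penalty_spec"),
            inherits(penalty_v, "penalty_spec"),
            inherits(control, "nscca_control"))
  if (nrow(X) != nrow(Y))
    stop("X has ", nrow(X), " rows but Y has ", nrow(Y),
         "; views must share subjects")
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y)))
    stop("X and Y must be finite; impute or drop missing values first")

  sx <- standardize_cols(X); sy <- standardize_cols(Y)
  Xs <- sx$M; Ys <- sy$M
  p <- ncol(Xs); q <- ncol(Ys)

  gram <- list(XtX = crossprod(Xs), YtY = crossprod(Ys),
               XtY = crossprod(Xs, Ys))

  if (control$init == "random") {
    rs <- local_seed(control$seed)
    on.exit(restore_seed(rs), add = TRUE)
    u <- stats::rnorm(p); v <- stats::rnorm(q)
  } else {
    u <- rep(1, p); v <- rep(1, q)
  }
  u <- rescale(u, Xs); v <- rescale(v, Ys)

  both_l1 <- penalty_u$family == "l1" && penalty_v$family == "l1"
  if (control$init == "l1" && !both_l1) {
    # one-step / LLA convention: start the folded-concave solve at the
    # converged convex solution
    warm <- scca_iterate(Xs, Ys, gram,
                         penalty_spec("l1", lam = penalty_u$lam),
                         penalty_spec("l1", lam = penalty_v$lam),
                         control, u, v)
    u <- warm$u; v <- warm$v
  }

  run <- scca_iterate(Xs, Ys, gram, penalty_u, penalty_v, control, u, v)
  u <- run$u; v <- run$v
  trace <- run$trace; n_iter <- run$n_iter; conv <- run$converged
  if (!conv)
    warning("nscca did not converge in ", control$max_iter,
            " iterations (epsilon = ", control$epsilon, ")")

  corr <- canonical_correlation(Xs, Ys, u, v)
  if (corr < 0) {  # sign indeterminacy: fix corr(Xu, Yv) >= 0
    v <- -v
    corr <- -corr
  }

  structure(list(
    u = u, v = v, corr = corr,
    objective_trace = trace, n_iter = n_iter, converged = conv,
    norm_dev = run$norm_dev,
    penalty_u = penalty_u, penalty_v = penalty_v, control = control,
    x_center = sx$center, x_scale = sx$scale,
    y_center = sy$center, y_scale = sy$scale,
    x_names = colnames(X), y_names = colnames(Y),
    n = nrow(X)), class = "nscca")
}

# Core LQA/ACS loop on standardized data with precomputed Gram
# matrices: reweight -> u-solve -> rescale -> reweight -> v-solve ->
# rescale, until both vectors move less than epsilon.
scca_iterate <- function(Xs, Ys, gram, penalty_u, penalty_v, control,
                         u, v) {
  YtX <- t(gram$XtY)
  trace <- numeric(0)
  n_iter <- 0L; conv <- FALSE; norm_dev <- 0
  for (it in seq_len(control$max_iter)) {
    u_old <- u; v_old <- v
    d1 <- lqa_weights(u, penalty_u, control$zeta)
    u <- update_u(Xs, Ys, v, d1, control$alpha1,
                  XtX = gram$XtX, XtY = gram$XtY)
    u <- rescale(u, Xs)
    d2 <- lqa_weights(v, penalty_v, control$zeta)
    v <- update_v(Xs, Ys, u, d2, control$alpha2,
                  YtY = gram$YtY, YtX = YtX)
    v <- rescale(v, Ys)
    n_iter <- it
    norm_dev <- max(norm_dev,
                    abs(sqrt(sum(drop(Xs %*% u)^2)) - 1),
                    abs(sqrt(sum(drop(Ys %*% v)^2)) - 1))
    trace[it] <- scca_objective(u, v, Xs, Ys, penalty_u, penalty_v,
                                control$alpha1, control$alpha2)
    if (converged(u, u_old, v, v_old, control$epsilon)) {
      conv <- TRUE
      break
    }
  }
  list(u = u, v = v, trace = trace, n_iter = n_iter, converged = conv,
       norm_dev = norm_dev)
}

# Seed hygiene: set the RNG locally and restore the caller's state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

# Display convention: loadings below this magnitude print/export as zero.
DISPLAY_ZERO_TOL <- 1e-5

#' @export
print.nscca <- function(x, ...) {
  cat("Sparse CCA with non-convex penalty\n")
  cat("  penalty u: "); print(x$penalty_u)
  cat("  penalty v: "); print(x$penalty_v)
  cat(sprintf("  n = %d, p = %d, q = %d\n", x$n, length(x$u), length(x$v)))
  cat(sprintf("  canonical correlation (train): %.4f\n", x$corr))
  cat(sprintf("  nonzero loadings (|w| > %g): u %d/%d, v %d/%d\n",
              DISPLAY_ZERO_TOL,
              sum(abs(x$u) > DISPLAY_ZERO_TOL), length(x$u),
              sum(abs(x$v) > DISPLAY_ZERO_TOL), length(x$v)))
  cat(sprintf("  %s in %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.nscca <- function(object, ...) {
  structure(list(fit = object,
                 top_u = head_loadings(object$u, object$x_names),
                 top_v = head_loadings(object$v, object$y_names)),
            class = "summary.nscca")
}

head_loadings <- function(w, nm, k = 10L) {
  if (is.null(nm)) nm <- paste0("f", seq_along(w))
  ord <- order(abs(w), decreasing = TRUE)
  keep <- ord[seq_len(min(k, sum(abs(w) > DISPLAY_ZERO_TOL)))]
  data.frame(feature = nm[keep], weight = w[keep], row.names = NULL)
}

#' @export
print.summary.nscca <- function(x, ...) {
  print(x$fit)
  cat("\nLargest |u| loadings:\n"); print(x$top_u, digits = 4)
  cat("\nLargest |v| loadings:\n"); print(x$top_v, digits = 4)
  invisible(x)
}

#' Extract canonical vectors
#'
#' @param object a fitted [nscca()] model.
#' @param view \code{"both"}, \code{"u"} or \code{"v"}.
#' @param zero_tol loadings with absolute value below this are reported
#'   as exact zeros (display convention; set 0 to disable).
#' @param ... unused.
#' @return a named numeric vector (single view) or a list with
#'   components \code{u} and \code{v}.
#' @export
coef.nscca <- function(object, view = c("both", "u", "v"),
                       zero_tol = DISPLAY_ZERO_TOL, ...) {
  view <- match.arg(view)
  zap <- function(w, nm) {
    w[abs(w) < zero_tol] <- 0
    if (!is.null(nm)) names(w) <- nm
    w
  }
  u <- zap(object$u, object$x_names); v <- zap(object$v, object$y_names)
  switch(view, both = list(u = u, v = v), u = u, v = v)
}

#' Canonical scores for new data
#'
#' Applies the training-set column standardization to new matrices and
#' projects them on the fitted canonical vectors.
#'
#' @param object a fitted [nscca()] model.
#' @param newX,newY matrices with the same columns as the training
#'   \code{X} and \code{Y}.
#' @param ... unused.
#' @return a list with score vectors \code{xu}, \code{yv} and their
#'   Pearson correlation \code{corr}.
#' @export
predict.nscca <- function(object, newX, newY, ...) {
  if (ncol(newX) != length(object$u))
    stop("newX has ", ncol(newX), " columns, expected ", length(object$u))
  if (ncol(newY) != length(object$v))
    stop("newY has ", ncol(newY), " columns, expected ", length(object$v))
  Xs <- standardize_cols(newX, object$x_center, object$x_scale)$M
  Ys <- standardize_cols(newY, object$y_center, object$y_scale)$M
  xu <- drop(Xs %*% object$u); yv <- drop(Ys %*% object$v)
  list(xu = xu, yv = yv,
       corr = canonical_correlation(Xs, Ys, object$u, object$v))
}

#' Plot a fitted non-convex sparse CCA model
#'
#' Draws the objective trace and needle plots of the two canonical
#' vectors.
#'
#' @param x a fitted [nscca()] model.
#' @param which subset of \code{1:3} selecting panels (1 = objective
#'   trace, 2 = u loadings, 3 = v loadings).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.nscca <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(length(which), 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (1 %in% which)
    graphics::plot(seq_along(x$objective_trace), x$objective_trace,
                   type = "b", pch = 20, xlab = "iteration",
                   ylab = "objective", main = "Objective trace", ...)
  if (2 %in% which)
    needle_plot(x$u, "u (view X)")
  if (3 %in% which)
    needle_plot(x$v, "v (view Y)")
  invisible(x)
}

needle_plot <- function(w, label) {
  graphics::plot(seq_along(w), w, type = "h", xlab = "feature index",
                 ylab = "weight", main = label)
  graphics::abline(h = 0, col = "grey60")
}
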