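#' Penalty specification for non-convex sparse CCA
#'
#' Constructs a validated specification of one of the eight penalty
#' families available to [nscca()]: the convex l1 baseline plus seven
#' folded-concave penalties that are singular at the origin (hence
#' sparsity-inducing) but level off for large coefficients (hence nearly
#' unbiased for strong signals).
#'
#' The families, with \eqn{t = |u| \ge 0}:
#' \describe{
#'   \item{\code{l1}}{\eqn{\lambda t}.}
#'   \item{\code{lgamma}}{bridge penalty \eqn{\lambda t^\gamma},
#'     \eqn{0 < \gamma < 1}.}
#'   \item{\code{geman}}{\eqn{\lambda t / (t + \gamma)}, \eqn{\gamma > 0}.}
#'   \item{\code{scad}}{smoothly clipped absolute deviation; linear up to
#'     \eqn{\lambda}, quadratic blend on \eqn{[\lambda, \gamma\lambda]},
#'     constant \eqn{\lambda^2(\gamma+1)/2} beyond; \eqn{\gamma > 2}.}
#'   \item{\code{laplace}}{\eqn{\lambda(1 - e^{-t/\gamma})}, \eqn{\gamma > 0}.}
#'   \item{\code{mcp}}{minimax concave penalty
#'     \eqn{\lambda t - t^2/(2\gamma)} on \eqn{[0, \gamma\lambda]},
#'     constant \eqn{\gamma\lambda^2/2} beyond; \eqn{\gamma > 0}.}
#'   \item{\code{etp}}{exponential-type penalty
#'     \eqn{\lambda(1 - e^{-\gamma t})/(1 - e^{-\gamma})}, \eqn{\gamma > 0}.}
#'   \item{\code{log}}{logarithm penalty
#'     \eqn{\lambda \log(\gamma t + 1)/\log(\gamma + 1)}, \eqn{\gamma > 0}.}
#' }
#'
#' @param family one of \code{"l1"}, \code{"lgamma"}, \code{"geman"},
#'   \code{"scad"}, \code{"laplace"}, \code{"mcp"}, \code{"etp"},
#'   \code{"log"}.
#' @param lam nonnegative penalty strength \eqn{\lambda}.
#' @param gamma positive shape parameter \eqn{\gamma}; ignored for
#'   \code{"l1"}. Admissible range depends on the family:
#'   \eqn{0 < \gamma < 1} for \code{lgamma}, \eqn{\gamma > 2} for
#'   \code{scad}, \eqn{\gamma > 0} otherwise. Defaults to the first value
#'   of [gamma_grid()] for the family.
#' @return an object of class \code{"penalty_spec"}.
#' @seealso [penalty_value()], [supergradient()], [gamma_grid()]
#' @examples
#' penalty_spec("scad", lam = 1)          # gamma defaults to 3.7
#' penalty_spec("mcp", lam = 1, gamma = 2)
#' @export
penalty_spec <- function(family = c("l1", "lgamma", "geman", "scad",
                                    "laplace", "mcp", "etp", "log"),
                         lam = 1, gamma = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("'lam' must be a single nonnegative finite number")
  if (is.null(gamma))
    gamma <- if (family == "l1") NA_real_ else gamma_grid(family)[1L]
  if (family != "l1") {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma))
      stop("'gamma' must be a single finite number for family '",
           family, "'")
    ok <- switch(family,
                 lgamma = gamma > 0 && gamma < 1,
                 scad   = gamma > 2,
                 gamma > 0)
    if (!ok)
      stop("'gamma' = ", gamma, " out of range for family '", family,
           "' (lgamma: 0 < gamma < 1; scad: gamma > 2; others: gamma > 0)")
  }
  structure(list(family = family, lam = lam, gamma = as.numeric(gamma)),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  g <- if (x$family == "l1") "" else sprintf(", gamma = %g", x$gamma)
  cat(sprintf("Penalty: %s (lambda = %g%s)\n", x$family, x$lam, g))
  invisible(x)
}

check_magnitude <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("magnitudes must be finite numbers")
  if (any(t < 0))
    stop("magnitudes must be nonnegative (pass |u|, not u)")
  as.numeric(t)
}

#' Evaluate a penalty function
#'
#' Evaluates \eqn{P_{\lambda,\gamma}(t)} for the penalty family in
#' \code{spec} at nonnegative magnitudes \code{t}. Vectorised over
#' \code{t}. All families satisfy \eqn{P(0) = 0}, are nondecreasing, and
#' (except l1 and lgamma) saturate at a finite ceiling.
#'
#' @param t vector of nonnegative magnitudes \eqn{|u_i|}.
#' @param spec a [penalty_spec()].
#' @return numeric vector of penalty values, same length as \code{t}.
#' @examples
#' penalty_value(0:5, penalty_spec("scad", lam = 1, gamma = 3.7))
#' @export
penalty_value <- function(t, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  t <- check_magnitude(t)
  lam <- spec$lam; g <- spec$gamma
  switch(spec$family,
    l1     = lam * t,
    lgamma = lam * t^g,
    geman  = lam * t / (t + g),
    scad   = {
      out <- lam * t
      mid <- t > lam & t < g * lam
      out[mid] <- (-t[mid]^2 + 2 * g * lam * t[mid] - lam^2) / (2 * (g - 1))
      out[t >= g * lam] <- lam^2 * (g + 1) / 2
      out
    },
    laplace = lam * (1 - exp(-t / g)),
    mcp    = {
      out <- lam * t - t^2 / (2 * g)
      out[t >= g * lam] <- g * lam^2 / 2
      out
    },
    etp    = lam / (1 - exp(-g)) * (1 - exp(-g * t)),
    log    = lam / log(g + 1) * log(g * t + 1)
  )
}

#' Supergradient of a penalty function
#'
#' Evaluates the supergradient \eqn{P'_{\lambda,\gamma}(t)} at
#' nonnegative magnitudes. The penalties are concave on \eqn{[0,\infty)},
#' so the supergradient exists everywhere and is nonincreasing in
#' \code{t}. The only infinite value occurs for the \code{lgamma} bridge
#' at \eqn{t = 0}, where \code{Inf} is returned.
#'
#' @inheritParams penalty_value
#' @return numeric vector of supergradient values (possibly \code{Inf}
#'   for \code{lgamma} at 0).
#' @examples
#' supergradient(c(0, 1, 4), penalty_spec("scad", lam = 1, gamma = 3.7))
#' @export
supergradient <- function(t, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  t <- check_magnitude(t)
  lam <- spec$lam; g <- spec$gamma
  switch(spec$family,
    l1     = rep(lam, length(t)),
    lgamma = ifelse(t == 0, Inf, lam * g * t^(g - 1)),
    geman  = lam * g / (t + g)^2,
    scad   = {
      out <- rep(lam, length(t))
      mid <- t > lam & t < g * lam
      out[mid] <- (g * lam - t[mid]) / (g - 1)
      out[t >= g * lam] <- 0
      out
    },
    laplace = lam / g * exp(-t / g),
    mcp    = pmax(lam - t / g, 0),
    etp    = lam * g / (1 - exp(-g)) * exp(-g * t),
    log    = lam * g / ((g * t + 1) * log(g + 1))
  )
}

#' Total penalty of a loading vector
#'
#' \eqn{\Omega(w) = \sum_i P_{\lambda,\gamma}(|w_i|)}, the separable
#' penalty applied entrywise to the absolute loadings.
#'
#' @param w numeric vector of loadings (may be signed).
#' @param spec a [penalty_spec()].
#' @return single nonnegative number.
#' @export
penalty_sum <- function(w, spec) {
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
    stop("'w' must be a finite numeric vector")
  sum(penalty_value(abs(w), spec))
}

#' Diagonal reweighting terms of the local quadratic approximation
#'
#' The LQA surrogate replaces each penalty term by a quadratic
#' majorizer, turning the update into a ridge-type linear solve with
#' diagonal weights \eqn{d_i = P'(s_i) / (|w_i| + \zeta)} where
#' \eqn{s_i = \max(|w_i|, \zeta)}. The perturbation \eqn{\zeta} keeps the
#' weights defined at exact zeros; evaluating the supergradient at
#' \eqn{s_i} rather than \eqn{|w_i|} keeps the lgamma family finite at
#' the origin. Weights are floored at \code{1e-12} so the update system
#' stays positive definite even where the supergradient vanishes (SCAD
#' and MCP beyond their clip point) and the Gram matrix is
#' rank-deficient.
#'
#' @param w numeric vector of current loadings.
#' @param spec a [penalty_spec()].
#' @param zeta tiny positive perturbation (default \code{1e-6}).
#' @return positive numeric vector of diagonal weights, same length as
#'   \code{w}.
#' @export
lqa_weights <- function(w, spec, zeta = 1e-6) {
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) ||
      zeta <= 0)
    stop("'zeta' must be a single positive number")
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
    stop("'w' must be a finite numeric vector")
  a <- abs(w)
  d <- supergradient(pmax(a, zeta), spec) / (a + zeta)
  pmax(d, 1e-12)
}

#' Default search grid for the shape parameter gamma
#'
#' Returns the candidate \eqn{\gamma} values searched by
#' [grid_search_gamma()] for each non-convex family: a small discrete
#' grid per family, and the single conventional value 3.7 for SCAD. The
#' l1 baseline has no shape parameter and returns an empty grid.
#'
#' @param family penalty family name.
#' @return numeric vector of gamma candidates (empty for \code{"l1"}).
#' @export
gamma_grid <- function(family = c("l1", "lgamma", "geman", "scad",
                                  "laplace", "mcp", "etp", "log")) {
  family <- match.arg(family)
  switch(family,
         l1      = numeric(0),
         lgamma  = c(0.1, 0.2, 0.3),
         scad    = 3.7,
         geman   = c(0.1, 0.01, 0.001),
         laplace = c(0.1, 0.01, 0.001),
         mcp     = c(0.1, 0.01, 0.001),
         etp     = c(10, 100, 1000),
         log     = c(10, 100, 1000))
}

#' All penalty family names
#'
#' @param nonconvex_only if \code{TRUE}, drop the l1 baseline.
#' @return character vector of family names.
#' @export
penalty_families <- function(nonconvex_only = FALSE) {
  fams <- c("l1", "lgamma", "geman", "scad", "laplace", "mcp", "etp", "log")
  if (nonconvex_only) fams[-1L] else fams
}
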