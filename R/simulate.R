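#' Block-sparse ground-truth loading vectors
#'
#' Builds a pair of piecewise-constant nonnegative loading vectors with
#' a few contiguous nonzero blocks, the sparsity pattern used by the
#' built-in simulation designs. Each vector is split into
#' \code{n_blocks} equal segments and one block of width
#' \code{block_width} is placed uniformly at random inside each segment,
#' so blocks never overlap.
#'
#' @param p,q lengths of the two vectors.
#' @param n_blocks number of nonzero blocks in each vector (default 3).
#' @param block_width width of each block; a length-2 vector gives
#'   different widths for u and v. The default (\code{NULL}) sizes each
#'   width as \code{round(length / (8 * n_blocks))} (at least 1), i.e.
#'   roughly 12\% of features carry signal.
#' @param amplitude positive block heights, recycled across blocks
#'   (default 1 for every block). Note that with the exponential-decay
#'   noise kernel, features sharing a loading value are perfectly
#'   correlated, so equal-height blocks make all signal features of a
#'   view exchangeable.
#' @param seed integer seed controlling block placement.
#' @return list with numeric vectors \code{u} (length p) and \code{v}
#'   (length q).
#' @export
block_signals <- function(p, q, n_blocks = 3L, block_width = NULL,
                          amplitude = NULL, seed = 1L) {
  stopifnot(p >= 1, q >= 1, n_blocks >= 1)
  if (is.null(amplitude)) amplitude <- 1
  if (any(amplitude <= 0)) stop("'amplitude' must be positive")
  if (is.null(block_width))
    block_width <- pmax(1L, as.integer(round(c(p, q) / (8 * n_blocks))))
  block_width <- rep_len(as.integer(block_width), 2L)
  rs <- local_seed(seed); on.exit(restore_seed(rs))
  list(u = one_block_vector(p, n_blocks, block_width[1L], amplitude),
       v = one_block_vector(q, n_blocks, block_width[2L], amplitude))
}

one_block_vector <- function(len, n_blocks, width, amplitude) {
  seg <- floor(len / n_blocks)
  if (width > seg)
    stop("block width ", width, " does not fit ", n_blocks,
         " non-overlapping blocks in a vector of length ", len)
  amplitude <- rep_len(amplitude, n_blocks)
  w <- numeric(len)
  for (b in seq_len(n_blocks)) {
    lo <- (b - 1L) * seg + 1L
    start <- lo + sample.int(seg - width + 1L, 1L) - 1L
    w[start:(start + width - 1L)] <- amplitude[b]
  }
  w
}

#' Simulation design for latent-variable paired data
#'
#' Describes one synthetic dataset: a shared latent factor
#' \eqn{z \sim N(0, I_n)} drives both views through sparse ground-truth
#' loadings, \eqn{x_i \sim N(z_i\, s\, u,\ \Sigma_x)} and
#' \eqn{y_i \sim N(z_i\, s\, v,\ \Sigma_y)}, where \eqn{s} is
#' \code{signal_scale} and the noise covariances are the Laplacian-decay
#' kernels \eqn{(\Sigma_x)_{jk} = \exp(-|u_j - u_k|)},
#' \eqn{(\Sigma_y)_{jk} = \exp(-|v_j - v_k|)} over the true loading
#' entries. Features within a signal block are therefore strongly
#' correlated with one another, as are the null features.
#'
#' @param n number of observations; the intended regime is
#'   \eqn{n < p + q} (a warning is raised otherwise).
#' @param p,q feature counts of the two views.
#' @param true_u,true_v ground-truth loading vectors; default
#'   block-sparse signals from [block_signals()].
#' @param signal_scale nonnegative multiplier \eqn{s} on the latent
#'   mean term; larger values give a stronger population canonical
#'   correlation. 0 gives null (uncorrelated) data.
#' @param seed integer seed used for both the default signals and data
#'   generation.
#' @return an object of class \code{"sim_design"}.
#' @seealso [sim_scca_data()], [sim_presets()]
#' @export
sim_design <- function(n = 100L, p = 250L, q = 600L,
                       true_u = NULL, true_v = NULL,
                       signal_scale = 3, seed = 1L) {
  stopifnot(n >= 2, p >= 2, q >= 2, signal_scale >= 0)
  if (is.null(true_u) || is.null(true_v)) {
    sig <- block_signals(p, q, seed = seed)
    if (is.null(true_u)) true_u <- sig$u
    if (is.null(true_v)) true_v <- sig$v
  }
  stopifnot(length(true_u) == p, length(true_v) == q)
  nz_u <- sum(true_u != 0); nz_v <- sum(true_v != 0)
  if (nz_u == 0 || nz_v == 0)
    stop("ground-truth loadings must have at least one nonzero entry")
  if (nz_u >= p || nz_v >= q)
    stop("ground-truth loadings must be sparse (fewer nonzeros than length)")
  if (n >= p + q)
    warning("n >= p + q: outside the intended high-dimensional regime")
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 true_u = as.numeric(true_u), true_v = as.numeric(true_v),
                 signal_scale = signal_scale, seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: n = %d, p = %d, q = %d, signal_scale = %g\n",
    x$n, x$p, x$q, x$signal_scale))
  cat(sprintf("  nonzeros: %d in u, %d in v; seed = %d\n",
              sum(x$true_u != 0), sum(x$true_v != 0), x$seed))
  invisible(x)
}

# exp(-|w_j - w_k|) kernel covariance over the loading entries.
signal_kernel <- function(w) {
  exp(-abs(outer(w, w, "-")))
}

# Upper Cholesky factor with a tiny diagonal jitter fallback.
chol_factor <- function(S) {
  tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-10, nrow(S)))
  })
}

#' Generate a synthetic paired dataset
#'
#' Draws one dataset from a [sim_design()]: latent
#' \eqn{z \sim N(0, I_n)}, then row-wise
#' \eqn{x_i \sim N(z_i\, s\, u, \Sigma_x)},
#' \eqn{y_i \sim N(z_i\, s\, v, \Sigma_y)} with the exponential-decay
#' kernel covariances described there. One Cholesky factor per view is
#' computed and reused across rows. Fully reproducible from the design's
#' seed.
#'
#' @param design a [sim_design()].
#' @return list of class \code{"sim_data"} with matrices \code{X}
#'   (n x p), \code{Y} (n x q), the latent \code{z}, ground truth
#'   \code{true_u}, \code{true_v}, and the \code{design}.
#' @export
sim_scca_data <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  rs <- local_seed(design$seed); on.exit(restore_seed(rs))
  n <- design$n; p <- design$p; q <- design$q
  Rx <- chol_factor(signal_kernel(design$true_u))
  Ry <- chol_factor(signal_kernel(design$true_v))
  z <- stats::rnorm(n)
  mu_x <- design$signal_scale * tcrossprod(z, design$true_u)
  mu_y <- design$signal_scale * tcrossprod(z, design$true_v)
  X <- mu_x + matrix(stats::rnorm(n * p), n, p) %*% Rx
  Y <- mu_y + matrix(stats::rnorm(n * q), n, q) %*% Ry
  colnames(X) <- paste0("x", seq_len(p))
  colnames(Y) <- paste0("y", seq_len(q))
  structure(list(X = X, Y = Y, z = z,
                 true_u = design$true_u, true_v = design$true_v,
                 design = design), class = "sim_data")
}

#' Built-in simulation designs
#'
#' Four standard designs in the high-dimensional, small-sample regime:
#' designs 1-3 have (p, q) = (250, 600) at three signal strengths
#' (strong, weak, intermediate), design 4 has (p, q) = (500, 900). All
#' use n = 100 observations and block-sparse ground truth.
#'
#' @param seed integer seed carried into each design.
#' @return list of four [sim_design()] objects.
#' @export
sim_presets <- function(seed = 1L) {
  shapes <- list(c(250L, 600L), c(250L, 600L), c(250L, 600L),
                 c(500L, 900L))
  scales <- c(3, 0.8, 1.5, 3)
  lapply(1:4, function(i)
    sim_design(n = 100L, p = shapes[[i]][1L], q = shapes[[i]][2L],
               signal_scale = scales[i], seed = seed))
}
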