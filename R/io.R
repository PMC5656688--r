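#' Read a numeric matrix from a delimited text file
#'
#' Strict reader for subjects-by-features tables: every row must have
#' the same number of fields and every data cell must parse as a
#' number. Parse problems are reported with the offending line (and
#' column) rather than silently coerced to NA.
#'
#' @param path file path.
#' @param delimiter field separator; \code{NULL} (default) infers tab
#'   vs comma from the first line.
#' @param header logical, is the first line a header of column names?
#' @param row_ids logical, is the first column a row identifier?
#' @return numeric matrix with any column/row names attached.
#' @export
read_matrix <- function(path, delimiter = NULL, header = TRUE,
                        row_ids = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty input file: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged table in ", path, ": line ", bad, " has ", widths[bad],
         " fields, expected ", widths[1L])
  }
  cn <- NULL
  if (header) {
    cn <- cells[[1L]]
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("no data rows in ", path)
  }
  rn <- NULL
  if (row_ids) {
    rn <- vapply(cells, `[[`, "", 1L)
    cells <- lapply(cells, `[`, -1L)
    if (!is.null(cn)) cn <- cn[-1L]
  }
  M <- matrix(NA_real_, length(cells), length(cells[[1L]]))
  for (i in seq_along(cells)) {
    vals <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop("non-numeric cell in ", path, " at data row ", i,
           ", column ", j, ": '", cells[[i]][j], "'")
    }
    M[i, ] <- vals
  }
  dimnames(M) <- list(rn, cn)
  M
}

#' Write a numeric matrix as delimited text
#'
#' @param M numeric matrix.
#' @param path output path.
#' @param delimiter field separator (default comma).
#' @export
write_matrix <- function(M, path, delimiter = ",") {
  utils::write.table(M, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE,
                     col.names = !is.null(colnames(M)))
  invisible(path)
}

write_loadings <- function(w, nm, path) {
  if (is.null(nm)) nm <- paste0("f", seq_along(w))
  shown <- ifelse(abs(w) < DISPLAY_ZERO_TOL, 0, w)
  utils::write.table(
    data.frame(feature_id = nm, weight = format(shown, digits = 17)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted model to an output directory
#'
#' Writes the two canonical vectors as two-column TSV files
#' (\code{feature_id}, \code{weight}; magnitudes below \code{1e-5} are
#' written as 0) and a JSON manifest recording the penalties, solver
#' settings, iteration count, convergence flag and training
#' correlation, sufficient to reproduce the run.
#'
#' @param fit a fitted [nscca()] model.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fit <- function(fit, outdir) {
  stopifnot(inherits(fit, "nscca"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pu <- file.path(outdir, "loadings_u.tsv")
  pv <- file.path(outdir, "loadings_v.tsv")
  write_loadings(fit$u, fit$x_names, pu)
  write_loadings(fit$v, fit$y_names, pv)
  manifest <- list(
    penalty_u = unclass(fit$penalty_u),
    penalty_v = unclass(fit$penalty_v),
    control = unclass(fit$control),
    n = fit$n, p = length(fit$u), q = length(fit$v),
    n_iter = fit$n_iter, converged = fit$converged,
    train_corr = fit$corr)
  pm <- file.path(outdir, "fit_manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(pu, pv, pm))
}

#' Write a cross-validation report
#'
#' One TSV row per fold plus a JSON manifest (penalty, control, seed,
#' fold assignment).
#'
#' @param cv an [cv_nscca()] report.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cv_report <- function(cv, outdir) {
  stopifnot(inherits(cv, "nscca_cv"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ps <- file.path(outdir, "cv_summary.tsv")
  utils::write.table(cv$summary, ps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(k = cv$k, seed = cv$seed, folds = cv$folds,
                   penalty_u = unclass(cv$penalty_u),
                   penalty_v = unclass(cv$penalty_v),
                   control = unclass(cv$control))
  pm <- file.path(outdir, "cv_manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(ps, pm))
}

#' Write a simulated dataset
#'
#' Writes X and Y as CSV, ground-truth loadings as TSV, and a JSON
#' manifest recording the design and seed.
#'
#' @param data a [sim_scca_data()] result.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_sim_data <- function(data, outdir) {
  stopifnot(inherits(data, "sim_data"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  px <- file.path(outdir, "X.csv"); py <- file.path(outdir, "Y.csv")
  write_matrix(data$X, px); write_matrix(data$Y, py)
  pu <- file.path(outdir, "true_u.tsv")
  pv <- file.path(outdir, "true_v.tsv")
  write_loadings(data$true_u, colnames(data$X), pu)
  write_loadings(data$true_v, colnames(data$Y), pv)
  d <- data$design
  manifest <- list(n = d$n, p = d$p, q = d$q,
                   signal_scale = d$signal_scale, seed = d$seed,
                   nonzeros_u = sum(d$true_u != 0),
                   nonzeros_v = sum(d$true_v != 0))
  pm <- file.path(outdir, "sim_manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(px, py, pu, pv, pm))
}

# Load paired matrices for the CLI, validating shared row counts.
load_views <- function(x_path, y_path, cov_path = NULL, header = TRUE) {
  X <- read_matrix(x_path, header = header)
  Y <- read_matrix(y_path, header = header)
  if (nrow(X) != nrow(Y))
    stop("row-count mismatch: ", x_path, " has ", nrow(X), " rows but ",
         y_path, " has ", nrow(Y))
  if (!is.null(cov_path)) {
    C <- read_matrix(cov_path, header = header)
    if (nrow(C) != nrow(X))
      stop("row-count mismatch: covariates have ", nrow(C),
           " rows but X has ", nrow(X))
    if (max(abs(C[, 1L] - 1)) > 0) C <- cbind(intercept = 1, C)
    X <- residualize_covariates(X, C)
    Y <- residualize_covariates(Y, C)
  }
  list(X = X, Y = Y)
}
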