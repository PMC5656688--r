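test_that("objective matches term-by-term dense recomputation", {
  l0 <- penalty_spec("l1", lam = 0)
  expect_equal(nscca:::scca_objective(c(0, 0), c(0, 0), diag(2), diag(2),
                                      l0, l0), 0)
  expect_equal(nscca:::scca_objective(c(1, 0), c(1, 0), diag(2), diag(2),
                                      l0, l0, 1, 1), 0)  # -1 + 0.5 + 0.5
  set.seed(7)
  X <- matrix(rnorm(8 * 5), 8); Y <- matrix(rnorm(8 * 6), 8)
  u <- rnorm(5); v <- rnorm(6)
  su <- penalty_spec("scad", lam = 0.7, gamma = 3.7)
  sv <- penalty_spec("mcp", lam = 1.2, gamma = 2)
  got <- nscca:::scca_objective(u, v, X, Y, su, sv, 1.3, 0.4)
  # independent dense recomputation, term by term
  want <- -t(u) %*% t(X) %*% Y %*% v +
    sum(sapply(abs(u), penalty_value, spec = su)) +
    sum(sapply(abs(v), penalty_value, spec = sv)) +
    1.3 / 2 * sum((X %*% u)^2) + 0.4 / 2 * sum((Y %*% v)^2)
  expect_equal(got, drop(want), tolerance = 1e-10)
  expect_error(nscca:::scca_objective(c(1, 2, 3), v, X, Y, su, sv),
               "ncol\\(X\\)")
})

test_that("ridge-type updates solve the reweighted normal equations", {
  expect_equal(nscca:::update_u(diag(2), diag(2), c(1, 0), c(1, 1), 1),
               c(0.5, 0))
  expect_equal(nscca:::update_v(diag(2), diag(2), c(0, 1), c(1, 1), 1),
               c(0, 0.5))
  set.seed(11)
  X <- matrix(rnorm(10 * 8), 10); Y <- matrix(rnorm(10 * 7), 10)
  v <- rnorm(7); d1 <- runif(8, 0.1, 2); a1 <- 1.7
  u <- nscca:::update_u(X, Y, v, d1, a1)
  # dense oracle: explicit solve of the full system
  A <- diag(d1) + a1 * t(X) %*% X
  expect_equal(u, drop(solve(A, t(X) %*% Y %*% v)), tolerance = 1e-9)
  # stationarity residual of the subproblem normal equations
  r <- -t(X) %*% Y %*% v + A %*% u
  expect_lt(max(abs(r)), 1e-8 * (1 + max(abs(t(X) %*% Y %*% v))))
  # role symmetry: update_v is update_u with views exchanged
  d2 <- runif(7, 0.1, 2); w <- rnorm(8)
  expect_equal(nscca:::update_v(X, Y, w, d2, a1),
               nscca:::update_u(Y, X, w, d2, a1), tolerance = 1e-12)
  expect_error(nscca:::update_u(X, Y, v, rep(0, 8), 1), "positive")
})

test_that("rescale enforces the unit score-norm constraint", {
  expect_equal(nscca:::rescale(c(3, 4), diag(2)), c(0.6, 0.8))
  set.seed(3)
  M <- matrix(rnorm(12), 4, 3); w <- rnorm(3)
  w1 <- nscca:::rescale(w, M)
  expect_equal(sqrt(sum((M %*% w1)^2)), 1, tolerance = 1e-12)
  expect_equal(nscca:::rescale(w1, M), w1, tolerance = 1e-12)  # idempotent
  expect_equal(nscca:::rescale(5 * w, M), w1, tolerance = 1e-12)
  expect_error(nscca:::rescale(c(1, -1, 0), matrix(0, 2, 3)), "degenerate")
})

test_that("convergence test requires both vectors to settle", {
  u <- runif(5); v <- runif(6)
  expect_true(nscca:::converged(u, u, v, v, 1e-5))
  expect_false(nscca:::converged(u + 2e-5, u, v, v, 1e-5))
  expect_true(nscca:::converged(u + 9e-6, u, v + 9e-6, v, 1e-5))
  expect_error(nscca:::converged(u, u[-1], v, v, 1e-5), "mismatch")
})

test_that("fitted models satisfy the scale constraints and recover strong signal", {
  d <- small_sim(seed = 5)
  for (fam in c("l1", "scad", "log")) {
    fit <- suppressWarnings(nscca(d$X, d$Y, penalty_spec(fam)))
    Xs <- scale(d$X); Ys <- scale(d$Y)
    expect_equal(sqrt(sum((Xs %*% fit$u)^2)), 1, tolerance = 1e-8)
    expect_equal(sqrt(sum((Ys %*% fit$v)^2)), 1, tolerance = 1e-8)
    expect_lt(fit$norm_dev, 1e-8)
    expect_gte(fit$corr, 0)
    expect_equal(auc_support(fit$u, d$true_u != 0), 1)
    expect_equal(auc_support(fit$v, d$true_v != 0), 1)
    expect_length(fit$objective_trace, fit$n_iter)
  }
})

test_that("objective trace decreases at the reference problem scale", {
  # full-trace monotonicity is an empirical property at the study scale
  # (the certified guarantee is the half-step inequality below)
  for (s in 1:2) {
    d <- sim_scca_data(sim_presets(seed = 40 + s)[[1]])
    for (fam in penalty_families()) {
      fit <- suppressWarnings(nscca(d$X, d$Y, penalty_spec(fam)))
      tr <- fit$objective_trace
      if (length(tr) > 1) {
        rel <- diff(tr) / pmax(abs(tr[-length(tr)]), 1)
        expect_lt(max(rel), 1e-8, label = paste(fam, "descent, seed", s))
      }
    }
  }
})

test_that("pre-rescale half-steps never increase the Lagrangian", {
  # the certified majorize-minimize inequality: each subproblem solve,
  # evaluated before rescaling, does not increase the objective
  d <- small_sim(seed = 9, n = 40, p = 20, q = 25)
  Xs <- scale(d$X); Ys <- scale(d$Y)
  XtX <- crossprod(Xs); YtY <- crossprod(Ys); XtY <- crossprod(Xs, Ys)
  for (fam in penalty_families()) {
    spec <- penalty_spec(fam)
    u <- nscca:::rescale(rep(1, 20), Xs)
    v <- nscca:::rescale(rep(1, 25), Ys)
    for (it in 1:15) {
      L0 <- nscca:::scca_objective(u, v, Xs, Ys, spec, spec)
      ut <- nscca:::update_u(Xs, Ys, v, lqa_weights(u, spec), 1, XtX, XtY)
      L1 <- nscca:::scca_objective(ut, v, Xs, Ys, spec, spec)
      expect_lte(L1, L0 + 1e-8 * max(abs(L0), 1), label = fam)
      u <- nscca:::rescale(ut, Xs)
      L2 <- nscca:::scca_objective(u, v, Xs, Ys, spec, spec)
      vt <- nscca:::update_v(Xs, Ys, u, lqa_weights(v, spec), 1, YtY,
                             t(XtY))
      L3 <- nscca:::scca_objective(u, vt, Xs, Ys, spec, spec)
      expect_lte(L3, L2 + 1e-8 * max(abs(L2), 1), label = fam)
      v <- nscca:::rescale(vt, Ys)
    }
  }
})

test_that("column permutations permute the loadings identically", {
  d <- small_sim(seed = 2)
  fit <- nscca(d$X, d$Y, penalty_spec("scad"))
  set.seed(1)
  pp <- sample(ncol(d$X)); pq <- sample(ncol(d$Y))
  fit2 <- nscca(d$X[, pp], d$Y[, pq], penalty_spec("scad"))
  expect_equal(fit2$u, fit$u[pp], tolerance = 1e-8)
  expect_equal(fit2$v, fit$v[pq], tolerance = 1e-8)
})

test_that("swapping the views swaps the canonical vectors", {
  d <- small_sim(seed = 4)
  f1 <- nscca(d$X, d$Y, penalty_spec("scad"))
  f2 <- nscca(d$Y, d$X, penalty_spec("scad"))
  expect_equal(f2$corr, f1$corr, tolerance = 1e-3)
  align <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(align(f2$u, f1$v), 0.999)
  expect_gt(align(f2$v, f1$u), 0.999)
})

test_that("l1 support shrinks as lambda grows", {
  d <- small_sim(seed = 6)
  sizes <- sapply(c(0.2, 0.5, 1, 2, 5), function(l) {
    fit <- suppressWarnings(
      nscca(d$X, d$Y, penalty_spec("l1", lam = l)))
    sum(abs(fit$u) > 1e-3)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("scad and mcp stop shrinking large converged coefficients", {
  # once |w| clears gamma*lambda the supergradient is 0 and the LQA
  # weight collapses to the floor, unlike the always-positive l1 weight
  spec <- penalty_spec("scad", lam = 1, gamma = 3.7)
  w <- c(5, 0.5)
  expect_equal(lqa_weights(w, spec)[1], 1e-12)
  expect_gt(lqa_weights(w, spec)[2], 1e-3)
  expect_gt(lqa_weights(w, penalty_spec("l1"))[1], 0.1)
  d <- small_sim(seed = 8)
  fit <- nscca(d$X, d$Y, penalty_spec("mcp", gamma = 0.001))
  big <- abs(fit$u) >= 0.001 * 1  # |u| >= gamma * lambda
  expect_true(any(big))
  expect_equal(unname(lqa_weights(fit$u, fit$penalty_u)[big]),
               rep(1e-12, sum(big)))
})

test_that("deterministic and seeded-random initializations reproduce", {
  d <- small_sim(seed = 10)
  f1 <- suppressWarnings(nscca(d$X, d$Y, penalty_spec("log")))
  f2 <- suppressWarnings(nscca(d$X, d$Y, penalty_spec("log")))
  expect_identical(f1$u, f2$u)
  cr <- nscca_control(init = "random", seed = 33)
  f3 <- suppressWarnings(nscca(d$X, d$Y, penalty_spec("log"), control = cr))
  f4 <- suppressWarnings(nscca(d$X, d$Y, penalty_spec("log"), control = cr))
  expect_identical(f3$u, f4$u)
  expect_error(nscca_control(init = "random"), "seed")
})

test_that("non-convergence is flagged, not thrown", {
  nv <- noise_views(seed = 12)
  expect_warning(
    fit <- nscca(nv$X, nv$Y, penalty_spec("mcp"),
                 control = nscca_control(max_iter = 3)),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 3L)
})

test_that("mismatched or non-finite inputs are rejected", {
  nv <- noise_views()
  expect_error(nscca(nv$X[-1, ], nv$Y, penalty_spec("l1")), "rows")
  Xbad <- nv$X; Xbad[2, 3] <- NA
  expect_error(nscca(Xbad, nv$Y, penalty_spec("l1")), "finite")
  Xconst <- nv$X; Xconst[, 2] <- 7
  expect_error(nscca(Xconst, nv$Y, penalty_spec("l1")), "standardize")
})

test_that("predict applies training standardization to new data", {
  d <- small_sim(seed = 13, n = 60, p = 40, q = 50)
  tr <- 1:45; te <- 46:60
  fit <- nscca(d$X[tr, ], d$Y[tr, ], penalty_spec("scad"))
  pr <- predict(fit, d$X[te, ], d$Y[te, ])
  expect_length(pr$xu, 15)
  expect_true(abs(pr$corr) <= 1)
  # manual standardization oracle
  Xs <- sweep(sweep(d$X[te, ], 2, fit$x_center), 2, fit$x_scale, "/")
  expect_equal(pr$xu, drop(Xs %*% fit$u), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(predict(fit, d$X[te, -1], d$Y[te, ]), "columns")
})

test_that("print, summary, coef and plot methods run", {
  d <- small_sim(seed = 14)
  fit <- suppressWarnings(nscca(d$X, d$Y, penalty_spec("etp")))
  expect_output(print(fit), "canonical correlation")
  expect_output(print(summary(fit)), "Largest")
  cf <- coef(fit)
  expect_named(cf, c("u", "v"))
  expect_true(all(cf$u[abs(fit$u) < 1e-5] == 0))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})
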