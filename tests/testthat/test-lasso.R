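test_that("binding matrix construction is binary and validates gene ids", {
  A <- build_binding_matrix(list(F1 = "g1"), c("g1", "g2"))
  expect_equal(unname(A[, "F1"]), c(1L, 0L))
  # repeated listing still yields a 0/1 entry
  A2 <- build_binding_matrix(list(F1 = c("g1", "g1")), c("g1", "g2"))
  expect_equal(unname(A2[, "F1"]), c(1L, 0L))
  expect_error(build_binding_matrix(list(F1 = "gX"), c("g1", "g2")), "gX")
})

test_that("above lambda_max the fit is the null model", {
  set.seed(21)
  X <- matrix(rbinom(400, 1, 0.3), 100, 4,
              dimnames = list(NULL, paste0("F", 1:4)))
  y <- rbinom(100, 1, 0.4)
  lmax <- lambda_max(X, y)
  fit <- fit_penalized_logistic(X, y, lmax * 1.01)
  expect_equal(unname(fit$coefficients), rep(0, 4))
  expect_equal(fit$intercept, log(mean(y) / (1 - mean(y))), tolerance = 1e-7)
})

test_that("the unpenalized limit matches an independent IRLS solver", {
  set.seed(22)
  X <- matrix(rbinom(300, 1, 0.4), 100, 3,
              dimnames = list(NULL, paste0("F", 1:3)))
  eta <- -0.5 + X %*% c(1, -0.7, 0)
  y <- rbinom(100, 1, plogis(eta))
  fit <- fit_penalized_logistic(X, y, 0)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$intercept), unname(coef(ref)[1]),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-6)
})

test_that("penalized fits agree with the reference path solver", {
  skip_if_not_installed("glmnet")
  set.seed(23)
  X <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6,
              dimnames = list(NULL, paste0("F", 1:6)))
  y <- rbinom(200, 1, plogis(-0.4 + X %*% c(1.2, -0.8, 0.5, 0, 0, 0)))
  lams <- lambda_grid(X, y, n_lambda = 25, min_ratio = 1e-2)
  ours <- epibuffr:::.fit_path(X, y, lams)
  ref <- glmnet::glmnet(X, y, family = "binomial", lambda = lams,
                        standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(ours$beta), unname(as.matrix(ref$beta)),
               tolerance = 1e-4)
  expect_equal(unname(ours$gamma), unname(ref$a0), tolerance = 1e-4)
})

test_that("a perfectly separating column is selected and decoys stay at exactly zero", {
  # 2-feature instance, oracle = grid optimization over (beta1, beta2,
  # gamma) using the pattern-collapsed objective
  set.seed(24)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x1 <- y                                   # perfect separator
  x2 <- rbinom(n, 1, 0.5)                   # decoy
  lambda <- 0.15
  pat <- table(x1 = x1, x2 = x2, y = y)
  idx <- expand.grid(x1 = 0:1, x2 = 0:1, y = 0:1)
  cnt <- mapply(function(a, b, c) pat[a + 1, b + 1, c + 1],
                idx$x1, idx$x2, idx$y)
  grid <- expand.grid(b1 = seq(0, 4, 0.02), b2 = seq(-1, 1, 0.02),
                      g = seq(-3, 1, 0.02))
  vals <- lambda * (abs(grid$b1) + abs(grid$b2))
  for (pt in seq_len(nrow(idx))) {
    eta <- grid$g + grid$b1 * idx$x1[pt] + grid$b2 * idx$x2[pt]
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    vals <- vals + cnt[pt] * (lse - idx$y[pt] * eta) / n
  }
  best <- grid[which.min(vals), ]
  expect_gt(best$b1, 0)
  expect_equal(best$b2, 0)

  fit <- fit_penalized_logistic(cbind(F1 = x1, F2 = x2), y, lambda)
  expect_gt(fit$coefficients["F1"], 0)
  expect_identical(unname(fit$coefficients["F2"]), 0)
  expect_equal(unname(fit$coefficients["F1"]), best$b1, tolerance = 0.03)
  expect_equal(fit$intercept, best$g, tolerance = 0.03)
})

test_that("KKT residuals are tiny and the active set grows down the path", {
  set.seed(25)
  X <- matrix(rbinom(500 * 8, 1, 0.25), 500, 8,
              dimnames = list(NULL, paste0("F", 1:8)))
  y <- rbinom(500, 1, plogis(-0.5 + X %*% c(1.5, -1, 0.6, 0, 0, 0, 0, 0)))
  lams <- lambda_grid(X, y, n_lambda = 40, min_ratio = 1e-3)
  path <- epibuffr:::.fit_path(X, y, lams)
  expect_true(all(path$kkt < 1e-6))
  active <- colSums(path$beta != 0)
  # lams decrease along the path: active set size is non-decreasing
  expect_true(all(diff(active) >= 0))
  # objective at each lambda is below the null-model objective
  null_obj <- {
    p0 <- mean(y)
    -mean(y * log(p0) + (1 - y) * log(1 - p0))
  }
  expect_true(all(path$objective <= null_obj + 1e-10))
})

test_that("outcome validation rejects non-binary and constant labels", {
  X <- matrix(rbinom(40, 1, 0.5), 20, 2)
  expect_error(fit_penalized_logistic(X, rnorm(20), 0.1), "binary")
  expect_error(fit_penalized_logistic(X, rep(1, 20), 0.1), "degenerate")
})

test_that("standardized coefficients back-transform to the original scale", {
  set.seed(26)
  X <- matrix(rbinom(300 * 5, 1, c(0.1, 0.3, 0.5, 0.2, 0.4)), 300, 5,
              byrow = TRUE, dimnames = list(NULL, paste0("F", 1:5)))
  y <- rbinom(300, 1, plogis(-0.3 + X %*% c(1, 0, -0.8, 0, 0.4)))
  lam <- 0.02
  fit_std <- fit_penalized_logistic(X, y, lam, standardize = TRUE)
  s <- sqrt(colMeans(X^2) - colMeans(X)^2)
  manual <- fit_penalized_logistic(sweep(X, 2, s, "/"), y, lam)
  expect_equal(fit_std$coefficients, manual$coefficients / s,
               tolerance = 1e-8)
})

test_that("cross-validation handles leave-one-out and degenerate designs", {
  set.seed(27)
  X <- matrix(rbinom(36, 1, 0.5), 12, 3,
              dimnames = list(NULL, paste0("F", 1:3)))
  y <- rep(c(0, 1), 6)
  cv <- cross_validate_select(X, y, k = 12, seed = 1)
  expect_s3_class(cv$fit, "penalized_fit")
  expect_true(cv$lambda_choice %in% cv$lambda)

  # a fold without both classes is refused with advice
  y_rare <- c(rep(0, 17), rep(1, 3))
  X20 <- matrix(rbinom(60, 1, 0.5), 20, 3)
  expect_error(cross_validate_select(X20, y_rare, k = 10, seed = 1),
               "smaller k")

  # constant columns are dropped with a warning
  Xc <- cbind(X, F4 = 1L)
  expect_warning(cvc <- cross_validate_select(Xc, y, k = 4, seed = 1),
                 "degenerate")
  expect_false("F4" %in% names(cvc$fit$coefficients))
})

test_that("duplicate binding columns resolve deterministically and are flagged aliased", {
  set.seed(28)
  n <- 400
  x <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 2 * x))
  X <- cbind(F1 = x, F2 = rbinom(n, 1, 0.3), F3 = x)
  cv1 <- cross_validate_select(X, y, k = 5, seed = 3)
  cv2 <- cross_validate_select(X, y, k = 5, seed = 3)
  expect_identical(cv1$fit$coefficients, cv2$fit$coefficients)
  expect_equal(cv1$aliased, list(c("F1", "F3")))
  rk <- rank_factors(cv1)
  expect_true(all(rk$aliased[rk$factor_id %in% c("F1", "F3")]))
  # the shared effect equals the single-copy fit's coefficient
  single <- fit_penalized_logistic(X[, 1:2], y, cv1$lambda_choice)
  expect_equal(sum(cv1$fit$coefficients[c("F1", "F3")]),
               unname(single$coefficients["F1"]), tolerance = 1e-6)
})

test_that("factor ranking reports both orientations and the all-zero case", {
  fit <- structure(
    list(coefficients = c(F2 = 0, F1 = 0, F3 = 0), intercept = 0.1,
         lambda = 1, objective = 0.6, kkt = 0, converged = TRUE),
    class = "penalized_fit"
  )
  rk <- rank_factors(fit)
  expect_equal(sum(rk$selected), 0L)
  expect_equal(nrow(rk), 3L)
  expect_equal(rk$factor_id, c("F1", "F2", "F3"))  # id breaks ties

  fit$coefficients <- c(F1 = 0.5, F2 = -0.2, F3 = 0)
  rk <- rank_factors(fit)
  expect_equal(rk$factor_id[rk$rank_non_sc == 1], "F1")
  expect_equal(rk$factor_id[rk$rank_sc == 1], "F2")
})
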