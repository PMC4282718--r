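test_that("design matrices encode the model as stated", {
  d <- make_grid_met(t = 2, m = 2, weight = 4)
  des <- build_design(d)
  expect_equal(dim(des$Z), c(4L, 4L))
  expect_true(all(rowSums(des$Z) == 1))
  expect_equal(unname(colSums(des$Z)), rep(1, 4))  # permutation of identity
  expect_equal(des$Sigma, rep(0.25, 4))
  expect_equal(colSums(des$X), c(L1_2000 = 2, L2_2000 = 2))

  # missing cell: 3 rows, still m*t = 4 columns, one of them empty
  d3 <- make_grid_met(t = 2, m = 2)
  d3$records <- d3$records[-4, ]
  des3 <- build_design(d3)
  expect_equal(dim(des3$Z), c(3L, 4L))
  expect_equal(sum(colSums(des3$Z) == 0), 1L)
})

test_that("blockwise likelihood equals the dense oracle for all structures", {
  d <- make_fa_met(t = 3, m = 6, seed = 9, miss = 4)
  set.seed(2)
  L <- matrix(rnorm(6), 3, 2)
  L[1, 2] <- 0
  psi <- runif(3, 0.1, 0.4)
  cases <- list(
    list(vm_diag(), list(sigma2 = c(0.5, 1, 0.2)), diag(c(0.5, 1, 0.2))),
    list(vm_cs(), list(sigma2_g = 0.4, sigma2_ge = 0.3),
         matrix(0.4, 3, 3) + diag(0.3, 3)),
    list(vm_fa(2), list(Lambda = L, psi = psi), tcrossprod(L) + diag(psi)),
    list(vm_us(), list(Ge = tcrossprod(L) + diag(psi)),
         tcrossprod(L) + diag(psi))
  )
  for (cs in cases) {
    expect_equal(residual_loglik(d, cs[[1]], cs[[2]]),
                 oracle_loglik(d, cs[[3]]), tolerance = 1e-8)
  }
})

test_that("jointly rescaling data and parameters shifts loglik by -(n-t)log c", {
  d <- make_fa_met(t = 3, m = 6, seed = 4)
  L <- matrix(c(0.5, 0.7, 0.3), 3, 1)
  psi <- c(0.2, 0.1, 0.3)
  ll1 <- residual_loglik(d, vm_fa(1), list(Lambda = L, psi = psi))
  cc <- 2.5
  d2 <- d
  d2$records$mean <- d2$records$mean * cc
  d2$records$weight <- d2$records$weight / cc^2
  ll2 <- residual_loglik(d2, vm_fa(1),
                         list(Lambda = L * cc, psi = psi * cc^2))
  n <- unname(met_dims(d)["n"])
  expect_equal(ll2, ll1 - (n - 3) * log(cc), tolerance = 1e-8)
})

test_that("single-environment REML equals the shrinkage closed form", {
  df <- data.frame(variety = letters[1:4], location = "L1", year = 2000,
                   region = "R", mean = 1:4, weight = 1e9)
  fit <- met_reml(as_met_data(df), vm_diag())
  expect_equal(fit$estimates$sigma2, var(1:4), tolerance = 1e-6)

  df$weight <- 2
  fit2 <- met_reml(as_met_data(df), vm_diag())
  expect_equal(fit2$estimates$sigma2, var(1:4) - 1 / 2, tolerance = 1e-8)

  # sample variance below the error variance: floored at (effectively) zero
  df$mean <- c(1, 1.01, 0.99, 1)
  fit3 <- met_reml(as_met_data(df), vm_diag())
  expect_lte(abs(fit3$estimates$sigma2 - 0), 1e-8)
})

test_that("balanced single-environment EBLUPs match analytic shrinkage", {
  y <- c(1.2, 2.7, 0.4, 3.1, 2.0, 1.4)
  w <- 5
  df <- data.frame(variety = letters[1:6], location = "L1", year = 2000,
                   region = "R", mean = y, weight = w)
  fit <- met_reml(as_met_data(df), vm_diag())
  s2 <- fit$estimates$sigma2
  shrink <- s2 / (s2 + 1 / w)
  expect_equal(unname(fit$blups$u[, 1]), shrink * (y - mean(y)),
               tolerance = 1e-8)
})

test_that("PEV of a cell decreases as that cell's weight increases", {
  base <- make_fa_met(t = 3, m = 8, seed = 5)
  L <- matrix(c(0.5, 0.7, 0.3), 3, 1)
  psi <- c(0.2, 0.1, 0.3)
  pevs <- purrr::map_dbl(c(1, 5, 25, 125), function(w) {
    d <- base
    i <- which(d$records$variety == "v01" & d$records$env_id == "L1_2001")
    d$records$weight[i] <- w
    fit <- met_reml(d, vm_fa(1),
                    fixed_params = list(Lambda = L, psi = psi))
    fit$blups$pev_u["v01", "L1_2001"]
  })
  expect_true(all(diff(pevs) < 0))
})

test_that("REML optimum matches a brute-force dense optimizer", {
  # small instances; the full sweep lives in the acceptance suite
  for (seed in 1:3) {
    d <- make_fa_met(t = 3, m = 8, seed = seed)
    fit <- met_reml(d, vm_fa(1))
    br <- oracle_fit(d, "fa", k = 1, restarts = 5, seed = seed)
    expect_lt(abs(fit$loglik - br$loglik), 1e-4)
    expect_lt(max(abs(fit$Ge - br$G)), 1e-3)
  }
})

test_that("t = 1 likelihood matches the one-way random-effects closed form", {
  y <- c(1.5, 2.2, 3.9)
  w <- 4
  df <- data.frame(variety = letters[1:3], location = "L1", year = 2000,
                   region = "R", mean = y, weight = w)
  d <- as_met_data(df)
  s2g <- 0.7
  # marginal: y ~ N(tau 1, (s2g + 1/w) I); REML of the single variance
  v <- s2g + 1 / w
  n <- 3
  ll_closed <- -0.5 * ((n - 1) * log(v) + log(n / v) + log(v) +
                         sum((y - mean(y))^2) / v + (n - 1) * log(2 * pi))
  expect_equal(residual_loglik(d, vm_diag(), list(sigma2 = s2g)),
               ll_closed, tolerance = 1e-8)
})

test_that("peripheral random terms are supported and match the oracle", {
  set.seed(12)
  df <- expand.grid(variety = sprintf("v%d", 1:6),
                    location = c("L1", "L2"), year = c(2001, 2002),
                    stringsAsFactors = FALSE)
  df$region <- "R1"
  df$mean <- rnorm(nrow(df), 3, 1)
  df$weight <- runif(nrow(df), 1, 10)
  d <- as_met_data(df)
  p <- list(sigma2_g = 0.4, sigma2_ge = 0.3, sigma2_p = c(year = 0.2))
  ll <- residual_loglik(d, vm_cs(peripheral = "year"), p)
  # oracle: dense H with the year blocks added by hand
  rec <- d$records
  env <- d$environments
  yr <- env$year[match(rec$env_id, env$env_id)]
  G <- matrix(0.4, 4, 4) + diag(0.3, 4)
  e <- match(rec$env_id, env$env_id)
  v <- match(rec$variety, d$varieties$variety)
  H <- G[e, e] * outer(v, v, "==") + 0.2 * outer(yr, yr, "==") +
    diag(1 / rec$weight)
  X <- matrix(0, nrow(rec), 4)
  X[cbind(seq_len(nrow(rec)), e)] <- 1
  Hi <- solve(H)
  A <- t(X) %*% Hi %*% X
  P <- Hi - Hi %*% X %*% solve(A, t(X) %*% Hi)
  ll_or <- -0.5 * (as.numeric(determinant(H)$modulus) +
                     as.numeric(determinant(A)$modulus) +
                     drop(t(rec$mean) %*% P %*% rec$mean) +
                     (nrow(rec) - 4) * log(2 * pi))
  expect_equal(ll, ll_or, tolerance = 1e-8)
  fit <- met_reml(d, vm_cs(peripheral = "year"))
  expect_true(fit$converged)
  expect_equal(fit$n_params, 3L)
})

test_that("REMLRT arithmetic, nesting checks and boundary flooring", {
  d <- make_fa_met(t = 3, m = 10, seed = 21)
  f1 <- met_reml(d, vm_fa(1))
  f2 <- met_reml(d, vm_fa(2))
  lrt <- remlrt(f1, f2)
  expect_equal(lrt$statistic, max(0, 2 * (f2$loglik - f1$loglik)))
  expect_equal(lrt$df, f2$n_params - f1$n_params)

  same <- remlrt(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(remlrt(f2, f1), "not nested",
               class = "metfa_validation_error")
  fd <- met_reml(d, vm_diag())
  expect_error(remlrt(met_reml(d, vm_cs()), f1), "not nested",
               class = "metfa_validation_error")
  expect_silent(remlrt(fd, f1))

  # chi-square arithmetic: 2 * 5 = 10 on 2 df
  expect_equal(stats::pchisq(10, 2, lower.tail = FALSE), 0.006737947,
               tolerance = 1e-6)
})

test_that("information criteria follow the stated formulas", {
  ic <- info_criteria(list(loglik = -100, n_params = 2),
                      residual_df = exp(2))
  expect_equal(ic$aic, 204)
  expect_equal(ic$bic, 204)

  d <- make_fa_met(t = 3, m = 8, seed = 2)
  fit <- met_reml(d, vm_diag())
  ic2 <- info_criteria(fit)
  n <- unname(fit$dims["n"])
  expect_equal(ic2$aic, -2 * fit$loglik + 2 * 3)
  expect_equal(ic2$bic, -2 * fit$loglik + 3 * log(n - 3))
  expect_error(info_criteria(fit, residual_df = 0),
               class = "metfa_validation_error")
})

test_that("FA preconditions are enforced", {
  d <- make_fa_met(t = 3, m = 8, seed = 2)
  expect_error(met_reml(d, vm_fa(3)), "below t",
               class = "metfa_schema_error")

  # disconnected data refuse an FA fit
  df <- rbind(
    data.frame(location = "L1", year = 2000, region = "R1",
               variety = c("a", "b"), mean = c(1, 2), weight = 1),
    data.frame(location = "L2", year = 2000, region = "R1",
               variety = c("c", "d"), mean = c(1, 2), weight = 1)
  )
  expect_error(met_reml(as_met_data(df), vm_fa(1)), "disconnected",
               class = "metfa_validation_error")
})
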