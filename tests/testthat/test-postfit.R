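test_that("variance accounted for follows the trace formulas", {
  # single factor, lambda = 2, psi = 1 -> 100 * 4 / 5 = 80
  ve <- variance_explained(list(Lambda = matrix(2, 1, 1), psi = 1))
  expect_equal(ve$v$v, 80)

  # psi = 0 everywhere -> all 100
  ve2 <- variance_explained(list(Lambda = matrix(c(1, 2), 2, 1),
                                 psi = c(0, 0)))
  expect_equal(ve2$v$v, c(100, 100))
  expect_equal(ve2$v_bar, 100)

  # (sum lambda^2, psi) = (4, 1) and (0, 1): v = (80, 0), vbar = 400/6
  ve3 <- variance_explained(list(Lambda = matrix(c(2, 0), 2, 1),
                                 psi = c(1, 1)))
  expect_equal(ve3$v$v, c(80, 0))
  expect_equal(ve3$v_bar, 100 * 4 / 6)

  # vbar is the genetic-variance-weighted mean of the v_j
  set.seed(8)
  L <- matrix(rnorm(12), 4, 3)
  psi <- runif(4, 0.05, 0.4)
  ve4 <- variance_explained(list(Lambda = L, psi = psi))
  tot <- rowSums(L^2) + psi
  expect_equal(ve4$v_bar, sum(ve4$v$v * tot) / sum(tot))

  # zero total variance -> NA with warning
  expect_warning(
    ve5 <- variance_explained(list(Lambda = matrix(c(1, 0), 2, 1),
                                   psi = c(0.5, 0))),
    "undefined"
  )
  expect_true(is.na(ve5$v$v[2]))
})

test_that("principal-component rotation preserves the FA covariance", {
  # 2 x 2 closed form: Lambda = [[1,0],[1,1]] -> eigenvalues of
  # Lambda' Lambda = [[2,1],[1,1]] are (3 +/- sqrt(5)) / 2
  d <- make_fa_met(t = 4, m = 12, seed = 31)
  fit <- met_reml(d, vm_fa(2))
  fit$estimates$Lambda <- matrix(c(1, 1, 0.5, 0.2, 0, 1, 0.3, -0.1), 4, 2)
  rot <- rotate_pc(fit)
  Ls <- rot$rotated_loadings
  expect_equal(tcrossprod(Ls), tcrossprod(fit$estimates$Lambda),
               tolerance = 1e-10)
  ip <- crossprod(Ls)
  expect_equal(ip[1, 2], 0, tolerance = 1e-10)
  expect_true(diff(diag(ip)) <= 0)
  expect_true(all(colSums(Ls) >= 0))
  expect_equal(crossprod(rot$rotation), diag(2), tolerance = 1e-12)

  L2 <- matrix(c(1, 1, 0, 1), 2, 2)
  ev <- eigen(crossprod(L2), symmetric = TRUE)$values
  expect_equal(ev, (3 + c(1, -1) * sqrt(5)) / 2)

  # random 10 x 3 loadings: covariance preserved to 1e-10
  set.seed(5)
  d2 <- make_fa_met(t = 10, m = 20, seed = 32)
  f2 <- met_reml(d2, vm_fa(3), control = met_control(restarts = 1))
  r2 <- rotate_pc(f2)
  expect_equal(tcrossprod(r2$rotated_loadings),
               tcrossprod(f2$estimates$Lambda), tolerance = 1e-10)
})

test_that("k = 1 rotation is the sign convention only", {
  d <- make_fa_met(t = 3, m = 10, seed = 41)
  fit <- met_reml(d, vm_fa(1))
  rot <- rotate_pc(fit)
  s <- if (sum(fit$estimates$Lambda) >= 0) 1 else -1
  expect_equal(rot$rotated_loadings[, 1], s * fit$estimates$Lambda[, 1],
               ignore_attr = TRUE)
})

test_that("the likelihood is invariant to orthogonal rotation of Lambda", {
  d <- make_fa_met(t = 4, m = 12, seed = 51)
  fit <- met_reml(d, vm_fa(2))
  ll0 <- residual_loglik(d, vm_fa(2), fit$estimates)
  rot <- rotate_pc(fit)
  llr <- residual_loglik(d, vm_fa(2),
                         list(Lambda = rot$rotated_loadings,
                              psi = fit$estimates$psi))
  expect_equal(llr, ll0, tolerance = 1e-8)
  # and an arbitrary rotation, not just the PC one
  th <- 0.77
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  llq <- residual_loglik(d, vm_fa(2),
                         list(Lambda = fit$estimates$Lambda %*% Q,
                              psi = fit$estimates$psi))
  expect_equal(llq, ll0, tolerance = 1e-8)
})

test_that("predictions decompose as u = beta + delta with consistent PEV", {
  d <- make_fa_met(t = 4, m = 12, seed = 61, miss = 6)
  fit <- met_reml(d, vm_fa(2))
  rot <- rotate_pc(fit)
  preds <- fa_predictions(fit, rot)

  # exact reassembly for every cell (delta = 0 where unobserved)
  expect_equal(preds$total, preds$beta + preds$delta, tolerance = 1e-14)
  expect_equal(preds$total[fit$observed], fit$blups$u[fit$observed],
               tolerance = 1e-10)
  expect_equal(preds$delta[!fit$observed],
               rep(0, sum(!fit$observed)))

  # rotated and unrotated regression components agree
  beta_unrot <- fit$blups$f %*% t(fit$estimates$Lambda)
  expect_equal(unname(preds$beta), unname(beta_unrot), tolerance = 1e-10)

  # beta is defined for every cell including unobserved ones
  expect_false(anyNA(preds$beta))

  # k = 1 scalar PEV case: V_beta = lambda*^2 V_f*
  d1 <- make_fa_met(t = 3, m = 8, seed = 62)
  f1 <- met_reml(d1, vm_fa(1))
  p1 <- fa_predictions(f1)
  i <- 1
  lam <- p1$rotation$rotated_loadings[, 1]
  vf <- p1$rotation$score_pev[[i]][1, 1]
  expect_equal(diag(p1$beta_pev[[i]]), lam^2 * vf, ignore_attr = TRUE)
})

test_that("rotated-score PEV equals a refit with rotated loadings fixed", {
  d <- make_fa_met(t = 4, m = 12, seed = 71, miss = 5)
  fit <- met_reml(d, vm_fa(2))
  rot <- rotate_pc(fit)
  refit <- met_reml(d, vm_fa(2),
                    fixed_params = list(Lambda = rot$rotated_loadings,
                                        psi = fit$estimates$psi))
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
  for (i in seq_along(rot$score_pev)) {
    expect_equal(rot$score_pev[[i]], refit$blups$pev_f[[i]],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # and the scores themselves agree with the transformed ones
  expect_equal(refit$blups$f, rot$rotated_scores, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("genetic correlation conversion and its guards", {
  expect_equal(genetic_correlation(matrix(c(4, 2, 2, 1), 2, 2)),
               matrix(1, 2, 2))
  expect_equal(genetic_correlation(diag(c(2, 3, 4))), diag(3))
  C <- genetic_correlation(matrix(c(1, -0.5, -0.5, 1), 2, 2))
  expect_equal(C[1, 2], -0.5)
  G <- diag(c(1, 0))
  rownames(G) <- colnames(G) <- c("good", "bad")
  expect_error(genetic_correlation(G), "bad",
               class = "metfa_validation_error")
})

test_that("accuracy is sqrt(1 - PEV/G) with sensible edge behavior", {
  d <- make_fa_met(t = 3, m = 10, seed = 81, miss = 4)
  fit <- met_reml(d, vm_fa(1))
  acc <- prediction_accuracy(fit)
  manual <- sqrt(pmax(1 - sweep(fit$blups$pev_u, 2, diag(fit$Ge), "/"), 0))
  expect_equal(acc$per_cell$accuracy, as.vector(t(manual)))
  expect_true(all(acc$per_cell$accuracy >= 0 & acc$per_cell$accuracy <= 1))

  # zero PEV -> accuracy 1; PEV = G -> accuracy 0
  f2 <- fit
  f2$blups$pev_u[] <- 0
  expect_true(all(prediction_accuracy(f2)$per_cell$accuracy == 1))
  f3 <- fit
  f3$blups$pev_u <- matrix(diag(fit$Ge), nrow(fit$blups$pev_u),
                           ncol(fit$blups$pev_u), byrow = TRUE)
  expect_true(all(prediction_accuracy(f3)$per_cell$accuracy == 0))

  # relabeling varieties and environments leaves accuracies unchanged
  d2 <- d
  d2$records$variety <- paste0("X", d2$records$variety)
  d2$varieties$variety <- paste0("X", d2$varieties$variety)
  fit2 <- met_reml(d2, vm_fa(1))
  a1 <- sort(prediction_accuracy(fit)$per_environment$accuracy)
  a2 <- sort(prediction_accuracy(fit2)$per_environment$accuracy)
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("order selection stops at the v_bar threshold", {
  cf <- sim_config(n_locations = 4, n_years = 2, m = 60, k_true = 2,
                   loading_sd = 0.3, psi_range = c(0.05, 0.15),
                   retention = 0.9, seed = 91)
  d <- simulate_met(cf)$data
  sel <- select_order(d, max_order = 3, vbar_threshold = 60)
  expect_gte(sel$chosen, 1)
  expect_true(sel$threshold_reached)
  ve <- variance_explained(sel$fits[[sel$chosen]])
  expect_gte(ve$v_bar, 60)
  if (sel$chosen > 1) {
    ve_prev <- variance_explained(sel$fits[[sel$chosen - 1]])
    expect_lt(ve_prev$v_bar, 60)
  }

  # unreachable threshold: runs to max_order and flags it
  sel2 <- select_order(d, max_order = 2, vbar_threshold = 100)
  expect_equal(sel2$chosen, 2L)
  expect_false(sel2$threshold_reached)
  expect_equal(nrow(sel2$summary), 2L)
  expect_true(all(c("aic", "bic", "remlrt_p") %in% names(sel2$summary)))

  expect_error(select_order(d, max_order = 50),
               class = "metfa_schema_error")
})
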