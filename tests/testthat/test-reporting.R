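test_that("dendrogram ordering keeps correlated blocks contiguous", {
  # two 3-environment blocks: within 0.9, between 0.0
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- 0.9
  C[4:6, 4:6] <- 0.9
  diag(C) <- 1
  rownames(C) <- colnames(C) <- paste0("E", 1:6)
  oc <- order_correlation(C)
  pos <- match(paste0("E", 1:6), oc$order)
  expect_lte(max(pos[1:3]) - min(pos[1:3]), 2)
  expect_lte(max(pos[4:6]) - min(pos[4:6]), 2)

  # reordered matrix stays symmetric with unit diagonal
  expect_true(isSymmetric(oc$correlation))
  expect_equal(diag(oc$correlation), rep(1, 6), ignore_attr = TRUE)
  expect_setequal(oc$order, rownames(C))

  # average-linkage merge heights are exact for the two-block case:
  # within-block dissimilarity 0.1, cross-block 1.0
  expect_equal(sort(unique(round(oc$merge_tree$height, 10))), c(0.1, 1.0))
})

test_that("t = 2 ordering has a single merge at 1 - c12", {
  C <- matrix(c(1, 0.35, 0.35, 1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  oc <- order_correlation(C)
  expect_length(oc$merge_tree$height, 1L)
  expect_equal(oc$merge_tree$height, 0.65)
  expect_setequal(oc$order, c("A", "B"))

  # identity correlation: all merges at height 1
  I4 <- diag(4)
  rownames(I4) <- colnames(I4) <- paste0("E", 1:4)
  expect_equal(unique(order_correlation(I4)$merge_tree$height), 1)
  expect_error(order_correlation(matrix(1, 2, 3)),
               class = "metfa_validation_error")
})

make_pred_fixture <- function(k = 2, seed = 101) {
  d <- make_fa_met(t = 4, m = 10, seed = seed, miss = 6)
  fit <- met_reml(d, vm_fa(k))
  fa_predictions(fit)
}

test_that("latent regressions telescope back to beta", {
  preds <- make_pred_fixture(k = 2)
  v <- preds$var_ids[3]
  lr1 <- latent_regression(preds, v, 1)
  lr2 <- latent_regression(preds, v, 2)
  i <- match(v, preds$var_ids)
  expect_equal(lr1$points$y, unname(preds$beta[i, ]))
  recon <- lr1$slope * lr1$points$x + lr2$slope * lr2$points$x
  expect_equal(recon, unname(preds$beta[i, ]), tolerance = 1e-10)
  # plot-2 y-values subtract exactly the factor-1 contribution
  expect_equal(lr2$points$y, lr1$points$y - lr1$slope * lr1$points$x,
               tolerance = 1e-12)
  expect_equal(lr1$points$observed, unname(preds$observed[i, ]))
  expect_error(latent_regression(preds, "nope", 1),
               class = "metfa_validation_error")
  expect_error(latent_regression(preds, v, 5),
               class = "metfa_validation_error")
})

test_that("k = 1 latent regression has zero scatter about the line", {
  d <- make_fa_met(t = 3, m = 8, seed = 102)
  fit <- met_reml(d, vm_fa(1))
  preds <- fa_predictions(fit)
  lr <- latent_regression(preds, preds$var_ids[1], 1)
  expect_equal(lr$points$y, lr$slope * lr$points$x, tolerance = 1e-10)
})

test_that("narrow loading coverage is flagged for under-tested varieties", {
  preds <- make_pred_fixture(k = 1, seed = 103)
  # force variety 1 to be observed only at the two lowest loadings
  i <- 1
  lam <- preds$rotation$rotated_loadings[, 1]
  keep <- rank(lam) <= 2
  preds$observed[i, ] <- keep
  lr <- latent_regression(preds, preds$var_ids[i], 1)
  expect_true(lr$narrow_coverage)
})

test_that("regional predictions average beta with proper standard errors", {
  preds <- make_pred_fixture(k = 2, seed = 104)
  envs <- preds$env_ids

  single <- regional_predictions(
    preds, tibble::tibble(env_id = envs[1], group = "g"))
  expect_equal(single$prediction, unname(preds$beta[, 1]))
  expect_equal(single$se,
               unname(purrr::map_dbl(preds$beta_pev, ~ sqrt(.x[1, 1]))),
               tolerance = 1e-10)

  two <- regional_predictions(
    preds, tibble::tibble(env_id = envs[1:2], group = "g"))
  expect_equal(two$prediction, unname(rowMeans(preds$beta[, 1:2])))

  degenerate <- regional_predictions(
    preds, tibble::tibble(env_id = envs[1:2], group = "g"),
    weights = tibble::tibble(env_id = envs[1:2], weight = c(1, 0)))
  expect_equal(degenerate$prediction, unname(preds$beta[, 1]))

  all_grp <- regional_predictions(
    preds, tibble::tibble(env_id = envs, group = "all"))
  expect_equal(all_grp$prediction, unname(rowMeans(preds$beta)))

  # SE uses the full V_beta block: for two environments it involves the
  # covariance, not just the diagonal
  w <- c(0.5, 0.5)
  i <- 2
  block <- preds$beta_pev[[i]][1:2, 1:2]
  expect_equal(two$se[i], sqrt(drop(w %*% block %*% w)), tolerance = 1e-10)

  expect_error(
    regional_predictions(preds,
                         tibble::tibble(env_id = "nope", group = "g")),
    class = "metfa_validation_error"
  )
})

test_that("environment panels are plot-ready long tables", {
  cf <- sim_config(n_locations = 2, n_years = 2, n_regions = 2, m = 12,
                   k_true = 1, retention = 1, entry_rate = 1, seed = 105)
  sim <- simulate_met(cf)
  fit <- met_reml(sim$data, vm_fa(1))
  preds <- fa_predictions(fit)
  region <- sim$data$environments$region[1]
  vars <- preds$var_ids[1:2]
  pan <- environment_panel(preds, region, varieties = vars)
  n_env_region <- sum(sim$data$environments$region == region)
  expect_equal(nrow(pan), n_env_region * 2L)
  expect_true(all(c("location", "year", "variety", "prediction", "se",
                    "observed", "trial_mean_yield") %in% names(pan)))
  # se column equals the matching V_beta diagonal entry
  r1 <- pan[1, ]
  i <- match(r1$variety, preds$var_ids)
  j <- match(r1$env_id, preds$env_ids)
  expect_equal(r1$se, sqrt(preds$beta_pev[[i]][j, j]))
  expect_equal(r1$trial_mean_yield,
               sim$data$environments$trial_mean_yield[
                 sim$data$environments$env_id == r1$env_id])
  expect_error(environment_panel(preds, "not-a-region"),
               class = "metfa_validation_error")
})

test_that("report plots build without evaluation errors", {
  preds <- make_pred_fixture(k = 2, seed = 106)
  oc <- order_correlation(genetic_correlation(tcrossprod(
    preds$rotation$rotated_loadings) + diag(0.1, 4)))
  expect_s3_class(ggplot2::ggplot_build(autoplot(oc)), "ggplot_built")
  lr <- latent_regression(preds, preds$var_ids[1], 1)
  expect_s3_class(ggplot2::ggplot_build(autoplot(lr)), "ggplot_built")
})
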