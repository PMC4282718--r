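# Independent dense-matrix REML oracle.  Deliberately naive: forms the full
# n x n marginal variance H = Z (G x I_m) Z' + Sigma from the explicit
# design matrices and evaluates the textbook REML log-likelihood
# -1/2 (log|H| + log|X'H^-1X| + y'Py + (n - rank X) log 2pi).
# Shares no code with the package's blockwise evaluation.
oracle_loglik <- function(data, G) {
  env_ids <- data$environments$env_id
  var_ids <- data$varieties$variety
  rec <- data$records
  n <- nrow(rec)
  t <- length(env_ids)
  m <- length(var_ids)
  e <- match(rec$env_id, env_ids)
  v <- match(rec$variety, var_ids)
  Z <- matrix(0, n, m * t)
  Z[cbind(seq_len(n), (e - 1) * m + v)] <- 1
  X <- matrix(0, n, t)
  X[cbind(seq_len(n), e)] <- 1
  H <- Z %*% kronecker(G, diag(m)) %*% t(Z) + diag(1 / rec$weight, n)
  Hi <- solve(H)
  A <- t(X) %*% Hi %*% X
  P <- Hi - Hi %*% X %*% solve(A, t(X) %*% Hi)
  y <- rec$mean
  -0.5 * (as.numeric(determinant(H)$modulus) +
            as.numeric(determinant(A)$modulus) +
            drop(t(y) %*% P %*% y) + (n - t) * log(2 * pi))
}

# Brute-force REML maximization: generic BFGS on the dense oracle
# likelihood under a raw parametrization, with multiple random restarts.
oracle_fit <- function(data, kind, k = 1, restarts = 6, seed = 1) {
  t <- nrow(data$environments)
  par_to_G <- switch(kind,
    diag = function(th) diag(exp(th), t),
    cs = function(th) matrix(exp(th[1]), t, t) + diag(exp(th[2]), t),
    fa = function(th) {
      L <- matrix(th[seq_len(t * k)], t, k)
      tcrossprod(L) + diag(exp(th[t * k + seq_len(t)]), t)
    },
    us = function(th) {
      L <- matrix(0, t, t)
      diag(L) <- exp(th[seq_len(t)])
      L[lower.tri(L)] <- th[t + seq_len(t * (t - 1) / 2)]
      tcrossprod(L)
    }
  )
  npar <- switch(kind, diag = t, cs = 2, fa = t * k + t,
                 us = t + t * (t - 1) / 2)
  obj <- function(th) {
    G <- par_to_G(th)
    ll <- tryCatch(oracle_loglik(data, G), error = function(e) -1e10)
    if (!is.finite(ll)) ll <- -1e10
    -ll
  }
  best <- Inf
  bp <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed * 1000 + r)
    th0 <- switch(kind,
      diag = log(runif(t, 0.05, 0.5)),
      cs = log(runif(2, 0.05, 0.5)),
      fa = c(rnorm(t * k, 0, 0.5), log(runif(t, 0.05, 0.5))),
      us = c(log(runif(t, 0.2, 0.8)), rnorm(t * (t - 1) / 2, 0, 0.3))
    )
    o <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    if (o$value < best) {
      best <- o$value
      bp <- o$par
    }
  }
  # polish from the best start: BFGS restarts reset the Hessian estimate
  o2 <- stats::optim(bp, obj, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  if (o2$value < best) {
    best <- o2$value
    bp <- o2$par
  }
  list(loglik = -best, G = par_to_G(bp))
}

# small complete or incomplete MET dataset with FA1-like genetic signal
make_fa_met <- function(t = 3, m = 8, seed = 1, miss = 0,
                        weights_range = c(2, 20)) {
  set.seed(seed)
  L <- runif(t, 0.3, 0.9)
  psi <- runif(t, 0.05, 0.3)
  f <- rnorm(m)
  u <- outer(f, L) + matrix(rnorm(m * t), m, t) %*% diag(sqrt(psi), t)
  ev <- 1 / runif(t, weights_range[1], weights_range[2])
  df <- expand.grid(variety = sprintf("v%02d", seq_len(m)),
                    j = seq_len(t), stringsAsFactors = FALSE)
  df$location <- sprintf("L%d", df$j)
  df$year <- 2001
  df$region <- "R1"
  i <- match(df$variety, sprintf("v%02d", seq_len(m)))
  df$mean <- 3 + u[cbind(i, df$j)] + rnorm(nrow(df), 0, sqrt(ev[df$j]))
  df$weight <- 1 / ev[df$j]
  if (miss > 0) df <- df[-sample(nrow(df), miss), ]
  as_met_data(df[setdiff(names(df), "j")])
}

# fully crossed toy dataset with explicit values
make_grid_met <- function(t = 2, m = 2, mean = NULL, weight = 1) {
  df <- expand.grid(variety = sprintf("v%d", seq_len(m)),
                    location = sprintf("L%d", seq_len(t)),
                    stringsAsFactors = FALSE)
  df$year <- 2000
  df$region <- "R1"
  df$mean <- if (is.null(mean)) seq_len(nrow(df)) else mean
  df$weight <- weight
  as_met_data(df)
}
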