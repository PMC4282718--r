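#' @keywords internal
#' Internal: index a MET dataset for the likelihood machinery.
#'
#' The marginal variance matrix H = Z (G_e x I_m) Z' + Sigma is block
#' diagonal by variety (records of different varieties are uncorrelated),
#' so the REML quantities decompose into per-variety blocks of size at most
#' t.  Varieties sharing the same incidence pattern and the same error
#' variances share the same block matrix, so they are grouped and each
#' distinct block is factorized once.
met_prepare <- function(data) {
  env_ids <- data$environments$env_id
  var_ids <- data$varieties$variety
  rec <- data$records
  e <- match(rec$env_id, env_ids)
  v <- match(rec$variety, var_ids)
  sig2e <- 1 / rec$weight          # Inf weight -> zero error variance

  empty <- setdiff(seq_along(env_ids), unique(e))
  if (length(empty) > 0) {
    stop_validation("environment '", env_ids[empty[1]],
                    "' has no records; trial means are not estimable")
  }

  ord <- order(v, e)
  by_var <- split(ord, v[ord])
  keys <- purrr::map_chr(by_var, function(idx) {
    paste(paste(e[idx], collapse = ","),
          paste(signif(sig2e[idx], 10), collapse = ","), sep = "|")
  })
  groups <- purrr::map(split(by_var, keys), function(members) {
    J <- e[members[[1]]]
    list(
      J = J,
      S2 = sig2e[members[[1]]],
      Y = vapply(members, function(idx) rec$mean[idx], numeric(length(J))),
      members = as.integer(names(members))
    )
  })
  groups <- purrr::map(groups, function(g) {
    if (!is.matrix(g$Y)) g$Y <- matrix(g$Y, ncol = length(g$members))
    g
  })
  list(
    env_ids = env_ids, var_ids = var_ids,
    environments = data$environments,
    n = nrow(rec), m = length(var_ids), t = length(env_ids),
    e = e, v = v, y = rec$mean, sig2e = sig2e,
    groups = groups
  )
}

#' Design matrices of the second-stage mixed model
#'
#' Materializes the model `y = X tau + Z u + eta`: `X` (n x t) maps each
#' record to its trial mean; `Z` (n x mt) maps each record to its variety
#' by environment cell, with `u` ordered as varieties within environments
#' (cell (i, j) at column (j-1) m + i) and all-zero columns for cells never
#' observed (n << mt in unbalanced data); `Sigma` is the diagonal of
#' `var(eta)`, the reciprocals of the weights.  The fitting engine never
#' forms these (it exploits the variety-block structure of H), so they are
#' mainly useful for inspection and cross-checking.
#'
#' @param data A [met_data] object.
#' @return A list with dense `X`, `Z` and the vector `Sigma`.
#' @export
build_design <- function(data) {
  stopifnot(inherits(data, "met_data"))
  prep <- met_prepare(data)
  n <- prep$n
  X <- matrix(0, n, prep$t, dimnames = list(NULL, prep$env_ids))
  X[cbind(seq_len(n), prep$e)] <- 1
  Z <- matrix(0, n, prep$m * prep$t)
  colnames(Z) <- as.vector(outer(prep$var_ids, prep$env_ids, paste,
                                 sep = ":"))
  Z[cbind(seq_len(n), (prep$e - 1) * prep$m + prep$v)] <- 1
  list(X = X, Z = Z, Sigma = prep$sig2e)
}

# Core REML evaluation on the variety-block decomposition.
# Returns loglik (exact, including the -(n - t)/2 log(2*pi) constant,
# with t = rank(X) the number of trial means) and, if requested, the
# gradient w.r.t. theta plus the byproducts needed for EBLUPs.
eval_reml_blocks <- function(theta, spec, prep, want_grad = FALSE,
                             want_aux = FALSE, params = NULL) {
  t <- prep$t
  if (is.null(params)) params <- vm_unpack(spec, theta, t)
  G <- ge_matrix(spec, params, prep$environments)
  A <- matrix(0, t, t)
  b <- numeric(t)
  yHy <- 0
  logdetH <- 0
  store <- vector("list", length(prep$groups))
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    Hg <- G[g$J, g$J, drop = FALSE]
    diag(Hg) <- diag(Hg) + g$S2
    ch <- tryCatch(chol(Hg), error = function(e) NULL)
    if (is.null(ch)) {
      return(list(loglik = -1e10, grad = rep(0, length(theta)), ok = FALSE))
    }
    Hi <- chol2inv(ch)
    ng <- ncol(g$Y)
    logdetH <- logdetH + 2 * ng * sum(log(diag(ch)))
    A[g$J, g$J] <- A[g$J, g$J] + ng * Hi
    HiY <- Hi %*% g$Y
    b[g$J] <- b[g$J] + rowSums(HiY)
    yHy <- yHy + sum(g$Y * HiY)
    store[[gi]] <- Hi
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) {
    stop_validation("X' H^-1 X is singular: trial means are confounded")
  }
  Ainv <- chol2inv(chA)
  tau <- drop(Ainv %*% b)
  yPy <- yHy - sum(b * tau)
  loglik <- -0.5 * (logdetH + 2 * sum(log(diag(chA))) + yPy +
                      (prep$n - t) * log(2 * pi))
  out <- list(loglik = loglik, ok = TRUE, tau = tau, Ainv = Ainv,
              params = params, G = G)
  if (want_grad || want_aux) {
    D <- matrix(0, t, t)
    for (gi in seq_along(prep$groups)) {
      g <- prep$groups[[gi]]
      Hi <- store[[gi]]
      ng <- ncol(g$Y)
      Pgg <- Hi - Hi %*% Ainv[g$J, g$J, drop = FALSE] %*% Hi
      Rres <- Hi %*% (g$Y - tau[g$J])
      D[g$J, g$J] <- D[g$J, g$J] + ng * Pgg - tcrossprod(Rres)
    }
    if (want_grad) {
      out$grad <- vm_grad_genetic(spec, params, D, prep$environments)
    }
    out$D <- D
  }
  if (want_aux) out$store <- store
  out
}

# Dense-H evaluation used when peripheral random terms are present: these
# couple records across varieties, so the variety-block shortcut no longer
# applies.  Intended for desk-scale n.
eval_reml_dense <- function(theta, spec, prep, want_grad = FALSE,
                            params = NULL) {
  t <- prep$t
  n <- prep$n
  if (is.null(params)) params <- vm_unpack(spec, theta, t)
  G <- ge_matrix(spec, params, prep$environments)
  same_var <- outer(prep$v, prep$v, "==")
  H <- G[prep$e, prep$e] * same_var
  plev <- purrr::map(spec$peripheral, function(f) {
    vals <- prep$environments[[f]]
    if (is.null(vals)) {
      stop_validation("peripheral factor '", f,
                      "' is not an environment attribute")
    }
    as.character(vals)[prep$e]
  })
  for (ip in seq_along(plev)) {
    H <- H + params$sigma2_p[[ip]] * outer(plev[[ip]], plev[[ip]], "==")
  }
  diag(H) <- diag(H) + prep$sig2e
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    return(list(loglik = -1e10, grad = rep(0, length(theta)), ok = FALSE))
  }
  Hi <- chol2inv(ch)
  X <- matrix(0, n, t)
  X[cbind(seq_len(n), prep$e)] <- 1
  HiX <- Hi %*% X
  A <- crossprod(X, HiX)
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) {
    stop_validation("X' H^-1 X is singular: trial means are confounded")
  }
  Ainv <- chol2inv(chA)
  b <- drop(crossprod(HiX, prep$y))
  tau <- drop(Ainv %*% b)
  Hiy <- drop(Hi %*% prep$y)
  yPy <- sum(prep$y * Hiy) - sum(b * tau)
  loglik <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chA))) + yPy +
                      (n - t) * log(2 * pi))
  out <- list(loglik = loglik, ok = TRUE, tau = tau, Ainv = Ainv,
              params = params, G = G)
  if (want_grad) {
    P <- Hi - HiX %*% Ainv %*% t(HiX)
    r <- drop(P %*% prep$y)
    D <- matrix(0, t, t)
    for (i in unique(prep$v)) {
      rows <- which(prep$v == i)
      J <- prep$e[rows]
      D[J, J] <- D[J, J] + P[rows, rows, drop = FALSE] - tcrossprod(r[rows])
    }
    gg <- vm_grad_genetic(spec, params, D, prep$environments)
    gp <- purrr::map_dbl(seq_along(plev), function(ip) {
      lv <- plev[[ip]]
      tr <- sum(purrr::map_dbl(unique(lv), function(l) {
        rows <- which(lv == l)
        sum(P[rows, rows]) - sum(r[rows])^2
      }))
      -0.5 * tr * params$sigma2_p[[ip]]
    })
    out$grad <- c(gg, gp)
  }
  out
}

eval_reml <- function(theta, spec, prep, want_grad = FALSE,
                      want_aux = FALSE, params = NULL) {
  if (length(spec$peripheral) > 0) {
    eval_reml_dense(theta, spec, prep, want_grad = want_grad,
                    params = params)
  } else {
    eval_reml_blocks(theta, spec, prep, want_grad = want_grad,
                     want_aux = want_aux, params = params)
  }
}

#' Residual log-likelihood of the second-stage mixed model
#'
#' Evaluates the REML log-likelihood of the weighted mixed model
#' `y = X tau + Z u + eta` with `var(u) = G_e(params) %x% I_m` and
#' `var(eta) = Sigma` (diagonal, reciprocals of the supplied weights),
#' profiled over the trial means `tau`:
#' `l = -1/2 (log|H| + log|X' H^-1 X| + y' P y + (n - t) log 2 pi)`,
#' where `H = Z (G_e x I_m) Z' + Sigma` and `t = rank(X)`.  The additive
#' constant `-(n - t)/2 log 2 pi` is always included, so values are
#' directly comparable across parameter sets on the same data.
#'
#' @param data A [met_data] object.
#' @param model A [variance_models] specification.
#' @param params Named parameter list for the structure: `sigma2` (DIAG);
#'   `sigma2_g`, `sigma2_ge` (CS); plus `sigma2_vc` (VC); `Lambda`, `psi`
#'   (FA); `Ge` (US); plus `sigma2_p` for peripheral terms.
#' @return The residual log-likelihood (scalar).
#' @export
residual_loglik <- function(data, model, params) {
  stopifnot(inherits(data, "met_data"), inherits(model, "met_vm"))
  prep <- met_prepare(data)
  # parameters are used as given (no estimation constraint is applied, so
  # e.g. rotated loadings evaluate to the identical likelihood)
  res <- eval_reml(NULL, model, prep, params = params)
  if (!res$ok) stop_validation("variance parameters give a singular model")
  res$loglik
}

# moment-based starting values -------------------------------------------

# crude per-environment genetic variances and a pairwise-complete genetic
# covariance matrix of the centred variety means, measurement error removed
moment_ge <- function(prep) {
  t <- prep$t
  ybar <- tapply(prep$y, prep$e, mean)
  yc <- prep$y - ybar[as.character(prep$e)]
  S <- matrix(0, t, t)
  counts <- matrix(0L, t, t)
  cells <- matrix(NA_real_, prep$m, t)
  cells[cbind(prep$v, prep$e)] <- yc
  obs <- !is.na(cells)
  for (j in seq_len(t)) {
    for (l in j:t) {
      common <- which(obs[, j] & obs[, l])
      if (length(common) >= 3) {
        S[j, l] <- S[l, j] <- stats::cov(cells[common, j], cells[common, l])
        counts[j, l] <- counts[l, j] <- length(common)
      }
    }
  }
  me <- tapply(prep$sig2e, prep$e, mean)
  vd <- pmax(diag(S) - as.numeric(me), 0.05 * pmax(diag(S), 0.01))
  diag(S) <- vd
  list(S = S, gvar = vd)
}

vm_init <- function(spec, prep) {
  mom <- moment_ge(prep)
  t <- prep$t
  params <- switch(spec$kind,
    diag = list(sigma2 = mom$gvar),
    cs = {
      avg_cov <- mean(mom$S[upper.tri(mom$S)])
      s2g <- max(avg_cov, 0.1 * mean(mom$gvar))
      list(sigma2_g = s2g,
           sigma2_ge = max(mean(mom$gvar) - s2g, 0.1 * mean(mom$gvar)))
    },
    vc = {
      tot <- mean(mom$gvar)
      nf <- length(spec$factors)
      list(sigma2_g = tot / 2,
           sigma2_vc = stats::setNames(rep(tot / (2 * (nf + 1)), nf),
                                       spec$factors),
           sigma2_ge = tot / (2 * (nf + 1)))
    },
    fa = {
      k <- spec$k
      ev <- eigen(mom$S, symmetric = TRUE)
      val <- pmax(ev$values[seq_len(k)], 1e-4)
      L0 <- ev$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
      # rotate onto the estimation constraint (zero upper triangle)
      qr0 <- qr(t(L0))
      L0 <- L0 %*% qr.Q(qr0)
      s <- sign(colSums(L0))
      s[s == 0] <- 1
      L0 <- sweep(L0, 2, s, `*`)
      psi0 <- pmax(mom$gvar - rowSums(L0^2), 0.1 * pmax(mom$gvar, 0.01))
      list(Lambda = L0, psi = psi0)
    },
    us = {
      S <- mom$S
      ev <- eigen(S, symmetric = TRUE)
      val <- pmax(ev$values, 0.01 * max(ev$values, 0.01))
      list(Ge = ev$vectors %*% diag(val, t) %*% t(ev$vectors))
    }
  )
  if (length(spec$peripheral) > 0) {
    params$sigma2_p <- stats::setNames(
      rep(0.1 * mean(mom$gvar) + 0.01, length(spec$peripheral)),
      spec$peripheral
    )
  }
  params
}

#' Optimizer and convergence control for [met_reml()]
#'
#' @param maxit Maximum L-BFGS-B iterations (default 500).
#' @param factr,pgtol Passed to [stats::optim()]; the defaults demand a
#'   relative log-likelihood change below about 2e-9 and a maximum
#'   projected gradient below 1e-6.
#' @param restarts Number of deterministic starts for FA/US structures
#'   (the moment start plus scaled variants); the best likelihood wins.
#' @return A list of control settings.
#' @export
met_control <- function(maxit = 500, factr = 1e7, pgtol = 1e-6,
                        restarts = 2) {
  list(maxit = maxit, factr = factr, pgtol = pgtol, restarts = restarts)
}

#' Fit the weighted second-stage MET mixed model by REML
#'
#' Maximizes the residual log-likelihood of the two-stage model over the
#' free parameters of the chosen between-environment genetic variance
#' structure, using an analytic-gradient quasi-Newton optimizer on an
#' unconstrained parametrization (variances log-transformed with a floor of
#' 1e-8 standing in for the zero boundary; for FA structures the k(k-1)/2
#' upper-triangle loadings are fixed at zero for identifiability, with
#' rotation deferred to [rotate_pc()]).  Starting values come from moment
#' estimates of the genetic covariances; FA/US fits add deterministic
#' rescaled restarts and keep the best optimum.
#'
#' On convergence the EBLUPs of the genetic effects are returned in the
#' extended form `u = (Lambda x I_m) f + delta`, so factor scores, genetic
#' regression residuals and their prediction error variances (PEV, from the
#' mixed-model-equations coefficient inverse) are directly available.  PEV
#' here, as usual, ignores the uncertainty in the estimated variance
#' parameters.
#'
#' @param data A [met_data] object (normally after [filter_met()]).
#' @param model A [variance_models] specification.
#' @param init Optional named parameter list of starting values (same
#'   format as [residual_loglik()]).
#' @param control A [met_control()] list.
#' @param fixed_params Optional parameter list at which to hold the
#'   variance parameters fixed: no optimization is performed and the
#'   EBLUPs/PEV are evaluated at these values (e.g. to re-express a fit in
#'   terms of rotated loadings).
#' @return A `met_fit` object; see [glance.met_fit()], [tidy.met_fit()],
#'   and the post-fit tools [variance_explained()], [rotate_pc()],
#'   [fa_predictions()], [prediction_accuracy()].
#' @export
met_reml <- function(data, model, init = NULL, control = met_control(),
                     fixed_params = NULL) {
  stopifnot(inherits(data, "met_data"), inherits(model, "met_vm"))
  prep <- met_prepare(data)
  t <- prep$t
  if (model$kind == "fa") {
    if (model$k >= t) {
      stop_schema("FA order k = ", model$k, " must be below t = ", t)
    }
    comps <- connectivity_components(met_connectivity(data), min_common = 1)
    if (length(comps) > 1) {
      stop_validation("dataset splits into ", length(comps),
                      " disconnected trial groups; FA models require a ",
                      "single connected component")
    }
  }
  if (model$kind == "us") {
    pc <- met_connectivity(data)$pairwise_common
    off <- pc[upper.tri(pc)]
    if (any(off < 2)) {
      warning("some trial pairs share fewer than 2 varieties; the ",
              "unstructured model may not be estimable", call. = FALSE)
    }
  }

  if (!is.null(fixed_params)) {
    # evaluated exactly as supplied: the identifiability constraint is an
    # estimation device, so e.g. rotated loadings are legitimate here
    final <- eval_reml(NULL, model, prep, want_aux = TRUE,
                       params = fixed_params)
    if (!final$ok) stop_validation("fixed parameters give a singular model")
    return(build_met_fit(data, model, prep, NULL, final,
                         converged = TRUE, n_iter = 0L, control = control))
  }

  starts <- list()
  if (!is.null(init)) {
    starts <- list(vm_pack(model, init, t))
  } else {
    base <- vm_init(model, prep)
    starts <- list(vm_pack(model, base, t))
    if (model$kind %in% c("fa", "us") && control$restarts > 1) {
      scales <- c(0.5, 1.5, 0.25, 2)[seq_len(control$restarts - 1)]
      for (s in scales) {
        alt <- base
        if (model$kind == "fa") {
          alt$Lambda <- base$Lambda * s
          alt$psi <- pmax(base$psi + (1 - s^2) * rowSums(base$Lambda^2),
                          VAR_FLOOR)
        } else {
          alt$Ge <- base$Ge * s
        }
        starts <- c(starts, list(vm_pack(model, alt, t)))
      }
    }
  }

  best <- NULL
  n_iter_total <- 0L
  for (th0 in starts) {
    cache <- new.env(parent = emptyenv())
    evalc <- function(th) {
      key <- paste(th, collapse = ",")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$res <- eval_reml(th, model, prep, want_grad = TRUE)
      }
      cache$res
    }
    opt <- stats::optim(
      par = th0,
      fn = function(th) -evalc(th)$loglik,
      gr = function(th) -evalc(th)$grad,
      method = "L-BFGS-B",
      lower = vm_lower(model, t),
      control = list(maxit = control$maxit, factr = control$factr,
                     pgtol = control$pgtol)
    )
    n_iter_total <- n_iter_total + opt$counts[["function"]]
    if (is.null(best) || -opt$value > best$value_ll) {
      best <- list(par = opt$par, value_ll = -opt$value,
                   converged = opt$convergence == 0)
    }
  }

  # boundary polish: the gradient on the log scale vanishes as a variance
  # approaches zero, so the optimizer can stall just above the floor; any
  # small variance whose pinning at the floor does not lower the
  # likelihood is fixed there (the "estimated at zero" boundary case)
  lo <- vm_lower(model, t)
  ll_best <- eval_reml(best$par, model, prep)$loglik
  for (i in which(lo == log(VAR_FLOOR) & best$par < log(1e-3))) {
    trial <- best$par
    trial[i] <- log(VAR_FLOOR)
    ll_trial <- eval_reml(trial, model, prep)$loglik
    if (ll_trial >= ll_best - 1e-9) {
      best$par <- trial
      ll_best <- ll_trial
    }
  }

  final <- eval_reml(best$par, model, prep, want_grad = TRUE,
                     want_aux = TRUE)
  fit <- build_met_fit(data, model, prep, best$par, final,
                       converged = best$converged, n_iter = n_iter_total,
                       control = control)
  fit
}

# assemble the met_fit object: estimates, fixed effects, EBLUPs, PEV
build_met_fit <- function(data, model, prep, theta, final, converged,
                          n_iter, control) {
  t <- prep$t
  m <- prep$m
  params <- final$params
  G <- final$G
  k <- if (model$kind == "fa") model$k else 0L
  Lambda <- if (k > 0) params$Lambda else NULL
  psi <- if (k > 0) params$psi else NULL

  fmat <- if (k > 0) matrix(0, m, k) else NULL
  delta <- matrix(0, m, t)
  u <- matrix(0, m, t)
  pev_u <- matrix(NA_real_, m, t)
  pev_delta <- matrix(NA_real_, m, t)
  pev_f <- if (k > 0) vector("list", m) else NULL
  observed <- matrix(FALSE, m, t)
  observed[cbind(prep$v, prep$e)] <- TRUE

  if (length(model$peripheral) == 0) {
    Ainv <- final$Ainv
    tau <- final$tau
    for (g in prep$groups) {
      J <- g$J
      Hg <- G[J, J, drop = FALSE]
      diag(Hg) <- diag(Hg) + g$S2
      Hi <- chol2inv(chol(Hg))
      Pgg <- Hi - Hi %*% Ainv[J, J, drop = FALSE] %*% Hi
      R <- Hi %*% (g$Y - tau[J])          # t_g x n_g, one column per member
      GJ <- G[, J, drop = FALSE]
      u[g$members, ] <- t(GJ %*% R)
      GP <- GJ %*% Pgg
      pevu_g <- pmax(diag(G) - rowSums(GP * GJ), 0)
      pev_u[g$members, ] <- matrix(pevu_g, length(g$members), t, byrow = TRUE)
      if (k > 0) {
        LJ <- Lambda[J, , drop = FALSE]
        fmat[g$members, ] <- t(crossprod(LJ, R))
        delta[g$members, J] <- t(psi[J] * R)
        pf <- diag(1, k) - crossprod(LJ, Pgg %*% LJ)
        for (i in g$members) pev_f[[i]] <- pf
        pd <- pmax(psi[J] - psi[J]^2 * diag(Pgg), 0)
        pev_delta[g$members, J] <- matrix(pd, length(g$members), length(J),
                                          byrow = TRUE)
      }
    }
  } else {
    # peripheral terms: genetic blups from per-variety blocks at the dense
    # fit's tau/Ainv (peripheral effects enter only through tau here)
    tau <- final$tau
    Ainv <- final$Ainv
    for (i in seq_len(m)) {
      rows <- which(prep$v == i)
      if (length(rows) == 0) next
      J <- prep$e[rows]
      Hg <- G[J, J, drop = FALSE]
      diag(Hg) <- diag(Hg) + prep$sig2e[rows]
      Hi <- chol2inv(chol(Hg))
      R <- drop(Hi %*% (prep$y[rows] - tau[J]))
      u[i, ] <- drop(G[, J, drop = FALSE] %*% R)
      Pgg <- Hi - Hi %*% Ainv[J, J, drop = FALSE] %*% Hi
      GJ <- G[, J, drop = FALSE]
      pev_u[i, ] <- pmax(diag(G) - rowSums((GJ %*% Pgg) * GJ), 0)
      if (k > 0) {
        LJ <- Lambda[J, , drop = FALSE]
        fmat[i, ] <- drop(crossprod(LJ, R))
        delta[i, J] <- psi[J] * R
        pev_f[[i]] <- diag(1, k) - crossprod(LJ, Pgg %*% LJ)
        pev_delta[i, J] <- pmax(psi[J] - psi[J]^2 * diag(Pgg), 0)
      }
    }
  }
  dimnames(u) <- list(prep$var_ids, prep$env_ids)
  dimnames(pev_u) <- dimnames(u)
  dimnames(delta) <- dimnames(u)
  dimnames(pev_delta) <- dimnames(u)
  dimnames(observed) <- dimnames(u)
  if (k > 0) {
    dimnames(fmat) <- list(prep$var_ids, paste0("fac", seq_len(k)))
    names(pev_f) <- prep$var_ids
    dimnames(params$Lambda) <- list(prep$env_ids, paste0("fac", seq_len(k)))
    names(params$psi) <- prep$env_ids
  }
  dimnames(G) <- list(prep$env_ids, prep$env_ids)

  structure(
    list(
      model = model,
      estimates = params,
      Ge = G,
      fixed = tibble::tibble(env_id = prep$env_ids, estimate = final$tau,
                             se = sqrt(pmax(diag(final$Ainv), 0))),
      loglik = final$loglik,
      n_params = vm_npar(model, t),
      converged = converged,
      n_iter = n_iter,
      blups = list(f = fmat, delta = delta, u = u, pev_f = pev_f,
                   pev_u = pev_u, pev_delta = pev_delta),
      observed = observed,
      dims = c(n = prep$n, m = m, t = t),
      env_ids = prep$env_ids,
      var_ids = prep$var_ids,
      environments = data$environments,
      theta = theta,
      control = control
    ),
    class = "met_fit"
  )
}

#' @export
print.met_fit <- function(x, ...) {
  d <- x$dims
  cat("<met_fit> ", vm_label(x$model), " model: n = ", d["n"], ", m = ",
      d["m"], ", t = ", d["t"], "\n", sep = "")
  cat(sprintf("  residual loglik %.4f (%d variance parameters), %s\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged"))
  if (x$model$kind == "fa") {
    ve <- variance_explained(x)
    cat(sprintf("  %% genetic variance accounted for: %.1f\n", ve$v_bar))
  }
  invisible(x)
}
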