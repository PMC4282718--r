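#' Between-environment genetic variance structures
#'
#' The second-stage mixed model assumes `var(u) = G_e %x% I_m`, where `G_e`
#' is the t x t between-environment genetic variance matrix.  These
#' constructors declare the structure imposed on `G_e`:
#'
#' * `vm_diag()` -- independent environments, a genetic variance per trial
#'   (analogous to separate trial analyses);
#' * `vm_cs()` -- compound symmetry, `G_e = sigma2_g J + sigma2_ge I`
#'   (variety main effects plus iid variety-by-environment interaction):
#'   equal variance and equal covariance everywhere;
#' * `vm_vc()` -- the partitioned variance component model: main effects
#'   plus interaction components for grouping factors of the environments
#'   (region, year, region:year) plus a residual V x E component;
#' * `vm_fa(k)` -- factor analytic of order k, `G_e = Lambda Lambda' + psi`
#'   with t x k loadings and diagonal specific variances; parsimonious and
#'   able to approximate the unstructured form;
#' * `vm_us()` -- unstructured, all t(t+1)/2 variances and covariances.
#'
#' All structures may carry optional peripheral (non-genetic) random terms:
#' iid effects for a named environment attribute (e.g. `"year"`), each with
#' a scaled-identity variance.  These default to absent.
#'
#' @param k Factor analytic order (>= 1 and < t at fit time).
#' @param factors Grouping factors for the partitioned model; any of
#'   `"region"`, `"year"`, `"region:year"`.
#' @param peripheral Optional character vector of environment attributes to
#'   include as iid random peripheral terms.
#' @return An object of class `met_vm`.
#' @name variance_models
NULL

new_met_vm <- function(kind, fields = list(), peripheral = NULL) {
  structure(c(list(kind = kind, peripheral = peripheral), fields),
            class = "met_vm")
}

#' @rdname variance_models
#' @export
vm_diag <- function(peripheral = NULL) new_met_vm("diag", peripheral = peripheral)

#' @rdname variance_models
#' @export
vm_cs <- function(peripheral = NULL) new_met_vm("cs", peripheral = peripheral)

#' @rdname variance_models
#' @export
vm_vc <- function(factors = c("region", "year", "region:year"),
                  peripheral = NULL) {
  bad <- setdiff(factors, c("region", "year", "region:year"))
  if (length(bad) > 0) {
    stop_schema("unknown partition factor(s): ", paste(bad, collapse = ", "))
  }
  new_met_vm("vc", list(factors = factors), peripheral = peripheral)
}

#' @rdname variance_models
#' @export
vm_fa <- function(k, peripheral = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop_schema("FA order k must be a positive integer")
  }
  new_met_vm("fa", list(k = as.integer(k)), peripheral = peripheral)
}

#' @rdname variance_models
#' @export
vm_us <- function(peripheral = NULL) new_met_vm("us", peripheral = peripheral)

#' @export
print.met_vm <- function(x, ...) {
  cat("<met_vm> ", vm_label(x), "\n", sep = "")
  invisible(x)
}

vm_label <- function(spec) {
  switch(spec$kind,
    diag = "DIAG", cs = "CS",
    vc = paste0("VC(", paste(spec$factors, collapse = "+"), ")"),
    fa = paste0("FA", spec$k), us = "US"
  )
}

# identification constraint: the k(k-1)/2 upper-triangle loadings are fixed 0
fa_mask <- function(t, k) {
  outer(seq_len(t), seq_len(k), function(j, r) r > j)
}

VAR_FLOOR <- 1e-8

# number of free variance parameters (genetic + peripheral)
vm_npar <- function(spec, t) {
  g <- switch(spec$kind,
    diag = t,
    cs = 2L,
    vc = 2L + length(spec$factors),
    fa = t * (spec$k + 1L) - spec$k * (spec$k - 1L) / 2L,
    us = t * (t + 1L) / 2L
  )
  as.integer(g + length(spec$peripheral))
}

# ---- packing between a named parameter list and the unconstrained theta ----
# log scale for variances (floored at VAR_FLOOR); loadings and unstructured
# off-diagonal Cholesky entries are free.

vm_pack <- function(spec, params, t) {
  lg <- function(v) log(pmax(v, VAR_FLOOR))
  th <- switch(spec$kind,
    diag = lg(params$sigma2),
    cs = lg(c(params$sigma2_g, params$sigma2_ge)),
    vc = lg(c(params$sigma2_g, params$sigma2_vc, params$sigma2_ge)),
    fa = {
      mask <- fa_mask(t, spec$k)
      c(params$Lambda[!mask], lg(params$psi))
    },
    us = {
      L <- t(chol(params$Ge + diag(1e-10, t)))
      c(lg(diag(L)^2) / 2, L[lower.tri(L)])
    }
  )
  if (length(spec$peripheral) > 0) th <- c(th, lg(params$sigma2_p))
  th
}

vm_unpack <- function(spec, theta, t) {
  np <- length(spec$peripheral)
  if (np > 0) {
    sigma2_p <- exp(theta[(length(theta) - np + 1):length(theta)])
    names(sigma2_p) <- spec$peripheral
    theta <- theta[seq_len(length(theta) - np)]
  } else {
    sigma2_p <- NULL
  }
  out <- switch(spec$kind,
    diag = list(sigma2 = exp(theta)),
    cs = list(sigma2_g = exp(theta[1]), sigma2_ge = exp(theta[2])),
    vc = {
      nf <- length(spec$factors)
      list(sigma2_g = exp(theta[1]),
           sigma2_vc = stats::setNames(exp(theta[1 + seq_len(nf)]),
                                       spec$factors),
           sigma2_ge = exp(theta[nf + 2]))
    },
    fa = {
      mask <- fa_mask(t, spec$k)
      nl <- sum(!mask)
      Lambda <- matrix(0, t, spec$k)
      Lambda[!mask] <- theta[seq_len(nl)]
      list(Lambda = Lambda, psi = exp(theta[nl + seq_len(t)]))
    },
    us = {
      L <- matrix(0, t, t)
      diag(L) <- exp(theta[seq_len(t)])
      L[lower.tri(L)] <- theta[t + seq_len(t * (t - 1) / 2)]
      list(L = L)
    }
  )
  out$sigma2_p <- sigma2_p
  out
}

vm_lower <- function(spec, t) {
  lo <- switch(spec$kind,
    diag = rep(log(VAR_FLOOR), t),
    cs = rep(log(VAR_FLOOR), 2),
    vc = rep(log(VAR_FLOOR), 2 + length(spec$factors)),
    fa = c(rep(-Inf, sum(!fa_mask(t, spec$k))), rep(log(VAR_FLOOR), t)),
    us = c(rep(log(VAR_FLOOR) / 2, t), rep(-Inf, t * (t - 1) / 2))
  )
  c(lo, rep(log(VAR_FLOOR), length(spec$peripheral)))
}

# indicator matrices for vc partition factors
vc_indicators <- function(spec, env) {
  purrr::map(spec$factors, function(f) {
    v <- switch(f,
      region = env$region,
      year = as.character(env$year),
      `region:year` = paste(env$region, env$year, sep = ":")
    )
    if (anyNA(v)) {
      stop_validation("partition factor '", f,
                      "' undefined for some environments")
    }
    outer(v, v, "==") * 1
  }) |>
    stats::setNames(spec$factors)
}

# assemble G_e from a parameter list
ge_matrix <- function(spec, params, env = NULL) {
  t <- if (!is.null(env)) nrow(env) else {
    switch(spec$kind,
      diag = length(params$sigma2),
      fa = nrow(params$Lambda),
      us = nrow(params$L),
      stop("environment register needed to size G_e for ", spec$kind)
    )
  }
  switch(spec$kind,
    diag = diag(params$sigma2, t),
    cs = matrix(params$sigma2_g, t, t) + diag(params$sigma2_ge, t),
    vc = {
      G <- matrix(params$sigma2_g, t, t) + diag(params$sigma2_ge, t)
      S <- vc_indicators(spec, env)
      for (f in spec$factors) G <- G + params$sigma2_vc[[f]] * S[[f]]
      G
    },
    fa = tcrossprod(params$Lambda) + diag(params$psi, t),
    us = if (!is.null(params$L)) tcrossprod(params$L) else {
      (params$Ge + t(params$Ge)) / 2
    }
  )
}

# gradient of the REML log-likelihood w.r.t. theta, given the t x t matrix
# D such that dl = -1/2 * tr(D dG_e) (plus peripheral pieces handled by the
# caller); chain rule through the log/Cholesky parametrizations.
vm_grad_genetic <- function(spec, params, D, env = NULL) {
  switch(spec$kind,
    diag = -0.5 * diag(D) * params$sigma2,
    cs = c(-0.5 * sum(D) * params$sigma2_g,
           -0.5 * sum(diag(D)) * params$sigma2_ge),
    vc = {
      S <- vc_indicators(spec, env)
      gf <- purrr::map_dbl(spec$factors, function(f) {
        -0.5 * sum(D * S[[f]]) * params$sigma2_vc[[f]]
      })
      c(-0.5 * sum(D) * params$sigma2_g, gf,
        -0.5 * sum(diag(D)) * params$sigma2_ge)
    },
    fa = {
      t <- nrow(params$Lambda)
      mask <- fa_mask(t, spec$k)
      gL <- -(D %*% params$Lambda)
      c(gL[!mask], -0.5 * diag(D) * params$psi)
    },
    us = {
      L <- params$L
      gL <- -(D %*% L)
      c(diag(gL) * diag(L), gL[lower.tri(gL)])
    }
  )
}
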