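# REML fitting on the Cholesky-factor parameterization.
#
# Sigma_G = L_G L_G', Sigma_E = L_E L_E' with 2x2 lower-triangular factors
# theta = (l1, l2, l3, m1, m2, m3):
#   Sigma_G = [[l1^2, l1 l2], [l1 l2, l2^2 + l3^2]], likewise Sigma_E.
# Positive semi-definiteness is then implicit, and the two null spaces of
# the indirect-effect test are linear restrictions:
#   Pa (mediator has no genetic variance, gMM = gMY = 0): l1 = l2 = 0
#   Pb (no mediator->outcome effect, eMY = 0):            m2 = 0

factors_to_vc <- function(th)
  c(th[1]^2, th[1] * th[2], th[2]^2 + th[3]^2,
    th[4]^2, th[4] * th[5], th[5]^2 + th[6]^2)

# Jacobian d(vc)/d(theta), 6x6
factors_jac <- function(th) {
  J <- matrix(0, 6, 6)
  J[1, 1] <- 2 * th[1]
  J[2, 1] <- th[2]; J[2, 2] <- th[1]
  J[3, 2] <- 2 * th[2]; J[3, 3] <- 2 * th[3]
  J[4, 4] <- 2 * th[4]
  J[5, 4] <- th[5]; J[5, 5] <- th[4]
  J[6, 5] <- 2 * th[5]; J[6, 6] <- 2 * th[6]
  J
}

# lower-triangular factor of a 2x2 covariance, jittered to PD if needed
chol2_factor <- function(S, floor = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, floor * max(abs(e$values), 1))
  S <- e$vectors %*% (lam * t(e$vectors))
  L <- t(chol(S))
  c(L[1, 1], L[2, 1], L[2, 2])
}

free_idx <- function(constraint)
  switch(constraint, none = 1:6, Pa = c(3, 4, 5, 6), Pb = c(1, 2, 3, 4, 6))

#' Fit the bivariate GREML model by REML
#'
#' Maximizes the restricted log-likelihood over positive semi-definite
#' genetic and environmental covariance matrices, parameterized through
#' their Cholesky factors (so boundary constraints are implicit), with a
#' quasi-Newton optimizer, analytic gradients and multiple starting values.
#'
#' @param data a [reml_data()] object (or a GRM, in which case
#'   \code{pheno}, \code{traits}, \code{covar}, \code{pcs} are forwarded to
#'   [reml_data()]).
#' @param pheno,traits,covar,pcs see [reml_data()]; ignored when
#'   \code{data} is already a \code{reml_data} object.
#' @param constraint \code{"none"} for the full model, \code{"Pa"} to force
#'   the mediator's genetic variance (and hence genetic covariance) to
#'   zero, \code{"Pb"} to force the environmental covariance to zero.
#' @param se compute the 6x6 sampling covariance of the variance components
#'   from the observed information (unconstrained fits only)?
#' @param start optional list of starting values (each a list with
#'   \code{sigma_G}, \code{sigma_E}); replaces the default three starts
#'   (Haseman-Elston moment estimate, equal variance split, randomized).
#' @param seed seed for the randomized start.
#' @param control optimizer options: \code{maxit} (default 500),
#'   \code{reltol} (1e-12), \code{grad_tol} (1e-6, relative infinity-norm
#'   of the gradient for the convergence flag).
#' @return an object of class \code{"greml_vc"} with elements
#'   \code{sigma_G}, \code{sigma_E}, \code{loglik}, \code{vcov_vc},
#'   \code{beta} (GLS fixed effects per trait), \code{n}, \code{n_used},
#'   \code{constraint}, \code{converged}, \code{theta}.
#' @seealso [mediation_effects()], [lrt_indirect()], [heritability()]
#' @export
reml_fit <- function(data, pheno = NULL, traits = NULL, covar = NULL,
                     pcs = NULL, constraint = c("none", "Pa", "Pb"),
                     se = (constraint == "none"), start = NULL, seed = NULL,
                     control = list()) {
  constraint <- match.arg(constraint)
  force(se)
  if (inherits(data, "grm"))
    data <- reml_data(data, pheno, traits, covar = covar, pcs = pcs)
  stopifnot(inherits(data, "reml_data"))
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12,
                                 grad_tol = 1e-6), control)
  free <- free_idx(constraint)

  if (is.null(start)) start <- default_starts(data, seed = seed)
  th0s <- lapply(start, function(s)
    c(chol2_factor(s$sigma_G), chol2_factor(s$sigma_E)))

  negll <- function(thf) {
    th <- numeric(6); th[free] <- thf
    r <- obj_eval(th, data, want_grad = FALSE)
    if (!is.finite(r$ll)) 1e10 else -r$ll
  }
  neggr <- function(thf) {
    th <- numeric(6); th[free] <- thf
    r <- obj_eval(th, data, want_grad = TRUE)
    if (!is.finite(r$ll)) return(numeric(length(free)))
    -(crossprod(factors_jac(th), r$grad))[free]
  }

  best <- NULL
  for (th0 in th0s) {
    fit <- tryCatch(
      stats::optim(th0[free], negll, neggr, method = "BFGS",
                   control = list(maxit = ctrl$maxit, reltol = ctrl$reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("REML optimization failed for every start")

  th <- numeric(6); th[free] <- best$par
  v <- factors_to_vc(th)
  final <- obj_eval(th, data, want_grad = TRUE)
  gnorm <- max(abs(crossprod(factors_jac(th), final$grad)[free]))
  converged <- best$convergence == 0 &&
    gnorm < ctrl$grad_tol * max(1, abs(final$ll))
  if (!converged)
    warning("REML fit (constraint ", constraint,
            ") may not have converged (gradient norm ",
            format(gnorm, digits = 3), ")")

  vc <- vc_unpack(v)
  out <- list(sigma_G = vc$sigma_G, sigma_E = vc$sigma_E,
              loglik = final$ll, vcov_vc = NULL,
              beta = split_beta(final$beta, data),
              n = data$n, n_used = data$n_used, p = data$p,
              constraint = constraint, converged = converged,
              grad_norm = gnorm, theta = th)
  class(out) <- "greml_vc"
  if (se && constraint == "none")
    out$vcov_vc <- vc_information_vcov(v, data)
  out
}

obj_eval <- function(th, data, want_grad = TRUE) {
  v <- factors_to_vc(th)
  if (data$complete) {
    reml_core(v, data, want_grad = want_grad)
  } else {
    s <- vc_unpack(v)
    ll <- reml_loglik_dense(s$sigma_G, s$sigma_E, data)
    g <- NULL
    if (want_grad && is.finite(ll)) {
      g <- numeric(6)
      h <- 1e-6 * (abs(v) + 1e-3)
      for (k in 1:6) {
        vp <- v; vm <- v
        vp[k] <- v[k] + h[k]; vm[k] <- v[k] - h[k]
        sp <- vc_unpack(vp); sm <- vc_unpack(vm)
        g[k] <- (reml_loglik_dense(sp$sigma_G, sp$sigma_E, data) -
                 reml_loglik_dense(sm$sigma_G, sm$sigma_E, data)) / (2 * h[k])
      }
    }
    list(ll = ll, grad = g, beta = rep(NA_real_, 2 * data$p))
  }
}

split_beta <- function(beta, data) {
  p <- data$p
  if (length(beta) != 2 * p) return(NULL)
  b <- cbind(M = beta[seq_len(p)], Y = beta[p + seq_len(p)])
  rownames(b) <- colnames(data$X)
  b
}

# Starting values: Haseman-Elston moment estimates, an equal split of the
# phenotypic covariance, and a randomized split.
default_starts <- function(data, seed = NULL) {
  X <- data$X
  cc <- !(is.na(data$M) | is.na(data$Y))
  Mv <- data$M[cc]; Yv <- data$Y[cc]; Xc <- X[cc, , drop = FALSE]
  rM <- stats::lm.fit(Xc, Mv)$residuals
  rY <- stats::lm.fit(Xc, Yv)$residuals
  S <- stats::cov(cbind(rM, rY))
  starts <- list(list(sigma_G = S / 2, sigma_E = S / 2))
  A <- data$A[cc, cc, drop = FALSE]
  dA <- diag(A)
  den <- sum(A^2) - sum(dA^2)
  if (den > 0) {
    he <- function(u, w) (sum(u * (A %*% w)) - sum(dA * u * w)) / den
    G <- matrix(c(he(rM, rM), he(rM, rY), he(rM, rY), he(rY, rY)), 2, 2)
    mD <- mean(dA)
    E <- S - G * mD
    starts <- c(list(list(sigma_G = G, sigma_E = E)), starts)
  }
  rng_with_seed(seed, {
    w <- stats::runif(1, 0.2, 0.8)
    starts[[length(starts) + 1]] <- list(sigma_G = w * S,
                                         sigma_E = (1 - w) * S)
  })
  starts
}

rng_with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

# Sampling covariance of the VC vector: inverse observed information,
# obtained by central finite differences of the analytic VC-space gradient.
vc_information_vcov <- function(v, data) {
  gradf <- function(vv) {
    r <- if (data$complete) reml_core(vv, data, want_grad = TRUE)
         else obj_eval_vc_dense(vv, data)
    if (!is.finite(r$ll)) return(rep(NA_real_, 6))
    r$grad
  }
  scale <- mean(abs(v[c(1, 3, 4, 6)]))
  h <- 1e-4 * (abs(v) + 0.01 * scale)
  H <- matrix(NA_real_, 6, 6)
  for (j in 1:6) {
    vp <- v; vm <- v
    vp[j] <- v[j] + h[j]; vm[j] <- v[j] - h[j]
    gp <- gradf(vp); gm <- gradf(vm)
    if (anyNA(gp) || anyNA(gm)) {   # boundary: fall back to forward step
      vp2 <- v; vp2[j] <- v[j] + h[j]
      gp <- gradf(vp2); gm <- gradf(v)
      if (anyNA(gp) || anyNA(gm)) return(NULL)
      H[, j] <- (gp - gm) / h[j]
    } else {
      H[, j] <- (gp - gm) / (2 * h[j])
    }
  }
  H <- (H + t(H)) / 2
  info <- -H
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V)) {                  # pseudo-inverse on the stable subspace
    e <- eigen(info, symmetric = TRUE)
    pos <- e$values > 1e-10 * max(abs(e$values))
    V <- e$vectors[, pos, drop = FALSE] %*%
      ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
    warning("observed information is singular; sampling covariance uses a pseudo-inverse")
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(vc_names, vc_names)
  V
}

obj_eval_vc_dense <- function(v, data) {
  s <- vc_unpack(v)
  ll <- reml_loglik_dense(s$sigma_G, s$sigma_E, data)
  g <- rep(NA_real_, 6)
  if (is.finite(ll)) {
    h <- 1e-6 * (abs(v) + 1e-3)
    for (k in 1:6) {
      vp <- v; vm <- v
      vp[k] <- v[k] + h[k]; vm[k] <- v[k] - h[k]
      sp <- vc_unpack(vp); sm <- vc_unpack(vm)
      g[k] <- (reml_loglik_dense(sp$sigma_G, sp$sigma_E, data) -
               reml_loglik_dense(sm$sigma_G, sm$sigma_E, data)) / (2 * h[k])
    }
  }
  list(ll = ll, grad = g)
}

#' @export
print.greml_vc <- function(x, digits = 4, ...) {
  cat("Bivariate GREML variance components",
      if (x$constraint != "none") paste0("(constraint ", x$constraint, ")"),
      "\n")
  v <- vc_pack(x$sigma_G, x$sigma_E)
  names(v) <- vc_names
  se <- if (!is.null(x$vcov_vc)) sqrt(pmax(diag(x$vcov_vc), 0)) else rep(NA, 6)
  print(round(cbind(estimate = v, se = se), digits))
  cat("logLik:", format(x$loglik, digits = 8), "  n:", x$n,
      "  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
logLik.greml_vc <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- length(free_idx(object$constraint))
  attr(val, "nobs") <- sum(object$n_used)
  class(val) <- "logLik"
  val
}

#' @export
vcov.greml_vc <- function(object, ...) object$vcov_vc

#' @export
coef.greml_vc <- function(object, ...) {
  v <- vc_pack(object$sigma_G, object$sigma_E)
  names(v) <- vc_names
  v
}

#' SNP-based heritability from fitted variance components
#'
#' \eqn{h^2_{SNP} = \sigma_G / (\sigma_G + \sigma_E)} for the requested
#' trait, with a delta-method standard error propagated from the sampling
#' covariance of the variance components.
#'
#' @param vc a [reml_fit()] result.
#' @param trait \code{"M"} (mediator) or \code{"Y"} (outcome).
#' @return named vector \code{c(h2, se)} (\code{se} is \code{NA} when the
#'   fit carries no sampling covariance).
#' @export
heritability <- function(vc, trait = c("Y", "M")) {
  trait <- match.arg(trait)
  i <- if (trait == "M") 1 else 2
  g <- vc$sigma_G[i, i]; e <- vc$sigma_E[i, i]
  tot <- g + e
  if (tot <= 0) stop("total variance of ", trait, " is not positive")
  h2 <- g / tot
  se <- NA_real_
  if (!is.null(vc$vcov_vc)) {
    J <- numeric(6)
    pos <- if (trait == "M") c(1, 4) else c(3, 6)
    J[pos] <- c(e, -g) / tot^2
    se <- sqrt(max(0, drop(J %*% vc$vcov_vc %*% J)))
  }
  c(h2 = h2, se = se)
}

#' Genetic correlation between mediator and outcome
#'
#' \eqn{\rho_G = \sigma^G_{MY} / \sqrt{\sigma^G_{MM}\sigma^G_{YY}}}, in
#' \eqn{[-1, 1]} whenever both genetic variances are positive, with a
#' delta-method standard error.
#'
#' @param vc a [reml_fit()] result with positive genetic variances.
#' @return named vector \code{c(rho, se)}.
#' @export
genetic_correlation <- function(vc) {
  g11 <- vc$sigma_G[1, 1]; g22 <- vc$sigma_G[2, 2]; g12 <- vc$sigma_G[1, 2]
  if (g11 <= 0 || g22 <= 0)
    stop("genetic correlation undefined: a genetic variance is zero ",
         "(the trait pair is not identified on this margin)")
  rho <- g12 / sqrt(g11 * g22)
  se <- NA_real_
  if (!is.null(vc$vcov_vc)) {
    J <- numeric(6)
    J[1] <- -rho / (2 * g11)
    J[2] <- 1 / sqrt(g11 * g22)
    J[3] <- -rho / (2 * g22)
    se <- sqrt(max(0, drop(J %*% vc$vcov_vc %*% J)))
  }
  c(rho = rho, se = se)
}
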