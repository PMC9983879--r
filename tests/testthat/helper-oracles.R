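# Independent reference implementations used as oracles. These are kept
# deliberately naive (dense matrices, solve/determinant, plain finite
# differences) so they share no code path with the package.

# Dense restricted log-likelihood of the stacked bivariate model,
# y = (M; Y), V = SG (x) A + SE (x) I, block-diagonal design.
oracle_reml_loglik <- function(A, M, Y, X, SG, SE) {
  n <- length(M)
  In <- diag(n)
  V <- rbind(cbind(SG[1, 1] * A + SE[1, 1] * In,
                   SG[1, 2] * A + SE[1, 2] * In),
             cbind(SG[1, 2] * A + SE[1, 2] * In,
                   SG[2, 2] * A + SE[2, 2] * In))
  Xf <- rbind(cbind(X, matrix(0, n, ncol(X))),
              cbind(matrix(0, n, ncol(X)), X))
  y <- c(M, Y)
  Vi <- solve(V)
  XtViX <- t(Xf) %*% Vi %*% Xf
  P <- Vi - Vi %*% Xf %*% solve(XtViX) %*% t(Xf) %*% Vi
  ld_V <- determinant(V, logarithm = TRUE)$modulus
  ld_X <- determinant(XtViX, logarithm = TRUE)$modulus
  -0.5 * (as.numeric(ld_V) + as.numeric(ld_X) + drop(y %*% P %*% y) +
          (2 * n - ncol(Xf)) * log(2 * pi))
}

# random 2x2 positive-definite covariance
rand_pd2 <- function(scale = 1) {
  L <- matrix(c(runif(1, 0.3, 1.5), runif(1, -0.8, 0.8), 0,
                runif(1, 0.3, 1.5)), 2, 2)
  scale * tcrossprod(L)
}

# random PSD relatedness-like matrix with unit-ish diagonal
rand_grm_values <- function(n, m = 4 * n) {
  Z <- matrix(rnorm(n * m), n, m)
  Z <- t((t(Z) - colMeans(Z)) / apply(Z, 2, sd))
  tcrossprod(Z) / m
}

# central finite-difference gradient of f at x
fd_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-5 * (abs(x) + 1e-2)
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]; xm[j] <- x[j] - h[j]
    (f(xp) - f(xm)) / (2 * h[j])
  }, numeric(1))
}

# build a greml_vc-shaped object from known VCs (for exercising the
# closed-form mediation map without a fit)
fake_vc <- function(v, vcov_vc = NULL, constraint = "none") {
  s <- magreml:::vc_unpack(v)
  structure(list(sigma_G = s$sigma_G, sigma_E = s$sigma_E,
                 loglik = NA_real_, vcov_vc = vcov_vc,
                 n = NA_integer_, constraint = constraint,
                 converged = TRUE),
            class = "greml_vc")
}

# small simulated dataset with GRM, for fitting tests
small_fixture <- function(n = 300, m = 400, scenario = "Baseline",
                          seed = 1) {
  d <- simulate_dataset(scenario_params(scenario), n = n, m = m,
                        seed = seed)
  g <- compute_grm(d$geno)
  list(geno = d$geno, pheno = d$pheno, grm = g,
       data = reml_data(g, d$pheno, c("M", "Y")))
}
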