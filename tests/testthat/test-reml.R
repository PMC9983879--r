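test_that("canonical-transform likelihood matches the dense oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(8:16, 1)
    A <- rand_grm_values(n)
    g <- magreml:::new_grm(A, paste0("f", 1:n), paste0("i", 1:n))
    X <- cbind(1, rnorm(n))
    M <- rnorm(n); Y <- rnorm(n)
    ph <- data.frame(FID = g$fid, IID = g$iid, M = M, Y = Y)
    cv <- data.frame(FID = g$fid, IID = g$iid, x = X[, 2])
    dat <- reml_data(g, ph, c("M", "Y"), covar = cv)
    SG <- rand_pd2(); SE <- rand_pd2()
    expect_equal(reml_loglik(SG, SE, dat),
                 oracle_reml_loglik(A, M, Y, X, SG, SE),
                 tolerance = 1e-8)
  }
})

test_that("with no genetic variance the likelihood reduces to the iid bivariate closed form", {
  set.seed(12)
  n <- 30
  A <- rand_grm_values(n)
  g <- magreml:::new_grm(A, paste0("f", 1:n), paste0("i", 1:n))
  ph <- data.frame(FID = g$fid, IID = g$iid, M = rnorm(n), Y = rnorm(n))
  dat <- reml_data(g, ph, c("M", "Y"))
  SE <- rand_pd2()
  z <- cbind(ph$M, ph$Y)
  zc <- sweep(z, 2, colMeans(z))
  Sc <- crossprod(zc)
  closed <- -0.5 * ((2 * n - 2) * log(2 * pi) + (n - 1) * log(det(SE)) +
                    2 * log(n) + sum(diag(solve(SE) %*% Sc)))
  expect_equal(reml_loglik(matrix(0, 2, 2), SE, dat), closed,
               tolerance = 1e-8)
})

test_that("likelihood is invariant to a consistent reordering of individuals", {
  set.seed(13)
  n <- 20
  A <- rand_grm_values(n)
  ids <- paste0("i", 1:n)
  g <- magreml:::new_grm(A, ids, ids)
  ph <- data.frame(FID = ids, IID = ids, M = rnorm(n), Y = rnorm(n))
  SG <- rand_pd2(); SE <- rand_pd2()
  ll1 <- reml_loglik(SG, SE, reml_data(g, ph, c("M", "Y")))
  perm <- sample(n)
  g2 <- magreml:::new_grm(A[perm, perm], ids[perm], ids[perm])
  ll2 <- reml_loglik(SG, SE, reml_data(g2, ph[perm, ], c("M", "Y")))
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("analytic VC-space gradient agrees with finite differences", {
  set.seed(14)
  n <- 25
  A <- rand_grm_values(n)
  g <- magreml:::new_grm(A, paste0("f", 1:n), paste0("i", 1:n))
  ph <- data.frame(FID = g$fid, IID = g$iid, M = rnorm(n), Y = rnorm(n))
  cv <- data.frame(FID = g$fid, IID = g$iid, x = rnorm(n))
  dat <- reml_data(g, ph, c("M", "Y"), covar = cv)
  v0 <- c(0.6, 0.2, 0.8, 1.0, 0.3, 1.2)
  ana <- magreml:::reml_core(v0, dat, want_grad = TRUE)$grad
  num <- fd_grad(function(v) magreml:::reml_core(v, dat)$ll, v0)
  expect_equal(ana, num, tolerance = 1e-6)
})

test_that("the dense missing-data path agrees with the fast path on complete data", {
  fx <- small_fixture(n = 40, m = 80, seed = 21)
  SG <- rand_pd2(); SE <- rand_pd2()
  ll_fast <- reml_loglik(SG, SE, fx$data)
  ll_dense <- magreml:::reml_loglik_dense(SG, SE, fx$data)
  expect_equal(ll_fast, ll_dense, tolerance = 1e-8)
})

test_that("per-trait missingness is handled and drops only the absent observations", {
  fx <- small_fixture(n = 60, m = 100, seed = 22)
  ph <- fx$pheno
  ph$M[1:5] <- NA
  ph$Y[6:8] <- NA
  dat <- reml_data(fx$grm, ph, c("M", "Y"))
  expect_false(dat$complete)
  expect_equal(unname(dat$n_used), c(55, 57))
  fit <- reml_fit(dat, se = FALSE, seed = 3)
  expect_true(is.finite(fit$loglik))
  # likelihood at the optimum beats nearby parameter values
  ll0 <- reml_loglik(fit$sigma_G, fit$sigma_E, dat)
  expect_lt(reml_loglik(fit$sigma_G * 1.3, fit$sigma_E, dat), ll0 + 1e-6)
})

test_that("REML recovers generative variance components within 3 SEs", {
  fx <- small_fixture(n = 600, m = 700, seed = 31)
  fit <- reml_fit(fx$data, seed = 31)
  truth <- sem_vcs(scenario_params("Baseline"))
  v <- coef(fit)
  tv <- c(truth$sigma_G[1, 1], truth$sigma_G[1, 2], truth$sigma_G[2, 2],
          truth$sigma_E[1, 1], truth$sigma_E[1, 2], truth$sigma_E[2, 2])
  se <- sqrt(diag(fit$vcov_vc))
  expect_true(all(abs(v - tv) < 3 * se))
  expect_true(fit$converged)
})

test_that("a heritability-0.25 outcome is recovered and the VC arithmetic is exact", {
  # mediator-free configuration: gYY = 0.25, eYY = 0.75
  par <- sem_params(a = 0, g = 0, f = 1, b = 0, c = 0.5, e = sqrt(0.75))
  vcs <- sem_vcs(par)
  expect_equal(vcs$sigma_G[2, 2] /
                 (vcs$sigma_G[2, 2] + vcs$sigma_E[2, 2]), 0.25)
  d <- simulate_dataset(par, n = 600, m = 700, seed = 32)
  fit <- reml_fit(compute_grm(d$geno), d$pheno, c("M", "Y"), seed = 32)
  h2 <- heritability(fit, "Y")
  expect_lt(abs(h2["h2"] - 0.25), 3 * max(h2["se"], 0.05))
})

test_that("constrained fits satisfy their restrictions exactly and are nested", {
  fx <- small_fixture(n = 250, m = 300, seed = 41)
  full <- reml_fit(fx$data, seed = 41)
  pa <- reml_fit(fx$data, constraint = "Pa", seed = 41)
  pb <- reml_fit(fx$data, constraint = "Pb", seed = 41)
  expect_identical(pa$sigma_G[1, 1], 0)
  expect_identical(pa$sigma_G[1, 2], 0)
  expect_identical(pb$sigma_E[1, 2], 0)
  expect_lte(pa$loglik, full$loglik + 1e-6)
  expect_lte(pb$loglik, full$loglik + 1e-6)
})

test_that("fitted variance components are scale-equivariant", {
  fx <- small_fixture(n = 250, m = 300, seed = 51)
  fit1 <- reml_fit(fx$data, se = FALSE, seed = 51)
  s <- 3
  ph2 <- fx$pheno
  ph2$Y <- s * ph2$Y
  fit2 <- reml_fit(fx$grm, ph2, c("M", "Y"), se = FALSE, seed = 51)
  expect_equal(fit2$sigma_G[2, 2], s^2 * fit1$sigma_G[2, 2],
               tolerance = 1e-3)
  expect_equal(fit2$sigma_E[2, 2], s^2 * fit1$sigma_E[2, 2],
               tolerance = 1e-3)
  expect_equal(fit2$sigma_G[1, 2], s * fit1$sigma_G[1, 2],
               tolerance = 1e-3)
  expect_equal(fit2$sigma_E[1, 2], s * fit1$sigma_E[1, 2],
               tolerance = 1e-3)
})

test_that("heritability and genetic correlation follow their closed forms with delta SEs", {
  v <- c(2, 3, 5, 1, 1, 2)
  vc <- fake_vc(v, vcov_vc = diag(6))
  expect_equal(unname(heritability(vc, "M")["h2"]), 2 / 3)
  expect_equal(unname(heritability(vc, "Y")["h2"]), 5 / 7)
  rg <- genetic_correlation(vc)
  expect_equal(unname(rg["rho"]), 3 / sqrt(10))
  # SEs against numerical Jacobians through the same covariance
  Jh <- fd_grad(function(x) x[3] / (x[3] + x[6]), v)
  expect_equal(unname(heritability(vc, "Y")["se"]),
               sqrt(sum(Jh^2)), tolerance = 1e-6)
  Jr <- fd_grad(function(x) x[2] / sqrt(x[1] * x[3]), v)
  expect_equal(unname(rg["se"]), sqrt(sum(Jr^2)), tolerance = 1e-6)
  # edge cases
  expect_equal(unname(heritability(fake_vc(c(0, 0, 1, 1, 0, 1)), "M")["h2"]), 0)
  expect_equal(unname(genetic_correlation(
    fake_vc(c(1, 0, 1, 1, 0, 1)))["rho"]), 0)
  expect_equal(unname(genetic_correlation(
    fake_vc(c(1, sqrt(2), 2, 1, 0, 1)))["rho"]), 1)
  expect_error(genetic_correlation(fake_vc(c(0, 0, 1, 1, 0, 1))),
               "identified")
})

test_that("a singular covariance block is reported with its eigenvalue index", {
  fx <- small_fixture(n = 30, m = 50, seed = 61)
  expect_error(reml_loglik(matrix(0, 2, 2), matrix(0, 2, 2), fx$data),
               "eigenvalue index")
})

test_that("rank-deficient covariates and duplicate ids are rejected", {
  fx <- small_fixture(n = 30, m = 50, seed = 62)
  cv <- data.frame(FID = fx$grm$fid, IID = fx$grm$iid, x = 1)  # = intercept
  expect_error(reml_data(fx$grm, fx$pheno, c("M", "Y"), covar = cv),
               "rank deficient")
  ph <- rbind(fx$pheno, fx$pheno[1, ])
  expect_error(reml_data(fx$grm, ph, c("M", "Y")), "duplicated")
  expect_error(reml_data(fx$grm, fx$pheno, c("M", "M")), "must differ")
})
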