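test_that("unit-coefficient structural model maps to (b=1, indirect=2, direct=1, cross=2)", {
  vcs <- sem_vcs(sem_params(1, 1, 1, 1, 1, 1))
  expect_equal(unname(magreml:::vc_pack(vcs$sigma_G, vcs$sigma_E)),
               c(2, 3, 5, 1, 1, 2))
  med <- mediation_effects(fake_vc(c(2, 3, 5, 1, 1, 2)))
  e <- med$estimates
  expect_equal(unname(e["b"]), 1)
  expect_equal(unname(e["indirect"]), 2)
  expect_equal(unname(e["direct"]), 1)
  expect_equal(unname(e["cross"]), 2)
  expect_equal(unname(e["prop_mediated"]), 2 / 5)
})

test_that("no environmental covariance means no mediated effect", {
  med <- mediation_effects(fake_vc(c(2, 1, 5, 1, 0, 2)))
  expect_equal(unname(med$estimates["b"]), 0)
  expect_equal(unname(med$estimates["indirect"]), 0)
  expect_equal(unname(med$estimates["direct"]), 5)
  # direct evaluation of the indirect-effect formula
  med2 <- mediation_effects(fake_vc(c(2, 1, 5, 1, 0.5, 2)))
  expect_equal(unname(med2$estimates["indirect"]), 2 * 0.25)
})

test_that("composing the forward map with the VC inversion recovers the path quantities exactly", {
  set.seed(71)
  for (i in 1:1000) {
    par <- sem_params(a = runif(1, -2, 2), g = runif(1, -2, 2),
                      f = runif(1, 0.2, 2), b = runif(1, -2, 2),
                      c = runif(1, -2, 2), e = runif(1, 0, 2))
    vcs <- sem_vcs(par)
    v <- magreml:::vc_pack(vcs$sigma_G, vcs$sigma_E)
    e <- suppressMessages(mediation_effects(fake_vc(v)))$estimates
    ag2 <- par$a^2 + par$g^2
    expect_lt(abs(e[["b"]] - par$b), 1e-10)
    expect_lt(abs(e[["indirect"]] - ag2 * par$b^2), 1e-10)
    expect_lt(abs(e[["direct"]] - par$c^2), 1e-9)
    expect_lt(abs(e[["cross"]] - 2 * par$a * par$b * par$c), 1e-9)
    # additive decomposition of the outcome's genetic variance is exact
    expect_lt(abs(e[["direct"]] + e[["indirect"]] + e[["cross"]] -
                  vcs$sigma_G[2, 2]), 1e-12)
  }
})

test_that("effects are equivariant under rescaling of the mediator", {
  v <- c(2, 3, 5, 1, 1, 2)
  s <- 2.5  # M -> s M scales gMM, eMM by s^2 and the covariances by s
  v2 <- c(v[1] * s^2, v[2] * s, v[3], v[4] * s^2, v[5] * s, v[6])
  e1 <- mediation_effects(fake_vc(v))$estimates
  e2 <- mediation_effects(fake_vc(v2))$estimates
  expect_equal(unname(e2["b"]), unname(e1["b"]) / s)
  expect_equal(unname(e2["indirect"]), unname(e1["indirect"]))
  expect_equal(unname(e2["direct"]), unname(e1["direct"]))
})

test_that("a mediator with zero genetic variance has zero indirect effect whatever b is", {
  med <- suppressMessages(mediation_effects(fake_vc(c(0, 0, 1, 1, 0.8, 2))))
  expect_equal(unname(med$estimates["indirect"]), 0)
})

test_that("zero environmental mediator variance is a model violation, not an estimate", {
  expect_error(mediation_effects(fake_vc(c(2, 1, 5, 1e-12, 0.5, 2))),
               "environmental variance")
})

test_that("delta-method SEs use the analytic Jacobian correctly", {
  # unit covariance: SE(b) at eMM = eMY = 1 is sqrt(J J') = sqrt(2)
  vc <- fake_vc(c(2, 3, 5, 1, 1, 2), vcov_vc = diag(6))
  expect_equal(delta_se(vc, "b"), sqrt(2))
  # zero covariance: all SEs zero
  vc0 <- fake_vc(c(2, 3, 5, 1, 1, 2), vcov_vc = matrix(0, 6, 6))
  for (w in c("b", "indirect", "direct"))
    expect_equal(delta_se(vc0, w), 0)
})

test_that("analytic Jacobian matches finite differences on random PSD covariances", {
  set.seed(72)
  for (i in 1:20) {
    v <- c(runif(1, 0.5, 3), runif(1, -1, 1), runif(1, 0.5, 3),
           runif(1, 0.5, 3), runif(1, -1, 1), runif(1, 0.5, 3))
    Jnum <- rbind(
      fd_grad(function(x) x[5] / x[4], v),
      fd_grad(function(x) x[1] * (x[5] / x[4])^2, v),
      fd_grad(function(x) x[3] + x[1] * (x[5] / x[4])^2 -
                2 * x[2] * x[5] / x[4], v))
    Jana <- mediation_jacobian(v)
    expect_equal(unname(Jana), Jnum, tolerance = 1e-6)
    # SE through a random PSD covariance agrees both ways
    R <- matrix(rnorm(36), 6)
    Vv <- crossprod(R) / 6
    vc <- fake_vc(v, vcov_vc = Vv)
    for (k in 1:3) {
      se_num <- sqrt(drop(Jnum[k, ] %*% Vv %*% Jnum[k, ]))
      se_ana <- delta_se(vc, c("b", "indirect", "direct")[k])
      expect_equal(se_ana, se_num, tolerance = 1e-6)
    }
  }
})

test_that("report serialization carries the estimates", {
  fx <- small_fixture(n = 200, m = 250, seed = 73)
  fit <- greml_mediation(fx$grm, fx$pheno, prune = NULL, lrt = TRUE,
                         seed = 73)
  pre <- tempfile()
  write_mediation_report(fit, pre)
  rep <- read.table(paste0(pre, ".report.txt"), sep = "\t",
                    stringsAsFactors = FALSE)
  kv <- setNames(rep$V2, rep$V1)
  expect_equal(as.numeric(kv["b"]),
               unname(fit$mediation$estimates["b"]))
  est <- read.table(paste0(pre, ".estimates.tsv"), header = TRUE, sep = "\t")
  expect_setequal(est$quantity,
                  c("b", "indirect", "direct", "cross", "prop_mediated",
                    "prop_of_total"))
  expect_true(file.exists(paste0(pre, ".lrt.txt")))
})
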