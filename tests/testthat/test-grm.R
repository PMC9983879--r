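test_that("standardized cross-products match hand arithmetic", {
  g <- genotype_matrix(matrix(c(0, 2), 2, 1), iid = c("a", "b"),
                       allele_freq = 0.5)
  A <- compute_grm(g)$values
  expect_equal(unname(A), matrix(c(2, -2, -2, 2), 2, 2))

  g2 <- genotype_matrix(rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0)),
                        iid = c("a", "b", "c"))
  A2 <- compute_grm(g2)$values
  expect_equal(A2[1, 2], A2[1, 1])   # identical dosage vectors
  expect_equal(A2[1, 2], A2[2, 2])
})

test_that("GRM is exactly symmetric and invariant to SNP order", {
  set.seed(4)
  n <- 40; m <- 60
  p <- runif(m, 0.1, 0.9)
  X <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  g <- genotype_matrix(X)
  A <- compute_grm(g)$values
  expect_identical(A, t(A))
  perm <- sample(m)
  g2 <- genotype_matrix(X[, perm], snp_ids = g$snp_ids[perm])
  expect_equal(compute_grm(g2)$values, A)
})

test_that("monomorphic-only input is rejected", {
  g <- genotype_matrix(matrix(2, 3, 2), iid = letters[1:3])
  expect_error(compute_grm(g), "polymorphic")
})

test_that("HWE genotypes give unit-mean diagonal and 1/m off-diagonal variance", {
  set.seed(99)
  g <- sim_genotypes(200, 5000)
  A <- compute_grm(g)$values
  expect_lt(abs(mean(diag(A)) - 1), 0.05)
  off <- A[upper.tri(A)]
  # sample-frequency centering makes all row sums of Z zero, so the
  # off-diagonal mean is exactly -tr(A)/(n(n-1)), i.e. about -1/(n-1)
  expect_equal(mean(off), -sum(diag(A)) / (200 * 199), tolerance = 1e-10)
  expect_lt(abs(mean(off)), 0.01)
  expect_lt(abs(var(off) - 1 / 5000), 0.1 / 5000)
})

test_that("missing dosages drop out of the pair sums with per-pair counts", {
  X <- rbind(c(0, 2, NA), c(2, 0, 2), c(1, 1, 1))
  g <- genotype_matrix(X, iid = c("a", "b", "c"), allele_freq = rep(0.5, 3))
  grm <- compute_grm(g)
  z <- (X - 1) / sqrt(0.5)            # standardized at p = 0.5
  expect_equal(grm$values[1, 2], sum(z[1, 1:2] * z[2, 1:2]) / 2)
  expect_equal(grm$values[2, 3], sum(z[2, ] * z[3, ]) / 3)
  expect_equal(grm$n_snps[1, 2], 2)
  expect_equal(grm$n_snps[2, 3], 3)
})

test_that("relatedness pruning removes a minimal hub set and is idempotent", {
  mk <- function(A) magreml:::new_grm(A, paste0("f", 1:nrow(A)),
                                      paste0("i", 1:nrow(A)))
  # single related pair: one of the two goes, the third stays
  A <- diag(3); A[1, 2] <- A[2, 1] <- 0.5
  pr <- prune_related(mk(A), 0.025)
  expect_length(pr$removed_ids, 1)
  expect_true(pr$removed_ids %in% c("f1:i1", "f2:i2"))
  expect_true("f3:i3" %in% rownames(pr$grm$values))

  # star graph: only the hub is removed
  A <- diag(4)
  A[1, 2:4] <- A[2:4, 1] <- 0.1
  pr <- prune_related(mk(A), 0.025)
  expect_identical(pr$removed_ids, "f1:i1")

  # below threshold: nothing happens
  A <- diag(3) + 0.01; diag(A) <- 1
  pr <- prune_related(mk(A), 0.025)
  expect_length(pr$removed_ids, 0)
  expect_equal(dim(pr$grm$values), c(3, 3))

  # idempotence on a random relatedness structure
  set.seed(2)
  A <- rand_grm_values(30, 40)
  pr1 <- prune_related(mk(A), 0.2)
  pr2 <- prune_related(pr1$grm, 0.2)
  expect_length(pr2$removed_ids, 0)

  # missing-phenotype tie-break: prefer dropping the less-phenotyped one
  A <- diag(2); A[1, 2] <- A[2, 1] <- 0.5
  pr <- prune_related(mk(A), 0.025, n_missing = c(2L, 0L))
  expect_identical(pr$removed_ids, "f1:i1")
})

test_that("GRM principal components are orthonormal eigenvectors with fixed signs", {
  set.seed(5)
  A <- rand_grm_values(25)
  g <- magreml:::new_grm(A, paste0("f", 1:25), paste0("i", 1:25))
  U <- grm_pcs(g, k = 4)
  expect_equal(crossprod(U), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  lam <- attr(U, "values")
  for (j in 1:4) {
    expect_lt(max(abs(A %*% U[, j] - lam[j] * U[, j])), 1e-8)
    expect_gt(U[which.max(abs(U[, j])), j], 0)
  }
  # rank-1 + ridge: leading PC parallel to the spike
  v <- rnorm(25); v <- v / sqrt(sum(v^2))
  g1 <- magreml:::new_grm(tcrossprod(v) + 0.01 * diag(25),
                          paste0("f", 1:25), paste0("i", 1:25))
  U1 <- grm_pcs(g1, k = 1)
  expect_gt(abs(sum(U1[, 1] * v)), 1 - 1e-8)
  expect_error(grm_pcs(g, k = 25), "k must")
})

test_that("GCTA binary round-trip is lossless to float32 and layout is lower-triangle row-wise", {
  tmp <- tempfile()
  g <- magreml:::new_grm(matrix(c(1, 0.1, 0.1, 1), 2, 2), c("f1", "f2"),
                         c("i1", "i2"))
  write_grm_gcta(g, tmp)
  con <- file(paste0(tmp, ".grm.bin"), "rb")
  raw <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  close(con)
  expect_equal(raw, c(1, 0.1, 1), tolerance = 1e-6)

  set.seed(6)
  A <- rand_grm_values(50)
  g2 <- magreml:::new_grm(A, paste0("f", 1:50), paste0("i", 1:50))
  write_grm_gcta(g2, tmp)
  g3 <- read_grm_gcta(tmp)
  expect_lt(max(abs(g3$values - A)), 1e-6)
  expect_identical(g3$fid, g2$fid)
  expect_identical(g3$iid, g2$iid)

  # inconsistent id/triangle sizes must be caught, naming both
  writeLines(c("f1\ti1", "f2\ti2", "f3\ti3"), paste0(tmp, ".grm.id"))
  con <- file(paste0(tmp, ".grm.bin"), "wb")
  writeBin(c(1, 0.1, 1), con, size = 4); close(con)
  expect_error(read_grm_gcta(tmp), "mismatch")
})
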