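# Bivariate GREML restricted likelihood.
#
# Model for traits (M, Y) on n individuals with relatedness matrix A:
#   vec(M, Y) ~ N(X beta, Sigma_G (x) A + Sigma_E (x) I)
# After rotating phenotypes and covariates by the eigenvectors U of
# A = U diag(d) U', the covariance block-diagonalizes into per-individual
# 2x2 blocks V_i = d_i Sigma_G + Sigma_E (the canonical transformation),
# so the restricted log-likelihood
#   l_R = -1/2 [ (N - p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
# and its gradient cost O(n) per evaluation. Individuals missing one trait
# break the Kronecker structure; they are handled exactly by a dense
# evaluation path (see reml_loglik_dense), quadratic in n.

#' Prepare aligned REML data
#'
#' Aligns a GRM with phenotype and covariate tables by (FID, IID), drops
#' individuals missing both traits or any covariate, and precomputes the
#' eigendecomposition of the relatedness matrix restricted to the analysis
#' sample. The returned object is consumed by [reml_loglik()] and
#' [reml_fit()].
#'
#' @param grm a GRM object.
#' @param pheno data frame with columns FID, IID and the two traits.
#' @param traits character vector of length 2: mediator and outcome column
#'   names (order (M, Y)).
#' @param covar optional data frame with columns FID, IID and numeric
#'   covariates (no missing values among retained individuals); an
#'   intercept is always added.
#' @param pcs optional matrix of GRM principal components (rownames
#'   \code{"FID:IID"}), appended to the covariates.
#' @return an object of class \code{"reml_data"}.
#' @export
reml_data <- function(grm, pheno, traits, covar = NULL, pcs = NULL) {
  stopifnot(inherits(grm, "grm"), length(traits) == 2L)
  if (traits[1] == traits[2]) stop("mediator and outcome must differ")
  if (!all(traits %in% names(pheno)))
    stop("phenotype table lacks column(s): ",
         paste(setdiff(traits, names(pheno)), collapse = ", "))
  gid <- paste(grm$fid, grm$iid, sep = ":")
  pid <- paste(pheno[[1]], pheno[[2]], sep = ":")
  if (anyDuplicated(pid)) stop("duplicated (FID, IID) in phenotype table")
  keep <- gid[gid %in% pid]
  ph <- pheno[match(keep, pid), , drop = FALSE]
  Mv <- as.numeric(ph[[traits[1]]])
  Yv <- as.numeric(ph[[traits[2]]])
  ok <- !(is.na(Mv) & is.na(Yv))
  X <- matrix(1, length(keep), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covar)) {
    cid <- paste(covar[[1]], covar[[2]], sep = ":")
    cm <- match(keep, cid)
    C <- as.matrix(covar[cm, -(1:2), drop = FALSE])
    storage.mode(C) <- "double"
    ok <- ok & !is.na(cm) & stats::complete.cases(C)
    C[is.na(C)] <- 0
    X <- cbind(X, C)
  }
  if (!is.null(pcs)) {
    pm <- match(keep, rownames(pcs))
    ok <- ok & !is.na(pm)
    pm[is.na(pm)] <- 1L
    X <- cbind(X, pcs[pm, , drop = FALSE])
  }
  keep <- keep[ok]
  if (length(keep) < 3L) stop("empty analysis sample")
  Mv <- Mv[ok]; Yv <- Yv[ok]; X <- X[ok, , drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  A <- grm$values[match(keep, gid), match(keep, gid), drop = FALSE]
  complete <- !anyNA(Mv) && !anyNA(Yv)
  out <- list(ids = keep, M = Mv, Y = Yv, X = X, A = A,
              n = length(keep), p = ncol(X), complete = complete,
              n_used = c(M = sum(!is.na(Mv)), Y = sum(!is.na(Yv))))
  if (complete) {
    e <- eigen(A, symmetric = TRUE)
    out$d <- e$values
    out$Mr <- drop(crossprod(e$vectors, Mv))
    out$Yr <- drop(crossprod(e$vectors, Yv))
    out$Xr <- crossprod(e$vectors, X)
  }
  class(out) <- "reml_data"
  out
}

#' @export
print.reml_data <- function(x, ...) {
  cat("REML data: n =", x$n, "individuals,", x$p, "fixed effects per trait\n")
  if (!x$complete)
    cat("  per-trait missingness present (dense likelihood path); n used:",
        paste(names(x$n_used), x$n_used, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Restricted log-likelihood of the bivariate GREML model
#'
#' Evaluates the restricted log-likelihood at given genetic and
#' environmental covariance matrices, using the canonical transformation
#' when both traits are complete and a dense evaluation otherwise.
#'
#' @param sigma_G,sigma_E symmetric 2x2 covariance matrices (traits ordered
#'   mediator, outcome).
#' @param data a [reml_data()] object.
#' @return the restricted log-likelihood (scalar); \code{-Inf} if the
#'   implied covariance is not positive definite.
#' @export
reml_loglik <- function(sigma_G, sigma_E, data) {
  stopifnot(inherits(data, "reml_data"))
  if (data$complete) {
    d <- data$d
    det <- (d * sigma_G[1, 1] + sigma_E[1, 1]) *
           (d * sigma_G[2, 2] + sigma_E[2, 2]) -
           (d * sigma_G[1, 2] + sigma_E[1, 2])^2
    if (any(det <= 0))
      stop("singular covariance block at eigenvalue index ", which(det <= 0)[1])
    reml_core(vc_pack(sigma_G, sigma_E), data, want_grad = FALSE)$ll
  } else {
    reml_loglik_dense(sigma_G, sigma_E, data)
  }
}

# VC vector layout used throughout: (gMM, gMY, gYY, eMM, eMY, eYY)
vc_pack <- function(sigma_G, sigma_E)
  c(sigma_G[1, 1], sigma_G[1, 2], sigma_G[2, 2],
    sigma_E[1, 1], sigma_E[1, 2], sigma_E[2, 2])

vc_unpack <- function(v)
  list(sigma_G = matrix(v[c(1, 2, 2, 3)], 2, 2,
                        dimnames = list(c("M", "Y"), c("M", "Y"))),
       sigma_E = matrix(v[c(4, 5, 5, 6)], 2, 2,
                        dimnames = list(c("M", "Y"), c("M", "Y"))))

vc_names <- c("gMM", "gMY", "gYY", "eMM", "eMY", "eYY")

# Canonical-transform likelihood and analytic gradient in VC space.
# Per-individual 2x2 blocks V_i = d_i Sigma_G + Sigma_E are inverted in
# closed form; the fixed effects are concentrated out by REML.
reml_core <- function(v, data, want_grad = TRUE) {
  d <- data$d; Mr <- data$Mr; Yr <- data$Yr; X <- data$Xr
  n <- data$n; p <- data$p
  v11 <- d * v[1] + v[4]
  v12 <- d * v[2] + v[5]
  v22 <- d * v[3] + v[6]
  det <- v11 * v22 - v12 * v12
  if (any(det <= 0) || any(v11 <= 0)) return(list(ll = -Inf))
  w11 <- v22 / det; w22 <- v11 / det; w12 <- -v12 / det
  logdetV <- sum(log(det))
  B11 <- crossprod(X, X * w11)
  B12 <- crossprod(X, X * w12)
  B22 <- crossprod(X, X * w22)
  XtVX <- rbind(cbind(B11, B12), cbind(B12, B22))
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  logdetX <- 2 * sum(log(diag(ch)))
  u <- c(crossprod(X, w11 * Mr + w12 * Yr),
         crossprod(X, w12 * Mr + w22 * Yr))
  beta <- backsolve(ch, backsolve(ch, u, transpose = TRUE))
  rM <- Mr - drop(X %*% beta[seq_len(p)])
  rY <- Yr - drop(X %*% beta[p + seq_len(p)])
  qM <- w11 * rM + w12 * rY        # elements of P y
  qY <- w12 * rM + w22 * rY
  yPy <- sum(rM * qM + rY * qY)
  ll <- -0.5 * (logdetV + logdetX + yPy + (2 * n - 2 * p) * log(2 * pi))
  out <- list(ll = ll, beta = beta)
  if (!want_grad) return(out)

  # gradient: dl/dv_k = -1/2 [ tr(V^-1 dV) - tr(K X'V^-1 dV V^-1 X)
  #                            - (Py)' dV (Py) ],  K = (X'V^-1 X)^-1
  K <- chol2inv(ch)
  c1 <- d                              # multiplier for genetic components
  c2 <- rep(1, n)
  g <- numeric(6)
  # pattern S for each VC: E11, E12+E21, E22 (per-block 2x2)
  trWS <- list(w11, 2 * w12, w22)
  qSq <- list(qM * qM, 2 * qM * qY, qY * qY)
  TT <- list(
    list(t11 = w11 * w11, t12 = w11 * w12, t22 = w12 * w12),
    list(t11 = 2 * w11 * w12, t12 = w11 * w22 + w12 * w12,
         t22 = 2 * w12 * w22),
    list(t11 = w12 * w12, t12 = w12 * w22, t22 = w22 * w22))
  for (blk in 1:2) {
    cc <- if (blk == 1) c1 else c2
    for (s in 1:3) {
      k <- (blk - 1) * 3 + s
      tr1 <- sum(cc * trWS[[s]])
      Tk <- TT[[s]]
      C11 <- crossprod(X, X * (cc * Tk$t11))
      C12 <- crossprod(X, X * (cc * Tk$t12))
      C22 <- crossprod(X, X * (cc * Tk$t22))
      Cfull <- rbind(cbind(C11, C12), cbind(C12, C22))
      tr2 <- sum(K * Cfull)
      g[k] <- -0.5 * (tr1 - tr2 - sum(cc * qSq[[s]]))
    }
  }
  out$grad <- g
  out
}

# Dense restricted likelihood supporting per-trait missingness: builds the
# observed-entry covariance explicitly. O(n^3); intended for modest n or
# validation.
reml_loglik_dense <- function(sigma_G, sigma_E, data) {
  A <- data$A; X1 <- data$X
  mi <- which(!is.na(data$M)); yi <- which(!is.na(data$Y))
  y <- c(data$M[mi], data$Y[yi])
  nm <- length(mi); ny <- length(yi)
  Imy <- outer(mi, yi, "==") * 1
  V <- rbind(
    cbind(sigma_G[1, 1] * A[mi, mi] + sigma_E[1, 1] * diag(nm),
          sigma_G[1, 2] * A[mi, yi] + sigma_E[1, 2] * Imy),
    cbind(sigma_G[1, 2] * A[yi, mi] + sigma_E[1, 2] * t(Imy),
          sigma_G[2, 2] * A[yi, yi] + sigma_E[2, 2] * diag(ny)))
  X <- rbind(cbind(X1[mi, , drop = FALSE],
                   matrix(0, nm, ncol(X1))),
             cbind(matrix(0, ny, ncol(X1)), X1[yi, , drop = FALSE]))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  Vi_X <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  XtVX <- crossprod(X, Vi_X)
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(-Inf)
  logdetX <- 2 * sum(log(diag(ch2)))
  u <- crossprod(X, Vi_y)
  beta <- backsolve(ch2, backsolve(ch2, u, transpose = TRUE))
  yPy <- sum(y * Vi_y) - sum(u * beta)
  -0.5 * (logdetV + logdetX + yPy +
          (length(y) - ncol(X)) * log(2 * pi))
}
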