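#' Genetic mediation analysis via bivariate GREML
#'
#' @description
#' One-stop analysis: given a genomic relatedness matrix and phenotypes
#' for a mediator and an outcome, fits the bivariate variance-component
#' model by REML, decomposes the outcome's genetic variance into the part
#' transmitted through the mediator (indirect effect), the part bypassing
#' it (direct effect) and a cross term, and tests the indirect effect with
#' the boundary-aware likelihood-ratio test.
#'
#' The analysis sample is the (FID, IID) intersection of the GRM and the
#' phenotype (and covariate) tables, optionally pruned so that no pair
#' exceeds the relatedness threshold; leading principal components of the
#' pruned GRM can be added to the fixed effects.
#'
#' Identification rests on assumptions the data cannot fully check: the
#' heritability model behind the GRM is correct; the mediator precedes the
#' outcome with a homogeneous effect; environmental paths from mediator to
#' outcome other than the causal effect are controlled via the supplied
#' covariates; and the mediator retains nonzero environmental variance
#' (the only one verified numerically here).
#'
#' @param grm a GRM object ([compute_grm()] or [read_grm_gcta()]).
#' @param pheno data frame (or file path) with columns FID, IID and the
#'   trait columns.
#' @param mediator,outcome trait column names (must differ).
#' @param covar optional covariate data frame or file path (FID, IID,
#'   numeric columns).
#' @param n_pcs number of GRM principal components added as fixed-effect
#'   covariates (0 to disable).
#' @param prune relatedness threshold for pruning, or \code{NULL} to skip.
#' @param lrt run the likelihood-ratio test for the indirect effect?
#' @param seed seed for the optimizer's randomized start.
#' @param control optimizer options, see [reml_fit()].
#' @return object of class \code{"magreml"}: list with \code{vc} (the
#'   unconstrained [reml_fit()]), \code{mediation}
#'   ([mediation_effects()]), \code{lrt} ([lrt_indirect()] or
#'   \code{NULL}), \code{h2}, \code{rg}, \code{pruned} (removed IDs),
#'   \code{n}, \code{call}.
#' @examples
#' sim <- simulate_dataset(scenario_params("Baseline"), n = 150, m = 120,
#'                         seed = 7)
#' fit <- greml_mediation(compute_grm(sim$geno), sim$pheno,
#'                        prune = NULL, lrt = FALSE, seed = 7)
#' coef(fit)
#' @export
greml_mediation <- function(grm, pheno, mediator = "M", outcome = "Y",
                            covar = NULL, n_pcs = 0, prune = 0.025,
                            lrt = TRUE, seed = NULL, control = list()) {
  cl <- match.call()
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  if (is.character(covar)) covar <- read_phenotypes(covar)
  if (identical(mediator, outcome))
    stop("mediator and outcome must be different columns")
  removed <- character(0)
  if (!is.null(prune)) {
    pid <- paste(pheno[[1]], pheno[[2]], sep = ":")
    gid <- paste(grm$fid, grm$iid, sep = ":")
    nm <- match(gid, pid)
    n_missing <- ifelse(is.na(nm), 2L,
                        is.na(pheno[[mediator]][nm]) +
                        is.na(pheno[[outcome]][nm]))
    pr <- prune_related(grm, threshold = prune, n_missing = n_missing)
    grm <- pr$grm
    removed <- pr$removed_ids
  }
  if (nrow(grm$values) < 3L) stop("empty analysis sample after pruning")
  pcs <- if (n_pcs > 0) grm_pcs(grm, k = n_pcs) else NULL
  dat <- reml_data(grm, pheno, traits = c(mediator, outcome),
                   covar = covar, pcs = pcs)
  fit <- reml_fit(dat, se = TRUE, seed = seed, control = control)
  med <- mediation_effects(fit)
  lr <- if (lrt) lrt_indirect(dat, fit_full = fit, seed = seed,
                              control = control) else NULL
  out <- list(vc = fit, mediation = med, lrt = lr,
              h2 = rbind(M = heritability(fit, "M"),
                         Y = heritability(fit, "Y")),
              rg = tryCatch(genetic_correlation(fit),
                            error = function(e) c(rho = NA, se = NA)),
              pruned = removed, n = dat$n, n_used = dat$n_used,
              traits = c(mediator = mediator, outcome = outcome),
              data = dat, seed = seed, call = cl)
  class(out) <- "magreml"
  out
}

#' @export
print.magreml <- function(x, digits = 4, ...) {
  cat("Genetic mediation analysis (bivariate GREML)\n")
  cat("  mediator:", x$traits["mediator"], "  outcome:", x$traits["outcome"],
      "  n =", x$n, "\n")
  if (length(x$pruned))
    cat("  pruned", length(x$pruned), "individuals (relatedness)\n")
  print(x$mediation, digits = digits)
  if (!is.null(x$lrt))
    cat(sprintf("LRT for indirect effect: stat = %.4g on %d df, p = %s (%s)\n",
                x$lrt$statistic, x$lrt$df,
                format.pval(x$lrt$p_value, digits = digits),
                x$lrt$active_space))
  invisible(x)
}

#' @export
summary.magreml <- function(object, ...) {
  structure(list(fit = object), class = "summary.magreml")
}

#' @export
print.summary.magreml <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f$vc, digits = digits)
  cat("\nSNP heritability (with delta-method SE):\n")
  print(round(f$h2, digits))
  cat(sprintf("genetic correlation: %.4f (SE %.4f)\n\n",
              f$rg["rho"], f$rg["se"]))
  print(f$mediation, digits = digits)
  cat("\nWald diagnostics (secondary; prefer the LRT):\n")
  print(round(f$mediation$wald, digits))
  if (!is.null(f$lrt)) {
    cat("\n")
    print(f$lrt, digits = digits)
  }
  invisible(x)
}

#' @export
coef.magreml <- function(object, ...)
  object$mediation$estimates[c("b", "indirect", "direct", "cross")]

#' @export
vcov.magreml <- function(object, ...) object$vc$vcov_vc

#' @export
logLik.magreml <- function(object, ...) logLik(object$vc)

#' @export
confint.magreml <- function(object, parm = c("b", "indirect", "direct"),
                            level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$mediation$estimates[parm]
  se <- object$mediation$se[parm]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  out
}

#' @export
residuals.magreml <- function(object, ...) {
  d <- object$data
  beta <- object$vc$beta
  cbind(M = d$M - drop(d$X %*% beta[, "M"]),
        Y = d$Y - drop(d$X %*% beta[, "Y"]))
}

#' @export
fitted.magreml <- function(object, ...) {
  d <- object$data
  beta <- object$vc$beta
  cbind(M = drop(d$X %*% beta[, "M"]), Y = drop(d$X %*% beta[, "Y"]))
}

#' Simulate phenotype pairs from a fitted mediation model
#'
#' Draws new (mediator, outcome) pairs from the fitted variance components
#' on the analysis sample's relatedness structure, with the fitted fixed
#' effects added back. Useful for parametric-bootstrap style checks.
#'
#' @param object a [greml_mediation()] fit.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of data frames (FID, IID, M, Y), length \code{nsim}.
#' @export
simulate.magreml <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  n <- d$n
  eA <- eigen(d$A, symmetric = TRUE)
  LA <- eA$vectors %*% (sqrt(pmax(eA$values, 0)) * t(eA$vectors))
  LG <- chol2_factor(object$vc$sigma_G)
  LE <- chol2_factor(object$vc$sigma_E)
  LG <- matrix(c(LG[1], LG[2], 0, LG[3]), 2, 2)
  LE <- matrix(c(LE[1], LE[2], 0, LE[3]), 2, 2)
  mu <- fitted(object)
  fi <- sub(":.*", "", d$ids); ii <- sub(".*:", "", d$ids)
  rng_with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      Gp <- LA %*% matrix(stats::rnorm(2 * n), n, 2) %*% t(LG)
      Ep <- matrix(stats::rnorm(2 * n), n, 2) %*% t(LE)
      data.frame(FID = fi, IID = ii,
                 M = mu[, "M"] + Gp[, 1] + Ep[, 1],
                 Y = mu[, "Y"] + Gp[, 2] + Ep[, 2],
                 stringsAsFactors = FALSE)
    })
  })
}
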