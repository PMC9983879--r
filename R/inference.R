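# Significance of the indirect effect.
#
# The indirect effect gMM * b^2 is zero iff the mediator has no genetic
# variance (parameter space Pa: gMM = 0, which forces gMY = 0 by positive
# semi-definiteness; two restrictions) or no effect on the outcome
# (parameter space Pb: b = 0, equivalently eMY = 0; one restriction). The
# null space is the union Pa U Pb, which lies partly on the boundary of
# the parameter space, so a Wald test on the indirect effect is unreliable
# (and not invariant to reparameterization). The likelihood-ratio test
# instead maximizes the restricted likelihood separately over Pa and Pb,
# takes the larger of the two as the null optimum, and sets the degrees of
# freedom by where that optimum is attained (2 for Pa, 1 for Pb).

#' Wald test for a scalar estimand
#'
#' \eqn{W = (\hat\theta / SE)^2} against \eqn{\chi^2(1)}. For the indirect
#' effect this is a diagnostic only: the Wald statistic is not invariant to
#' reparameterization and the null lies partly on the parameter-space
#' boundary, so the likelihood-ratio test of [lrt_indirect()] is the
#' recommended test.
#'
#' @param estimate point estimate.
#' @param se its standard error (> 0).
#' @return list with \code{W} and \code{p}.
#' @export
wald_test <- function(estimate, se) {
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  W <- (estimate / se)^2
  list(W = W, p = stats::pchisq(W, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio test for the indirect effect
#'
#' Fits the bivariate GREML model unconstrained and under each of the two
#' null subspaces (mediator without genetic variance; mediator without
#' effect on the outcome), warm-starting the constrained fits from the
#' unconstrained solution projected onto the constraint. The null
#' log-likelihood is the larger of the two constrained optima and the
#' degrees of freedom follow the active subspace. Exact ties are resolved
#' to the one-restriction space, which gives the smaller p-value for a
#' given statistic; ties only occur in degenerate inputs.
#'
#' @param data a [reml_data()] object, or a GRM with \code{pheno},
#'   \code{traits}, \code{covar}, \code{pcs} as in [reml_data()].
#' @param pheno,traits,covar,pcs forwarded to [reml_data()] when
#'   \code{data} is a GRM.
#' @param fit_full optional precomputed unconstrained [reml_fit()] (reused
#'   for the point estimates; avoids refitting).
#' @param seed,control forwarded to [reml_fit()].
#' @param tie_tol absolute log-likelihood difference treated as a tie.
#' @return object of class \code{"lrt_result"}: list with
#'   \code{loglik_full}, \code{loglik_Pa}, \code{loglik_Pb},
#'   \code{loglik_null}, \code{active_space}, \code{df}, \code{statistic},
#'   \code{p_value}, \code{converged}, and the three fits.
#' @export
lrt_indirect <- function(data, pheno = NULL, traits = NULL, covar = NULL,
                         pcs = NULL, fit_full = NULL, seed = NULL,
                         control = list(), tie_tol = 1e-8) {
  if (inherits(data, "grm"))
    data <- reml_data(data, pheno, traits, covar = covar, pcs = pcs)
  if (is.null(fit_full))
    fit_full <- reml_fit(data, se = TRUE, seed = seed, control = control)
  warm <- function(constraint) {
    th <- fit_full$theta
    proj <- vc_unpack(factors_to_vc(
      if (constraint == "Pa") replace(th, 1:2, 0) else replace(th, 5, 0)))
    starts <- c(list(proj), default_starts(data, seed = seed))
    reml_fit(data, constraint = constraint, se = FALSE, start = starts,
             seed = seed, control = control)
  }
  fit_Pa <- warm("Pa")
  fit_Pb <- warm("Pb")
  ll_a <- fit_Pa$loglik; ll_b <- fit_Pb$loglik
  # tie -> Pb (df = 1)
  active <- if (ll_a > ll_b + tie_tol) "Pa" else "Pb"
  ll0 <- max(ll_a, ll_b)
  stat <- 2 * (fit_full$loglik - ll0)
  if (stat < -1e-5 * max(1, abs(fit_full$loglik)))
    stop("null log-likelihood exceeds the unconstrained one; ",
         "optimizer failure on the nested model")
  stat <- max(stat, 0)
  df <- if (active == "Pa") 2L else 1L
  out <- list(loglik_full = fit_full$loglik, loglik_Pa = ll_a,
              loglik_Pb = ll_b, loglik_null = ll0,
              active_space = active, df = df, statistic = stat,
              p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
              converged = fit_full$converged && fit_Pa$converged &&
                fit_Pb$converged,
              fit_full = fit_full, fit_Pa = fit_Pa, fit_Pb = fit_Pb)
  class(out) <- "lrt_result"
  out
}

#' @export
print.lrt_result <- function(x, digits = 4, ...) {
  cat("Likelihood-ratio test for the indirect effect\n")
  cat(sprintf("  logLik: full %.4f | Pa %.4f | Pb %.4f\n",
              x$loglik_full, x$loglik_Pa, x$loglik_Pb))
  cat(sprintf("  null optimum in %s -> df = %d\n", x$active_space, x$df))
  cat(sprintf("  LR statistic = %.*f, p = %s\n", digits, x$statistic,
              format.pval(x$p_value, digits = digits)))
  if (!x$converged) cat("  WARNING: at least one fit did not converge\n")
  invisible(x)
}

#' Power of GREML to detect nonzero SNP heritability
#'
#' Standard GREML power approximation: the sampling variance of the
#' heritability estimate is \eqn{var(\hat h^2) = 2 / (N^2 var(A_{jk}))},
#' with \eqn{var(A_{jk})} the variance of the off-diagonal relatedness
#' entries (about 2e-5 for genome-wide SNP data on unrelated individuals).
#' Power is the upper tail of a noncentral chi-square(1) with
#' noncentrality \eqn{h^4 / var(\hat h^2)} beyond the central
#' chi-square(1) critical value at \code{alpha}. The power to detect the
#' mediator's heritability is a practical upper bound for the power to
#' detect the indirect effect.
#'
#' @param n sample size.
#' @param h2 true SNP heritability in [0, 1).
#' @param var_relatedness variance of off-diagonal GRM entries; default
#'   2e-5.
#' @param alpha two-sided significance level; default 0.05.
#' @return power in [0, 1].
#' @examples
#' greml_power(10000, 0.125)   # ~0.977
#' @export
greml_power <- function(n, h2, var_relatedness = 2e-5, alpha = 0.05) {
  stopifnot(n > 0, h2 >= 0, h2 < 1, var_relatedness > 0,
            alpha > 0, alpha < 1)
  var_h2 <- 2 / (n^2 * var_relatedness)
  ncp <- h2^2 / var_h2
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
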