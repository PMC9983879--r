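# Mediation estimands from the six variance components.
#
# Under the structural model  M = G a + G* g + E* f,  Y = G c + M b + E e,
# the VCs determine the quantities of interest in closed form:
#   b        = eMY / eMM                    (effect of M on Y)
#   indirect = gMM * b^2                    (= (a^2 + g^2) b^2)
#   direct   = gYY + gMM b^2 - 2 gMY b      (= c^2)
#   cross    = gYY - direct - indirect      (= 2abc)
# The environmental covariance identifies b because, with environmental
# confounders controlled, the only remaining environmental path from M to
# Y is the causal effect b itself.

#' Mediation effects from fitted variance components
#'
#' Maps a bivariate GREML fit onto the effect of the mediator on the
#' outcome (\code{b}), the genetic variance of the outcome transmitted
#' through the mediator (\code{indirect}), the genetic variance bypassing
#' it (\code{direct}), and the cross term (\code{2abc}) that arises when
#' the same genetic factor acts on the outcome both directly and through
#' the mediator. Standard errors come from the delta method with analytic
#' Jacobians applied to the sampling covariance of the variance
#' components.
#'
#' The decomposition \code{direct + indirect + cross = gYY} holds exactly
#' by construction. Two proportions mediated are reported:
#' \code{prop_mediated} (indirect / genetic variance of the outcome) and
#' \code{prop_of_total} (indirect / (indirect + direct)), which excludes
#' the cross term from the denominator.
#'
#' A mediator with (numerically) zero environmental variance violates the
#' identifying assumption that the mediator has residual environmental
#' variation; below \code{floor_frac} times the mediator's total variance
#' this is reported as an error rather than an exploding \code{b}.
#'
#' @param vc an unconstrained [reml_fit()] result.
#' @param floor_frac lower bound for \code{eMM} as a fraction of the
#'   mediator's total variance.
#' @return object of class \code{"mediation_result"}: list with
#'   \code{estimates} (named vector: b, indirect, direct, cross,
#'   prop_mediated, prop_of_total), \code{se} (named, for b / indirect /
#'   direct), \code{wald} (statistics and p-values, diagnostic only) and
#'   the input VCs.
#' @export
mediation_effects <- function(vc, floor_frac = 1e-6) {
  stopifnot(inherits(vc, "greml_vc"))
  if (vc$constraint != "none")
    stop("mediation effects require the unconstrained fit")
  v <- vc_pack(vc$sigma_G, vc$sigma_E)
  gMM <- v[1]; gMY <- v[2]; gYY <- v[3]; eMM <- v[4]; eMY <- v[5]
  totM <- gMM + eMM
  if (eMM <= floor_frac * totM)
    stop("environmental variance of the mediator is (numerically) zero; ",
         "the model requires a mediator with non-zero environmental variance")
  b <- eMY / eMM
  indirect <- gMM * b^2
  direct <- gYY + gMM * b^2 - 2 * gMY * b
  cross <- gYY - direct - indirect
  prop <- if (gYY > 0) indirect / gYY else NA_real_
  prop2 <- if (indirect + direct > 0) indirect / (indirect + direct) else NA_real_
  if (gYY <= 0)
    message("outcome has no genetic variance; proportion mediated undefined")
  est <- c(b = b, indirect = indirect, direct = direct, cross = cross,
           prop_mediated = prop, prop_of_total = prop2)
  se <- c(b = NA_real_, indirect = NA_real_, direct = NA_real_)
  if (!is.null(vc$vcov_vc)) {
    J <- mediation_jacobian(v)
    Vq <- J %*% vc$vcov_vc %*% t(J)
    dvar <- diag(Vq)
    if (any(dvar < 0)) {
      warning("negative delta-method variance clipped at 0")
      dvar <- pmax(dvar, 0)
    }
    se <- sqrt(dvar)
    names(se) <- c("b", "indirect", "direct")
  }
  wald <- t(vapply(c("b", "indirect", "direct"), function(k) {
    if (is.na(se[k]) || se[k] <= 0) c(W = NA_real_, p = NA_real_)
    else unlist(wald_test(unname(est[k]), unname(se[k])))
  }, numeric(2)))
  structure(list(estimates = est, se = se, wald = wald,
                 sigma_G = vc$sigma_G, sigma_E = vc$sigma_E,
                 vcov_vc = vc$vcov_vc),
            class = "mediation_result")
}

#' Analytic Jacobian of (b, indirect, direct) in the variance components
#'
#' Rows are gradients with respect to
#' \code{(gMM, gMY, gYY, eMM, eMY, eYY)}; used by the delta method and
#' validated against numerical differentiation in the test suite.
#'
#' @param v numeric vector of the six VCs in the order above.
#' @return 3 x 6 matrix.
#' @export
mediation_jacobian <- function(v) {
  gMM <- v[1]; gMY <- v[2]; eMM <- v[4]; eMY <- v[5]
  b <- eMY / eMM
  J <- matrix(0, 3, 6,
              dimnames = list(c("b", "indirect", "direct"), vc_names))
  J["b", ] <- c(0, 0, 0, -eMY / eMM^2, 1 / eMM, 0)
  J["indirect", ] <- c(b^2, 0, 0, -2 * gMM * b^2 / eMM, 2 * gMM * b / eMM, 0)
  J["direct", ] <- c(b^2, -2 * b, 1,
                     -2 * b * (gMM * b - gMY) / eMM,
                     2 * (gMM * b - gMY) / eMM, 0)
  J
}

#' Delta-method standard error for one mediation estimand
#'
#' @param vc an unconstrained [reml_fit()] result carrying \code{vcov_vc}.
#' @param which one of \code{"b"}, \code{"indirect"}, \code{"direct"}.
#' @return the standard error (scalar).
#' @export
delta_se <- function(vc, which = c("b", "indirect", "direct")) {
  which <- match.arg(which)
  if (is.null(vc$vcov_vc)) stop("fit carries no sampling covariance")
  v <- vc_pack(vc$sigma_G, vc$sigma_E)
  J <- mediation_jacobian(v)[which, ]
  q <- drop(J %*% vc$vcov_vc %*% J)
  if (q < 0) {
    warning("negative delta-method variance clipped at 0")
    q <- 0
  }
  sqrt(q)
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat("Genetic mediation decomposition\n")
  est <- x$estimates
  tab <- cbind(estimate = est[c("b", "indirect", "direct", "cross")],
               se = c(x$se[c("b", "indirect", "direct")], NA))
  rownames(tab) <- c("b (M -> Y)", "indirect (gVar via M)",
                     "direct (gVar not via M)", "cross term (2abc)")
  print(round(tab, digits), na.print = "")
  cat(sprintf("proportion of outcome genetic variance mediated: %.4f\n",
              est["prop_mediated"]))
  cat(sprintf("  (excluding cross term from denominator: %.4f)\n",
              est["prop_of_total"]))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  keys <- c("b", "indirect", "direct")
  data.frame(quantity = c(keys, "cross", "prop_mediated", "prop_of_total"),
             estimate = unname(x$estimates[c(keys, "cross", "prop_mediated",
                                             "prop_of_total")]),
             se = c(unname(x$se[keys]), NA, NA, NA),
             row.names = NULL)
}
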