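#' Read phenotype or covariate tables
#'
#' Whitespace- or comma-delimited text with a header row; the first two
#' columns are FID and IID, remaining columns are numeric traits or
#' covariates. Missing values: \code{NA} or \code{-9}.
#'
#' @param path file path.
#' @return data frame with character FID/IID and numeric value columns.
#' @export
read_phenotypes <- function(path) {
  tab <- read_idtable(path)
  for (j in seq_along(tab)[-(1:2)]) tab[[j]] <- as.numeric(tab[[j]])
  tab
}

#' Write a mediation analysis report
#'
#' Writes a flat key-value text report (\code{<prefix>.report.txt}), a
#' machine-readable estimate table (\code{<prefix>.estimates.tsv}) and, if
#' the fit includes one, the likelihood-ratio test audit trail
#' (\code{<prefix>.lrt.txt}).
#'
#' @param fit a [greml_mediation()] result.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_mediation_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "magreml"))
  v <- coef(fit$vc)
  se_vc <- if (!is.null(fit$vc$vcov_vc)) sqrt(pmax(diag(fit$vc$vcov_vc), 0))
           else rep(NA_real_, 6)
  kv <- c(
    n = fit$n,
    n_pruned = length(fit$pruned),
    converged = fit$vc$converged,
    loglik = fit$vc$loglik,
    stats::setNames(v, paste0("vc_", names(v))),
    stats::setNames(se_vc, paste0("se_vc_", names(v))),
    h2_M = fit$h2["M", "h2"], se_h2_M = fit$h2["M", "se"],
    h2_Y = fit$h2["Y", "h2"], se_h2_Y = fit$h2["Y", "se"],
    rg = fit$rg[["rho"]], se_rg = fit$rg[["se"]],
    stats::setNames(fit$mediation$estimates,
                    names(fit$mediation$estimates)),
    stats::setNames(fit$mediation$se, paste0("se_", names(fit$mediation$se))))
  if (!is.null(fit$lrt))
    kv <- c(kv, lrt_stat = fit$lrt$statistic, lrt_df = fit$lrt$df,
            lrt_p = fit$lrt$p_value, lrt_space = fit$lrt$active_space)
  writeLines(paste(names(kv), unname(vapply(kv, as.character, "")),
                   sep = "\t"),
             paste0(prefix, ".report.txt"))
  utils::write.table(as.data.frame(fit$mediation),
                     paste0(prefix, ".estimates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$lrt)) {
    lr <- fit$lrt
    writeLines(c(
      sprintf("loglik_full\t%.8f", lr$loglik_full),
      sprintf("loglik_Pa\t%.8f", lr$loglik_Pa),
      sprintf("loglik_Pb\t%.8f", lr$loglik_Pb),
      sprintf("loglik_null\t%.8f", lr$loglik_null),
      sprintf("active_space\t%s", lr$active_space),
      sprintf("df\t%d", lr$df),
      sprintf("statistic\t%.8f", lr$statistic),
      sprintf("p_value\t%.6g", lr$p_value)),
      paste0(prefix, ".lrt.txt"))
  }
  invisible(prefix)
}
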