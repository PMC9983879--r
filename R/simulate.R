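# Generative structural model for (M, Y).
#
# Two latent genetic factors G and G* (covariance across individuals equal
# to the GRM), two latent environmental factors E and E* (iid standard
# normal), and path coefficients (a, g, f, b, c, e):
#   M = G a + G* g + E* f
#   Y = G c + M b + E e
# G affects Y both directly (c) and through M (a b); G* affects Y only
# through M. The implied variance components are:
#   gMM = a^2 + g^2            eMM = f^2
#   gMY = (a^2 + g^2) b + a c  eMY = f^2 b
#   gYY = (a^2+g^2) b^2 + c^2 + 2abc
#   eYY = f^2 b^2 + e^2
# Genetic factors are built from the simulated SNPs themselves, with
# independent effect vectors ~ N(0, 1/m) on sample-standardized dosages,
# so the realized GRM is the exact covariance model of G and G*.

#' Path coefficients of the generative structural model
#'
#' @param a,g loadings of the shared and mediator-specific genetic factors
#'   on the mediator.
#' @param f loading of the mediator-specific environmental factor (must be
#'   nonzero for a well-posed mediation analysis).
#' @param b effect of the mediator on the outcome.
#' @param c direct loading of the shared genetic factor on the outcome.
#' @param e loading of the outcome-specific environmental factor.
#' @return object of class \code{"sem_params"}.
#' @export
sem_params <- function(a = 1, g = 1, f = 1, b = 1, c = 1, e = 1) {
  stopifnot(is.finite(c(a, g, f, b, c, e)))
  structure(list(a = a, g = g, f = f, b = b, c = c, e = e),
            class = "sem_params")
}

#' @export
print.sem_params <- function(x, ...) {
  cat(sprintf("SEM paths: a=%.3g g=%.3g f=%.3g b=%.3g c=%.3g e=%.3g\n",
              x$a, x$g, x$f, x$b, x$c, x$e))
  cat(sprintf("  implies indirect = %.3g, direct = %.3g, cross = %.3g\n",
              (x$a^2 + x$g^2) * x$b^2, x$c^2, 2 * x$a * x$b * x$c))
  invisible(x)
}

#' Variance components implied by SEM path coefficients
#'
#' The forward map from path coefficients to the six VCs (see the model
#' description above); its composition with [mediation_effects()] recovers
#' \code{b}, the indirect effect \code{(a^2+g^2) b^2} and the direct
#' effect \code{c^2} exactly whenever \code{f != 0}.
#'
#' @param params a [sem_params()] object.
#' @return list with \code{sigma_G} and \code{sigma_E} (2x2 matrices).
#' @export
sem_vcs <- function(params) {
  stopifnot(inherits(params, "sem_params"))
  p <- params
  ag2 <- p$a^2 + p$g^2
  sigma_G <- matrix(c(ag2, ag2 * p$b + p$a * p$c,
                      ag2 * p$b + p$a * p$c,
                      ag2 * p$b^2 + p$c^2 + 2 * p$a * p$b * p$c), 2, 2,
                    dimnames = list(c("M", "Y"), c("M", "Y")))
  sigma_E <- matrix(c(p$f^2, p$f^2 * p$b,
                      p$f^2 * p$b, p$f^2 * p$b^2 + p$e^2), 2, 2,
                    dimnames = list(c("M", "Y"), c("M", "Y")))
  list(sigma_G = sigma_G, sigma_E = sigma_E)
}

#' Named verification scenarios
#'
#' Coefficient patterns of the standard verification study: a Baseline
#' with partial mediation (\code{a^2+g^2 = 2, b = 1, c^2 = 1}) and four
#' contrasts -- (i) mediator without genetic variance, (ii) mediator
#' without effect on the outcome, (iii) neither, (iv) full mediation
#' (\code{c^2 = 0}). The split of \code{a^2+g^2} between the two genetic
#' loadings defaults to equal (\code{a = g}); the quantities of interest
#' depend on the loadings only through \code{a^2+g^2} except for the cross
#' term, which also involves \code{a}. Scales \code{f} and \code{e} are
#' fixed at 1.
#'
#' @param name one of \code{"Baseline"}, \code{"i"}, \code{"ii"},
#'   \code{"iii"}, \code{"iv"}.
#' @param split fraction of \code{a^2+g^2} assigned to \code{a^2}; default
#'   0.5.
#' @return a [sem_params()] object.
#' @export
scenario_params <- function(name = c("Baseline", "i", "ii", "iii", "iv"),
                            split = 0.5) {
  name <- match.arg(name)
  pat <- switch(name,
    Baseline = c(ag2 = 2, b = 1, c2 = 1),
    i   = c(ag2 = 0, b = 1, c2 = 1),
    ii  = c(ag2 = 2, b = 0, c2 = 1),
    iii = c(ag2 = 0, b = 0, c2 = 1),
    iv  = c(ag2 = 2, b = 1, c2 = 0))
  sem_params(a = sqrt(pat[["ag2"]] * split),
             g = sqrt(pat[["ag2"]] * (1 - split)),
             f = 1, b = pat[["b"]], c = sqrt(pat[["c2"]]), e = 1)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' SNP-wise binomial(2, p) dosages with allele frequencies drawn uniformly
#' on \code{maf_range}.
#'
#' @param n individuals; \code{m} SNPs.
#' @param m number of SNPs.
#' @param seed RNG seed (optional).
#' @param maf_range allele-frequency range; default (0.05, 0.95).
#' @return a [genotype_matrix()].
#' @export
sim_genotypes <- function(n, m, seed = NULL, maf_range = c(0.05, 0.95)) {
  stopifnot(n >= 2, m >= 1)
  rng_with_seed(seed, {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    genotype_matrix(X, iid = sprintf("id%04d", seq_len(n)),
                    snp_ids = sprintf("snp%05d", seq_len(m)))
  })
}

# standardized dosage matrix (sample allele frequencies), monomorphic
# SNPs dropped
standardize_dosages <- function(geno) {
  p <- colMeans(geno$dosages, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(geno$dosages[, keep, drop = FALSE], 2L, 2 * p[keep], "-")
  sweep(Z, 2L, sqrt(2 * p[keep] * (1 - p[keep])), "/")
}

# phenotypes given a standardized genotype matrix
simulate_phenotypes_z <- function(Z, params, seed = NULL, fid = NULL,
                                  iid = NULL) {
  n <- nrow(Z); m <- ncol(Z)
  rng_with_seed(seed, {
    G <- drop(Z %*% stats::rnorm(m, sd = sqrt(1 / m)))
    Gs <- drop(Z %*% stats::rnorm(m, sd = sqrt(1 / m)))
    Ev <- stats::rnorm(n)
    Es <- stats::rnorm(n)
    M <- params$a * G + params$g * Gs + params$f * Es
    Y <- params$c * G + params$b * M + params$e * Ev
    data.frame(FID = if (is.null(fid)) sprintf("id%04d", seq_len(n)) else fid,
               IID = if (is.null(iid)) sprintf("id%04d", seq_len(n)) else iid,
               M = M, Y = Y, stringsAsFactors = FALSE)
  })
}

#' Simulate a genotype-phenotype dataset under the structural model
#'
#' Draws HWE genotypes, builds latent genetic factors as independent
#' random linear combinations of the standardized SNPs (so that their
#' covariance across individuals equals the realized GRM), adds iid
#' standard-normal environmental factors, and assembles mediator and
#' outcome from the path coefficients. Deterministic given \code{seed}.
#'
#' @param params a [sem_params()] object.
#' @param n,m individuals and SNPs.
#' @param seed RNG seed.
#' @return list with \code{geno} (a [genotype_matrix()]) and \code{pheno}
#'   (data frame FID, IID, M, Y).
#' @examples
#' d <- simulate_dataset(scenario_params("Baseline"), n = 100, m = 50, seed = 1)
#' var(d$pheno$M)   # approx gMM + eMM = 3 for large n
#' @export
simulate_dataset <- function(params, n, m, seed = NULL) {
  stopifnot(inherits(params, "sem_params"), n >= 2, m >= 1)
  rng_with_seed(seed, {
    geno <- sim_genotypes(n, m)
    Z <- standardize_dosages(geno)
    pheno <- simulate_phenotypes_z(Z, params, fid = geno$fid, iid = geno$iid)
    list(geno = geno, pheno = pheno)
  })
}

#' Run replicated verification scenarios
#'
#' For each replicate a fresh genotype panel is simulated and its GRM
#' eigendecomposition computed once; phenotypes for every requested
#' scenario are then drawn on that shared panel and the bivariate GREML
#' model is fitted per scenario. Sharing the panel across scenarios cuts
#' the dominant cost (the n x n eigendecomposition) without coupling the
#' phenotype draws.
#'
#' @param scenarios character vector of scenario names (see
#'   [scenario_params()]) or a named list of [sem_params()].
#' @param n_runs number of replicates.
#' @param n,m individuals and SNPs per replicate.
#' @param seed master seed; per-replicate and per-scenario seeds are
#'   derived from it.
#' @param lrt run the likelihood-ratio test for the indirect effect in
#'   each replicate (three fits instead of one)?
#' @param se compute delta-method standard errors (needs the observed
#'   information; modest extra cost)?
#' @param progress print a dot per replicate?
#' @return object of class \code{"magreml_sim"}: a data frame with one row
#'   per (scenario, run) -- estimates, standard errors, heritabilities,
#'   LRT results, convergence -- with the run conditions in attributes.
#' @seealso [run_scenario()], [summary.magreml_sim()], [plot.magreml_sim()]
#' @export
replicate_study <- function(scenarios = "Baseline", n_runs = 10, n = 2000,
                            m = 2500, seed = 1, lrt = TRUE, se = TRUE,
                            progress = FALSE) {
  if (is.character(scenarios)) {
    scen <- lapply(scenarios, scenario_params)
    names(scen) <- scenarios
  } else {
    scen <- scenarios
    if (is.null(names(scen))) names(scen) <- paste0("S", seq_along(scen))
  }
  geno_seeds <- rng_with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_runs))
  rows <- vector("list", n_runs * length(scen))
  k <- 0L
  for (r in seq_len(n_runs)) {
    geno <- sim_genotypes(n, m, seed = geno_seeds[r])
    Z <- standardize_dosages(geno)
    A <- tcrossprod(Z) / ncol(Z)
    A <- (A + t(A)) / 2
    eig <- eigen(A, symmetric = TRUE)
    for (s in seq_along(scen)) {
      k <- k + 1L
      ps <- (geno_seeds[r] + 7919 * s) %% (.Machine$integer.max - 1L) + 1L
      pheno <- simulate_phenotypes_z(Z, scen[[s]], seed = ps,
                                     fid = geno$fid, iid = geno$iid)
      dat <- reml_data_precomp(A, eig, pheno$M, pheno$Y,
                               ids = paste(geno$fid, geno$iid, sep = ":"))
      rows[[k]] <- one_replicate(dat, name = names(scen)[s], run = r,
                                 lrt = lrt, se = se, seed = ps + 1L)
    }
    if (progress) {
      cat("."); if (r %% 50 == 0) cat(" ", r, "\n"); utils::flush.console()
    }
  }
  if (progress) cat("\n")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("magreml_sim", "data.frame"),
            conditions = list(n = n, m = m, n_runs = n_runs, seed = seed,
                              scenarios = names(scen)))
}

# reml_data from a precomputed GRM eigendecomposition (complete data,
# intercept-only fixed effects)
reml_data_precomp <- function(A, eig, M, Y, ids) {
  n <- length(M)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  structure(list(ids = ids, M = M, Y = Y, X = X, A = A, n = n, p = 1L,
                 complete = TRUE, n_used = c(M = n, Y = n),
                 d = eig$values,
                 Mr = drop(crossprod(eig$vectors, M)),
                 Yr = drop(crossprod(eig$vectors, Y)),
                 Xr = crossprod(eig$vectors, X)),
            class = "reml_data")
}

one_replicate <- function(dat, name, run, lrt, se, seed) {
  out <- data.frame(scenario = name, run = run, ok = FALSE,
                    b = NA_real_, indirect = NA_real_, direct = NA_real_,
                    cross = NA_real_, se_b = NA_real_,
                    se_indirect = NA_real_, se_direct = NA_real_,
                    h2_M = NA_real_, h2_Y = NA_real_,
                    gMM = NA_real_, gMY = NA_real_, gYY = NA_real_,
                    eMM = NA_real_, eMY = NA_real_, eYY = NA_real_,
                    lrt_p = NA_real_, lrt_df = NA_integer_,
                    lrt_stat = NA_real_, active = NA_character_,
                    converged = NA, stringsAsFactors = FALSE)
  res <- tryCatch({
    fit <- reml_fit(dat, se = se, seed = seed)
    med <- suppressMessages(mediation_effects(fit))
    out$ok <- TRUE
    out$b <- med$estimates["b"]
    out$indirect <- med$estimates["indirect"]
    out$direct <- med$estimates["direct"]
    out$cross <- med$estimates["cross"]
    out$se_b <- med$se["b"]
    out$se_indirect <- med$se["indirect"]
    out$se_direct <- med$se["direct"]
    out$h2_M <- heritability(fit, "M")["h2"]
    out$h2_Y <- heritability(fit, "Y")["h2"]
    out[c("gMM", "gMY", "gYY", "eMM", "eMY", "eYY")] <- as.list(coef(fit))
    out$converged <- fit$converged
    if (lrt) {
      lr <- lrt_indirect(dat, fit_full = fit, seed = seed)
      out$lrt_p <- lr$p_value
      out$lrt_df <- lr$df
      out$lrt_stat <- lr$statistic
      out$active <- lr$active_space
      out$converged <- out$converged && lr$converged
    }
    out
  }, error = function(e) {
    out$active <- conditionMessage(e)
    out
  })
  res
}

#' Run one named verification scenario
#'
#' Thin wrapper around [replicate_study()] for a single scenario.
#'
#' @param name scenario name, see [scenario_params()].
#' @param n_runs,n,m,seed,lrt,se,progress see [replicate_study()].
#' @return a \code{"magreml_sim"} object.
#' @export
run_scenario <- function(name = "Baseline", n_runs = 100, n = 2000, m = 2500,
                         seed = 1, lrt = TRUE, se = TRUE, progress = FALSE) {
  replicate_study(name, n_runs = n_runs, n = n, m = m, seed = seed,
                  lrt = lrt, se = se, progress = progress)
}

#' Summarize a replicated simulation study
#'
#' Per-scenario means of the estimates with their across-run mean standard
#' errors (the usual verification-table layout), Monte-Carlo standard
#' errors of the means, and failure counts.
#'
#' @param object a \code{"magreml_sim"} object.
#' @param ... unused.
#' @return data frame, one row per scenario.
#' @export
summary.magreml_sim <- function(object, ...) {
  sp <- split(as.data.frame(object), object$scenario)
  cond <- attr(object, "conditions")
  rows <- lapply(sp, function(d) {
    ok <- d[d$ok & !is.na(d$b), , drop = FALSE]
    nr <- nrow(ok)
    mcse <- function(x) stats::sd(x) / sqrt(length(x))
    data.frame(scenario = d$scenario[1], n_runs = nrow(d), n_ok = nr,
               mean_b = mean(ok$b), mean_se_b = mean(ok$se_b),
               mcse_b = mcse(ok$b),
               mean_indirect = mean(ok$indirect),
               mean_se_indirect = mean(ok$se_indirect),
               mcse_indirect = mcse(ok$indirect),
               mean_direct = mean(ok$direct),
               mean_se_direct = mean(ok$se_direct),
               mcse_direct = mcse(ok$direct),
               reject_05 = if (all(is.na(ok$lrt_p))) NA_real_
                           else mean(ok$lrt_p < 0.05, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- match(cond$scenarios, out$scenario)
  out[ord[!is.na(ord)], , drop = FALSE]
}

#' QQ data for likelihood-ratio test p-values
#'
#' Sorted observed p-values against uniform quantiles, per scenario; the
#' raw material for calibration QQ plots.
#'
#' @param x a \code{"magreml_sim"} object with LRT results.
#' @param scenario optional scenario name; defaults to all.
#' @return data frame with \code{scenario}, \code{expected},
#'   \code{observed}.
#' @export
qq_data <- function(x, scenario = NULL) {
  d <- as.data.frame(x)
  if (!is.null(scenario)) d <- d[d$scenario %in% scenario, , drop = FALSE]
  d <- d[!is.na(d$lrt_p), , drop = FALSE]
  sp <- split(d, d$scenario)
  out <- lapply(sp, function(g) {
    k <- nrow(g)
    data.frame(scenario = g$scenario[1],
               expected = stats::ppoints(k),
               observed = sort(g$lrt_p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' QQ plot of LRT p-values across replicates
#'
#' @param x a \code{"magreml_sim"} object.
#' @param scenario optional scenario subset.
#' @param ... passed to \code{plot}.
#' @export
plot.magreml_sim <- function(x, scenario = NULL, ...) {
  q <- qq_data(x, scenario)
  if (nrow(q) == 0) stop("no LRT p-values to plot")
  scen <- unique(q$scenario)
  cols <- seq_along(scen)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "expected p (uniform)", ylab = "observed p", ...)
  graphics::abline(0, 1, col = "grey60")
  for (i in seq_along(scen)) {
    g <- q[q$scenario == scen[i], ]
    graphics::points(g$expected, g$observed, pch = 16, cex = 0.6,
                     col = cols[i])
  }
  if (length(scen) > 1)
    graphics::legend("topleft", legend = scen, col = cols, pch = 16,
                     bty = "n")
  invisible(q)
}

#' Read a scenario specification from a text config file
#'
#' Plain \code{key: value} lines; recognized keys: \code{name},
#' \code{ag2}, \code{b}, \code{c2}, \code{f}, \code{e}, \code{split},
#' \code{n}, \code{m}, \code{runs}, \code{seed}. A \code{name} entry takes
#' the coefficient pattern from [scenario_params()]; explicit coefficient
#' keys override it.
#'
#' @param path config file path.
#' @return list with \code{params} (a [sem_params()]) and the run sizes.
#' @export
read_scenario_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "[:=][[:space:]]*")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = " ")), "")
  getn <- function(k, default) if (k %in% keys) as.numeric(vals[keys == k][1]) else default
  split <- getn("split", 0.5)
  if ("name" %in% keys) {
    par <- scenario_params(vals[keys == "name"][1], split = split)
  } else {
    par <- sem_params()
  }
  ag2 <- getn("ag2", par$a^2 + par$g^2)
  c2 <- getn("c2", par$c^2)
  par <- sem_params(a = sqrt(ag2 * split), g = sqrt(ag2 * (1 - split)),
                    f = getn("f", par$f), b = getn("b", par$b),
                    c = sqrt(c2), e = getn("e", par$e))
  list(params = par,
       n = as.integer(getn("n", 2000)), m = as.integer(getn("m", 2500)),
       n_runs = as.integer(getn("runs", 100)),
       seed = as.integer(getn("seed", 1)))
}
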