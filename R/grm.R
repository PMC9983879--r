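#' Genomic relatedness matrix (GRM)
#'
#' @description
#' The GRM models the covariance of the latent additive-genetic factor
#' between individuals. Under the equal-variance-per-SNP heritability model
#' its (j, k) entry is
#' \deqn{A_{jk} = \frac{1}{m} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)},}
#' the average cross-product of standardized dosages over the \eqn{m} SNPs
#' non-missing for both members of the pair.
#'
#' \code{compute_grm} excludes monomorphic SNPs (allele frequency 0 or 1),
#' whose standardized dosage is undefined. Missing dosages contribute
#' nothing to a pair's sum and, with \code{per_pair = TRUE} (the default,
#' matching GCTA's \code{.grm.N.bin} semantics), decrement that pair's SNP
#' count; \code{per_pair = FALSE} divides every pair by the global SNP
#' count instead.
#'
#' @param geno a [genotype_matrix()] with at least one polymorphic SNP.
#' @param per_pair divide each pair by its own non-missing SNP count?
#' @return an object of class \code{"grm"}: list with \code{values}
#'   (symmetric n x n matrix), \code{fid}, \code{iid}, and \code{n_snps}
#'   (integer matrix of per-pair SNP counts).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2), 2, 1), iid = c("a", "b"),
#'                      allele_freq = 0.5)
#' compute_grm(g)$values       # [[2, -2], [-2, 2]]
#' @export
compute_grm <- function(geno, per_pair = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- geno$allele_freq
  poly <- which(p > 0 & p < 1)
  if (length(poly) == 0L) stop("no polymorphic SNPs")
  X <- geno$dosages[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(X)
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(Z)
  if (all(obs)) {
    N <- matrix(ncol(Z), n, n)
    A <- tcrossprod(Z) / ncol(Z)
  } else {
    Z0 <- Z
    Z0[!obs] <- 0
    N <- tcrossprod(obs * 1)          # non-missing SNPs per pair
    S <- tcrossprod(Z0)
    denom <- if (per_pair) pmax(N, 1) else ncol(Z)
    A <- S / denom
  }
  A <- (A + t(A)) / 2                  # enforce exact symmetry
  new_grm(A, geno$fid, geno$iid, n_snps = N)
}

new_grm <- function(values, fid, iid, n_snps = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), nrow(values) == length(iid))
  ids <- paste(fid, iid, sep = ":")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, fid = as.character(fid),
                 iid = as.character(iid), n_snps = n_snps),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat("GRM:", n, "individuals\n")
  cat(sprintf("  diagonal mean %.4f; off-diagonal mean %.2e, var %.2e\n",
              mean(diag(x$values)), mean(off), stats::var(off)))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$values)

grm_keep <- function(grm, keep) {
  new_grm(grm$values[keep, keep, drop = FALSE], grm$fid[keep], grm$iid[keep],
          n_snps = if (!is.null(grm$n_snps)) grm$n_snps[keep, keep, drop = FALSE])
}

#' Prune a GRM to approximately unrelated individuals
#'
#' Greedy removal: while any off-diagonal entry exceeds \code{threshold},
#' drop the individual involved in the largest number of above-threshold
#' pairs. Ties are broken in favour of removing the individual with more
#' missing phenotypes (if \code{n_missing} is given), then the one with the
#' larger sample index. On graphs where one individual links many otherwise
#' unrelated ones, this keeps the maximal unrelated set. The default cutoff
#' of 0.025 is the conventional relatedness bound for GREML samples of
#' nominally unrelated individuals.
#'
#' @param grm a [compute_grm()] result (or GRM read from disk).
#' @param threshold positive relatedness cutoff; default 0.025.
#' @param n_missing optional integer vector (one per individual): number of
#'   missing phenotypes, used for tie-breaking.
#' @return list with \code{grm} (pruned) and \code{removed_ids} (character
#'   vector \code{"FID:IID"} in removal order).
#' @export
prune_related <- function(grm, threshold = 0.025, n_missing = NULL) {
  stopifnot(inherits(grm, "grm"), threshold > 0)
  n <- nrow(grm$values)
  if (is.null(n_missing)) n_missing <- integer(n)
  adj <- abs(grm$values) > threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  removed <- integer(0)
  deg <- rowSums(adj)
  while (any(deg > 0)) {
    cand <- which(deg == max(deg))
    if (length(cand) > 1L) {
      cand <- cand[n_missing[cand] == max(n_missing[cand])]
      cand <- max(cand)
    }
    alive[cand] <- FALSE
    removed <- c(removed, cand)
    deg <- deg - adj[, cand]
    deg[cand] <- 0L
    adj[cand, ] <- FALSE
    adj[, cand] <- FALSE
  }
  ids <- paste(grm$fid, grm$iid, sep = ":")
  list(grm = grm_keep(grm, alive), removed_ids = ids[removed])
}

#' Principal components of a GRM
#'
#' Leading eigenvectors of the relatedness matrix, commonly included as
#' fixed-effect covariates to absorb population stratification. Columns are
#' unit-norm eigenvectors for the k largest eigenvalues, with a fixed sign
#' convention (the entry of largest magnitude in each column is positive)
#' so results are reproducible across platforms.
#'
#' @param grm a GRM object.
#' @param k number of components, \code{1 <= k < n}.
#' @return n x k matrix with rownames \code{"FID:IID"} and columns
#'   \code{PC1..PCk}; eigenvalues in attribute \code{"values"}.
#' @export
grm_pcs <- function(grm, k = 20) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  e <- eigen(grm$values, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  dimnames(U) <- list(rownames(grm$values), paste0("PC", seq_len(k)))
  attr(U, "values") <- e$values[seq_len(k)]
  U
}

#' Read and write GRMs in GCTA binary format
#'
#' @description
#' The GCTA triplet \code{prefix.grm.bin} (lower triangle, row-wise,
#' diagonal included, little-endian float32), \code{prefix.grm.N.bin}
#' (per-pair SNP counts, same layout, float32) and \code{prefix.grm.id}
#' (tab-separated FID IID) is the de-facto interchange format for
#' relatedness matrices. Round-tripping preserves IDs exactly and values to
#' float32 precision.
#'
#' @param prefix path prefix (files \code{<prefix>.grm.bin} etc.).
#' @param grm GRM object to write.
#' @return \code{read_grm_gcta}: a GRM object. \code{write_grm_gcta}:
#'   \code{prefix}, invisibly.
#' @export
read_grm_gcta <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  if (!file.exists(idf)) stop("missing ", idf)
  if (!file.exists(binf)) stop("missing ", binf)
  ids <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(ids)
  ntri <- n * (n + 1) / 2
  nval <- file.size(binf) / 4
  if (nval != ntri)
    stop(sprintf(
      "GRM size mismatch: %d IDs imply %d triangle values but %s holds %d",
      n, ntri, binf, nval))
  con <- file(binf, "rb"); on.exit(close(con))
  vals <- readBin(con, "numeric", n = ntri, size = 4, endian = "little")
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals   # column-wise upper == row-wise lower
  A <- A + t(A) - diag(diag(A))
  N <- NULL
  nf <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nf)) {
    con2 <- file(nf, "rb"); on.exit(close(con2), add = TRUE)
    nvals <- readBin(con2, "numeric", n = ntri, size = 4, endian = "little")
    N <- matrix(0, n, n)
    N[upper.tri(N, diag = TRUE)] <- nvals
    N <- N + t(N) - diag(diag(N))
  }
  new_grm(A, ids[[1]], ids[[2]], n_snps = N)
}

#' @rdname read_grm_gcta
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  tri <- grm$values[upper.tri(grm$values, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4, endian = "little")
  close(con)
  N <- grm$n_snps
  if (is.null(N)) N <- matrix(1, n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(N[upper.tri(N, diag = TRUE)]), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$fid, grm$iid),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
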