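#' Genotype dosage matrix
#'
#' Container for an individuals-by-SNPs matrix of allele dosages (0, 1 or 2
#' copies of the counted allele; \code{NA} for missing calls), together with
#' sample identifiers (family ID + individual ID, the usual PLINK/GCTA
#' convention) and per-SNP allele frequencies.
#'
#' Allele frequencies default to the frequencies observed in the sample
#' (missing dosages are ignored when computing them). Supplying external
#' frequencies is useful when the analysis sample is a subset of a larger
#' reference panel.
#'
#' @param dosages numeric matrix, n individuals x m SNPs, entries in
#'   \{0, 1, 2\} or \code{NA}.
#' @param fid,iid character vectors of family and individual IDs; the pair
#'   must be unique per row. If \code{fid} is omitted it defaults to
#'   \code{iid}.
#' @param snp_ids character vector of SNP identifiers (unique).
#' @param allele_freq optional numeric vector of counted-allele frequencies
#'   in (0, 1); computed from \code{dosages} when \code{NULL}.
#' @return an object of class \code{"genotype_matrix"}: a list with elements
#'   \code{dosages}, \code{fid}, \code{iid}, \code{snp_ids},
#'   \code{allele_freq}.
#' @seealso [compute_grm()], [read_genotypes()]
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2, 1, 1), 2, 2), iid = c("a", "b"))
#' g$allele_freq
#' @export
genotype_matrix <- function(dosages, fid = NULL, iid = NULL, snp_ids = NULL,
                            allele_freq = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(iid)) iid <- if (!is.null(rownames(dosages))) rownames(dosages) else as.character(seq_len(n))
  if (is.null(fid)) fid <- iid
  fid <- as.character(fid); iid <- as.character(iid)
  if (length(fid) != n || length(iid) != n)
    stop("fid/iid length must equal nrow(dosages)")
  if (anyDuplicated(paste(fid, iid)))
    stop("duplicated (FID, IID) pairs")
  if (is.null(snp_ids)) snp_ids <- if (!is.null(colnames(dosages))) colnames(dosages) else paste0("snp", seq_len(m))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != m) stop("snp_ids length must equal ncol(dosages)")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && any(bad != 0 & bad != 1 & bad != 2))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(allele_freq)) {
    allele_freq <- colMeans(dosages, na.rm = TRUE) / 2
  } else {
    if (length(allele_freq) != m) stop("allele_freq length must equal number of SNPs")
  }
  structure(list(dosages = dosages, fid = fid, iid = iid,
                 snp_ids = snp_ids, allele_freq = as.numeric(allele_freq)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$iid), "individuals x",
      length(x$snp_ids), "SNPs\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat("  missing dosages:", nmiss, "\n")
  poly <- sum(x$allele_freq > 0 & x$allele_freq < 1)
  cat("  polymorphic SNPs:", poly, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotype dosages from a delimited text file
#'
#' Expected layout: a header row \code{FID IID snp1 snp2 ...}, then one row
#' per individual with dosages in \{0, 1, 2\} and \code{NA} for missing.
#' Whitespace, comma and tab delimiters are auto-detected.
#'
#' @param path file path.
#' @param allele_freq optional externally supplied allele frequencies.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, allele_freq = NULL) {
  tab <- read_idtable(path)
  if (ncol(tab) < 3) stop("genotype file needs FID, IID and at least one SNP column")
  dos <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_matrix(dos, fid = tab[[1]], iid = tab[[2]],
                  snp_ids = colnames(tab)[-(1:2)], allele_freq = allele_freq)
}

#' Filter SNPs by minor allele frequency and missingness
#'
#' Quality-control thresholds are study-specific, so nothing is filtered by
#' default beyond monomorphic SNPs being dropped at GRM construction time.
#'
#' @param geno a [genotype_matrix()].
#' @param min_maf minimum minor allele frequency (inclusive); 0 keeps all
#'   polymorphic SNPs.
#' @param max_missing maximum fraction of missing calls per SNP.
#' @return a filtered [genotype_matrix()] (allele frequencies preserved for
#'   retained SNPs).
#' @export
filter_snps <- function(geno, min_maf = 0, max_missing = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- geno$allele_freq
  maf <- pmin(p, 1 - p)
  missfrac <- colMeans(is.na(geno$dosages))
  keep <- maf >= min_maf & maf > 0 & missfrac <= max_missing
  genotype_matrix(geno$dosages[, keep, drop = FALSE], fid = geno$fid,
                  iid = geno$iid, snp_ids = geno$snp_ids[keep],
                  allele_freq = p[keep])
}

# Shared reader for (FID, IID, value...) tables; sniffs the delimiter from
# the header line.
read_idtable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl(",", hdr)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "na", "-9"))
  names(tab)[1:2] <- c("FID", "IID")
  tab$FID <- as.character(tab$FID)
  tab$IID <- as.character(tab$IID)
  tab
}
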