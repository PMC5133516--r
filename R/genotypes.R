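#' Construct a genotype matrix object
#'
#' The central genotype container: diploid calls for a set of individuals at
#' ordered variant sites. Calls are coded `0` (homozygous reference), `1`
#' (heterozygous), `2` (homozygous alternate) and `NA` (missing).
#'
#' @param calls Integer matrix, individuals in rows and sites in columns,
#'   values in `{0, 1, 2, NA}`. Row names are individual IDs.
#' @param sites `data.frame` with one row per site and columns `chrom`, `pos`
#'   (1-based bp) and optionally `ref`, `alt`. Within each chromosome,
#'   positions must be strictly increasing.
#' @param individuals `data.frame` with columns `id` and optionally `pedigree`.
#'   Defaults to the row names of `calls` with no pedigree labels.
#' @return An object of class `hd_genotypes` with elements `calls`, `sites`
#'   and `individuals`.
#' @export
hd_genotypes <- function(calls, sites, individuals = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("genotype calls must be 0 (hom ref), 1 (het), 2 (hom alt) or NA")
  }
  sites <- as.data.frame(sites)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    stop("`sites` needs columns `chrom` and `pos`")
  }
  if (nrow(sites) != ncol(calls)) {
    stop("number of site rows (", nrow(sites), ") does not match number of ",
         "call columns (", ncol(calls), ")")
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  check_sorted_sites(sites)
  if (is.null(individuals)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(calls)))
    individuals <- data.frame(id = ids, pedigree = NA_character_,
                              stringsAsFactors = FALSE)
  }
  individuals <- as.data.frame(individuals)
  if (!"id" %in% names(individuals)) stop("`individuals` needs an `id` column")
  if (nrow(individuals) != nrow(calls)) {
    stop("number of individuals does not match number of call rows")
  }
  if (!"pedigree" %in% names(individuals)) {
    individuals$pedigree <- NA_character_
  }
  rownames(calls) <- individuals$id
  structure(list(calls = calls, sites = sites, individuals = individuals),
            class = "hd_genotypes")
}

check_sorted_sites <- function(sites) {
  for (chr in unique(sites$chrom)) {
    pos <- sites$pos[sites$chrom == chr]
    bad <- which(diff(pos) <= 0)
    if (length(bad)) {
      stop("sites on chromosome ", chr, " are not strictly increasing in ",
           "position: violation at position ", pos[bad[1] + 1],
           " (record ", bad[1] + 1, " of that chromosome)")
    }
  }
  invisible(TRUE)
}

#' @method print hd_genotypes
#' @export
print.hd_genotypes <- function(x, ...) {
  cat("hd_genotypes:", nrow(x$calls), "individuals x", ncol(x$calls),
      "sites on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  n_ped <- length(unique(x$individuals$pedigree[!is.na(x$individuals$pedigree)]))
  if (n_ped > 0) cat("  pedigrees:", n_ped, "\n")
  invisible(x)
}

#' @method dim hd_genotypes
#' @export
dim.hd_genotypes <- function(x) dim(x$calls)

#' Per-site minor allele frequency
#'
#' Counts alternate alleles among non-missing calls at each site and returns
#' `min(f, 1 - f)` where `f` is the alternate-allele frequency. Sites where
#' every call is missing get `NA` and are excluded from locus weighting
#' downstream.
#'
#' @param g An [hd_genotypes] object.
#' @return Numeric vector of per-site MAF values in `[0, 0.5]` (`NA` where
#'   undefined).
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "hd_genotypes"))
  alt <- colSums(g$calls, na.rm = TRUE)
  n <- colSums(!is.na(g$calls))
  f <- ifelse(n > 0, alt / (2 * n), NA_real_)
  pmin(f, 1 - f)
}

#' Per-site alternate allele frequency
#'
#' Unfolded counterpart of [compute_maf()]; used to pick the major allele when
#' simulated heterozygotes are replaced by homozygotes.
#' @inheritParams compute_maf
#' @return Numeric vector of alternate-allele frequencies (`NA` where all
#'   calls are missing).
#' @export
alt_allele_freq <- function(g) {
  stopifnot(inherits(g, "hd_genotypes"))
  alt <- colSums(g$calls, na.rm = TRUE)
  n <- colSums(!is.na(g$calls))
  ifelse(n > 0, alt / (2 * n), NA_real_)
}

#' Homozygosity indicator matrix
#'
#' Maps each genotype call to the indicator used by the local polynomial
#' model: 1 for a homozygote (reference or alternate), 0 for a heterozygote,
#' `NA` for a missing call.
#'
#' @param g An [hd_genotypes] object.
#' @return Integer matrix with the same dimensions and dimnames as the call
#'   matrix, values in `{0, 1, NA}`, of class `hd_indicators`.
#' @export
homozygosity_indicator <- function(g) {
  stopifnot(inherits(g, "hd_genotypes"))
  ind <- ifelse(is.na(g$calls), NA_integer_, as.integer(g$calls != 1L))
  dim(ind) <- dim(g$calls)
  dimnames(ind) <- dimnames(g$calls)
  class(ind) <- c("hd_indicators", class(ind))
  ind
}
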