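#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file (plain or gzipped) and converts diploid GT calls to
#' the package's coded genotype matrix. Multiallelic records are split into
#' one biallelic site per alternate allele; a genotype carrying an allele not
#' represented at a split site becomes missing there, which keeps the per-site
#' MAF well defined. Split sites after the first are shifted by +1 bp so site
#' positions remain strictly increasing; an error is raised if the shift would
#' collide with the next record.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @return An [hd_genotypes] object with sites sorted by position within each
#'   chromosome.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    stop("VCF records without a GT FORMAT field are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    bad <- which(diff(p) <= 0)
    if (length(bad)) {
      stop("VCF records on chromosome ", chr, " are not sorted by position: ",
           "violation at position ", p[bad[1] + 1])
    }
  }
  samples <- colnames(gt)
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]

  site_chrom <- character(0); site_pos <- numeric(0)
  site_ref <- character(0); site_alt <- character(0)
  call_cols <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(alt_field[r], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(sub(":.*", "", gt[r, ]), "[/|]")
    for (a in seq_along(alts)) {
      codes <- vapply(alleles, function(al) {
        if (length(al) != 2 || any(al == ".")) return(NA_integer_)
        al <- suppressWarnings(as.integer(al))
        if (any(is.na(al)) || !all(al %in% c(0L, a))) return(NA_integer_)
        sum(al == a)
      }, integer(1))
      p <- pos[r] + (a - 1)
      if (a > 1 && r < nrow(fix) &&
          chrom[r + 1] == chrom[r] && p >= pos[r + 1]) {
        stop("cannot split multiallelic record at ", chrom[r], ":", pos[r],
             " without colliding with the next record")
      }
      site_chrom <- c(site_chrom, chrom[r]); site_pos <- c(site_pos, p)
      site_ref <- c(site_ref, ref[r]); site_alt <- c(site_alt, alts[a])
      call_cols[[length(call_cols) + 1L]] <- codes
    }
  }
  calls <- do.call(cbind, call_cols)
  rownames(calls) <- samples
  hd_genotypes(calls,
               data.frame(chrom = site_chrom, pos = site_pos, ref = site_ref,
                          alt = site_alt, stringsAsFactors = FALSE))
}

#' Read genotypes from the sites-by-individuals CSV dialect
#'
#' The dialect has one row per site and one column per individual. The first
#' four columns are `chrom`, `pos`, `ref`, `alt`; the header row carries
#' individual IDs. Cells are either an unordered allele pair spelled with the
#' ref/alt bases (e.g. `"AA"`, `"AG"`, `"GG"`), a dosage code `0`/`1`/`2`
#' counting alternate alleles, or `NA`/`""`/`"NN"` for missing. Gzipped files
#' are read transparently.
#'
#' @param path Path to the CSV file.
#' @param pedigrees Optional named vector mapping individual ID to pedigree.
#' @return An [hd_genotypes] object.
#' @export
read_genotype_csv <- function(path, pedigrees = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)[1:4])) {
    stop("genotype CSV must start with columns chrom, pos, ref, alt")
  }
  ids <- names(tab)[-(1:4)]
  if (length(ids) == 0) stop("genotype CSV has no individual columns")
  m <- nrow(tab)
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = m,
                  dimnames = list(ids, NULL))
  for (i in seq_len(m)) {
    ref <- tab$ref[i]; alt <- tab$alt[i]
    hom_ref <- paste0(ref, ref); hom_alt <- paste0(alt, alt)
    het <- c(paste0(ref, alt), paste0(alt, ref))
    for (j in seq_along(ids)) {
      cell <- tab[[ids[j]]][i]
      code <- if (is.na(cell) || cell %in% c("", "NN", ".")) {
        NA_integer_
      } else if (cell %in% c("0", "1", "2")) {
        as.integer(cell)
      } else if (cell == hom_ref) 0L else if (cell %in% het) 1L
        else if (cell == hom_alt) 2L else {
        stop("malformed genotype cell \"", cell, "\" at row ", i,
             " (site ", tab$chrom[i], ":", tab$pos[i], "), column ", ids[j])
      }
      calls[j, i] <- code
    }
  }
  individuals <- data.frame(id = ids, pedigree = NA_character_,
                            stringsAsFactors = FALSE)
  if (!is.null(pedigrees)) {
    individuals$pedigree <- as.character(pedigrees[ids])
  }
  hd_genotypes(calls,
               data.frame(chrom = tab$chrom, pos = as.numeric(tab$pos),
                          ref = tab$ref, alt = tab$alt,
                          stringsAsFactors = FALSE),
               individuals)
}

#' Write genotypes in the sites-by-individuals CSV dialect
#'
#' Inverse of [read_genotype_csv()]: emits allele-pair cells (`NN` for
#' missing). Sites without recorded ref/alt bases are written as `A`/`G`.
#'
#' @param g An [hd_genotypes] object.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(g, path) {
  stopifnot(inherits(g, "hd_genotypes"))
  ref <- if ("ref" %in% names(g$sites)) g$sites$ref else rep("A", ncol(g$calls))
  alt <- if ("alt" %in% names(g$sites)) g$sites$alt else rep("G", ncol(g$calls))
  cells <- matrix("NN", nrow = ncol(g$calls), ncol = nrow(g$calls))
  for (i in seq_len(ncol(g$calls))) {
    map <- c(paste0(ref[i], ref[i]), paste0(ref[i], alt[i]),
             paste0(alt[i], alt[i]))
    v <- g$calls[, i]
    cells[i, !is.na(v)] <- map[v[!is.na(v)] + 1L]
  }
  out <- data.frame(chrom = g$sites$chrom, pos = g$sites$pos,
                    ref = ref, alt = alt, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-(1:4)] <- g$individuals$id
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects named columns `ID`, `PED`, `AGE`, `SEX`, `DBP`, `SBP`, `MED`
#' (case-insensitive). Sex may be coded 0/1 or `F`/`M` (mapped to 0/1);
#' the medication flag 0/1 or yes/no.
#'
#' @param path Path to the phenotype CSV.
#' @return A `data.frame` of class `hd_phenotypes` with columns `id`, `ped`,
#'   `age`, `sex`, `dbp`, `sbp`, `med` and an attribute `med_adjusted = FALSE`.
#' @export
read_phenotype_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("id", "ped", "age", "sex", "dbp", "sbp", "med")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab <- tab[need]
  if (is.character(tab$sex)) {
    tab$sex <- ifelse(toupper(tab$sex) %in% c("M", "MALE"), 1L,
                      ifelse(toupper(tab$sex) %in% c("F", "FEMALE"), 0L,
                             NA_integer_))
  }
  if (is.character(tab$med)) {
    tab$med <- as.integer(toupper(tab$med) %in% c("1", "Y", "YES", "TRUE"))
  }
  tab$id <- as.character(tab$id)
  as_hd_phenotypes(tab)
}

as_hd_phenotypes <- function(tab, med_adjusted = FALSE) {
  class(tab) <- c("hd_phenotypes", "data.frame")
  attr(tab, "med_adjusted") <- med_adjusted
  tab
}

#' Read an expression matrix
#'
#' First column is the transcript ID; remaining columns are individuals.
#'
#' @param path Path to the expression CSV.
#' @return Numeric matrix, transcripts in rows, individuals in columns.
#' @export
read_expression_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}
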