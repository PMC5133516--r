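# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files these helpers write to tempdir().

# Small genotype object with explicit calls (individuals x sites).
toy_genotypes <- function(calls, pos = NULL, chrom = "1", pedigree = NULL) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  }
  ind <- data.frame(id = rownames(calls),
                    pedigree = if (is.null(pedigree)) NA_character_ else
                      pedigree,
                    stringsAsFactors = FALSE)
  hd_genotypes(calls, data.frame(chrom = chrom, pos = pos), ind)
}

# Random genotype matrix in Hardy-Weinberg proportions, unrelated individuals.
random_genotypes <- function(n_ind, n_sites, seed = 1, maf_range = c(0.1, 0.5),
                             spacing = 1e5) {
  set.seed(seed)
  maf <- runif(n_sites, maf_range[1], maf_range[2])
  calls <- sapply(maf, function(f) rbinom(n_ind, 2, f))
  rownames(calls) <- paste0("ind", seq_len(n_ind))
  toy_genotypes(calls, pos = cumsum(rep(spacing, n_sites)))
}

# Profile object assembled directly from an intensity matrix.
toy_profile <- function(intensity, pos, chrom = "1") {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)) || any(rownames(intensity) == "")) {
    rownames(intensity) <- paste0("ind", seq_len(nrow(intensity)))
  }
  structure(list(intensity = intensity,
                 anchors = data.frame(chrom = chrom, pos = pos,
                                      stringsAsFactors = FALSE),
                 individuals = data.frame(id = rownames(intensity),
                                          stringsAsFactors = FALSE),
                 spec = window_spec()),
            class = "hd_profile")
}

# Minimal VCF written to a temp file.
write_toy_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# Independent brute-force weighted least squares for one window.
brute_force_wls <- function(dx, y, w, degree) {
  keep <- !is.na(y) & w > 0
  D <- outer(dx[keep], 0:degree, "^")
  solve(t(D) %*% diag(w[keep], nrow = sum(keep)) %*% D,
        t(D) %*% diag(w[keep], nrow = sum(keep)) %*% y[keep])
}

# Independent step-up BH adjustment.
brute_force_bh <- function(p) {
  keep <- !is.na(p)
  pk <- p[keep]
  m <- length(pk)
  o <- order(pk)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, pk[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  out <- rep(NA_real_, length(p))
  out[keep] <- pmin(adj, 1)
  out
}

# Phenotype table from scratch.
toy_phenotypes <- function(df) {
  hdscan:::as_hd_phenotypes(df)
}
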