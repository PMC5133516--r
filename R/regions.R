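#' Call sizable regions of homozygosity disequilibrium
#'
#' A region of HD for an individual is a maximal run of consecutive anchors
#' on one chromosome whose intensity is at or above `threshold`, spanning at
#' least `min_length_mb` megabases from the first to the last qualifying
#' anchor. Both cutoffs are inclusive. Anchors with missing intensity break
#' runs.
#'
#' @param profile An `hd_profile` from [estimate_profile()].
#' @param threshold Minimum intensity, default 0.9.
#' @param min_length_mb Minimum anchor-to-anchor span in Mb, default 5.
#' @return `data.frame` of class `hd_regions`: `individual`, `chrom`,
#'   `start_bp`, `end_bp`, `length_mb`, `mean_intensity`, `n_anchors`.
#' @export
call_hd_regions <- function(profile, threshold = 0.9, min_length_mb = 5.0) {
  stopifnot(inherits(profile, "hd_profile"))
  res <- list()
  ids <- rownames(profile$intensity)
  for (chr in unique(profile$anchors$chrom)) {
    sel <- which(profile$anchors$chrom == chr)
    pos <- profile$anchors$pos[sel]
    for (i in seq_along(ids)) {
      v <- profile$intensity[i, sel]
      qual <- !is.na(v) & v >= threshold
      r <- rle(qual)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        span_mb <- (pos[ends[j]] - pos[starts[j]]) / 1e6
        if (span_mb >= min_length_mb) {
          res[[length(res) + 1L]] <- data.frame(
            individual = ids[i], chrom = chr,
            start_bp = pos[starts[j]], end_bp = pos[ends[j]],
            length_mb = span_mb,
            mean_intensity = mean(v[starts[j]:ends[j]]),
            n_anchors = ends[j] - starts[j] + 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(individual = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               length_mb = numeric(0), mean_intensity = numeric(0),
               n_anchors = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("hd_regions", "data.frame")
  out
}

#' Summarize called HD regions over a cohort
#'
#' Reports the carrier fraction (individuals with at least one region), the
#' five-number summary (min, quartiles, max; type-7 quantiles) of region
#' lengths, and the same summary of per-individual total lengths.
#'
#' @param regions An `hd_regions` table from [call_hd_regions()].
#' @param n_individuals Cohort size the carrier fraction is relative to.
#' @return List with `n_individuals`, `n_regions`, `n_carriers`,
#'   `carrier_fraction`, `length_quantiles`, `total_length_quantiles` and
#'   `per_individual` (a `data.frame` of region counts and total Mb).
#' @export
summarize_regions <- function(regions, n_individuals) {
  stopifnot(inherits(regions, "data.frame"), n_individuals >= 1)
  probs <- c(0, 0.25, 0.5, 0.75, 1)
  if (nrow(regions) == 0) {
    return(list(n_individuals = n_individuals, n_regions = 0L,
                n_carriers = 0L, carrier_fraction = 0,
                length_quantiles = stats::setNames(rep(NA_real_, 5),
                  c("min", "q1", "median", "q3", "max")),
                total_length_quantiles = stats::setNames(rep(NA_real_, 5),
                  c("min", "q1", "median", "q3", "max")),
                per_individual = data.frame(individual = character(0),
                                            n_regions = integer(0),
                                            total_length_mb = numeric(0))))
  }
  totals <- tapply(regions$length_mb, regions$individual, sum)
  counts <- tapply(regions$length_mb, regions$individual, length)
  per_ind <- data.frame(individual = names(totals),
                        n_regions = as.integer(counts),
                        total_length_mb = as.numeric(totals),
                        stringsAsFactors = FALSE)
  qn <- function(x) stats::setNames(stats::quantile(x, probs, type = 7,
                                                    names = FALSE),
                                    c("min", "q1", "median", "q3", "max"))
  list(n_individuals = n_individuals, n_regions = nrow(regions),
       n_carriers = nrow(per_ind),
       carrier_fraction = nrow(per_ind) / n_individuals,
       length_quantiles = qn(regions$length_mb),
       total_length_quantiles = qn(per_ind$total_length_mb),
       per_individual = per_ind)
}

#' Write HD regions as BED
#'
#' BED uses 0-based half-open coordinates; internal coordinates are 1-based
#' inclusive, so `start_bp` is decremented by one. The individual ID goes in
#' the name column and the mean intensity in the score column.
#'
#' @param regions An `hd_regions` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start_bp - 1),
                    end = as.integer(regions$end_bp),
                    name = regions$individual,
                    score = round(regions$mean_intensity, 4))
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
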