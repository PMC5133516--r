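#' Sliding-window specification
#'
#' Windows are built by the nearest-neighbor method: each window, anchored at
#' a variant site, contains the `b_percent`% of the chromosome's sites closest
#' in physical distance to the anchor. The bandwidth `h` is set per window so
#' that every member lies strictly inside it.
#'
#' @param b_percent Percentage of a chromosome's sites per window. Default 5.
#' @param degree Polynomial order of the local fit (0-3). Default 1 (local
#'   linear), the usual bias/variance compromise for local polynomial
#'   regression.
#' @param anchor_stride Evaluate every `anchor_stride`-th site. Default 1
#'   (every site is an anchor).
#' @param clamp Clamp the fitted intensity into `[0, 1]`. Default `TRUE`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(b_percent = 5, degree = 1, anchor_stride = 1,
                        clamp = TRUE) {
  stopifnot(b_percent > 0, b_percent <= 100, degree >= 0, degree <= 3,
            anchor_stride >= 1)
  structure(list(b_percent = b_percent, degree = as.integer(degree),
                 anchor_stride = as.integer(anchor_stride),
                 clamp = isTRUE(clamp)),
            class = "window_spec")
}

#' Build nearest-neighbor windows along a chromosome
#'
#' For each anchor site, the window holds the `k = ceiling(b_percent/100 * m)`
#' sites nearest to the anchor in physical distance (ties broken toward the
#' lower position). Because positions are sorted, the members form a
#' contiguous index range. The bandwidth is `h = (1 + 1e-9) * d_(k)` where
#' `d_(k)` is the distance of the farthest member, so every member has
#' `|x_i - x| < h` and a strictly positive kernel weight.
#'
#' @param positions Strictly increasing numeric vector of site positions (bp).
#' @param spec A [window_spec].
#' @return `data.frame` with one row per anchor: `anchor` (site index), `lo`,
#'   `hi` (member index range) and `h` (bandwidth, bp).
#' @export
build_windows <- function(positions, spec = window_spec()) {
  m <- length(positions)
  if (m < 2) stop("need at least 2 sites to build windows")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  k <- ceiling(spec$b_percent / 100 * m)
  if (k > m) {
    stop("window size k = ", k, " exceeds the ", m, " sites on the ",
         "chromosome; supply more sites or a smaller b_percent")
  }
  anchors <- seq(1L, m, by = spec$anchor_stride)
  lo <- hi <- integer(length(anchors))
  h <- numeric(length(anchors))
  for (idx in seq_along(anchors)) {
    a <- anchors[idx]
    l <- r <- a
    while (r - l + 1L < k) {
      d_left <- if (l > 1L) positions[a] - positions[l - 1L] else Inf
      d_right <- if (r < m) positions[r + 1L] - positions[a] else Inf
      if (d_left <= d_right) l <- l - 1L else r <- r + 1L
    }
    lo[idx] <- l; hi[idx] <- r
    h[idx] <- (1 + 1e-9) * max(positions[a] - positions[l],
                               positions[r] - positions[a])
  }
  data.frame(anchor = anchors, lo = lo, hi = hi, h = h)
}

#' Cubic kernel weight
#'
#' `K(u) = (1 - |u|^3)^3` for `|u| < 1` and 0 otherwise: sites closer to the
#' anchor receive higher weight, reflecting the local correlation of
#' homozygosity along the chromosome.
#'
#' @param u Scaled distance `(x_i - x) / h`.
#' @return Weights in `[0, 1]`.
#' @export
kernel_weight <- function(u) {
  stopifnot(all(is.finite(u)))
  ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)
}

#' Rare-variant locus weight
#'
#' `L = 1` for MAF at or above 0.05 and `MAF/0.05` below it: common
#' homozygotes at rare sites carry little homozygosity information, so rare
#' sites are down-weighted in proportion to their MAF. An undefined MAF
#' (site with no non-missing calls) gets weight 0.
#'
#' @param maf Minor allele frequencies in `[0, 0.5]`; `NA` allowed.
#' @return Weights in `[0, 1]`.
#' @export
locus_weight <- function(maf) {
  bad <- !is.na(maf) & (maf < 0 | maf > 0.5)
  if (any(bad)) {
    stop("MAF outside [0, 0.5]: ", paste(utils::head(maf[bad], 3),
                                         collapse = ", "))
  }
  ifelse(is.na(maf), 0, ifelse(maf >= 0.05, 1, maf / 0.05))
}

#' Fit the double-weight local polynomial at one anchor
#'
#' Minimizes the weighted least squares criterion
#' `sum_i w_i (y_i - sum_j alpha_j dx_i^j)^2` over the polynomial
#' coefficients, where `w_i` combines the kernel and locus weights and
#' `dx_i = x_i - x` is the signed distance of member site `i` from the
#' anchor. The homozygosity intensity is the fitted value at the anchor,
#' `alpha_0`, clamped into `[0, 1]`. Member sites with a missing indicator
#' receive weight zero. If fewer than `degree + 1` members have positive
#' weight, or the design is singular, the fit falls back to degree 0 (the
#' weighted mean); if no member has positive weight the intensity is `NA`.
#'
#' @param dx Signed distances `x_i - x` of the member sites from the anchor.
#' @param y Homozygosity indicators (0/1/NA) at the member sites.
#' @param weights Nonnegative site weights (kernel x locus).
#' @param degree Polynomial order.
#' @param clamp Clamp `alpha_0` into `[0, 1]`.
#' @return List with `alpha` (coefficient vector of the degree actually
#'   used), `intensity`, `n_effective` and `degree_used`.
#' @export
fit_local_polynomial <- function(dx, y, weights, degree = 1, clamp = TRUE) {
  stopifnot(length(dx) == length(y), length(y) == length(weights),
            all(weights >= 0))
  w <- ifelse(is.na(y), 0, weights)
  y0 <- ifelse(is.na(y), 0, y)
  n_eff <- sum(w > 0)
  if (n_eff == 0) {
    return(list(alpha = NA_real_, intensity = NA_real_, n_effective = 0L,
                degree_used = NA_integer_))
  }
  deg <- as.integer(degree)
  alpha <- NULL
  while (deg > 0L) {
    if (n_eff < deg + 1L) { deg <- 0L; break }
    D <- outer(dx, 0:deg, "^")
    A <- crossprod(D, D * w)
    ok <- TRUE
    alpha <- tryCatch(solve(A, crossprod(D, w * y0)),
                      error = function(e) { ok <<- FALSE; NULL })
    if (ok && all(is.finite(alpha))) break
    deg <- 0L
  }
  if (deg == 0L) alpha <- sum(w * y0) / sum(w)
  a0 <- alpha[1]
  list(alpha = as.numeric(alpha),
       intensity = if (clamp) min(max(a0, 0), 1) else a0,
       n_effective = as.integer(n_eff), degree_used = deg)
}

#' Estimate homozygosity intensity profiles
#'
#' Runs the double-weight local polynomial fit at every anchor of every
#' chromosome for every individual. Within a window the kernel and locus
#' weights are shared across individuals, so individuals without missing
#' indicators in the window are solved in one matrix operation; individuals
#' with missing members are refit individually with those members at weight
#' zero.
#'
#' @param ind An `hd_indicators` matrix from [homozygosity_indicator()], or
#'   `NULL` to derive it from `g`.
#' @param g The [hd_genotypes] object (supplies positions and MAF).
#' @param spec A [window_spec].
#' @param maf Optional per-site MAF vector; computed from `g` by default.
#' @return An `hd_profile` object: `intensity` (individuals x anchors matrix,
#'   values in `[0, 1]` or `NA`), `anchors` (`data.frame` of `chrom`, `pos`),
#'   `individuals`, and the `spec` used.
#' @export
estimate_profile <- function(ind = NULL, g, spec = window_spec(),
                             maf = NULL) {
  stopifnot(inherits(g, "hd_genotypes"))
  if (is.null(ind)) ind <- homozygosity_indicator(g)
  stopifnot(ncol(ind) == nrow(g$sites))
  if (is.null(maf)) maf <- compute_maf(g)
  lw <- locus_weight(maf)
  n <- nrow(ind)
  chroms <- unique(g$sites$chrom)
  blocks <- vector("list", length(chroms))
  anchor_chrom <- list(); anchor_pos <- list()
  n_degenerate <- 0L
  for (ci in seq_along(chroms)) {
    on_chr <- which(g$sites$chrom == chroms[ci])
    pos <- g$sites$pos[on_chr]
    win <- build_windows(pos, spec)
    Y <- ind[, on_chr, drop = FALSE]
    lw_c <- lw[on_chr]
    out <- matrix(NA_real_, nrow = n, ncol = nrow(win))
    for (wi in seq_len(nrow(win))) {
      mem <- win$lo[wi]:win$hi[wi]
      dx <- pos[mem] - pos[win$anchor[wi]]
      h <- win$h[wi]
      kw <- if (h > 0) kernel_weight(dx / h) else as.numeric(dx == 0)
      w <- kw * lw_c[mem]
      Yw <- Y[, mem, drop = FALSE]
      has_na <- rowSums(is.na(Yw)) > 0L
      if (sum(w) <= 0) { n_degenerate <- n_degenerate + 1L; next }
      if (any(!has_na)) {
        cvec <- window_coefficients(dx, w, spec$degree)
        vals <- as.numeric(Yw[!has_na, , drop = FALSE] %*% cvec)
        if (spec$clamp) vals <- pmin(pmax(vals, 0), 1)
        out[!has_na, wi] <- vals
      }
      for (i in which(has_na)) {
        fit <- fit_local_polynomial(dx, Yw[i, ], w, spec$degree, spec$clamp)
        out[i, wi] <- fit$intensity
      }
    }
    blocks[[ci]] <- out
    anchor_chrom[[ci]] <- rep(chroms[ci], nrow(win))
    anchor_pos[[ci]] <- pos[win$anchor]
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " window(s) had zero total weight; ",
            "their intensities are NA")
  }
  intensity <- do.call(cbind, blocks)
  rownames(intensity) <- rownames(ind)
  structure(list(intensity = intensity,
                 anchors = data.frame(chrom = unlist(anchor_chrom),
                                      pos = unlist(anchor_pos),
                                      stringsAsFactors = FALSE),
                 individuals = g$individuals, spec = spec),
            class = "hd_profile")
}

# Weight vector c such that alpha_0 = c %*% y for the shared-weight window;
# falls back to degree 0 when the polynomial design is singular.
window_coefficients <- function(dx, w, degree) {
  deg <- degree
  while (deg > 0L) {
    if (sum(w > 0) < deg + 1L) { deg <- 0L; break }
    D <- outer(dx, 0:deg, "^")
    A <- crossprod(D, D * w)
    cmat <- tryCatch(solve(A, t(D * w)), error = function(e) NULL)
    if (!is.null(cmat) && all(is.finite(cmat))) return(cmat[1, ])
    deg <- 0L
  }
  w / sum(w)
}

#' @method print hd_profile
#' @export
print.hd_profile <- function(x, ...) {
  cat("hd_profile:", nrow(x$intensity), "individuals x", ncol(x$intensity),
      "anchors on", length(unique(x$anchors$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a profile as long-format TSV
#'
#' Columns: chrom, anchor_pos, individual, intensity.
#' @param profile An `hd_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "hd_profile"))
  n <- nrow(profile$intensity); m <- ncol(profile$intensity)
  out <- data.frame(
    chrom = rep(profile$anchors$chrom, each = n),
    anchor_pos = rep(profile$anchors$pos, each = n),
    individual = rep(rownames(profile$intensity), times = m),
    intensity = as.vector(profile$intensity))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
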