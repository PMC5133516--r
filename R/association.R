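#' Describe a response for the association scan
#'
#' Binds a response name to its link and transformation. DBP and SBP use the
#' identity link with log + winsorization; HTN uses the logit link; any other
#' name (a simulated trait, a transcript) defaults to an untransformed
#' identity-link response.
#'
#' @param name Response name, matched case-insensitively against a phenotype
#'   column.
#' @param link `"identity"` or `"logit"`; default chosen from `name`.
#' @param transform `"log_winsorize"` or `"none"`; default chosen from
#'   `name`.
#' @param winsor_q Winsorization tail probability when transforming.
#' @return A `response_spec` list.
#' @export
response_spec <- function(name, link = NULL, transform = NULL,
                          winsor_q = 0.01) {
  key <- toupper(name)
  if (is.null(link)) link <- if (key == "HTN") "logit" else "identity"
  if (is.null(transform)) {
    transform <- if (key %in% c("DBP", "SBP")) "log_winsorize" else "none"
  }
  link <- match.arg(link, c("identity", "logit"))
  transform <- match.arg(transform, c("none", "log_winsorize"))
  if (key == "HTN" && link != "logit") {
    stop("HTN is binary and must use the logit link")
  }
  structure(list(name = name, link = link, transform = transform,
                 winsor_q = winsor_q), class = "response_spec")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1. Missing p-values are
#' excluded from the number of tests and stay missing.
#'
#' @param p_values Numeric vector in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p_values) {
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Window-wise homozygosity association scan
#'
#' At each window anchor, fits the marginal model
#' `response ~ intercept + intensity + age + sex` with the response's link by
#' pedigree-clustered GEE ([gee_fit()], exchangeable working correlation,
#' robust sandwich covariance) and reports the Wald test of the intensity
#' coefficient. P-values are FDR-adjusted across all windows genome-wide.
#' Windows where the intensity does not vary are flagged untestable (missing
#' p) rather than dropped, as are non-converged fits.
#'
#' @param profile An `hd_profile`.
#' @param response A [response_spec] (or a response name).
#' @param pheno Phenotype `data.frame` with columns `id`, `age`, `sex`, the
#'   response column, and `ped` unless `clusters` is given. For DBP/SBP pass
#'   a medication-adjusted table (see [adjust_medication()]); for HTN derive
#'   the flag first (see [define_htn()]).
#' @param clusters Optional cluster labels overriding `pheno$ped`; `NULL`
#'   with no `ped` column treats individuals as independent.
#' @param fdr_level Retained in the output attributes; default 0.05.
#' @return `data.frame` of class `hd_assoc`: `chrom`, `pos`, `response`,
#'   `beta`, `se`, `p_value`, `p_adjusted`, `untestable`, `converged`.
#' @export
gee_association <- function(profile, response, pheno, clusters = NULL,
                            fdr_level = 0.05) {
  stopifnot(inherits(profile, "hd_profile"))
  if (!inherits(response, "response_spec")) response <- response_spec(response)
  pheno <- as.data.frame(pheno)
  names(pheno) <- tolower(names(pheno))
  rcol <- tolower(response$name)
  need <- c("id", "age", "sex", rcol)
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  pheno$id <- as.character(pheno$id)
  if (is.null(clusters)) {
    clusters <- if ("ped" %in% names(pheno)) pheno$ped else pheno$id
  }
  pheno$.cluster <- clusters

  ids <- intersect(rownames(profile$intensity), pheno$id)
  if (length(ids) < 3) stop("fewer than 3 individuals shared between ",
                            "profile and phenotype table")
  pheno <- pheno[match(ids, pheno$id), , drop = FALSE]
  keep <- stats::complete.cases(pheno[, c("age", "sex", rcol)])
  pheno <- pheno[keep, , drop = FALSE]
  ids <- pheno$id
  if (length(unique(pheno$.cluster)) < 2) {
    stop("need at least 2 clusters for the clustered association test")
  }
  Y <- profile$intensity[ids, , drop = FALSE]

  y <- pheno[[rcol]]
  names(y) <- ids
  if (response$transform == "log_winsorize") {
    y <- transform_bp(y, response$winsor_q)
  }
  fam <- if (response$link == "logit") stats::binomial() else
    stats::gaussian()

  n_win <- ncol(Y)
  beta <- se <- p <- rep(NA_real_, n_win)
  untestable <- rep(FALSE, n_win)
  converged <- rep(NA, n_win)
  age <- pheno$age; sex <- pheno$sex
  for (w in seq_len(n_win)) {
    x <- Y[, w]
    ok <- !is.na(x)
    if (sum(ok) < 10 || stats::var(x[ok]) < 1e-12) {
      untestable[w] <- TRUE
      next
    }
    X <- cbind(`(Intercept)` = 1, intensity = x[ok], age = age[ok],
               sex = sex[ok])
    fit <- tryCatch(
      gee_fit(y[ok], X, pheno$.cluster[ok], family = fam),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
      converged[w] <- FALSE
      next
    }
    converged[w] <- TRUE
    beta[w] <- fit$coefficients["intensity"]
    se[w] <- fit$se["intensity"]
    p[w] <- fit$p_value["intensity"]
  }
  out <- data.frame(chrom = profile$anchors$chrom, pos = profile$anchors$pos,
                    response = response$name, beta = beta, se = se,
                    p_value = p, p_adjusted = fdr_adjust(p),
                    untestable = untestable, converged = converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("hd_assoc", "data.frame")
  attr(out, "fdr_level") <- fdr_level
  attr(out, "n_individuals") <- length(ids)
  out
}

#' Collapse a scan into significant regions of HD
#'
#' A significant region is a maximal run of consecutive windows on one
#' chromosome with FDR-adjusted p at or below `level`; its bounds are the
#' first and last significant anchor positions.
#'
#' @param assoc An `hd_assoc` table from [gee_association()].
#' @param level Adjusted-p cutoff, default 0.05.
#' @return `data.frame`: `chrom`, `start_bp`, `end_bp`, `response`,
#'   `n_windows`, `min_p_adjusted`.
#' @export
significant_regions <- function(assoc, level = 0.05) {
  res <- list()
  for (chr in unique(assoc$chrom)) {
    sub <- assoc[assoc$chrom == chr, , drop = FALSE]
    sig <- !is.na(sub$p_adjusted) & sub$p_adjusted <= level
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = chr, start_bp = sub$pos[starts[j]],
        end_bp = sub$pos[ends[j]], response = sub$response[1],
        n_windows = ends[j] - starts[j] + 1L,
        min_p_adjusted = min(sub$p_adjusted[starts[j]:ends[j]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start_bp = numeric(0),
               end_bp = numeric(0), response = character(0),
               n_windows = integer(0), min_p_adjusted = numeric(0),
               stringsAsFactors = FALSE)
}

#' Test transcripts for regulation by an HD region
#'
#' Summarizes each individual's intensity over the anchors inside the region
#' (their mean), then fits `expression ~ intensity + age + sex` per
#' transcript with identity-link clustered GEE and adjusts p-values by FDR
#' across transcripts. The reported fold change is the log2 ratio of mean
#' expression between individuals with region intensity at or above 0.9 and
#' the rest; it is descriptive (volcano-plot axis) and plays no role in the
#' test.
#'
#' @param expr Expression matrix, transcripts x individuals.
#' @param profile An `hd_profile` covering the region.
#' @param region A single-row `hd_regions` entry or a list with `chrom`,
#'   `start_bp`, `end_bp`.
#' @param pheno Phenotype table with `id`, `age`, `sex` (and `ped`).
#' @param clusters Optional cluster labels overriding `pheno$ped`.
#' @param fdr_level Cutoff stored with the result, default 0.05.
#' @return `data.frame` of class `hd_regulation`: `transcript`, `beta`, `se`,
#'   `p_value`, `p_adjusted`, `fold_change_log2`, `untestable`.
#' @export
expression_regulation <- function(expr, profile, region, pheno,
                                  clusters = NULL, fdr_level = 0.05) {
  stopifnot(inherits(profile, "hd_profile"))
  in_region <- profile$anchors$chrom == region$chrom &
    profile$anchors$pos >= region$start_bp &
    profile$anchors$pos <= region$end_bp
  if (!any(in_region)) stop("region contains no profile anchors")
  reg_int <- rowMeans(profile$intensity[, in_region, drop = FALSE],
                      na.rm = TRUE)

  pheno <- as.data.frame(pheno)
  names(pheno) <- tolower(names(pheno))
  pheno$id <- as.character(pheno$id)
  if (is.null(clusters)) {
    clusters <- if ("ped" %in% names(pheno)) pheno$ped else pheno$id
  }
  pheno$.cluster <- clusters
  ids <- Reduce(intersect, list(names(reg_int), colnames(expr), pheno$id))
  if (length(ids) < 3) stop("fewer than 3 individuals shared between ",
                            "expression, profile and phenotypes")
  pheno <- pheno[match(ids, pheno$id), , drop = FALSE]
  keep <- stats::complete.cases(pheno[, c("age", "sex")])
  ids <- ids[keep]; pheno <- pheno[keep, , drop = FALSE]
  x <- reg_int[ids]
  X <- cbind(`(Intercept)` = 1, intensity = x, age = pheno$age,
             sex = pheno$sex)
  hi <- x >= 0.9

  n_t <- nrow(expr)
  beta <- se <- p <- fc <- rep(NA_real_, n_t)
  untestable <- rep(FALSE, n_t)
  testable_x <- stats::var(x) >= 1e-12
  for (t in seq_len(n_t)) {
    y <- expr[t, ids]
    if (!testable_x || stats::var(y) < 1e-12) {
      untestable[t] <- TRUE
      next
    }
    fit <- tryCatch(gee_fit(y, X, pheno$.cluster), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    beta[t] <- fit$coefficients["intensity"]
    se[t] <- fit$se["intensity"]
    p[t] <- fit$p_value["intensity"]
    if (any(hi) && any(!hi)) {
      m1 <- mean(y[hi]); m0 <- mean(y[!hi])
      if (is.finite(m1) && is.finite(m0) && m1 > 0 && m0 > 0) {
        fc[t] <- log2(m1 / m0)
      }
    }
  }
  out <- data.frame(transcript = rownames(expr), beta = beta, se = se,
                    p_value = p, p_adjusted = fdr_adjust(p),
                    fold_change_log2 = fc, untestable = untestable,
                    stringsAsFactors = FALSE)
  class(out) <- c("hd_regulation", "data.frame")
  attr(out, "fdr_level") <- fdr_level
  out
}
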