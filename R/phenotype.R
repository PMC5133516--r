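#' Adjust blood pressure for antihypertensive medication
#'
#' For individuals on antihypertensive medication, DBP is increased by 5 mm Hg
#' and SBP by 10 mm Hg to offset the treatment effect. Individuals with a
#' missing medication flag are excluded with a warning. The adjustment is
#' guarded by an attribute so a second call is a no-op.
#'
#' @param pheno An `hd_phenotypes` table (see [read_phenotype_csv()]).
#' @return The adjusted table, with attribute `med_adjusted = TRUE`.
#' @export
adjust_medication <- function(pheno) {
  stopifnot(inherits(pheno, "hd_phenotypes"))
  if (isTRUE(attr(pheno, "med_adjusted"))) return(pheno)
  if (anyNA(pheno$med)) {
    warning(sum(is.na(pheno$med)),
            " individual(s) with missing medication flag excluded")
    pheno <- pheno[!is.na(pheno$med), , drop = FALSE]
  }
  on_med <- pheno$med == 1
  pheno$dbp[on_med] <- pheno$dbp[on_med] + 5
  pheno$sbp[on_med] <- pheno$sbp[on_med] + 10
  attr(pheno, "med_adjusted") <- TRUE
  pheno
}

#' Derive the hypertension flag
#'
#' An individual is hypertensive if they have ever taken antihypertensive
#' medication, or raw DBP exceeds 90 mm Hg, or raw SBP exceeds 140 mm Hg
#' (strict inequalities). Must be applied to raw, pre-adjustment blood
#' pressure values.
#'
#' @param pheno An `hd_phenotypes` table that has not been medication
#'   adjusted.
#' @return The table with an added integer `htn` column.
#' @export
define_htn <- function(pheno) {
  stopifnot(inherits(pheno, "hd_phenotypes"))
  if (isTRUE(attr(pheno, "med_adjusted"))) {
    stop("define_htn() needs raw blood pressure; apply it before ",
         "adjust_medication()")
  }
  pheno$htn <- as.integer(pheno$med == 1 | pheno$dbp > 90 | pheno$sbp > 140)
  pheno
}

#' Log-transform and winsorize a positive trait
#'
#' Applies the natural log, then caps values below the `winsor_q` quantile
#' and above the `1 - winsor_q` quantile at those quantiles (type-7 linear
#' interpolation). Used for DBP and SBP so the association model is
#' multiplicative and outliers carry less influence.
#'
#' @param values Positive numeric vector; names identify individuals in error
#'   messages.
#' @param winsor_q Winsorization tail probability, default 0.01.
#' @return Transformed vector of the same length.
#' @export
transform_bp <- function(values, winsor_q = 0.01) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    who <- if (!is.null(names(values))) names(values)[bad[1]] else
      paste("element", bad[1])
    stop("nonpositive blood pressure for ", who,
         "; log transform undefined")
  }
  lv <- log(values)
  qs <- stats::quantile(lv, c(winsor_q, 1 - winsor_q), na.rm = TRUE,
                        type = 7, names = FALSE)
  pmin(pmax(lv, qs[1]), qs[2])
}
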