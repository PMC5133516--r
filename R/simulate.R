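#' Configuration for the pedigree genotype simulator
#'
#' Defines the synthetic study conditions: pedigree-clustered diploid
#' genotypes over ordered positions with a mixture of common SNPs and rare
#' variants. Genotypes are produced by gene-dropping founder haplotypes
#' through three-generation pedigrees, so relatives share alleles identical
#' by descent and each site is in Hardy-Weinberg proportions among founders.
#'
#' @param n_pedigrees Number of independent pedigrees, default 20.
#' @param pedigree_couples Number of second-generation children (each with a
#'   married-in spouse), default 6.
#' @param children_range Inclusive range of third-generation children per
#'   couple, default `c(4, 7)`; with the defaults a pedigree has about 45
#'   members.
#' @param n_sites Variant sites on the simulated chromosome, default 2000.
#' @param mean_spacing_bp Mean inter-site spacing (exponential), default
#'   5e4 bp, giving a chromosome of roughly 100 Mb.
#' @param rare_fraction Fraction of sites that are rare variants
#'   (MAF < 0.05), default 0.3.
#' @param rare_maf_range,common_maf_range MAF ranges for the two site
#'   classes; rare defaults to `c(0.005, 0.05)`, common to `c(0.05, 0.5)`.
#' @param chrom Chromosome label, default `"1"`.
#' @param seed Base seed; every stochastic operation derives its own named
#'   stream from it, so regenerating one component does not perturb the
#'   others.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pedigrees = 20, pedigree_couples = 6,
                              children_range = c(4, 7), n_sites = 2000,
                              mean_spacing_bp = 5e4, rare_fraction = 0.3,
                              rare_maf_range = c(0.005, 0.05),
                              common_maf_range = c(0.05, 0.5),
                              chrom = "1", seed = 1) {
  stopifnot(n_pedigrees >= 1, pedigree_couples >= 0, n_sites >= 2,
            rare_fraction >= 0, rare_fraction <= 1, mean_spacing_bp > 0,
            children_range[1] >= 0, children_range[2] >= children_range[1])
  structure(list(n_pedigrees = n_pedigrees,
                 pedigree_couples = pedigree_couples,
                 children_range = children_range, n_sites = n_sites,
                 mean_spacing_bp = mean_spacing_bp,
                 rare_fraction = rare_fraction,
                 rare_maf_range = rare_maf_range,
                 common_maf_range = common_maf_range,
                 chrom = as.character(chrom), seed = as.integer(seed)),
            class = "simulation_config")
}

# Derive an independent 31-bit sub-seed from the base seed and a stream name.
derive_seed <- function(seed, stream) {
  chars <- utf8ToInt(stream)
  h <- as.double(seed %% 2147483647L)
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Build the pedigree structure table
#'
#' Three generations: a founding couple, `pedigree_couples` of their children
#' each married to a founder spouse, and a third generation of grandchildren.
#' Parents always precede children in the table, as gene-dropping requires.
#'
#' @param cfg A [simulation_config].
#' @return `data.frame`: `id`, `pedigree`, `father`, `mother` (`NA` for
#'   founders), `generation`.
#' @export
simulate_pedigree_structure <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "pedigree"))
  rows <- list()
  for (p in seq_len(cfg$n_pedigrees)) {
    ped <- sprintf("PED%02d", p)
    gp1 <- paste0(ped, "_G1_1"); gp2 <- paste0(ped, "_G1_2")
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(gp1, gp2), pedigree = ped, father = NA_character_,
      mother = NA_character_, generation = 1L, stringsAsFactors = FALSE)
    for (cpl in seq_len(cfg$pedigree_couples)) {
      child <- sprintf("%s_G2_%dC", ped, cpl)
      spouse <- sprintf("%s_G2_%dS", ped, cpl)
      rows[[length(rows) + 1L]] <- data.frame(
        id = c(child, spouse), pedigree = ped,
        father = c(gp1, NA_character_), mother = c(gp2, NA_character_),
        generation = 2L, stringsAsFactors = FALSE)
      kid_counts <- cfg$children_range[1]:cfg$children_range[2]
      n_kids <- if (length(kid_counts) == 1) kid_counts else
        sample(kid_counts, 1)
      if (n_kids > 0) {
        kids <- sprintf("%s_G3_%d_%d", ped, cpl, seq_len(n_kids))
        rows[[length(rows) + 1L]] <- data.frame(
          id = kids, pedigree = ped, father = child, mother = spouse,
          generation = 3L, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate pedigree-clustered genotypes by gene dropping
#'
#' Site positions are cumulative exponential spacings; each site is assigned
#' a MAF from the rare or common class. Founders receive two haplotypes with
#' independent Bernoulli(MAF) alternate alleles (the minor allele is the
#' alternate); every non-founder inherits one uniformly chosen allele from
#' each parent, independently across sites. Deterministic given the config
#' seed.
#'
#' @param cfg A [simulation_config].
#' @param structure Optional pedigree table from
#'   [simulate_pedigree_structure()]; built from `cfg` when omitted.
#' @return An [hd_genotypes] object; the configured per-site MAF is attached
#'   as attribute `true_maf`.
#' @export
simulate_genotypes <- function(cfg, structure = NULL) {
  if (is.null(structure)) structure <- simulate_pedigree_structure(cfg)
  set.seed(derive_seed(cfg$seed, "sites"))
  m <- cfg$n_sites
  spacings <- pmax(1, round(stats::rexp(m, rate = 1 / cfg$mean_spacing_bp)))
  pos <- cumsum(spacings)
  is_rare <- stats::runif(m) < cfg$rare_fraction
  maf <- ifelse(is_rare,
                stats::runif(m, cfg$rare_maf_range[1], cfg$rare_maf_range[2]),
                stats::runif(m, cfg$common_maf_range[1],
                             cfg$common_maf_range[2]))
  maf <- pmin(maf, 0.5)

  set.seed(derive_seed(cfg$seed, "genotypes"))
  n <- nrow(structure)
  hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
  idx <- stats::setNames(seq_len(n), structure$id)
  for (i in seq_len(n)) {
    if (is.na(structure$father[i])) {
      hap1[i, ] <- as.integer(stats::runif(m) < maf)
      hap2[i, ] <- as.integer(stats::runif(m) < maf)
    } else {
      fa <- idx[[structure$father[i]]]; mo <- idx[[structure$mother[i]]]
      pick_f <- stats::runif(m) < 0.5
      pick_m <- stats::runif(m) < 0.5
      hap1[i, ] <- ifelse(pick_f, hap1[fa, ], hap2[fa, ])
      hap2[i, ] <- ifelse(pick_m, hap1[mo, ], hap2[mo, ])
    }
  }
  calls <- hap1 + hap2
  rownames(calls) <- structure$id
  g <- hd_genotypes(calls,
                    data.frame(chrom = cfg$chrom, pos = pos,
                               stringsAsFactors = FALSE),
                    data.frame(id = structure$id,
                               pedigree = structure$pedigree,
                               stringsAsFactors = FALSE))
  attr(g, "true_maf") <- maf
  g
}

#' Simulate the genotype-independent quantitative trait
#'
#' I.i.d. normal draws on their own random stream, so the trait is
#' independent of every genotype draw.
#'
#' @param n Number of individuals.
#' @param mean,sd Trait mean and standard deviation, defaults 10 and 2.
#' @param seed Seed for the trait stream.
#' @return Numeric vector of length `n`.
#' @export
simulate_q1 <- function(n, mean = 10, sd = 2, seed = 1) {
  stopifnot(sd > 0)
  set.seed(derive_seed(seed, "q1"))
  stats::rnorm(n, mean, sd)
}

#' Logistic HD-implantation model
#'
#' Each individual's probability that every genotype in the target region is
#' replaced by a homozygote is `p = plogis(b0 + b1 * Q1)`.
#'
#' @param b0,b1 Logistic intercept and slope on the trait.
#' @param q1 Per-individual trait values.
#' @param chrom,start_bp,end_bp Target region.
#' @return An `implant_model` list with the per-individual `p_rep`.
#' @export
implant_model <- function(b0, b1, q1, chrom, start_bp, end_bp) {
  stopifnot(end_bp >= start_bp)
  structure(list(b0 = b0, b1 = b1, q1 = q1, chrom = as.character(chrom),
                 start_bp = start_bp, end_bp = end_bp,
                 p_rep = stats::plogis(b0 + b1 * q1)),
            class = "implant_model")
}

#' Implant a trait-associated region of HD
#'
#' With probability `p_rep` (from the logistic model) an individual's every
#' genotype in the region is replaced by a homozygote: heterozygotes become
#' the homozygote of the site's major allele, existing homozygotes are kept.
#' Sites outside the region are never touched.
#'
#' @param g An [hd_genotypes] object.
#' @param model An [implant_model] whose `q1` is ordered like the rows of
#'   `g`.
#' @param seed Seed for the implantation stream.
#' @return The modified [hd_genotypes]; which individuals were replaced is
#'   attached as logical attribute `replaced`.
#' @export
implant_hd <- function(g, model, seed = 1) {
  stopifnot(inherits(g, "hd_genotypes"), inherits(model, "implant_model"),
            length(model$q1) == nrow(g$calls))
  in_region <- g$sites$chrom == model$chrom &
    g$sites$pos >= model$start_bp & g$sites$pos <= model$end_bp
  if (!any(in_region)) stop("implantation region covers no sites")
  set.seed(derive_seed(seed, "implant"))
  replaced <- stats::runif(nrow(g$calls)) < model$p_rep
  if (any(replaced)) {
    af <- alt_allele_freq(g)[in_region]
    major_hom <- ifelse(!is.na(af) & af > 0.5, 2L, 0L)
    block <- g$calls[replaced, in_region, drop = FALSE]
    het <- !is.na(block) & block == 1L
    block[het] <- matrix(rep(major_hom, each = nrow(block)),
                         nrow = nrow(block))[het]
    g$calls[replaced, in_region] <- block
  }
  attr(g, "replaced") <- replaced
  g
}

#' Type-I-error experiment for the homozygosity association scan
#'
#' Simulates one genotype panel, estimates its intensity profile once, then
#' repeatedly draws a normal trait independent of the genotypes and runs the
#' clustered association scan with FDR control. The per-replicate type-I
#' error is the fraction of testable windows declared significant after
#' adjustment; the experiment reports its mean and Monte-Carlo standard
#' error.
#'
#' @param cfg A [simulation_config].
#' @param n_replicates Number of trait replicates, default 200.
#' @param spec [window_spec] for the scan; the experiment default thins
#'   anchors to every 10th site because adjacent 5%-windows share 99% of
#'   their members.
#' @param fdr_level Significance level after FDR, default 0.05.
#' @param q1_mean,q1_sd Trait distribution, defaults 10 and 2.
#' @param progress Print a dot every 10 replicates.
#' @return List of class `hd_experiment`: `rate` (mean type-I error),
#'   `mc_se`, `per_replicate`, `n_replicates`, `n_windows`,
#'   `n_individuals`.
#' @export
type1_experiment <- function(cfg, n_replicates = 200,
                             spec = window_spec(anchor_stride = 10),
                             fdr_level = 0.05, q1_mean = 10, q1_sd = 2,
                             progress = FALSE) {
  g <- simulate_genotypes(cfg)
  prof <- estimate_profile(g = g, spec = spec)
  covars <- simulate_covariates(cfg$seed, g$individuals$id)
  rates <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    q1 <- simulate_q1(nrow(g$calls), q1_mean, q1_sd,
                      seed = cfg$seed + 7919L * r)
    pheno <- data.frame(id = g$individuals$id, ped = g$individuals$pedigree,
                        age = covars$age, sex = covars$sex, q1 = q1,
                        stringsAsFactors = FALSE)
    res <- gee_association(prof, response_spec("q1"), pheno,
                           fdr_level = fdr_level)
    tested <- !is.na(res$p_adjusted)
    rates[r] <- if (any(tested)) {
      mean(res$p_adjusted[tested] <= fdr_level)
    } else 0
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(rate = mean(rates),
                 mc_se = stats::sd(rates) / sqrt(n_replicates),
                 per_replicate = rates, n_replicates = n_replicates,
                 n_windows = ncol(prof$intensity),
                 n_individuals = nrow(g$calls)),
            class = "hd_experiment")
}

#' Power experiment for the homozygosity association scan
#'
#' For each `(b0, b1)` combination: per replicate, draws the trait, implants
#' the target region with replacement probability `plogis(b0 + b1 * Q1)`,
#' re-estimates the intensity profile and runs the scan. The region counts
#' as detected when at least one FDR-significant window anchor falls inside
#' it; power is the detection fraction over replicates.
#'
#' @param cfg A [simulation_config].
#' @param grid `data.frame` with columns `b0` and `b1`.
#' @param region List with `start_bp`, `end_bp` (and optionally `chrom`);
#'   default spans the central 10% of the simulated sites.
#' @param n_replicates Replicates per combination, default 200.
#' @param spec,fdr_level,q1_mean,q1_sd,progress As in [type1_experiment()].
#' @return List of class `hd_experiment_grid`: `results` (`data.frame` with
#'   `b0`, `b1`, `power`, `mc_se`, `n_replicates`), plus the shared setup
#'   sizes.
#' @export
power_experiment <- function(cfg, grid = data.frame(b0 = -10, b1 = 1),
                             region = NULL, n_replicates = 200,
                             spec = window_spec(anchor_stride = 10),
                             fdr_level = 0.05, q1_mean = 10, q1_sd = 2,
                             progress = FALSE) {
  base <- simulate_genotypes(cfg)
  if (is.null(region)) {
    qs <- stats::quantile(base$sites$pos, c(0.45, 0.55), type = 7)
    region <- list(chrom = cfg$chrom, start_bp = qs[[1]], end_bp = qs[[2]])
  }
  if (is.null(region$chrom)) region$chrom <- cfg$chrom
  covars <- simulate_covariates(cfg$seed, base$individuals$id)
  maf <- compute_maf(base)
  out <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    b0 <- grid$b0[gi]; b1 <- grid$b1[gi]
    hits <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- cfg$seed + 7919L * r + 104729L * gi
      q1 <- simulate_q1(nrow(base$calls), q1_mean, q1_sd, seed = rep_seed)
      model <- implant_model(b0, b1, q1, region$chrom, region$start_bp,
                             region$end_bp)
      g <- implant_hd(base, model, seed = rep_seed)
      prof <- estimate_profile(g = g, spec = spec, maf = maf)
      pheno <- data.frame(id = g$individuals$id,
                          ped = g$individuals$pedigree,
                          age = covars$age, sex = covars$sex, q1 = q1,
                          stringsAsFactors = FALSE)
      res <- gee_association(prof, response_spec("q1"), pheno,
                             fdr_level = fdr_level)
      sig <- !is.na(res$p_adjusted) & res$p_adjusted <= fdr_level
      hits[r] <- any(sig & res$chrom == region$chrom &
                       res$pos >= region$start_bp &
                       res$pos <= region$end_bp)
      if (progress && r %% 10 == 0) cat(".")
    }
    if (progress) cat("\n")
    pw <- mean(hits)
    out[[gi]] <- data.frame(b0 = b0, b1 = b1, power = pw,
                            mc_se = sqrt(pw * (1 - pw) / n_replicates),
                            n_replicates = n_replicates)
  }
  structure(list(results = do.call(rbind, out), region = region,
                 n_windows = NA_integer_,
                 n_individuals = nrow(base$calls)),
            class = "hd_experiment_grid")
}

#' Pick implantation regions by local rare-variant content
#'
#' Slides a block of `width_sites` sites along the chromosome, computes each
#' block's fraction of rare variants, and returns the blocks whose rare
#' fraction sits at the requested percentiles of the blockwise distribution.
#' Mirrors choosing target regions representative of low, typical and high
#' rare-variant density.
#'
#' @param g An [hd_genotypes] object (single chromosome).
#' @param width_sites Sites per candidate block, default 10% of the sites.
#' @param percentiles Percentiles of blockwise rare fraction, default
#'   `c(0.1, 0.5, 0.9)`.
#' @param rare_cutoff MAF below which a site counts as rare, default 0.05.
#' @return `data.frame`: `chrom`, `start_bp`, `end_bp`, `rare_fraction`,
#'   `percentile`.
#' @export
select_rv_percentile_regions <- function(g, width_sites = NULL,
                                         percentiles = c(0.1, 0.5, 0.9),
                                         rare_cutoff = 0.05) {
  stopifnot(inherits(g, "hd_genotypes"))
  m <- nrow(g$sites)
  if (is.null(width_sites)) width_sites <- max(2L, floor(m / 10))
  maf <- compute_maf(g)
  is_rare <- !is.na(maf) & maf < rare_cutoff
  starts <- seq(1L, m - width_sites + 1L,
                by = max(1L, floor(width_sites / 2)))
  frac <- vapply(starts, function(s) {
    mean(is_rare[s:(s + width_sites - 1L)])
  }, numeric(1))
  targets <- stats::quantile(frac, percentiles, type = 7, names = FALSE)
  picked <- vapply(targets, function(t) starts[which.min(abs(frac - t))],
                   numeric(1))
  data.frame(chrom = g$sites$chrom[picked],
             start_bp = g$sites$pos[picked],
             end_bp = g$sites$pos[picked + width_sites - 1L],
             rare_fraction = frac[match(picked, starts)],
             percentile = percentiles, stringsAsFactors = FALSE)
}

# Age and sex covariates for simulated individuals (their own stream).
simulate_covariates <- function(seed, ids) {
  set.seed(derive_seed(seed, "covariates"))
  n <- length(ids)
  data.frame(id = ids,
             age = round(stats::runif(n, 20, 80)),
             sex = stats::rbinom(n, 1, 0.5), stringsAsFactors = FALSE)
}

#' @method print hd_experiment
#' @export
print.hd_experiment <- function(x, ...) {
  cat("hd_experiment:", x$n_replicates, "replicates,", x$n_windows,
      "windows,", x$n_individuals, "individuals\n")
  cat("  mean rate =", signif(x$rate, 4), " MC-SE =", signif(x$mc_se, 3),
      "\n")
  invisible(x)
}
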