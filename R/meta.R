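# Cohort-level aggregation: inverse-variance and sample-size-weighted
# meta-analysis, multiple-testing adjustment, significance tiers, PRS
# scoring and the polygenic transmission disequilibrium test.

#' Inverse-variance weighted meta-analysis
#'
#' Fixed-effect combination with weights w_i = 1/se_i^2: the pooled
#' estimate is sum(w b)/sum(w) with SE = 1/sqrt(sum(w)).  Records with
#' non-positive SE are excluded with a warning; a single valid record is
#' returned unchanged.
#'
#' @param beta,se numeric vectors of per-cohort estimates and standard
#'   errors.
#' @return list with `beta`, `se`, `z`, `p`, `n_studies`.
#' @export
ivw_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (any(is.finite(se) & se <= 0))
    warning(sum(is.finite(se) & se <= 0),
            " record(s) with non-positive SE excluded")
  beta <- beta[ok]; se <- se[ok]
  if (!length(beta)) stop("no valid records to meta-analyze")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)),
       n_studies = length(beta))
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Stouffer combination with weights w_i = sqrt(N_i):
#' z = sum(w z) / sqrt(sum(w^2)).  Used to fold in replication cohorts
#' that report no effect sizes.  For trio cohorts N is the number of
#' informative families.
#'
#' @param z numeric vector of per-study z-scores.
#' @param n numeric vector of per-study sample sizes (> 0).
#' @return list with `z`, `p`, `n_studies`.
#' @export
stouffer_meta <- function(z, n) {
  stopifnot(length(z) == length(n))
  if (any(!is.finite(n) | n <= 0)) stop("sample sizes must be positive")
  w <- sqrt(n)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z = zc, p = 2 * stats::pnorm(-abs(zc)), n_studies = length(z))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]);
#' input outside \[0, 1\] is an error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-tissue FDR and cross-tissue Bonferroni significance flags
#'
#' Two tiers: BH-significant at FDR `alpha` within each tissue, and
#' Bonferroni-significant at `alpha / n_tests` across all gene-tissue
#' tests (e.g. 125,000 tests at alpha 0.05 give the 4.0e-7 cross-tissue
#' cutoff).
#'
#' @param records data.frame with columns `p` and `tissue`.
#' @param alpha significance level (default 0.05).
#' @param n_tests total number of gene-tissue tests for the Bonferroni
#'   tier; defaults to `nrow(records)`.
#' @return the input with logical columns `fdr_significant`,
#'   `bonferroni_significant` and numeric `p_adjusted` appended (empty
#'   input passes through).
#' @export
significance_tiers <- function(records, alpha = 0.05, n_tests = NULL) {
  if (!nrow(records)) {
    records$p_adjusted <- numeric(0)
    records$fdr_significant <- logical(0)
    records$bonferroni_significant <- logical(0)
    return(records)
  }
  if (is.null(n_tests)) n_tests <- nrow(records)
  padj <- stats::ave(records$p, records$tissue,
                     FUN = function(p) bh_adjust(p))
  records$p_adjusted <- padj
  records$fdr_significant <- !is.na(padj) & padj < alpha
  cutoff <- alpha / n_tests
  records$bonferroni_significant <- !is.na(records$p) & records$p < cutoff
  attr(records, "bonferroni_cutoff") <- cutoff
  records
}

#' Polygenic score from effect weights and dosages
#'
#' Additive score sum_j effect_j x dosage_j per sample; variants missing
#' from the dosage matrix are skipped and counted.
#'
#' @param effects data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `weight` (the weight-table predictor dialect).
#' @param geno [phased_geno()] object.
#' @param samples samples to score (default all).
#' @return named numeric vector of scores with attribute `n_missing`.
#' @export
prs_score <- function(effects, geno, samples = NULL) {
  if (is.null(samples)) samples <- geno$samples
  model <- expr_model(gene = "PRS", tissue = ".", predictors = effects)
  if (is.null(model))      # every weight zero: score is identically 0
    return(structure(stats::setNames(rep(0, length(samples)), samples),
                     n_missing = 0L))
  aligned <- harmonize_model(model, geno, drop_ambiguous = FALSE)
  if (is.null(aligned)) stop("no overlapping variants between weights and genotypes")
  idx <- attr(aligned, "var_index")
  dos <- dosage(geno)[idx, samples, drop = FALSE]
  sc <- impute_expression(aligned, t(dos))
  structure(stats::setNames(sc, samples),
            n_missing = nrow(attr(aligned, "report")))
}

#' Polygenic transmission disequilibrium test
#'
#' For each trio the deviation of the proband's polygenic score from the
#' midparent mean, scaled by the SD of the midparent scores:
#' d_i = (proband_i - mp_i) / sd(mp), mp_i = (father_i + mother_i)/2.
#' Over-transmission is assessed by a two-sided one-sample t-test of the
#' mean deviation against zero (df = n - 1).
#'
#' @param proband,father,mother numeric vectors of per-family polygenic
#'   scores (complete triples, n >= 2).
#' @return list with `mean_deviation`, `se`, `t`, `df`, `p`, `n`.
#' @export
ptdt <- function(proband, father, mother) {
  n <- length(proband)
  stopifnot(length(father) == n, length(mother) == n)
  if (n < 2) stop("pTDT needs at least 2 families")
  mp <- (father + mother) / 2
  s <- stats::sd(mp)
  if (s == 0) stop("zero SD of midparent scores")
  dev <- (proband - mp) / s
  if (stats::sd(dev) == 0) {
    # degenerate: constant deviation (proband == midparent everywhere
    # gives mean 0, t = 0, p = 1)
    t_stat <- if (mean(dev) == 0) 0 else sign(mean(dev)) * Inf
    return(list(mean_deviation = mean(dev), se = 0, t = t_stat,
                df = n - 1, p = if (t_stat == 0) 1 else 0, n = n))
  }
  tt <- stats::t.test(dev, mu = 0)
  list(mean_deviation = mean(dev), se = stats::sd(dev) / sqrt(n),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n)
}

#' Two-stage mixed meta-analysis
#'
#' Stage 1: inverse-variance-weighted combination of the trio cohorts.
#' Stage 2: sample-size-weighted z-combination of the stage-1 z-score
#' with replication studies that provide only z and N.
#'
#' @param beta,se,n per-trio-cohort estimates, SEs and informative family
#'   counts.
#' @param rep_z,rep_n replication-stage z-scores and sample sizes
#'   (optional).
#' @return list with `stage1` (the [ivw_meta()] result) and `z`, `p`,
#'   `n_studies` of the final combination.
#' @export
two_stage_meta <- function(beta, se, n, rep_z = NULL, rep_n = NULL) {
  s1 <- ivw_meta(beta, se)
  if (is.null(rep_z) || !length(rep_z))
    return(list(stage1 = s1, z = s1$z, p = s1$p,
                n_studies = s1$n_studies))
  s2 <- stouffer_meta(c(s1$z, rep_z), c(sum(n), rep_n))
  list(stage1 = s1, z = s2$z, p = s2$p,
       n_studies = s1$n_studies + length(rep_z))
}
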