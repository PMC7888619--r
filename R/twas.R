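# Association pipelines: gene-level trio TWAS on imputed expression,
# SNP-level trio GWAS on allele counts, the one-sibling and parent-control
# alternative designs, stratified analysis and conditional fine-mapping.

#' Assemble matched exposure sets for one expression model
#'
#' For each trio: build the four pseudo-sibling configurations, impute
#' expression, and exclude the configuration closest to the proband.
#'
#' @param model harmonized `expr_model`.
#' @param geno [phased_geno()] object.
#' @param trio_tab trio table from [trios()].
#' @return list with `case` (length-N), `ctrl` (N x 3 matrix), `father`,
#'   `mother` (length-N) imputed expressions.
#' @export
matched_exposures <- function(model, geno, trio_tab) {
  N <- nrow(trio_tab)
  case <- father <- mother <- numeric(N)
  ctrl <- matrix(NA_real_, N, 3)
  for (i in seq_len(N)) {
    fam <- impute_family(model, geno, trio_tab[i, ])
    sel <- select_controls(fam$proband, fam$configs)
    case[i] <- fam$proband
    ctrl[i, ] <- sel$controls
    father[i] <- fam$father
    mother[i] <- fam$mother
  }
  list(case = case, ctrl = ctrl, father = father, mother = mother)
}

std_matched <- function(case, ctrl) {
  v <- standardize_exposures(c(case, as.numeric(ctrl)))
  flat <- isTRUE(attr(v, "uninformative"))
  n <- length(case)
  list(case = v[seq_len(n)], ctrl = matrix(v[-seq_len(n)], n),
       uninformative = flat)
}

assoc_row <- function(model, fit, note = "") {
  data.frame(gene = model$gene, tissue = model$tissue,
             feature_type = model$feature_type, cluster = model$cluster,
             beta = unname(fit$coefficients[1]), se = unname(fit$se[1]),
             z = unname(fit$z[1]), p = unname(fit$p[1]),
             n_total = fit$n_total, n_informative = fit$n_informative,
             converged = fit$converged, separation = fit$separation,
             note = note, stringsAsFactors = FALSE)
}

na_assoc_row <- function(model, n_total, note) {
  data.frame(gene = model$gene, tissue = model$tissue,
             feature_type = model$feature_type, cluster = model$cluster,
             beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
             n_total = n_total, n_informative = 0L,
             converged = FALSE, separation = FALSE, note = note,
             stringsAsFactors = FALSE)
}

#' Trio-based TWAS with pseudo-sibling matching
#'
#' For every expression model: harmonize against the genotypes, build the
#' four recombined pseudo-offspring per family, impute expression, exclude
#' the configuration closest to the proband, and fit the 1:3 conditional
#' logistic transmission model on the (optionally standardized) exposures.
#'
#' @param geno [phased_geno()] object with probands and parents.
#' @param ped FAM data.frame ([read_fam()]) or trio table ([trios()]).
#' @param models list of `expr_model` objects.
#' @param standardize z-score exposures per gene over probands + retained
#'   pseudo siblings (population SD); default TRUE.
#' @param min_weight_retained minimum fraction of the model's total
#'   absolute weight that must survive harmonization (default 0.5).
#' @param drop_ambiguous drop strand-ambiguous predictors (default TRUE).
#' @return data.frame of class `twas_result`, one row per model: `gene`,
#'   `tissue`, `feature_type`, `cluster`, `beta`, `se`, `z`, `p`,
#'   `n_total`, `n_informative`, `converged`, `separation`, `note`
#'   (skip/quality reason, empty when clean).
#' @export
run_twas <- function(geno, ped, models, standardize = TRUE,
                     min_weight_retained = 0.5, drop_ambiguous = TRUE) {
  trio_tab <- as_trio_tab(ped)
  if (inherits(models, "expr_model")) models <- list(models)
  rows <- lapply(models, function(model) {
    aligned <- tryCatch(
      suppressWarnings(harmonize_model(model, geno,
                                       drop_ambiguous = drop_ambiguous)),
      error = function(e) NULL)
    if (is.null(aligned))
      return(na_assoc_row(model, nrow(trio_tab), "no_usable_predictors"))
    if (weight_mass_retained(aligned, model) < min_weight_retained)
      return(na_assoc_row(model, nrow(trio_tab), "weight_mass_lost"))
    ex <- tryCatch(matched_exposures(aligned, geno, trio_tab),
                   error = function(e) NULL)
    if (is.null(ex))
      return(na_assoc_row(model, nrow(trio_tab), "exposure_failure"))
    case <- ex$case; ctrl <- ex$ctrl
    if (standardize) {
      s <- std_matched(case, ctrl)
      if (s$uninformative)
        return(na_assoc_row(model, nrow(trio_tab), "uninformative"))
      case <- s$case; ctrl <- s$ctrl
    }
    fit <- suppressWarnings(clr_fit(case, ctrl))
    if (fit$n_informative == 0)
      return(na_assoc_row(model, nrow(trio_tab), "uninformative"))
    assoc_row(model, fit)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("twas_result", "data.frame")
  out
}

as_trio_tab <- function(ped) {
  if (!is.null(ped$proband)) ped else trios(ped)
}

#' Trio GWAS with single-variant pseudo-controls
#'
#' For each biallelic variant, forms the four recombined offspring
#' alternate-allele counts per family, removes one configuration matching
#' the proband, and fits the 1:3 conditional logistic model on the raw A1
#' counts.  Variants monomorphic in the parents are reported as
#' uninformative; families where no configuration matches the proband at
#' the variant are excluded from that variant's test.
#'
#' @inheritParams run_twas
#' @return data.frame, one row per variant: `variant`, `chrom`, `pos`,
#'   `beta`, `se`, `z`, `p`, `n_total`, `n_informative`, `n_excluded`,
#'   `note`.
#' @export
run_trio_gwas <- function(geno, ped) {
  trio_tab <- as_trio_tab(ped)
  N <- nrow(trio_tab)
  f1 <- geno$hap1[, trio_tab$father, drop = FALSE]
  f2 <- geno$hap2[, trio_tab$father, drop = FALSE]
  m1 <- geno$hap1[, trio_tab$mother, drop = FALSE]
  m2 <- geno$hap2[, trio_tab$mother, drop = FALSE]
  pd <- geno$hap1[, trio_tab$proband, drop = FALSE] +
    geno$hap2[, trio_tab$proband, drop = FALSE]
  keys <- variant_key(geno$variants)
  rows <- lapply(seq_len(nrow(geno$variants)), function(v) {
    cfg <- rbind(f1[v, ] + m1[v, ], f1[v, ] + m2[v, ],
                 f2[v, ] + m1[v, ], f2[v, ] + m2[v, ])   # 4 x N counts
    prob <- pd[v, ]
    eq <- cfg == rep(prob, each = 4)
    has_match <- colSums(eq) > 0
    n_exc <- sum(!has_match)
    base <- data.frame(variant = keys[v], chrom = geno$variants$chrom[v],
                       pos = geno$variants$pos[v], stringsAsFactors = FALSE)
    if (!any(has_match))
      return(cbind(base, beta = NA_real_, se = NA_real_, z = NA_real_,
                   p = NA_real_, n_total = N, n_informative = 0L,
                   n_excluded = n_exc, note = "no_matching_configuration"))
    drop_idx <- apply(eq[, has_match, drop = FALSE], 2, which.max)
    cfgm <- cfg[, has_match, drop = FALSE]
    ctrl <- vapply(seq_along(drop_idx),
                   function(i) cfgm[-drop_idx[i], i], numeric(3))
    case <- prob[has_match]
    fit <- suppressWarnings(clr_fit(case, t(ctrl)))
    note <- if (fit$n_informative == 0) "uninformative" else
      if (n_exc > 0) "families_excluded" else ""
    if (fit$n_informative == 0)
      return(cbind(base, beta = NA_real_, se = NA_real_, z = NA_real_,
                   p = NA_real_, n_total = N, n_informative = 0L,
                   n_excluded = n_exc, note = note))
    cbind(base, beta = unname(fit$coefficients[1]), se = unname(fit$se[1]),
          z = unname(fit$z[1]), p = unname(fit$p[1]), n_total = N,
          n_informative = fit$n_informative, n_excluded = n_exc,
          note = note)
  })
  do.call(rbind, rows)
}

#' One-sibling alternative design
#'
#' Each proband is contrasted with the single pseudo sibling made of the
#' two non-transmitted parental haplotypes (expression = father + mother
#' - proband).  The default regression is unconditional logistic (glm of
#' status on exposure with intercept); `method = "clr"` fits the 1:1
#' matched conditional model instead.
#'
#' @param case proband exposures (length N).
#' @param sib non-transmitted sibling exposures (length N).
#' @param method `"glm"` (default) or `"clr"`.
#' @return For `"clr"`, a [clr_fit()] object; for `"glm"`, a list of class
#'   `sib_glm_fit` with `coefficients`, `se`, `z`, `p`, `n_total`.
#' @export
fit_one_sibling <- function(case, sib, method = c("glm", "clr")) {
  method <- match.arg(method)
  stopifnot(length(case) == length(sib))
  if (method == "clr")
    return(clr_fit(case, matrix(sib, ncol = 1)))
  y <- c(rep(1L, length(case)), rep(0L, length(sib)))
  x <- c(case, sib)
  g <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  cf <- summary(g)$coefficients
  structure(list(coefficients = c(exposure = unname(cf["x", 1])),
                 se = c(exposure = unname(cf["x", 2])),
                 z = c(exposure = unname(cf["x", 3])),
                 p = c(exposure = unname(cf["x", 4])),
                 n_total = length(case), glm = g),
            class = "sib_glm_fit")
}

#' @export
print.sib_glm_fit <- function(x, ...) {
  cat("One-sibling logistic regression (unconditional), ", x$n_total,
      " families\n", sep = "")
  print(data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Parent-control alternative design
#'
#' Conditional logistic regression of each proband against its two
#' parents (1 case : 2 matched controls).
#'
#' @param case proband exposures (length N).
#' @param father,mother parental exposures (length N).
#' @return A [clr_fit()] object.
#' @export
fit_parent_control <- function(case, father, mother) {
  stopifnot(length(case) == length(father), length(case) == length(mother))
  clr_fit(case, cbind(father, mother))
}

#' Stratified TWAS with permutation p-value for the effect ratio
#'
#' Fits the pseudo-sibling transmission model separately in two family
#' subgroups and assesses the ratio beta_group1 / beta_group2 against a
#' permutation null obtained by shuffling the group labels across
#' families.  One-sided p = (r + 1) / (B + 1) where r counts shuffled
#' ratios >= observed.
#'
#' @inheritParams run_twas
#' @param model a single `expr_model`.
#' @param group length-N vector with exactly two distinct labels, aligned
#'   to the trio table rows.
#' @param B number of permutations (default 10000); must be >= 1.
#' @param seed RNG seed for the label shuffles.
#' @return list with `fits` (named list of per-group [clr_fit()]s, `NA`
#'   entries for groups with < 2 informative families), `ratio`,
#'   `perm_p`.
#' @export
stratified_twas <- function(geno, ped, model, group, B = 10000L, seed = 1L,
                            standardize = TRUE) {
  if (B < 1) stop("need >= 1 permutation")
  trio_tab <- as_trio_tab(ped)
  stopifnot(length(group) == nrow(trio_tab))
  lv <- unique(group)
  if (length(lv) != 2) stop("exactly two group labels required")
  aligned <- harmonize_model(model, geno)
  ex <- matched_exposures(aligned, geno, trio_tab)
  case <- ex$case; ctrl <- ex$ctrl
  if (standardize) {
    s <- std_matched(case, ctrl)
    case <- s$case; ctrl <- s$ctrl
  }
  fit_group <- function(idx) {
    if (sum(idx) < 2) return(NULL)
    f <- suppressWarnings(clr_fit(case[idx], ctrl[idx, , drop = FALSE]))
    if (f$n_informative < 2) NULL else f
  }
  ratio_of <- function(g) {
    f1 <- fit_group(g == lv[1])
    f2 <- fit_group(g == lv[2])
    if (is.null(f1) || is.null(f2)) return(NA_real_)
    unname(f1$coefficients[1] / f2$coefficients[1])
  }
  f1 <- fit_group(group == lv[1])
  f2 <- fit_group(group == lv[2])
  obs <- if (is.null(f1) || is.null(f2)) NA_real_ else
    unname(f1$coefficients[1] / f2$coefficients[1])
  perm_p <- NA_real_
  if (is.finite(obs)) {
    set.seed(seed)
    r <- 0L
    for (b in seq_len(B)) {
      rb <- ratio_of(sample(group))
      if (is.finite(rb) && rb >= obs) r <- r + 1L
    }
    perm_p <- (r + 1) / (B + 1)
  }
  list(fits = stats::setNames(list(f1, f2), as.character(lv)),
       ratio = obs, perm_p = perm_p)
}

#' Conditional fine-mapping of multiple genes at one locus
#'
#' Joint multivariate conditional logistic fit for two or more expression
#' models in the same tissue.  A single pseudo-sibling window covering the
#' union of all predictors is built per family (one haplotype draw, so
#' gene exposures stay phase-consistent), the configuration with the
#' lowest sum of squared differences to the proband across the normalized
#' gene exposures is excluded, and the joint effect vector with per-gene
#' conditional p-values is estimated.  Collinear exposures trigger a
#' condition-number warning and a ridge-stabilized step.
#'
#' @inheritParams run_twas
#' @param models list of >= 2 `expr_model`s from the same tissue.
#' @return A multivariate [clr_fit()] with one coefficient per gene.
#' @export
conditional_fine_mapping <- function(geno, ped, models, standardize = TRUE) {
  if (inherits(models, "expr_model")) models <- list(models)
  if (length(models) < 1) stop("need at least one model")
  tis <- unique(vapply(models, function(m) m$tissue, character(1)))
  if (length(tis) != 1)
    stop("fine-mapping requires models from a single tissue")
  trio_tab <- as_trio_tab(ped)
  aligned <- lapply(models, harmonize_model, geno = geno)
  if (any(vapply(aligned, is.null, logical(1))))
    stop("model(s) with no usable predictors at this locus")
  union_idx <- sort(unique(unlist(lapply(aligned, attr, "var_index"))))
  sub <- lapply(aligned, function(m) match(attr(m, "var_index"), union_idx))
  q <- length(models)
  N <- nrow(trio_tab)
  case <- matrix(NA_real_, N, q)
  cfg <- array(NA_real_, c(N, 4, q))
  for (i in seq_len(N)) {
    s <- pseudo_siblings(geno, trio_tab[i, ], variants = union_idx)
    for (j in seq_len(q)) {
      case[i, j] <- impute_expression(aligned[[j]],
                                      as.numeric(s$proband[sub[[j]]]))
      cfg[i, , j] <- impute_expression(aligned[[j]],
                                       s$configs[, sub[[j]], drop = FALSE])
    }
  }
  # exclusion uses normalized exposures, so genes contribute to the
  # sum-of-squares on a common scale
  if (standardize) {
    for (j in seq_len(q)) {
      v <- standardize_exposures(c(case[, j], as.numeric(cfg[, , j])))
      case[, j] <- v[seq_len(N)]
      cfg[, , j] <- v[-seq_len(N)]
    }
  }
  gene_names <- make.unique(vapply(models, function(m) m$gene, character(1)))
  colnames(case) <- gene_names
  ctrls <- lapply(1:3, function(k) matrix(NA_real_, N, q))
  for (i in seq_len(N)) {
    sel <- select_controls(case[i, ], matrix(cfg[i, , ], 4, q))
    for (k in 1:3) ctrls[[k]][i, ] <- sel$controls[k, ]
  }
  clr_fit(case, ctrls)
}
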