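# Linear SNP-weight expression models: loading, allele harmonization and
# imputation of genetically regulated expression x = sum_j w_j d_j.

#' Read a SNP-weight table of expression/intron-usage models
#'
#' Canonical tab-delimited dialect with header columns: `gene`, `tissue`,
#' `feature_type` (`expression` or `intron_usage`), `cluster` (intron
#' cluster id or `.`), `chrom`, `pos`, `ref`, `alt`, `effect_allele`,
#' `weight`.  One model is formed per (gene, tissue, feature_type,
#' cluster) group; zero-weight predictors are dropped, rows whose effect
#' allele matches neither ref nor alt are rejected with a warning, and a
#' duplicated variant key within a model is an error.
#'
#' @param path weight table file.
#' @return list of `expr_model` objects (empty models are skipped).
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("cannot read weight table: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(gene = "character",
                                          tissue = "character",
                                          feature_type = "character",
                                          cluster = "character",
                                          chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          effect_allele = "character"))
  need <- c("gene", "tissue", "feature_type", "cluster", "chrom", "pos",
            "ref", "alt", "effect_allele", "weight")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("weight table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- tab$effect_allele != tab$ref & tab$effect_allele != tab$alt
  if (any(bad)) {
    warning(sum(bad), " weight row(s) rejected: effect allele matches ",
            "neither ref nor alt")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[is.finite(tab$weight) & tab$weight != 0, , drop = FALSE]
  grp <- interaction(tab$gene, tab$tissue, tab$feature_type, tab$cluster,
                     drop = TRUE)
  models <- lapply(split(tab, grp), function(g) {
    expr_model(gene = g$gene[1], tissue = g$tissue[1],
               feature_type = g$feature_type[1], cluster = g$cluster[1],
               predictors = data.frame(chrom = as.character(g$chrom),
                                       pos = as.integer(g$pos),
                                       ref = g$ref, alt = g$alt,
                                       effect_allele = g$effect_allele,
                                       weight = g$weight,
                                       stringsAsFactors = FALSE))
  })
  unname(models[!vapply(models, is.null, logical(1))])
}

#' Construct an expression model
#'
#' @param gene,tissue,feature_type,cluster model identifiers.
#' @param predictors data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `weight`.
#' @return `expr_model` object, or `NULL` for an empty predictor set.
#' @export
expr_model <- function(gene, tissue, feature_type = "expression",
                       cluster = ".", predictors) {
  predictors <- predictors[predictors$weight != 0, , drop = FALSE]
  if (!nrow(predictors)) return(NULL)
  key <- paste(predictors$chrom, predictors$pos, predictors$ref,
               predictors$alt, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate predictor variant in model for gene ", gene, ": ",
         key[duplicated(key)][1])
  stopifnot(all(is.finite(predictors$weight)))
  structure(list(gene = gene, tissue = tissue, feature_type = feature_type,
                 cluster = cluster, predictors = predictors,
                 harmonized = FALSE),
            class = "expr_model")
}

#' @export
print.expr_model <- function(x, ...) {
  cat("Expression model", x$gene, "/", x$tissue, "(", x$feature_type, "):",
      nrow(x$predictors), "predictor SNPs\n")
  invisible(x)
}

is_strand_ambiguous <- function(ref, alt) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  toupper(alt) == comp[toupper(ref)]
}

#' Harmonize an expression model with a genotype matrix
#'
#' Matches predictors to variants by (chrom, pos); where the effect allele
#' equals the alternate allele the weight applies to the alternate-allele
#' dosage directly, where it equals the reference allele the dosage is
#' complemented (d -> 2 - d) at scoring time.  Predictors absent from the
#' matrix are dropped and reported; strand-ambiguous pairs (A/T, C/G) are
#' dropped by default.  Harmonizing twice is a no-op.
#'
#' @param model an `expr_model`.
#' @param geno a [phased_geno()] object.
#' @param drop_ambiguous drop strand-ambiguous predictors (default TRUE).
#' @return Aligned `expr_model` with extra predictor column `complement`
#'   and attributes `var_index` (row index into `geno`) and `report`
#'   (dropped predictors with reasons), or `NULL` when every predictor is
#'   dropped (with a warning).
#' @export
harmonize_model <- function(model, geno, drop_ambiguous = TRUE) {
  stopifnot(inherits(model, "expr_model"), inherits(geno, "phased_geno"))
  if (isTRUE(model$harmonized)) return(model)
  pr <- model$predictors
  gk <- paste(geno$variants$chrom, geno$variants$pos, sep = ":")
  idx <- match(paste(pr$chrom, pr$pos, sep = ":"), gk)
  reason <- rep(NA_character_, nrow(pr))
  reason[is.na(idx)] <- "absent"
  ok <- !is.na(idx)
  if (any(ok)) {
    same <- pr$ref[ok] == geno$variants$ref[idx[ok]] &
      pr$alt[ok] == geno$variants$alt[idx[ok]]
    reason[ok][!same] <- "allele_mismatch"
    ambig <- is_strand_ambiguous(pr$ref[ok], pr$alt[ok]) & same & drop_ambiguous
    reason[ok][ambig] <- "strand_ambiguous"
  }
  keep <- is.na(reason)
  report <- data.frame(variant = paste(pr$chrom, pr$pos, pr$ref, pr$alt,
                                       sep = ":"),
                       reason = reason, stringsAsFactors = FALSE)
  report <- report[!keep, , drop = FALSE]
  if (!any(keep)) {
    warning("model ", model$gene, "/", model$tissue,
            ": all predictors dropped in harmonization; model unusable")
    return(NULL)
  }
  pr <- pr[keep, , drop = FALSE]
  pr$complement <- pr$effect_allele == pr$ref
  out <- model
  out$predictors <- pr
  out$harmonized <- TRUE
  attr(out, "var_index") <- idx[keep]
  attr(out, "report") <- report
  out
}

#' Fraction of absolute weight mass retained after harmonization
#'
#' Families or genes are dropped when more than `1 - threshold` of the
#' model's total |weight| is lost to missing predictors.
#'
#' @param model aligned model (after [harmonize_model()]).
#' @param original the model before harmonization.
#' @return numeric in \[0, 1\].
#' @export
weight_mass_retained <- function(model, original) {
  if (is.null(model)) return(0)
  sum(abs(model$predictors$weight)) / sum(abs(original$predictors$weight))
}

#' Impute genetically regulated expression
#'
#' Linear score `sum_j w_j d_j` with reference-allele complementation
#' (`d -> 2 - d`) applied where the aligned model flags it.
#'
#' @param model aligned `expr_model` (see [harmonize_model()]).
#' @param dosages numeric vector of alternate-allele dosages aligned to the
#'   model's predictors, or a matrix with one column per predictor (rows =
#'   individuals/configurations).
#' @return numeric scalar (vector input) or vector (matrix input).
#' @export
impute_expression <- function(model, dosages) {
  stopifnot(inherits(model, "expr_model"))
  pr <- model$predictors
  comp <- if (!is.null(pr$complement)) pr$complement else
    rep(FALSE, nrow(pr))
  if (is.matrix(dosages)) {
    if (ncol(dosages) != nrow(pr))
      stop("dosage length ", ncol(dosages), " does not match model (",
           nrow(pr), " predictors)")
    d <- dosages
    if (any(comp)) d[, comp] <- 2 - d[, comp]
    return(as.numeric(d %*% pr$weight))
  }
  if (length(dosages) != nrow(pr))
    stop("dosage length ", length(dosages), " does not match model (",
         nrow(pr), " predictors)")
  d <- as.numeric(dosages)
  d[comp] <- 2 - d[comp]
  sum(pr$weight * d)
}

#' Non-transmitted one-sibling expression
#'
#' The single pseudo sibling built from the two non-transmitted parental
#' haplotypes has imputed expression `father + mother - proband` (a direct
#' consequence of the linear score and dosage conservation).
#'
#' @param father,mother,proband imputed expression values on a common
#'   scale; vectorized.
#' @return numeric.
#' @export
one_sibling_expression <- function(father, mother, proband) {
  father + mother - proband
}

#' Standardize exposures within analysis groups
#'
#' Z-scores exposure values using the mean and population SD (divide by n)
#' over all values in each group — for TWAS, the probands plus their
#' retained pseudo siblings of one gene/tissue/cohort.  A zero-variance
#' group is set to 0 and flagged uninformative.
#'
#' @param values numeric vector (or matrix: standardized by column).
#' @param group optional grouping factor (vector input only).
#' @return numeric of the same shape with attribute `uninformative`
#'   (logical per group or column).
#' @export
standardize_exposures <- function(values, group = NULL) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  zscore <- function(v) {
    s <- pop_sd(v)
    if (s == 0) list(z = rep(0, length(v)), flat = TRUE)
    else list(z = (v - mean(v)) / s, flat = FALSE)
  }
  if (is.matrix(values)) {
    out <- values
    flat <- logical(ncol(values))
    for (j in seq_len(ncol(values))) {
      r <- zscore(values[, j])
      out[, j] <- r$z
      flat[j] <- r$flat
    }
    attr(out, "uninformative") <- flat
    return(out)
  }
  if (is.null(group)) {
    r <- zscore(values)
    return(structure(r$z, uninformative = r$flat))
  }
  group <- as.factor(group)
  out <- numeric(length(values))
  flat <- logical(nlevels(group))
  names(flat) <- levels(group)
  for (g in levels(group)) {
    i <- group == g
    r <- zscore(values[i])
    out[i] <- r$z
    flat[g] <- r$flat
  }
  structure(out, uninformative = flat)
}

#' Impute expression for a whole family
#'
#' Convenience wrapper returning the imputed expression of the proband,
#' the four pseudo-sibling configurations and both parents for one model.
#'
#' @param model aligned `expr_model`.
#' @param geno a [phased_geno()] object.
#' @param trio one-row trio data.frame.
#' @return list with `proband`, `configs` (length-4, order f1m1, f1m2,
#'   f2m1, f2m2), `father`, `mother`, and the underlying `pseudo_sib_set`.
#' @export
impute_family <- function(model, geno, trio) {
  idx <- attr(model, "var_index")
  if (is.null(idx)) stop("model must be harmonized against `geno` first")
  s <- pseudo_siblings(geno, trio, variants = idx)
  dos <- dosage(geno)[idx, , drop = FALSE]
  list(proband = impute_expression(model, as.numeric(s$proband)),
       configs = impute_expression(model, s$configs),
       father = impute_expression(model, as.numeric(dos[, trio$father])),
       mother = impute_expression(model, as.numeric(dos[, trio$mother])),
       set = s)
}
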