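# Gene-set and de novo mutation enrichment statistics, plus the
# coexpression and spatiotemporal permutation tests.

#' Hypergeometric gene-set enrichment of TWAS hits
#'
#' Tests whether association hits are over-represented in a pre-specified
#' gene set.  The set is first intersected with the analysis universe
#' (the genes actually tested); fold = observed / expected with
#' expected = |hits| x |set ∩ universe| / |universe|, and the p-value is
#' the exact upper tail P(X >= observed) of the hypergeometric
#' distribution.  Symbols are matched case-insensitively.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param gene_set character vector of set members.
#' @param universe character vector of all tested genes.
#' @return list with `overlap`, `expected`, `fold`, `p`, `set_size`
#'   (after intersection), `n_hits`, `n_universe`; `NA` values with a
#'   `reason` when the universe or intersection is empty.
#' @export
hypergeom_enrichment <- function(hits, gene_set, universe) {
  universe <- unique(toupper(universe))
  hits <- unique(toupper(hits))
  gene_set <- unique(toupper(gene_set))
  if (!length(universe))
    return(list(overlap = NA, expected = NA, fold = NA, p = NA,
                reason = "empty universe"))
  if (!all(hits %in% universe))
    stop("hit genes must be a subset of the universe")
  set_u <- intersect(gene_set, universe)
  if (!length(set_u))
    return(list(overlap = NA, expected = NA, fold = NA, p = NA,
                reason = "gene set does not intersect universe"))
  k <- length(intersect(hits, set_u))
  expected <- length(hits) * length(set_u) / length(universe)
  # upper tail P(X >= k), X ~ Hypergeom(white = |set|, black = rest, drawn = |hits|)
  p <- stats::phyper(k - 1, length(set_u),
                     length(universe) - length(set_u), length(hits),
                     lower.tail = FALSE)
  list(overlap = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_, p = p,
       set_size = length(set_u), n_hits = length(hits),
       n_universe = length(universe))
}

LOF_LABELS <- c("frameshift", "stop-gained", "splice-donor",
                "stop-gained-near-splice", "frameshift-near-splice",
                "stop-lost", "splice-acceptor")
MISSENSE_LABELS <- c("missense", "missense-near-splice")
SYNONYMOUS_LABELS <- c("synonymous", "synonymous-near-splice")

normalize_label <- function(label) {
  gsub("[ _]+", "-", tolower(trimws(label)))
}

#' Classify a de novo mutation by annotation label
#'
#' Controlled vocabulary: loss-of-function = frameshift, stop-gained,
#' splice-donor, stop-gained near splice, frameshift near splice,
#' stop-lost, splice-acceptor; missense = missense, missense near splice;
#' synonymous = synonymous, synonymous near splice.  A missense variant
#' with MPC strictly greater than 2 is additionally deleterious missense.
#' Unknown labels classify as `"other"` (counted, excluded from tests).
#'
#' @param label annotation label(s); spaces/underscores and case are
#'   normalized.
#' @param mpc optional MPC score(s), recycled.
#' @return character vector in `{"lof", "missense",
#'   "deleterious_missense", "synonymous", "other"}`, the most specific
#'   class per record.
#' @export
classify_mutation <- function(label, mpc = NA_real_) {
  lab <- normalize_label(label)
  mpc <- rep_len(mpc, length(lab))
  cls <- rep("other", length(lab))
  cls[lab %in% SYNONYMOUS_LABELS] <- "synonymous"
  mis <- lab %in% MISSENSE_LABELS
  cls[mis] <- "missense"
  cls[mis & !is.na(mpc) & mpc > 2] <- "deleterious_missense"
  cls[lab %in% LOF_LABELS] <- "lof"
  cls
}

#' Expected de novo mutation count in a gene set
#'
#' expected = scaling_factor x n_individuals x sum over set genes of the
#' per-class mutability mu.  The default factor 2 converts per-chromosome
#' mutation probabilities to diploid per-offspring expectations.  Genes
#' absent from the mutability table are reported and skipped.
#'
#' @param mutability data.frame with columns `gene`, `class`, `mu`.
#' @param gene_set character vector of genes.
#' @param n_individuals number of offspring (> 0).
#' @param class mutation class to look up (`"lof"`, `"missense"`,
#'   `"deleterious_missense"`, `"synonymous"`, `"all"`).
#' @param scaling_factor multiplier on n x sum(mu) (default 2).
#' @return numeric expected count with attribute `missing_genes`.
#' @export
expected_denovo_count <- function(mutability, gene_set, n_individuals,
                                  class = "lof", scaling_factor = 2) {
  if (n_individuals <= 0) stop("n_individuals must be positive")
  gene_set <- unique(toupper(gene_set))
  if (!length(gene_set))
    return(structure(0, missing_genes = character(0)))
  tab <- mutability[tolower(mutability$class) == tolower(class), ,
                    drop = FALSE]
  idx <- match(gene_set, toupper(tab$gene))
  missing_genes <- gene_set[is.na(idx)]
  if (length(missing_genes))
    warning(length(missing_genes),
            " gene(s) absent from mutability table skipped")
  mu <- tab$mu[idx[!is.na(idx)]]
  structure(scaling_factor * n_individuals * sum(mu),
            missing_genes = missing_genes)
}

#' Exact Poisson enrichment test
#'
#' fold = observed / expected; one-sided upper-tail
#' p = P(X >= observed | lambda = expected) evaluated exactly.
#'
#' @param observed non-negative integer count.
#' @param expected positive expected count.
#' @return list with `fold`, `p` (both `NA` when `expected <= 0`).
#' @export
poisson_enrichment <- function(observed, expected) {
  stopifnot(observed >= 0, observed == round(observed))
  if (!is.finite(expected) || expected <= 0)
    return(list(fold = NA_real_, p = NA_real_))
  list(fold = observed / expected,
       p = stats::ppois(observed - 1, lambda = expected,
                        lower.tail = FALSE))
}

#' Count observed de novo mutations per class in a gene set
#'
#' @param denovo data.frame with columns `gene`, `label` and optionally
#'   `mpc`.
#' @param gene_set character vector of genes.
#' @param class `"lof"`, `"missense"`, `"deleterious_missense"`,
#'   `"synonymous"` or `"all"` (union of the three base classes;
#'   unclassified labels never count).
#' @return integer count.
#' @export
count_denovo <- function(denovo, gene_set, class = "lof") {
  mpc <- if (!is.null(denovo$mpc)) denovo$mpc else NA_real_
  cls <- classify_mutation(denovo$label, mpc)
  in_set <- toupper(denovo$gene) %in% unique(toupper(gene_set))
  hit <- switch(class,
                all = cls != "other",
                missense = cls %in% c("missense", "deleterious_missense"),
                cls == class)
  sum(in_set & hit)
}

#' Coexpression permutation test against a focal gene
#'
#' Pearson correlation (with its t-test p-value) between the focal gene
#' and every set gene across samples; the number of set genes significant
#' after Bonferroni correction over the set is compared with a
#' permutation null obtained by shuffling the sample ids of the focal
#' gene's expression vector.  p = (r + 1)/(B + 1), r = permutations with
#' at least as many significant genes.
#'
#' @param expr numeric matrix, genes x samples (rownames = gene ids).
#' @param focal_gene focal gene id (row of `expr`).
#' @param gene_set character vector of set gene ids.
#' @param alpha per-test significance level before Bonferroni correction
#'   (default 0.05).
#' @param B number of permutations (default 10000).
#' @param seed RNG seed.
#' @param plus_one use the (r+1)/(B+1) correction (default TRUE; FALSE
#'   gives the raw proportion).
#' @return list with `cor` (data.frame gene/r/p; constant vectors give
#'   `NA`), `n_significant`, `perm_p`.
#' @export
coexpression_test <- function(expr, focal_gene, gene_set, alpha = 0.05,
                              B = 10000L, seed = 1L, plus_one = TRUE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  rn <- rownames(expr)
  if (!(focal_gene %in% rn)) stop("focal gene not in expression matrix")
  gene_set <- gene_set[gene_set %in% rn]
  if (!length(gene_set)) stop("no set gene present in expression matrix")
  x <- expr[focal_gene, ]
  Y <- expr[gene_set, , drop = FALSE]
  cut <- alpha / length(gene_set)
  cor_p <- function(xv) {
    apply(Y, 1, function(y) {
      if (stats::sd(y) == 0 || stats::sd(xv) == 0)
        return(c(NA_real_, NA_real_))
      ct <- stats::cor.test(xv, y)
      c(ct$estimate, ct$p.value)
    })
  }
  obs <- cor_p(x)
  n_sig <- sum(obs[2, ] < cut, na.rm = TRUE)
  set.seed(seed)
  r <- 0L
  for (b in seq_len(B)) {
    nb <- sum(cor_p(sample(x))[2, ] < cut, na.rm = TRUE)
    if (nb >= n_sig) r <- r + 1L
  }
  perm_p <- if (plus_one) (r + 1) / (B + 1) else r / B
  list(cor = data.frame(gene = gene_set, r = obs[1, ], p = obs[2, ],
                        significant = !is.na(obs[2, ]) & obs[2, ] < cut,
                        row.names = NULL, stringsAsFactors = FALSE),
       n_significant = n_sig, perm_p = perm_p, bonferroni_cutoff = cut)
}

#' Prenatal-vs-postnatal expression elevation permutation test
#'
#' Averages log2(RPKM+1) expression over samples of the same (region,
#' developmental stage), splits stages at a prenatal/postnatal boundary
#' (birth by default), and takes as statistic the mean over regions of
#' (mean prenatal stage-average - mean postnatal stage-average).  The
#' null permutes stage labels within each region.  One-sided
#' p = (r + 1)/(B + 1).  Regions lacking either side of the boundary are
#' dropped with a warning.
#'
#' @param values numeric vector of per-sample expression (log2(RPKM+1)).
#' @param region,stage per-sample region and developmental-stage labels
#'   (stage must be orderable; numeric stage recommended, e.g. age with
#'   birth = 0).
#' @param boundary stages `< boundary` are prenatal (default 0 = birth).
#' @param B number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `statistic`, `p`, `per_region` (data.frame of
#'   per-region prenatal and postnatal means), `n_regions`.
#' @export
spatiotemporal_elevation_test <- function(values, region, stage,
                                          boundary = 0, B = 10000L,
                                          seed = 1L) {
  stopifnot(length(values) == length(region),
            length(values) == length(stage))
  stage_avg <- stats::aggregate(
    values, by = list(region = region, stage = stage), FUN = mean)
  names(stage_avg)[3] <- "value"
  stat_of <- function(sa) {
    pre <- sa$stage < boundary
    per <- vapply(split(seq_len(nrow(sa)), sa$region), function(i) {
      if (!any(pre[i]) || !any(!pre[i])) return(NA_real_)
      mean(sa$value[i][pre[i]]) - mean(sa$value[i][!pre[i]])
    }, numeric(1))
    per
  }
  per <- stat_of(stage_avg)
  if (anyNA(per)) {
    warning(sum(is.na(per)),
            " region(s) without both prenatal and postnatal stages dropped")
    keep_regions <- names(per)[!is.na(per)]
    stage_avg <- stage_avg[stage_avg$region %in% keep_regions, ,
                           drop = FALSE]
    per <- per[!is.na(per)]
  }
  if (!length(per)) stop("no region with both prenatal and postnatal stages")
  obs <- mean(per)
  set.seed(seed)
  r <- 0L
  for (b in seq_len(B)) {
    sa <- stage_avg
    for (rg in unique(sa$region)) {
      i <- which(sa$region == rg)
      sa$stage[i] <- sa$stage[sample(i)]
    }
    if (mean(stat_of(sa), na.rm = TRUE) >= obs) r <- r + 1L
  }
  pre <- stage_avg$stage < boundary
  per_region <- do.call(rbind, lapply(split(stage_avg, stage_avg$region),
    function(sa) data.frame(region = sa$region[1],
                            prenatal = mean(sa$value[sa$stage < boundary]),
                            postnatal = mean(sa$value[sa$stage >= boundary]),
                            stringsAsFactors = FALSE)))
  list(statistic = obs, p = (r + 1) / (B + 1), per_region = per_region,
       n_regions = length(per))
}

#' Read a one-symbol-per-line gene-set file
#'
#' @param path text file, one gene symbol per line (blank lines and lines
#'   starting with `#` ignored).
#' @return character vector of unique, uppercased symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("cannot read gene set: ", path)
  x <- trimws(readLines(path))
  unique(toupper(x[nzchar(x) & !startsWith(x, "#")]))
}
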