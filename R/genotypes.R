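# Phased trio genotypes and pseudo-sibling construction.
#
# A cis-window of phased biallelic genotypes is held as a `phased_geno`
# object: a variant table plus two 0/1 haplotype matrices (variants x
# samples).  Under the no-crossover model a pseudo-offspring inherits one
# whole parental haplotype per parent across the window, so exactly four
# recombined offspring configurations exist per family: (paternal hap,
# maternal hap) in {1,2} x {1,2}.

CONFIG_LABELS <- c("f1m1", "f1m2", "f2m1", "f2m2")
CONFIG_PAIRS <- cbind(paternal = c(1L, 1L, 2L, 2L),
                      maternal = c(1L, 2L, 1L, 2L))

#' Construct a phased genotype matrix
#'
#' Low-level constructor used by [load_phased_vcf()] and the simulator.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param samples character vector of sample identifiers.
#' @param hap1,hap2 integer matrices (variants x samples) of 0/1 alleles for
#'   the first and second haplotype of each sample.
#' @param skipped named integer vector of counts of records excluded on
#'   loading (`multiallelic`, `unphased`, `missing`).
#' @return An object of class `phased_geno`.
#' @export
phased_geno <- function(variants, samples, hap1, hap2,
                        skipped = c(multiallelic = 0L, unphased = 0L,
                                    missing = 0L)) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            nrow(variants) == nrow(hap1), nrow(variants) == nrow(hap2),
            length(samples) == ncol(hap1), length(samples) == ncol(hap2))
  if (nrow(variants)) {
    stopifnot(all(variants$pos >= 1),
              all(hap1 %in% c(0L, 1L)), all(hap2 %in% c(0L, 1L)))
    key <- variant_key(variants)
    if (anyDuplicated(key))
      stop("duplicate variant key: ", key[duplicated(key)][1])
  }
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  colnames(hap1) <- colnames(hap2) <- samples
  structure(list(variants = variants, samples = samples,
                 hap1 = hap1, hap2 = hap2, skipped = skipped),
            class = "phased_geno")
}

#' @export
print.phased_geno <- function(x, ...) {
  cat("Phased genotype matrix:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  if (any(x$skipped > 0))
    cat("Skipped on load:",
        paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.phased_geno <- function(x) c(nrow(x$variants), length(x$samples))

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Allele dosage matrix
#'
#' @param geno a `phased_geno` object.
#' @return Integer matrix (variants x samples) of alternate-allele dosages
#'   (hap1 + hap2, values 0/1/2).
#' @export
dosage <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  geno$hap1 + geno$hap2
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4)
    stop("region must be 'chrom:start-end' (1-based inclusive): ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Load phased biallelic genotypes from a VCF file
#'
#' Reads a VCF with phased GT calls ("a|b") and keeps only biallelic
#' variants whose calls are fully phased and non-missing for the requested
#' samples.  Multiallelic, unphased and missing records are skipped and
#' counted.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param region optional region string `"chrom:start-end"`, 1-based
#'   inclusive.
#' @param samples optional character vector restricting the sample set; an
#'   absent sample is an error.
#' @return A [phased_geno()] object.  Zero retained variants yields an
#'   empty matrix with a warning, not an error.
#' @export
load_phased_vcf <- function(path, region = NULL, samples = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  all_samples <- colnames(gt)
  if (is.null(samples)) samples <- all_samples
  absent <- setdiff(samples, all_samples)
  if (length(absent))
    stop("sample(s) not present in VCF: ", paste(absent, collapse = ", "))
  gt <- gt[, samples, drop = FALSE]

  pos <- as.integer(fix$POS)
  keep_region <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep_region <- fix$CHROM == r$chrom & pos >= r$start & pos <= r$end
  }

  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  miss <- apply(gt, 1, function(g) any(is.na(g) | grepl("\\.", g)))
  unph <- !miss & apply(gt, 1, function(g) any(!grepl("\\|", g)))

  keep <- keep_region & !multi & !miss & !unph
  skipped <- c(multiallelic = sum(keep_region & multi),
               unphased = sum(keep_region & unph),
               missing = sum(keep_region & miss & !multi))

  if (!any(keep)) {
    warning("no phased biallelic variants retained",
            if (!is.null(region)) paste0(" in region ", region))
    empty <- data.frame(chrom = character(), pos = integer(),
                        id = character(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
    return(phased_geno(empty, samples,
                       matrix(integer(), 0, length(samples)),
                       matrix(integer(), 0, length(samples)), skipped))
  }

  gtk <- gt[keep, , drop = FALSE]
  h1 <- matrix(as.integer(substr(gtk, 1, 1)), nrow = nrow(gtk))
  h2 <- matrix(as.integer(substr(gtk, 3, 3)), nrow = nrow(gtk))
  variants <- data.frame(chrom = fix$CHROM[keep], pos = pos[keep],
                         id = ifelse(is.na(fix$ID[keep]), ".", fix$ID[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  phased_geno(variants, samples, h1, h2, skipped)
}

#' Read a PLINK FAM pedigree and extract trios
#'
#' @param path whitespace-delimited 6-column FAM file:
#'   FID IID father mother sex phenotype ("0" marks a missing parent;
#'   phenotype 2 = affected, 1 = unaffected in the PLINK convention).
#' @return data.frame with one row per individual.
#' @export
read_fam <- function(path) {
  if (!file.exists(path)) stop("cannot read FAM file: ", path)
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "phenotype"))
  fam$fid <- as.character(fam$fid)
  fam$iid <- as.character(fam$iid)
  fam$father <- as.character(fam$father)
  fam$mother <- as.character(fam$mother)
  fam
}

#' @rdname read_fam
#' @param fam data.frame as returned by `read_fam`.
#' @return `trios()`: data.frame with columns `family`, `proband`,
#'   `father`, `mother`, `sex`, `affected` — one row per offspring with
#'   both parents recorded.
#' @export
trios <- function(fam) {
  off <- fam[fam$father != "0" & fam$mother != "0", , drop = FALSE]
  bad <- off$iid == off$father | off$iid == off$mother |
    off$father == off$mother
  if (any(bad))
    stop("proband/father/mother ids not distinct in family ",
         paste(off$fid[bad], collapse = ", "))
  data.frame(family = off$fid, proband = off$iid, father = off$father,
             mother = off$mother, sex = off$sex,
             affected = off$phenotype == 2,
             stringsAsFactors = FALSE)
}

check_trio_samples <- function(geno, trio) {
  ids <- c(trio$proband, trio$father, trio$mother)
  if (anyDuplicated(ids))
    stop("proband/father/mother ids must be distinct in family ",
         trio$family)
  absent <- setdiff(ids, geno$samples)
  if (length(absent))
    stop("trio member(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
}

#' Generate the four pseudo-sibling genotype configurations for one trio
#'
#' Each configuration joins one whole paternal haplotype with one whole
#' maternal haplotype over the cis-window (no within-window crossover), in
#' the fixed order (f1,m1), (f1,m2), (f2,m1), (f2,m2).
#'
#' @param geno a [phased_geno()] object containing all three trio members.
#' @param trio one-row data.frame (or list) with `family`, `proband`,
#'   `father`, `mother`.
#' @param variants optional integer indices (or variant-key strings)
#'   selecting the cis-window; default all variants.
#' @return An object of class `pseudo_sib_set`: list with `family`,
#'   `configs` (4 x m dosage matrix, rows labelled by configuration),
#'   `haps` (the four (paternal, maternal) haplotype index pairs),
#'   `proband` (dosage vector), `match` (lowest configuration index whose
#'   dosages equal the proband's at every variant, or `NA`),
#'   `variant_key`.
#' @export
pseudo_siblings <- function(geno, trio, variants = NULL) {
  stopifnot(inherits(geno, "phased_geno"))
  check_trio_samples(geno, trio)
  idx <- resolve_variants(geno, variants)
  f1 <- geno$hap1[idx, trio$father]
  f2 <- geno$hap2[idx, trio$father]
  m1 <- geno$hap1[idx, trio$mother]
  m2 <- geno$hap2[idx, trio$mother]
  drop <- is.na(f1) | is.na(f2) | is.na(m1) | is.na(m2)
  if (any(drop)) {
    warning(sum(drop), " variant(s) with missing parental calls dropped ",
            "for family ", trio$family)
    idx <- idx[!drop]
    f1 <- f1[!drop]; f2 <- f2[!drop]; m1 <- m1[!drop]; m2 <- m2[!drop]
  }
  if (!length(idx))
    stop("no usable variants left in window for family ", trio$family)
  pat <- rbind(f1, f1, f2, f2)
  mat <- rbind(m1, m2, m1, m2)
  configs <- pat + mat
  rownames(configs) <- CONFIG_LABELS
  proband <- geno$hap1[idx, trio$proband] + geno$hap2[idx, trio$proband]
  matches <- which(rowSums(configs != rep(proband, each = 4)) == 0)
  structure(list(family = trio$family,
                 configs = configs,
                 haps = CONFIG_PAIRS,
                 proband = proband,
                 match = if (length(matches)) unname(matches[1]) else NA_integer_,
                 n_match = length(matches),
                 variant_key = variant_key(geno$variants[idx, , drop = FALSE])),
            class = "pseudo_sib_set")
}

resolve_variants <- function(geno, variants) {
  if (is.null(variants)) return(seq_len(nrow(geno$variants)))
  if (is.character(variants)) {
    idx <- match(variants, variant_key(geno$variants))
    if (anyNA(idx))
      stop("variant key(s) not found: ",
           paste(variants[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(variants)
}

#' @export
print.pseudo_sib_set <- function(x, ...) {
  cat("Pseudo-sibling set, family", x$family, "-", ncol(x$configs),
      "variants; proband matches configuration",
      if (is.na(x$match)) "NONE" else CONFIG_LABELS[x$match], "\n")
  invisible(x)
}

#' Mendelian/phase consistency report for pseudo-sibling sets
#'
#' With error-free phasing and no crossover, one of the four recombined
#' configurations must equal the proband's genotype exactly.  Families where
#' none does are flagged; for those, the per-variant mismatch count of the
#' best (closest) configuration is reported.
#'
#' @param sets list of `pseudo_sib_set` objects (a single set is accepted).
#' @return data.frame with columns `family`, `consistent`, `best_config`,
#'   `n_mismatch`.
#' @export
check_mendelian_consistency <- function(sets) {
  if (inherits(sets, "pseudo_sib_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    mism <- rowSums(s$configs != rep(s$proband, each = 4))
    best <- which.min(mism)
    data.frame(family = s$family, consistent = !is.na(s$match),
               best_config = CONFIG_LABELS[best],
               n_mismatch = as.integer(mism[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-variant pseudo-controls for trio GWAS
#'
#' At one biallelic variant, enumerates the four recombined offspring
#' alternate-allele counts, removes exactly one configuration whose count
#' equals the proband's (ties broken by lowest configuration index), and
#' returns the proband count plus the three remaining control counts.
#'
#' @inheritParams pseudo_siblings
#' @param variant single variant index or key.
#' @return list with `proband` (count), `controls` (3 counts), `excluded`
#'   (configuration label removed) and `ok`; `ok = FALSE` with the family
#'   flagged when no configuration matches the proband (phase error).
#' @export
snp_pseudo_controls <- function(geno, trio, variant) {
  s <- pseudo_siblings(geno, trio, variants = variant)
  counts <- as.integer(s$configs[, 1])
  p <- as.integer(s$proband[1])
  hit <- which(counts == p)
  if (!length(hit)) {
    warning("family ", trio$family, ": no configuration matches proband at ",
            s$variant_key, "; excluded from this variant")
    return(list(ok = FALSE, family = trio$family, proband = p,
                controls = NULL, excluded = NA_character_))
  }
  drop <- hit[1]
  list(ok = TRUE, family = trio$family, proband = p,
       controls = counts[-drop], excluded = CONFIG_LABELS[drop])
}

#' Serialize pseudo-sibling sets to long-format TSV
#'
#' Debug output: one row per (family, configuration, variant) with the
#' configuration dosage.
#'
#' @param sets list of `pseudo_sib_set` objects.
#' @param path output file.
#' @export
write_pseudo_sib_tsv <- function(sets, path) {
  if (inherits(sets, "pseudo_sib_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    m <- ncol(s$configs)
    data.frame(family = s$family,
               config = rep(CONFIG_LABELS, each = m),
               variant = rep(s$variant_key, times = 4),
               dosage = as.integer(t(s$configs)),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
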