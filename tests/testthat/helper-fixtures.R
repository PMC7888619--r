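# Fixtures are built in code at test time; nothing binary is stored.

# phased_geno for one trio from explicit haplotypes.
# hap lists: each member a 2-row matrix (hap x variant) of 0/1 alleles.
trio_geno <- function(proband, father, mother, chrom = "1",
                      pos = NULL, ref = "A", alt = "G") {
  m <- ncol(father)
  if (is.null(pos)) pos <- 100L * seq_len(m)
  variants <- data.frame(chrom = chrom, pos = pos,
                         id = paste0("v", seq_len(m)), ref = ref,
                         alt = alt, stringsAsFactors = FALSE)
  h1 <- cbind(proband[1, ], father[1, ], mother[1, ])
  h2 <- cbind(proband[2, ], father[2, ], mother[2, ])
  phased_geno(variants, c("P1", "F1", "M1"), h1, h2)
}

one_trio <- data.frame(family = "FAM1", proband = "P1", father = "F1",
                       mother = "M1", sex = 1L, affected = TRUE,
                       stringsAsFactors = FALSE)

# small VCF with filterable quirks: 3 clean phased records, one
# unphased, one multiallelic, one with a missing call
write_quirky_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1\t1|0",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0/1\t0|0\t0|0",
    "1\t400\trs4\tT\tC,G\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0",
    "1\t500\trs5\tA\tC\t.\tPASS\t.\tGT\t.|.\t0|0\t0|1",
    "2\t100\trs6\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1")
  writeLines(lines, path)
  path
}

# brute-force conditional log-likelihood for scalar exposure
oracle_loglik <- function(beta, case, ctrl) {
  sum(vapply(seq_along(case), function(i) {
    eta <- beta * c(case[i], ctrl[i, ])
    eta[1] - log(sum(exp(eta)))
  }, numeric(1)))
}

# fine-grid MLE + numerical-Hessian SE, independent of clr_fit
oracle_clr <- function(case, ctrl, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  x <- cbind(case, ctrl)
  ll <- numeric(length(grid))
  for (i in seq_along(case)) {
    eta <- outer(grid, x[i, ])
    ll <- ll + eta[, 1] - log(rowSums(exp(eta)))
  }
  bhat <- grid[which.max(ll)]
  h <- 1e-4
  d2 <- (oracle_loglik(bhat + h, case, ctrl) -
           2 * oracle_loglik(bhat, case, ctrl) +
           oracle_loglik(bhat - h, case, ctrl)) / h^2
  list(beta = bhat, se = 1 / sqrt(-d2))
}
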