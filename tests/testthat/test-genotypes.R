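# Phased genotype loading and pseudo-sibling construction.

test_that("load_phased_vcf keeps only fully phased biallelic records and counts skips", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_quirky_vcf(path)
  g <- load_phased_vcf(path)
  expect_s3_class(g, "phased_geno")
  expect_equal(dim(g), c(3L, 3L))                     # rs1, rs2, rs6 survive
  expect_equal(g$variants$id, c("rs1", "rs2", "rs6"))
  expect_equal(unname(g$skipped["unphased"]), 1L)
  expect_equal(unname(g$skipped["multiallelic"]), 1L)
  expect_equal(unname(g$skipped["missing"]), 1L)
  expect_equal(unname(dosage(g)[, "S1"]), c(1L, 0L, 2L))
})

test_that("region strings are 1-based inclusive and sample subsetting is checked", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_quirky_vcf(path)
  g <- load_phased_vcf(path, region = "1:100-200")
  expect_equal(g$variants$id, c("rs1", "rs2"))
  g2 <- load_phased_vcf(path, region = "1:200-200", samples = c("S1", "S2"))
  expect_equal(dim(g2), c(1L, 2L))
  expect_error(load_phased_vcf(path, samples = "S9"), "S9")
  expect_warning(ge <- load_phased_vcf(path, region = "1:900-999"),
                 "no phased biallelic")
  expect_equal(nrow(ge$variants), 0L)
})

test_that("round-trip through the simulator's VCF writer is lossless", {
  cfg <- sim_config(n_trios = 8, n_snps = 4, beta0 = 0, ascertain = FALSE,
                    seed = 11)
  dir <- withr::local_tempdir()
  ds <- simulate_twas_dataset(cfg, dir = dir)
  g <- load_phased_vcf(ds$files$vcf)
  expect_equal(g$hap1, ds$geno$hap1)
  expect_equal(g$hap2, ds$geno$hap2)
  expect_equal(g$variants$pos, ds$geno$variants$pos)
  fam <- read_fam(ds$files$fam)
  expect_equal(trios(fam), ds$trios)
})

test_that("four configurations pair whole parental haplotypes and conserve dosage", {
  # father haps (0|1), mother (0|0) at one SNP -> config dosages 0,0,1,1
  g <- trio_geno(proband = rbind(0L, 0L), father = rbind(0L, 1L),
                 mother = rbind(0L, 0L))
  s <- pseudo_siblings(g, one_trio)
  expect_equal(unname(s$configs[, 1]), c(0L, 0L, 1L, 1L))

  # two SNPs: brute-force enumeration of the 2x2 haplotype pairings
  fa <- rbind(c(0L, 1L), c(0L, 1L))     # f1 = (0,1), f2 = (0,1)
  mo <- rbind(c(1L, 0L), c(0L, 0L))     # m1 = (1,0), m2 = (0,0)
  g2 <- trio_geno(proband = rbind(c(0L, 1L), c(1L, 0L)),
                  father = fa, mother = mo)
  s2 <- pseudo_siblings(g2, one_trio)
  expected <- rbind(fa[1, ] + mo[1, ], fa[1, ] + mo[2, ],
                    fa[2, ] + mo[1, ], fa[2, ] + mo[2, ])
  expect_equal(unname(s2$configs), unname(expected))
  expect_equal(colSums(s2$configs),
               2 * (colSums(fa) + colSums(mo)))
  expect_equal(s2$match, 1L)            # proband = f1 + m1

  # proband carrying paternal hap 1 + maternal hap 2
  g3 <- trio_geno(proband = rbind(c(0L, 1L), c(0L, 0L)),
                  father = fa, mother = mo)
  expect_equal(pseudo_siblings(g3, one_trio)$match, 2L)   # (f1, m2)
})

test_that("pseudo-sibling sets are deterministic and Mendelian-closed", {
  cfg <- sim_config(n_trios = 12, n_snps = 6, beta0 = 0,
                    ascertain = FALSE, seed = 3)
  ds <- simulate_twas_dataset(cfg)
  for (i in seq_len(4)) {
    s <- pseudo_siblings(ds$geno, ds$trios[i, ])
    s_again <- pseudo_siblings(ds$geno, ds$trios[i, ])
    expect_identical(s, s_again)
    fd <- dosage(ds$geno)[, ds$trios$father[i]]
    md <- dosage(ds$geno)[, ds$trios$mother[i]]
    expect_equal(unname(colSums(s$configs)), unname(2 * (fd + md)))
    # closure: each configuration is Mendelian-compatible with parents
    for (k in 1:4)
      expect_true(all(s$configs[k, ] >= pmax(0, fd + md - 2) &
                        s$configs[k, ] <= pmin(2, fd + md)))
  }
})

test_that("consistency report flags phase errors with best-configuration mismatch counts", {
  cfg <- sim_config(n_trios = 10, n_snps = 5, beta0 = 0,
                    ascertain = FALSE, seed = 21)
  ds <- simulate_twas_dataset(cfg)
  sets <- lapply(seq_len(10), function(i)
    pseudo_siblings(ds$geno, ds$trios[i, ]))
  rep <- check_mendelian_consistency(sets)
  expect_true(all(rep$consistent))           # simulator injects no errors
  expect_true(all(rep$n_mismatch == 0L))

  # flip one proband allele at one heterozygous-in-parents SNP
  g <- trio_geno(proband = rbind(c(1L, 0L), c(0L, 0L)),
                 father = rbind(c(1L, 0L), c(0L, 1L)),
                 mother = rbind(c(0L, 0L), c(0L, 0L)))
  g$hap1[1, "P1"] <- 0L                      # flip
  bad <- pseudo_siblings(g, one_trio)
  r <- check_mendelian_consistency(bad)
  expect_false(r$consistent)
  expect_equal(r$n_mismatch, 1L)

  # homozygous-identical parents: all configurations equal the proband
  g4 <- trio_geno(proband = rbind(1L, 1L), father = rbind(1L, 1L),
                  mother = rbind(1L, 1L))
  s4 <- pseudo_siblings(g4, one_trio)
  expect_equal(s4$n_match, 4L)
  expect_equal(s4$match, 1L)                 # lowest-index tie-break
  expect_true(check_mendelian_consistency(s4)$consistent)
})

test_that("single-variant pseudo-controls remove exactly one proband-identical count", {
  # father 0|1, mother 0|1, proband count 2 -> controls 0,1,1
  g <- trio_geno(proband = rbind(1L, 1L), father = rbind(0L, 1L),
                 mother = rbind(0L, 1L))
  r <- snp_pseudo_controls(g, one_trio, 1L)
  expect_true(r$ok)
  expect_equal(r$proband, 2L)
  expect_equal(sort(r$controls), c(0L, 1L, 1L))
  expect_equal(r$proband + sum(r$controls), 2L * (1L + 1L))

  # both parents 0|0: uninformative set
  g0 <- trio_geno(proband = rbind(0L, 0L), father = rbind(0L, 0L),
                  mother = rbind(0L, 0L))
  r0 <- snp_pseudo_controls(g0, one_trio, 1L)
  expect_equal(r0$controls, c(0L, 0L, 0L))

  # father 1|1, mother 0|0: all configurations have count 1
  g1 <- trio_geno(proband = rbind(1L, 0L), father = rbind(1L, 1L),
                  mother = rbind(0L, 0L))
  r1 <- snp_pseudo_controls(g1, one_trio, 1L)
  expect_equal(r1$controls, c(1L, 1L, 1L))
  expect_equal(r1$excluded, "f1m1")          # tie-break: lowest index

  # phase-error family flagged at this variant
  gx <- trio_geno(proband = rbind(1L, 1L), father = rbind(0L, 0L),
                  mother = rbind(0L, 0L))
  expect_warning(rx <- snp_pseudo_controls(gx, one_trio, 1L),
                 "no configuration")
  expect_false(rx$ok)
})

test_that("long-format serialization round-trips dosages", {
  g <- trio_geno(proband = rbind(c(0L, 1L), c(1L, 0L)),
                 father = rbind(c(0L, 1L), c(1L, 0L)),
                 mother = rbind(c(1L, 0L), c(0L, 0L)))
  s <- pseudo_siblings(g, one_trio)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pseudo_sib_tsv(s, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 8L)                # 4 configs x 2 variants
  expect_equal(tab$dosage[tab$config == "f1m1"],
               unname(s$configs[1, ]))
})
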