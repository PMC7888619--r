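# Gene-set, de novo mutation, coexpression and spatiotemporal tests.

test_that("hypergeometric enrichment matches naive tail summation", {
  universe <- paste0("g", 1:100)
  hits <- paste0("g", 1:10)
  gene_set <- paste0("g", c(1:5, 40:54))      # 20 genes, 5 overlap hits
  r <- hypergeom_enrichment(hits, gene_set, universe)
  expect_equal(r$overlap, 5L)
  expect_equal(r$expected, 10 * 20 / 100)
  expect_equal(r$fold, 2.5)
  naive <- sum(vapply(5:10, function(k)
    choose(20, k) * choose(80, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(r$p, naive, tolerance = 1e-12)
  # monotone decreasing in overlap at fixed margins
  ps <- vapply(1:8, function(k) {
    hs <- paste0("g", c(1:k, 60:(69 - k)))
    hypergeom_enrichment(hs, paste0("g", 1:20), universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # hits = universe: overlap is the whole set and p = 1
  r2 <- hypergeom_enrichment(universe, gene_set, universe)
  expect_equal(r2$overlap, 20L)
  expect_equal(r2$p, 1)
  expect_match(hypergeom_enrichment(character(0), gene_set,
                                    character(0))$reason, "universe")
})

test_that("mutation classes follow the label vocabulary and the strict MPC rule", {
  expect_equal(classify_mutation("frameshift near splice"), "lof")
  expect_equal(classify_mutation("stop-gained"), "lof")
  expect_equal(classify_mutation("splice_acceptor"), "lof")
  expect_equal(classify_mutation("missense", mpc = 2.5),
               "deleterious_missense")
  expect_equal(classify_mutation("missense", mpc = 2.0), "missense")
  expect_equal(classify_mutation("missense"), "missense")
  expect_equal(classify_mutation("synonymous-near-splice"), "synonymous")
  expect_equal(classify_mutation("intronic"), "other")
  expect_equal(classify_mutation(c("missense", "stop-lost"), c(3, NA)),
               c("deleterious_missense", "lof"))
})

test_that("expected de novo counts scale as factor * n * sum(mu)", {
  mut <- data.frame(gene = c("A", "B", "C"), class = "lof",
                    mu = c(4e-5, 6e-5, 1e-3))
  e <- expected_denovo_count(mut, c("A", "B"), 2508, class = "lof")
  expect_equal(as.numeric(e), 2 * 2508 * 1e-4)
  expect_equal(as.numeric(e), 0.5016)
  e1 <- expected_denovo_count(mut, c("A", "B"), 2508, class = "lof",
                              scaling_factor = 1)
  expect_equal(as.numeric(e) / as.numeric(e1), 2)
  expect_equal(as.numeric(expected_denovo_count(mut, character(0), 10)), 0)
  expect_warning(em <- expected_denovo_count(mut, c("A", "ZZZ"), 10),
                 "absent")
  expect_equal(attr(em, "missing_genes"), "ZZZ")
  expect_error(expected_denovo_count(mut, "A", 0), "positive")
})

test_that("Poisson enrichment equals naive tail summation", {
  r <- poisson_enrichment(10, 5)
  expect_equal(r$fold, 2)
  naive <- 1 - sum(exp(-5) * 5^(0:9) / factorial(0:9))
  expect_equal(r$p, naive, tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0318)
  r0 <- poisson_enrichment(0, 2)
  expect_equal(r0$fold, 0)
  expect_equal(r0$p, 1)
  expect_equal(poisson_enrichment(4, 4)$fold, 1)
  expect_true(is.na(poisson_enrichment(3, 0)$p))
  # monotone decreasing in observed at fixed expected
  ps <- vapply(0:12, function(k) poisson_enrichment(k, 4)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("observed de novo counting respects classes and the 'all' union", {
  dn <- data.frame(gene = c("A", "A", "B", "C", "A"),
                   label = c("missense", "stop-gained", "synonymous",
                             "missense", "intronic"),
                   mpc = c(2.5, NA, NA, 1.0, NA))
  set <- c("A", "B")
  expect_equal(count_denovo(dn, set, "lof"), 1L)
  expect_equal(count_denovo(dn, set, "missense"), 1L)
  expect_equal(count_denovo(dn, set, "deleterious_missense"), 1L)
  expect_equal(count_denovo(dn, set, "synonymous"), 1L)
  expect_equal(count_denovo(dn, set, "all"), 3L)   # 'other' never counts
})

test_that("coexpression permutation test detects planted correlation and stays calibrated", {
  set.seed(50)
  n <- 30
  expr <- matrix(rnorm(27 * n), 27, n,
                 dimnames = list(c("FOCAL", paste0("g", 1:26)), NULL))
  # duplicate of the focal gene correlates perfectly
  expr["g1", ] <- expr["FOCAL", ]
  r <- coexpression_test(expr, "FOCAL", paste0("g", 1:26), B = 200,
                         seed = 3)
  expect_equal(r$cor$r[r$cor$gene == "g1"], 1)
  expect_gte(r$perm_p, 1 / 201)
  # plant strong correlation in 5 set genes
  for (g in paste0("g", 2:6))
    expr[g, ] <- 0.9 * expr["FOCAL", ] + sqrt(1 - 0.81) * rnorm(n)
  r2 <- coexpression_test(expr, "FOCAL", paste0("g", 1:26), B = 500,
                          seed = 3)
  expect_gte(r2$n_significant, 5)
  expect_lt(r2$perm_p, 0.01)
  # constant gene gives NA, not an error
  expr["g7", ] <- 1
  r3 <- coexpression_test(expr, "FOCAL", paste0("g", 1:26), B = 50,
                          seed = 3)
  expect_true(is.na(r3$cor$r[r3$cor$gene == "g7"]))
})

test_that("spatiotemporal test finds planted prenatal elevation and drops bad regions", {
  set.seed(51)
  regions <- rep(c("CBC", "STR", "HIP", "MD", "AMY"), each = 12)
  stages <- rep(c(-20, -10, -2, 1, 12, 40), times = 10)  # months vs birth
  vals <- rnorm(60, mean = 5)
  pre <- stages < 0
  r_null <- spatiotemporal_elevation_test(vals, regions, stages, B = 400,
                                          seed = 4)
  expect_gt(r_null$p, 0.05)
  vals2 <- vals + 2 * pre                       # +2 log2 units prenatally
  r <- spatiotemporal_elevation_test(vals2, regions, stages, B = 2000,
                                     seed = 4)
  expect_equal(r$statistic, r_null$statistic + 2, tolerance = 1e-10)
  expect_lte(r$p, 0.001 + 1 / 2001)
  expect_equal(r$n_regions, 5L)
  # region with only postnatal samples is dropped with a warning
  keep <- !(regions == "AMY" & stages < 0)
  expect_warning(
    r2 <- spatiotemporal_elevation_test(vals2[keep], regions[keep],
                                        stages[keep], B = 100, seed = 4),
    "dropped")
  expect_equal(r2$n_regions, 4L)
})

test_that("gene-set files are read one symbol per line, case-folded", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "Chd8", "SCN2A", "", "chd8"), path)
  expect_equal(read_gene_set(path), c("CHD8", "SCN2A"))
})
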