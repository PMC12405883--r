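test_that("CNV matrix conserves class and chromosome counts", {
  rec <- data.frame(gene_id = paste0("n", 1:5), genotype = "g1",
                    nlr_class = c("NL", "NL", "CNL", "TNL", "RNL"),
                    complete = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  genes <- make_genes((1:5) * 1000L, (1:5) * 1000L + 100L,
                      chrom = c("Chr1", "Chr1", "Chr2", "Chr2", "Chr2"),
                      prefix = "n")
  m <- build_cnv_matrix(rec, genes, genotypes = "g1")
  expect_equal(m$total, 5L)
  expect_equal(m$NL + m$CNL + m$TNL + m$RNL, m$total)
  expect_equal(m$Chr1 + m$Chr2, m$total)
  # a genotype absent from the records still gets an all-zero row
  m2 <- build_cnv_matrix(rec, genes, genotypes = c("g1", "g2"))
  expect_equal(m2$total[m2$genotype == "g2"], 0L)
})

test_that("the CNV split matches brute-force 2-partition minimisation", {
  totals <- c(a = 80, b = 85, c = 95, d = 300, e = 310)
  g <- assign_cnv_groups(totals)
  expect_equal(unname(g[c("a", "b", "c")]), rep("LowCNV", 3))
  expect_equal(unname(g[c("d", "e")]), rep("HighCNV", 2))
  expect_gt(attr(g, "gap"), 0.8)
  expect_warning(assign_cnv_groups(c(a = 5, b = 5)), "equal")

  # oracle: enumerate every 2-subset, minimise within-group sum of squares
  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    x <- stats::setNames(sample.int(400, n), paste0("g", seq_len(n)))
    if (length(unique(x)) < 2) next
    best <- NULL
    for (mask in 1:(2^n - 2)) {
      inA <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      wss <- sum((x[inA] - mean(x[inA]))^2) +
        sum((x[!inA] - mean(x[!inA]))^2)
      if (is.null(best) || wss < best$wss - 1e-9) best <- list(wss = wss, inA = inA)
    }
    hi_oracle <- if (mean(x[best$inA]) > mean(x[!best$inA])) best$inA else !best$inA
    got <- assign_cnv_groups(x)
    expect_equal(unname(got == "HighCNV"), unname(hi_oracle))
  }
})

test_that("group summaries compute SEM, CI and the high-low difference", {
  gs <- group_summary(c(1, 2, 3, 10, 11, 12),
                      rep(c("LowCNV", "HighCNV"), each = 3))
  expect_equal(gs$LowCNV$mean, 2)
  expect_equal(gs$LowCNV$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(gs$mean_difference, 9)
  expect_true(gs$LowCNV$ci95[1] < 2 && gs$LowCNV$ci95[2] > 2)
  # printed-group identity: means 314.86 vs 89.75 differ by 225.11
  gp <- group_summary(c(314.86, 89.75), c("HighCNV", "LowCNV"))
  expect_equal(gp$mean_difference, 225.11)
  expect_true(is.na(gp$HighCNV$sem))
})

test_that("exact Mann-Whitney equals full enumeration and wilcox.test", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 labelings are as extreme
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p, 1)
  r2 <- mann_whitney(101:107, 1:4)
  expect_equal(r2$p, 2 / choose(11, 4), tolerance = 1e-12)

  set.seed(55)
  for (nx in 1:4) {
    for (ny in nx:(8 - nx)) {
      if (ny < 1) next
      x <- sample(seq(0, 1, by = 1e-4), nx)
      y <- sample(seq(2, 3, by = 1e-4), ny) - runif(1, 0, 2.5)
      got <- mann_whitney(x, y)
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                                 correct = FALSE))
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
      expect_equal(got$U, unname(ref$statistic))
    }
  }
  # large samples fall back to the tie-corrected normal approximation
  big <- mann_whitney(rnorm(20), rnorm(20) + 2)
  expect_equal(big$method, "normal")
  expect_lt(big$p, 0.01)
})

test_that("phenotype scoring maps categories and classes the mean", {
  expect_equal(phenotype_score(c("susceptible", "susceptible")),
               list(mean = 1, class = "susceptible"))
  expect_equal(phenotype_score(c("moderately resistant", "resistant")),
               list(mean = 3.5, class = "resistant"))
  expect_equal(phenotype_score(c("moderately susceptible",
                                 "moderately resistant"))$class,
               "unclassified")
  expect_equal(phenotype_score(character(0))$class, "no_information")
  expect_error(phenotype_score("intermediate"), "unknown rating")
})

test_that("complete/partial proportions and chi-square match references", {
  # counts from the two CNV groups: 24/335 vs 103/2101 complete NLRs
  rec <- data.frame(
    gene_id = paste0("n", 1:2436),
    genotype = c(rep("lo", 335), rep("hi", 2101)),
    complete = c(rep(c(TRUE, FALSE), c(24, 311)),
                 rep(c(TRUE, FALSE), c(103, 1998))),
    stringsAsFactors = FALSE)
  groups <- c(lo = "LowCNV", hi = "HighCNV")
  cp <- complete_partial_table(rec, groups)
  expect_equal(unname(cp$proportions["LowCNV"]), 24 / 335)
  expect_equal(unname(cp$proportions["HighCNV"]), 103 / 2101)
  expect_gt(cp$p, 0.05)
  # Monte Carlo reference on the same margins
  set.seed(4)
  sim <- stats::r2dtable(4000, rowSums(cp$table), colSums(cp$table))
  stat <- function(tb) {
    e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    sum((tb - e)^2 / e)
  }
  p_mc <- mean(vapply(sim, stat, numeric(1)) >= cp$statistic - 1e-9)
  expect_equal(cp$p, p_mc, tolerance = 0.03)
  # identical proportions give a zero statistic
  rec0 <- rec
  rec0$complete <- rep(c(TRUE, FALSE), length.out = nrow(rec0))
  rec0$complete[rec0$genotype == "lo"] <-
    rep(c(TRUE, FALSE), length.out = 335)
  tab0 <- complete_partial_table(
    data.frame(gene_id = 1:8, genotype = rep(c("lo", "hi"), each = 4),
               complete = rep(c(TRUE, FALSE), 4), stringsAsFactors = FALSE),
    groups)
  expect_equal(tab0$statistic, 0, tolerance = 1e-12)
})

test_that("the count GLM recovers a planted group effect", {
  set.seed(9)
  counts <- data.frame(
    count = c(stats::rnbinom(40, mu = 10, size = 5),
              stats::rnbinom(40, mu = 30, size = 5)),
    group = rep(c("LowCNV", "HighCNV"), each = 40),
    class = "NL", stringsAsFactors = FALSE)
  counts$group <- stats::relevel(factor(counts$group), "LowCNV")
  fit <- report_glms(counts)
  expect_true(fit$converged)
  co <- fit$coefficients
  hi <- grep("HighCNV", rownames(co))
  expect_gt(co[hi, "Estimate"], 0)
  expect_lt(co[hi, "Pr(>|z|)"], 0.01)
  expect_error(report_glms(counts[0, ]), "nrow")
})
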