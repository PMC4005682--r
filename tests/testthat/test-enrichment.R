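test_that("hypergeometric enrichment matches tail summation and Fisher", {
  expect_equal(hypergeomEnrichment(0, 10, 50, 1000), 1)
  expect_equal(hypergeomEnrichment(7, 20, 7, 20), 1)  # draws = population
  expect_equal(hypergeomEnrichment(5, 10, 10, 100),
               tailSumHyper(5, 10, 10, 100))
  set.seed(55)
  for (i in 1:500) {
    n <- sample(4:200, 1)
    X <- sample.int(n, 1)
    n_i <- sample.int(n, 1)
    ks <- max(0, n_i + X - n):min(n_i, X)  # feasible 2x2 tables only
    x_i <- ks[sample.int(length(ks), 1)]
    p <- hypergeomEnrichment(x_i, n_i, X, n)
    expect_equal(p, tailSumHyper(x_i, n_i, X, n), tolerance = 1e-10)
    f <- stats::fisher.test(
      matrix(c(x_i, X - x_i, n_i - x_i, n - n_i - (X - x_i)), 2),
      alternative = "greater")$p.value
    expect_equal(p, f, tolerance = 1e-10)
  }
  expect_error(hypergeomEnrichment(5, 4, 10, 100), "x_i")
  expect_error(hypergeomEnrichment(1, 2, 10, 5), "n_i <= n")
})

test_that("enrichment p is monotone in x_i and in X", {
  ps <- hypergeomEnrichment(0:10, 10, 50, 500)
  expect_true(all(diff(ps) <= 0))
  pX <- vapply(seq(20, 300, 20),
               function(X) hypergeomEnrichment(5, 10, X, 500), 0)
  expect_true(all(diff(pX) >= 0))
})

test_that("censoring scales counts conservatively", {
  cc <- censorCounts(50, 100, 30)
  expect_equal(cc$x, 15); expect_equal(cc$n, 30); expect_true(cc$censored)
  cc2 <- censorCounts(5, 20, 30)
  expect_equal(cc2$x, 5); expect_equal(cc2$n, 20); expect_false(cc2$censored)
  # censoring reduces significance at a fixed background rate
  n <- 1e6; X <- 1e5
  expect_gt(hypergeomEnrichment(15, 30, X, n),
            hypergeomEnrichment(50, 100, X, n))
})

test_that("BH/BY adjustment matches the definitional step-up oracle", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04), "by"),
               rep(0.04 * 25 / 12, 4))
  expect_equal(adjustFdr(0.37, "bh"), 0.37)
  set.seed(77)
  for (len in 1:12) for (r in 1:20) {
    p <- runif(len)^sample(1:3, 1)
    expect_equal(adjustFdr(p, "bh"), stepUpBH(p), tolerance = 1e-12)
    expect_equal(adjustFdr(p, "by"), stepUpBY(p), tolerance = 1e-12)
  }
  expect_error(adjustFdr(c(0.5, 1.2), "bh"), "0, 1")
})

# a deterministic classification fixture: 100 probes, 10 up, 10 down
fixedCls <- function() {
  lab <- factor(rep(c("up", "down", "none"), c(10, 10, 80)),
                levels = c("up", "down", "none"))
  names(lab) <- sprintf("p%03d", 1:100)
  new("ProbeClassification", label = lab, alpha = 0.05,
      mode = "two_group", design = twoGroupDesign("a", "b"))
}

test_that("testTargets computes per-direction enrichment with both tails", {
  cls <- fixedCls()
  # gene1 holds the 10 up probes + 10 unchanged; gene2 the rest
  ann <- ProbeAnnotation(sprintf("p%03d", 1:100),
                         rep(c("gene1", "gene2", "gene1", "gene2"),
                             c(10, 10, 10, 70)), "gene")
  res <- testTargets(cls, ann, u = NULL, t = 1, fdr_method = "bh")
  t <- as.data.frame(res)
  expect_equal(nrow(t), 4L)  # 2 targets x 2 directions
  g1up <- t[t$target_id == "gene1" & t$direction == "up", ]
  expect_equal(g1up$probes_total, 20L)
  expect_equal(g1up$probes_signif, 10L)
  expect_equal(g1up$p_value, tailSumHyper(10, 20, 10, 100))
  g1dn <- t[t$target_id == "gene1" & t$direction == "down", ]
  expect_equal(g1dn$probes_signif, 0L)
  expect_equal(g1dn$p_value, 1)
  expect_equal(unlist(background(res)[c("n", "X_up", "X_down")],
                      use.names = FALSE), c(100L, 10L, 10L))
})

test_that("multiplicity filter removes probes from counts and background", {
  cls <- fixedCls()
  # p001 maps to both genes -> with t=1 it must vanish everywhere
  ann <- ProbeAnnotation(c(sprintf("p%03d", 1:100), "p001"),
                         c(rep(c("gene1", "gene2"), c(20, 80)), "gene2"),
                         "gene")
  res <- testTargets(cls, ann, u = NULL, t = 1)
  t <- as.data.frame(res)
  expect_equal(background(res)$n, 99L)
  expect_equal(background(res)$X_up, 9L)
  expect_equal(t$probes_total[t$target_id == "gene1" & t$direction == "up"], 19L)
  expect_equal(t$probes_total[t$target_id == "gene2" & t$direction == "up"], 80L)
  # with t=2 the probe is kept in both genes
  res2 <- testTargets(cls, ann, u = NULL, t = 2)
  t2 <- as.data.frame(res2)
  expect_equal(t2$probes_total[t2$target_id == "gene2" & t2$direction == "up"], 81L)
  expect_equal(background(res2)$n, 100L)
})

test_that("unclassified targets get p = 1 in both directions", {
  cls <- fixedCls()
  ann <- ProbeAnnotation(sprintf("p%03d", 30:50), "geneN", "gene")
  t <- as.data.frame(testTargets(cls, ann, u = NULL, t = 1))
  expect_true(all(t$p_value == 1))
  expect_false(any(t$significant))
})

test_that("censoring is applied inside testTargets when n_i > u", {
  cls <- fixedCls()
  ann <- ProbeAnnotation(sprintf("p%03d", 1:100), "big", "gene")
  t <- as.data.frame(testTargets(cls, ann, u = 30, t = NULL))
  expect_true(all(t$censored))
  up <- t[t$direction == "up", ]
  expect_equal(up$n_censored, 30L)
  expect_equal(up$x_censored, as.integer(floor(10 * 30 / 100)))
})

test_that("direction relabeling swaps the up/down result lists exactly", {
  cls <- fixedCls()
  swapped <- cls
  lv <- swapped@label
  lv2 <- factor(c(up = "down", down = "up", none = "none")[as.character(lv)],
                levels = c("up", "down", "none"))
  names(lv2) <- names(lv)
  swapped@label <- lv2
  ann <- ProbeAnnotation(sprintf("p%03d", 1:100),
                         rep(c("gene1", "gene2"), c(20, 80)), "gene")
  r1 <- as.data.frame(testTargets(cls, ann, u = NULL, t = 1))
  r2 <- as.data.frame(testTargets(swapped, ann, u = NULL, t = 1))
  up1 <- r1[r1$direction == "up", c("target_id", "p_value", "fdr")]
  dn2 <- r2[r2$direction == "down", c("target_id", "p_value", "fdr")]
  rownames(up1) <- rownames(dn2) <- NULL
  expect_identical(up1, dn2)
})

test_that("parameter errors and missing-probe preconditions are enforced", {
  cls <- fixedCls()
  ann <- ProbeAnnotation("pZZZ", "geneX", "gene")
  expect_error(testTargets(cls, ann), "pZZZ")
  ann2 <- ProbeAnnotation("p001", "geneX", "gene")
  expect_error(testTargets(cls, ann2, t = 0), "t must be")
  expect_error(testTargets(cls, ann2, u = 0), "u must be")
})

test_that("exon-within-gene uses the parent gene as background", {
  # gene with 30 probes, 15 up; exon = 5 probes, all up
  lab <- factor(rep(c("up", "none"), c(15, 15)), levels = c("up", "down", "none"))
  names(lab) <- sprintf("p%03d", 1:30)
  cls <- new("ProbeClassification", label = lab, alpha = 0.05,
             mode = "two_group", design = twoGroupDesign("a", "b"))
  ann <- ProbeAnnotation(
    probe_id = c(sprintf("p%03d", 1:30), sprintf("p%03d", 1:5),
                 sprintf("p%03d", 26:30)),
    target_id = c(rep("geneG", 30), rep("exon1", 5), rep("exon2", 5)),
    target_type = c(rep("gene", 30), rep("exon", 10)),
    parent_gene_id = c(rep(NA, 30), rep("geneG", 10)))
  t <- as.data.frame(testExonsWithinGene(cls, ann, u = NULL, t = NULL))
  e1 <- t[t$target_id == "exon1" & t$direction == "up", ]
  expect_equal(e1$p_value, choose(15, 5) / choose(30, 5))
  expect_equal(e1$p_value, 0.0211, tolerance = 2e-3)
  # exon whose probes are all unchanged: upper tail at 0 -> p = 1
  e2 <- t[t$target_id == "exon2" & t$direction == "up", ]
  expect_equal(e2$p_value, 1)
})

test_that("exon equal to its gene and unclassified genes give p = 1", {
  lab <- factor(rep("none", 10), levels = c("up", "down", "none"))
  names(lab) <- sprintf("p%03d", 1:10)
  cls <- new("ProbeClassification", label = lab, alpha = 0.05,
             mode = "two_group", design = twoGroupDesign("a", "b"))
  ann <- ProbeAnnotation(
    probe_id = c(sprintf("p%03d", 1:10), sprintf("p%03d", 1:10)),
    target_id = c(rep("geneG", 10), rep("exonAll", 10)),
    target_type = rep(c("gene", "exon"), each = 10),
    parent_gene_id = c(rep(NA, 10), rep("geneG", 10)))
  t <- as.data.frame(testExonsWithinGene(cls, ann, u = NULL, t = NULL))
  expect_true(all(t$p_value == 1))
  # exon probes outside the gene's probe set are rejected
  bad <- ProbeAnnotation(
    probe_id = c(sprintf("p%03d", 1:5), sprintf("p%03d", 4:10)),
    target_id = c(rep("geneG", 5), rep("exonX", 7)),
    target_type = c(rep("gene", 5), rep("exon", 7)),
    parent_gene_id = c(rep(NA, 5), rep("geneG", 7)))
  expect_error(testExonsWithinGene(cls, bad, u = NULL, t = NULL),
               "outside its parent gene")
})

test_that("gene-set enrichment treats genes as probes with BY default", {
  calls <- factor(rep(c("up", "none"), c(100, 900)),
                  levels = c("up", "down", "none"))
  names(calls) <- sprintf("g%04d", 1:1000)
  sets <- ProbeAnnotation(
    probe_id = c(sprintf("g%04d", c(1:5, 500:504)), sprintf("g%04d", 200:209),
                 "absent1", "absent2"),
    target_id = c(rep("setA", 10), rep("setB", 10), rep("setC", 2)),
    target_type = "gene_set")
  expect_warning(res <- testGeneSets(calls, sets), "no gene in the universe")
  t <- as.data.frame(res)
  a <- t[t$target_id == "setA" & t$direction == "up", ]
  expect_equal(a$p_value, tailSumHyper(5, 10, 100, 1000))
  expect_equal(a$p_value, 2.1e-4, tolerance = 0.05)
  expect_equal(a$fdr_method, "by")
  expect_false("setC" %in% t$target_id)
  # no up genes -> all sets p = 1
  none <- factor(rep("none", 1000), levels = c("up", "down", "none"))
  names(none) <- names(calls)
  t2 <- as.data.frame(suppressWarnings(testGeneSets(none, sets)))
  expect_true(all(t2$p_value == 1))
})

test_that("fdr adjustment within testTargets is per direction", {
  cls <- fixedCls()
  ann <- ProbeAnnotation(sprintf("p%03d", 1:100),
                         rep(sprintf("g%02d", 1:10), each = 10), "gene")
  res <- testTargets(cls, ann, u = NULL, t = 1, fdr_method = "bh")
  t <- as.data.frame(res)
  for (dir in c("up", "down")) {
    sub <- t[t$direction == dir, ]
    expect_equal(sub$fdr, stepUpBH(sub$p_value), tolerance = 1e-12)
  }
})
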