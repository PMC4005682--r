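test_that("generator respects the configured counts and truth bookkeeping", {
  cfg <- smallSimConfig(seed = 5)
  sim <- simulateExperiment(cfg)
  expect_equal(ncol(sim@matrix), 8L)
  expect_equal(sum(sim@truth$label != "null"), cfg$de_genes)
  # probe total close to target (gamma mean = target/genes)
  expect_equal(nrow(sim@matrix), cfg$target_total_probes, tolerance = 0.1)
  # per-DE-gene shifted probes = round(frac_on_target * n_i)
  m <- as.data.frame(sim@annotation@map)
  primary <- m[!duplicated(m$probe_id), ]  # first record is the true gene
  nByGene <- table(primary$target_id)
  de <- sim@truth$gene_id[sim@truth$label != "null"]
  shiftByGene <- table(primary$target_id[match(sim@shifted, primary$probe_id)])
  for (g in de)
    expect_equal(unname(shiftByGene[g]),
                 round(cfg$frac_on_target * nByGene[[g]]),
                 ignore_attr = TRUE)
  # noise drawn from the remaining probes at frac_noise
  expect_equal(length(sim@noise),
               round(cfg$frac_noise * (nrow(sim@matrix) - length(sim@shifted))))
  expect_length(intersect(sim@noise, sim@shifted), 0)
})

test_that("identical seeds give identical output, different seeds differ", {
  s1 <- simulateExperiment(smallSimConfig(seed = 9))
  s2 <- simulateExperiment(smallSimConfig(seed = 9))
  expect_identical(SummarizedExperiment::assay(s1@matrix, 1),
                   SummarizedExperiment::assay(s2@matrix, 1))
  expect_identical(s1@truth, s2@truth)
  s3 <- simulateExperiment(smallSimConfig(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(s1@matrix, 1),
                         SummarizedExperiment::assay(s3@matrix, 1)))
})

test_that("null config makes TEST and REFERENCE exchangeable", {
  sim <- simulateExperiment(smallSimConfig(de_genes = 0, frac_noise = 0,
                                           seed = 3))
  v <- SummarizedExperiment::assay(sim@matrix, 1)
  # same generative law: group means indistinguishable
  expect_equal(mean(v[, 1:4]), mean(v[, 5:8]), tolerance = 0.01)
  expect_equal(length(sim@shifted), 0L)
  expect_equal(length(sim@noise), 0L)
})

test_that("confusion matrix and MCC follow the labeling rules", {
  mkRes <- function(df) {
    new("EnrichmentResults",
        table = S4Vectors::DataFrame(
          target_id = df$id, target_type = "gene", direction = df$dir,
          probes_total = 10L, probes_signif = 5L, censored = FALSE,
          x_censored = 5L, n_censored = 10L, p_value = df$fdr,
          fdr = df$fdr, fdr_method = "bh", significant = df$fdr < 0.05),
        background = list(n = 100L, X_up = 10L, X_down = 10L),
        params = list(u = NULL, t = NULL, fdr_method = "bh",
                      sig_threshold = 0.05))
  }
  truth <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      label = rep(c("up", "down", "null"), c(3, 0, 97)))
  # g001, g002 correct up; g100 wrongly called up; g003 missed;
  # g004 (null) called down at 0.02 only
  res <- mkRes(data.frame(
    id = c("g001", "g002", "g100", "g004"),
    dir = c("up", "up", "up", "down"),
    fdr = c(0.001, 0.004, 0.01, 0.02)))
  ev <- evaluateCalls(res, truth, cutoffs = c(0.05, 0.01))
  at05 <- ev["0.05", ]
  expect_equal(unlist(at05[c("TP", "FP", "TN", "FN")], use.names = FALSE),
               c(2, 2, 95, 1))
  at01 <- ev["0.01", ]  # only fdr < 0.01 calls survive
  expect_equal(unlist(at01[c("TP", "FP", "TN", "FN")], use.names = FALSE),
               c(2, 0, 97, 1))
  # frozen MCC checkpoint: TP=2, FP=1, TN=96, FN=1 -> 191/291
  res2 <- mkRes(data.frame(id = c("g001", "g002", "g100"),
                           dir = c("up", "up", "up"),
                           fdr = c(0.001, 0.004, 0.01)))
  ev2 <- evaluateCalls(res2, truth, cutoffs = 0.05)
  expect_equal(ev2["0.05", "MCC"], 191 / 291, tolerance = 1e-12)
  # a true up-gene called down is a false positive (not a TP), and the
  # four cells still partition the evaluable targets
  res3 <- mkRes(data.frame(id = "g001", dir = "down", fdr = 0.001))
  ev3 <- evaluateCalls(res3, truth, cutoffs = 0.05)
  expect_equal(unlist(ev3["0.05", c("TP", "FP", "FN")], use.names = FALSE),
               c(0, 1, 2))
  expect_equal(sum(ev3["0.05", c("TP", "FP", "TN", "FN")]), 100)
  expect_error(evaluateCalls(mkRes(data.frame(id = "gX", dir = "up",
                                              fdr = 0.01)), truth),
               "gX")
})

test_that("evaluateCalls agrees with an independent confusion recomputation", {
  set.seed(31)
  for (r in 1:100) {
    ids <- sprintf("g%03d", 1:50)
    truth <- data.frame(gene_id = ids,
                        label = sample(c("up", "down", "null"), 50, TRUE,
                                       prob = c(.15, .15, .7)))
    called <- sample(ids, 12)
    df <- data.frame(id = called,
                     dir = sample(c("up", "down"), 12, TRUE),
                     fdr = runif(12, 0, 0.2))
    res <- new("EnrichmentResults",
               table = S4Vectors::DataFrame(
                 target_id = df$id, target_type = "gene", direction = df$dir,
                 probes_total = 5L, probes_signif = 2L, censored = FALSE,
                 x_censored = 2L, n_censored = 5L, p_value = df$fdr,
                 fdr = df$fdr, fdr_method = "bh",
                 significant = df$fdr < 0.05),
               background = list(n = 1L, X_up = 0L, X_down = 0L),
               params = list(sig_threshold = 0.05))
    cut <- 0.05
    ev <- evaluateCalls(res, truth, cutoffs = cut)
    # independent recomputation
    keep <- df[df$fdr < cut, ]
    keep <- keep[order(keep$fdr), ]
    keep <- keep[!duplicated(keep$id), ]
    call <- setNames(rep("none", 50), ids)
    call[keep$id] <- keep$dir
    tl <- setNames(truth$label, ids)
    TP <- sum(call != "none" & tl != "null" & call == tl)
    FP <- sum(call != "none") - TP
    FN <- sum(call == "none" & tl != "null")
    TN <- sum(call == "none" & tl == "null")
    expect_equal(unlist(ev[1, c("TP", "FP", "TN", "FN")], use.names = FALSE),
                 c(TP, FP, TN, FN))
  }
})

test_that("benchmark is deterministic in the master seed", {
  cfg <- smallSimConfig(seed = 77)
  b1 <- runBenchmark(cfg, reps = 2)
  b2 <- runBenchmark(cfg, reps = 2)
  expect_identical(b1$summary, b2$summary)
})

test_that("Fisher power: conservative under the null, saturating, monotone", {
  null <- powerFisher(30, 0.1, 0.1, n = 1e5, reps = 400, seed = 2)
  expect_lte(null$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  strong <- powerFisher(100, 0.1, 0.8, n = 1e6, reps = 300, seed = 3)
  expect_gte(strong$power, 0.99)
  grid <- powerFisher(c(5, 10, 30, 100), 0.1, 0.8, n = 1e6, reps = 300,
                      seed = 4)
  expect_true(all(diff(grid$power) >= -0.02))  # monotone up to MC jitter
  expect_error(powerFisher(10, 0.1, 0.8, reps = 0), "reps")
  expect_error(powerFisher(10, 0.5, 0.2), "p0 <= p1")
})
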