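#' Simulation configuration
#'
#' Defaults reproduce the benchmark's study conditions: two groups of
#' N = 4 arrays, 45,000 genes interrogated by ~1.3 million probes,
#' 1,000 differentially expressed genes with a log2 fold-change of +/-2
#' applied to 80\% of their probes, and the same-magnitude shift applied
#' to a random 10\% of the remaining probes as noise. The baseline
#' intensity model is hierarchical normal on the log2 scale: gene mean ~
#' U[4, 12], probe offset sd 0.5, per-array replicate noise sd 0.25.
#' Per-gene probe counts are drawn from a discretized gamma (shape 4)
#' with mean target_total_probes / genes, clipped to [1, 200]. A fraction
#' of probes additionally maps to a second random gene so that the
#' multiplicity filter has something to act on.
#'
#' @param genes number of genes.
#' @param target_total_probes expected total probe count.
#' @param de_genes number of differentially expressed genes.
#' @param log2_fc fold-change magnitude on the log2 scale, applied as +/-.
#' @param frac_on_target fraction of a DE gene's probes that shift.
#' @param frac_noise fraction of the remaining probes receiving a
#'   same-magnitude shift of random sign.
#' @param noise_placement "random_group" (default) applies each noise
#'   probe's shift to the TEST or the REFERENCE columns with equal
#'   probability, so both groups' intensity distributions are distorted
#'   identically in law; "test_only" puts every noise shift into the TEST
#'   columns. One-sided placement skews the TEST arrays' signal
#'   distribution, and rank normalization then transmits that skew as a
#'   systematic rank drift to unshifted probes near the edges of the
#'   intensity range — an artifact that is correlated within genes and
#'   inflates gene-level false positives far beyond what probe
#'   multiplicity causes.
#' @param replicates arrays per group (N).
#' @param multimap_fraction fraction of probes mapped to a second gene.
#' @param gene_mean_range,probe_sd,replicate_sd baseline model parameters.
#' @param probe_count_shape gamma shape for per-gene probe counts.
#' @param seed RNG seed.
#' @return a named list (class "SimulationConfig").
#' @export
simulationConfig <- function(genes = 45000, target_total_probes = 1300000,
                             de_genes = 1000, log2_fc = 2,
                             frac_on_target = 0.8, frac_noise = 0.1,
                             noise_placement = c("random_group", "test_only"),
                             replicates = 4, multimap_fraction = 0.1,
                             gene_mean_range = c(4, 12), probe_sd = 0.5,
                             replicate_sd = 0.25, probe_count_shape = 4,
                             seed = 1) {
  noise_placement <- match.arg(noise_placement)
  cfg <- list(genes = genes, target_total_probes = target_total_probes,
              de_genes = de_genes, log2_fc = log2_fc,
              frac_on_target = frac_on_target, frac_noise = frac_noise,
              noise_placement = noise_placement,
              replicates = replicates, multimap_fraction = multimap_fraction,
              gene_mean_range = gene_mean_range, probe_sd = probe_sd,
              replicate_sd = replicate_sd,
              probe_count_shape = probe_count_shape, seed = seed)
  for (f in c("frac_on_target", "frac_noise", "multimap_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (de_genes > genes) stop("de_genes must not exceed genes")
  if (genes < 2 || replicates < 1) stop("need genes >= 2 and replicates >= 1")
  structure(cfg, class = "SimulationConfig")
}

#' Generate one synthetic two-group microarray experiment
#'
#' Fully reproducible from \code{config$seed}: identical configs yield
#' identical output. Up- and down-regulation of \code{de_genes} randomly
#' picked genes (sign equiprobable per gene) is simulated by adding the
#' fold-change to round(frac_on_target * n_i) of each gene's probes in
#' every TEST column; a random frac_noise of the remaining probes gets a
#' shift of the same magnitude with random sign.
#'
#' @param config a [simulationConfig()] list.
#' @return a [SimulationOutput-class].
#' @export
simulateExperiment <- function(config = simulationConfig()) {
  cfg <- config
  if (is.null(cfg$noise_placement)) cfg$noise_placement <- "random_group"
  set.seed(cfg$seed)
  meanProbes <- cfg$target_total_probes / cfg$genes
  shape <- cfg$probe_count_shape
  counts <- pmin(pmax(round(stats::rgamma(cfg$genes, shape = shape,
                                          rate = shape / meanProbes)),
                      1L), 200L)
  q <- sum(counts)
  geneIds <- sprintf("g%05d", seq_len(cfg$genes))
  probeIds <- sprintf("p%07d", seq_len(q))
  probeGene <- rep.int(seq_len(cfg$genes), counts)

  geneMean <- stats::runif(cfg$genes, cfg$gene_mean_range[1L],
                           cfg$gene_mean_range[2L])
  baseline <- geneMean[probeGene] + stats::rnorm(q, 0, cfg$probe_sd)
  N <- cfg$replicates
  vals <- baseline + stats::rnorm(q * 2L * N, 0, cfg$replicate_sd)
  dim(vals) <- c(q, 2L * N)
  dimnames(vals) <- list(probeIds,
                         c(paste0("TEST_", seq_len(N)),
                           paste0("REF_", seq_len(N))))
  testCols <- seq_len(N)

  # differential expression: per-gene sign, 80% of on-target probes
  label <- rep("null", cfg$genes)
  shifted <- integer(0)
  shiftSign <- numeric(0)
  if (cfg$de_genes > 0) {
    de <- sample.int(cfg$genes, cfg$de_genes)
    sgn <- sample(c(1, -1), cfg$de_genes, replace = TRUE)
    label[de] <- ifelse(sgn > 0, "up", "down")
    probeList <- split(seq_len(q), probeGene)
    for (k in seq_along(de)) {
      gp <- probeList[[de[k]]]
      nShift <- round(cfg$frac_on_target * length(gp))
      if (nShift > 0) {
        sel <- if (nShift == length(gp)) gp else sample(gp, nShift)
        shifted <- c(shifted, sel)
        shiftSign <- c(shiftSign, rep(sgn[k], nShift))
      }
    }
    if (length(shifted))
      vals[shifted, testCols] <- vals[shifted, testCols] +
        shiftSign * cfg$log2_fc
  }

  # noise: same magnitude, random sign per probe; by default each noise
  # probe is shifted in a random group so the two groups' intensity
  # distributions stay identical in law (see simulationConfig)
  rest <- setdiff(seq_len(q), shifted)
  nNoise <- round(cfg$frac_noise * length(rest))
  noise <- integer(0)
  if (nNoise > 0) {
    noise <- sample(rest, nNoise)
    nsgn <- sample(c(1, -1), nNoise, replace = TRUE)
    refCols <- N + seq_len(N)
    inTest <- if (identical(cfg$noise_placement, "test_only"))
      rep(TRUE, nNoise) else sample(c(TRUE, FALSE), nNoise, replace = TRUE)
    if (any(inTest))
      vals[noise[inTest], testCols] <- vals[noise[inTest], testCols] +
        nsgn[inTest] * cfg$log2_fc
    if (any(!inTest))
      vals[noise[!inTest], refCols] <- vals[noise[!inTest], refCols] +
        nsgn[!inTest] * cfg$log2_fc
  }

  # annotation with a second gene for a fraction of probes; the second
  # gene is a randomly drawn partner per gene (not per probe), emulating
  # the concentrated cross-hybridization structure of paralogous gene
  # pairs on real arrays — scattered per-probe multimapping would never
  # put enough shared differentially expressed probes on one off-target
  # gene to matter
  annProbe <- probeIds
  annGene <- geneIds[probeGene]
  nMulti <- round(cfg$multimap_fraction * q)
  if (nMulti > 0) {
    partner <- sample.int(cfg$genes, cfg$genes, replace = TRUE)
    clash <- partner == seq_len(cfg$genes)
    partner[clash] <- (partner[clash] %% cfg$genes) + 1L
    mp <- sample.int(q, nMulti)
    annProbe <- c(annProbe, probeIds[mp])
    annGene <- c(annGene, geneIds[partner[probeGene[mp]]])
  }
  vals <- pmax(vals, 0)  # raw intensities are non-negative on log2 scale
  new("SimulationOutput",
      matrix = ProbeMatrix(vals),
      annotation = ProbeAnnotation(annProbe, annGene, "gene"),
      truth = data.frame(gene_id = geneIds, label = label,
                         stringsAsFactors = FALSE),
      shifted = probeIds[shifted], noise = probeIds[noise],
      config = unclass(cfg))
}

#' Two-group design matching a [simulateExperiment()] output
#' @param sim a SimulationOutput (or any matrix with TEST_/REF_ columns).
#' @return a [DemiDesign-class].
#' @export
simulationDesign <- function(sim) {
  cols <- colnames(if (is(sim, "SimulationOutput")) sim@matrix else sim)
  twoGroupDesign(grep("^TEST_", cols, value = TRUE),
                 grep("^REF_", cols, value = TRUE))
}

#' Confusion-matrix evaluation of target calls against simulation truth
#'
#' At each FDR cutoff a target is "called" in the direction of its
#' smallest adjusted p among directions passing the cutoff. A call is TP
#' when the target is truly DE and the direction agrees; a call on a null
#' target or in the wrong direction is FP; an uncalled DE target is FN.
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), reported
#' as 0 with \code{mcc_undefined = TRUE} when a marginal is zero. Metrics
#' are also averaged across the cutoffs (row "mean").
#'
#' @param results an [EnrichmentResults-class] over the simulated genes.
#' @param truth data.frame with columns gene_id and label (up/down/null),
#'   covering every evaluated target.
#' @param cutoffs FDR cutoffs (default c(0.05, 0.01)).
#' @return data.frame with one row per cutoff plus the "mean" row.
#' @export
evaluateCalls <- function(results, truth, cutoffs = c(0.05, 0.01)) {
  t <- as.data.frame(results)
  unknown <- setdiff(unique(t$target_id), truth$gene_id)
  if (length(unknown))
    stop(sprintf("target '%s' not covered by the truth table", unknown[1L]))
  trueLab <- truth$label
  names(trueLab) <- truth$gene_id
  rows <- lapply(cutoffs, function(cut) {
    sig <- t[t$fdr < cut, , drop = FALSE]
    call <- rep("none", nrow(truth))
    names(call) <- truth$gene_id
    if (nrow(sig)) {
      sig <- sig[order(sig$fdr), , drop = FALSE]
      first <- sig[!duplicated(sig$target_id), , drop = FALSE]
      call[first$target_id] <- first$direction
    }
    isTrue <- trueLab != "null"
    called <- call != "none"
    agree <- called & isTrue & (call == trueLab)
    TP <- sum(agree)
    FP <- sum(called) - TP
    FN <- sum(!called & isTrue)
    TN <- sum(!called & !isTrue)
    denom <- as.numeric(TP + FP) * as.numeric(TP + FN) *
      as.numeric(TN + FP) * as.numeric(TN + FN)
    und <- denom == 0
    mcc <- if (und) 0 else (TP * TN - FP * FN) / sqrt(denom)
    data.frame(cutoff = cut, TP = TP, FP = FP, TN = TN, FN = FN,
               TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
               FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
               TNR = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
               FNR = if (FN + TP > 0) FN / (FN + TP) else NA_real_,
               MCC = mcc, mcc_undefined = und)
  })
  out <- do.call(rbind, rows)
  meanRow <- data.frame(cutoff = NA_real_, t(colMeans(out[, 2:10])),
                        mcc_undefined = any(out$mcc_undefined))
  rownames(out) <- as.character(cutoffs)
  rbind(out, mean = meanRow)
}

#' Run the simulation benchmark
#'
#' For each repetition: simulate an experiment, rank-normalize, classify
#' probes with the two-group Wilcoxon workflow, score genes with
#' [testTargets()] under the given u and t, and evaluate against the
#' ground truth with metrics averaged over the FDR cutoffs. Per-rep seeds
#' are \code{config$seed + rep - 1}, so the whole benchmark is
#' reproducible from the master seed.
#'
#' @param config a [simulationConfig()].
#' @param reps repetitions (>= 1).
#' @param u,t enrichment filters (NULL = not in effect, the baseline).
#' @param cutoffs FDR cutoffs for the evaluation.
#' @param alpha probe-level significance level.
#' @return list with \code{per_rep} (data.frame of averaged metrics, one
#'   row per rep) and \code{summary} (mean and sd of each metric).
#' @export
runBenchmark <- function(config = simulationConfig(), reps = 1, u = 30,
                         t = 1, cutoffs = c(0.05, 0.01), alpha = 0.05) {
  if (reps < 1) stop("reps must be >= 1")
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulateExperiment(cfg)
    ranks <- rankNormalize(sim@matrix)
    cls <- classifyTwoGroup(ranks, simulationDesign(sim), alpha = alpha)
    res <- testTargets(cls, sim@annotation, u = u, t = t,
                       fdr_method = "bh", target_type = "gene")
    ev <- evaluateCalls(res, sim@truth, cutoffs = cutoffs)
    per[[r]] <- cbind(rep = r, ev["mean", , drop = FALSE])
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  num <- c("TP", "FP", "TN", "FN", "TPR", "FPR", "TNR", "FNR", "MCC")
  summary <- data.frame(metric = num,
                        mean = vapply(per[num], mean, 0),
                        sd = vapply(per[num], stats::sd, 0),
                        row.names = NULL)
  list(per_rep = per, summary = summary)
}

#' Monte-Carlo power of the hypergeometric enrichment test
#'
#' Power to detect a target whose probes are differentially expressed at
#' rate p1 against a background rate p0: per repetition,
#' X_i ~ Binomial(n_i, p1), background X = round(p0 * n) + X_i, and the
#' one-sided enrichment p is compared to alpha.
#'
#' @param n_i on-target probe count(s); vectorized.
#' @param p0 background DE-probe rate.
#' @param p1 on-target DE-probe rate (> p0 under the alternative).
#' @param n background probe total (default 1e6).
#' @param alpha significance level (default 0.05).
#' @param reps Monte-Carlo repetitions (default 1000).
#' @param seed RNG seed.
#' @return data.frame with n_i, power and the Monte-Carlo standard error.
#' @export
powerFisher <- function(n_i, p0, p1, n = 1e6, alpha = 0.05, reps = 1000,
                        seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  if (p0 < 0 || p1 > 1 || p0 > p1) stop("need 0 <= p0 <= p1 <= 1")
  if (any(n_i > n)) stop("n_i must not exceed n")
  set.seed(seed)
  out <- lapply(n_i, function(ni) {
    x <- stats::rbinom(reps, ni, p1)
    X <- round(p0 * n) + x
    p <- hypergeomEnrichment(x, ni, X, n)
    pow <- mean(p <= alpha)
    data.frame(n_i = ni, power = pow,
               se = sqrt(pow * (1 - pow) / reps))
  })
  do.call(rbind, out)
}
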