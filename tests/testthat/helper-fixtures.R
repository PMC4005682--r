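# Fixture builders shared across the suite. Everything is generated in
# code; no binary files.

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyMatrixFile <- function() {
  writeTsv(data.frame(probe_id = paste0("p", 1:4),
                      s1 = c(1.1, 3.2, 5.0, 9.9),
                      s2 = c(4, 3, 2, 1)))
}

# random probe matrix with named dims
randomMatrix <- function(q, samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(q * length(samples), 0.2), q, length(samples),
              dimnames = list(sprintf("p%03d", seq_len(q)), samples))
  m
}

# brute-force one-sided rank-sum tail probabilities by enumeration of all
# C(m+n, m) assignments of the observed pooled values to the TEST group
enumRankSum <- function(test, ref) {
  pooled <- c(test, ref)
  m <- length(test)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  sets <- utils::combn(length(pooled), m)
  sums <- apply(sets, 2L, function(ix) sum(r[ix]))
  c(up = mean(sums >= obs), down = mean(sums <= obs))
}

# independent hypergeometric upper-tail oracle: explicit summation of
# choose() ratios
tailSumHyper <- function(x_i, n_i, X, n) {
  ks <- x_i:min(n_i, X)
  sum(exp(lchoose(X, ks) + lchoose(n - X, n_i - ks) - lchoose(n, n_i)))
}

# definitional BH step-up oracle: adj_i = min over j >= i (ordered) of
# m * p_(j) / j, capped at 1
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
stepUpBY <- function(p) pmin(stepUpBH(p) * sum(1 / seq_along(p)), 1)

# small two-group classification direct from raw vectors
classifyOne <- function(test, ref, alpha = 0.05) {
  m <- matrix(c(test, ref, test, ref), nrow = 2, byrow = TRUE)
  rownames(m) <- c("probe", "pad")
  colnames(m) <- c(paste0("T", seq_along(test)), paste0("R", seq_along(ref)))
  d <- twoGroupDesign(paste0("T", seq_along(test)), paste0("R", seq_along(ref)))
  cls <- classifyTwoGroup(m, d, alpha = alpha)
  as.character(cls@label["probe"])
}

# synthetic regional-silencing fixture: 4v4 arrays over one chromosome
# with a 1-Mbp block of down-shifted probes
silencedGenomeFixture <- function(seed = 1, shift = -2,
                                  chromLen = 10e6, block = c(5e6, 6e6),
                                  probeEvery = 500) {
  set.seed(seed)
  nProbe <- chromLen / probeEvery
  start0 <- as.integer((seq_len(nProbe) - 1) * probeEvery)
  ids <- sprintf("pr%06d", seq_len(nProbe))
  base <- runif(nProbe, 4, 12)
  vals <- base + matrix(rnorm(nProbe * 8, 0, 0.25), nProbe, 8)
  dimnames(vals) <- list(ids, c(paste0("T", 1:4), paste0("R", 1:4)))
  inBlock <- start0 >= block[1] & start0 < block[2]
  sel <- inBlock & (runif(nProbe) < 0.8)
  vals[sel, 1:4] <- vals[sel, 1:4] + shift
  aln <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(start0 + 1L, start0 + 25L))
  names(aln) <- ids
  ann <- ProbeAnnotation(ids, ids, "custom", alignments = aln)
  list(vals = pmax(vals, 0), ann = ann, block = block)
}

smallSimConfig <- function(...) {
  args <- utils::modifyList(
    list(genes = 300, target_total_probes = 9000, de_genes = 20, seed = 1),
    list(...))
  do.call(simulationConfig, args)
}
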