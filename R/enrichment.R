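#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least \code{x_i} differentially expressed
#' probes among the \code{n_i} on-target probes when \code{X} of the
#' \code{n} background probes are differentially expressed: P(K >= x_i)
#' for K ~ Hypergeometric(population n, successes X, draws n_i). Equal to
#' the one-sided Fisher's exact test on the 2x2 table with cells
#' a = X_i, b = X - X_i, c = n_i - X_i, d = n - n_i - (X - X_i).
#' All arguments are vectorized.
#'
#' @param x_i on-target probes classified in the tested direction.
#' @param n_i on-target probe count.
#' @param X background count of probes classified in that direction.
#' @param n background total.
#' @return p-value(s) in (0, 1].
#' @examples
#' hypergeomEnrichment(5, 10, 10, 100)
#' @export
hypergeomEnrichment <- function(x_i, n_i, X, n) {
  if (any(x_i < 0) || any(x_i > pmin(n_i, X)))
    stop("need 0 <= x_i <= min(n_i, X)")
  if (any(n_i > n) || any(X > n))
    stop("need n_i <= n and X <= n")
  stats::phyper(x_i - 1, X, n - X, n_i, lower.tail = FALSE)
}

#' Censor on-target counts at an upper probe limit
#'
#' Targets interrogated by very many probes would otherwise reach
#' significance at biologically trivial enrichment over the background
#' rate. When n_i exceeds the limit u, the pair (x_i, n_i) is scaled to
#' (floor(x_i * u / n_i), u): the proportion is preserved up to the
#' conservative floor, which can only reduce significance. A suitable u is
#' about 30, close to the median gene-specific probe count on high-density
#' arrays.
#'
#' @param x_i,n_i on-target counts (vectorized).
#' @param u censoring limit (>= 1).
#' @return list with components \code{x}, \code{n} and logical
#'   \code{censored}.
#' @examples
#' censorCounts(50, 100, 30)  # -> x=15, n=30
#' @export
censorCounts <- function(x_i, n_i, u) {
  if (any(u < 1)) stop("u must be >= 1")
  cens <- n_i > u
  x <- ifelse(cens, floor(x_i * u / n_i), x_i)
  n <- ifelse(cens, u, n_i)
  list(x = x, n = n, censored = cens)
}

#' Adjust p-values for multiple testing (BH / BY)
#'
#' Benjamini-Hochberg step-up adjusted values, or the
#' Benjamini-Yekutieli variant valid under arbitrary dependency
#' (BH multiplied by the harmonic sum 1 + 1/2 + ... + 1/m, capped at 1).
#' Input order is preserved.
#'
#' @param p numeric p-values in [0, 1].
#' @param method "bh" or "by".
#' @return adjusted p-values, same length and order.
#' @export
adjustFdr <- function(p, method = c("bh", "by")) {
  method <- match.arg(tolower(method), c("bh", "by"))
  if (any(p < 0 | p > 1) || anyNA(p)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = toupper(method))
}

.autoFdr <- function(target_type) {
  # substantial on-target probe overlap is anticipated for everything but
  # genes, so the dependency-robust BY procedure is the default there
  if (target_type == "gene") "bh" else "by"
}

.enrichmentTable <- function(target_id, target_type, n_i, x_up, x_down,
                             n, X_up, X_down, u, fdr_method, sig_threshold) {
  res <- lapply(c(up = "up", down = "down"), function(dir) {
    x_i <- if (dir == "up") x_up else x_down
    X <- if (dir == "up") X_up else X_down
    cc <- if (!is.null(u)) censorCounts(x_i, n_i, u)
      else list(x = x_i, n = n_i, censored = rep(FALSE, length(n_i)))
    p <- hypergeomEnrichment(cc$x, cc$n, X, n)
    fdr <- adjustFdr(p, fdr_method)
    DataFrame(target_id = target_id,
              target_type = target_type,
              direction = dir,
              probes_total = as.integer(n_i),
              probes_signif = as.integer(x_i),
              censored = cc$censored,
              x_censored = as.integer(cc$x),
              n_censored = as.integer(cc$n),
              p_value = p, fdr = fdr,
              fdr_method = fdr_method,
              significant = fdr < sig_threshold)
  })
  rbind(res$up, res$down)
}

.perTargetCounts <- function(probe_id, target_id, lab) {
  tf <- factor(target_id)
  plab <- lab[probe_id]
  list(target = levels(tf),
       n_i = tabulate(tf, nbins = nlevels(tf)),
       x_up = tabulate(tf[plab == "up"], nbins = nlevels(tf)),
       x_down = tabulate(tf[plab == "down"], nbins = nlevels(tf)))
}

#' Target-level differential expression by probe enrichment
#'
#' Scores every target of one category against the array-wide background:
#' after removing probes that map to more than \code{t} distinct targets
#' (from the on-target sets and from the background totals alike), each
#' target's per-direction counts (X_i, n_i) are censored at \code{u} and
#' tested with [hypergeomEnrichment()] against the direction's background
#' (X = |H| or |L|, n = remaining probes). Both tails are computed for
#' every target. FDR adjustment is applied within each direction across
#' all targets; method "auto" selects BH for genes and BY (dependency-
#' robust) for overlapping categories. Adjusted p below
#' \code{sig_threshold} is flagged significant.
#'
#' @param cls a [ProbeClassification-class] covering every annotated probe.
#' @param ann a [ProbeAnnotation-class].
#' @param u censoring limit (default 30); NULL disables censoring.
#' @param t probe multiplicity limit (default 1); NULL disables the filter.
#' @param fdr_method "auto", "bh" or "by".
#' @param sig_threshold adjusted-p significance threshold (default 0.05).
#' @param target_type category to analyze when the annotation holds
#'   several.
#' @return an [EnrichmentResults-class]; targets with no probes left after
#'   filtering are omitted.
#' @export
testTargets <- function(cls, ann, u = 30, t = 1,
                        fdr_method = c("auto", "bh", "by"),
                        sig_threshold = 0.05, target_type = NULL) {
  stopifnot(is(cls, "ProbeClassification"), is(ann, "ProbeAnnotation"))
  fdr_method <- match.arg(tolower(fdr_method[1L]), c("auto", "bh", "by"))
  if (!is.null(u) && u < 1) stop("u must be >= 1 (or NULL)")
  if (!is.null(t) && t < 1) stop("t must be >= 1 (or NULL)")
  m <- ann@map
  if (is.null(target_type)) {
    tt <- unique(m$target_type)
    if (length(tt) > 1L)
      stop("annotation holds several target types; give target_type=")
    target_type <- tt
  }
  m <- m[m$target_type == target_type, , drop = FALSE]
  if (nrow(m) == 0L) stop("no annotation records of type '", target_type, "'")
  lab <- cls@label
  missing <- setdiff(unique(m$probe_id), names(lab))
  if (length(missing))
    stop(sprintf("annotated probe '%s' absent from the classification",
                 missing[1L]))
  if (fdr_method == "auto") fdr_method <- .autoFdr(target_type)

  removed <- character()
  if (!is.null(t)) {
    mult <- multiplicity(ann, target_type)
    removed <- names(mult)[mult > t]
    if (length(removed))
      m <- m[!m$probe_id %in% removed, , drop = FALSE]
  }
  keep <- setdiff(names(lab), removed)
  lab <- lab[keep]
  n <- length(lab)
  X_up <- sum(lab == "up")
  X_down <- sum(lab == "down")
  if (nrow(m) == 0L) stop("no annotated probes left after the multiplicity filter")

  cnt <- .perTargetCounts(m$probe_id, m$target_id, lab)
  tab <- .enrichmentTable(cnt$target, target_type, cnt$n_i, cnt$x_up,
                          cnt$x_down, n, X_up, X_down, u, fdr_method,
                          sig_threshold)
  new("EnrichmentResults", table = tab,
      background = list(n = n, X_up = X_up, X_down = X_down,
                        removed_probes = length(removed)),
      params = list(u = u, t = t, fdr_method = fdr_method,
                    sig_threshold = sig_threshold))
}

#' Differential exon usage within genes
#'
#' Identical enrichment machinery, but each exon is tested against its
#' parent gene's probe set instead of the whole array: n becomes the gene
#' probe count and X the classified probes within the gene, so a
#' significant exon is one whose probes respond out of proportion with the
#' rest of the gene. BH adjustment is applied across all exons (per
#' direction).
#'
#' @param cls a [ProbeClassification-class].
#' @param ann a [ProbeAnnotation-class] with exon records (each carrying a
#'   parent_gene_id); gene records, when present, define the gene probe
#'   sets, otherwise the union of the gene's exon probes is used.
#' @param u,t,sig_threshold as in [testTargets()].
#' @param fdr_method default "bh".
#' @return an [EnrichmentResults-class] over exons.
#' @export
testExonsWithinGene <- function(cls, ann, u = 30, t = 1, fdr_method = "bh",
                                sig_threshold = 0.05) {
  stopifnot(is(cls, "ProbeClassification"), is(ann, "ProbeAnnotation"))
  fdr_method <- match.arg(tolower(fdr_method), c("bh", "by"))
  if (!is.null(u) && u < 1) stop("u must be >= 1 (or NULL)")
  if (!is.null(t) && t < 1) stop("t must be >= 1 (or NULL)")
  m <- ann@map
  ex <- m[m$target_type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon annotation records")
  lab <- cls@label
  missing <- setdiff(unique(ex$probe_id), names(lab))
  if (length(missing))
    stop(sprintf("annotated probe '%s' absent from the classification",
                 missing[1L]))
  if (!is.null(t)) {
    mult <- multiplicity(ann, "exon")
    drop <- names(mult)[mult > t]
    if (length(drop)) ex <- ex[!ex$probe_id %in% drop, , drop = FALSE]
    if (nrow(ex) == 0L) stop("no exon probes left after the multiplicity filter")
  }
  genes <- m[m$target_type == "gene", , drop = FALSE]
  geneProbes <- if (nrow(genes))
    split(genes$probe_id, genes$target_id)
  else
    lapply(split(ex$probe_id, ex$parent_gene_id), unique)

  exonSplit <- split(seq_len(nrow(ex)), ex$target_id)
  rows <- lapply(names(exonSplit), function(eid) {
    idx <- exonSplit[[eid]]
    gene <- unique(ex$parent_gene_id[idx])
    if (length(gene) != 1L)
      stop("exon '", eid, "' maps to several parent genes")
    gp <- geneProbes[[gene]]
    if (is.null(gp) || !length(gp)) stop("parent gene '", gene, "' has no probes")
    ep <- unique(ex$probe_id[idx])
    if (!all(ep %in% gp))
      stop("exon '", eid, "' has probes outside its parent gene's probe set")
    gl <- lab[gp]
    data.frame(target_id = eid, gene = gene,
               n_i = length(ep),
               x_up = sum(lab[ep] == "up"), x_down = sum(lab[ep] == "down"),
               n = length(gp),
               X_up = sum(gl == "up"), X_down = sum(gl == "down"))
  })
  d <- do.call(rbind, rows)
  tabs <- lapply(c(up = "up", down = "down"), function(dir) {
    x_i <- if (dir == "up") d$x_up else d$x_down
    X <- if (dir == "up") d$X_up else d$X_down
    cc <- if (!is.null(u)) censorCounts(x_i, d$n_i, u)
      else list(x = x_i, n = d$n_i, censored = rep(FALSE, nrow(d)))
    # censored draws must not exceed the (gene-local) background
    p <- hypergeomEnrichment(pmin(cc$x, X), pmin(cc$n, d$n), X, d$n)
    DataFrame(target_id = d$target_id, target_type = "exon",
              direction = dir, probes_total = as.integer(d$n_i),
              probes_signif = as.integer(x_i), censored = cc$censored,
              x_censored = as.integer(cc$x), n_censored = as.integer(cc$n),
              p_value = p, fdr = adjustFdr(p, fdr_method),
              fdr_method = fdr_method, significant = NA)
  })
  tab <- rbind(tabs$up, tabs$down)
  tab$significant <- tab$fdr < sig_threshold
  new("EnrichmentResults", table = tab,
      background = list(n = NA_integer_, X_up = NA_integer_,
                        X_down = NA_integer_, per_gene = TRUE),
      params = list(u = u, t = t, fdr_method = fdr_method,
                    sig_threshold = sig_threshold))
}

#' Gene-set (functional category) enrichment from gene-level calls
#'
#' Genes play the role of probes: with X up- (or down-) regulated genes in
#' a universe of n tested genes, a set of n_i genes containing X_i in that
#' direction is scored by the same hypergeometric upper tail. BY
#' adjustment is the default because functional categories overlap.
#'
#' @param gene_calls factor or character named by gene id with values in
#'   up/down/none — e.g. derived from the significant directions of a
#'   [testTargets()] run.
#' @param sets a [ProbeAnnotation-class] with target_type "gene_set"
#'   (probe_id column = gene ids).
#' @param fdr_method default "by".
#' @param sig_threshold default 0.05.
#' @return an [EnrichmentResults-class] over gene sets; sets with no gene
#'   in the universe are omitted with a warning.
#' @export
testGeneSets <- function(gene_calls, sets, fdr_method = "by",
                         sig_threshold = 0.05) {
  stopifnot(is(sets, "ProbeAnnotation"))
  fdr_method <- match.arg(tolower(fdr_method), c("bh", "by"))
  lab <- factor(as.character(gene_calls), levels = c("up", "down", "none"))
  names(lab) <- names(gene_calls)
  if (is.null(names(lab))) stop("gene_calls must be named by gene id")
  m <- sets@map[sets@map$target_type == "gene_set", , drop = FALSE]
  if (nrow(m) == 0L) stop("no gene_set annotation records")
  inUniverse <- m$probe_id %in% names(lab)
  lost <- setdiff(unique(m$target_id), unique(m$target_id[inUniverse]))
  if (length(lost))
    warning(length(lost), " gene set(s) with no gene in the universe omitted",
            call. = FALSE)
  m <- m[inUniverse, , drop = FALSE]
  if (nrow(m) == 0L) stop("no gene set overlaps the gene universe")
  n <- length(lab)
  X_up <- sum(lab == "up"); X_down <- sum(lab == "down")
  cnt <- .perTargetCounts(m$probe_id, m$target_id, lab)
  tab <- .enrichmentTable(cnt$target, "gene_set", cnt$n_i, cnt$x_up,
                          cnt$x_down, n, X_up, X_down, NULL, fdr_method,
                          sig_threshold)
  new("EnrichmentResults", table = tab,
      background = list(n = n, X_up = X_up, X_down = X_down),
      params = list(u = NULL, t = NULL, fdr_method = fdr_method,
                    sig_threshold = sig_threshold))
}

#' Derive per-gene direction calls from an EnrichmentResults
#'
#' A gene is labeled up (down) when significant in that direction; if both
#' directions are significant the smaller adjusted p wins.
#'
#' @param results an [EnrichmentResults-class].
#' @return factor named by target id with levels up/down/none.
#' @export
geneCalls <- function(results) {
  t <- as.data.frame(results)
  ids <- unique(t$target_id)
  lab <- factor(rep("none", length(ids)), levels = c("up", "down", "none"))
  names(lab) <- ids
  sig <- t[t$significant, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$fdr), , drop = FALSE]
    first <- sig[!duplicated(sig$target_id), , drop = FALSE]
    lab[first$target_id] <- first$direction
  }
  lab
}
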