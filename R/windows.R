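## Sliding-genomic-window mode: regional expression changes (e.g.
## long-range epigenetic silencing) are detected by testing overlapping
## fixed-width windows as genomic_region targets. Window ids use 0-based
## half-open (BED) coordinates; GRanges objects are 1-based closed
## internally.

.windowId <- function(chrom, start1, end1)
  sprintf("%s:%d-%d", chrom, start1 - 1L, end1)

#' Tile chromosomes with overlapping windows
#'
#' Windows of the given width are laid per chromosome at starts 0, step,
#' 2*step, ... (step = width * (1 - overlap_fraction)) while the start
#' lies inside the chromosome; trailing windows are truncated at the
#' chromosome end and kept, so silencing near telomeres stays detectable.
#' With 50\% overlap every interior base is covered by exactly two
#' windows.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param width window width in bp (default 500000).
#' @param overlap_fraction fraction of overlap between consecutive
#'   windows, in [0, 1) (default 0.5); width * (1 - overlap_fraction)
#'   must be a whole number of bases.
#' @return a GRanges with an \code{id} metadata column
#'   ("chrom:start-end", 0-based half-open) also used as names.
#' @examples
#' makeWindows(c(chr1 = 1250000))
#' @export
makeWindows <- function(chrom_sizes, width = 500000, overlap_fraction = 0.5) {
  if (width < 2) stop("width must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  step <- width * (1 - overlap_fraction)
  if (abs(step - round(step)) > 1e-8)
    stop("width * (1 - overlap_fraction) must be integral")
  step <- as.integer(round(step))
  parts <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    if (len <= 0) {
      warning("zero-length chromosome '", chr, "' skipped", call. = FALSE)
      return(NULL)
    }
    starts0 <- seq(0L, len - 1L, by = step)
    # a trailing start whose remaining span is below one step adds no new
    # coverage beyond the previous (already truncated) window; chromosomes
    # shorter than the width yield a single window
    starts0 <- starts0[starts0 == 0L | (len - starts0) >= step]
    data.frame(chrom = chr, start0 = starts0,
               end0 = pmin(starts0 + width, len))
  })
  d <- do.call(rbind, parts)
  if (is.null(d)) stop("no usable chromosome in chrom_sizes")
  gr <- GRanges(d$chrom, IRanges(d$start0 + 1L, d$end0))
  ids <- .windowId(as.character(seqnames(gr)), start(gr), end(gr))
  names(gr) <- ids
  gr$id <- ids
  gr
}

#' Assign probes to genomic windows by alignment midpoint
#'
#' A probe belongs to a window iff its alignment midpoint (floor of the
#' mean of the 0-based half-open endpoints) lies in [start, end). Probes
#' aligning to more than \code{t} distinct genomic loci are dropped (same
#' multiplicity semantics as [testTargets()]); membership in up to
#' 1/(1-overlap) overlapping windows is by construction and exempt from
#' the filter — which is why the dependency-robust BY adjustment is the
#' default for windows. Probes without any alignment are dropped with a
#' warning.
#'
#' @param ann a [ProbeAnnotation-class] carrying genomic alignments (e.g.
#'   from [readAnnotation()] on a BED file).
#' @param windows GRanges from [makeWindows()].
#' @param t maximum distinct alignment loci per probe (default 1); NULL
#'   disables the filter.
#' @return a [ProbeAnnotation-class] with target_type "genomic_region"
#'   (target ids = window ids), alignments retained.
#' @export
assignProbesToWindows <- function(ann, windows, t = 1) {
  stopifnot(is(ann, "ProbeAnnotation"))
  aln <- ann@alignments
  if (!length(aln)) stop("annotation carries no genomic alignments")
  annotated <- unique(ann@map$probe_id)
  noAln <- setdiff(annotated, names(aln))
  if (length(noAln))
    warning(length(noAln), " probe(s) without alignment dropped", call. = FALSE)
  if (!is.null(t)) {
    if (t < 1) stop("t must be >= 1 (or NULL)")
    locus <- paste0(seqnames(aln), ":", start(aln), "-", end(aln))
    nloci <- tapply(locus, names(aln), function(z) length(unique(z)))
    multi <- names(nloci)[nloci > t]
    if (length(multi)) aln <- aln[!names(aln) %in% multi]
    if (!length(aln)) stop("no probes left after the multiplicity filter")
  }
  # 0-based midpoint floor((s0+e0)/2) as a 1-based point
  s0 <- start(aln) - 1L
  e0 <- end(aln)
  mid1 <- as.integer(floor((s0 + e0) / 2)) + 1L
  pts <- GRanges(seqnames(aln), IRanges(mid1, mid1))
  hits <- findOverlaps(pts, windows)
  if (!length(hits)) stop("no probe midpoint falls into any window")
  ProbeAnnotation(probe_id = names(aln)[S4Vectors::queryHits(hits)],
                  target_id = names(windows)[S4Vectors::subjectHits(hits)],
                  target_type = "genomic_region",
                  alignments = aln)
}

#' Window-level differential expression
#'
#' Delegates to [testTargets()] with target_type "genomic_region" and BY
#' adjustment by default; the locus-multiplicity filter has already been
#' applied during window assignment, so no further t-filter runs here
#' (probes legitimately sit in two overlapping windows).
#'
#' @param cls a [ProbeClassification-class].
#' @param window_ann output of [assignProbesToWindows()].
#' @param u censoring limit (default 30).
#' @param fdr_method default "by".
#' @param sig_threshold default 0.05.
#' @return an [EnrichmentResults-class] over windows.
#' @export
windowsDiff <- function(cls, window_ann, u = 30, fdr_method = "by",
                        sig_threshold = 0.05) {
  testTargets(cls, window_ann, u = u, t = NULL, fdr_method = fdr_method,
              sig_threshold = sig_threshold, target_type = "genomic_region")
}

#' Overlap significant windows with candidate regions
#'
#' A candidate region counts as detected when some significant window
#' overlaps it by at least \code{min_overlap} bp. Enrichment of
#' candidate-overlapping windows among the significant windows is scored
#' with the one-sided hypergeometric test over the full window universe.
#'
#' @param significant_windows GRanges of significant windows (subset of
#'   \code{windows}; e.g. the down-regulated ones).
#' @param candidates GRanges of candidate regions (e.g. from
#'   [readBedRegions()]).
#' @param min_overlap minimum overlap in bp (default 250000).
#' @param windows the full window tiling the analysis was run on.
#' @return list with \code{candidates} (data.frame: id, detected,
#'   best_overlap in bp) and \code{p} (enrichment p-value; 1 when no
#'   window is significant).
#' @export
overlapCandidates <- function(significant_windows, candidates,
                              min_overlap = 250000, windows) {
  if (!length(candidates)) stop("empty candidate region set")
  ov <- function(gr) {
    h <- findOverlaps(candidates, gr)
    best <- rep(0L, length(candidates))
    if (length(h)) {
      w <- width(pintersect(candidates[S4Vectors::queryHits(h)],
                            gr[S4Vectors::subjectHits(h)]))
      agg <- tapply(w, S4Vectors::queryHits(h), max)
      best[as.integer(names(agg))] <- as.integer(agg)
    }
    best
  }
  best <- ov(significant_windows)
  ids <- if (!is.null(names(candidates))) names(candidates)
    else .windowId(as.character(seqnames(candidates)), start(candidates),
                   end(candidates))
  det <- data.frame(id = ids, detected = best >= min_overlap,
                    best_overlap = best, stringsAsFactors = FALSE)

  candWin <- ov2 <- findOverlaps(windows, candidates)
  hitWidth <- rep(0L, length(windows))
  if (length(ov2)) {
    w <- width(pintersect(windows[S4Vectors::queryHits(ov2)],
                          candidates[S4Vectors::subjectHits(ov2)]))
    agg <- tapply(w, S4Vectors::queryHits(ov2), max)
    hitWidth[as.integer(names(agg))] <- as.integer(agg)
  }
  isHit <- hitWidth >= min_overlap
  sigIds <- names(significant_windows)
  if (is.null(sigIds) && length(significant_windows))
    stop("significant_windows must carry window names (ids)")
  isSig <- names(windows) %in% sigIds
  p <- hypergeomEnrichment(sum(isHit & isSig), sum(isHit),
                           sum(isSig), length(windows))
  list(candidates = det, p = p)
}
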