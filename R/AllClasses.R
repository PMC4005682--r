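#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges
NULL

TARGET_TYPES <- c("gene", "transcript", "exon", "genomic_region",
                  "gene_set", "custom")

#' ProbeMatrix: probe-by-sample intensity container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' of raw probe intensities (rows = probes, columns = samples/arrays).
#' Validity enforces unique probe and sample identifiers, finite
#' non-negative values, at least two probes and at least one sample.
#'
#' @slot .  inherits all slots from SummarizedExperiment; the single assay
#'   is named \code{"intensity"}.
#' @seealso [ProbeMatrix()], [rankNormalize()]
#' @export
setClass("ProbeMatrix", contains = "SummarizedExperiment")

#' RankMatrix: relative-rank normalized probe matrix
#'
#' Same shape as \linkS4class{ProbeMatrix} but each column holds relative
#' ranks in (0, 100]: the weakest signal on an array maps near 0, the
#' strongest to 100, and a value of 25 sits at the first quartile of that
#' array's intensities. Produced by [rankNormalize()]; the assay is named
#' \code{"relrank"}.
#'
#' @export
setClass("RankMatrix", contains = "SummarizedExperiment")

.validProbeValues <- function(v, what, nonneg = TRUE, upper = Inf) {
  if (!is.numeric(v)) return(sprintf("%s values must be numeric", what))
  if (any(!is.finite(v)))
    return(sprintf("%s contains missing or non-finite values", what))
  if (nonneg && any(v < 0))
    return(sprintf("%s contains negative values", what))
  if (any(v > upper))
    return(sprintf("%s contains values above %g", what, upper))
  NULL
}

.validDimnames <- function(object) {
  pid <- rownames(object); sid <- colnames(object)
  msg <- character()
  if (is.null(pid) || anyNA(pid) || any(pid == ""))
    msg <- c(msg, "probe ids (rownames) must be present and non-empty")
  else if (anyDuplicated(pid))
    msg <- c(msg, sprintf("duplicate probe id: '%s'",
                          pid[duplicated(pid)][1L]))
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    msg <- c(msg, "sample ids (colnames) must be present and non-empty")
  else if (anyDuplicated(sid))
    msg <- c(msg, sprintf("duplicate sample id: '%s'",
                          sid[duplicated(sid)][1L]))
  if (nrow(object) < 2L) msg <- c(msg, "need at least 2 probes (q >= 2)")
  if (ncol(object) < 1L) msg <- c(msg, "need at least 1 sample")
  msg
}

setValidity("ProbeMatrix", function(object) {
  msg <- .validDimnames(object)
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else
    msg <- c(msg, .validProbeValues(assay(object, "intensity"), "intensity"))
  if (length(msg)) msg else TRUE
})

setValidity("RankMatrix", function(object) {
  msg <- .validDimnames(object)
  if (!"relrank" %in% assayNames(object)) {
    msg <- c(msg, "assay 'relrank' is required")
  } else {
    v <- assay(object, "relrank")
    msg <- c(msg, .validProbeValues(v, "relrank", nonneg = FALSE,
                                    upper = 100))
    if (is.numeric(v) && all(is.finite(v)) && any(v <= 0))
      msg <- c(msg, "relative ranks must lie in (0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeMatrix from a numeric matrix
#'
#' @param values numeric matrix of raw intensities with probe ids as
#'   rownames and sample ids as colnames.
#' @return a validated [ProbeMatrix-class] object.
#' @examples
#' m <- matrix(runif(8, 1, 10), 4, 2,
#'             dimnames = list(paste0("p", 1:4), c("s1", "s2")))
#' pm <- ProbeMatrix(m)
#' @export
ProbeMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ProbeMatrix",
      SummarizedExperiment(assays = list(intensity = values)))
}

.RankMatrix <- function(values) {
  new("RankMatrix",
      SummarizedExperiment(assays = list(relrank = values)))
}

#' Number of probes
#'
#' @param object a ProbeMatrix, RankMatrix or ProbeClassification.
#' @return integer probe count (the background size q).
#' @export
setGeneric("nProbes", function(object) standardGeneric("nProbes"))

#' @rdname nProbes
#' @export
setMethod("nProbes", "SummarizedExperiment", function(object) nrow(object))

#' ProbeAnnotation: many-to-many probe-to-target mapping
#'
#' Records linking probes to the targets they interrogate. A probe may map
#' to several targets (its multiplicity); exon records must carry the
#' parent gene so exon usage can be tested within the gene. Optional
#' genomic alignments (as a \linkS4class{GRanges} named by probe id) are
#' carried for the sliding-window mode.
#'
#' @slot map DataFrame with columns \code{probe_id}, \code{target_id},
#'   \code{target_type} and \code{parent_gene_id} (NA when not an exon).
#' @slot alignments GRanges of probe genomic alignments, names = probe ids;
#'   may be empty. Coordinates follow GRanges (1-based closed) internally;
#'   BED input/output uses 0-based half-open.
#' @export
setClass("ProbeAnnotation",
         representation(map = "DataFrame", alignments = "GRanges"))

setValidity("ProbeAnnotation", function(object) {
  m <- object@map
  need <- c("probe_id", "target_id", "target_type", "parent_gene_id")
  if (!all(need %in% colnames(m)))
    return(paste("map must have columns", paste(need, collapse = ", ")))
  msg <- character()
  bad <- setdiff(unique(m$target_type), TARGET_TYPES)
  if (length(bad))
    msg <- c(msg, sprintf("unknown target_type: '%s'", bad[1L]))
  ex <- m$target_type == "exon"
  if (any(ex) && anyNA(m$parent_gene_id[ex]))
    msg <- c(msg, "every exon record needs a parent_gene_id")
  if (nrow(m) && anyDuplicated(paste(m$probe_id, m$target_id, m$target_type)))
    msg <- c(msg, "duplicate (probe, target, type) records")
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeAnnotation
#'
#' @param probe_id,target_id character vectors of equal length.
#' @param target_type one of gene, transcript, exon, genomic_region,
#'   gene_set, custom (recycled).
#' @param parent_gene_id parent gene for exon records (NA otherwise).
#' @param alignments optional GRanges of probe alignments named by probe id.
#' @return a validated [ProbeAnnotation-class].
#' @export
ProbeAnnotation <- function(probe_id, target_id, target_type = "gene",
                            parent_gene_id = NA_character_,
                            alignments = GRanges()) {
  n <- length(probe_id)
  map <- DataFrame(probe_id = as.character(probe_id),
                   target_id = as.character(target_id),
                   target_type = rep_len(as.character(target_type), n),
                   parent_gene_id = rep_len(as.character(parent_gene_id), n))
  key <- paste(map$probe_id, map$target_id, map$target_type)
  map <- map[!duplicated(key), , drop = FALSE]
  new("ProbeAnnotation", map = map, alignments = alignments)
}

#' Per-probe target multiplicity
#'
#' Number of distinct targets of one target type that each probe maps to.
#' Probes exceeding the multiplicity limit \code{t} are excluded from both
#' the on-target counts and the enrichment background.
#'
#' @param object a ProbeAnnotation.
#' @param target_type the target category to count within (default: the
#'   single type present).
#' @return named integer vector, one entry per annotated probe.
#' @export
setGeneric("multiplicity",
           function(object, target_type = NULL) standardGeneric("multiplicity"))

#' @rdname multiplicity
#' @export
setMethod("multiplicity", "ProbeAnnotation", function(object, target_type = NULL) {
  m <- object@map
  if (is.null(target_type)) {
    tt <- unique(m$target_type)
    if (length(tt) > 1L)
      stop("annotation holds several target types; give target_type=")
    target_type <- tt
  }
  m <- m[m$target_type == target_type, , drop = FALSE]
  tab <- table(m$probe_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

setMethod("show", "ProbeAnnotation", function(object) {
  m <- object@map
  cat("ProbeAnnotation with", nrow(m), "records:",
      length(unique(m$probe_id)), "probes ->",
      length(unique(m$target_id)), "targets",
      sprintf("(%s)\n", paste(unique(m$target_type), collapse = ", ")))
  if (length(object@alignments))
    cat(" ", length(object@alignments), "genomic alignments\n")
})

#' Experimental design for probe classification
#'
#' Either a two-group comparison (TEST vs REFERENCE sample sets) or a
#' monotonic design with one numeric covariate per sample (e.g. hours of
#' treatment).
#'
#' @slot mode "two_group" or "monotonic".
#' @slot test,reference character sample ids (two_group mode).
#' @slot covariate named numeric covariate (monotonic mode).
#' @export
setClass("DemiDesign",
         representation(mode = "character", test = "character",
                        reference = "character", covariate = "numeric"))

setValidity("DemiDesign", function(object) {
  if (object@mode == "two_group") {
    if (length(object@test) < 1L || length(object@reference) < 1L)
      return("two_group design needs m >= 1 TEST and n >= 1 REFERENCE samples")
    if (length(intersect(object@test, object@reference)))
      return("TEST and REFERENCE sample sets must be disjoint")
  } else if (object@mode == "monotonic") {
    if (is.null(names(object@covariate)) || anyNA(object@covariate))
      return("monotonic design needs a complete named numeric covariate")
    if (length(unique(object@covariate)) < 4L)
      return("monotonic design needs >= 4 distinct covariate values (no probe can reach significance below 4)")
  } else return("mode must be 'two_group' or 'monotonic'")
  TRUE
})

#' @rdname DemiDesign-class
#' @param test,reference character vectors of sample ids.
#' @export
twoGroupDesign <- function(test, reference) {
  new("DemiDesign", mode = "two_group", test = as.character(test),
      reference = as.character(reference), covariate = numeric())
}

#' @rdname DemiDesign-class
#' @param covariate named numeric vector (names = sample ids).
#' @export
monotonicDesign <- function(covariate) {
  new("DemiDesign", mode = "monotonic", test = character(),
      reference = character(), covariate = covariate)
}

setMethod("show", "DemiDesign", function(object) {
  if (object@mode == "two_group")
    cat(sprintf("DemiDesign: two_group, m=%d TEST vs n=%d REFERENCE\n",
                length(object@test), length(object@reference)))
  else
    cat(sprintf("DemiDesign: monotonic over %d samples (%d distinct covariate values)\n",
                length(object@covariate),
                length(unique(object@covariate))))
})

#' ProbeClassification: per-probe differential-expression labels
#'
#' The result of a probe-level test: each probe carries a label in
#' \{up, down, none\}. The up set H and down set L, with their sizes
#' X_up = |H| and X_down = |L| against the background of n tested probes,
#' feed the target-level hypergeometric enrichment.
#'
#' @slot label factor (levels up, down, none) named by probe id.
#' @slot alpha per-direction probe significance level.
#' @slot mode "two_group" or "monotonic".
#' @slot design the DemiDesign used.
#' @export
setClass("ProbeClassification",
         representation(label = "factor", alpha = "numeric",
                        mode = "character", design = "DemiDesign"))

setValidity("ProbeClassification", function(object) {
  if (!identical(levels(object@label), c("up", "down", "none")))
    return("label levels must be up, down, none")
  if (is.null(names(object@label)) || anyDuplicated(names(object@label)))
    return("labels must be uniquely named by probe id")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  TRUE
})

#' @rdname ProbeClassification-class
#' @param object a ProbeClassification.
#' @export
setGeneric("upProbes", function(object) standardGeneric("upProbes"))
#' @rdname ProbeClassification-class
#' @export
setGeneric("downProbes", function(object) standardGeneric("downProbes"))

#' @rdname ProbeClassification-class
#' @export
setMethod("upProbes", "ProbeClassification",
          function(object) names(object@label)[object@label == "up"])
#' @rdname ProbeClassification-class
#' @export
setMethod("downProbes", "ProbeClassification",
          function(object) names(object@label)[object@label == "down"])
#' @rdname nProbes
#' @export
setMethod("nProbes", "ProbeClassification",
          function(object) length(object@label))

setMethod("show", "ProbeClassification", function(object) {
  tab <- table(object@label)
  cat(sprintf("ProbeClassification (%s, alpha=%g): %d probes, %d up (H), %d down (L)\n",
              object@mode, object@alpha, length(object@label),
              tab[["up"]], tab[["down"]]))
})

#' EnrichmentResults: target-level differential-expression table
#'
#' One row per (target, direction). \code{probes_total} is the on-target
#' probe count after the multiplicity filter (n_i), \code{probes_signif}
#' the probes classified in that direction (X_i); when a target exceeds
#' the censoring limit u, the p-value is computed from the scaled counts
#' (n_censored, x_censored) and \code{censored} is TRUE. The background
#' totals (X per direction, grand total n) are kept in \code{background()}.
#'
#' @slot table DataFrame with columns target_id, target_type, direction,
#'   probes_total, probes_signif, censored, x_censored, n_censored,
#'   p_value, fdr, fdr_method, significant.
#' @slot background named list: n, X_up, X_down after filtering.
#' @slot params named list: u, t, alpha threshold used for the
#'   significance flag.
#' @export
setClass("EnrichmentResults",
         representation(table = "DataFrame", background = "list",
                        params = "list"))

#' @rdname EnrichmentResults-class
#' @param object an EnrichmentResults.
#' @export
setGeneric("background", function(object) standardGeneric("background"))
#' @rdname EnrichmentResults-class
#' @export
setMethod("background", "EnrichmentResults", function(object) object@background)

#' @rdname EnrichmentResults-class
#' @param x an EnrichmentResults.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "EnrichmentResults",
          function(x, row.names = NULL, optional = FALSE, ...)
            as.data.frame(x@table))

setMethod("show", "EnrichmentResults", function(object) {
  t <- object@table
  cat(sprintf("EnrichmentResults: %d rows (%d targets), %d significant at fdr < %g\n",
              nrow(t), length(unique(t$target_id)),
              sum(t$significant), object@params$sig_threshold))
  cat(sprintf("  background: n=%d, X_up=%d, X_down=%d; u=%s, t=%s\n",
              object@background$n, object@background$X_up,
              object@background$X_down,
              if (is.null(object@params$u)) "none" else object@params$u,
              if (is.null(object@params$t)) "none" else object@params$t))
})

#' SimulationOutput: one synthetic two-group experiment
#'
#' @slot matrix ProbeMatrix of raw log2 intensities (TEST then REFERENCE
#'   columns).
#' @slot annotation ProbeAnnotation (gene targets, with multimapped probes).
#' @slot truth data.frame with gene_id and label in \{up, down, null\}.
#' @slot shifted character vector of on-target shifted probe ids.
#' @slot noise character vector of noise-shifted off-target probe ids.
#' @slot config the SimulationConfig list used.
#' @export
setClass("SimulationOutput",
         representation(matrix = "ProbeMatrix", annotation = "ProbeAnnotation",
                        truth = "data.frame", shifted = "character",
                        noise = "character", config = "list"))

setMethod("show", "SimulationOutput", function(object) {
  cat(sprintf("SimulationOutput: %d probes x %d arrays, %d genes (%d DE), %d on-target shifted, %d noise probes\n",
              nrow(object@matrix), ncol(object@matrix),
              nrow(object@truth), sum(object@truth$label != "null"),
              length(object@shifted), length(object@noise)))
})
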