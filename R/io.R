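#' Read a probe intensity matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids; the first
#' column holds probe ids. Decimal point is '.', encoding UTF-8. Row order
#' is preserved.
#'
#' @param path path to the TSV file.
#' @return a validated [ProbeMatrix-class].
#' @export
readProbeMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed probe matrix file: ", path)
  pid <- df[[1L]]
  dup <- pid[duplicated(pid)]
  if (length(dup))
    stop(sprintf("duplicate probe id '%s' in %s", dup[1L], path))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or non-finite value '%s' at row %d (probe '%s'), column '%s'",
      vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], pid[bad[1L, 1L]],
      colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(pid, colnames(df)[-1L])
  ProbeMatrix(num)
}

#' Write a probe or rank matrix to TSV
#'
#' Values are serialized with full decimal precision so that a write/read
#' round trip is bit-exact.
#'
#' @param x a ProbeMatrix or RankMatrix.
#' @param path output path.
#' @export
writeProbeMatrix <- function(x, path) {
  v <- if (is(x, "RankMatrix")) assay(x, "relrank") else assay(x, "intensity")
  df <- data.frame(probe_id = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rank matrix written by [writeProbeMatrix()]
#' @param path path to the TSV file.
#' @return a [RankMatrix-class].
#' @export
readRankMatrix <- function(path) {
  pm <- readProbeMatrix(path)
  v <- assay(pm, "intensity")
  rm <- .RankMatrix(v)
  validObject(rm)
  rm
}

#' Read probe-to-target annotation
#'
#' TSV input needs columns \code{probe_id}, \code{target_id},
#' \code{target_type} and, for exon records, \code{parent_gene_id}.
#' BED input (4+ columns, 0-based half-open) carries probe alignments: the
#' name field is the probe id; each line becomes a genomic alignment
#' record retained for the sliding-window mode.
#'
#' @param path path to a .tsv or .bed file.
#' @param format "tsv" or "bed"; inferred from the extension by default.
#' @return a [ProbeAnnotation-class]; duplicate (probe, target) pairs are
#'   deduplicated.
#' @export
readAnnotation <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") return(.readAnnotationBed(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "target_id", "target_type")
  if (!all(need %in% colnames(df)))
    stop("annotation TSV needs columns ", paste(need, collapse = ", "))
  parent <- if ("parent_gene_id" %in% colnames(df)) {
    p <- df$parent_gene_id
    p[!nzchar(p)] <- NA_character_
    p
  } else rep(NA_character_, nrow(df))
  bad <- setdiff(unique(df$target_type), TARGET_TYPES)
  if (length(bad)) stop(sprintf("unknown target_type '%s' in %s", bad[1L], path))
  ex <- df$target_type == "exon"
  if (any(ex & is.na(parent)))
    stop("exon annotation record without parent_gene_id (probe '",
         df$probe_id[ex & is.na(parent)][1L], "')")
  ProbeAnnotation(df$probe_id, df$target_id, df$target_type, parent)
}

.readAnnotationBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 4L))
    stop("BED probe alignments need >= 4 columns (chrom start end name)")
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- as.integer(vapply(fields, `[`, "", 2L))
  e0 <- as.integer(vapply(fields, `[`, "", 3L))
  name <- vapply(fields, `[`, "", 4L)
  if (anyNA(s0) || anyNA(e0) || any(e0 <= s0))
    stop("malformed BED interval in ", path)
  # BED is 0-based half-open; GRanges 1-based closed
  aln <- GRanges(chrom, IRanges(s0 + 1L, e0))
  names(aln) <- name
  ProbeAnnotation(probe_id = name, target_id = name,
                  target_type = "custom", alignments = aln)
}

#' Read a two-column chromosome sizes TSV (chrom, length in bp)
#' @param path path to the TSV (no header required; one is tolerated).
#' @return named integer-ish numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]
  sizes <- as.numeric(df[[2L]])
  names(sizes) <- df[[1L]]
  if (anyNA(sizes) || any(sizes < 0)) stop("malformed chrom sizes file: ", path)
  sizes
}

#' Read a sample design TSV
#'
#' Two-group mode: columns \code{sample_id} and \code{group} with values
#' TEST/REFERENCE (case-insensitive; \code{test}/\code{ref} accepted).
#' Monotonic mode: columns \code{sample_id} and a numeric covariate column
#' (default name \code{time}).
#'
#' @param path path to the TSV file.
#' @param mode "two_group" or "monotonic".
#' @param covariate_column covariate column name for monotonic mode.
#' @return a [DemiDesign-class].
#' @export
readDesign <- function(path, mode = c("two_group", "monotonic"),
                       covariate_column = "time") {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("design file needs a sample_id column")
  if (mode == "two_group") {
    if (!"group" %in% colnames(df)) stop("two_group design needs a group column")
    g <- tolower(df$group)
    test <- df$sample_id[g %in% c("test", "t")]
    ref <- df$sample_id[g %in% c("reference", "ref", "r")]
    unknown <- setdiff(g, c("test", "t", "reference", "ref", "r"))
    if (length(unknown)) stop("unknown group label: ", unknown[1L])
    twoGroupDesign(test, ref)
  } else {
    if (!covariate_column %in% colnames(df))
      stop("monotonic design needs a '", covariate_column, "' column")
    cov <- as.numeric(df[[covariate_column]])
    if (anyNA(cov)) stop("non-numeric covariate value in design file")
    names(cov) <- df$sample_id
    monotonicDesign(cov)
  }
}

#' Write an enrichment result table to TSV
#'
#' Columns: target_id, target_type, direction, probes_total (post-filter
#' n_i), probes_signif (X_i), censored, p_value, fdr — sorted by fdr
#' ascending with ties broken by target_id, so identical input yields
#' byte-identical output.
#'
#' @param results an [EnrichmentResults-class] (or its data.frame).
#' @param path output path.
#' @export
writeResults <- function(results, path) {
  df <- as.data.frame(results)
  cols <- c("target_id", "target_type", "direction", "probes_total",
            "probes_signif", "censored", "p_value", "fdr")
  if (nrow(df)) {
    df <- df[order(df$fdr, df$target_id, df$direction), cols, drop = FALSE]
    df$p_value <- formatC(df$p_value, digits = 15, format = "g")
    df$fdr <- formatC(df$fdr, digits = 15, format = "g")
  } else {
    df <- df[, cols, drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read candidate regions from BED (0-based half-open) as GRanges
#' @param path path to BED file.
#' @return GRanges (1-based closed internally); names from column 4 when
#'   present.
#' @export
readBedRegions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t")
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- as.integer(vapply(fields, `[`, "", 2L))
  e0 <- as.integer(vapply(fields, `[`, "", 3L))
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
  if (all(lengths(fields) >= 4L))
    names(gr) <- vapply(fields, `[`, "", 4L)
  gr
}
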