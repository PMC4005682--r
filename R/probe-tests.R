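## Probe-level classification: each probe is tested on its own row of the
## rank-normalized matrix and labeled up/down/none. Both tests are pure
## rank statistics, so classification depends on raw intensities only
## through within-row orderings.

.rowMaxs <- function(m) Reduce(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
.rowMins <- function(m) Reduce(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))

.designColumns <- function(x, ids, what) {
  miss <- setdiff(ids, colnames(x))
  if (length(miss))
    stop(sprintf("%s sample '%s' not found in the matrix", what, miss[1L]))
  ids
}

.extraSamplesWarning <- function(x, used) {
  extra <- setdiff(colnames(x), used)
  if (length(extra))
    warning(length(extra), " sample(s) in the matrix but not in the design were dropped: ",
            paste(utils::head(extra, 3L), collapse = ", "),
            if (length(extra) > 3L) ", ..." else "", call. = FALSE)
}

# Mann-Whitney U per row: number of (TEST, REFERENCE) pairs with
# TEST > REFERENCE, ties counting 1/2. Vectorized over rows.
.rowU <- function(xt, xr) {
  U <- numeric(nrow(xt))
  for (a in seq_len(ncol(xt))) {
    ta <- xt[, a]
    for (b in seq_len(ncol(xr))) {
      rb <- xr[, b]
      U <- U + (ta > rb) + 0.5 * (ta == rb)
    }
  }
  U
}

# TRUE for rows holding at least one tied pair among the used columns
.rowHasTie <- function(x) {
  N <- ncol(x)
  tie <- logical(nrow(x))
  for (a in seq_len(N - 1L))
    for (b in seq((a + 1L), N))
      tie <- tie | (x[, a] == x[, b])
  tie
}

#' Classify probes in a two-group design
#'
#' Applies a one-sided Wilcoxon-Mann-Whitney rank-sum test to every probe
#' row: a probe joins the up set H when the null probability of a TEST
#' rank sum equal to or larger than the observed one is at most
#' \code{alpha}, and the down set L symmetrically. The exact null
#' distribution is used whenever m*n <= 400 and the row has no ties;
#' otherwise a normal approximation with tie and continuity correction.
#' When one group has at most 3 samples a p-value below 0.05 is
#' unattainable, so the small-sample heuristic applies instead: a probe is
#' labeled up (down) only if every TEST value exceeds (falls below) every
#' REFERENCE value — exactly the configurations where the one-sided exact
#' p attains its minimum.
#'
#' @param ranks a [RankMatrix-class] (any probe-by-sample numeric matrix
#'   is accepted; only within-row orderings matter).
#' @param design a two-group [DemiDesign-class].
#' @param alpha per-direction probe significance level, default 0.05.
#' @return a [ProbeClassification-class].
#' @examples
#' rm <- rankNormalize(ProbeMatrix(matrix(
#'   c(1, 2, 3, 4, 5, 6, 7, 8, 8, 7, 6, 5, 4, 3, 2, 1), 2, 8, byrow = TRUE,
#'   dimnames = list(c("pA", "pB"), paste0("s", 1:8)))))
#' d <- twoGroupDesign(paste0("s", 1:4), paste0("s", 5:8))
#' classifyTwoGroup(rm, d)
#' @export
classifyTwoGroup <- function(ranks, design, alpha = 0.05) {
  stopifnot(is(design, "DemiDesign"))
  if (design@mode != "two_group") stop("design must be two_group")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  x <- if (is(ranks, "SummarizedExperiment")) assay(ranks, 1L) else as.matrix(ranks)
  test <- .designColumns(x, design@test, "TEST")
  ref <- .designColumns(x, design@reference, "REFERENCE")
  .extraSamplesWarning(x, c(test, ref))
  m <- length(test); n <- length(ref)
  xt <- x[, test, drop = FALSE]
  xr <- x[, ref, drop = FALSE]
  q <- nrow(x)

  if (min(m, n) <= 3L) {
    up <- .rowMins(xt) > .rowMaxs(xr)
    down <- .rowMaxs(xt) < .rowMins(xr)
  } else {
    U <- .rowU(xt, xr)
    tie <- .rowHasTie(cbind(xt, xr))
    mn <- m * n
    p_up <- p_down <- rep(NA_real_, q)
    exact <- (mn <= 400L) & !tie
    if (any(exact)) {
      # P(U >= u) = P(U <= mn - u) by null symmetry
      p_up[exact] <- stats::pwilcox(mn - U[exact], m, n)
      p_down[exact] <- stats::pwilcox(U[exact], m, n)
    }
    if (any(!exact)) {
      idx <- which(!exact)
      N <- m + n
      sumT <- vapply(idx, function(i) {
        tt <- table(c(xt[i, ], xr[i, ]))
        sum(tt^3 - tt)
      }, 0)
      sigma <- sqrt(mn / 12 * ((N + 1) - sumT / (N * (N - 1))))
      mu <- mn / 2
      p_up[idx] <- stats::pnorm((U[idx] - 0.5 - mu) / sigma, lower.tail = FALSE)
      p_down[idx] <- stats::pnorm((U[idx] + 0.5 - mu) / sigma)
    }
    up <- p_up <= alpha
    down <- p_down <= alpha
    if (any(up & down))
      stop("internal error: probe significant in both directions")
  }
  lab <- factor(rep("none", q), levels = c("up", "down", "none"))
  lab[up] <- "up"
  lab[down] <- "down"
  names(lab) <- rownames(x)
  new("ProbeClassification", label = lab, alpha = alpha,
      mode = "two_group", design = design)
}

# Mahonian numbers: counts of permutations of 1..n by inversion number.
# Generating function prod_{k=1..n} (1 + z + ... + z^{k-1}).
.mahonian <- function(n) {
  counts <- 1
  if (n >= 2L) for (k in 2:n) {
    out <- numeric(length(counts) + k - 1L)
    for (i in 0:(k - 1L))
      out[seq_along(counts) + i] <- out[seq_along(counts) + i] + counts
    counts <- out
  }
  counts  # counts[i] = #permutations with i-1 inversions
}

# One-sided exact upper-tail p for Kendall's T (concordant - discordant)
# with n untied observations: P(T >= t_obs) under the permutation null.
.kendallExactUpper <- function(t_obs, n) {
  npairs <- n * (n - 1) / 2
  counts <- .mahonian(n)
  # T = npairs - 2 * inversions; T >= t_obs  <=>  inv <= (npairs - t_obs)/2
  kmax <- floor((npairs - t_obs) / 2)
  if (kmax < 0) return(0)
  sum(counts[seq_len(min(kmax + 1L, length(counts)))]) / factorial(n)
}

#' Classify probes by monotonic trend over a covariate
#'
#' For designs such as time courses: per probe, Kendall's tau between the
#' normalized signal and the numeric covariate. A probe joins the up set
#' when the one-sided null probability of a concordance statistic at least
#' as large as observed is at most \code{alpha} (down symmetrically). The
#' exact permutation null is used for up to 9 untied covariate values when
#' the probe's signal has no ties; otherwise tau-b with the normal
#' approximation (tie-corrected variance). Fewer than 4 distinct covariate
#' values is rejected: the smallest attainable one-sided p (1/3! = 1/6)
#' can never reach 0.05.
#'
#' @param ranks a [RankMatrix-class] or numeric matrix.
#' @param design a monotonic [DemiDesign-class] (named covariate).
#' @param alpha per-direction significance level, default 0.05.
#' @return a [ProbeClassification-class].
#' @export
classifyMonotonic <- function(ranks, design, alpha = 0.05) {
  stopifnot(is(design, "DemiDesign"))
  if (design@mode != "monotonic") stop("design must be monotonic")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  x <- if (is(ranks, "SummarizedExperiment")) assay(ranks, 1L) else as.matrix(ranks)
  ids <- .designColumns(x, names(design@covariate), "covariate")
  .extraSamplesWarning(x, ids)
  x <- x[, ids, drop = FALSE]
  y <- design@covariate[ids]
  ns <- length(y)
  q <- nrow(x)

  # T = sum over pairs of sign(dx) * sign(dy), vectorized over probes
  Tstat <- numeric(q)
  tieX <- logical(q)
  for (i in seq_len(ns - 1L)) for (j in seq((i + 1L), ns)) {
    dx <- x[, j] - x[, i]
    dy <- y[j] - y[i]
    Tstat <- Tstat + sign(dx) * sign(dy)
    tieX <- tieX | (dx == 0)
  }
  constantX <- .rowMaxs(x) == .rowMins(x)

  yUntied <- !anyDuplicated(y)
  exactRows <- yUntied && ns <= 9L
  p_up <- p_down <- rep(1, q)
  useExact <- if (exactRows) !tieX else rep(FALSE, q)
  if (any(useExact)) {
    tv <- Tstat[useExact]
    p_up[useExact] <- vapply(tv, .kendallExactUpper, 0, n = ns)
    p_down[useExact] <- vapply(-tv, .kendallExactUpper, 0, n = ns)
  }
  approx <- !useExact & !constantX
  if (any(approx)) {
    idx <- which(approx)
    yt <- table(y)
    vy <- sum(yt * (yt - 1) * (2 * yt + 5))
    sy1 <- sum(yt * (yt - 1)); sy2 <- sum(yt * (yt - 1) * (yt - 2))
    v0 <- ns * (ns - 1) * (2 * ns + 5)
    varT <- vapply(idx, function(i) {
      xt <- table(x[i, ])
      vx <- sum(xt * (xt - 1) * (2 * xt + 5))
      sx1 <- sum(xt * (xt - 1)); sx2 <- sum(xt * (xt - 1) * (xt - 2))
      (v0 - vx - vy) / 18 +
        sx1 * sy1 / (2 * ns * (ns - 1)) +
        sx2 * sy2 / (9 * ns * (ns - 1) * (ns - 2))
    }, 0)
    z <- Tstat[idx] / sqrt(varT)
    p_up[idx] <- stats::pnorm(z, lower.tail = FALSE)
    p_down[idx] <- stats::pnorm(z)
  }
  lab <- factor(rep("none", q), levels = c("up", "down", "none"))
  lab[p_up <= alpha & !constantX] <- "up"
  lab[p_down <= alpha & !constantX] <- "down"
  names(lab) <- rownames(x)
  new("ProbeClassification", label = lab, alpha = alpha,
      mode = "monotonic", design = design)
}
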