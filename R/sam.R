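# Two-class unpaired Significance Analysis of Microarrays, implemented from
# scratch: regularized d-statistic, fudge-factor search, permutation null of
# expected order statistics, delta/FDR table and the two selection rules
# (FDR = 0 set; top-k by delta gap).

#' SAM analysis configuration
#'
#' @param n_permutations Number of sampled label arrangements `B` when
#'   exhaustive enumeration is infeasible (>= 100).
#' @param s0_mode `"percentile_cv_min"` (search the percentile grid minimizing
#'   the coefficient of variation of the d-statistic's scale across
#'   s-quantile windows) or `"fixed"`.
#' @param s0_fixed Fudge factor used when `s0_mode = "fixed"`.
#' @param seed Seed for sampled permutations.
#' @param exhaustive_if_feasible Enumerate all label arrangements when their
#'   number is at most `exhaustive_limit`.
#' @param exhaustive_limit Cap on exhaustive enumeration (default 10,000).
#' @param fdr_convention Summary of the per-permutation false-call counts:
#'   `"mean"` (default, the original SAM averaging rule), `"median"` or
#'   `"q90"` (90th percentile). The mean is the only summary that keeps the
#'   FDR = 0 set empty on null data: with the median, the single most extreme
#'   observed order statistic beats the permutation median in about half of
#'   null datasets, yielding spurious one-probe "FDR = 0" sets.
#' @return A `sam_config` list.
#' @export
sam_config <- function(n_permutations = 1000,
                       s0_mode = c("percentile_cv_min", "fixed"),
                       s0_fixed = NULL, seed = 1L,
                       exhaustive_if_feasible = TRUE,
                       exhaustive_limit = 10000,
                       fdr_convention = c("mean", "median", "q90")) {
  s0_mode <- match.arg(s0_mode)
  if (s0_mode == "fixed" && (is.null(s0_fixed) || s0_fixed < 0))
    stop_config("s0_mode = 'fixed' requires s0_fixed >= 0")
  if (n_permutations < 100) stop_config("n_permutations must be >= 100 when sampling")
  structure(list(n_permutations = as.integer(n_permutations), s0_mode = s0_mode,
                 s0_fixed = s0_fixed, seed = as.integer(seed),
                 exhaustive_if_feasible = isTRUE(exhaustive_if_feasible),
                 exhaustive_limit = exhaustive_limit,
                 fdr_convention = match.arg(fdr_convention)),
            class = "sam_config")
}

# normalize labels to a logical "is class 2" vector; class 1 = first level
as_two_class <- function(labels, n) {
  if (length(labels) != n) stop("labels length must equal sample count", call. = FALSE)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes", call. = FALSE)
  g2 <- f == levels(f)[2]
  if (sum(g2) < 2 || sum(!g2) < 2)
    stop("both classes need >= 2 samples", call. = FALSE)
  g2
}

#' SAM relative difference d and pooled scatter s
#'
#' For each probe row, `d = (mean_class2 - mean_class1) / (s + s0)` with the
#' pooled-variance scatter
#' `s = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`. Missing cells are
#' excluded per probe with class sizes recomputed; a probe with fewer than two
#' values in either class, or with `s + s0 = 0`, gets `d = NA` and is flagged
#' in `excluded`.
#'
#' @param x Probes x samples numeric matrix.
#' @param labels Two-class vector over columns (first factor level = class 1).
#' @param s0 Fudge factor added to the denominator.
#' @return list: `d`, `s`, `numerator` (class2 - class1 mean difference),
#'   `excluded` (logical), `n1`, `n2`.
#' @export
d_statistic <- function(x, labels, s0) {
  g2 <- as_two_class(labels, ncol(x))
  M <- !is.na(x)
  x0 <- x; x0[!M] <- 0
  n1 <- rowSums(M[, !g2, drop = FALSE]); n2 <- rowSums(M[, g2, drop = FALSE])
  sum1 <- rowSums(x0[, !g2, drop = FALSE]); sum2 <- rowSums(x0[, g2, drop = FALSE])
  m1 <- sum1 / n1; m2 <- sum2 / n2
  ss1 <- pmax(rowSums(x0[, !g2, drop = FALSE]^2) - n1 * m1^2, 0)
  ss2 <- pmax(rowSums(x0[, g2, drop = FALSE]^2) - n2 * m2^2, 0)
  ok <- n1 >= 2 & n2 >= 2
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / pmax(n1 + n2 - 2, 1))
  num <- m2 - m1
  d <- num / (s + s0)
  d[!ok | (s + s0) == 0] <- NA_real_
  excluded <- !ok | (s + s0) == 0
  names(d) <- rownames(x)
  list(d = d, s = s, numerator = num, excluded = excluded, n1 = n1, n2 = n2)
}

# Bulk d over many label arrangements. W is an n x B logical matrix, column b
# giving the class-2 membership of arrangement b. Everything reduces to six
# matrix products, so B arrangements cost one BLAS call each way.
d_bulk <- function(x, W, s0) {
  M <- !is.na(x) + 0
  x0 <- x; x0[is.na(x)] <- 0
  Wn <- W + 0
  n2 <- M %*% Wn
  n1 <- M %*% (1 - Wn)
  s2x <- x0 %*% Wn
  s1x <- x0 %*% (1 - Wn)
  s2xx <- (x0 * x0) %*% Wn
  s1xx <- (x0 * x0) %*% (1 - Wn)
  m1 <- s1x / n1; m2 <- s2x / n2
  ss <- pmax(s1xx - n1 * m1^2, 0) + pmax(s2xx - n2 * m2^2, 0)
  s <- sqrt((1 / n1 + 1 / n2) * ss / pmax(n1 + n2 - 2, 1))
  (m2 - m1) / (s + s0)
}

#' Choose the SAM fudge factor s0
#'
#' Searches the 0th-100th percentiles of the scatter `s` in steps of 5,
#' choosing the candidate that minimizes the coefficient of variation of the
#' median absolute deviation of `d` computed within s-quantile windows
#' (the standard automatic tuning that decouples `d`'s spread from `s`).
#' Deterministic given its inputs.
#'
#' @param s Per-probe scatter values (>= 20 probes).
#' @param numerator Per-probe mean-difference numerators.
#' @return list: `s0`, `alpha` (chosen percentile), `cv` (per-candidate
#'   criterion values, named by percentile).
#' @export
choose_s0 <- function(s, numerator) {
  if (length(s) < 20) stop("choose_s0 needs >= 20 probes", call. = FALSE)
  alphas <- seq(0, 1, by = 0.05)
  if (max(s) - min(s) < .Machine$double.eps) {
    # flat scatter: every percentile gives the common value
    return(list(s0 = s[1], alpha = 0,
                cv = setNames(rep(NA_real_, length(alphas)), alphas)))
  }
  nw <- min(100, max(3, floor(length(s) / 10)))
  br <- unique(quantile(s, seq(0, 1, length.out = nw + 1)))
  grp <- cut(s, br, include.lowest = TRUE, labels = FALSE)
  cand <- quantile(s, alphas, names = FALSE)
  cv <- vapply(cand, function(s0) {
    dd <- numerator / (s + s0)
    v <- tapply(dd, grp, mad)
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, 0)
  names(cv) <- alphas
  pick <- which.min(cv)  # ties -> smallest percentile
  list(s0 = cand[pick], alpha = alphas[pick], cv = cv)
}

#' Permutation null of SAM order statistics
#'
#' Recomputes `d` under permuted class labels and sorts each permutation; the
#' expected relative difference at rank r, `dbarE_r`, is the mean over
#' permutations of the r-th order statistic. All `choose(n, n2)` label
#' arrangements are enumerated when feasible (at most
#' `config$exhaustive_limit`); otherwise `B` arrangements are sampled
#' uniformly using `config$seed`.
#'
#' @param x Probes x samples matrix (rows with insufficient data must already
#'   be removed; see [sam_twoclass()]).
#' @param labels Two-class vector over columns.
#' @param s0 Fudge factor (fixed at the observed-data value).
#' @param config A [sam_config()].
#' @return list: `dbarE` (non-decreasing, length = rows of `x`),
#'   `perm_sorted` (probes x permutations matrix of sorted permuted d),
#'   `n_arrangements`, `exhaustive`.
#' @export
permutation_null <- function(x, labels, s0, config = sam_config()) {
  g2 <- as_two_class(labels, ncol(x))
  n <- ncol(x); n2 <- sum(g2)
  n_arr <- choose(n, n2)
  if (n_arr <= 1) stop("classes are degenerate: only one label arrangement", call. = FALSE)
  exhaustive <- config$exhaustive_if_feasible && n_arr <= config$exhaustive_limit
  W <- if (exhaustive) {
    combs <- combn(n, n2)
    W <- matrix(FALSE, n, ncol(combs))
    W[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n2))] <- TRUE
    W
  } else {
    with_seed(config$seed, {
      B <- config$n_permutations
      W <- matrix(FALSE, n, B)
      for (b in seq_len(B)) W[sample.int(n, n2), b] <- TRUE
      W
    })
  }
  D <- d_bulk(x, W, s0)
  if (anyNA(D)) {
    # a permutation can in principle isolate the missing cells of a probe;
    # treat such degenerate permuted statistics as null (0)
    warning(sum(is.na(D)), " degenerate permuted d value(s) set to 0", call. = FALSE)
    D[is.na(D)] <- 0
  }
  Ds <- apply(D, 2, sort)
  list(dbarE = rowMeans(Ds), perm_sorted = Ds,
       n_arrangements = ncol(W), exhaustive = exhaustive)
}

#' Delta table: calls and permutation FDR at a grid of thresholds
#'
#' For each `delta`, the asymmetric SAM cutpoints are found on the observed
#' order statistics: scanning the rank-ordered `d` against `dbarE`, the upper
#' cut is the smallest `d` whose gap `d - dbarE` reaches `delta`, the lower
#' cut the largest `d` with `dbarE - d >= delta`. All probes beyond a cut are
#' called. The false-call estimate is the median (or configured summary) over
#' permutations of the number of permuted `d` values beyond the cuts, and
#' `FDR = false / max(called, 1)`, capped at 1. `delta = 0` calls every probe;
#' a `delta` beyond the largest gap calls none and reports `FDR = 0` with
#' `no_calls = TRUE`.
#'
#' @param d Observed per-probe d (no NAs).
#' @param dbarE Expected order statistics from [permutation_null()].
#' @param perm_sorted Sorted permuted d matrix from the same analysis.
#' @param delta_grid Non-empty increasing vector of thresholds.
#' @param convention `"median"`, `"q90"` or `"mean"`.
#' @return data.frame: `delta`, `n_called`, `false_est`, `fdr`, `cut_lower`,
#'   `cut_upper`, `no_calls`.
#' @export
fdr_table <- function(d, dbarE, perm_sorted, delta_grid,
                      convention = c("mean", "median", "q90")) {
  convention <- match.arg(convention)
  if (!length(delta_grid)) stop("empty delta grid", call. = FALSE)
  p <- length(d)
  ds <- sort(d)
  gaps <- ds - dbarE
  B <- ncol(perm_sorted)
  rows <- lapply(delta_grid, function(delta) {
    iu <- which(gaps >= delta)
    il <- which(gaps <= -delta)
    cut_up <- if (length(iu)) ds[min(iu)] else Inf
    cut_lo <- if (length(il)) ds[max(il)] else -Inf
    n_called <- if (cut_lo >= cut_up) p else sum(ds >= cut_up) + sum(ds <= cut_lo)
    false_b <- vapply(seq_len(B), function(b) {
      col <- perm_sorted[, b]
      n_up <- if (is.finite(cut_up)) p - findInterval(cut_up, col, left.open = TRUE) else 0L
      n_lo <- if (is.finite(cut_lo)) findInterval(cut_lo, col) else 0L
      min(n_up + n_lo, p)
    }, 0)
    false_est <- switch(convention,
                        median = median(false_b),
                        q90 = unname(quantile(false_b, 0.9, type = 1)),
                        mean = mean(false_b))
    data.frame(delta = delta, n_called = n_called, false_est = false_est,
               fdr = if (n_called == 0) 0 else min(false_est / n_called, 1),
               cut_lower = cut_lo, cut_upper = cut_up,
               no_calls = n_called == 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "convention") <- convention
  out
}

default_delta_grid <- function(gaps, length.out = 50) {
  gmax <- max(abs(gaps))
  if (gmax == 0) return(0)
  sort(unique(c(seq(0, gmax, length.out = length.out), gmax)))
}

#' Full two-class SAM analysis
#'
#' Runs the complete SAM sequence on an FR matrix: probe filtering (rows with
#' fewer than two values in a class are excluded and logged), fudge-factor
#' selection, observed d, permutation null, per-probe delta gaps and the
#' delta/FDR table.
#'
#' @param fr Probes x samples matrix.
#' @param labels Two-class vector over columns (e.g. `"lymphoid"` vs
#'   `"other"`; the first factor level is class 1, and positive `d` means a
#'   higher mean in class 2).
#' @param config A [sam_config()].
#' @param delta_grid Optional explicit delta grid.
#' @return A `sam_result` list: `probes` data.frame (`probe_id`, `d`, `s`,
#'   `numerator`, `rank`, `dbarE`, `gap`), `s0`, `s0_alpha`, `delta_table`,
#'   `dbarE`, `perm_sorted`, `n_arrangements`, `exhaustive`, `excluded`
#'   (probe ids), `config`, `labels`.
#' @export
sam_twoclass <- function(fr, labels, config = sam_config(), delta_grid = NULL) {
  g2 <- as_two_class(labels, ncol(fr))
  base <- d_statistic(fr, labels, s0 = 0)
  drop <- base$excluded & (base$n1 < 2 | base$n2 < 2)
  x <- fr[!drop, , drop = FALSE]
  if (!nrow(x)) stop("no probe has >= 2 values in both classes", call. = FALSE)
  if (any(drop))
    message(sum(drop), " probe(s) excluded: fewer than 2 values in a class")

  s <- base$s[!drop]; num <- base$numerator[!drop]
  if (config$s0_mode == "fixed") {
    s0 <- config$s0_fixed; s0_alpha <- NA_real_
  } else {
    ch <- choose_s0(s, num)
    s0 <- ch$s0; s0_alpha <- ch$alpha
  }
  d <- num / (s + s0)
  flagged <- (s + s0) == 0
  if (any(flagged)) {
    message(sum(flagged), " probe(s) with s + s0 = 0 flagged (d undefined, treated as 0)")
    d[flagged] <- 0
  }
  names(d) <- rownames(x)

  nul <- permutation_null(x, labels, s0, config)
  rk <- rank(d, ties.method = "first")
  dbar_at <- nul$dbarE[rk]
  gap <- d - dbar_at

  dg <- delta_grid %||% default_delta_grid(gap)
  tab <- fdr_table(d, nul$dbarE, nul$perm_sorted, dg, config$fdr_convention)

  probes <- data.frame(probe_id = rownames(x), d = d, s = s, numerator = num,
                       rank = rk, dbarE = dbar_at, gap = gap,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(probes = probes, s0 = s0, s0_alpha = s0_alpha,
                 delta_table = tab, dbarE = nul$dbarE,
                 perm_sorted = nul$perm_sorted,
                 n_arrangements = nul$n_arrangements,
                 exhaustive = nul$exhaustive,
                 excluded = rownames(fr)[drop],
                 config = config, labels = labels),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d probes, s0 = %.4g, %s%d permutations (%s)\n",
              nrow(x$probes), x$s0,
              if (x$exhaustive) "exhaustive " else "", x$n_arrangements,
              attr(x$delta_table, "convention")))
  fdr0 <- select_fdr_zero(x)
  cat(sprintf("  probes at FDR = 0: %d\n", length(fdr0)))
  invisible(x)
}

#' Probe set at the smallest delta reaching FDR = 0
#'
#' Returns the called set at the smallest delta whose estimated FDR equals 0
#' with at least one call — the largest FDR = 0 set. If no delta achieves it,
#' an empty set is returned with a `notice` attribute.
#'
#' @param result A [sam_twoclass()] result.
#' @return Character vector of probe ids (possibly empty).
#' @export
select_fdr_zero <- function(result) {
  tab <- result$delta_table
  ok <- tab$fdr == 0 & !tab$no_calls
  if (!any(ok)) {
    out <- character(0)
    attr(out, "notice") <- "no delta achieves FDR = 0 with calls"
    return(out)
  }
  row <- tab[which(ok)[1], ]
  d <- result$probes$d
  sel <- d >= row$cut_upper | d <= row$cut_lower
  result$probes$probe_id[sel]
}

#' Top probes by enhanced delta gap
#'
#' Ranks probes by the absolute gap between observed and expected relative
#' difference at their rank, descending; ties are broken by `|d|`, then by
#' genome address (the row order of the analysed matrix), then probe id.
#'
#' @param result A [sam_twoclass()] result.
#' @param k Number of probes to return (1 <= k <= probes analysed).
#' @return Character vector of `k` probe ids, most enhanced first.
#' @export
top_by_delta_gap <- function(result, k = 22) {
  p <- result$probes
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(p)) stop("k exceeds number of analysed probes", call. = FALSE)
  o <- order(-abs(p$gap), -abs(p$d), seq_len(nrow(p)), p$probe_id)
  p$probe_id[o][seq_len(k)]
}
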