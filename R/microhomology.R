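#' Canonicalize a deletion breakpoint to its leftmost placement
#'
#' When a deletion breakpoint lies inside a microhomology tract, the same
#' acceptor sequence results from a window of equivalent placements: the
#' window can shift left by one whenever the base before the deletion equals
#' the last deleted base.  This shifts the window as far left as the contig
#' allows, giving a unique canonical placement.
#'
#' @param seq contig sequence (character string) carrying the segment.
#' @param start,end 0-based half-open deletion coordinates.
#' @return integer vector `c(start, end)` of the canonical placement.
#' @export
canonicalize_breakpoint <- function(seq, start, end) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  while (start > 0 && ch[start] == ch[end]) {  # 1-based: base before start
    start <- start - 1L
    end <- end - 1L
  }
  c(start = as.integer(start), end = as.integer(end))
}

mh_run <- function(ch, i, j, step, lo, hi) {
  # length of the maximal run with ch[i + t*step] == ch[j + t*step],
  # indices kept within [lo, hi]
  k <- 0L
  while (i >= lo && i <= hi && j >= lo && j <= hi && ch[i] == ch[j]) {
    k <- k + 1L
    i <- i + step; j <- j + step
  }
  k
}

#' Extract the exact microhomology at a deletion breakpoint
#'
#' After canonicalizing the placement (see [canonicalize_breakpoint()]),
#' computes the maximal exact match on each side of the breakpoint: on the
#' right, the longest `k` such that the first `k` deleted bases equal the
#' `k` bases following the deletion end; on the left, the longest `k` such
#' that the last `k` deleted bases equal the `k` bases preceding the
#' deletion start.  The longer side is reported; ties go to the right.  A
#' deletion at a contig edge has no flank on that side, which contributes 0.
#'
#' @param seq contig sequence carrying the deleted segment.
#' @param start,end 0-based half-open deletion coordinates.
#' @param canonical canonicalize the placement first (default `TRUE`).
#' @return list of class `mh_result`: `length` (bp), `motif` (the matched
#'   sequence, `""` if none), `side` (`"left"` or `"right"`), `start`/`end`
#'   (the placement used).
#' @export
extract_microhomology <- function(seq, start, end, canonical = TRUE) {
  n <- nchar(seq)
  if (!(start >= 0 && start < end && end <= n))
    stop("invalid breakpoint: need 0 <= start < end <= contig length")
  if (canonical) {
    ce <- canonicalize_breakpoint(seq, start, end)
    start <- ce[["start"]]; end <- ce[["end"]]
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  del_len <- end - start
  # right: deleted prefix vs bases after end (1-based indices start+1, end+1)
  right <- mh_run(ch, start + 1L, end + 1L, +1L, 1L, n)
  right <- as.integer(min(right, del_len, n - end))
  # left: deleted suffix vs bases before start
  left <- mh_run(ch, end, start, -1L, 1L, n)
  left <- as.integer(min(left, del_len, start))
  if (right >= left) {
    structure(list(length = right,
                   motif = if (right > 0)
                     substr(seq, start + 1L, start + right) else "",
                   side = "right", start = start, end = end),
              class = "mh_result")
  } else {
    structure(list(length = left,
                   motif = substr(seq, end - left + 1L, end),
                   side = "left", start = start, end = end),
              class = "mh_result")
  }
}

#' @export
print.mh_result <- function(x, ...) {
  cat("microhomology:", x$length, "bp",
      if (x$length > 0) paste0("(", x$motif, ", ", x$side, " side)") else "",
      "\n")
  invisible(x)
}

#' Summarise a set of microhomology lengths
#'
#' Lengths below `mh_min` count as "no microhomology" (very short exact
#' matches arise by chance); the summary reports the fraction of breakpoints
#' with microhomology and the size statistics of those that have it,
#' together with the length histogram.
#'
#' @param lengths integer vector of per-breakpoint microhomology lengths
#'   (or a list of `mh_result` objects).
#' @param mh_min minimum length considered a genuine microhomology.
#' @return list of class `mh_summary`: `n`, `n_with_mh`, `fraction_with_mh`,
#'   `min`, `max`, `mean` (over breakpoints with microhomology), and
#'   `histogram` (a table over observed lengths `>= mh_min`).
#' @export
mh_size_distribution <- function(lengths, mh_min = 3L) {
  if (is.list(lengths))
    lengths <- vapply(lengths, `[[`, numeric(1), "length")
  if (length(lengths) == 0) stop("no microhomology results supplied")
  mh <- lengths[lengths >= mh_min]
  structure(list(n = length(lengths), n_with_mh = length(mh),
                 fraction_with_mh = length(mh) / length(lengths),
                 min = if (length(mh)) min(mh) else NA_integer_,
                 max = if (length(mh)) max(mh) else NA_integer_,
                 mean = if (length(mh)) mean(mh) else NA_real_,
                 histogram = table(factor(mh, levels =
                   if (length(mh)) seq(min(mh), max(mh)) else integer(0))),
                 mh_min = mh_min),
            class = "mh_summary")
}

#' @export
print.mh_summary <- function(x, ...) {
  cat(sprintf("%d breakpoints, %d (%.1f%%) with microhomology >= %d bp\n",
              x$n, x$n_with_mh, 100 * x$fraction_with_mh, x$mh_min))
  if (x$n_with_mh)
    cat(sprintf("  sizes: %d-%d bp, mean %.2f bp\n", x$min, x$max, x$mean))
  invisible(x)
}

# ML fit of a geometric decay on lengths in [m, max], excluding the bin at
# `exclude`; the likelihood is the multinomial over the remaining bins,
# renormalized.  Support treated as unbounded above m.
fit_geometric_excluding <- function(lengths, m, exclude) {
  tab <- table(lengths)
  j <- as.integer(names(tab))
  use <- j != exclude
  nj <- as.integer(tab)[use]; jj <- j[use]
  negll <- function(p) {
    lpj <- (jj - m) * log1p(-p) + log(p)
    norm <- 1 - p * (1 - p)^(exclude - m)
    -(sum(nj * lpj) - sum(nj) * log(norm))
  }
  p <- optimize(negll, c(1e-6, 1 - 1e-6))$minimum
  p
}

#' Test for an excess of microhomologies at a focal size
#'
#' The bulk of microhomology sizes decays roughly exponentially, as expected
#' when end-joining repair reuses short chance matches; an extra mode at a
#' focal size (5 bp is the target-site-duplication length of LTR
#' retrotransposons) shows up as observed mass at that size exceeding the
#' geometric-null prediction.  The null is fitted by maximum likelihood to
#' all bins except the focal one (renormalized), and the excess is the
#' observed share at the focal size minus the null-predicted share.  A
#' seeded bootstrap gives its uncertainty.
#'
#' @param lengths microhomology lengths (only values `>= mh_min` used).
#' @param mode_bp focal size in bp.
#' @param mh_min minimum genuine microhomology length; also the support
#'   start of the geometric null.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list of class `mh_excess`: `p_geom` (fitted decay), `observed`
#'   (share at `mode_bp`), `expected` (null share), `excess`, `se`
#'   (bootstrap), `ci` (2.5/97.5% bootstrap quantiles), `n`.
#' @export
excess_at_mode <- function(lengths, mode_bp = 5L, mh_min = 3L, B = 1000L,
                           seed = 1L) {
  x <- lengths[lengths >= mh_min]
  if (length(unique(x)) < 2)
    stop("degenerate histogram: need at least two distinct lengths >= mh_min")
  one <- function(x) {
    p <- fit_geometric_excluding(x, mh_min, mode_bp)
    obs <- mean(x == mode_bp)
    exp_share <- p * (1 - p)^(mode_bp - mh_min)
    c(p = p, observed = obs, expected = exp_share,
      excess = obs - exp_share)
  }
  est <- one(x)
  set.seed(substream_seed(seed, "mh_bootstrap"))
  boot <- replicate(B, {
    xb <- x[sample.int(length(x), replace = TRUE)]
    if (length(unique(xb)) < 2) NA_real_ else one(xb)[["excess"]]
  })
  boot <- boot[!is.na(boot)]
  structure(list(p_geom = est[["p"]], observed = est[["observed"]],
                 expected = est[["expected"]], excess = est[["excess"]],
                 se = sd(boot),
                 ci = quantile(boot, c(0.025, 0.975), names = FALSE),
                 n = length(x), mode_bp = mode_bp),
            class = "mh_excess")
}

#' @export
print.mh_excess <- function(x, ...) {
  cat(sprintf(paste0("share at %d bp: observed %.3f, geometric null %.3f\n",
                     "excess %.3f (bootstrap se %.3f, 95%% CI %.3f-%.3f)\n"),
              x$mode_bp, x$observed, x$expected, x$excess, x$se,
              x$ci[1], x$ci[2]))
  invisible(x)
}
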