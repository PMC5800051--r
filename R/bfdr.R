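#' Bayesian FDR classification of posterior cluster memberships
#'
#' Each region's MAP call (present or absent) carries a posterior
#' misclassification probability `q = 1 - max(tau_absent, tau_present)`.
#' Sorting regions by ascending `q`, the largest prefix whose running mean
#' of `q` stays at or below `alpha` is classified; the rest remain
#' unclassified.  The running mean over the classified prefix is the
#' posterior expected proportion of wrong calls among those made — the
#' realized Bayesian FDR estimate.
#'
#' @param tau a `pav_mixture` fit, an n x 2 posterior matrix, or a vector of
#'   cluster-1 ("present") posteriors.
#' @param alpha nominal BFDR level in (0, 1).
#' @return data frame of class `pav_calls` with columns `call`
#'   (`"present"`, `"absent"`, `"unclassified"`), `tau_present`, `q`,
#'   `classified`; attributes `alpha`, `bfdr` (realized estimate, NA when
#'   nothing is classified) and `n_classified`.
#' @examples
#' bfdr_classify(c(0.999, 0.998, 0.95, 0.60), alpha = 0.01)
#' @export
bfdr_classify <- function(tau, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (inherits(tau, "pav_mixture")) tau <- tau$tau
  t1 <- if (is.matrix(tau)) tau[, 2] else as.numeric(tau)
  if (any(t1 < 0 | t1 > 1, na.rm = TRUE))
    stop("posterior probabilities must lie in [0, 1]")
  q <- 1 - pmax(t1, 1 - t1)
  ord <- order(q)
  cm <- cumsum(q[ord]) / seq_along(ord)
  k <- if (any(cm <= alpha)) max(which(cm <= alpha)) else 0L
  classified <- logical(length(q))
  if (k > 0) classified[ord[seq_len(k)]] <- TRUE
  call <- ifelse(classified, ifelse(t1 >= 0.5, "present", "absent"),
                 "unclassified")
  out <- data.frame(call = call, tau_present = t1, q = q,
                    classified = classified)
  attr(out, "alpha") <- alpha
  attr(out, "bfdr") <- if (k > 0) cm[k] else NA_real_
  attr(out, "n_classified") <- k
  class(out) <- c("pav_calls", "data.frame")
  out
}

#' @export
print.pav_calls <- function(x, ...) {
  cat(sprintf("%d regions: %d classified at nominal BFDR %.3g (realized %.4g)\n",
              nrow(x), attr(x, "n_classified"), attr(x, "alpha"),
              attr(x, "bfdr")))
  print(table(x$call))
  invisible(x)
}

# single-component weighted regression used for model selection against the
# two-component fit (a line whose counts track the donor everywhere, or
# nowhere, has no second cluster to find)
.single_fit <- function(x, y) {
  f <- .wls(x, y, rep(1, length(x)))
  ll <- sum(dnorm(y, f["a"] + f["b"] * x, sqrt(f[["s2"]]), log = TRUE))
  list(a = f[["a"]], b = f[["b"]], sigma2 = f[["s2"]], loglik = ll)
}

#' Genotype a panel of lines from a PAV depth matrix
#'
#' For each line (the donor control included), fits the two-component
#' regression mixture of [pav_mixture()] on that line's sqrt counts against
#' the donor's, computes posteriors, and classifies regions with
#' [bfdr_classify()].  Lines are fitted independently.
#'
#' A control line carrying every region (or none) has a single cluster and
#' the two-component fit either collapses or splits noise; each line is
#' therefore also fitted with a single regression line, and the
#' single-component model is adopted when its BIC is lower (or when every
#' EM start collapses).  Under a single component all regions are classified
#' to the one cluster — present when the fitted slope is at least 0.5,
#' absent otherwise — with posterior 1.
#'
#' Lines whose raw counts are all zero are skipped and reported.
#'
#' @param depth a `pav_depth` ([simulate_depth_matrix()],
#'   [as_depth_matrix()]).
#' @param alpha nominal BFDR level.
#' @param seed seed forwarded to the EM random starts.
#' @param ... passed to [pav_mixture()].
#' @return object of class `pav_callset`: `calls` (region x line matrix with
#'   1 = present, 0 = absent, NA = unclassified), `posterior` (matrix of
#'   present-cluster posteriors), `fits` (per-line model objects), `bfdr`
#'   (per-line realized estimates), `skipped` (all-zero lines), `alpha`.
#' @export
genotype_panel <- function(depth, alpha = 0.01, seed = 1L, ...) {
  stopifnot(inherits(depth, "pav_depth"))
  if (!isTRUE(depth$transformed)) depth <- sqrt_transform(depth)
  if (nrow(depth$Y) == 0 || ncol(depth$Y) == 0)
    stop("empty depth matrix")
  x <- depth$x
  lines <- depth$lines
  calls <- matrix(NA_integer_, nrow(depth$Y), length(lines),
                  dimnames = list(depth$regions, lines))
  post <- matrix(NA_real_, nrow(depth$Y), length(lines),
                 dimnames = list(depth$regions, lines))
  fits <- list(); bfdr <- setNames(rep(NA_real_, length(lines)), lines)
  skipped <- character(0)
  n <- length(x)

  for (ln in lines) {
    y <- depth$Y[, ln]
    if (!is.null(depth$counts) && all(depth$counts[, ln] == 0)) {
      skipped <- c(skipped, ln)
      next
    }
    fit2 <- tryCatch(pav_mixture(x, y, seed = substream_seed(seed, ln), ...),
                     error = function(e) e)
    fit1 <- .single_fit(x, y)
    use_single <- inherits(fit2, "error")
    if (!use_single) {
      bic2 <- -2 * fit2$loglik + 7 * log(n)
      bic1 <- -2 * fit1$loglik + 3 * log(n)
      use_single <- bic1 < bic2
    }
    if (use_single) {
      lab <- if (fit1$b >= 0.5) 1L else 0L
      calls[, ln] <- lab
      post[, ln] <- if (lab == 1L) 1 else 0
      fits[[ln]] <- structure(fit1, class = "pav_single_fit")
      bfdr[ln] <- 0
    } else {
      cl <- bfdr_classify(fit2, alpha = alpha)
      calls[, ln] <- ifelse(cl$classified,
                            ifelse(cl$call == "present", 1L, 0L),
                            NA_integer_)
      post[, ln] <- cl$tau_present
      fits[[ln]] <- fit2
      bfdr[ln] <- attr(cl, "bfdr")
    }
  }
  structure(list(calls = calls, posterior = post, fits = fits,
                 bfdr = bfdr, skipped = skipped, alpha = alpha,
                 donor = depth$donor),
            class = "pav_callset")
}

#' @export
print.pav_callset <- function(x, ...) {
  cl <- x$calls
  cat(sprintf("PAV genotype calls: %d regions x %d lines (nominal BFDR %g)\n",
              nrow(cl), ncol(cl), x$alpha))
  cat(sprintf("  classified: %.1f%% (present %.1f%%, absent %.1f%%)\n",
              100 * mean(!is.na(cl)), 100 * mean(cl == 1, na.rm = TRUE) *
                mean(!is.na(cl)),
              100 * mean(cl == 0, na.rm = TRUE) * mean(!is.na(cl))))
  if (length(x$skipped)) cat("  skipped lines:",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
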