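#' Two-component mixture of linear regressions on sqrt-scale read counts
#'
#' Fits the read-depth genotyping model: with `x` the donor line's
#' sqrt-transformed count for each region and `y` the target line's, each
#' region belongs to an unobserved cluster `Z` — cluster 1 ("present", the
#' line carries the region, so its depth scales with the donor's) or
#' cluster 0 ("absent", depth near zero regardless of `x`):
#'
#' \deqn{Y_i = a_0 + b_0 x_i + E_i \ (Z_i = 0), \qquad
#'       Y_i = a_1 + b_1 x_i + E_i \ (Z_i = 1),}
#'
#' with independent Gaussian errors of cluster-specific variance and mixing
#' proportion `pi` for cluster 1.  Maximum likelihood is obtained by EM: the
#' E-step computes posterior cluster memberships `tau` from the Gaussian
#' densities; the M-step solves two weighted least-squares regressions and
#' weighted variances, and updates `pi`.  The best of `n_starts` runs by
#' final log-likelihood is kept, and labels are canonicalized so cluster 1
#' has the larger slope.
#'
#' @param x sqrt-scale donor counts (covariate), length n >= 10.
#' @param y sqrt-scale target-line counts (response).
#' @param init optional list with starting values `a0,b0,sigma0,a1,b1,sigma1,pi`
#'   used as an additional first start.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of starts: the first splits the points at the
#'   median of `y/x`, the rest assign random memberships.
#' @param seed optional seed for the random starts.
#' @return object of class `pav_mixture` with components `coefficients`
#'   (2 x 2 matrix, rows `absent`/`present`, columns `intercept`/`slope`),
#'   `sigma2`, `pi` (mixing proportion of `present`), `tau` (n x 2 posterior
#'   matrix), `loglik`, `loglik_trace`, `n_iter`, `converged`, and the data.
#' @examples
#' set.seed(1)
#' x <- runif(200, 10, 40)
#' z <- rbinom(200, 1, 0.5)
#' y <- ifelse(z == 1, x, 0) + rnorm(200, 0, 0.8)
#' fit <- pav_mixture(x, y, seed = 1)
#' coef(fit)
#' @export
pav_mixture <- function(x, y, init = NULL, tol = 1e-8, max_iter = 500L,
                        n_starts = 5L, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (!is.null(seed)) set.seed(substream_seed(seed, "em_starts"))

  starts <- list()
  r <- y / pmax(x, 1e-8)
  starts[[1]] <- as.numeric(r > median(r))
  if (n_starts > 1)
    for (s in 2:n_starts) starts[[s]] <- runif(n)
  init_tau <- lapply(starts, function(z1) cbind(1 - z1, z1))
  if (!is.null(init))
    init_tau <- c(list(.tau_from_params(x, y, init)), init_tau)

  best <- NULL
  degenerate <- 0L
  for (tau in init_tau) {
    fit <- tryCatch(.em_run(x, y, tau, tol, max_iter),
                    error = function(e) e)
    if (inherits(fit, "error")) { degenerate <- degenerate + 1L; next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("degenerate fit: every EM start collapsed a component below 2 ",
         "effective points (data may contain a single cluster)")
  # two essentially coincident components mean the data hold one cluster:
  # the mixture is unidentifiable and its calls meaningless
  sep <- mean(abs((best$coef[2, 1] + best$coef[2, 2] * x) -
                  (best$coef[1, 1] + best$coef[1, 2] * x))) /
    sqrt(max(best$sigma2))
  if (sep < 1)
    stop("degenerate fit: fitted components are not separated ",
         sprintf("(separation %.2f sd)", sep),
         "; the data appear to contain a single cluster")

  # canonical labels: cluster 1 ("present") has the larger slope
  if (best$coef[1, 2] > best$coef[2, 2] ||
      (best$coef[1, 2] == best$coef[2, 2] &&
       best$coef[1, 1] > best$coef[2, 1])) {
    best$coef <- best$coef[2:1, ]
    best$sigma2 <- best$sigma2[2:1]
    best$pi <- 1 - best$pi
    best$tau <- best$tau[, 2:1]
  }
  dimnames(best$coef) <- list(c("absent", "present"),
                              c("intercept", "slope"))
  names(best$sigma2) <- c("absent", "present")
  colnames(best$tau) <- c("absent", "present")

  structure(list(coefficients = best$coef, sigma2 = best$sigma2,
                 pi = best$pi, tau = best$tau, loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged,
                 degenerate_starts = degenerate,
                 x = x, y = y, n = n, call = match.call()),
            class = "pav_mixture")
}

.tau_from_params <- function(x, y, p) {
  l0 <- log1p(-p$pi) + dnorm(y, p$a0 + p$b0 * x, max(p$sigma0, 1e-6),
                             log = TRUE)
  l1 <- log(p$pi) + dnorm(y, p$a1 + p$b1 * x, max(p$sigma1, 1e-6),
                          log = TRUE)
  m <- pmax(l0, l1)
  t1 <- exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
  cbind(1 - t1, t1)
}

.wls <- function(x, y, w) {
  sw <- sum(w)
  if (sw < 2) stop("component weight below 2 effective points")
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  b <- if (sxx < 1e-12) 0 else sum(w * (x - mx) * (y - my)) / sxx
  a <- my - b * mx
  s2 <- sum(w * (y - a - b * x)^2) / sw
  c(a = a, b = b, s2 = max(s2, 1e-12))
}

.em_run <- function(x, y, tau, tol, max_iter) {
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step
    f0 <- .wls(x, y, tau[, 1])
    f1 <- .wls(x, y, tau[, 2])
    pi1 <- mean(tau[, 2])
    pi1 <- min(max(pi1, 1e-12), 1 - 1e-12)
    # E-step (log space)
    l0 <- log1p(-pi1) + dnorm(y, f0["a"] + f0["b"] * x, sqrt(f0["s2"]),
                              log = TRUE)
    l1 <- log(pi1) + dnorm(y, f1["a"] + f1["b"] * x, sqrt(f1["s2"]),
                           log = TRUE)
    m <- pmax(l0, l1)
    d0 <- exp(l0 - m); d1 <- exp(l1 - m)
    tau <- cbind(d0, d1) / (d0 + d1)
    ll <- sum(m + log(d0 + d1))
    trace <- c(trace, ll)
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(coef = rbind(c(f0["a"], f0["b"]), c(f1["a"], f1["b"])),
       sigma2 = c(f0[["s2"]], f1[["s2"]]), pi = pi1, tau = tau,
       loglik = ll, trace = trace, n_iter = it, converged = converged)
}

#' Posterior cluster membership under a fitted mixture
#'
#' @param fit a `pav_mixture`.
#' @param x,y new data on the sqrt scale; defaults to the training data.
#' @return n x 2 matrix of posterior probabilities (`absent`, `present`),
#'   rows summing to 1; computed in log space so extreme outliers never
#'   yield NaN.
#' @export
posterior <- function(fit, x = fit$x, y = fit$y) {
  stopifnot(inherits(fit, "pav_mixture"))
  co <- fit$coefficients
  l0 <- log1p(-fit$pi) + dnorm(y, co[1, 1] + co[1, 2] * x,
                               sqrt(fit$sigma2[1]), log = TRUE)
  l1 <- log(fit$pi) + dnorm(y, co[2, 1] + co[2, 2] * x,
                            sqrt(fit$sigma2[2]), log = TRUE)
  m <- pmax(l0, l1)
  d0 <- exp(l0 - m); d1 <- exp(l1 - m)
  tau <- cbind(absent = d0, present = d1) / (d0 + d1)
  tau
}

#' @export
print.pav_mixture <- function(x, ...) {
  cat("Two-component regression mixture (sqrt-count scale)\n")
  cat(sprintf("  n = %d, logLik = %.3f, %s in %d EM iterations\n", x$n,
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  tab <- cbind(x$coefficients, sigma2 = x$sigma2,
               pi = c(1 - x$pi, x$pi))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.pav_mixture <- function(object, ...) {
  co <- object$coefficients
  c(a0 = unname(co[1, 1]), b0 = unname(co[1, 2]),
    a1 = unname(co[2, 1]), b1 = unname(co[2, 2]),
    sigma2_0 = unname(object$sigma2[1]), sigma2_1 = unname(object$sigma2[2]),
    pi = object$pi)
}

#' @export
logLik.pav_mixture <- function(object, ...) {
  structure(object$loglik, df = 7L, nobs = object$n, class = "logLik")
}

#' @export
fitted.pav_mixture <- function(object, ...) {
  co <- object$coefficients
  mu0 <- co[1, 1] + co[1, 2] * object$x
  mu1 <- co[2, 1] + co[2, 2] * object$x
  object$tau[, 1] * mu0 + object$tau[, 2] * mu1
}

#' Residuals of a fitted read-depth mixture
#'
#' @param object a `pav_mixture`.
#' @param type `"posterior"` (default): residual against the
#'   posterior-weighted mean; `"map"`: residual against the MAP component's
#'   line.
#' @param ... unused.
#' @export
residuals.pav_mixture <- function(object, type = c("posterior", "map"),
                                  ...) {
  type <- match.arg(type)
  if (type == "posterior") return(object$y - fitted(object))
  co <- object$coefficients
  k <- max.col(object$tau)
  object$y - (co[k, 1] + co[k, 2] * object$x)
}

#' Predict from a fitted read-depth mixture
#'
#' @param object a `pav_mixture`.
#' @param x,y new sqrt-scale data; default the training data.
#' @param type `"posterior"` returns the posterior membership matrix,
#'   `"class"` the MAP cluster (`"absent"`/`"present"`), `"response"` the
#'   posterior-weighted mean of `y` given `x`.
#' @param ... unused.
#' @export
predict.pav_mixture <- function(object, x = object$x, y = object$y,
                                type = c("posterior", "class", "response"),
                                ...) {
  type <- match.arg(type)
  if (type == "response") {
    co <- object$coefficients
    mu0 <- co[1, 1] + co[1, 2] * x
    mu1 <- co[2, 1] + co[2, 2] * x
    return((1 - object$pi) * mu0 + object$pi * mu1)
  }
  tau <- posterior(object, x, y)
  if (type == "posterior") tau
  else colnames(tau)[max.col(tau)]
}

#' Simulate responses from a fitted read-depth mixture
#'
#' Draws cluster memberships from the fitted mixing proportion and responses
#' from the corresponding regression line plus Gaussian noise.
#'
#' @param object a `pav_mixture`.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param x covariate values; default the training covariates.
#' @param ... unused.
#' @return a data frame of `nsim` simulated response columns; the drawn
#'   memberships are attached as attribute `"z"` (a matrix).
#' @export
simulate.pav_mixture <- function(object, nsim = 1, seed = NULL,
                                 x = object$x, ...) {
  if (!is.null(seed)) set.seed(substream_seed(seed, "mixture_sim"))
  co <- object$coefficients
  n <- length(x)
  z <- matrix(rbinom(n * nsim, 1L, object$pi), n, nsim)
  ys <- vapply(seq_len(nsim), function(j) {
    mu <- ifelse(z[, j] == 1, co[2, 1] + co[2, 2] * x,
                 co[1, 1] + co[1, 2] * x)
    sg <- ifelse(z[, j] == 1, sqrt(object$sigma2[2]), sqrt(object$sigma2[1]))
    mu + rnorm(n, 0, sg)
  }, numeric(n))
  out <- as.data.frame(ys)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "z") <- z
  out
}

#' @export
summary.pav_mixture <- function(object, ...) {
  tau1 <- object$tau[, 2]
  structure(list(coefficients = object$coefficients,
                 sigma2 = object$sigma2, pi = object$pi,
                 loglik = object$loglik, n = object$n,
                 n_iter = object$n_iter, converged = object$converged,
                 mean_max_tau = mean(pmax(1 - tau1, tau1)),
                 call = object$call),
            class = "summary.pav_mixture")
}

#' @export
print.summary.pav_mixture <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d regions; logLik %.3f; %d EM iterations (%s)\n",
              x$n, x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  tab <- cbind(x$coefficients, sigma2 = x$sigma2,
               pi = c(1 - x$pi, x$pi))
  print(round(tab, 4))
  cat(sprintf("mean MAP posterior: %.3f\n", x$mean_max_tau))
  invisible(x)
}

#' Scatter plot of a fitted read-depth mixture
#'
#' Donor sqrt counts against target-line sqrt counts, with the two fitted
#' regression lines; points are coloured by their BFDR-controlled call
#' (present / absent / unclassified) at level `alpha`.
#'
#' @param x a `pav_mixture`.
#' @param alpha nominal Bayesian FDR level for the colouring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pav_mixture <- function(x, alpha = 0.01, ...) {
  calls <- bfdr_classify(x, alpha = alpha)
  col <- c(present = "#1b7837", absent = "#d73027",
           unclassified = "grey60")[calls$call]
  plot(x$x, x$y, col = col, pch = 16, cex = 0.6,
       xlab = "donor sqrt count (x)", ylab = "line sqrt count (y)", ...)
  co <- x$coefficients
  abline(co[1, 1], co[1, 2], col = "#d73027", lwd = 2)
  abline(co[2, 1], co[2, 2], col = "#1b7837", lwd = 2)
  legend("topleft", bty = "n", pch = 16,
         col = c("#1b7837", "#d73027", "grey60"),
         legend = c("present", "absent", "unclassified"))
  invisible(x)
}
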