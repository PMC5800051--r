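# Shared fixtures, built in code at test time.

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L)
      cache <<- c(simulate_genome_pair(cfg), list(config = cfg))
    }
    cache
  }
})

# Independent brute-force microhomology oracle: try every k on each side.
brute_force_mh <- function(seq, start, end) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  del_len <- end - start
  right <- 0L
  for (k in seq_len(min(del_len, n - end))) {
    if (identical(ch[(start + 1):(start + k)], ch[(end + 1):(end + k)]))
      right <- k else break
  }
  left <- 0L
  for (k in seq_len(min(del_len, start))) {
    if (identical(ch[(end - k + 1):end], ch[(start - k + 1):start]))
      left <- k else break
  }
  list(left = left, right = right, max = max(left, right))
}

# Independent re-application of the five written filter rules to one
# candidate, given its profiles; returns TRUE if the candidate survives.
brute_force_rules <- function(cand, opp_depth, self_proper,
                              min_bp = 1000, depth_cutoff = 5, spec = 0.70,
                              support = 0.90, max_bp = 200000) {
  len <- cand$end - cand$start
  if (isTRUE(cand$detected_in_self_mapping)) return(FALSE)
  if (len < min_bp) return(FALSE)
  if (mean(opp_depth < depth_cutoff) < spec) return(FALSE)
  if (!(mean(self_proper >= 1) > support)) return(FALSE)
  if (len > max_bp) return(FALSE)
  TRUE
}

# simulate sqrt-scale mixture data with known truth
sim_mixture <- function(n, a0 = 0, b0 = 0, s0 = 0.8, a1 = 0, b1 = 1,
                        s1 = 0.8, pi1 = 0.5, xlo = 10, xhi = 40,
                        seed = 1L) {
  set.seed(seed)
  x <- runif(n, xlo, xhi)
  z <- rbinom(n, 1, pi1)
  y <- ifelse(z == 1, a1 + b1 * x, a0 + b0 * x) +
    rnorm(n, 0, ifelse(z == 1, s1, s0))
  list(x = x, y = y, z = z)
}
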