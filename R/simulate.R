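#' Simulation configuration for the synthetic PAV study
#'
#' Bundles every knob of the synthetic-data generator: the genome pair with
#' planted genotype-specific segments, breakpoint microhomology, coverage
#' profiles, the sqrt-scale read-count mixture and the group-structured
#' genotype panel.  The same configuration (including `seed`) always produces
#' byte-identical outputs; each generator stage draws from its own sub-stream
#' derived from `seed` and a stable stage label, so adding a stage never
#' shifts the draws of another.
#'
#' @param seed integer master seed.
#' @param genome_length donor genome length in bp.
#' @param n_pavs number of uniquely anchorable planted PAVs (deleted from the
#'   acceptor genome).
#' @param pav_length_range bp range (min, max) for planted PAV lengths; the
#'   discovery size threshold is 1 kb, so defaults start there.
#' @param n_ambiguous planted PAVs whose breakpoint junction context also
#'   occurs elsewhere in the genome, so exact-flank anchoring finds two
#'   placements.
#' @param n_decoy_small planted deletions of 200-999 bp: true variants that
#'   the >= 1 kb size rule must reject.
#' @param n_decoy_dup intervals flagged as candidate deletions but present in
#'   both genomes (misclassified duplications): the opposite-genotype
#'   specificity rule must reject them.
#' @param n_incomplete donor-specific scaffolds with no shared flanks, almost
#'   uncovered by opposite-genotype reads (the "incomplete PAV" class).
#' @param incomplete_length_range bp range for incomplete scaffolds.
#' @param mh_mixture list describing the planted microhomology (MH) length
#'   distribution at deletion breakpoints: `geometric_p` (decay of the
#'   geometric base), `spike_at` (focal length, bp), `spike_mass` (extra
#'   probability mass placed on the focal length), `p_no_mh` (probability a
#'   breakpoint carries no MH at all), `mh_min`/`mh_max` (support of the
#'   geometric base, bp).  Conditional on MH being present,
#'   `spike_mass + (1 - spike_mass)` (truncated geometric) sums to 1.
#' @param depth_params list `a0,b0,sigma0` (absent cluster), `a1,b1,sigma1`
#'   (present cluster) and mixing proportion `pi` of the present cluster, all
#'   on the sqrt-count scale.
#' @param x_range range of the donor-line sqrt counts (Uniform draw).
#' @param n_lines panel size excluding the two reference controls.
#' @param group_spec list of groups, each a list with `name`, `n` (lines) and
#'   `beta` (two Beta shape parameters for the per-group PAV frequency);
#'   optionally `n_private` PAVs forced private to that group.  `n` values
#'   must sum to `n_lines`.
#' @param base_depth mean fold-coverage of shared sequence.
#' @param leak_frac fraction of `base_depth` still observed over a truly
#'   absent region (cross-mapping leak); 0 means exactly zero coverage.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_pavs = 8L,
                       pav_length_range = c(1000L, 3000L),
                       n_ambiguous = 2L,
                       n_decoy_small = 2L,
                       n_decoy_dup = 2L,
                       n_incomplete = 3L,
                       incomplete_length_range = c(2000L, 8000L),
                       mh_mixture = list(geometric_p = 1 / 3, spike_at = 5L,
                                         spike_mass = 0.10, p_no_mh = 0.6,
                                         mh_min = 3L, mh_max = 37L),
                       depth_params = list(a0 = 0, b0 = 0, sigma0 = 0.8,
                                           a1 = 0, b1 = 1, sigma1 = 0.8,
                                           pi = 0.5),
                       x_range = c(10, 40),
                       n_lines = 20L,
                       group_spec = list(
                         list(name = "EuropeanFlint", n = 5L, beta = c(2, 2)),
                         list(name = "NorthernFlint", n = 5L, beta = c(1.5, 3)),
                         list(name = "StiffStalk",    n = 5L, beta = c(1, 4)),
                         list(name = "CornBeltDent",  n = 5L, beta = c(1, 4))),
                       base_depth = 40,
                       leak_frac = 0) {
  mh_def <- list(geometric_p = 1 / 3, spike_at = 5L, spike_mass = 0.10,
                 p_no_mh = 0.6, mh_min = 3L, mh_max = 37L)
  mh_mixture <- utils::modifyList(mh_def, mh_mixture)
  dp_def <- list(a0 = 0, b0 = 0, sigma0 = 0.8, a1 = 0, b1 = 1, sigma1 = 0.8,
                 pi = 0.5)
  depth_params <- utils::modifyList(dp_def, depth_params)

  stopifnot(length(seed) == 1, is.finite(seed),
            genome_length > 0, n_pavs >= 0, n_ambiguous >= 0,
            n_decoy_small >= 0, n_decoy_dup >= 0, n_incomplete >= 0,
            length(pav_length_range) == 2,
            pav_length_range[1] > 0,
            pav_length_range[1] <= pav_length_range[2])
  with(mh_mixture, stopifnot(geometric_p > 0, geometric_p < 1,
                             spike_mass >= 0, spike_mass < 1,
                             p_no_mh >= 0, p_no_mh < 1,
                             mh_min >= 1, mh_max >= mh_min,
                             spike_at >= mh_min, spike_at <= mh_max))
  with(depth_params, stopifnot(sigma0 >= 0, sigma1 >= 0, pi > 0, pi < 1))
  stopifnot(x_range[1] >= 0, x_range[1] < x_range[2], base_depth >= 0,
            leak_frac >= 0, leak_frac <= 1)
  if (length(group_spec) == 0) stop("group_spec must contain at least one group")
  gn <- vapply(group_spec, function(g) as.integer(g$n), integer(1))
  if (any(gn <= 0)) stop("every group must contain at least one line")
  if (sum(gn) != n_lines)
    stop("group sizes (", sum(gn), ") must sum to n_lines (", n_lines, ")")

  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_pavs = as.integer(n_pavs),
                 pav_length_range = as.integer(pav_length_range),
                 n_ambiguous = as.integer(n_ambiguous),
                 n_decoy_small = as.integer(n_decoy_small),
                 n_decoy_dup = as.integer(n_decoy_dup),
                 n_incomplete = as.integer(n_incomplete),
                 incomplete_length_range = as.integer(incomplete_length_range),
                 mh_mixture = mh_mixture, depth_params = depth_params,
                 x_range = x_range, n_lines = as.integer(n_lines),
                 group_spec = group_spec, base_depth = base_depth,
                 leak_frac = leak_frac),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_bases <- function(n) sample(BASES, n, replace = TRUE)

# sample() with a length-one x would sample 1:x; this never does
sample_range <- function(lo, hi, n) {
  v <- seq.int(lo, hi)
  v[sample.int(length(v), n, replace = TRUE)]
}

# Draw microhomology lengths from the configured mixture: with probability
# p_no_mh the breakpoint carries none (length 0); otherwise a spike at
# spike_at with mass spike_mass plus a truncated geometric on
# [mh_min, mh_max] with the remaining mass.
draw_mh_lengths <- function(n, mh) {
  k <- integer(n)
  has <- runif(n) >= mh$p_no_mh
  n_has <- sum(has)
  if (n_has > 0) {
    supp <- mh$mh_min:mh$mh_max
    pg <- mh$geometric_p * (1 - mh$geometric_p)^(supp - mh$mh_min)
    pg <- pg / sum(pg)
    base <- sample(supp, n_has, replace = TRUE, prob = pg)
    spike <- runif(n_has) < mh$spike_mass
    k[has] <- ifelse(spike, mh$spike_at, base)
  }
  k
}

# Place m intervals of the given lengths without overlap, keeping `margin` bp
# between neighbours and off both genome ends.  Random placement by
# distributing the leftover length over the m+1 gaps.
pack_intervals <- function(genome_length, lengths, margin = 300L) {
  m <- length(lengths)
  if (m == 0) return(data.frame(start = integer(0), end = integer(0)))
  slack <- genome_length - sum(lengths) - (m + 1L) * margin
  if (slack < 0)
    stop("infeasible packing: genome_length ", genome_length,
         " cannot hold ", m, " segments totalling ", sum(lengths),
         " bp with ", margin, " bp margins")
  cuts <- sort(runif(m, 0, slack))
  extra <- diff(c(0, cuts))
  starts <- integer(m)
  pos <- margin
  for (i in seq_len(m)) {
    pos <- pos + as.integer(floor(extra[i]))
    starts[i] <- pos
    pos <- pos + lengths[i] + margin
  }
  data.frame(start = starts, end = starts + lengths)
}

pick_other_base <- function(b) {
  alt <- setdiff(BASES, b)
  alt[sample.int(3L, 1L)]
}

#' Simulate a donor/acceptor genome pair with planted PAVs
#'
#' Generates a random donor genome, plants genotype-specific segments and
#' decoys, and derives the acceptor genome by deleting the planted segments.
#' Each deletion breakpoint carries an exact microhomology of a drawn length
#' `k`: the first `k` bases of the deleted segment equal the `k` bases that
#' follow the deletion end, and the flanking bases are forced to mismatch so
#' the maximal microhomology is exactly `k`.  Deletions are planted at their
#' leftmost placement (shifting the window left changes the deleted content).
#'
#' Categories in the truth set: `anchored_unique` (junction context occurs
#' once), `anchored_ambiguous` (junction context copied elsewhere),
#' `decoy_small` (deleted but under the 1 kb size rule), `decoy_dup` (listed
#' as a candidate but present in both genomes), and `incomplete` scaffolds
#' (donor-specific sequences with no shared flanks, returned separately).
#'
#' All coordinates are 0-based, half-open, on the donor genome.
#'
#' @param config a [sim_config()].
#' @return a list with elements `donor` and `acceptor` (character strings)
#'   and `truth`, an object of class `pav_truth` holding the interval table
#'   (`intervals`: id, start, end, length, category, mh_len), the incomplete
#'   scaffolds (named character vector), and the configuration.
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genome"))
  G <- config$genome_length
  flank <- 100L

  n_del <- config$n_pavs + config$n_ambiguous + config$n_decoy_small
  lens <- c(
    if (config$n_pavs > 0)
      sample_range(config$pav_length_range[1], config$pav_length_range[2],
                   config$n_pavs),
    if (config$n_ambiguous > 0)
      sample_range(config$pav_length_range[1], config$pav_length_range[2],
                   config$n_ambiguous),
    if (config$n_decoy_small > 0)
      sample_range(200L, 999L, config$n_decoy_small),
    if (config$n_decoy_dup > 0)
      sample_range(config$pav_length_range[1], config$pav_length_range[2],
                   config$n_decoy_dup),
    # one 2*flank "copy slot" per ambiguous PAV, receiving a second copy of
    # its junction context
    rep(2L * flank, config$n_ambiguous))
  lens <- as.integer(lens)
  category <- c(rep("anchored_unique", config$n_pavs),
                rep("anchored_ambiguous", config$n_ambiguous),
                rep("decoy_small", config$n_decoy_small),
                rep("decoy_dup", config$n_decoy_dup),
                rep(".copy_slot", config$n_ambiguous))

  iv <- pack_intervals(G, lens, margin = 300L)
  iv$category <- category
  donor <- random_bases(G)

  # plant microhomology at every true deletion (decoy_dup is never deleted,
  # copy slots are shared sequence)
  del <- which(iv$category %in%
                 c("anchored_unique", "anchored_ambiguous", "decoy_small"))
  mh_len <- integer(nrow(iv))
  mh_len[del] <- draw_mh_lengths(length(del), config$mh_mixture)
  for (i in del) {
    s <- iv$start[i] + 1L   # 1-based
    e <- iv$end[i] + 1L     # 1-based index of first base after the deletion
    k <- mh_len[i]
    if (k > 0) donor[e:(e + k - 1L)] <- donor[s:(s + k - 1L)]
    donor[e + k] <- pick_other_base(donor[s + k])  # right MH is exactly k
    donor[s - 1L] <- pick_other_base(donor[e - 1L])  # leftmost placement
  }

  # duplicate the junction context of each ambiguous PAV into its copy slot
  amb <- which(iv$category == "anchored_ambiguous")
  slots <- which(iv$category == ".copy_slot")
  for (j in seq_along(amb)) {
    i <- amb[j]
    ctx <- c(donor[(iv$start[i] - flank + 1L):iv$start[i]],
             donor[(iv$end[i] + 1L):(iv$end[i] + flank)])
    sl <- slots[j]
    donor[(iv$start[sl] + 1L):iv$end[sl]] <- ctx
  }

  keep <- rep(TRUE, G)
  for (i in del) keep[(iv$start[i] + 1L):iv$end[i]] <- FALSE
  acceptor <- donor[keep]

  intervals <- iv[iv$category != ".copy_slot", , drop = FALSE]
  intervals$mh_len <- mh_len[iv$category != ".copy_slot"]
  intervals$length <- intervals$end - intervals$start
  intervals$id <- sprintf("pav%03d", seq_len(nrow(intervals)))
  intervals <- intervals[, c("id", "start", "end", "length", "category",
                             "mh_len")]
  rownames(intervals) <- NULL

  scaffolds <- character(0)
  if (config$n_incomplete > 0) {
    sl <- sample_range(config$incomplete_length_range[1],
                       config$incomplete_length_range[2],
                       config$n_incomplete)
    scaffolds <- vapply(sl, function(n) paste(random_bases(n), collapse = ""),
                        character(1))
    names(scaffolds) <- sprintf("scaffold%03d", seq_along(scaffolds))
  }

  truth <- structure(list(intervals = intervals, scaffolds = scaffolds,
                          donor_length = G,
                          acceptor_length = length(acceptor),
                          config = config),
                     class = "pav_truth")
  list(donor = paste(donor, collapse = ""),
       acceptor = paste(acceptor, collapse = ""),
       truth = truth)
}

#' @export
print.pav_truth <- function(x, ...) {
  cat("Synthetic PAV truth set\n")
  cat("  donor genome:   ", x$donor_length, "bp\n")
  cat("  acceptor genome:", x$acceptor_length, "bp\n")
  print(table(x$intervals$category))
  if (length(x$scaffolds))
    cat("  incomplete scaffolds:", length(x$scaffolds), "\n")
  invisible(x)
}

#' Derive the candidate SV table an external caller would report
#'
#' Every planted interval — true PAVs, sub-threshold deletions and
#' duplication decoys alike — enters the candidate list, as an SV caller
#' cannot tell them apart; the filter cascade has to.  Caller support is
#' drawn Poisson around a third of the base depth (at least the ingestion
#' minimum of 3).
#'
#' @param truth a `pav_truth`.
#' @param config the [sim_config()].
#' @return a candidate data frame (see [as_candidates()]).
#' @export
simulate_candidates <- function(truth, config = truth$config) {
  set.seed(substream_seed(config$seed, "candidates"))
  iv <- truth$intervals
  data.frame(id = iv$id, contig = "donor", start = iv$start, end = iv$end,
             caller_support = pmax(3L, rpois(nrow(iv),
                                             config$base_depth / 3)),
             detected_in_self_mapping = FALSE)
}

new_profile <- function(depth, proper_depth = depth) {
  stopifnot(length(depth) == length(proper_depth), all(depth >= 0),
            all(proper_depth >= 0))
  structure(list(depth = as.integer(depth),
                 proper_depth = as.integer(proper_depth)),
            class = "coverage_profile")
}

#' Simulate per-base coverage profiles for both genotypes
#'
#' Emulates read-depth over the donor genome for the donor's own reads
#' ("self") and the acceptor genotype's reads mapped onto the donor
#' ("opposite").  Shared sequence receives Poisson(`base_depth`) depth per
#' base; truly deleted segments receive Poisson(`leak_frac * base_depth`)
#' opposite depth (exactly 0 when `leak_frac = 0`); duplication decoys are
#' present in both genomes and receive full opposite depth.  Incomplete
#' scaffolds get full self coverage but opposite coverage over under 20% of
#' their bases, at depths below 5.
#'
#' @param truth a `pav_truth` from [simulate_genome_pair()].
#' @param config the [sim_config()] used to build `truth`.
#' @return a list of class `pav_coverage`: `self` and `opposite` are
#'   `coverage_profile` objects spanning the donor genome (fields `depth`
#'   and `proper_depth`); `scaffold_self` and `scaffold_opposite` are named
#'   lists of profiles, one per incomplete scaffold.
#' @export
simulate_coverage <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "pav_truth"))
  if (config$base_depth < 0) stop("base_depth must be non-negative")
  set.seed(substream_seed(config$seed, "coverage"))
  G <- truth$donor_length

  self_depth <- rpois(G, config$base_depth)
  self_proper <- rpois(G, config$base_depth)
  opp_depth <- rpois(G, config$base_depth)
  iv <- truth$intervals
  deleted <- iv$category %in% c("anchored_unique", "anchored_ambiguous",
                                "decoy_small")
  for (i in which(deleted)) {
    idx <- (iv$start[i] + 1L):iv$end[i]
    opp_depth[idx] <- rpois(length(idx), config$leak_frac * config$base_depth)
  }
  opp_proper <- opp_depth

  scaffold_self <- list()
  scaffold_opp <- list()
  for (nm in names(truth$scaffolds)) {
    n <- nchar(truth$scaffolds[[nm]])
    scaffold_self[[nm]] <- new_profile(rpois(n, config$base_depth))
    cov_frac <- runif(1, 0.02, 0.15)
    d <- integer(n)
    w <- max(1L, as.integer(round(cov_frac * n)))
    at <- sample.int(n - w + 1L, 1L)
    d[at:(at + w - 1L)] <- sample(1:4, w, replace = TRUE)
    scaffold_opp[[nm]] <- new_profile(d)
  }

  structure(list(self = new_profile(self_depth, self_proper),
                 opposite = new_profile(opp_depth, opp_proper),
                 scaffold_self = scaffold_self,
                 scaffold_opposite = scaffold_opp),
            class = "pav_coverage")
}

#' Simulate group-structured presence/absence genotypes for a line panel
#'
#' For each group, each PAV's presence frequency is drawn from that group's
#' Beta distribution; lines then carry the PAV as independent Bernoulli
#' draws.  A configurable number of PAVs per group is forced group-private
#' (frequency 1 inside the group, 0 elsewhere).  Two control columns are
#' appended: the donor line (all present) and the opposite reference (all
#' absent).
#'
#' @param truth a `pav_truth`; rows of the panel are its genotyped regions
#'   (anchored PAVs plus incomplete scaffolds).
#' @param config the [sim_config()].
#' @param region_ids optional explicit region ids overriding the truth set.
#' @return a list of class `pav_panel`: `genotypes` (region x line 0/1
#'   matrix, controls included), `groups` (named character vector mapping
#'   panel lines to groups; controls carry group `"control"`), `frequencies`
#'   (region x group matrix of the drawn frequencies), `donor` and
#'   `opposite` (the control line names).
#' @export
simulate_panel <- function(truth, config = truth$config, region_ids = NULL) {
  if (length(config$group_spec) == 0) stop("group_spec must be nonempty")
  set.seed(substream_seed(config$seed, "panel"))
  if (is.null(region_ids)) {
    iv <- truth$intervals
    region_ids <- c(iv$id[iv$category %in% c("anchored_unique",
                                             "anchored_ambiguous")],
                    names(truth$scaffolds))
  }
  n_r <- length(region_ids)
  groups <- character(0)
  for (g in config$group_spec) groups <- c(groups, rep(g$name, g$n))
  line_ids <- sprintf("L%02d", seq_along(groups))
  names(groups) <- line_ids

  freq <- matrix(0, n_r, length(config$group_spec),
                 dimnames = list(region_ids,
                                 vapply(config$group_spec, `[[`, "",
                                        "name")))
  geno <- matrix(0L, n_r, length(line_ids),
                 dimnames = list(region_ids, line_ids))
  for (j in seq_along(config$group_spec)) {
    g <- config$group_spec[[j]]
    freq[, j] <- rbeta(n_r, g$beta[1], g$beta[2])
  }
  # force group-private PAVs, allocated from the top of the region list
  row0 <- 1L
  for (j in seq_along(config$group_spec)) {
    np <- config$group_spec[[j]]$n_private
    if (is.null(np) || np == 0) next
    np <- min(np, n_r - row0 + 1L)
    rows <- row0:(row0 + np - 1L)
    freq[rows, ] <- 0
    freq[rows, j] <- 1
    row0 <- row0 + np
  }
  for (i in seq_len(n_r))
    geno[i, ] <- rbinom(length(line_ids), 1L, freq[i, groups])

  donor <- "F2"; opposite <- "B73"
  geno <- cbind(geno,
                matrix(c(rep(1L, n_r), rep(0L, n_r)), n_r, 2,
                       dimnames = list(NULL, c(donor, opposite))))
  groups <- c(groups, setNames(c("control", "control"), c(donor, opposite)))

  structure(list(genotypes = geno, groups = groups, frequencies = freq,
                 donor = donor, opposite = opposite),
            class = "pav_panel")
}

#' Simulate a regions-by-lines depth matrix from the read-count mixture
#'
#' Generates, for every line, sqrt-scale responses following the
#' two-component regression model: `Y = a1 + b1 x + E` where the line
#' carries the region (cluster 1) and `Y = a0 + b0 x + E` where it does not
#' (cluster 0), with Gaussian `E` and `x` the donor line's own sqrt count
#' drawn Uniform over `x_range`.  Raw counts are derived as
#' `round(pmax(Y, 0)^2)`; the exact Gaussian responses are stored so the
#' genotyper's model assumptions hold exactly in fixtures.  A
#' model-misspecified mode draws raw counts as Poisson with mean
#' `(a_z + b_z x)^2` instead.
#'
#' @param truth a `pav_truth`, or `NULL` when `panel` is given directly.
#' @param config the [sim_config()].
#' @param panel a `pav_panel` giving the true 0/1 membership per region and
#'   line; simulated from `truth` when missing.
#' @param noise `"gaussian_sqrt"` (model-exact, default) or `"poisson"`
#'   (misspecified robustness mode).
#' @return an object of class `pav_depth`: sqrt-scale `x` (donor), response
#'   matrix `Y` (regions x lines), raw `counts`, true membership `Z`, line
#'   and region ids.
#' @export
simulate_depth_matrix <- function(truth, config = truth$config,
                                  panel = NULL,
                                  noise = c("gaussian_sqrt", "poisson")) {
  noise <- match.arg(noise)
  p <- config$depth_params
  if (p$sigma0 < 0 || p$sigma1 < 0) stop("sigma must be non-negative")
  if (is.null(panel)) panel <- simulate_panel(truth, config)
  set.seed(substream_seed(config$seed, "depth"))

  Z <- panel$genotypes
  n_r <- nrow(Z)
  x <- runif(n_r, config$x_range[1], config$x_range[2])
  Y <- matrix(NA_real_, n_r, ncol(Z), dimnames = dimnames(Z))
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    mu <- ifelse(z == 1, p$a1 + p$b1 * x, p$a0 + p$b0 * x)
    sg <- ifelse(z == 1, p$sigma1, p$sigma0)
    if (noise == "gaussian_sqrt") {
      Y[, j] <- mu + rnorm(n_r, 0, sg)
    } else {
      Y[, j] <- sqrt(rpois(n_r, pmax(mu, 0)^2))
    }
  }
  counts <- round(pmax(Y, 0)^2)
  new_depth_matrix(x = x, Y = Y, counts = counts, Z = Z,
                   donor = panel$donor)
}

new_depth_matrix <- function(x, Y, counts, Z = NULL, donor = NULL) {
  structure(list(regions = rownames(Y), lines = colnames(Y),
                 x = x, Y = Y, counts = counts, Z = Z, donor = donor,
                 transformed = TRUE),
            class = "pav_depth")
}

#' Build a depth matrix from raw read counts
#'
#' Applies the square-root transform once, recording that it has been done;
#' [sqrt_transform()] refuses to transform twice.
#'
#' @param counts non-negative regions x lines count matrix (row and column
#'   names required).
#' @param donor name of the donor line column, whose sqrt counts provide the
#'   covariate `x`.
#' @param normalize if `TRUE`, scale each line's counts by the ratio of the
#'   overall median count to the line median before transforming
#'   (per-line sequencing-depth correction; off by default).
#' @return a `pav_depth` object.
#' @export
as_depth_matrix <- function(counts, donor, normalize = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!donor %in% colnames(counts))
    stop("donor line '", donor, "' not found among columns")
  if (normalize) {
    med <- apply(counts, 2, median, na.rm = TRUE)
    counts <- sweep(counts, 2, median(med) / pmax(med, 1e-9), `*`)
  }
  Y <- sqrt(counts)
  new_depth_matrix(x = Y[, donor], Y = Y, counts = counts, donor = donor)
}

#' Square-root transform guard
#'
#' The genotyping model lives on the sqrt-count scale and the transform must
#' be applied exactly once; calling this on an already-transformed
#' `pav_depth` is an error.
#'
#' @param x a `pav_depth` object.
#' @return the object, transformed.
#' @export
sqrt_transform <- function(x) {
  stopifnot(inherits(x, "pav_depth"))
  if (isTRUE(x$transformed))
    stop("depth matrix is already on the sqrt scale; refusing to transform twice")
  x$Y <- sqrt(x$counts)
  x$x <- x$Y[, x$donor]
  x$transformed <- TRUE
  x
}

#' @export
print.pav_depth <- function(x, ...) {
  cat("PAV depth matrix:", nrow(x$Y), "regions x", ncol(x$Y), "lines",
      if (isTRUE(x$transformed)) "(sqrt scale)" else "(raw)", "\n")
  if (!is.null(x$donor)) cat("  donor line:", x$donor, "\n")
  invisible(x)
}

#' Simulate directly from the sqrt-scale read-count mixture
#'
#' The generative side of the genotyping model, without the genome scaffold:
#' draws `x ~ Uniform(x_range)`, cluster memberships `z ~ Bernoulli(pi)`,
#' and responses `y = a_z + b_z x + N(0, sigma_z)`.
#'
#' @param n number of regions.
#' @param params depth parameter list as in [sim_config()] (`a0,b0,sigma0,
#'   a1,b1,sigma1,pi`).
#' @param x_range Uniform range of the donor sqrt counts.
#' @param seed integer seed.
#' @return list `x`, `y`, `z` (true memberships).
#' @export
simulate_mixture <- function(n, params = list(a0 = 0, b0 = 0, sigma0 = 0.8,
                                              a1 = 0, b1 = 1, sigma1 = 0.8,
                                              pi = 0.5),
                             x_range = c(10, 40), seed = 1L) {
  p <- utils::modifyList(list(a0 = 0, b0 = 0, sigma0 = 0.8, a1 = 0, b1 = 1,
                              sigma1 = 0.8, pi = 0.5), params)
  if (p$sigma0 < 0 || p$sigma1 < 0) stop("sigma must be non-negative")
  set.seed(substream_seed(seed, "mixture"))
  x <- runif(n, x_range[1], x_range[2])
  z <- rbinom(n, 1L, p$pi)
  y <- ifelse(z == 1, p$a1 + p$b1 * x, p$a0 + p$b0 * x) +
    rnorm(n, 0, ifelse(z == 1, p$sigma1, p$sigma0))
  list(x = x, y = y, z = z)
}

#' Simulate correlated biallelic haplotypes along a chromosome
#'
#' A first-order model for linkage disequilibrium on an inbred (homozygous)
#' panel: alleles are generated locus-to-locus along the sorted positions,
#' each line's allele at a locus matching the previous locus with
#' probability `0.5 + 0.5 * exp(-d / corr_length)` where `d` is the bp
#' distance.  Marginal allele frequencies are 0.5 and the correlation
#' between loci at distance `d` is `exp(-d / corr_length)`, so binned mean
#' r-squared decays smoothly with distance; `corr_length = Inf` gives a fully
#' linked region (r-squared 1 everywhere).
#'
#' @param positions sorted bp positions of the loci.
#' @param n_lines panel size.
#' @param corr_length decay length in bp.
#' @param seed integer seed.
#' @return loci x lines 0/1 matrix.
#' @export
simulate_ld_haplotypes <- function(positions, n_lines, corr_length = 5000,
                                   seed = 1L) {
  stopifnot(!is.unsorted(positions), n_lines >= 2, corr_length > 0)
  set.seed(substream_seed(seed, "ld"))
  L <- length(positions)
  H <- matrix(0L, L, n_lines)
  H[1, ] <- rbinom(n_lines, 1L, 0.5)
  if (L > 1) for (i in 2:L) {
    keep_p <- 0.5 + 0.5 * exp(-(positions[i] - positions[i - 1]) / corr_length)
    same <- rbinom(n_lines, 1L, keep_p)
    H[i, ] <- ifelse(same == 1L, H[i - 1, ], 1L - H[i - 1, ])
  }
  dimnames(H) <- list(sprintf("locus%04d", seq_len(L)),
                      sprintf("L%02d", seq_len(n_lines)))
  H
}
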