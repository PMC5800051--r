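#' Candidate structural-variant table
#'
#' Candidates are plain data frames with columns `id`, `contig`, `start`,
#' `end` (0-based, half-open), `caller_support` (supporting read count;
#' callers are required to have applied a minimum of 3 reads at Q20, and
#' [check_caller_support()] can re-assert it) and, optionally,
#' `detected_in_self_mapping` (logical).  This constructor validates and
#' normalises such a table.
#'
#' @param df data frame of candidates.
#' @return the validated data frame.
#' @export
as_candidates <- function(df) {
  need <- c("id", "contig", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("candidate table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("candidate ids must be unique")
  if (any(df$end <= df$start)) stop("intervals must satisfy end > start")
  if (is.null(df$caller_support)) df$caller_support <- NA_integer_
  if (any(df$caller_support < 0, na.rm = TRUE))
    stop("caller_support must be non-negative")
  df
}

#' Re-check the caller support precondition
#'
#' External SV callers are run with a minimum local coverage of 3 reads at
#' Q20 mapping quality; that rule is an ingestion precondition here, not a
#' pipeline stage, and this helper re-asserts it on demand.
#'
#' @param candidates candidate table.
#' @param min_support minimum supporting reads.
#' @return candidates whose support meets the minimum (NA support passes).
#' @export
check_caller_support <- function(candidates, min_support = 3L) {
  keep <- is.na(candidates$caller_support) |
    candidates$caller_support >= min_support
  candidates[keep, , drop = FALSE]
}

overlaps_any <- function(s, e, starts, ends, contig, contigs,
                         reciprocal = NULL) {
  same <- contigs == contig
  if (!any(same)) return(FALSE)
  os <- pmax(s, starts[same]); oe <- pmin(e, ends[same])
  ov <- pmax(0, oe - os)
  if (is.null(reciprocal)) return(any(ov > 0))
  any(ov >= reciprocal * (e - s) & ov >= reciprocal * (ends[same] - starts[same]))
}

#' Drop candidates also detected in the self-mapping control
#'
#' Variants called both when mapping the opposite genotype's reads and when
#' mapping the genotype's own reads back to its assembly are assembly
#' artefacts, not genuine differences, and are discarded.  A candidate is
#' removed either when its `detected_in_self_mapping` flag is set or when it
#' overlaps an interval in `self_calls`.
#'
#' @param candidates candidate table.
#' @param self_calls optional data frame (`contig`, `start`, `end`) of
#'   variants detected in the self-mapping control.
#' @param mode `"any"` removes on any overlap (default); `"reciprocal50"`
#'   requires 50% reciprocal overlap.
#' @return list with `keep` (retained candidates) and `rejected`
#'   (data frame id/reason).
#' @export
filter_self_consistency <- function(candidates, self_calls = NULL,
                                    mode = c("any", "reciprocal50")) {
  mode <- match.arg(mode)
  rec <- if (mode == "reciprocal50") 0.5 else NULL
  flagged <- if (!is.null(candidates$detected_in_self_mapping))
    candidates$detected_in_self_mapping %in% TRUE
  else rep(FALSE, nrow(candidates))
  if (!is.null(self_calls) && nrow(self_calls) > 0) {
    hit <- vapply(seq_len(nrow(candidates)), function(i)
      overlaps_any(candidates$start[i], candidates$end[i],
                   self_calls$start, self_calls$end,
                   candidates$contig[i], self_calls$contig, rec),
      logical(1))
    flagged <- flagged | hit
  }
  list(keep = candidates[!flagged, , drop = FALSE],
       rejected = data.frame(id = candidates$id[flagged],
                             reason = rep("detected_in_self_mapping",
                                          sum(flagged))))
}

#' Drop candidates below the minimum size
#'
#' Only variants of at least `min_bp` (default 1 kb) are considered PAVs;
#' the boundary is inclusive.
#'
#' @param candidates candidate table.
#' @param min_bp minimum length in bp; must be positive.
#' @return list with `keep` and `rejected` as in [filter_self_consistency()].
#' @export
filter_min_size <- function(candidates, min_bp = 1000L) {
  if (min_bp <= 0) stop("min_bp must be positive")
  len <- candidates$end - candidates$start
  small <- len < min_bp
  list(keep = candidates[!small, , drop = FALSE],
       rejected = data.frame(id = candidates$id[small],
                             reason = rep(sprintf("size_below_%dbp", min_bp),
                                          sum(small))))
}

#' Opposite-genotype specificity test for one candidate
#'
#' A genuine genotype-specific region is almost uncovered by the opposite
#' genotype's reads; regions covered because a near-identical copy exists
#' elsewhere (CNVs, misclassified duplications) are not specific.  The rule:
#' keep iff the fraction of bases with opposite depth strictly below
#' `depth_cutoff` is at least `frac` of the candidate length.
#'
#' @param depth integer vector of opposite-genotype per-base depth spanning
#'   the candidate (exactly its length, or longer with `offset` giving the
#'   candidate's start within it).
#' @param length_bp candidate length; defaults to `length(depth)`.
#' @param depth_cutoff depth below which a base counts as uncovered
#'   (strict `<`).
#' @param frac minimum low-coverage fraction (inclusive `>=`).
#' @return list `keep` (logical) and `fraction` (low-coverage fraction).
#' @export
filter_specificity <- function(depth, length_bp = length(depth),
                               depth_cutoff = 5L, frac = 0.70) {
  if (length(depth) < length_bp)
    stop("coverage profile (", length(depth),
         " bp) shorter than candidate (", length_bp, " bp)")
  depth <- depth[seq_len(length_bp)]
  f <- mean(depth < depth_cutoff)
  list(keep = f >= frac, fraction = f)
}

#' Assembly-support test for one candidate
#'
#' Retains only sequences whose own genotype's properly-mapped read pairs
#' (correct orientation and insert size) cover more than `frac` of the
#' region, guarding against local assembly errors.  The inequality is
#' strict (`> 90%` by default).
#'
#' @param proper_depth per-base depth of properly-paired own-genotype reads.
#' @param length_bp candidate length.
#' @param frac minimum covered fraction (strict `>`).
#' @return list `keep` and `fraction` (covered fraction, depth >= 1).
#' @export
filter_assembly_support <- function(proper_depth,
                                    length_bp = length(proper_depth),
                                    frac = 0.90) {
  if (length(proper_depth) < length_bp)
    stop("coverage profile shorter than candidate")
  proper_depth <- proper_depth[seq_len(length_bp)]
  f <- mean(proper_depth >= 1)
  list(keep = f > frac, fraction = f)
}

#' Flag oversize candidates as suspect duplications
#'
#' Putative deletions larger than `max_bp` (default 200 kb) are, on manual
#' inspection, misclassified genome duplications; they are flagged
#' `oversize_suspect` and excluded from the PAV output by default.  The
#' inequality is strict.
#'
#' @param candidates candidate table.
#' @param max_bp flag threshold in bp.
#' @return candidates with a logical `oversize_suspect` column added.
#' @export
flag_oversize <- function(candidates, max_bp = 200000L) {
  candidates$oversize_suspect <- (candidates$end - candidates$start) > max_bp
  candidates
}

#' Classify unanchorable scaffolds as incomplete PAVs
#'
#' Scaffolds nearly uncovered by the opposite genotype's reads cannot enter
#' SV detection (no shared flanks to align) but are still genotype-specific.
#' A scaffold becomes an "incomplete PAV" iff (i) the fraction of its bases
#' with any opposite coverage is below `covered_frac_max` and (ii) the
#' specificity criterion holds over the whole scaffold (depth below
#' `depth_cutoff` on at least `low_frac` of bases).  No breakpoint exists
#' for such records.
#'
#' @param scaffolds named character vector of scaffold sequences (or named
#'   integer lengths).
#' @param opposite_profiles named list of per-base opposite-depth integer
#'   vectors (or `coverage_profile` objects), one per scaffold.
#' @param covered_frac_max maximum covered-base fraction (strict `<`).
#' @param depth_cutoff,low_frac specificity parameters as in
#'   [filter_specificity()].
#' @return data frame of incomplete `PavRecord`s (id, contig, start, end,
#'   length, category, breakpoint = NA).
#' @export
classify_incomplete_scaffolds <- function(scaffolds, opposite_profiles,
                                          covered_frac_max = 0.20,
                                          depth_cutoff = 5L,
                                          low_frac = 0.70) {
  out <- list()
  for (nm in names(scaffolds)) {
    n <- if (is.character(scaffolds)) nchar(scaffolds[[nm]])
         else as.integer(scaffolds[[nm]])
    d <- opposite_profiles[[nm]]
    if (inherits(d, "coverage_profile")) d <- d$depth
    if (length(d) < n) stop("profile shorter than scaffold ", nm)
    d <- d[seq_len(n)]
    covered <- mean(d >= 1)
    spec <- mean(d < depth_cutoff)
    if (covered < covered_frac_max && spec >= low_frac)
      out[[nm]] <- data.frame(id = nm, contig = nm, start = 0L, end = n,
                              length = n, category = "incomplete",
                              breakpoint = NA_integer_)
  }
  if (!length(out))
    return(data.frame(id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), category = character(0),
                      breakpoint = integer(0)))
  do.call(rbind, unname(out))
}

#' Count exact-flank anchor placements on the acceptor genome
#'
#' Toy anchoring: the deletion-junction context (the `flank` bases on each
#' side of the removed segment, concatenated) is searched for as an exact
#' match in the acceptor sequence; each distinct placement is one hit.
#'
#' @param acceptor acceptor genome sequence (character string).
#' @param left_flank,right_flank flank sequences around the junction.
#' @return list `hits` (count) and `positions` (0-based junction positions,
#'   i.e. starts of the right flank within the acceptor).
#' @export
count_anchor_hits <- function(acceptor, left_flank, right_flank) {
  pat <- paste0(left_flank, right_flank)
  m <- gregexpr(pat, acceptor, fixed = TRUE)[[1]]
  if (m[1] == -1) return(list(hits = 0L, positions = integer(0)))
  list(hits = length(m),
       positions = as.integer(m) - 1L + nchar(left_flank))
}

#' Assign an anchor category from a placement count
#'
#' One placement on the acceptor makes the region unambiguously anchored
#' (its breakpoint is known); several placements make it ambiguously
#' anchored; none leaves it unanchored.
#'
#' @param hits non-negative placement count.
#' @return `"anchored_unique"`, `"anchored_ambiguous"` or `"unanchored"`.
#' @export
assign_anchor_category <- function(hits) {
  if (hits < 0) stop("anchor hit count must be non-negative")
  if (hits == 0) "unanchored" else if (hits == 1) "anchored_unique"
  else "anchored_ambiguous"
}

slice_profile <- function(profile, start, end) {
  list(depth = profile$depth[(start + 1L):end],
       proper_depth = profile$proper_depth[(start + 1L):end])
}

#' Run the full PAV discovery filter cascade
#'
#' Applies, in order: self-consistency, minimum size, opposite-genotype
#' specificity, assembly support, the oversize flag, and anchoring; then
#' appends incomplete scaffolds.  The filters are conjunctive, so the
#' retained set does not depend on stage order, but the audit report
#' attributes each rejection to the first failing stage.
#'
#' @param candidates candidate table ([as_candidates()]).
#' @param coverage a `pav_coverage` (from [simulate_coverage()]) or a list
#'   with `self`/`opposite` genome-wide `coverage_profile`s and
#'   `scaffold_opposite` profiles.
#' @param scaffolds named character vector of unanchorable scaffolds (may be
#'   empty).
#' @param donor donor genome sequence, needed for flank extraction when
#'   anchoring is computed here.
#' @param acceptor acceptor genome sequence for toy exact-flank anchoring;
#'   alternatively supply `anchor_hits`, a named integer vector of
#'   precomputed placement counts per candidate id.
#' @param anchor_hits optional precomputed anchor hit counts.
#' @param params list overriding defaults: `min_bp` (1000), `depth_cutoff`
#'   (5), `spec_frac` (0.70), `support_frac` (0.90), `max_bp` (200000),
#'   `covered_frac_max` (0.20), `flank` (100), `overlap_mode` ("any").
#' @param self_calls optional self-mapping call set for overlap-based
#'   self-consistency filtering.
#' @return list of class `pav_discovery`: `records` (PavRecord data frame:
#'   id, contig, start, end, length, category, breakpoint, oversize_suspect),
#'   `report` (per-stage in/out counts; they telescope), `rejections`
#'   (id, stage, reason).
#' @export
run_discovery_pipeline <- function(candidates, coverage, scaffolds = NULL,
                                   donor = NULL, acceptor = NULL,
                                   anchor_hits = NULL, params = list(),
                                   self_calls = NULL) {
  p <- utils::modifyList(list(min_bp = 1000L, depth_cutoff = 5L,
                              spec_frac = 0.70, support_frac = 0.90,
                              max_bp = 200000L, covered_frac_max = 0.20,
                              flank = 100L, overlap_mode = "any"),
                         params)
  candidates <- as_candidates(candidates)
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0))
  rejections <- data.frame(id = character(0), stage = character(0),
                           reason = character(0))
  note <- function(stage, n_in, n_out, rej) {
    report <<- rbind(report, data.frame(stage = stage, n_in = n_in,
                                        n_out = n_out))
    if (nrow(rej))
      rejections <<- rbind(rejections,
                           data.frame(id = rej$id, stage = stage,
                                      reason = rej$reason))
  }

  st <- filter_self_consistency(candidates, self_calls, p$overlap_mode)
  note("self_consistency", nrow(candidates), nrow(st$keep), st$rejected)
  cur <- st$keep

  st <- filter_min_size(cur, p$min_bp)
  note("min_size", nrow(cur), nrow(st$keep), st$rejected)
  cur <- st$keep

  if (nrow(cur)) {
    verdict <- logical(nrow(cur)); fracs <- numeric(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      d <- slice_profile(coverage$opposite, cur$start[i], cur$end[i])$depth
      r <- filter_specificity(d, depth_cutoff = p$depth_cutoff,
                              frac = p$spec_frac)
      verdict[i] <- r$keep; fracs[i] <- r$fraction
    }
    note("specificity", nrow(cur), sum(verdict),
         data.frame(id = cur$id[!verdict],
                    reason = sprintf("low_coverage_fraction_%.2f",
                                     fracs[!verdict])))
    cur <- cur[verdict, , drop = FALSE]
  } else note("specificity", 0L, 0L, data.frame(id = character(0),
                                                reason = character(0)))

  if (nrow(cur)) {
    verdict <- logical(nrow(cur)); fracs <- numeric(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      d <- slice_profile(coverage$self, cur$start[i],
                         cur$end[i])$proper_depth
      r <- filter_assembly_support(d, frac = p$support_frac)
      verdict[i] <- r$keep; fracs[i] <- r$fraction
    }
    note("assembly_support", nrow(cur), sum(verdict),
         data.frame(id = cur$id[!verdict],
                    reason = sprintf("proper_pair_fraction_%.2f",
                                     fracs[!verdict])))
    cur <- cur[verdict, , drop = FALSE]
  } else note("assembly_support", 0L, 0L,
              data.frame(id = character(0), reason = character(0)))

  cur <- flag_oversize(cur, p$max_bp)
  keep <- !cur$oversize_suspect
  note("oversize", nrow(cur), sum(keep),
       data.frame(id = cur$id[!keep],
                  reason = rep("oversize_suspect", sum(!keep))))
  cur <- cur[keep, , drop = FALSE]

  # anchoring
  hits <- integer(nrow(cur)); bp <- rep(NA_integer_, nrow(cur))
  if (!is.null(anchor_hits)) {
    hits <- unname(anchor_hits[cur$id])
    hits[is.na(hits)] <- 0L
  } else if (!is.null(acceptor) && !is.null(donor)) {
    for (i in seq_len(nrow(cur))) {
      lf <- substr(donor, cur$start[i] - p$flank + 1L, cur$start[i])
      rf <- substr(donor, cur$end[i] + 1L, cur$end[i] + p$flank)
      a <- count_anchor_hits(acceptor, lf, rf)
      hits[i] <- a$hits
      if (a$hits == 1) bp[i] <- a$positions[1]
    }
  } else stop("supply either anchor_hits or donor+acceptor sequences")
  cat_of <- vapply(hits, assign_anchor_category, character(1))
  note("anchoring", nrow(cur), nrow(cur),
       data.frame(id = character(0), reason = character(0)))

  records <- data.frame(id = cur$id, contig = cur$contig,
                        start = cur$start, end = cur$end,
                        length = cur$end - cur$start,
                        category = cat_of, breakpoint = bp,
                        oversize_suspect = FALSE)

  if (!is.null(scaffolds) && length(scaffolds)) {
    inc <- classify_incomplete_scaffolds(scaffolds,
                                         coverage$scaffold_opposite,
                                         p$covered_frac_max,
                                         p$depth_cutoff, p$spec_frac)
    if (nrow(inc)) {
      inc$oversize_suspect <- FALSE
      records <- rbind(records, inc)
    }
    note("incomplete_scaffolds", length(scaffolds), nrow(inc),
         {
           left <- setdiff(names(scaffolds), inc$id)
           data.frame(id = left, reason = rep("not_incomplete_pav",
                                              length(left)))
         })
  }
  rownames(records) <- NULL
  structure(list(records = records, report = report,
                 rejections = rejections, params = p),
            class = "pav_discovery")
}

#' @export
print.pav_discovery <- function(x, ...) {
  cat("PAV discovery result:", nrow(x$records), "records\n")
  print(table(x$records$category))
  cat("\nFilter report:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
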