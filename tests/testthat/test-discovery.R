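make_cand <- function(id, start, end, self_mapped = FALSE)
  data.frame(id = id, contig = "donor", start = start, end = end,
             caller_support = 10L, detected_in_self_mapping = self_mapped)

test_that("self-consistency filter: flag, overlap rule and reciprocal mode", {
  cands <- rbind(make_cand("a", 0, 2000, self_mapped = TRUE),
                 make_cand("b", 5000, 7000),
                 make_cand("c", 10000, 12000))
  r <- filter_self_consistency(cands)
  expect_identical(r$keep$id, c("b", "c"))
  expect_identical(r$rejected$id, "a")

  # 1-bp overlap removes under any-overlap, survives under reciprocal-50%
  self_calls <- data.frame(contig = "donor", start = 6999, end = 9000)
  cands2 <- make_cand("b", 5000, 7000)
  expect_identical(nrow(filter_self_consistency(cands2, self_calls)$keep), 0L)
  expect_identical(
    filter_self_consistency(cands2, self_calls, "reciprocal50")$keep$id, "b")

  # no self-mapping detections: identity
  r3 <- filter_self_consistency(rbind(make_cand("x", 0, 1500)))
  expect_identical(r3$keep$id, "x")
})

test_that("size filter boundaries: 999 out, 1000 in (inclusive)", {
  cands <- rbind(make_cand("small", 0, 999),
                 make_cand("edge", 2000, 3000),
                 make_cand("big", 5000, 44900))
  r <- filter_min_size(cands)
  expect_setequal(r$keep$id, c("edge", "big"))
  expect_identical(r$rejected$id, "small")
  expect_error(filter_min_size(cands, 0), "positive")
})

test_that("specificity rule: strict depth < 5, inclusive fraction >= 70%", {
  # 2000 bp, 80% at depth 0, 20% at depth 12
  d <- c(rep(0L, 1600), rep(12L, 400))
  r <- filter_specificity(d)
  expect_true(r$keep)
  expect_equal(r$fraction, 0.80)
  # 50% below cutoff: drop
  expect_false(filter_specificity(c(rep(0L, 500), rep(9L, 500)))$keep)
  # boundary enumeration: exactly 70% at depth 4 (counts, strict <5),
  # 30% at depth 5 (does not count) -> keep
  d2 <- c(rep(4L, 700), rep(5L, 300))
  r2 <- filter_specificity(d2)
  expect_true(r2$keep)
  expect_equal(r2$fraction, 0.70)
  # one base flipped to 5 drops below the inclusive boundary
  d2[1] <- 5L
  expect_false(filter_specificity(d2)$keep)
  expect_error(filter_specificity(d[1:10], length_bp = 100), "shorter")
})

test_that("assembly support is strictly greater than 90%", {
  expect_true(filter_assembly_support(rep(1L, 95) |> c(rep(0L, 5)))$keep)
  expect_false(filter_assembly_support(c(rep(1L, 90), rep(0L, 10)))$keep)  # exactly 0.90
  expect_false(filter_assembly_support(rep(0L, 100))$keep)
})

test_that("oversize flagging is strict at 200 kb", {
  cands <- rbind(make_cand("at", 0, 200000),
                 make_cand("over", 300000, 550000))
  r <- flag_oversize(cands)
  expect_identical(r$oversize_suspect, c(FALSE, TRUE))
  expect_identical(nrow(flag_oversize(cands[0, ])), 0L)
})

test_that("incomplete scaffold rule needs both the <20% covered and the
           70%-below-5X criteria", {
  mk <- function(n, covered_frac, depth_val) {
    d <- rep(0L, n)
    if (covered_frac > 0) d[seq_len(round(covered_frac * n))] <- depth_val
    d
  }
  sc <- c(good = strrep("A", 8000), over20 = strrep("A", 8000))
  profs <- list(good = mk(8000, 0.05, 2L),     # 5% covered, all < 5
                over20 = mk(8000, 0.25, 2L))   # 25% covered
  inc <- classify_incomplete_scaffolds(sc, profs)
  expect_identical(inc$id, "good")
  expect_identical(inc$category, "incomplete")
  expect_true(all(is.na(inc$breakpoint)))
  # the specificity clause is an independent conjunct: relax the covered
  # bound to 100% and fail only the 70%-below-5X criterion
  sc2 <- c(deep = strrep("A", 1000))
  inc2 <- classify_incomplete_scaffolds(sc2, list(deep = mk(1000, 0.4, 9L)),
                                        covered_frac_max = 1.0)
  expect_identical(nrow(inc2), 0L)
})

test_that("anchor categories follow the placement count", {
  expect_identical(assign_anchor_category(1L), "anchored_unique")
  expect_identical(assign_anchor_category(3L), "anchored_ambiguous")
  expect_identical(assign_anchor_category(0L), "unanchored")
  expect_error(assign_anchor_category(-1L), "non-negative")
})

test_that("toy exact-flank anchoring counts distinct placements", {
  acc <- paste0(strrep("C", 50), "AAATTT", strrep("G", 50), "AAATTT",
                strrep("C", 30))
  r <- count_anchor_hits(acc, "AAA", "TTT")
  expect_identical(r$hits, 2L)
  expect_identical(r$positions, c(53L, 109L))
  expect_identical(count_anchor_hits(acc, "AAA", "GGGAA")$hits, 0L)
})

test_that("pipeline equals brute-force rule application and rejects every
           planted decoy at the right stage", {
  sim <- default_sim()
  cfg <- sim$config
  cov <- simulate_coverage(sim$truth, cfg)
  cands <- simulate_candidates(sim$truth, cfg)
  res <- run_discovery_pipeline(cands, cov, scaffolds = sim$truth$scaffolds,
                                donor = sim$donor, acceptor = sim$acceptor)
  iv <- sim$truth$intervals

  # oracle equivalence candidate-by-candidate
  for (i in seq_len(nrow(cands))) {
    opp <- cov$opposite$depth[(cands$start[i] + 1):cands$end[i]]
    own <- cov$self$proper_depth[(cands$start[i] + 1):cands$end[i]]
    keep_bf <- brute_force_rules(cands[i, ], opp, own)
    expect_identical(cands$id[i] %in% res$records$id, keep_bf)
  }

  # truth bookkeeping: all true PAVs recovered with the right category
  m <- merge(res$records, iv, by = "id", suffixes = c("", ".true"))
  anchored <- m$category.true %in% c("anchored_unique", "anchored_ambiguous")
  expect_identical(m$category[anchored], m$category.true[anchored])
  expect_identical(sum(res$records$category == "incomplete"),
                   length(sim$truth$scaffolds))
  # unique anchors carry a breakpoint; nothing else does
  expect_true(all(!is.na(m$breakpoint[m$category == "anchored_unique"])))
  expect_true(all(is.na(m$breakpoint[m$category != "anchored_unique"])))
  # no duplication decoy survives; small decoys die at min_size
  expect_identical(res$rejections$stage[res$rejections$id %in%
    iv$id[iv$category == "decoy_dup"]], rep("specificity", 2L))
  expect_identical(res$rejections$stage[res$rejections$id %in%
    iv$id[iv$category == "decoy_small"]], rep("min_size", 2L))

  # report telescopes over the candidate stages
  rep_c <- res$report[res$report$stage != "incomplete_scaffolds", ]
  expect_identical(rep_c$n_in[-1], rep_c$n_out[-nrow(rep_c)])
})

test_that("pipeline verdicts are order-insensitive (conjunctive filters)", {
  sim <- default_sim()
  cfg <- sim$config
  cov <- simulate_coverage(sim$truth, cfg)
  cands <- simulate_candidates(sim$truth, cfg)
  res1 <- run_discovery_pipeline(cands, cov, donor = sim$donor,
                                 acceptor = sim$acceptor)
  # shuffle candidate order; retained set must be identical
  set.seed(1)
  res2 <- run_discovery_pipeline(cands[sample(nrow(cands)), ], cov,
                                 donor = sim$donor, acceptor = sim$acceptor)
  expect_setequal(res1$records$id, res2$records$id)
})
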