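panel_fixture <- function() {
  geno <- matrix(c(1, 1, 0, NA,
                   1, 0, 1, 1,
                   0, 0, 0, 0,
                   1, 1, 1, 1), 4, 4, byrow = TRUE,
                 dimnames = list(paste0("p", 1:4),
                                 c("F2", "L1", "L2", "B73")))
  groups <- c(F2 = "control", L1 = "A", L2 = "B", B73 = "control")
  list(geno = geno, groups = groups)
}

test_that("shared fraction: controls pin 100%/0% and NA leaves the
           denominator", {
  fx <- panel_fixture()
  # line with calls {1,1,0,NA} over 4 donor PAVs -> 2/3 = 66.7%
  geno <- matrix(c(1, 1, 0, NA), 4, 1,
                 dimnames = list(paste0("p", 1:4), "L9"))
  expect_equal(unname(shared_fraction(geno)), 100 * 2 / 3, tolerance = 1e-12)

  sf <- shared_fraction(fx$geno)
  expect_equal(unname(sf["B73"]), 100 * mean(c(NA, 1, 0, 1), na.rm = TRUE))
  expect_error(shared_fraction(fx$geno, lines = "L99"), "absent")
  expect_error(shared_fraction(fx$geno, donor_pavs = "p99"), "absent")

  # simulated controls: donor 100%, opposite reference 0%
  cfg <- sim_config(seed = 8L)
  sim <- simulate_genome_pair(cfg)
  panel <- simulate_panel(sim$truth, cfg)
  sf2 <- shared_fraction(panel$genotypes)
  expect_equal(unname(sf2["F2"]), 100)
  expect_equal(unname(sf2["B73"]), 0)
})

test_that("group frequencies conserve the underlying counts", {
  fx <- panel_fixture()
  fr <- group_frequencies(fx$geno, fx$groups)
  cnt <- attr(fr, "counts")
  expect_equal(fr, cnt$present / cnt$typed, ignore_attr = TRUE)
  expect_equal(unname(fr["p1", ]), c(1, 0))
  expect_equal(unname(fr["p3", ]), c(0, 0))
})

test_that("sharing classes: donor-only, one-group-only, all-groups,
           NA-row exclusion", {
  fx <- panel_fixture()
  cl <- classify_sharing(fx$geno, fx$groups)
  expect_identical(as.character(cl),
                   c("one_group_only", "one_group_only", "donor_only",
                     "all_groups"))

  # a synthetic group-private PAV from the generator lands one-group-only
  cfgp <- sim_config(seed = 13L, group_spec = list(
    list(name = "A", n = 10L, beta = c(2, 2), n_private = 2L),
    list(name = "B", n = 10L, beta = c(2, 2))), n_lines = 20L)
  simp <- simulate_genome_pair(cfgp)
  pp <- simulate_panel(simp$truth, cfgp)
  clp <- classify_sharing(pp$genotypes, pp$groups)
  expect_identical(as.character(clp[1:2]),
                   rep("one_group_only", 2L))

  # NA anywhere in the panel row excludes it
  g2 <- fx$geno; g2["p2", "L1"] <- NA
  expect_true(is.na(classify_sharing(g2, fx$groups)[2]))
})

test_that("PCA separates constructed groups, is deterministic in sign, and
           satisfies the Gram identity", {
  set.seed(20)
  # two perfectly separated groups of lines over 40 loci
  geno <- cbind(matrix(1, 40, 5), matrix(0, 40, 5)) # loci x 10 lines
  geno[1:20, 1:5] <- 1; geno[1:20, 6:10] <- 0
  geno[21:40, 1:5] <- 0; geno[21:40, 6:10] <- 1
  colnames(geno) <- paste0("L", 1:10)
  rownames(geno) <- paste0("m", 1:40)
  pc <- pca_coords(geno)
  g1 <- pc$coords[1:5, 1]; g2 <- pc$coords[6:10, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))

  # duplicated line: identical coordinates
  geno2 <- cbind(geno, Ldup = geno[, 1])
  pc2 <- pca_coords(geno2)
  expect_equal(pc2$coords["Ldup", ], pc2$coords["L1", ], tolerance = 1e-9)

  # constant locus gets zero loading
  geno3 <- rbind(geno, const = rep(1, 10))
  pc3 <- pca_coords(geno3)
  expect_lt(abs(pc3$loadings["const", 1]), 1e-12)

  # Gram identity: full scores reproduce centered cross-products
  G1 <- tcrossprod(pc$scores_full)
  G2 <- tcrossprod(pc$centered)
  expect_equal(G1, G2, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pca_coords(matrix(1, 5, 4)), "rank-0")
})

test_that("hierarchical clustering of group frequencies is deterministic", {
  fx <- panel_fixture()
  cfg <- sim_config(seed = 16L)
  sim <- simulate_genome_pair(cfg)
  panel <- simulate_panel(sim$truth, cfg)
  fr <- group_frequencies(panel$genotypes, panel$groups)
  h1 <- group_dendrogram(fr)
  h2 <- group_dendrogram(fr)
  expect_identical(h1$merge, h2$merge)
  expect_identical(h1$order, h2$order)
})

test_that("r2 reproduces hand values, is symmetric and label-swap
           invariant", {
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 0)), 1 / 3, tolerance = 1e-12)
  a <- c(0, 1, 1, 0, 1); b <- c(1, 1, 0, 0, 1)
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_equal(ld_r2(a, b), ld_r2(1 - a, b))
  expect_equal(ld_r2(a, b), ld_r2(a, 1 - b))
  mono <- ld_r2(c(1, 1, 1, 1), c(0, 1, 0, 1))
  expect_true(is.na(mono))
  expect_identical(attr(mono, "reason"), "monomorphic_or_insufficient")
  # pairwise-complete NA handling
  expect_equal(ld_r2(c(0, 0, 1, 1, NA), c(0, 0, 1, 0, 1)), 1 / 3,
               tolerance = 1e-12)
})

test_that("LD decay: flat at full linkage, monotone under generated decay,
           empty bins omitted", {
  pos <- sort(sample(0:20000, 60))
  H <- simulate_ld_haplotypes(pos, n_lines = 40, corr_length = 1e12,
                              seed = 2)
  info <- data.frame(pos = pos, type = "SNP", region = "flank")
  dec <- ld_decay(H, info, pairing = "within_flank")
  expect_true(all(dec$r2 > 0.999))

  H2 <- simulate_ld_haplotypes(pos, n_lines = 120, corr_length = 3000,
                               seed = 3)
  dec2 <- ld_decay(H2, info, pairing = "within_flank", bin_width = 4000)
  # binned curve tracks the analytic decay exp(-d/L)^2 within sampling error
  expect_gt(dec2$r2[1], dec2$r2[nrow(dec2)])
  expect_lt(mean(abs(dec2$r2 - exp(-2 * dec2$dist / 3000))), 0.15)

  # no qualifying pairs warns and returns empty
  expect_warning(
    empty <- ld_decay(H[1:2, ], info[1:2, ], pairing = "pav_vs_flank"),
    "no qualifying")
  expect_identical(nrow(empty), 0L)

  # PAV vs flank with both codings
  info3 <- data.frame(pos = c(5000, 5100, 9000, 12000),
                      type = c("PAV01", "SNP", "SNP", "SNP"),
                      region = c("pav", "pav", "flank", "flank"))
  G3 <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 0, 1, 0))
  d01 <- ld_decay(G3, info3, pairing = "pav_vs_flank",
                  pav_coding = "zero_one", bin_width = 20000)
  dsnp <- ld_decay(G3, info3, pairing = "pav_vs_flank",
                   pav_coding = "internal_snp", bin_width = 20000)
  # same allele vectors here, so identical mean r2
  expect_equal(d01$r2, dsnp$r2, tolerance = 1e-12)
  expect_equal(d01$r2, mean(c(0, 1 / 3)), tolerance = 1e-12)
})

test_that("windowed density: flat for uniform features, support width for a
           point feature, empty input", {
  # single feature in mid-contig: counted by exactly window/step windows
  wd <- windowed_density(55e6, 100e6, window = 1e7, step = 1e6)
  expect_identical(sum(wd$count > 0), 10L)
  # uniform features: interior windows all equal
  pos <- seq(0, 100e6 - 1, by = 1e5)
  wd2 <- windowed_density(pos, 100e6, window = 1e7, step = 1e6)
  interior <- wd2$count[wd2$end - wd2$start == 1e7]
  expect_identical(length(unique(interior)), 1L)
  # empty input: all-zero track
  wd3 <- windowed_density(numeric(0), 1e6)
  expect_true(all(wd3$count == 0))
  expect_identical(nrow(windowed_density(numeric(0), 0)), 0L)
  # max-scaling
  wd4 <- windowed_density(c(1e6, 1.2e6), 1e7, window = 1e6, step = 5e5,
                          scale_max = TRUE)
  expect_equal(max(wd4$scaled), 1)
})
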