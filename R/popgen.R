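#' Per-line fraction of donor PAVs called present
#'
#' For each line, the percentage of the donor's PAVs called present in that
#' line; unclassified (NA) calls are excluded from the denominator.  The
#' donor control is 100% and the opposite reference 0% by construction.
#'
#' @param geno region x line matrix in \{0, 1, NA\}.
#' @param donor_pavs row ids forming the donor PAV set; defaults to all
#'   rows.
#' @param lines columns to report; defaults to all.
#' @return named numeric vector of percentages.
#' @export
shared_fraction <- function(geno, donor_pavs = rownames(geno),
                            lines = colnames(geno)) {
  missing_lines <- setdiff(lines, colnames(geno))
  if (length(missing_lines))
    stop("lines absent from the matrix: ",
         paste(missing_lines, collapse = ", "))
  bad <- setdiff(donor_pavs, rownames(geno))
  if (length(bad)) stop("donor PAVs absent from the matrix: ",
                        paste(bad, collapse = ", "))
  sub <- geno[donor_pavs, lines, drop = FALSE]
  100 * colMeans(sub == 1, na.rm = TRUE)
}

#' Per-group PAV presence frequencies
#'
#' @param geno region x line matrix in \{0, 1, NA\}.
#' @param groups named character vector mapping line names to group names;
#'   lines with group `"control"` are excluded.
#' @return region x group matrix of presence frequencies (NA calls excluded
#'   from each denominator); the attribute `"counts"` carries the present /
#'   typed counts behind each frequency.
#' @export
group_frequencies <- function(geno, groups) {
  groups <- groups[names(groups) %in% colnames(geno)]
  groups <- groups[groups != "control"]
  gnames <- unique(groups)
  if (!length(gnames)) stop("no non-control groups")
  freq <- matrix(NA_real_, nrow(geno), length(gnames),
                 dimnames = list(rownames(geno), gnames))
  npres <- ntyped <- freq
  for (g in gnames) {
    cols <- names(groups)[groups == g]
    sub <- geno[, cols, drop = FALSE]
    npres[, g] <- rowSums(sub == 1, na.rm = TRUE)
    ntyped[, g] <- rowSums(!is.na(sub))
    freq[, g] <- npres[, g] / ntyped[, g]
  }
  attr(freq, "counts") <- list(present = npres, typed = ntyped)
  freq
}

#' Sharing class of each PAV across groups
#'
#' Using only complete-case rows (no NA call in any panel line), classifies
#' each PAV by which groups contain at least one carrier: `donor_only`
#' (present in no panel line — only the donor control carries it),
#' `one_group_only`, `all_groups`, or `other`.
#'
#' @param geno region x line matrix in \{0, 1, NA\}.
#' @param groups named character vector line -> group (`"control"` lines
#'   excluded from the classification).
#' @return factor per region, NA for rows with missing calls.
#' @export
classify_sharing <- function(geno, groups) {
  groups <- groups[names(groups) %in% colnames(geno)]
  groups <- groups[groups != "control"]
  gnames <- unique(groups)
  panel <- geno[, names(groups), drop = FALSE]
  cc <- complete.cases(panel)
  out <- rep(NA_character_, nrow(geno))
  carrier <- sapply(gnames, function(g)
    rowSums(panel[, names(groups)[groups == g], drop = FALSE] == 1) > 0)
  if (is.null(dim(carrier))) carrier <- matrix(carrier, nrow = 1)
  ng <- rowSums(carrier)
  ng[!cc | is.na(ng)] <- -1L
  out[cc & ng == 0] <- "donor_only"
  out[cc & ng == 1] <- "one_group_only"
  out[cc & ng == length(gnames)] <- "all_groups"
  out[cc & is.na(out)] <- "other"
  factor(out, levels = c("donor_only", "one_group_only", "all_groups",
                         "other"))
}

#' Principal-component coordinates of the lines
#'
#' Lines are the observations and complete-case loci the variables; the
#' matrix is column-centered but not scaled (presence frequencies carry the
#' signal), then eigen-decomposed.  The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making coordinates
#' deterministic.
#'
#' @param geno region x line matrix in \{0, 1, NA\} (regions become the
#'   variables).
#' @param k number of components to return.
#' @param scale. scale loci to unit variance as well.
#' @return list of class `pav_pca`: `coords` (line x k), `loadings`,
#'   `sdev`, `var_explained`.
#' @export
pca_coords <- function(geno, k = 2L, scale. = FALSE) {
  m <- t(geno[complete.cases(geno), , drop = FALSE])  # lines x loci
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 lines and 2 complete-case loci")
  if (all(apply(m, 2, function(v) length(unique(v)) == 1)))
    stop("rank-0 matrix: every locus is constant")
  if (scale.) {
    v <- apply(m, 2, sd)
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = scale.)
  k <- min(k, ncol(pc$x))
  for (j in seq_len(ncol(pc$x))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev, var_explained = ve,
                 scores_full = pc$x, centered = scale(m, scale = FALSE)),
            class = "pav_pca")
}

#' @export
print.pav_pca <- function(x, ...) {
  cat("PCA of", nrow(x$coords), "lines;",
      sprintf("PC1 %.1f%%, PC2 %.1f%%\n", 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Average-linkage dendrogram of groups from their PAV frequencies
#'
#' Euclidean distances between the group columns of a
#' [group_frequencies()] matrix, clustered with average linkage;
#' deterministic given the input order.
#'
#' @param freq region x group frequency matrix.
#' @return an `hclust` object.
#' @export
group_dendrogram <- function(freq) {
  hclust(dist(t(freq), method = "euclidean"), method = "average")
}

#' Squared allele-frequency correlation between two biallelic loci
#'
#' On a fully homozygous (inbred) panel the 0/1 genotype codes are
#' haplotype-equivalent, so linkage disequilibrium reduces to the squared
#' Pearson correlation of the allele codes.  Missing values are dropped
#' pairwise.
#'
#' @param a,b 0/1/NA vectors over the same lines.
#' @return r-squared, or NA (with attribute `"reason"`) when either locus is
#'   monomorphic among the complete pairs.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "monomorphic_or_insufficient"
    return(out)
  }
  cor(a, b)^2
}

#' Binned LD decay over a locus table
#'
#' Computes r-squared for every qualifying locus pair within `max_dist` and
#' averages it in distance bins.  Loci are rows of `geno`, with bp positions
#' and a type (`"PAV01"` for a presence/absence variant coded 0/1 at its
#' breakpoint, `"SNP"` otherwise) and a region tag (`"pav"` for SNPs inside
#' PAV sequence, `"flank"` for flanking SNPs).
#'
#' Pairings: `"pav_vs_flank"` pairs each PAV01 locus (or, with
#' `pav_coding = "internal_snp"`, the pav-region SNP closest to each PAV01
#' position) with every flank SNP; `"within_pav"` pairs pav-region loci with
#' each other; `"within_flank"` pairs flank SNPs with each other.
#'
#' @param geno locus x line 0/1/NA matrix.
#' @param info data frame with one row per locus: `pos` (bp), `type`
#'   (`"PAV01"`/`"SNP"`), `region` (`"pav"`/`"flank"`); row order matches
#'   `geno`.
#' @param pairing which pairs to evaluate.
#' @param pav_coding how a PAV enters the pair: as its own 0/1 locus or via
#'   its nearest internal SNP.
#' @param max_dist maximum pair distance (bp).
#' @param bin_width distance bin width (bp).
#' @return data frame of class `ld_decay`: bin midpoints, mean r-squared
#'   and pair counts; bins with no pairs are omitted.
#' @export
ld_decay <- function(geno, info,
                     pairing = c("pav_vs_flank", "within_pav",
                                 "within_flank"),
                     pav_coding = c("zero_one", "internal_snp"),
                     max_dist = 20000, bin_width = 500) {
  pairing <- match.arg(pairing)
  pav_coding <- match.arg(pav_coding)
  stopifnot(nrow(geno) == nrow(info))
  idx_pav01 <- which(info$type == "PAV01")
  idx_pav_snp <- which(info$type == "SNP" & info$region == "pav")
  idx_flank <- which(info$type == "SNP" & info$region == "flank")

  pav_side <- if (pairing == "pav_vs_flank" && pav_coding == "internal_snp") {
    vapply(idx_pav01, function(i)
      idx_pav_snp[which.min(abs(info$pos[idx_pav_snp] - info$pos[i]))],
      integer(1))
  } else idx_pav01

  pairs <- switch(pairing,
    pav_vs_flank = expand.grid(i = pav_side, j = idx_flank),
    within_pav = {
      ii <- c(idx_pav_snp, if (pav_coding == "zero_one") idx_pav01)
      if (length(ii) < 2) data.frame(i = integer(0), j = integer(0))
      else { cm <- utils::combn(sort(ii), 2); data.frame(i = cm[1, ], j = cm[2, ]) }
    },
    within_flank = {
      if (length(idx_flank) < 2) data.frame(i = integer(0), j = integer(0))
      else { cm <- utils::combn(idx_flank, 2); data.frame(i = cm[1, ], j = cm[2, ]) }
    })
  if (nrow(pairs) == 0) {
    warning("no qualifying locus pairs for pairing '", pairing, "'")
    return(structure(data.frame(dist = numeric(0), r2 = numeric(0),
                                n_pairs = integer(0)),
                     class = c("ld_decay", "data.frame")))
  }
  d <- abs(info$pos[pairs$i] - info$pos[pairs$j])
  keep <- d <= max_dist & d > 0
  pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
  r2 <- vapply(seq_len(nrow(pairs)), function(r)
    as.numeric(ld_r2(geno[pairs$i[r], ], geno[pairs$j[r], ])), numeric(1))
  bin <- floor(d / bin_width)
  ok <- !is.na(r2)
  agg <- tapply(r2[ok], bin[ok], mean)
  cnt <- tapply(r2[ok], bin[ok], length)
  out <- data.frame(dist = (as.integer(names(agg)) + 0.5) * bin_width,
                    r2 = as.numeric(agg), n_pairs = as.integer(cnt))
  structure(out[order(out$dist), ], class = c("ld_decay", "data.frame"))
}

#' @export
plot.ld_decay <- function(x, ...) {
  plot(x$dist, x$r2, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "distance (bp)", ylab = expression(mean ~ r^2), ...)
  invisible(x)
}

#' Sliding-window feature density along a contig
#'
#' Counts features (point positions) in windows of `window` bp advanced by
#' `step` bp from the contig start; the last window is truncated at the
#' contig end.  Optionally scales counts relative to the highest window.
#'
#' @param positions feature bp positions (0-based), need not be sorted.
#' @param contig_length contig length in bp.
#' @param window,step window and step sizes in bp.
#' @param scale_max divide counts by the maximum window count.
#' @return data frame `start`, `end`, `count` (+ `scaled` when requested).
#' @export
windowed_density <- function(positions, contig_length, window = 1e7,
                             step = 1e6, scale_max = FALSE) {
  if (contig_length <= 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      count = integer(0)))
  starts <- seq(0, max(0, contig_length - 1), by = step)
  ends <- pmin(starts + window, contig_length)
  counts <- vapply(seq_along(starts), function(i)
    sum(positions >= starts[i] & positions < ends[i]), integer(1))
  out <- data.frame(start = starts, end = ends, count = counts)
  if (scale_max) out$scaled <- if (max(counts) > 0) counts / max(counts)
                               else counts
  out
}
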