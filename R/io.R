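#' Write intervals as a BED file
#'
#' Emits 0-based half-open intervals with the record id in the name column
#' and an integer category code in the score column.
#'
#' @param df data frame with `contig` (or a single `contig` value for all
#'   rows), `start`, `end`, `id` and optionally `category`.
#' @param path output file.
#' @param contig fallback contig name when `df` lacks the column.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path, contig = "donor") {
  chrom <- if (!is.null(df$contig)) df$contig else rep(contig, nrow(df))
  score <- if (!is.null(df$category))
    as.integer(factor(df$category)) else rep(0L, nrow(df))
  bed <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = df$id, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a matrix as TSV with row names in the first column
#'
#' @param m matrix (e.g. counts, genotype calls).
#' @param path output file.
#' @param id_col name of the first column.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
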