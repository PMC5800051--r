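#' Build a two-pseudomolecule pan-genome
#'
#' Appends the genotype-specific sequences to a reference as two
#' pseudomolecule-like sequences: one concatenating the anchored sequences
#' (in reference-position order as supplied) and one the unanchored
#' sequences (input order), consecutive sequences separated by a run of
#' exactly `spacer` N characters.  Spacers are internal only: none before
#' the first or after the last sequence.  An exact bidirectional coordinate
#' map records where each input sequence lies in its pseudomolecule.  A
#' pseudomolecule whose input set is empty is omitted from the output.
#'
#' @param reference named character vector of reference sequences (kept
#'   untouched), may be empty.
#' @param anchored named character vector of anchored genotype-specific
#'   sequences (names are the PAV ids).
#' @param unanchored named character vector of unanchored sequences.
#' @param spacer spacer length in N characters.
#' @return object of class `pan_genome`: `sequences` (reference plus the
#'   pseudomolecules `pav_anchored` / `pav_unanchored`), `map` (data frame
#'   pav_id, molecule, start, end; 0-based half-open), `spacer`.
#' @export
build_pangenome <- function(reference = character(0),
                            anchored = character(0),
                            unanchored = character(0), spacer = 100L) {
  ids <- c(names(anchored), names(unanchored))
  if (length(ids) == 0) stop("no genotype-specific sequences supplied")
  if (is.null(ids) || any(!nzchar(ids)) || length(ids) <
      length(anchored) + length(unanchored))
    stop("every sequence must be named with its PAV id")
  if (anyDuplicated(ids)) stop("duplicate PAV ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (any(!nzchar(c(anchored, unanchored)))) stop("empty sequence supplied")
  stopifnot(spacer >= 0)

  assemble <- function(seqs, molecule) {
    if (!length(seqs)) return(NULL)
    lens <- nchar(seqs)
    starts <- cumsum(c(0L, head(lens, -1L) + spacer))
    list(seq = paste(seqs, collapse = strrep("N", spacer)),
         map = data.frame(pav_id = names(seqs), molecule = molecule,
                          start = as.integer(starts),
                          end = as.integer(starts + lens)))
  }
  a <- assemble(anchored, "pav_anchored")
  u <- assemble(unanchored, "pav_unanchored")
  sequences <- reference
  map <- list()
  if (!is.null(a)) { sequences[["pav_anchored"]] <- a$seq; map <- c(map, list(a$map)) }
  if (!is.null(u)) { sequences[["pav_unanchored"]] <- u$seq; map <- c(map, list(u$map)) }
  map <- do.call(rbind, map)
  rownames(map) <- NULL
  structure(list(sequences = sequences, map = map, spacer = spacer),
            class = "pan_genome")
}

#' @export
print.pan_genome <- function(x, ...) {
  cat("Pan-genome:", length(x$sequences), "sequences,",
      nrow(x$map), "mapped PAV blocks,", x$spacer, "N spacers\n")
  for (nm in intersect(c("pav_anchored", "pav_unanchored"),
                       names(x$sequences)))
    cat(" ", nm, ":", nchar(x$sequences[[nm]]), "bp\n")
  invisible(x)
}

#' Map a PAV-local offset to a pan-genome position
#'
#' @param pg a `pan_genome`.
#' @param pav_id id of the mapped sequence.
#' @param offset 0-based offset within the PAV sequence.
#' @return list `molecule`, `position` (0-based on the pseudomolecule).
#' @export
map_to_pan <- function(pg, pav_id, offset) {
  row <- pg$map[pg$map$pav_id == pav_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown PAV id: ", pav_id)
  if (offset < 0 || offset >= row$end - row$start)
    stop("offset ", offset, " out of range for ", pav_id)
  list(molecule = row$molecule, position = row$start + as.integer(offset))
}

#' Map a pan-genome position back to its PAV
#'
#' Inverse of [map_to_pan()] on non-spacer positions; positions inside a
#' spacer return the sentinel `pav_id = NA` with `spacer = TRUE`.
#'
#' @param pg a `pan_genome`.
#' @param molecule pseudomolecule name.
#' @param position 0-based position on the pseudomolecule.
#' @return list `pav_id`, `offset`, `spacer`.
#' @export
map_from_pan <- function(pg, molecule, position) {
  if (!molecule %in% pg$map$molecule) stop("unknown molecule: ", molecule)
  if (position < 0 || position >= nchar(pg$sequences[[molecule]]))
    stop("position ", position, " out of range on ", molecule)
  m <- pg$map[pg$map$molecule == molecule, , drop = FALSE]
  hit <- which(position >= m$start & position < m$end)
  if (length(hit) == 0)
    return(list(pav_id = NA_character_, offset = NA_integer_, spacer = TRUE))
  list(pav_id = m$pav_id[hit], offset = as.integer(position - m$start[hit]),
       spacer = FALSE)
}

#' Write a pan-genome (or any named sequences) as 60-column FASTA
#'
#' @param x a `pan_genome` or a named character vector of sequences.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pangenome <- function(x, path) {
  seqs <- if (inherits(x, "pan_genome")) x$sequences else x
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(dna, path, width = 60L)
  invisible(path)
}

#' Read FASTA sequences as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}

#' Write the pan-genome coordinate map as TSV
#'
#' Columns: pav_id, molecule, start, end (0-based half-open).
#'
#' @param pg a `pan_genome`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_coordinate_map <- function(pg, path) {
  utils::write.table(pg$map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
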