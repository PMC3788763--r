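#' Labeled haplotype alignments
#'
#' An alignment is a tibble with columns `id` (unique individual
#' identifiers), `pop` (population label) and `seq` (aligned A/C/G/T
#' sequence, all the same length). [haplotype_alignment()] validates a data
#' frame; [read_alignment()]/[write_alignment()] round-trip the FASTA +
#' two-column population-map representation.
#'
#' @param x A data frame with columns `id`, `pop`, `seq`.
#' @return A validated alignment tibble.
#' @export
haplotype_alignment <- function(x) {
  x <- as_tibble(x)
  need <- c("id", "pop", "seq")
  if (!all(need %in% names(x)))
    abort("an alignment needs columns id, pop, seq")
  if (nrow(x) == 0) abort("alignment has no sequences")
  if (anyDuplicated(x$id)) abort("individual ids must be unique")
  if (any(is.na(x$pop)) || any(x$pop == ""))
    abort("every individual must have a population label")
  if (length(unique(nchar(x$seq))) != 1)
    abort("all sequences must have the same aligned length")
  if (any(grepl("[^ACGT]", x$seq)))
    abort("sequences may contain only A, C, G, T")
  x[need]
}

#' Locus length of an alignment
#' @param aln An alignment tibble.
#' @return Number of aligned sites.
#' @export
locus_length <- function(aln) nchar(aln$seq[1])

#' @rdname haplotype_alignment
#' @param fasta Path to a FASTA file of aligned sequences.
#' @param popmap Path to a two-column tab-separated file
#'   (individual id, population), no header.
#' @export
read_alignment <- function(fasta, popmap) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  map <- read.table(popmap, sep = "\t", header = FALSE,
                    col.names = c("id", "pop"),
                    colClasses = c("character", "character"))
  ids <- names(seqs)
  missing <- setdiff(ids, map$id)
  if (length(missing))
    abort(paste0("individuals absent from the population map: ",
                 paste(head(missing, 5), collapse = ", ")))
  haplotype_alignment(tibble(id = ids,
                             pop = map$pop[match(ids, map$id)],
                             seq = as.character(seqs)))
}

#' @rdname haplotype_alignment
#' @param aln An alignment tibble.
#' @export
write_alignment <- function(aln, fasta, popmap) {
  aln <- haplotype_alignment(aln)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(aln$seq, aln$id)), fasta)
  write.table(aln[, c("id", "pop")], popmap, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, popmap = popmap))
}
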