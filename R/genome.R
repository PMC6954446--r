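#' Reference genome container
#'
#' A minimal container for a single reference sequence. Sequences are held in
#' the DNA alphabet; uridine positions of the (+)-strand RNA genome are the
#' positions where the DNA sequence reads `T`. All coordinates in the package
#' are 1-based and fully closed, matching SAM convention.
#'
#' @param id reference identifier (used as the SAM `@SQ` name).
#' @param seq character scalar over `A`,`C`,`G`,`T`,`N` (lowercase accepted,
#'   `U` accepted and stored as `T`).
#' @return an object of class `Genome` with elements `id` and `seq`.
#' @export
genome <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- chartr("acgtun", "ACGTTN", seq)
  seq <- chartr("U", "T", seq)
  if (nzchar(seq) && grepl("[^ACGTN]", seq))
    stop("genome sequence contains characters outside {A,C,G,T,N,U}")
  structure(list(id = id, seq = seq), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d nt (%d U positions)\n",
              x$id, genome_length(x), length(uridine_positions(x))))
  invisible(x)
}

#' Genome length in nucleotides
#' @param g a [genome()].
#' @export
genome_length <- function(g) nchar(g$seq)

#' Genome sequence as a per-position character vector
#' @param g a [genome()].
#' @return character vector of length `genome_length(g)`.
#' @export
genome_bases <- function(g) {
  if (genome_length(g) == 0L) return(character(0))
  strsplit(g$seq, "", fixed = TRUE)[[1]]
}

#' Uridine positions of a genome
#'
#' Positions where the DNA-alphabet reference reads `T`, i.e. the uridines of
#' the (+)-strand RNA.
#'
#' @param g a [genome()].
#' @return ascending integer vector of 1-based positions.
#' @export
uridine_positions <- function(g) which(genome_bases(g) == "T")

#' Count uridines in a genome
#' @param g a [genome()].
#' @export
count_uridines <- function(g) length(uridine_positions(g))

#' Read genomes from a FASTA file
#'
#' @param path FASTA file; may contain several records.
#' @return a named list of [genome()] objects (first word of each header as
#'   both name and id).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  out <- lapply(seq_along(ss), function(i) genome(ids[i], as.character(ss[[i]])))
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#' @param genomes a [genome()] or list of them.
#' @param path output file.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$seq, character(1)))
  names(ss) <- vapply(genomes, function(g) g$id, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
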