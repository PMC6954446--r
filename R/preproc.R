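#' @title Read-level preprocessing
#' @description Trimming and quality filtering applied to raw single-end reads
#'   before alignment: adapter removal (exact match plus terminal partial
#'   matches), removal of a fixed 5' prefix (random-primed bases from library
#'   construction), and a whole-read Phred quality filter.
#' @name preproc
NULL

#' Construct a sequencing read
#'
#' @param id read identifier.
#' @param bases character scalar over `A`,`C`,`G`,`T`,`N`.
#' @param quals integer vector of Phred scores, one per base.
#' @return an object of class `Read`.
#' @export
seq_read <- function(id, bases, quals) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("length(bases) must equal length(quals)")
  if (any(quals < 0L)) stop("Phred scores must be >= 0")
  if (nzchar(bases) && grepl("[^ACGTN]", bases))
    stop("read bases outside {A,C,G,T,N}")
  structure(list(id = as.character(id), bases = bases, quals = quals),
            class = "Read")
}

#' Trim an adapter from the 3' end of a read
#'
#' Removes the read suffix starting at the first exact occurrence of the
#' adapter; if the adapter does not occur in full, a terminal partial match
#' (a read suffix equal to an adapter prefix of at least `min_match` bases)
#' is trimmed instead. Reads shorter than `min_len` after trimming are
#' discarded.
#'
#' @param read a [seq_read()].
#' @param adapter adapter sequence (default the Illumina TruSeq adapter).
#' @param min_len minimum post-trim read length to keep (default 40).
#' @param min_match minimum length of a terminal partial adapter match
#'   (default 3).
#' @return the trimmed `Read`, or `NULL` when the read is discarded.
#' @export
trim_adapter <- function(read, adapter = "AGATCGGAAGAGC", min_len = 40L,
                         min_match = 3L) {
  stopifnot(inherits(read, "Read"), nzchar(adapter))
  adapter <- toupper(adapter)
  n <- nchar(read$bases)
  cut <- regexpr(adapter, read$bases, fixed = TRUE)[1]
  if (cut < 0L) {
    # longest read suffix that is a prefix of the adapter, >= min_match bases
    kmax <- min(nchar(adapter) - 1L, n)
    cut <- -1L
    if (kmax >= min_match) {
      for (k in kmax:min_match) {
        if (substring(read$bases, n - k + 1L, n) == substring(adapter, 1L, k)) {
          cut <- n - k + 1L
          break
        }
      }
    }
  }
  if (cut > 0L) {
    keep <- cut - 1L
    read <- seq_read(read$id, substring(read$bases, 1L, keep),
                     read$quals[seq_len(keep)])
  }
  if (nchar(read$bases) < min_len) NULL else read
}

#' Remove a fixed number of 5' bases
#'
#' Drops the first `n` bases and qualities. The default of 6 corresponds to
#' keeping from base 7 onwards, removing the random bases introduced by
#' random-primed library construction.
#'
#' @param read a [seq_read()].
#' @param n number of leading bases to remove (default 6).
#' @return the trimmed `Read`, or `NULL` when the read is shorter than `n`.
#' @export
trim_fixed_prefix <- function(read, n = 6L) {
  stopifnot(inherits(read, "Read"), n >= 0L)
  len <- nchar(read$bases)
  if (len < n) return(NULL)
  if (n == 0L) return(read)
  seq_read(read$id, substring(read$bases, n + 1L, len),
           read$quals[-seq_len(n)])
}

#' Whole-read quality filter
#'
#' Discards a read when more than `max_low_frac` of its bases have a Phred
#' score below `min_phred`. The boundary is kept: a read with exactly
#' `max_low_frac` low-quality bases passes. Zero-length reads are discarded.
#'
#' @param read a [seq_read()].
#' @param min_phred Phred threshold (default 20).
#' @param max_low_frac maximum tolerated fraction of low-quality bases
#'   (default 0.04).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_by_quality <- function(read, min_phred = 20L, max_low_frac = 0.04) {
  stopifnot(inherits(read, "Read"))
  n <- length(read$quals)
  if (n == 0L) return(FALSE)
  sum(read$quals < min_phred) / n <= max_low_frac
}

#' Preprocess a set of reads
#'
#' Applies, in order: adapter trimming, fixed 5'-prefix trimming, and the
#' quality filter. The chain is idempotent after the first pass. No read's
#' bases are modified other than by truncation.
#'
#' @param reads list of [seq_read()] objects.
#' @param adapter,min_len,min_match passed to [trim_adapter()].
#' @param trim_prefix passed to [trim_fixed_prefix()] as `n`.
#' @param min_phred,max_low_frac passed to [filter_by_quality()].
#' @return list of surviving `Read`s (possibly shorter than the input).
#' @export
preprocess_reads <- function(reads, adapter = "AGATCGGAAGAGC", min_len = 40L,
                             min_match = 3L, trim_prefix = 6L, min_phred = 20L,
                             max_low_frac = 0.04) {
  out <- vector("list", length(reads))
  j <- 0L
  for (r in reads) {
    r <- trim_adapter(r, adapter, min_len, min_match)
    if (is.null(r)) next
    r <- trim_fixed_prefix(r, trim_prefix)
    if (is.null(r)) next
    if (!filter_by_quality(r, min_phred, max_low_frac)) next
    j <- j + 1L
    out[[j]] <- r
  }
  out[seq_len(j)]
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ file.
#' @return list of [seq_read()] objects.
#' @export
read_fastq <- function(path) {
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      # Biostrings warns about dropping its own metadata columns here
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  quals <- as(Biostrings::quality(qs), "IntegerList")
  ids <- vapply(strsplit(names(qs), "\\s+"), `[[`, character(1), 1L)
  lapply(seq_along(qs), function(i)
    seq_read(ids[i], as.character(qs[[i]]), quals[[i]]))
}

#' Write reads to a FASTQ file (Phred+33)
#' @param reads list of [seq_read()] objects.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$id), r$bases, "+",
                 intToUtf8(pmin(r$quals, 93L) + 33L)), con)
  }
  invisible(path)
}
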