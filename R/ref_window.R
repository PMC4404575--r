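#' Reference sequence windows
#'
#' A `ref_window` holds the genomic plus-strand sequence of a region of a
#' chromosome together with its coordinates, so that sequence for a locus at,
#' say, 79.5 Mb can be exchanged without materialising a chromosome-length
#' FASTA. On disk a window is an ordinary FASTA record whose name uses the
#' `samtools faidx` region convention, `chrom:start-end` (1-based inclusive).
#'
#' @param chrom Chromosome name.
#' @param start 1-based genomic position of the first base of `seq`.
#' @param seq A single character string of A/C/G/T/N.
#' @return An object of class `ref_window`.
#' @export
ref_window <- function(chrom, start, seq) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.numeric(start), length(start) == 1L, start >= 1,
            is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  structure(
    list(chrom = chrom, start = as.numeric(start), seq = toupper(seq)),
    class = "ref_window"
  )
}

#' @export
print.ref_window <- function(x, ...) {
  cat(sprintf("<ref_window> %s:%s-%s (%d bp)\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$start + nchar(x$seq) - 1, scientific = FALSE),
              nchar(x$seq)))
  invisible(x)
}

ref_end <- function(ref) ref$start + nchar(ref$seq) - 1

#' Fetch sequence from a reference window
#'
#' @param ref A [ref_window()].
#' @param chrom,lo,hi Genomic 1-based inclusive coordinates (`lo <= hi`).
#' @param strand `"+"` returns the plus-strand sequence, `"-"` its reverse
#'   complement (i.e. the transcribed-strand sequence of a minus-strand gene).
#' @return A character string.
#' @export
ref_fetch <- function(ref, chrom, lo, hi, strand = "+") {
  stopifnot(inherits(ref, "ref_window"), lo <= hi)
  if (!identical(chrom, ref$chrom)) {
    stop("ref_window covers ", ref$chrom, ", not ", chrom, call. = FALSE)
  }
  if (lo < ref$start || hi > ref_end(ref)) {
    stop(sprintf("requested %s:%s-%s outside ref_window %s:%s-%s",
                 chrom, lo, hi, ref$chrom, ref$start, ref_end(ref)),
         call. = FALSE)
  }
  s <- substr(ref$seq, lo - ref$start + 1, hi - ref$start + 1)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

#' @rdname ref_fetch
#' @param pos A single genomic position.
#' @export
ref_base <- function(ref, chrom, pos, strand = "+") {
  ref_fetch(ref, chrom, pos, pos, strand)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

#' Read and write region-FASTA reference windows
#'
#' `write_ref_fasta()` writes a [ref_window()] as a FASTA record named
#' `chrom:start-end`; `read_ref_fasta()` parses such a record back. A record
#' whose name carries no region suffix is taken to start at position 1.
#'
#' @param ref A [ref_window()].
#' @param path File path.
#' @return `read_ref_fasta()` returns a [ref_window()]; `write_ref_fasta()`
#'   returns `path` invisibly.
#' @export
write_ref_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "ref_window"))
  dss <- Biostrings::DNAStringSet(ref$seq)
  names(dss) <- sprintf("%s:%s-%s", ref$chrom,
                        format(ref$start, scientific = FALSE),
                        format(ref_end(ref), scientific = FALSE))
  Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_ref_fasta
#' @export
read_ref_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) != 1L) {
    stop("expected a single reference record in ", path, call. = FALSE)
  }
  nm <- names(dss)[1]
  m <- regmatches(nm, regexec("^(\\S+):(\\d+)-(\\d+)", nm))[[1]]
  if (length(m) == 4L) {
    ref_window(m[2], as.numeric(m[3]), as.character(dss[[1]]))
  } else {
    ref_window(sub("\\s.*$", "", nm), 1, as.character(dss[[1]]))
  }
}
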