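#' Stranded multi-exon gene models
#'
#' A `gene_model` describes one transcript: its exons in transcript order
#' (genomic 1-based inclusive coordinates), the strand, and where the coding
#' sequence starts and ends along the spliced transcript. It supports the
#' coordinate arithmetic the pipeline needs: transcript to genomic mapping and
#' back (with HGVS-style intronic offsets), donor/acceptor site lookup, and
#' spliced-sequence extraction.
#'
#' Transcript positions are 1-based along the spliced transcript, 5' to 3'.
#' c.-style anchors used elsewhere in the package are these transcript
#' positions.
#'
#' @param gene_id Gene or transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with columns `gstart`, `gend` (genomic 1-based,
#'   `gstart <= gend`), one row per exon *in transcript order* (for a
#'   minus-strand gene the first row has the highest genomic coordinates).
#' @param cds_start,cds_end First and last coding base in transcript
#'   coordinates (inclusive; `cds_end` includes the stop codon).
#' @param primers Optional list with elements `fwd` and `rev`, each a
#'   length-2 integer vector of transcript coordinates (outer ends included),
#'   used by [insilico_rtpcr()].
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end,
                       primers = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- tibble::as_tibble(exons)
  stopifnot(all(c("gstart", "gend") %in% names(exons)),
            all(exons$gstart <= exons$gend))
  # transcript order must advance along the strand
  if (nrow(exons) > 1L) {
    ord_ok <- if (strand == "+") all(diff(exons$gstart) > 0)
              else all(diff(exons$gstart) < 0)
    if (!ord_ok) stop("exons are not in transcript order for strand ", strand,
                      call. = FALSE)
  }
  exons$exon <- seq_len(nrow(exons))
  exons$width <- exons$gend - exons$gstart + 1
  exons$tx_start <- cumsum(dplyr::lag(exons$width, default = 0)) + 1
  exons$tx_end <- cumsum(exons$width)
  tx_len <- sum(exons$width)
  stopifnot(cds_start >= 1, cds_end <= tx_len, cds_start < cds_end,
            (cds_end - cds_start + 1) %% 3 == 0)
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons[, c("exon", "gstart", "gend", "width",
                           "tx_start", "tx_end")],
         tx_len = tx_len, cds_start = cds_start, cds_end = cds_end,
         primers = primers),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%s-%s (%s), %d exons, tx %d nt, CDS %d-%d\n",
              x$gene_id, x$chrom,
              format(min(x$exons$gstart), scientific = FALSE),
              format(max(x$exons$gend), scientific = FALSE),
              x$strand, nrow(x$exons), x$tx_len, x$cds_start, x$cds_end))
  print(x$exons)
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

gene_span <- function(model) {
  c(min(model$exons$gstart), max(model$exons$gend))
}

#' Map transcript positions to genomic positions
#'
#' @param model A [gene_model()].
#' @param tx_pos Vector of transcript positions (1-based, spliced).
#' @return Numeric vector of genomic positions.
#' @export
tx_to_genomic <- function(model, tx_pos) {
  stopifnot(all(tx_pos >= 1 & tx_pos <= model$tx_len))
  ex <- model$exons
  idx <- findInterval(tx_pos, ex$tx_start)
  off <- tx_pos - ex$tx_start[idx]
  if (model$strand == "+") ex$gstart[idx] + off else ex$gend[idx] - off
}

#' Map genomic positions to transcript anchors
#'
#' Exonic positions map to their transcript coordinate with offset 0. Intronic
#' positions map, HGVS-style, to the nearest exonic base: offset `+k` means
#' `k` bases into the intron downstream of the anchored exon end (donor side),
#' `-k` means `k` bases upstream of the anchored exon start (acceptor side).
#' Distances are measured along the transcribed strand.
#'
#' @param model A [gene_model()].
#' @param gpos Vector of genomic positions within the gene span.
#' @return A tibble with columns `gpos`, `tx_anchor`, `offset`, `region`
#'   (`"exon"`/`"intron"`), `exon` (containing or nearest exon index),
#'   `intron` (intron index or `NA`).
#' @export
genomic_to_tx <- function(model, gpos) {
  ex <- model$exons
  span <- gene_span(model)
  purrr::map_dfr(gpos, function(g) {
    if (g < span[1] || g > span[2]) {
      stop("genomic position ", g, " outside gene span", call. = FALSE)
    }
    hit <- which(ex$gstart <= g & g <= ex$gend)
    if (length(hit) == 1L) {
      off_in <- if (model$strand == "+") g - ex$gstart[hit]
                else ex$gend[hit] - g
      return(tibble::tibble(gpos = g, tx_anchor = ex$tx_start[hit] + off_in,
                            offset = 0L, region = "exon",
                            exon = hit, intron = NA_integer_))
    }
    # intronic: find flanking exons in transcript order
    for (k in seq_len(nrow(ex) - 1L)) {
      bounds <- sort(c(
        if (model$strand == "+") c(ex$gend[k] + 1, ex$gstart[k + 1] - 1)
        else c(ex$gend[k + 1] + 1, ex$gstart[k] - 1)))
      if (g >= bounds[1] && g <= bounds[2]) {
        d_donor <- if (model$strand == "+") g - ex$gend[k]
                   else ex$gstart[k] - g
        d_accept <- if (model$strand == "+") ex$gstart[k + 1] - g
                    else g - ex$gend[k + 1]
        if (d_donor <= d_accept) {
          return(tibble::tibble(gpos = g, tx_anchor = ex$tx_end[k],
                                offset = as.integer(d_donor),
                                region = "intron", exon = k,
                                intron = k))
        } else {
          return(tibble::tibble(gpos = g, tx_anchor = ex$tx_start[k + 1],
                                offset = -as.integer(d_accept),
                                region = "intron", exon = k + 1L,
                                intron = k))
        }
      }
    }
    stop("genomic position ", g, " not located in gene model", call. = FALSE)
  })
}

#' Splice-site positions of a gene model
#'
#' The acceptor site of exon `k` is its first base in transcript sense; the
#' donor site is its last. Returned positions are genomic.
#'
#' @param model A [gene_model()].
#' @return A tibble with columns `exon`, `acceptor` (genomic position of the
#'   first exonic base; `NA` for exon 1 it is the transcription start),
#'   `donor` (last exonic base).
#' @export
splice_sites <- function(model) {
  ex <- model$exons
  if (model$strand == "+") {
    tibble::tibble(exon = ex$exon, acceptor = ex$gstart, donor = ex$gend)
  } else {
    tibble::tibble(exon = ex$exon, acceptor = ex$gend, donor = ex$gstart)
  }
}

intron_bounds <- function(model, intron) {
  ex <- model$exons
  stopifnot(intron >= 1, intron < nrow(ex))
  sort(c(
    if (model$strand == "+") c(ex$gend[intron] + 1, ex$gstart[intron + 1] - 1)
    else c(ex$gend[intron + 1] + 1, ex$gstart[intron] - 1)))
}

#' Spliced transcript sequence of an isoform
#'
#' @param model A [gene_model()].
#' @param ref A [ref_window()] covering the gene.
#' @param exons Integer vector of retained exon indices (transcript order).
#' @param trim5 Named integer vector: bases to trim from the 5' (transcript
#'   sense) end of given exons, e.g. `c("3" = 3)` for a cryptic acceptor 3 nt
#'   into exon 3.
#' @return Character string, 5' to 3' transcribed-strand sequence.
#' @export
spliced_sequence <- function(model, ref, exons = seq_len(n_exons(model)),
                             trim5 = c()) {
  ex <- model$exons
  pieces <- purrr::map_chr(exons, function(k) {
    s <- ref_fetch(ref, model$chrom, ex$gstart[k], ex$gend[k], model$strand)
    tr <- trim5[as.character(k)]
    if (length(tr) == 1L && !is.na(tr) && tr > 0) {
      s <- substr(s, tr + 1, nchar(s))
    }
    s
  })
  paste(pieces, collapse = "")
}
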