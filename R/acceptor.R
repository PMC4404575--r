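#' Acceptor-site windows and polypyrimidine-tract scoring
#'
#' An acceptor window is the transcribed-strand sequence covering positions
#' -20..+3 around an acceptor splice junction: 20 intronic bases (position -1
#' is the last intron base, expected G of the invariant AG) followed by the
#' first 3 exonic bases (+1..+3). The score is deliberately transparent: the
#' fraction of pyrimidines (C/T) across the tract positions -16..-5, gated to
#' zero unless AG is present at -2/-1. `N` counts as a purine. A single
#' pyrimidine-to-purine substitution in the tract therefore changes the score
#' by exactly -1/12.
#'
#' @name acceptor_scoring
NULL

ACC_WINDOW_POS <- c(-20:-1, 1:3)
ACC_TRACT_POS <- -16:-5

acc_index <- function(w) ifelse(w < 0, w + 21L, w + 20L)

#' Build the acceptor window of an internal exon
#'
#' @param model A [gene_model()].
#' @param ref A [ref_window()].
#' @param exon_idx Exon whose acceptor is windowed (>= 2).
#' @return A 23-character transcribed-strand string (positions -20..+3).
#' @export
acceptor_window <- function(model, ref, exon_idx) {
  stopifnot(exon_idx >= 2L, exon_idx <= n_exons(model))
  acc <- splice_sites(model)$acceptor[exon_idx]
  if (model$strand == "+") {
    ref_fetch(ref, model$chrom, acc - 20, acc + 2, "+")
  } else {
    ref_fetch(ref, model$chrom, acc - 2, acc + 20, "-")
  }
}

#' Score an acceptor window
#'
#' @param window A 23-nt transcribed-strand acceptor window (-20..+3), as a
#'   string or character vector of single bases.
#' @return Score in `[0, 1]`: pyrimidine fraction of tract positions -16..-5,
#'   multiplied by the AG gate at -2/-1.
#' @export
score_acceptor <- function(window) {
  b <- window_bases(window)
  tract <- b[acc_index(ACC_TRACT_POS)]
  pyr <- mean(tract %in% c("C", "T"))
  ag <- identical(paste0(b[acc_index(-2)], b[acc_index(-1)]), "AG")
  pyr * as.numeric(ag)
}

window_bases <- function(window) {
  b <- if (length(window) == 1L) strsplit(toupper(window), "")[[1]]
       else toupper(window)
  if (length(b) != 23L)
    stop("acceptor window must be 23 nt (-20..+3), got ", length(b),
         call. = FALSE)
  if (!all(b %in% c("A", "C", "G", "T", "N")))
    stop("acceptor window contains non-ACGTN characters", call. = FALSE)
  b
}

#' Effect of a variant on an acceptor site
#'
#' Locates the variant within the -20..+3 acceptor window of each internal
#' exon (strand-aware), builds the reference and alternate windows, scores
#' both, and flags the site as disrupted when the score drop reaches
#' `disrupt_threshold` or the invariant AG is lost. Variants outside every
#' acceptor window return an explicit not-applicable row.
#'
#' @param model A [gene_model()].
#' @param ref A [ref_window()].
#' @param variant One-row data frame `chrom`, `pos`, `ref`, `alt` (genomic
#'   plus strand, single nucleotide).
#' @param disrupt_threshold Minimum score drop flagged as disruptive
#'   (default 1/24, half a tract position).
#' @return A one-row tibble: `applicable`, `exon`, `window_pos` (-20..+3),
#'   `tract_position` (logical), `ref_score`, `alt_score`, `delta`,
#'   `ag_intact`, `disrupted`.
#' @export
variant_acceptor_delta <- function(model, ref, variant,
                                   disrupt_threshold = 1 / 24) {
  variant <- tibble::as_tibble(variant)
  stopifnot(nrow(variant) == 1L)
  na_row <- tibble::tibble(applicable = FALSE, exon = NA_integer_,
                           window_pos = NA_integer_, tract_position = NA,
                           ref_score = NA_real_, alt_score = NA_real_,
                           delta = NA_real_, ag_intact = NA,
                           disrupted = NA)
  if (!identical(variant$chrom, model$chrom) ||
      nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    return(na_row)
  }
  for (k in seq(2L, length.out = max(0L, n_exons(model) - 1L))) {
    acc <- splice_sites(model)$acceptor[k]
    w <- if (model$strand == "+") {
      d <- variant$pos - acc
      if (d >= -20 && d <= 2) { if (d < 0) d else d + 1L } else NA
    } else {
      d <- acc - variant$pos
      if (d >= -20 && d <= 2) { if (d < 0) d else d + 1L } else NA
    }
    if (is.na(w)) next
    win_ref <- window_bases(acceptor_window(model, ref, k))
    alt_tx <- if (model$strand == "+") toupper(variant$alt)
              else complement_base(toupper(variant$alt))
    ref_tx <- if (model$strand == "+") toupper(variant$ref)
              else complement_base(toupper(variant$ref))
    idx <- acc_index(w)
    if (win_ref[idx] != ref_tx)
      stop("variant ref allele does not match the acceptor window",
           call. = FALSE)
    win_alt <- win_ref
    win_alt[idx] <- alt_tx
    rs <- score_acceptor(win_ref); as_ <- score_acceptor(win_alt)
    ag <- identical(paste0(win_alt[acc_index(-2)], win_alt[acc_index(-1)]),
                    "AG")
    delta <- as_ - rs
    return(tibble::tibble(applicable = TRUE, exon = k,
                          window_pos = as.integer(w),
                          tract_position = w %in% ACC_TRACT_POS,
                          ref_score = rs, alt_score = as_, delta = delta,
                          ag_intact = ag,
                          disrupted = (delta <= -disrupt_threshold) || !ag))
  }
  na_row
}

#' Cross-species conservation of an alignment column
#'
#' Counts the species whose base matches the reference base at one column of
#' a multiple alignment. Gaps are excluded from the denominator by default
#' (set `gap_as_mismatch = TRUE` to count them against conservation).
#'
#' @param column Character vector of per-species bases (single characters;
#'   `-` or `.` are gaps).
#' @param reference_base The base to match (case-insensitive).
#' @param gap_as_mismatch Count gapped species in the total?
#' @return A one-row tibble: `matching`, `total`, `fraction`.
#' @export
conservation_fraction <- function(column, reference_base,
                                  gap_as_mismatch = FALSE) {
  if (length(column) == 0L) stop("empty alignment column", call. = FALSE)
  col <- toupper(column)
  gap <- col %in% c("-", ".")
  if (!gap_as_mismatch) col <- col[!gap]
  matching <- sum(col == toupper(reference_base))
  total <- length(col)
  tibble::tibble(matching = matching, total = total,
                 fraction = if (total > 0) matching / total else NA_real_)
}

#' Conservation of one position in an aligned FASTA
#'
#' @param alignment Path to an aligned FASTA (one record per species, equal
#'   lengths) or a named character vector of aligned sequences.
#' @param column 1-based alignment column.
#' @param reference_base Base to match; defaults to the first record's base.
#' @param ... Passed to [conservation_fraction()].
#' @return A one-row tibble as [conservation_fraction()].
#' @export
alignment_conservation <- function(alignment, column, reference_base = NULL,
                                   ...) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    ss <- Biostrings::readBStringSet(alignment)
    alignment <- stats::setNames(as.character(ss), names(ss))
  }
  bases <- substr(alignment, column, column)
  if (any(bases == ""))
    stop("column ", column, " beyond alignment length", call. = FALSE)
  if (is.null(reference_base)) reference_base <- bases[[1]]
  conservation_fraction(unname(bases), reference_base, ...)
}
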