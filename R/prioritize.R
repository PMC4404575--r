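#' Link DNA candidates to RNA splice events and rank them
#'
#' The decisive integrative step: each filter-cascade candidate is linked to
#' a detected splice event when it lies within `max_link_bp` of a splice site
#' (acceptor or donor) of the event's affected exon. Candidates are then
#' ranked lexicographically: (1) linked before unlinked; (2) acceptor-site
#' disruption before none; (3) smaller distance to the linked splice site;
#' (4) genomic position as the final deterministic tie-break.
#'
#' @param candidates Variant tibble (columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, ...), e.g. `filter_cascade(...)$candidates`.
#' @param events Event tibble from [detect_events()].
#' @param model A [gene_model()] (the gene carrying the events).
#' @param ref Optional [ref_window()]; enables the acceptor-disruption
#'   criterion via [variant_acceptor_delta()].
#' @param max_link_bp Maximum candidate-to-splice-site distance for a link.
#' @return A tibble of class `ranked_candidates`: the candidates augmented
#'   with `linked`, `linked_exon`, `dist_to_splice_site`, `acceptor_delta`,
#'   `disrupts_acceptor`, `rank`, sorted by rank.
#' @export
link_and_rank <- function(candidates, events, model, ref = NULL,
                          max_link_bp = 50) {
  candidates <- tibble::as_tibble(candidates)
  events <- tibble::as_tibble(events)
  affected <- unique(events$exon)
  ss <- splice_sites(model)
  site_pos <- ss[ss$exon %in% affected, c("acceptor", "donor")]
  sites <- unlist(site_pos, use.names = FALSE)
  site_exon <- rep(ss$exon[ss$exon %in% affected], times = 2L)

  refwin <- ref
  ann <- purrr::pmap_dfr(
    candidates[, c("chrom", "pos", "ref", "alt")],
    function(chrom, pos, ref, alt) {
      # positional matching only on the event gene's chromosome
      if (length(sites) == 0L || !identical(chrom, model$chrom)) {
        d <- NA_real_; ex <- NA_integer_
      } else {
        dd <- abs(sites - pos)
        d <- min(dd); ex <- site_exon[which.min(dd)]
      }
      linked <- !is.na(d) && d <= max_link_bp
      delta <- NA_real_; disrupts <- FALSE
      if (!is.null(refwin)) {
        vr <- variant_acceptor_delta(model, refwin,
                                     tibble::tibble(chrom = chrom, pos = pos,
                                                    ref = ref, alt = alt))
        if (isTRUE(vr$applicable)) {
          delta <- vr$delta
          disrupts <- isTRUE(vr$disrupted)
        }
      }
      tibble::tibble(linked = linked,
                     linked_exon = if (linked) ex else NA_integer_,
                     dist_to_splice_site = if (is.na(d)) NA_real_ else d,
                     acceptor_delta = delta, disrupts_acceptor = disrupts)
    }
  )
  out <- dplyr::bind_cols(candidates, ann)
  ord <- order(!out$linked, !out$disrupts_acceptor,
               ifelse(out$linked, out$dist_to_splice_site, Inf),
               out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("ranked_candidates", class(out))
  out
}

#' Protein consequence of skipping an exon
#'
#' Maps the coding nucleotides of a skipped exon onto the amino-acid interval
#' removed from the protein, with explicit codon-phase handling: a residue is
#' deleted when any of its codon's nucleotides lie in the skipped coding
#' interval. Reports whether the deletion is in frame (skipped coding length
#' divisible by 3), the remaining protein length, and the overlap of the
#' deleted interval with each annotated domain.
#'
#' @param model A [gene_model()].
#' @param skipped_exon Exon index whose coding bases are removed.
#' @param domains Data frame `domain`, `aa_start`, `aa_end` (e.g.
#'   [fixture_protein_domains()]).
#' @return An object of class `protein_effect`: list with `deleted_start`,
#'   `deleted_end`, `deleted_count`, `protein_length`, `remaining`,
#'   `in_frame`, `cds_nt_removed`, `overlaps` (tibble `domain`,
#'   `overlap_start`, `overlap_end`, `overlap_aa`).
#' @export
protein_effect <- function(model, skipped_exon, domains = NULL) {
  ex <- model$exons[skipped_exon, ]
  cds_lo_tx <- max(ex$tx_start, model$cds_start)
  cds_hi_tx <- min(ex$tx_end, model$cds_end)
  if (cds_lo_tx > cds_hi_tx)
    stop("exon ", skipped_exon, " carries no coding sequence", call. = FALSE)
  cds_lo <- cds_lo_tx - model$cds_start + 1L
  cds_hi <- cds_hi_tx - model$cds_start + 1L
  nt_removed <- cds_hi - cds_lo + 1L
  protein_length <- as.integer((model$cds_end - model$cds_start + 1L) / 3L -
                                 1L)   # minus the stop codon
  aa_lo <- as.integer(ceiling(cds_lo / 3))
  aa_hi <- as.integer(min(ceiling(cds_hi / 3), protein_length))
  deleted <- aa_hi - aa_lo + 1L
  in_frame <- nt_removed %% 3L == 0L
  remaining <- protein_length - deleted
  overlaps <- if (is.null(domains)) NULL
              else domain_overlaps(aa_lo, aa_hi, domains)
  structure(list(deleted_start = aa_lo, deleted_end = aa_hi,
                 deleted_count = deleted, protein_length = protein_length,
                 remaining = remaining, in_frame = in_frame,
                 cds_nt_removed = nt_removed, overlaps = overlaps),
            class = "protein_effect")
}

#' @export
print.protein_effect <- function(x, ...) {
  cat(sprintf(
    "<protein_effect> deletes aa %d-%d (%d aa) of %d; %d remain; %s\n",
    x$deleted_start, x$deleted_end, x$deleted_count, x$protein_length,
    x$remaining, if (x$in_frame) "in frame" else "frameshift"))
  if (!is.null(x$overlaps) && nrow(x$overlaps)) print(x$overlaps)
  invisible(x)
}

#' @rdname protein_effect
#' @param x A `protein_effect`.
#' @param ... Unused.
#' @export
tidy.protein_effect <- function(x, ...) {
  tibble::tibble(deleted_start = x$deleted_start, deleted_end = x$deleted_end,
                 deleted_count = x$deleted_count,
                 protein_length = x$protein_length, remaining = x$remaining,
                 in_frame = x$in_frame, cds_nt_removed = x$cds_nt_removed)
}

#' Intersect a deleted amino-acid range with a domain table
#'
#' @param deleted_start,deleted_end Deleted residue interval (inclusive).
#' @param domains Data frame `domain`, `aa_start`, `aa_end`.
#' @return Tibble `domain`, `overlap_start`, `overlap_end`, `overlap_aa`.
#' @export
domain_overlaps <- function(deleted_start, deleted_end, domains) {
  tibble::as_tibble(domains) |>
    dplyr::mutate(overlap_start = pmax(.data$aa_start, deleted_start),
                  overlap_end = pmin(.data$aa_end, deleted_end),
                  overlap_aa = pmax(0L, .data$overlap_end -
                                      .data$overlap_start + 1L)) |>
    dplyr::filter(.data$overlap_aa > 0) |>
    dplyr::select("domain", "overlap_start", "overlap_end", "overlap_aa")
}
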