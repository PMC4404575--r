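#' Find the shared homozygous segment among cases
#'
#' Autozygosity mapping of a recessive locus: returns the maximal run of
#' consecutive markers at which every case is homozygous *and* all cases are
#' homozygous for the same allele - the signature of a segment inherited
#' identical-by-descent through both parental paths. Missing genotypes are
#' treated as compatible with homozygosity, but a marker where every case is
#' missing does not qualify. Ties in run length are broken by the leftmost
#' start; the interval spans the outermost qualifying markers.
#'
#' @param cases A [genotype_matrix()] of the affected samples (or a larger
#'   matrix together with `sample_ids`).
#' @param chrom Chromosome to scan.
#' @param sample_ids Optional subset of sample ids to use as cases.
#' @return A one-row tibble `chrom`, `start`, `end`, `n_markers`, or a
#'   zero-row tibble of the same shape when no marker qualifies.
#' @export
find_shared_homozygous_segment <- function(cases, chrom = NULL,
                                           sample_ids = NULL) {
  stopifnot(inherits(cases, "genotype_matrix"))
  if (!is.null(sample_ids)) cases <- gm_subset(cases, sample_ids)
  if (is.null(chrom)) {
    chrom <- unique(cases$map$chrom)
    if (length(chrom) > 1L)
      stop("multiple chromosomes present; pass `chrom`", call. = FALSE)
  }
  on_chr <- cases$map$chrom == chrom
  if (!any(on_chr)) stop("no markers on chromosome ", chrom, call. = FALSE)
  g <- cases$geno[, on_chr, drop = FALSE]
  pos <- cases$map$pos[on_chr]

  ok <- unname(marker_shared_hom(g))
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_markers = integer(0))
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]   # which.max: leftmost on ties
  i0 <- starts[best]; i1 <- ends[best]
  tibble::tibble(chrom = chrom, start = pos[i0], end = pos[i1],
                 n_markers = i1 - i0 + 1L)
}

# Per-marker predicate: every case homozygous (missing compatible), at least
# one non-missing call, and all non-missing calls equal (shared allele).
marker_shared_hom <- function(g) {
  apply(g, 2L, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0L && all(obs %in% c(0L, 2L)) && length(unique(obs)) == 1L
  })
}

#' Case/control haplotype-sharing scan
#'
#' Slides a window of `window_size` consecutive markers along the chromosome.
#' A window is "case-shared" when every case is homozygous for one identical
#' window haplotype (unphased homozygous genotypes define the haplotype; a
#' missing call is compatible but at most `max_missing` of the cases' calls in
#' the window may be missing). For case-shared windows a one-sided Fisher
#' exact test compares the count of haplotype-homozygous cases (all of them,
#' by construction) against the count of controls homozygous for the same
#' window haplotype; other windows get p = 1. Significance is declared at a
#' Bonferroni-adjusted 0.05 over the number of windows.
#'
#' @param cases,controls [genotype_matrix()] objects sharing a marker set.
#' @param window_size Window width in markers.
#' @param chrom Chromosome to scan (default: the single chromosome present).
#' @param max_missing Maximum tolerated fraction of missing case calls per
#'   window.
#' @param alpha Family-wise error rate before Bonferroni adjustment.
#' @return An object of class `scan_result`: list with `track` (tibble
#'   `chrom`, `start`, `end`, `shared`, `control_hom`, `p`, `mlog10p`),
#'   `best` (top window row), `threshold` (Bonferroni p cutoff),
#'   `n_windows`, `significant` (logical).
#' @export
haplotype_sharing_scan <- function(cases, controls, window_size = 20,
                                   chrom = NULL, max_missing = 0.05,
                                   alpha = 0.05) {
  stopifnot(inherits(cases, "genotype_matrix"),
            inherits(controls, "genotype_matrix"))
  if (!identical(cases$map$marker_id, controls$map$marker_id))
    stop("cases and controls must share the same marker map", call. = FALSE)
  if (is.null(chrom)) {
    chrom <- unique(cases$map$chrom)
    if (length(chrom) > 1L)
      stop("multiple chromosomes present; pass `chrom`", call. = FALSE)
  }
  on_chr <- which(cases$map$chrom == chrom)
  m <- length(on_chr)
  if (window_size > m)
    stop("window_size (", window_size, ") exceeds the ", m,
         " markers on chromosome ", chrom, call. = FALSE)
  gc_ <- cases$geno[, on_chr, drop = FALSE]
  gk <- controls$geno[, on_chr, drop = FALSE]
  pos <- cases$map$pos[on_chr]
  n_case <- nrow(gc_); n_ctrl <- nrow(gk)
  n_win <- m - window_size + 1L

  track <- purrr::map_dfr(seq_len(n_win), function(w) {
    idx <- w:(w + window_size - 1L)
    gw <- gc_[, idx, drop = FALSE]
    miss_frac <- mean(is.na(gw))
    shared <- FALSE; ctrl_hom <- NA_integer_; p <- 1
    hom_ok <- all(gw %in% c(0L, 2L) | is.na(gw)) && miss_frac <= max_missing
    if (hom_ok) {
      # consensus haplotype: per-marker shared homozygous allele
      hap <- apply(gw, 2L, function(col) {
        obs <- unique(col[!is.na(col)])
        if (length(obs) == 1L) obs else NA_integer_
      })
      if (!anyNA(hap)) {
        shared <- TRUE
        kw <- gk[, idx, drop = FALSE]
        same <- sweep(kw, 2L, hap, `==`)
        ctrl_hom <- sum(apply(same, 1L, function(r) all(r %in% TRUE)))
        p <- stats::fisher.test(
          matrix(c(n_case, 0L, ctrl_hom, n_ctrl - ctrl_hom), nrow = 2),
          alternative = "greater")$p.value
      }
    }
    tibble::tibble(chrom = chrom, start = pos[w],
                   end = pos[w + window_size - 1L], shared = shared,
                   control_hom = ctrl_hom, p = p)
  })
  track$mlog10p <- -log10(pmax(track$p, 1e-300))
  threshold <- alpha / n_win
  best <- track[which.min(track$p), ]
  structure(list(track = track, best = best, threshold = threshold,
                 n_windows = n_win, window_size = window_size,
                 significant = best$p < threshold),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d windows of %d markers; best %s:%s-%s p=%.3g (%ssignificant at Bonferroni %0.3g)\n",
    x$n_windows, x$window_size, x$best$chrom,
    format(x$best$start, scientific = FALSE),
    format(x$best$end, scientific = FALSE), x$best$p,
    if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

#' @rdname haplotype_sharing_scan
#' @param x A `scan_result`.
#' @param ... Unused.
#' @export
tidy.scan_result <- function(x, ...) x$track

#' @rdname haplotype_sharing_scan
#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(n_windows = x$n_windows, window_size = x$window_size,
                 min_p = x$best$p, threshold = x$threshold,
                 significant = x$significant)
}

#' Manhattan-style plot of a haplotype-sharing scan
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_result <- function(object, ...) {
  tr <- object$track
  tr$mid <- (tr$start + tr$end) / 2
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$mid / 1e6, y = .data$mlog10p)) +
    ggplot2::geom_point(colour = "steelblue", size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = sprintf("position on %s (Mb)", tr$chrom[1]),
                  y = expression(-log[10](p)),
                  title = "Haplotype-sharing scan") +
    ggplot2::theme_minimal()
}

#' Interval length in megabases
#'
#' `(end - start) / 1e6`, rounded to one decimal - the convention used when
#' quoting mapped intervals such as "a 2.2 Mb region".
#'
#' @param interval A data frame with columns `start` and `end` (1-based
#'   inclusive bp), e.g. from [find_shared_homozygous_segment()].
#' @return Numeric vector of lengths in Mb (one decimal).
#' @export
interval_length_mb <- function(interval) {
  stopifnot(all(c("start", "end") %in% names(interval)),
            all(interval$start <= interval$end))
  round((interval$end - interval$start) / 1e6, 1)
}
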