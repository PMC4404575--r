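#' SNP-array genotype matrices
#'
#' Container for samples-by-markers genotypes coded as alt-allele counts
#' (0/1/2, `NA` for missing) together with a marker map. Markers must be
#' sorted by (chrom, pos). The container is a light S3 wrapper around an
#' integer matrix so that window scans stay vectorised; [tidy.genotype_matrix()]
#' converts to a long tibble.
#'
#' @param geno Integer matrix, samples in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids), values 0/1/2/`NA`.
#' @param map Data frame with columns `marker_id`, `chrom`, `pos` (1-based
#'   bp), `ref`, `alt`, one row per column of `geno`, same order.
#' @param samples Optional data frame with columns `sample_id`, `role`;
#'   defaults to role `"unknown"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, samples = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- tibble::as_tibble(map)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(map)),
            ncol(geno) == nrow(map))
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("sample", seq_len(nrow(geno)))
  colnames(geno) <- map$marker_id
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, ]
    geno <- geno[, ord, drop = FALSE]
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = rownames(geno), role = "unknown")
  } else {
    samples <- tibble::as_tibble(samples)
    stopifnot(all(rownames(geno) %in% samples$sample_id))
    samples <- samples[match(rownames(geno), samples$sample_id), ]
  }
  structure(list(geno = geno, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d markers (%s)\n",
              nrow(x$geno), ncol(x$geno),
              paste(unique(x$map$chrom), collapse = ", ")))
  print(utils::head(x$samples))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sample ids
#'
#' @param gm A [genotype_matrix()].
#' @param sample_ids Character vector of sample ids to keep.
#' @return A [genotype_matrix()].
#' @export
gm_subset <- function(gm, sample_ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_ids <- setdiff(sample_ids, rownames(gm$geno))
  if (length(missing_ids))
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  genotype_matrix(gm$geno[sample_ids, , drop = FALSE], gm$map,
                  gm$samples[gm$samples$sample_id %in% sample_ids, ])
}

#' Tidy a genotype matrix into a long tibble
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `role`, `marker_id`, `chrom`,
#'   `pos`, `genotype`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$geno, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "marker_id",
                        values_to = "genotype")
  long |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::left_join(x$map[, c("marker_id", "chrom", "pos")],
                     by = "marker_id") |>
    dplyr::select("sample_id", "role", "marker_id", "chrom", "pos",
                  "genotype")
}

#' Build a genotype matrix from a long tibble
#'
#' Inverse of [tidy.genotype_matrix()].
#'
#' @param x A data frame with columns `sample_id`, `marker_id`, `chrom`,
#'   `pos`, `genotype` (and optionally `role`, `ref`, `alt`).
#' @return A [genotype_matrix()].
#' @export
as_genotype_matrix <- function(x) {
  x <- tibble::as_tibble(x)
  map_cols <- intersect(c("marker_id", "chrom", "pos", "ref", "alt"),
                        names(x))
  map <- dplyr::distinct(x[, map_cols]) |> dplyr::arrange(.data$chrom,
                                                          .data$pos)
  wide <- x |>
    dplyr::select("sample_id", "marker_id", "genotype") |>
    tidyr::pivot_wider(names_from = "marker_id", values_from = "genotype")
  geno <- as.matrix(wide[, map$marker_id, drop = FALSE])
  rownames(geno) <- wide$sample_id
  samples <- if ("role" %in% names(x)) {
    dplyr::distinct(x[, c("sample_id", "role")])
  } else NULL
  genotype_matrix(geno, map, samples)
}
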