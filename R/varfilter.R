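#' Candidate-variant filter cascade
#'
#' Applies, in order, the five filters that reduce a resequencing callset to
#' candidate recessive mutations: (1) inside the mapped interval; (2) quality
#' strictly above `qual_min`; (3) homozygous for the alternate allele in every
#' case; (4) alternate allele absent from every control genotype (het or
#' hom); (5) not present in the known-variant catalog (matched on
#' chrom+pos+ref+alt, so a novel allele at a known site is kept). Stage
#' counts are monotone non-increasing and the final set is invariant under
#' permutation of stages 2-5.
#'
#' A missing case genotype fails stage 3 (an explicit hom-alt call is
#' required); a missing control genotype is not an observation of the allele
#' and passes stage 4.
#'
#' @param variants Variant tibble: columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qual`, optionally `in_catalog`, plus one integer genotype column
#'   (0/1/2/NA alt-allele count) per sample.
#' @param interval One-row data frame `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param case_ids,control_ids Sample column names.
#' @param known_catalog Optional catalog: data frame with columns `chrom`,
#'   `pos`, `ref`, `alt`; overrides any `in_catalog` column.
#' @param qual_min Strict lower quality bound (variants with
#'   `qual == qual_min` are removed).
#' @return An object of class `filter_report`: list with `stages` (tibble
#'   `stage`, `n`) and `candidates` (the surviving variant rows).
#' @export
filter_cascade <- function(variants, interval, case_ids, control_ids,
                           known_catalog = NULL, qual_min = 100) {
  variants <- tibble::as_tibble(variants)
  missing_samp <- setdiff(c(case_ids, control_ids), names(variants))
  if (length(missing_samp))
    stop("unknown sample id(s): ", paste(missing_samp, collapse = ", "),
         call. = FALSE)
  variants <- split_multiallelic(variants)

  in_cat <- catalog_membership(variants, known_catalog)

  stage_names <- c("input", "in_interval", paste0("qual_gt_", qual_min),
                   "hom_alt_all_cases", "absent_in_controls",
                   "not_in_catalog")
  n <- integer(6); n[1] <- nrow(variants)

  v <- variants[variants$chrom == interval$chrom &
                  variants$pos >= interval$start &
                  variants$pos <= interval$end, , drop = FALSE]
  in_cat <- in_cat[variants$chrom == interval$chrom &
                     variants$pos >= interval$start &
                     variants$pos <= interval$end]
  n[2] <- nrow(v)

  keep <- v$qual > qual_min
  v <- v[keep, , drop = FALSE]; in_cat <- in_cat[keep]
  n[3] <- nrow(v)

  case_gt <- as.matrix(v[, case_ids, drop = FALSE])
  keep <- nrow(v) > 0 & apply(case_gt == 2L, 1L, function(r) all(r %in% TRUE))
  if (nrow(v) == 0) keep <- logical(0)
  v <- v[keep, , drop = FALSE]; in_cat <- in_cat[keep]
  n[4] <- nrow(v)

  ctrl_gt <- as.matrix(v[, control_ids, drop = FALSE])
  keep <- apply(ctrl_gt, 1L, function(r) !any(r >= 1L, na.rm = TRUE))
  if (nrow(v) == 0) keep <- logical(0)
  v <- v[keep, , drop = FALSE]; in_cat <- in_cat[keep]
  n[5] <- nrow(v)

  v <- v[!in_cat, , drop = FALSE]
  n[6] <- nrow(v)

  structure(list(stages = tibble::tibble(stage = stage_names, n = n),
                 candidates = v),
            class = "filter_report")
}

catalog_membership <- function(variants, known_catalog) {
  if (!is.null(known_catalog)) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
    key(variants) %in% key(tibble::as_tibble(known_catalog))
  } else if ("in_catalog" %in% names(variants)) {
    variants$in_catalog %in% TRUE
  } else {
    rep(FALSE, nrow(variants))
  }
}

#' Split multi-allelic variant records
#'
#' Records whose `alt` holds comma-separated alleles are expanded into one
#' biallelic record per alternate allele; genotype columns are not
#' re-interpreted (codes refer to "an alt allele") and are copied.
#'
#' @param variants Variant tibble.
#' @return Variant tibble with one alt allele per row.
#' @export
split_multiallelic <- function(variants) {
  if (!any(grepl(",", variants$alt, fixed = TRUE))) return(variants)
  tidyr::separate_rows(variants, "alt", sep = ",")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stages)
  invisible(x)
}

#' @rdname filter_cascade
#' @param x A `filter_report`.
#' @param ... Unused.
#' @export
tidy.filter_report <- function(x, ...) x$stages

#' @rdname filter_cascade
#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(n_input = x$stages$n[1],
                 n_candidates = utils::tail(x$stages$n, 1))
}

#' Classify the consequence of a single-nucleotide variant
#'
#' Exonic coding variants are classified by codon comparison into missense /
#' nonsense / synonymous; exonic non-coding positions are `utr`. Non-exonic
#' variants inside the gene get a signed distance to the nearest exon-intron
#' junction (intronic side negative); intronic variants within 3 bp of a
#' junction are `canonical_splice_region`. Positions outside the gene span
#' are `intergenic`. Alleles longer than 1 nt fall outside this SNV taxonomy
#' and are reported as class `indel`.
#'
#' @param variant One-row data frame `chrom`, `pos`, `ref`, `alt` (genomic
#'   plus strand).
#' @param model A [gene_model()].
#' @param ref A [ref_window()] covering the gene (needed for codon
#'   comparison of coding variants).
#' @param splice_region_bp Junction distance defining the canonical splice
#'   region (default 3).
#' @return A one-row tibble: `class`, `distance_to_junction` (signed bp,
#'   `NA` when not applicable), `exon` (affected/nearest exon index or `NA`),
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`.
#' @export
classify_consequence <- function(variant, model, ref = NULL,
                                 splice_region_bp = 3) {
  variant <- tibble::as_tibble(variant)
  stopifnot(nrow(variant) == 1L)
  out <- tibble::tibble(class = NA_character_,
                        distance_to_junction = NA_integer_,
                        exon = NA_integer_,
                        codon_ref = NA_character_, codon_alt = NA_character_,
                        aa_ref = NA_character_, aa_alt = NA_character_)
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    out$class <- "indel"
    return(out)
  }
  if (!identical(variant$chrom, model$chrom)) {
    out$class <- "intergenic"
    return(out)
  }
  span <- gene_span(model)
  if (variant$pos < span[1] || variant$pos > span[2]) {
    out$class <- "intergenic"
    return(out)
  }
  loc <- genomic_to_tx(model, variant$pos)
  if (loc$region == "intron") {
    out$distance_to_junction <- -abs(loc$offset)
    out$exon <- loc$exon
    out$class <- if (abs(loc$offset) <= splice_region_bp)
      "canonical_splice_region" else "intronic"
    return(out)
  }
  # exonic
  ex <- model$exons[loc$exon, ]
  out$exon <- loc$exon
  out$distance_to_junction <-
    as.integer(min(loc$tx_anchor - ex$tx_start, ex$tx_end - loc$tx_anchor))
  if (loc$tx_anchor < model$cds_start || loc$tx_anchor > model$cds_end) {
    out$class <- "utr"
    return(out)
  }
  if (is.null(ref))
    stop("a ref_window is required to classify coding variants",
         call. = FALSE)
  cds_pos <- loc$tx_anchor - model$cds_start + 1L
  codon_idx <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon_tx0 <- model$cds_start + codon_idx * 3L
  codon_ref <- paste0(vapply(codon_tx0 + 0:2, function(tp) {
    g <- tx_to_genomic(model, tp)
    ref_base(ref, model$chrom, g, model$strand)
  }, character(1)), collapse = "")
  # variant alleles are plus-strand; convert to transcribed strand
  alt_tx <- if (model$strand == "+") variant$alt
            else complement_base(variant$alt)
  ref_tx <- if (model$strand == "+") variant$ref
            else complement_base(variant$ref)
  if (substr(codon_ref, within, within) != ref_tx)
    stop("variant ref allele does not match the reference sequence",
         call. = FALSE)
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_tx
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon_ref)))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(codon_alt)))
  out$codon_ref <- codon_ref; out$codon_alt <- codon_alt
  out$aa_ref <- aa_ref; out$aa_alt <- aa_alt
  out$class <- if (aa_ref == aa_alt) "synonymous"
               else if (aa_alt == "*") "nonsense"
               else "missense"
  out
}

#' Parse an HGVS-style c. designation against a gene model
#'
#' Accepts `c.<pos><ref>><alt>` and the intronic forms
#' `c.<pos>+<k><ref>><alt>` / `c.<pos>-<k><ref>><alt>` (the dot may be
#' omitted, tolerating designations as printed in genotyping-assay reports).
#' Positions are transcript coordinates (1-based along the spliced
#' transcript); the intronic offset counts bases into the adjoining intron.
#' Given a gene model, the anchor is resolved to a strand-corrected genomic
#' position.
#'
#' @param notation A single designation, e.g. `"c.211-10C>G"`.
#' @param model Optional [gene_model()] to resolve genomic coordinates.
#' @return A one-row tibble: `tx_pos`, `offset`, `ref`, `alt` (transcribed
#'   strand), and - with a model - `chrom`, `gpos`, `gref`, `galt` (genomic
#'   plus strand), `region` (`"exon"`/`"intron"`), `exon` (anchored exon),
#'   `acceptor_offset` (bp upstream of the anchored exon's acceptor for
#'   intronic acceptor-side anchors, else `NA`).
#' @export
parse_hgvs_c <- function(notation, model = NULL) {
  stopifnot(is.character(notation), length(notation) == 1L)
  m <- regmatches(notation,
                  regexec("^c\\.?(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$",
                          notation))[[1]]
  if (length(m) == 0L)
    stop("malformed c. designation: ", notation, call. = FALSE)
  tx_pos <- as.integer(m[2])
  offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  out <- tibble::tibble(tx_pos = tx_pos, offset = offset,
                        ref = m[4], alt = m[5])
  if (is.null(model)) return(out)

  if (tx_pos < 1L || tx_pos > model$tx_len)
    stop("anchor position ", tx_pos, " outside the ", model$tx_len,
         "-nt transcript", call. = FALSE)
  ex <- model$exons
  k <- findInterval(tx_pos, ex$tx_start)
  if (offset > 0L) {
    if (tx_pos != ex$tx_end[k])
      stop("'+' offset must anchor at an exon's last base", call. = FALSE)
    if (k == nrow(ex)) stop("no intron downstream of the last exon",
                            call. = FALSE)
    intron_len <- abs(ex$gstart[k + 1] - ex$gend[k]) - 1L
    if (model$strand == "-")
      intron_len <- ex$gstart[k] - ex$gend[k + 1] - 1L
    if (offset > intron_len)
      stop("offset +", offset, " walks out of intron ", k, call. = FALSE)
    g_anchor <- tx_to_genomic(model, tx_pos)
    gpos <- if (model$strand == "+") g_anchor + offset else g_anchor - offset
    region <- "intron"; acceptor_offset <- NA_integer_
  } else if (offset < 0L) {
    if (tx_pos != ex$tx_start[k])
      stop("'-' offset must anchor at an exon's first base", call. = FALSE)
    if (k == 1L) stop("no intron upstream of the first exon", call. = FALSE)
    intron_len <- if (model$strand == "+")
      ex$gstart[k] - ex$gend[k - 1] - 1L
    else ex$gstart[k - 1] - ex$gend[k] - 1L
    if (-offset > intron_len)
      stop("offset ", offset, " walks out of intron ", k - 1L, call. = FALSE)
    g_anchor <- tx_to_genomic(model, tx_pos)
    gpos <- if (model$strand == "+") g_anchor + offset else g_anchor - offset
    region <- "intron"; acceptor_offset <- -offset
  } else {
    gpos <- tx_to_genomic(model, tx_pos)
    region <- "exon"; acceptor_offset <- NA_integer_
  }
  gref <- if (model$strand == "+") out$ref else complement_base(out$ref)
  galt <- if (model$strand == "+") out$alt else complement_base(out$alt)
  dplyr::bind_cols(out,
                   tibble::tibble(chrom = model$chrom, gpos = gpos,
                                  gref = gref, galt = galt, region = region,
                                  exon = k,
                                  acceptor_offset = acceptor_offset))
}

#' Genomic position to c.-style designation
#'
#' Inverse of [parse_hgvs_c()] for positions inside the gene span: exonic
#' positions become `c.<tx>`, intronic positions `c.<anchor>+<k>` or
#' `c.<anchor>-<k>` anchored at the nearest exonic base.
#'
#' @param model A [gene_model()].
#' @param gpos Genomic position.
#' @param gref,galt Plus-strand alleles.
#' @return A c. designation string.
#' @export
format_hgvs_c <- function(model, gpos, gref, galt) {
  loc <- genomic_to_tx(model, gpos)
  ref_tx <- if (model$strand == "+") gref else complement_base(gref)
  alt_tx <- if (model$strand == "+") galt else complement_base(galt)
  anchor <- if (loc$offset == 0L) as.character(loc$tx_anchor)
            else sprintf("%d%+d", loc$tx_anchor, loc$offset)
  sprintf("c.%s%s>%s", anchor, ref_tx, alt_tx)
}
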