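#' Genotype TSV dialect
#'
#' Two files: a genotype table (first column `sample_id`, then one 0/1/2/NA
#' column per marker) and a marker map (`marker_id`, `chrom`, `pos`, `ref`,
#' `alt`), both tab-separated.
#'
#' @param gm A [genotype_matrix()].
#' @param geno_path,map_path Output paths.
#' @return `read_genotype_tsv()` returns a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(gm, geno_path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tbl <- tibble::as_tibble(gm$geno, rownames = "sample_id")
  tbl <- dplyr::bind_cols(tbl[, "sample_id"], role = gm$samples$role,
                          tbl[, -1])
  readr::write_tsv(tbl, geno_path)
  readr::write_tsv(gm$map, map_path)
  invisible(c(geno_path, map_path))
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(geno_path, map_path) {
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c"))
  tbl <- readr::read_tsv(geno_path, show_col_types = FALSE)
  samples <- tibble::tibble(sample_id = tbl$sample_id,
                            role = if ("role" %in% names(tbl)) tbl$role
                                   else "unknown")
  geno <- as.matrix(tbl[, map$marker_id, drop = FALSE])
  rownames(geno) <- tbl$sample_id
  genotype_matrix(geno, map, samples)
}

#' Read PLINK-style text genotypes
#'
#' Minimal `.ped`/`.map` reader: the `.map` gives chrom, marker id, (cM),
#' bp position; the `.ped` gives family/id/father/mother/sex/phenotype then
#' two allele columns per marker (`0` = missing). Genotypes are recoded as
#' counts of the marker's lexicographically larger allele.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chrom", "marker_id", "cm",
                                             "pos"),
                               colClasses = c("character", "character",
                                              "numeric", "numeric"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  n_mark <- nrow(map_raw)
  stopifnot(ncol(ped) == 6 + 2 * n_mark)
  ids <- ped[[2]]
  geno <- matrix(NA_integer_, nrow(ped), n_mark)
  alt_alleles <- character(n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- ped[[6 + 2 * j - 1]]; a2 <- ped[[6 + 2 * j]]
    obs <- setdiff(sort(unique(c(a1, a2))), "0")
    if (length(obs) > 2)
      stop("marker ", map_raw$marker_id[j], " has >2 alleles", call. = FALSE)
    alt <- if (length(obs)) obs[length(obs)] else NA_character_
    alt_alleles[j] <- alt
    miss <- a1 == "0" | a2 == "0"
    geno[, j] <- ifelse(miss, NA_integer_,
                        (a1 == alt) + (a2 == alt))
  }
  rownames(geno) <- ids
  map <- tibble::tibble(marker_id = map_raw$marker_id,
                        chrom = map_raw$chrom, pos = map_raw$pos,
                        ref = NA_character_, alt = alt_alleles)
  genotype_matrix(geno, map)
}

#' Write and read variant tables as VCF 4.2
#'
#' The writer emits one record per variant with per-sample `GT` calls
#' (`0/0`, `0/1`, `1/1`, `./.`) and flags known-catalog members with `KC` in
#' INFO. The reader (via vcfR) recodes genotypes as alt-allele counts and
#' splits multi-allelic records.
#'
#' @param variants Variant tibble (see [filter_cascade()]).
#' @param path File path.
#' @param sample_ids Genotype columns to write; defaults to every column
#'   after the core ones.
#' @return `read_vcf()` returns a variant tibble.
#' @export
write_vcf <- function(variants, path, sample_ids = NULL) {
  variants <- tibble::as_tibble(variants)
  core <- c("chrom", "pos", "id", "ref", "alt", "qual", "in_catalog")
  if (is.null(sample_ids)) sample_ids <- setdiff(names(variants), core)
  gt_str <- function(code) {
    dplyr::case_when(is.na(code) ~ "./.", code == 0 ~ "0/0",
                     code == 1 ~ "0/1", code == 2 ~ "1/1")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=splicemapr",
    "##INFO=<ID=KC,Number=0,Type=Flag,Description=\"Known catalog member\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  info <- if ("in_catalog" %in% names(variants)) {
    ifelse(variants$in_catalog %in% TRUE, "KC", ".")
  } else rep(".", nrow(variants))
  body_cols <- c(list(variants$chrom,
                      format(variants$pos, scientific = FALSE, trim = TRUE),
                      variants$id, variants$ref, variants$alt,
                      format(variants$qual, trim = TRUE), rep("PASS", nrow(variants)),
                      info, rep("GT", nrow(variants))),
                 lapply(sample_ids, function(s) gt_str(variants[[s]])))
  body <- do.call(paste, c(body_cols, sep = "\t"))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  out <- tibble::tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    in_catalog = grepl("(^|;)KC($|;)", fix$INFO %||% "."))
  if (ncol(v@gt) > 1) {
    gtm <- vcfR::extract.gt(v, element = "GT")
    codes <- apply(gtm, 2L, function(col) {
      vapply(col, function(g) {
        if (is.na(g) || g %in% c("./.", ".")) return(NA_integer_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
      }, integer(1))
    })
    codes <- matrix(codes, nrow = nrow(out),
                    dimnames = list(NULL, colnames(gtm)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(codes))
  }
  split_multiallelic(out)
}

#' Write and read gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (via rtracklayer); the reader
#' rebuilds a [gene_model()], normalising exons to transcript order (for a
#' minus-strand gene, descending genomic coordinates).
#'
#' @param model A [gene_model()].
#' @param path File path.
#' @return `read_gff3()` returns a [gene_model()].
#' @export
write_gff3 <- function(model, path) {
  ex <- model$exons
  span <- gene_span(model)
  cds <- cds_genomic_pieces(model)
  gid <- model$gene_id
  tid <- paste0(gid, ".t1")
  feats <- dplyr::bind_rows(
    tibble::tibble(start = span[1], end = span[2], type = "gene",
                   ID = gid, Parent = NA_character_),
    tibble::tibble(start = span[1], end = span[2], type = "mRNA",
                   ID = tid, Parent = gid),
    tibble::tibble(start = ex$gstart, end = ex$gend, type = "exon",
                   ID = sprintf("%s.exon%d", tid, ex$exon), Parent = tid),
    tibble::tibble(start = cds$gstart, end = cds$gend, type = "CDS",
                   ID = paste0(tid, ".cds"), Parent = tid)
  )
  gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = model$strand)
  gr$type <- feats$type
  gr$ID <- feats$ID
  gr$Parent <- ifelse(is.na(feats$Parent), "", feats$Parent)
  gr$phase <- c(rep(NA_integer_, nrow(feats) - nrow(cds)), cds$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Genomic spans of the coding pieces of each exon, with GFF phase.
cds_genomic_pieces <- function(model) {
  ex <- model$exons
  pieces <- list()
  cds_done <- 0L
  for (k in seq_len(nrow(ex))) {
    lo <- max(ex$tx_start[k], model$cds_start)
    hi <- min(ex$tx_end[k], model$cds_end)
    if (lo > hi) next
    g1 <- tx_to_genomic(model, lo); g2 <- tx_to_genomic(model, hi)
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      exon = k, gstart = min(g1, g2), gend = max(g1, g2),
      phase = (3L - cds_done %% 3L) %% 3L)
    cds_done <- cds_done + (hi - lo + 1L)
  }
  dplyr::bind_rows(pieces)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path, call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  strand <- as.character(GenomicRanges::strand(ex))[1]
  if (!strand %in% c("+", "-"))
    stop("gene model must be stranded", call. = FALSE)
  exons <- tibble::tibble(gstart = GenomicRanges::start(ex),
                          gend = GenomicRanges::end(ex))
  exons <- exons[order(exons$gstart, decreasing = (strand == "-")), ]
  gene_id <- {
    g <- gr[gr$type == "gene"]
    if (length(g) && !is.null(g$ID)) g$ID[1] else "gene1"
  }
  cds <- gr[gr$type == "CDS"]
  model0 <- gene_model(gene_id, chrom, strand, exons,
                       cds_start = 1L, cds_end = 3L)  # placeholder CDS
  if (length(cds) == 0L) return(model0)
  cds_g <- c(GenomicRanges::start(cds), GenomicRanges::end(cds))
  cds_tx <- genomic_to_tx(model0, cds_g)$tx_anchor
  gene_model(gene_id, chrom, strand, exons,
             cds_start = min(cds_tx), cds_end = max(cds_tx))
}

#' Junction, assay and catalog TSV dialects
#'
#' Junction tables: `chrom`, `donor_end`, `acceptor_start`, `sample`,
#' `count` (1-based inclusive flanking exonic bases). Assay tables: `id`,
#' `role`, `genotype`. Catalogs: `chrom`, `pos`, `ref`, `alt`.
#'
#' @param junctions,table,catalog Tibbles in the respective dialect.
#' @param path File path.
#' @return Readers return the corresponding tibble.
#' @export
write_junction_tsv <- function(junctions, path) {
  readr::write_tsv(junctions[, c("chrom", "donor_end", "acceptor_start",
                                 "sample", "count")], path)
  invisible(path)
}

#' @rdname write_junction_tsv
#' @export
read_junction_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", sample = "c")) |>
    dplyr::select("sample", "chrom", "donor_end", "acceptor_start",
                  "count")
}

#' @rdname write_junction_tsv
#' @export
write_assay_tsv <- function(table, path) {
  readr::write_tsv(validate_assay_table(table), path)
  invisible(path)
}

#' @rdname write_junction_tsv
#' @export
read_assay_tsv <- function(path) {
  validate_assay_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname write_junction_tsv
#' @export
read_catalog_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c"))
}

#' Minimal SAM text I/O
#'
#' The dialect carries only what junction extraction needs: `@` header
#' lines, then QNAME/FLAG/RNAME/POS/MAPQ/CIGAR and star placeholders.
#'
#' @param path SAM file path.
#' @return `read_sam()` returns a tibble `qname`, `flag`, `rname`, `pos`,
#'   `cigar`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(tibble::tibble(qname = character(0), flag = integer(0),
                          rname = character(0), pos = numeric(0),
                          cigar = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop("malformed SAM line ", bad[1], " in ", path, call. = FALSE)
  tibble::tibble(qname = vapply(fields, `[[`, "", 1L),
                 flag = as.integer(vapply(fields, `[[`, "", 2L)),
                 rname = vapply(fields, `[[`, "", 3L),
                 pos = as.numeric(vapply(fields, `[[`, "", 4L)),
                 cigar = vapply(fields, `[[`, "", 6L))
}

#' Emit gapped reads supporting a junction table
#'
#' Writes one SAM alignment per junction read: 20 nt anchors flanking a
#' single `N` gap spanning the intron, so `extract_junctions()` recovers the
#' input table exactly.
#'
#' @param junctions Junction tibble.
#' @param path Output SAM path.
#' @param anchor Anchor length on each side of the gap.
#' @param ref_len Declared reference length for the `@SQ` line.
#' @return `path`, invisibly.
#' @export
write_junction_sam <- function(junctions, path, anchor = 20,
                               ref_len = NULL) {
  chroms <- unique(junctions$chrom)
  if (is.null(ref_len))
    ref_len <- max(junctions$acceptor_start) + anchor + 1000
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, round(ref_len)))
  rows <- junctions[rep(seq_len(nrow(junctions)), junctions$count), ]
  gap <- rows$acceptor_start - rows$donor_end - 1
  body <- sprintf("%s\t0\t%s\t%s\t60\t%dM%dN%dM\t*\t0\t0\t*\t*",
                  sprintf("r%06d_%s", seq_len(nrow(rows)), rows$sample),
                  rows$chrom,
                  format(rows$donor_end - anchor + 1, scientific = FALSE,
                         trim = TRUE),
                  anchor, as.integer(gap), anchor)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Convert a 1-based interval to BED and write it
#'
#' BED is 0-based half-open: a 1-based inclusive interval `start..end`
#' becomes `start-1, end`.
#'
#' @param interval Data frame `chrom`, `start`, `end` (1-based inclusive).
#' @param path Optional path; when given, a BED file is written.
#' @return A tibble `chrom`, `bed_start`, `bed_end` (0-based half-open).
#' @export
interval_to_bed <- function(interval, path = NULL) {
  bed <- tibble::tibble(chrom = interval$chrom,
                        bed_start = interval$start - 1,
                        bed_end = interval$end)
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  bed
}

`%||%` <- function(a, b) if (is.null(a)) b else a
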