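#' Extract splice junctions from gapped alignments
#'
#' Walks each alignment's CIGAR from its POS: every `N` gap whose flanking
#' aligned segments (M/=/X run immediately on each side of the gap) are at
#' least `anchor_min` nt long contributes one count to the junction whose
#' flanking exonic bases are the reference base before and after the gap.
#' Reads without an `N` operation contribute nothing.
#'
#' @param x Either a path to a SAM file (minimal dialect: tab-separated, POS
#'   and CIGAR columns used; `@` header lines skipped), or a data frame of
#'   alignments with columns `rname`, `pos`, `cigar` (and optionally
#'   `sample`).
#' @param sample Sample id to assign when the input has no `sample` column.
#' @param anchor_min Minimum aligned anchor on both sides of a gap.
#' @return A junction tibble: `sample`, `chrom`, `donor_end`,
#'   `acceptor_start`, `count`.
#' @export
extract_junctions <- function(x, sample = "sample1", anchor_min = 8) {
  if (is.character(x) && length(x) == 1L) x <- read_sam(x)
  x <- tibble::as_tibble(x)
  stopifnot(all(c("rname", "pos", "cigar") %in% names(x)))
  if (!"sample" %in% names(x)) x$sample <- sample
  jl <- purrr::pmap_dfr(x[, c("rname", "pos", "cigar", "sample")],
                        function(rname, pos, cigar, sample) {
    j <- cigar_junctions(pos, cigar, anchor_min)
    if (nrow(j) == 0L) return(j)
    tibble::tibble(sample = sample, chrom = rname,
                   donor_end = j$donor_end,
                   acceptor_start = j$acceptor_start)
  })
  if (nrow(jl) == 0L) {
    return(tibble::tibble(sample = character(0), chrom = character(0),
                          donor_end = numeric(0), acceptor_start = numeric(0),
                          count = integer(0)))
  }
  jl |>
    dplyr::count(.data$sample, .data$chrom, .data$donor_end,
                 .data$acceptor_start, name = "count") |>
    dplyr::arrange(.data$sample, .data$chrom, .data$donor_end,
                   .data$acceptor_start)
}

# Junctions of one alignment: reference positions flanking each N gap,
# subject to the anchor filter.
cigar_junctions <- function(pos, cigar, anchor_min = 8) {
  ops <- parse_cigar(cigar)
  refpos <- pos
  out <- list()
  aligned_run <- 0
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      aligned_run <- aligned_run + len
      refpos <- refpos + len
    } else if (op == "D") {
      refpos <- refpos + len
    } else if (op == "N") {
      left_anchor <- aligned_run
      right_anchor <- aligned_after(ops, i)
      if (left_anchor >= anchor_min && right_anchor >= anchor_min) {
        out[[length(out) + 1L]] <-
          tibble::tibble(donor_end = refpos - 1, acceptor_start = refpos + len)
      }
      refpos <- refpos + len
      aligned_run <- 0
    } else if (!op %in% c("I", "S", "H", "P")) {
      stop("malformed CIGAR operation '", op, "' in ", cigar, call. = FALSE)
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(donor_end = numeric(0), acceptor_start = numeric(0)))
  dplyr::bind_rows(out)
}

aligned_after <- function(ops, i) {
  run <- 0
  for (j in seq(i + 1L, length.out = nrow(ops) - i)) {
    if (ops$op[j] %in% c("M", "=", "X")) run <- run + ops$len[j]
    else if (ops$op[j] == "N") break
  }
  run
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(tibble::tibble(op = character(0), len = integer(0)))
  toks <- regmatches(cigar, gregexpr("\\d+[A-Za-z=]", cigar))[[1]]
  if (!nzchar(cigar) || paste(toks, collapse = "") != cigar)
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  tibble::tibble(op = substr(toks, nchar(toks), nchar(toks)),
                 len = as.integer(substr(toks, 1, nchar(toks) - 1L)))
}

lookup_count <- function(junctions, sample, donor_end, acceptor_start) {
  hit <- junctions$sample == sample &
    junctions$donor_end == donor_end &
    junctions$acceptor_start == acceptor_start
  if (!any(hit)) 0L else sum(junctions$count[hit])
}

#' Percent-spliced-in of an internal exon
#'
#' PSI = inclusion / (inclusion + skip). The inclusion count is the average
#' of the two flanking inclusion junctions (upstream-exon to exon, exon to
#' downstream-exon), rounded half up, which avoids double counting each
#' included transcript's two junctions. The skip count sums junctions joining
#' the two neighbouring exons directly, including acceptor-shifted variants
#' of that skip junction within `max_shift` nt (cryptic-acceptor skip
#' isoforms also omit the exon).
#'
#' @param junctions Junction tibble (see [extract_junctions()]).
#' @param model A [gene_model()].
#' @param exon_idx Internal exon index (not first or last).
#' @param sample Sample id to quantify.
#' @param max_shift Maximum acceptor shift folded into the skip count.
#' @return A one-row tibble: `sample`, `exon`, `inclusion_count`,
#'   `skip_count`, `psi`.
#' @export
exon_psi <- function(junctions, model, exon_idx, sample, max_shift = 10) {
  if (exon_idx <= 1L || exon_idx >= n_exons(model))
    stop("exon ", exon_idx, " is terminal; PSI is defined for internal exons",
         call. = FALSE)
  up <- junction_coords(model, exon_idx - 1L, exon_idx)
  dn <- junction_coords(model, exon_idx, exon_idx + 1L)
  inc <- round_half_up((
    lookup_count(junctions, sample, up$donor_end, up$acceptor_start) +
    lookup_count(junctions, sample, dn$donor_end, dn$acceptor_start)) / 2)
  sk <- skip_junction_counts(junctions, model, exon_idx, sample, max_shift)
  skip <- sum(sk$count)
  tibble::tibble(sample = sample, exon = exon_idx,
                 inclusion_count = as.integer(inc),
                 skip_count = as.integer(skip),
                 psi = if (inc + skip == 0) NA_real_ else inc / (inc + skip))
}

round_half_up <- function(x) floor(x + 0.5)

# Skip junctions for an internal exon: donor of the upstream exon joined to
# the downstream exon's acceptor, exactly or shifted <= max_shift nt.
skip_junction_counts <- function(junctions, model, exon_idx, sample,
                                 max_shift = 10) {
  canon <- junction_coords(model, exon_idx - 1L, exon_idx + 1L)
  j <- junctions[junctions$sample == sample &
                   junctions$chrom == model$chrom, , drop = FALSE]
  donor_side <- if (model$strand == "+") j$donor_end else j$acceptor_start
  canon_donor <- if (model$strand == "+") canon$donor_end
                 else canon$acceptor_start
  acc_side <- if (model$strand == "+") j$acceptor_start else j$donor_end
  canon_acc <- if (model$strand == "+") canon$acceptor_start
               else canon$donor_end
  shift <- if (model$strand == "+") acc_side - canon_acc
           else canon_acc - acc_side
  hit <- donor_side == canon_donor & abs(shift) <= max_shift
  tibble::tibble(donor_end = j$donor_end[hit],
                 acceptor_start = j$acceptor_start[hit],
                 count = j$count[hit], acceptor_shift = shift[hit])
}

#' Detect aberrant splicing events
#'
#' Scans every internal exon of the gene model for exon skipping (PSI below
#' `psi_max_normal` with at least `min_reads` informative reads) and reports
#' cryptic-acceptor usage: junctions sharing an annotated donor whose
#' acceptor is shifted by 1..`max_shift` nt relative to the annotated
#' acceptor, with a sequence check that the transcribed strand carries AG
#' immediately 5' of the new acceptor. For skip events, isoform fractions
#' split the skipping reads into the exact skip junction and its
#' acceptor-shifted (cryptic) forms.
#'
#' @param junctions Junction tibble.
#' @param model A [gene_model()].
#' @param sample Sample id.
#' @param ref Optional [ref_window()] for the AG sequence check.
#' @param min_reads Minimum informative reads for a skip call.
#' @param psi_max_normal PSI at or above which an exon is considered normally
#'   included.
#' @param max_shift Maximum acceptor shift searched.
#' @param min_cryptic_reads Minimum reads supporting a cryptic junction.
#' @return A tibble of events: `sample`, `type` (`"exon_skip"` /
#'   `"cryptic_acceptor"`), `exon`, `inclusion_count`, `skip_count`, `psi`,
#'   `acceptor_shift`, `ag_ok`, `iso_skip_only`, `iso_cryptic`,
#'   `event_count`. Empty tibble when nothing is aberrant.
#' @export
detect_events <- function(junctions, model, sample, ref = NULL,
                          min_reads = 10, psi_max_normal = 0.8,
                          max_shift = 10, min_cryptic_reads = 2) {
  events <- list()
  for (k in seq(2L, length.out = max(0L, n_exons(model) - 2L))) {
    q <- exon_psi(junctions, model, k, sample, max_shift = max_shift)
    total <- q$inclusion_count + q$skip_count
    sk <- skip_junction_counts(junctions, model, k, sample, max_shift)
    exact <- sum(sk$count[sk$acceptor_shift == 0])
    shifted <- sk[sk$acceptor_shift != 0, , drop = FALSE]
    if (!is.na(q$psi) && q$psi < psi_max_normal && total >= min_reads) {
      denom <- q$skip_count
      events[[length(events) + 1L]] <- tibble::tibble(
        sample = sample, type = "exon_skip", exon = k,
        inclusion_count = q$inclusion_count, skip_count = q$skip_count,
        psi = q$psi, acceptor_shift = NA_integer_, ag_ok = NA,
        iso_skip_only = if (denom > 0) exact / denom else NA_real_,
        iso_cryptic = if (denom > 0) sum(shifted$count) / denom
                      else NA_real_,
        event_count = q$skip_count)
    }
    for (i in seq_len(nrow(shifted))) {
      if (shifted$count[i] < min_cryptic_reads) next
      shift <- shifted$acceptor_shift[i]
      ag_ok <- if (is.null(ref)) NA else
        cryptic_ag_check(model, ref, k + 1L, shift)
      events[[length(events) + 1L]] <- tibble::tibble(
        sample = sample, type = "cryptic_acceptor", exon = k + 1L,
        inclusion_count = q$inclusion_count, skip_count = q$skip_count,
        psi = q$psi, acceptor_shift = as.integer(shift), ag_ok = ag_ok,
        iso_skip_only = NA_real_, iso_cryptic = NA_real_,
        event_count = shifted$count[i])
    }
  }
  if (length(events) == 0L) {
    return(tibble::tibble(sample = character(0), type = character(0),
                          exon = integer(0), inclusion_count = integer(0),
                          skip_count = integer(0), psi = numeric(0),
                          acceptor_shift = integer(0), ag_ok = logical(0),
                          iso_skip_only = numeric(0), iso_cryptic = numeric(0),
                          event_count = integer(0)))
  }
  dplyr::bind_rows(events)
}

# Is the transcribed strand AG immediately 5' of an acceptor shifted `shift`
# nt into exon `exon_idx`?
cryptic_ag_check <- function(model, ref, exon_idx, shift) {
  ss <- splice_sites(model)
  acc <- ss$acceptor[exon_idx]
  if (model$strand == "+") {
    new_acc <- acc + shift
    din <- ref_fetch(ref, model$chrom, new_acc - 2, new_acc - 1, "+")
  } else {
    new_acc <- acc - shift
    din <- ref_fetch(ref, model$chrom, new_acc + 1, new_acc + 2, "-")
  }
  identical(din, "AG")
}

#' In-silico RT-PCR on an isoform
#'
#' Computes the product a primer pair would amplify from the cDNA of a given
#' isoform. Primer sites are transcript coordinates on the *wild-type*
#' transcript (outer ends included); the product length is the distance
#' between the primer outer ends measured along the isoform's spliced
#' transcript. A primer falling in a skipped exon (or in trimmed bases)
#' yields an explicit no-product result.
#'
#' @param model A [gene_model()] with a `primers` element, or pass
#'   `primer_fwd` / `primer_rev` explicitly.
#' @param ref Optional [ref_window()]; when supplied the product sequence is
#'   returned.
#' @param isoform `"wt"`, `"skip"` (drop exon 2), `"skip_cryptic"` (drop exon
#'   2, trim 3 nt off exon 3), or a list with elements `exons` (retained exon
#'   indices) and optional `trim5` (named vector, see [spliced_sequence()]).
#' @param primer_fwd,primer_rev Length-2 transcript coordinate vectors.
#' @return A list: `product` (`TRUE`/`FALSE`), `length` (bp or `NA`),
#'   `sequence` (or `NA`), `isoform`.
#' @export
insilico_rtpcr <- function(model, ref = NULL, isoform = "wt",
                           primer_fwd = NULL, primer_rev = NULL) {
  if (is.null(primer_fwd)) primer_fwd <- model$primers$fwd
  if (is.null(primer_rev)) primer_rev <- model$primers$rev
  if (is.null(primer_fwd) || is.null(primer_rev))
    stop("no primer sites supplied and none stored in the model",
         call. = FALSE)
  iso <- standard_isoform(model, isoform)
  # map wild-type transcript coordinates onto the isoform transcript
  tx_map <- isoform_tx_map(model, iso)
  f <- tx_map[primer_fwd[1]]; r <- tx_map[primer_rev[2]]
  lbl <- if (is.character(isoform)) isoform else "custom"
  if (is.na(f) || is.na(r) || anyNA(tx_map[primer_fwd[1]:primer_fwd[2]]) ||
      anyNA(tx_map[primer_rev[1]:primer_rev[2]])) {
    return(list(product = FALSE, length = NA_integer_,
                sequence = NA_character_, isoform = lbl))
  }
  len <- as.integer(r - f + 1L)
  seqn <- NA_character_
  if (!is.null(ref)) {
    full <- spliced_sequence(model, ref, exons = iso$exons,
                             trim5 = iso$trim5)
    seqn <- substr(full, f, r)
  }
  list(product = TRUE, length = len, sequence = seqn, isoform = lbl)
}

standard_isoform <- function(model, isoform) {
  if (is.list(isoform)) {
    iso <- isoform
    if (is.null(iso$trim5)) iso$trim5 <- c()
    return(iso)
  }
  switch(isoform,
         wt = list(exons = seq_len(n_exons(model)), trim5 = c()),
         skip = list(exons = setdiff(seq_len(n_exons(model)), 2L),
                     trim5 = c()),
         skip_cryptic = list(exons = setdiff(seq_len(n_exons(model)), 2L),
                             trim5 = c("3" = 3L)),
         stop("unknown isoform: ", isoform, call. = FALSE))
}

# Vector mapping wild-type transcript positions to isoform transcript
# positions (NA where the base is absent from the isoform).
isoform_tx_map <- function(model, iso) {
  ex <- model$exons
  keep <- rep(FALSE, model$tx_len)
  for (k in iso$exons) {
    from <- ex$tx_start[k]
    tr <- iso$trim5[as.character(k)]
    if (length(tr) == 1L && !is.na(tr)) from <- from + tr
    keep[from:ex$tx_end[k]] <- TRUE
  }
  m <- rep(NA_integer_, model$tx_len)
  m[keep] <- seq_len(sum(keep))
  m
}
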