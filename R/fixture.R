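#' Four-exon splice-fixture gene
#'
#' Generates the packaged gene fixture the splicing and scoring modules are
#' exercised against: a four-exon, PIGH-like transcript whose internal exon 2
#' (216 nt) is skipped in mutant transcripts, whose exon 3 begins with an AAG
#' lysine codon ending in the AG dinucleotide that can act as a cryptic
#' acceptor 3 nt into the exon, and whose intron 1 carries one C residue at
#' acceptor-offset -10 inside the polypyrimidine tract - the site of the
#' causal C>G substitution.
#'
#' Fixed geometry (transcript sense): exon lengths 210/216/150/200 nt, intron
#' lengths 400/300/350 nt, 30-nt 5'UTR, 567-nt CDS (188 aa + stop). RT-PCR
#' primers sit at transcript 21-40 (exon 1) and 594-613 (exon 4), so the
#' wild-type spliced product is 593 bp, the exon-2-skip product 377 bp and the
#' skip-plus-cryptic product 374 bp. Every acceptor has an all-pyrimidine
#' -16..-5 tract and the invariant AG at -2/-1; donors start with GT.
#'
#' @param strand Strand of the gene on the reference (`"-"` by default, as for
#'   bovine *PIGH*; `"+"` mirrors the whole construction).
#' @param chrom Chromosome name.
#' @param gene_start Leftmost genomic base of the gene.
#' @param flank Extra reference sequence kept on each side of the gene.
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @return A list with elements `model` (a [gene_model()]), `ref` (a
#'   [ref_window()]), `causal` (one-row tibble: `chrom`, `pos`, `id`, `ref`,
#'   `alt` on the genomic plus strand), and `exon2_len`.
#' @examples
#' fx <- simulate_gene_fixture(seed = 1)
#' insilico_rtpcr(fx$model, fx$ref, isoform = "wt")$length  # 593
#' @export
simulate_gene_fixture <- function(strand = "-", chrom = "chr10",
                                  gene_start = 79511000, flank = 500,
                                  seed = 1) {
  stopifnot(strand %in% c("+", "-"))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    exon_len <- c(210L, 216L, 150L, 200L)
    intron_len <- c(400L, 300L, 350L)
    utr5 <- 30L
    n_aa <- 188L
    cds_len <- 3L * (n_aa + 1L)             # 567, incl. stop
    tx_len <- sum(exon_len)                 # 776

    bases <- c("A", "C", "G", "T")
    tx <- sample(bases, tx_len, replace = TRUE)
    # coding sequence: ATG, 187 random non-stop codons, TAA stop
    codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    body <- sample(codons, n_aa - 1L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    # exon 3 starts codon-aligned at codon 133; force its first codon to AAG
    substr(cds, 397, 399) <- "AAG"
    tx[utr5 + seq_len(cds_len)] <- strsplit(cds, "")[[1]]

    introns <- lapply(intron_len, function(L) {
      s <- sample(bases, L, replace = TRUE)
      s[1:2] <- c("G", "T")                       # donor
      s[c(L - 1L, L)] <- c("A", "G")              # acceptor AG
      s[(L - 15L):(L - 4L)] <- sample(c("C", "T"), 12L, replace = TRUE)
      s
    })
    # causal site: intron 1, acceptor offset -10 = intron position L-9
    introns[[1]][intron_len[1] - 9L] <- "C"

    exon_tx_start <- cumsum(c(1L, exon_len))[1:4]
    gene_axis <- character(0)
    for (k in 1:4) {
      gene_axis <- c(gene_axis,
                     tx[exon_tx_start[k]:(exon_tx_start[k] + exon_len[k] - 1L)])
      if (k < 4) gene_axis <- c(gene_axis, introns[[k]])
    }
    L <- length(gene_axis)
    # exon spans on the gene axis (transcript sense)
    ax_start <- cumsum(c(1L, exon_len[1:3] + intron_len))
    ax_end <- ax_start + exon_len - 1L
    if (strand == "+") {
      plus_seq <- paste(gene_axis, collapse = "")
      ex <- tibble::tibble(gstart = gene_start + ax_start - 1L,
                           gend = gene_start + ax_end - 1L)
    } else {
      plus_seq <- revcomp(paste(gene_axis, collapse = ""))
      ex <- tibble::tibble(gstart = gene_start + L - ax_end,
                           gend = gene_start + L - ax_start)
    }

    model <- gene_model(
      gene_id = "SPFX1", chrom = chrom, strand = strand, exons = ex,
      cds_start = utr5 + 1L, cds_end = utr5 + cds_len,
      primers = list(fwd = c(21L, 40L), rev = c(594L, 613L))
    )

    flank_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                   collapse = "")
    ref <- ref_window(chrom, gene_start - flank,
                      paste0(flank_seq(flank), plus_seq, flank_seq(flank)))

    acc2 <- splice_sites(model)$acceptor[2]
    causal_pos <- if (strand == "+") acc2 - 10L else acc2 + 10L
    causal <- tibble::tibble(
      chrom = chrom, pos = causal_pos, id = "causal",
      ref = if (strand == "+") "C" else "G",
      alt = if (strand == "+") "G" else "C"
    )
    stopifnot(identical(ref_base(ref, chrom, causal_pos), causal$ref))

    list(model = model, ref = ref, causal = causal, exon2_len = exon_len[2])
  })
}

#' PIGH-like protein domain table
#'
#' Domain architecture of the 188-residue fixture protein: a short N-terminal
#' cytoplasmic segment, two transmembrane helices separated by a short
#' ER-luminal loop, and a long C-terminal cytoplasmic tail.
#'
#' @return A tibble with columns `domain`, `aa_start`, `aa_end`.
#' @export
fixture_protein_domains <- function() {
  tibble::tribble(
    ~domain,              ~aa_start, ~aa_end,
    "N-terminal",                 1L,     37L,
    "TM1",                       38L,     55L,
    "luminal loop",              56L,     59L,
    "TM2",                       60L,     78L,
    "C-terminal tail",           79L,    188L
  )
}
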