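#' Simulate the half-sib mapping population
#'
#' Generates a two-generation half-sib pedigree in which one elite sire
#' carries a recessive lethal founder haplotype: affected calves receive the
#' haplotype on the paternal path directly from the sire and on the maternal
#' path through carrier daughters of the same sire, so every case is
#' homozygous identical-by-descent across the configured interval.
#' Controls are unrelated founders carrying the haplotype at
#' `carrier_freq_controls`, never homozygous. Within the IBD segment the
#' founder haplotype is transmitted without recombination; crossovers occur
#' only at the segment boundaries, with uniformly drawn overhangs, so the
#' region of homozygosity shared by all cases closely matches the configured
#' interval.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{pedigree}{tibble `id`, `sire`, `dam`, `role`}
#'     \item{geno}{a [genotype_matrix()] over all individuals}
#'     \item{truth}{list: `interval` (tibble `chrom`,`start`,`end`),
#'       `founder_hap` (0/1 vector over markers), `case_ids`, `control_ids`,
#'       `carrier_controls`}
#'   }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, "population"), {
    chrom <- "chr10"
    pos <- sort(sample.int(cfg$region_span, cfg$n_markers)) +
      cfg$region_start - 1
    p_alt <- stats::runif(cfg$n_markers, 0.1, 0.9)
    rand_hap <- function() stats::rbinom(cfg$n_markers, 1L, p_alt)
    hstar <- rand_hap()

    ibd_len <- round(cfg$region_span * cfg$ibd_interval)
    istart <- round(cfg$region_start + (cfg$region_span - ibd_len) / 2)
    iend <- istart + ibd_len - 1
    ext_max <- max(1, round(cfg$region_span * 0.02))
    # founder-haplotype mosaic: hstar inside an extended segment, `other`
    # outside -- a valid double recombinant of a (hstar, other) parent
    mosaic <- function(other, lo_ext, hi_ext) {
      inside <- pos >= (istart - lo_ext) & pos <= (iend + hi_ext)
      ifelse(inside, hstar, other)
    }
    u <- function() stats::runif(1, 0, ext_max)

    ids <- character(0); sires <- character(0); dams <- character(0)
    roles <- character(0); haps <- list()
    add <- function(id, sire, dam, role, h1, h2) {
      ids <<- c(ids, id); sires <<- c(sires, sire); dams <<- c(dams, dam)
      roles <<- c(roles, role); haps[[id]] <<- list(h1, h2)
    }

    add("S1", NA, NA, "sire", hstar, rand_hap())
    sire_other <- haps[["S1"]][[2]]
    case_ids <- sprintf("case%02d", seq_len(cfg$n_cases))
    for (i in seq_len(cfg$n_cases)) {
      fid <- sprintf("F%02d", i)       # founder mate of the sire
      did <- sprintf("D%02d", i)       # carrier daughter, dam of the case
      add(fid, NA, NA, "founder", rand_hap(), rand_hap())
      d_lo <- u(); d_hi <- u()
      d_pat <- mosaic(sire_other, d_lo, d_hi)
      d_mat <- haps[[fid]][[sample.int(2, 1)]]
      add(did, "S1", fid, "dam", d_pat, d_mat)
      # case: paternal gamete from the sire, maternal through the daughter;
      # the maternal overhang is trimmed within the daughter's own segment
      c_pat <- mosaic(sire_other, u(), u())
      c_mat <- mosaic(d_mat, stats::runif(1, 0, d_lo),
                      stats::runif(1, 0, d_hi))
      add(case_ids[i], "S1", did, "case", c_pat, c_mat)
    }
    control_ids <- sprintf("ctrl%03d", seq_len(cfg$n_controls))
    is_carrier <- stats::runif(cfg$n_controls) < cfg$carrier_freq_controls
    for (j in seq_len(cfg$n_controls)) {
      h1 <- if (is_carrier[j]) hstar else rand_hap()
      add(control_ids[j], NA, NA, "control", h1, rand_hap())
    }

    geno <- do.call(rbind, lapply(ids, function(id) {
      haps[[id]][[1]] + haps[[id]][[2]]
    }))
    rownames(geno) <- ids
    map <- tibble::tibble(
      marker_id = sprintf("snp%04d", seq_len(cfg$n_markers)),
      chrom = chrom, pos = pos, ref = "A", alt = "B")
    samples <- tibble::tibble(sample_id = ids, role = roles)
    gm <- genotype_matrix(geno, map, samples)

    list(
      pedigree = tibble::tibble(id = ids, sire = sires, dam = dams,
                                role = roles),
      geno = gm,
      truth = list(
        interval = tibble::tibble(chrom = chrom, start = istart, end = iend),
        founder_hap = hstar,
        case_ids = case_ids,
        control_ids = control_ids,
        carrier_controls = control_ids[is_carrier]
      )
    )
  })
}

#' Simulate the resequencing variant calls
#'
#' Draws decoy variants across the region (randomised genotypes, quality
#' scores and known-catalog membership), plants `n_candidate_decoys` decoys
#' that survive every filter stage but sit far from any splice site, and adds
#' exactly one causal variant: the fixture's intron-1 substitution at acceptor
#' offset -10, homozygous in all sequenced cases, absent from controls and
#' from the catalog.
#'
#' @param config A [sim_config()].
#' @param pop Output of [simulate_population()].
#' @param fixture Output of [simulate_gene_fixture()]; if `NULL`, one is
#'   generated from the config's strand and seed, placed at the centre of the
#'   true interval.
#' @return A list with `variants` (tibble: `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qual`, `in_catalog`, plus one integer genotype column per
#'   sequenced sample), `case_ids` (4 sequenced cases), `control_ids`
#'   (15 sequenced non-carrier controls), `fixture`, and `truth`
#'   (list with `causal_id`).
#' @export
simulate_variant_calls <- function(config, pop, fixture = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (is.null(fixture)) {
    iv <- pop$truth$interval
    gstart <- round((iv$start + iv$end) / 2) - 913
    fixture <- simulate_gene_fixture(strand = cfg$strand, chrom = iv$chrom,
                                     gene_start = gstart, seed = cfg$seed)
  }
  withr::with_seed(derive_seed(cfg$seed, "variants"), {
    iv <- pop$truth$interval
    seq_cases <- utils::head(pop$truth$case_ids, 4L)
    noncarrier <- setdiff(pop$truth$control_ids,
                          pop$truth$carrier_controls)
    if (length(noncarrier) < 15L)
      stop("need at least 15 non-carrier controls to emulate resequencing",
           call. = FALSE)
    seq_ctrls <- utils::head(noncarrier, 15L)
    samp <- c(seq_cases, seq_ctrls)
    bases <- c("A", "C", "G", "T")
    span <- gene_span(fixture$model)
    guard <- 1000L

    n_plain <- cfg$n_decoy_variants - cfg$n_candidate_decoys
    draw_pos <- function(n, inside_interval = FALSE, avoid_gene = FALSE) {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- if (inside_interval) {
          round(stats::runif(n * 2, iv$start, iv$end))
        } else {
          round(stats::runif(n * 2, cfg$region_start,
                             cfg$region_start + cfg$region_span - 1))
        }
        if (avoid_gene)
          cand <- cand[cand < span[1] - guard | cand > span[2] + guard]
        cand <- setdiff(unique(cand), c(out, fixture$causal$pos))
        out <- c(out, cand)
      }
      out[seq_len(n)]
    }

    gt_cols <- function(gts) {
      stats::setNames(as.list(as.data.frame(gts)), samp)
    }

    plain <- NULL
    if (n_plain > 0) {
      ppos <- draw_pos(n_plain)
      af <- stats::runif(n_plain, 0.05, 0.5)
      gts <- t(vapply(af, function(a) stats::rbinom(length(samp), 2L, a),
                      integer(length(samp))))
      refalt <- t(vapply(seq_len(n_plain), function(i) sample(bases, 2L),
                         character(2L)))
      lowq <- stats::runif(n_plain) < 0.2
      qual <- ifelse(lowq, stats::runif(n_plain, 30, 100),
                     stats::runif(n_plain, 101, 999))
      plain <- tibble::tibble(
        chrom = iv$chrom, pos = ppos, id = sprintf("v%05d", seq_len(n_plain)),
        ref = refalt[, 1], alt = refalt[, 2], qual = round(qual, 1),
        in_catalog = stats::runif(n_plain) < 0.3, !!!gt_cols(gts))
    }

    cand <- NULL
    if (cfg$n_candidate_decoys > 0) {
      cpos <- draw_pos(cfg$n_candidate_decoys, inside_interval = TRUE,
                       avoid_gene = TRUE)
      refalt <- t(vapply(seq_len(cfg$n_candidate_decoys),
                         function(i) sample(bases, 2L), character(2L)))
      gts <- matrix(rep(c(rep(2L, length(seq_cases)),
                          rep(0L, length(seq_ctrls))),
                        each = cfg$n_candidate_decoys),
                    nrow = cfg$n_candidate_decoys)
      cand <- tibble::tibble(
        chrom = iv$chrom, pos = cpos,
        id = sprintf("cand%03d", seq_len(cfg$n_candidate_decoys)),
        ref = refalt[, 1], alt = refalt[, 2],
        qual = round(stats::runif(cfg$n_candidate_decoys, 150, 950), 1),
        in_catalog = FALSE, !!!gt_cols(gts))
    }

    causal <- tibble::tibble(
      chrom = fixture$causal$chrom, pos = fixture$causal$pos,
      id = fixture$causal$id, ref = fixture$causal$ref,
      alt = fixture$causal$alt,
      qual = round(stats::runif(1, 500, 999), 1), in_catalog = FALSE,
      !!!gt_cols(matrix(c(rep(2L, length(seq_cases)),
                          rep(0L, length(seq_ctrls))), nrow = 1)))

    variants <- dplyr::bind_rows(plain, cand, causal) |>
      dplyr::arrange(.data$chrom, .data$pos)

    list(variants = variants, case_ids = seq_cases, control_ids = seq_ctrls,
         fixture = fixture, truth = list(causal_id = fixture$causal$id))
  })
}

#' Simulate junction read counts at the fixture locus
#'
#' Poisson junction counts for one RNA-Seq sample, given its genotype at the
#' causal locus. Transcripts skip exon 2 with the configured fraction
#' (`skip_fraction_het` / `skip_fraction_hom`); of the skipping transcripts,
#' `cryptic_fraction` additionally use the cryptic acceptor 3 nt into exon 3.
#'
#' @param config A [sim_config()].
#' @param genotype_at_locus One of `"ref"`, `"het"`, `"hom"`.
#' @param fixture A gene fixture from [simulate_gene_fixture()].
#' @param sample_id Sample name for the junction table.
#' @return A junction tibble: `sample`, `chrom`, `donor_end`,
#'   `acceptor_start`, `count` (1-based inclusive flanking exonic bases on
#'   the forward genome axis).
#' @export
simulate_junction_reads <- function(config, genotype_at_locus, fixture,
                                    sample_id = genotype_at_locus) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  skip <- switch(genotype_at_locus,
                 ref = 0,
                 het = cfg$skip_fraction_het,
                 hom = cfg$skip_fraction_hom,
                 stop("unknown genotype label: ", genotype_at_locus,
                      " (use 'ref', 'het' or 'hom')", call. = FALSE))
  withr::with_seed(derive_seed(cfg$seed, paste0("junctions_", sample_id)), {
    d <- cfg$read_depth
    cf <- cfg$cryptic_fraction
    counts <- c(
      j12 = stats::rpois(1, d * (1 - skip)),
      j23 = stats::rpois(1, d * (1 - skip)),
      j13 = stats::rpois(1, d * skip * (1 - cf)),
      j13c = stats::rpois(1, d * skip * cf),
      j34 = stats::rpois(1, d)
    )
    jc <- dplyr::bind_rows(
      junction_coords(fixture$model, 1, 2),
      junction_coords(fixture$model, 2, 3),
      junction_coords(fixture$model, 1, 3),
      junction_coords(fixture$model, 1, 3, shift = 3),
      junction_coords(fixture$model, 3, 4)
    )
    tibble::tibble(sample = sample_id, chrom = fixture$model$chrom,
                   donor_end = jc$donor_end,
                   acceptor_start = jc$acceptor_start,
                   count = as.integer(counts)) |>
      dplyr::filter(.data$count > 0) |>
      dplyr::arrange(.data$donor_end, .data$acceptor_start)
  })
}

#' Genomic coordinates of a splice junction
#'
#' Forward-genome-axis flanking exonic bases of the junction joining the
#' donor of `from_exon` to the acceptor of `to_exon` (transcript order), the
#' acceptor optionally shifted `shift` nt into the exon (cryptic acceptor).
#'
#' @param model A [gene_model()].
#' @param from_exon,to_exon Exon indices in transcript order.
#' @param shift Acceptor shift in transcript sense (positive = into the exon).
#' @return One-row tibble `donor_end`, `acceptor_start`.
#' @export
junction_coords <- function(model, from_exon, to_exon, shift = 0) {
  ss <- splice_sites(model)
  donor_g <- ss$donor[from_exon]
  acceptor_g <- if (model$strand == "+") ss$acceptor[to_exon] + shift
                else ss$acceptor[to_exon] - shift
  tibble::tibble(donor_end = min(donor_g, acceptor_g),
                 acceptor_start = max(donor_g, acceptor_g))
}

#' Simulate a complete study
#'
#' Runs the population, variant-call and junction generators with a shared
#' configuration, producing every input the pipeline consumes plus the truth
#' labels used for testing.
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `pop`, `calls`, `fixture`, `junctions` (one
#'   table over samples `rna_ctrl` (wild type), `rna_carrier` (het),
#'   `rna_case` (hom)), `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  pop <- simulate_population(config)
  calls <- simulate_variant_calls(config, pop)
  fixture <- calls$fixture
  junctions <- dplyr::bind_rows(
    simulate_junction_reads(config, "ref", fixture, "rna_ctrl"),
    simulate_junction_reads(config, "het", fixture, "rna_carrier"),
    simulate_junction_reads(config, "hom", fixture, "rna_case")
  )
  list(config = config, pop = pop, calls = calls, fixture = fixture,
       junctions = junctions,
       truth = c(pop$truth, calls$truth))
}
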