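test_that("CIGAR walk places junction coordinates correctly", {
  # POS=100 20M50N20M: last exonic base 119, first after gap 170
  aln <- tibble::tibble(rname = "chr1", pos = 100, cigar = "20M50N20M")
  j <- extract_junctions(aln, sample = "s1")
  expect_equal(j$donor_end, 119)
  expect_equal(j$acceptor_start, 170)
  expect_equal(j$count, 1L)

  # reads without an N contribute nothing
  none <- extract_junctions(tibble::tibble(rname = "chr1", pos = 100,
                                           cigar = "40M"))
  expect_equal(nrow(none), 0)

  # soft clips and insertions do not consume reference
  j2 <- extract_junctions(tibble::tibble(rname = "chr1", pos = 100,
                                         cigar = "5S20M2I30N20M3S"))
  expect_equal(j2$donor_end, 119)
  expect_equal(j2$acceptor_start, 150)

  # short anchors are filtered
  weak <- extract_junctions(tibble::tibble(rname = "chr1", pos = 100,
                                           cigar = "5M50N40M"))
  expect_equal(nrow(weak), 0)

  expect_error(extract_junctions(tibble::tibble(rname = "chr1", pos = 1,
                                                cigar = "20Q")),
               "malformed CIGAR")
})

test_that("junction extraction equals the brute-force CIGAR interpreter", {
  withr::with_seed(31, {
    ops <- c("M", "N", "I", "D", "S")
    for (rep in 1:60) {
      n_ops <- sample(3:9, 1)
      op <- c("M", sample(ops, n_ops - 2, replace = TRUE,
                          prob = c(0.5, 0.25, 0.1, 0.1, 0.05)), "M")
      len <- sample(1:60, n_ops, replace = TRUE)
      cigar <- paste0(len, op, collapse = "")
      pos <- sample(1:5000, 1)
      got <- cigar_junctions(pos, cigar, anchor_min = 8)
      want <- brute_cigar_junctions(pos, cigar, anchor_min = 8)
      expect_equal(got, want, info = cigar)
    }
  })
})

test_that("junction TSV round-trips through disk", {
  fx <- simulate_gene_fixture(seed = 2)
  j <- simulate_junction_reads(sim_config(seed = 2), "het", fx, "s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_junction_tsv(j, path)
  expect_equal(read_junction_tsv(path), j)
})

test_that("SAM emission of a junction table is recovered exactly by extraction", {
  fx <- simulate_gene_fixture(seed = 3)
  j <- simulate_junction_reads(sim_config(seed = 3), "het", fx, "s1")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_junction_sam(j, sam)
  back <- extract_junctions(sam, sample = "s1")
  expect_equal(back[, c("chrom", "donor_end", "acceptor_start", "count")],
               j[, c("chrom", "donor_end", "acceptor_start", "count")])
})

test_that("PSI arithmetic reproduces the carrier worked example (20 skip / 45)", {
  fx <- simulate_gene_fixture(seed = 1)
  model <- fx$model
  j12 <- junction_coords(model, 1, 2)
  j23 <- junction_coords(model, 2, 3)
  j13 <- junction_coords(model, 1, 3)
  junctions <- tibble::tibble(
    sample = "carrier", chrom = model$chrom,
    donor_end = c(j12$donor_end, j23$donor_end, j13$donor_end),
    acceptor_start = c(j12$acceptor_start, j23$acceptor_start,
                       j13$acceptor_start),
    count = c(25L, 25L, 20L))
  q <- exon_psi(junctions, model, 2, "carrier")
  expect_equal(q$inclusion_count, 25L)
  expect_equal(q$skip_count, 20L)
  expect_equal(q$psi, 25 / 45)
  expect_equal(1 - q$psi, 20 / 45)
})

test_that("PSI is 1 with no skip reads and errors on terminal exons", {
  fx <- simulate_gene_fixture(seed = 1)
  j <- simulate_junction_reads(sim_config(seed = 1), "ref", fx, "wt")
  expect_equal(exon_psi(j, fx$model, 2, "wt")$psi, 1)
  expect_error(exon_psi(j, fx$model, 1, "wt"), "terminal")
  expect_error(exon_psi(j, fx$model, 4, "wt"), "terminal")
})

test_that("PSI stays in [0,1] and decreases with the planted skip fraction", {
  fx <- simulate_gene_fixture(seed = 5)
  fracs <- seq(0.05, 0.95, length.out = 50)
  psis <- purrr::map_dbl(seq_along(fracs), function(i) {
    cfg <- sim_config(skip_fraction_het = fracs[i], seed = 400 + i)
    j <- simulate_junction_reads(cfg, "het", fx, "s")
    exon_psi(j, fx$model, 2, "s")$psi
  })
  expect_true(all(psis >= 0 & psis <= 1))
  expect_gt(abs(stats::cor(fracs, psis, method = "spearman")), 0.95)
  expect_lt(stats::cor(fracs, psis, method = "spearman"), 0)
})

test_that("het and hom simulations recover their configured PSI within binomial error", {
  fx <- simulate_gene_fixture(seed = 6)
  psi_het <- purrr::map_dbl(1:20, function(s) {
    j <- simulate_junction_reads(sim_config(seed = s), "het", fx, "s")
    exon_psi(j, fx$model, 2, "s")$psi
  })
  psi_hom <- purrr::map_dbl(1:20, function(s) {
    j <- simulate_junction_reads(sim_config(seed = s), "hom", fx, "s")
    exon_psi(j, fx$model, 2, "s")$psi
  })
  expect_equal(mean(psi_het), 0.5, tolerance = 0.05)
  expect_lt(mean(psi_hom), 0.02)
})

test_that("event detection reports the exon-2 skip and +3 cryptic acceptor in the case", {
  study <- default_study()
  ev <- detect_events(study$junctions, study$fixture$model, "rna_case",
                      ref = study$fixture$ref)
  expect_setequal(ev$type, c("exon_skip", "cryptic_acceptor"))
  skip <- ev[ev$type == "exon_skip", ]
  expect_equal(skip$exon, 2L)
  expect_lt(skip$psi, 0.05)
  cry <- ev[ev$type == "cryptic_acceptor", ]
  expect_equal(cry$exon, 3L)
  expect_equal(cry$acceptor_shift, 3L)
  expect_true(cry$ag_ok)
  # isoform split close to the configured 75/25
  expect_equal(skip$iso_skip_only, 0.75, tolerance = 0.2)
  expect_equal(skip$iso_skip_only + skip$iso_cryptic, 1)
})

test_that("wild-type junctions produce no events", {
  study <- default_study()
  ev <- detect_events(study$junctions, study$fixture$model, "rna_ctrl",
                      ref = study$fixture$ref)
  expect_equal(nrow(ev), 0)
})

test_that("isoform fractions on 15 skip-only + 5 cryptic reads are 75%/25%", {
  fx <- simulate_gene_fixture(seed = 1)
  model <- fx$model
  j13 <- junction_coords(model, 1, 3)
  j13c <- junction_coords(model, 1, 3, shift = 3)
  j12 <- junction_coords(model, 1, 2)
  junctions <- tibble::tibble(
    sample = "case", chrom = model$chrom,
    donor_end = c(j12$donor_end, j13$donor_end, j13c$donor_end),
    acceptor_start = c(j12$acceptor_start, j13$acceptor_start,
                       j13c$acceptor_start),
    count = c(2L, 15L, 5L))
  ev <- detect_events(junctions, model, "case", ref = fx$ref)
  skip <- ev[ev$type == "exon_skip", ]
  expect_equal(skip$iso_skip_only, 0.75)
  expect_equal(skip$iso_cryptic, 0.25)
})

test_that("in-silico RT-PCR reproduces the fixture product lengths", {
  for (strand in c("-", "+")) {
    fx <- simulate_gene_fixture(strand = strand, seed = 1)
    wt <- insilico_rtpcr(fx$model, fx$ref, "wt")
    expect_equal(wt$length, 593L)
    expect_equal(nchar(wt$sequence), 593L)
    expect_equal(insilico_rtpcr(fx$model, fx$ref, "skip")$length, 377L)
    expect_equal(insilico_rtpcr(fx$model, fx$ref, "skip_cryptic")$length,
                 374L)
  }
})

test_that("a primer inside a skipped exon yields an explicit no-product result", {
  fx <- simulate_gene_fixture(seed = 1)
  ex2_mid <- fx$model$exons$tx_start[2] + 10
  res <- insilico_rtpcr(fx$model, fx$ref, "skip",
                        primer_fwd = c(ex2_mid, ex2_mid + 19),
                        primer_rev = fx$model$primers$rev)
  expect_false(res$product)
  expect_true(is.na(res$length))
})

test_that("RT-PCR product sequences match the spliced transcript", {
  fx <- simulate_gene_fixture(seed = 1)
  wt <- insilico_rtpcr(fx$model, fx$ref, "wt")
  tx <- spliced_sequence(fx$model, fx$ref)
  expect_equal(wt$sequence, substr(tx, 21, 613))
  # the cryptic product lacks exon 2 and the first AAG of exon 3
  cry <- insilico_rtpcr(fx$model, fx$ref, "skip_cryptic")
  ex3_start <- fx$model$exons$tx_start[3]
  expect_equal(substr(tx, ex3_start, ex3_start + 2), "AAG")
})
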