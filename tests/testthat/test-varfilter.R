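make_variants <- function() {
  tibble::tibble(
    chrom = "chr1",
    pos = c(500, 1500, 2500, 3500, 4500, 5500, 9500),
    id = sprintf("v%d", 1:7),
    ref = "A", alt = "T",
    qual = c(500, 100, 150, 500, 500, 500, 500),
    in_catalog = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    caseA = c(2L, 2L, 1L, 2L, 2L, 2L, 2L),
    caseB = c(2L, 2L, 2L, 2L, 2L, 2L, 2L),
    ctrl1 = c(0L, 0L, 0L, 1L, 0L, 0L, 0L),
    ctrl2 = c(0L, 0L, 0L, 0L, NA, 0L, 0L)
  )
}

test_that("filter cascade applies the five stages in order with correct counts", {
  v <- make_variants()
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 8000)
  rep_ <- filter_cascade(v, iv, c("caseA", "caseB"), c("ctrl1", "ctrl2"))
  # v1 outside interval; v7 outside; v2 qual==100 (strict); v3 het case;
  # v4 control carries alt; v5 control missing passes; v6 in catalog
  expect_equal(rep_$stages$n, c(7, 5, 4, 3, 2, 1))
  expect_equal(rep_$candidates$id, "v5")
  expect_true(all(diff(rep_$stages$n) <= 0))
})

test_that("variant with quality exactly at the threshold is removed (strict >)", {
  v <- make_variants()[2, ]
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 8000)
  rep_ <- filter_cascade(v, iv, c("caseA", "caseB"), c("ctrl1", "ctrl2"))
  expect_equal(rep_$stages$n[3], 0)
  rep2 <- filter_cascade(dplyr::mutate(v, qual = 100.01), iv,
                         c("caseA", "caseB"), c("ctrl1", "ctrl2"))
  expect_equal(rep2$stages$n[3], 1)
})

test_that("empty variant list yields all-zero counts", {
  v <- make_variants()[0, ]
  iv <- tibble::tibble(chrom = "chr1", start = 1, end = 10)
  rep_ <- filter_cascade(v, iv, c("caseA", "caseB"), c("ctrl1", "ctrl2"))
  expect_true(all(rep_$stages$n == 0))
  expect_equal(nrow(rep_$candidates), 0)
})

test_that("unknown sample ids are rejected; foreign-chromosome interval is empty", {
  v <- make_variants()
  iv <- tibble::tibble(chrom = "chr1", start = 1, end = 10000)
  expect_error(filter_cascade(v, iv, c("caseA", "nope"), "ctrl1"),
               "unknown sample")
  iv2 <- tibble::tibble(chrom = "chr9", start = 1, end = 10000)
  rep_ <- filter_cascade(v, iv2, c("caseA", "caseB"), c("ctrl1", "ctrl2"))
  expect_equal(rep_$stages$n[2], 0)
})

test_that("final candidate set is invariant under permutation of stages 2-5", {
  # set-intersection commutativity: apply each filter independently and
  # intersect, then compare with the cascade
  v <- make_variants()
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 8000)
  cases <- c("caseA", "caseB"); ctrls <- c("ctrl1", "ctrl2")
  cascade <- filter_cascade(v, iv, cases, ctrls)$candidates$id
  s1 <- v$id[v$chrom == iv$chrom & v$pos >= iv$start & v$pos <= iv$end]
  s2 <- v$id[v$qual > 100]
  s3 <- v$id[apply(as.matrix(v[, cases]) == 2L, 1,
                   function(r) all(r %in% TRUE))]
  s4 <- v$id[apply(as.matrix(v[, ctrls]), 1,
                   function(r) !any(r >= 1L, na.rm = TRUE))]
  s5 <- v$id[!v$in_catalog]
  expect_setequal(cascade, Reduce(intersect, list(s1, s2, s3, s4, s5)))
})

test_that("explicit catalog matching requires allele identity, not just position", {
  v <- make_variants()
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 8000)
  # catalog holds v6's site but with a different alt allele: v6 survives now
  cat_tbl <- tibble::tibble(chrom = "chr1", pos = 5500, ref = "A",
                            alt = "G")
  rep_ <- filter_cascade(v, iv, c("caseA", "caseB"), c("ctrl1", "ctrl2"),
                         known_catalog = cat_tbl)
  expect_setequal(rep_$candidates$id, c("v5", "v6"))
  # matching allele removes it again
  cat_tbl$alt <- "T"
  rep2 <- filter_cascade(v, iv, c("caseA", "caseB"), c("ctrl1", "ctrl2"),
                         known_catalog = cat_tbl)
  expect_setequal(rep2$candidates$id, "v5")
})

test_that("multi-allelic records are split before filtering", {
  v <- tibble::tibble(chrom = "chr1", pos = 100, id = "m1", ref = "A",
                      alt = "T,G", qual = 500, in_catalog = FALSE,
                      caseA = 2L, ctrl1 = 0L)
  out <- split_multiallelic(v)
  expect_equal(nrow(out), 2)
  expect_setequal(out$alt, c("T", "G"))
})

test_that("cascade recovers the planted candidates from the default simulation", {
  study <- default_study()
  cases <- gm_subset(study$pop$geno, study$truth$case_ids)
  iv <- find_shared_homozygous_segment(cases)
  rep_ <- filter_cascade(study$calls$variants, iv,
                         study$calls$case_ids, study$calls$control_ids)
  expect_true(study$truth$causal_id %in% rep_$candidates$id)
  # survivors are exactly the causal plus planted candidate decoys that lie
  # inside the *detected* interval
  expect_true(all(grepl("^cand|^causal$", rep_$candidates$id)))
})

test_that("consequence classification handles intronic, splice-region and coding classes", {
  fx <- simulate_gene_fixture(seed = 1)
  cons <- classify_consequence(fx$causal, fx$model, fx$ref)
  expect_equal(cons$class, "intronic")
  expect_equal(cons$distance_to_junction, -10L)
  expect_equal(cons$exon, 2L)

  # -3 from the same acceptor: canonical splice region
  v3 <- fx$causal
  v3$pos <- splice_sites(fx$model)$acceptor[2] + 3   # minus strand
  v3$ref <- ref_base(fx$ref, v3$chrom, v3$pos)
  v3$alt <- setdiff(c("A", "C", "G", "T"), v3$ref)[1]
  cons3 <- classify_consequence(v3, fx$model, fx$ref)
  expect_equal(cons3$class, "canonical_splice_region")
  expect_equal(cons3$distance_to_junction, -3L)

  # identity codon change is synonymous
  g <- tx_to_genomic(fx$model, fx$model$cds_start + 30)
  b <- ref_base(fx$ref, fx$model$chrom, g)
  syn <- tibble::tibble(chrom = fx$model$chrom, pos = g, ref = b, alt = b)
  expect_equal(classify_consequence(syn, fx$model, fx$ref)$class,
               "synonymous")

  # indels fall outside the SNV taxonomy
  ind <- tibble::tibble(chrom = fx$model$chrom, pos = g, ref = "AT",
                        alt = "A")
  expect_equal(classify_consequence(ind, fx$model, fx$ref)$class, "indel")

  # positions outside the gene are intergenic
  far <- tibble::tibble(chrom = fx$model$chrom,
                        pos = gene_span(fx$model)[2] + 200,
                        ref = "A", alt = "T")
  expect_equal(classify_consequence(far, fx$model, fx$ref)$class,
               "intergenic")
})

test_that("coding classification agrees with brute-force CDS retranslation", {
  fx <- simulate_gene_fixture(seed = 4)
  model <- fx$model; ref <- fx$ref
  cds_tx <- model$cds_start:model$cds_end
  full_cds <- function(win) {
    paste(vapply(cds_tx, function(tp) {
      g <- tx_to_genomic(model, tp)
      ref_base(win, model$chrom, g, model$strand)
    }, character(1)), collapse = "")
  }
  base_cds <- full_cds(ref)
  withr::with_seed(13, {
    picks <- sample(cds_tx, 40)
    for (tp in picks) {
      g <- tx_to_genomic(model, tp)
      refb <- ref_base(ref, model$chrom, g)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      v <- tibble::tibble(chrom = model$chrom, pos = g, ref = refb,
                          alt = altb)
      got <- classify_consequence(v, model, ref)$class
      # oracle: substitute in the genomic window, retranslate the whole CDS
      alt_win <- ref
      substr(alt_win$seq, g - alt_win$start + 1, g - alt_win$start + 1) <-
        altb
      mut_cds <- full_cds(alt_win)
      p_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(base_cds)))
      p_alt <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(mut_cds))))
      cds_idx <- tp - model$cds_start + 1
      aa_idx <- ceiling(cds_idx / 3)
      want <- if (substr(p_ref, aa_idx, aa_idx) ==
                    substr(p_alt, aa_idx, aa_idx)) "synonymous"
              else if (substr(p_alt, aa_idx, aa_idx) == "*") "nonsense"
              else "missense"
      expect_equal(got, want)
    }
  })
})

test_that("consequence classes and distances are strand-symmetric", {
  for (sd in c(2, 8)) {
    fp <- simulate_gene_fixture(strand = "+", seed = sd)
    fm <- simulate_gene_fixture(strand = "-", seed = sd)
    cp <- classify_consequence(fp$causal, fp$model, fp$ref)
    cm <- classify_consequence(fm$causal, fm$model, fm$ref)
    expect_equal(cp$class, cm$class)
    expect_equal(abs(cp$distance_to_junction),
                 abs(cm$distance_to_junction))
    dp <- variant_acceptor_delta(fp$model, fp$ref, fp$causal)
    dm <- variant_acceptor_delta(fm$model, fm$ref, fm$causal)
    expect_equal(dp$delta, dm$delta)
    expect_equal(dp$window_pos, dm$window_pos)
  }
})

test_that("HGVS c. parsing resolves intronic anchors on the fixture", {
  fx <- simulate_gene_fixture(seed = 1)
  h <- parse_hgvs_c("c.211-10C>G", fx$model)
  expect_equal(h$tx_pos, 211L)
  expect_equal(h$offset, -10L)
  expect_equal(h$acceptor_offset, 10L)
  expect_equal(h$region, "intron")
  expect_equal(h$exon, 2L)
  expect_equal(h$gpos, fx$causal$pos)
  expect_equal(h$gref, fx$causal$ref)
  expect_equal(h$galt, fx$causal$alt)
  # the dotless form seen in assay reports parses identically
  expect_equal(parse_hgvs_c("c211-10C>G", fx$model), h)

  e <- parse_hgvs_c("c.100A>T")
  expect_equal(e$tx_pos, 100L)
  expect_equal(e$offset, 0L)

  expect_error(parse_hgvs_c("c.10del"), "malformed")
  expect_error(parse_hgvs_c("c.211-500C>G", fx$model), "walks out")
  expect_error(parse_hgvs_c("c.10-2C>G", fx$model), "anchor")
})

test_that("genomic -> c. -> genomic round-trips across the fixture", {
  fx <- simulate_gene_fixture(seed = 6)
  model <- fx$model
  span <- gene_span(model)
  withr::with_seed(21, {
    pool <- setdiff(seq(span[1], span[2]),
                    unlist(purrr::map2(model$exons$gstart, model$exons$gend,
                                       seq)))
    gpos <- c(sample(pool, 50),
              sample(unlist(purrr::map2(model$exons$gstart,
                                        model$exons$gend, seq)), 50))
    for (g in gpos) {
      refb <- ref_base(fx$ref, model$chrom, g)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      note <- format_hgvs_c(model, g, refb, altb)
      back <- parse_hgvs_c(note, model)
      expect_equal(back$gpos, g)
      expect_equal(back$gref, refb)
      expect_equal(back$galt, altb)
    }
  })
})
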