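test_that("the planted causal variant is ranked first in the default study", {
  study <- default_study()
  cases <- gm_subset(study$pop$geno, study$truth$case_ids)
  iv <- find_shared_homozygous_segment(cases)
  rep_ <- filter_cascade(study$calls$variants, iv,
                         study$calls$case_ids, study$calls$control_ids)
  ev <- detect_events(study$junctions, study$fixture$model, "rna_case",
                      ref = study$fixture$ref)
  ranked <- link_and_rank(rep_$candidates, ev, study$fixture$model,
                          ref = study$fixture$ref)
  expect_equal(ranked$id[1], study$truth$causal_id)
  expect_true(ranked$linked[1])
  expect_true(ranked$disrupts_acceptor[1])
})

test_that("without events all candidates are unlinked and ordered by position", {
  cands <- tibble::tibble(chrom = "chr1", pos = c(900, 100, 500),
                          id = c("c", "a", "b"), ref = "A", alt = "T")
  fx <- simulate_gene_fixture(seed = 1)
  empty_events <- detect_events(tibble::tibble(sample = character(0),
                                               chrom = character(0),
                                               donor_end = numeric(0),
                                               acceptor_start = numeric(0),
                                               count = integer(0)),
                                fx$model, "none")
  ranked <- link_and_rank(cands, empty_events, fx$model)
  expect_false(any(ranked$linked))
  expect_equal(ranked$id, c("a", "b", "c"))
})

test_that("an acceptor-disrupting linked candidate outranks a non-disrupting one", {
  fx <- simulate_gene_fixture(seed = 1)
  events <- tibble::tibble(type = "exon_skip", exon = 2L)
  acc2 <- splice_sites(fx$model)$acceptor[2]
  # candidate 1: the causal variant (disrupts, distance 10)
  # candidate 2: intronic at -20, outside the tract (linked, no disruption)
  pos20 <- acc2 + 20
  cands <- dplyr::bind_rows(
    fx$causal,
    tibble::tibble(chrom = fx$model$chrom, pos = pos20, id = "near",
                   ref = ref_base(fx$ref, fx$model$chrom, pos20),
                   alt = "N"))
  cands$alt[2] <- setdiff(c("A", "C", "G", "T"),
                          c(cands$ref[2], "A"))[1]
  ranked <- link_and_rank(cands, events, fx$model, ref = fx$ref)
  expect_equal(ranked$id, c("causal", "near"))
  expect_true(all(ranked$linked))
  expect_equal(ranked$disrupts_acceptor, c(TRUE, FALSE))
  # without acceptor scoring the smaller distance decides instead
  cands2 <- cands
  cands2$pos[2] <- acc2 + 5     # nearer than the causal variant (10 bp)
  ranked2 <- link_and_rank(cands2, events, fx$model, ref = NULL)
  expect_equal(ranked2$id[1], "near")
})

test_that("ranking is a deterministic total order and unlinked never displaces linked", {
  fx <- simulate_gene_fixture(seed = 1)
  events <- tibble::tibble(type = "exon_skip", exon = 2L)
  withr::with_seed(61, {
    span <- gene_span(fx$model)
    cands <- tibble::tibble(
      chrom = fx$model$chrom,
      pos = sample(seq(span[1] - 5000, span[2] + 5000), 30),
      id = sprintf("x%02d", 1:30), ref = "A", alt = "T")
  })
  r1 <- link_and_rank(cands, events, fx$model)
  r2 <- link_and_rank(r1[sample(nrow(r1)), names(cands)], events, fx$model)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  # append a far-away (unlinked) candidate: linked order is unchanged
  far <- tibble::tibble(chrom = fx$model$chrom, pos = span[2] + 99999,
                        id = "far", ref = "A", alt = "T")
  r3 <- link_and_rank(dplyr::bind_rows(cands, far), events, fx$model)
  expect_equal(r3$id[r3$linked], r1$id[r1$linked])
  expect_gt(which(r3$id == "far"), sum(r3$linked))
})

test_that("exon-2 skip maps to the phased amino-acid deletion with domain overlaps", {
  fx <- simulate_gene_fixture(seed = 1)
  pe <- protein_effect(fx$model, 2, fixture_protein_domains())
  expect_equal(pe$deleted_start, 61L)
  expect_equal(pe$deleted_end, 132L)
  expect_equal(pe$deleted_count, 72L)
  expect_equal(pe$protein_length, 188L)
  expect_equal(pe$remaining, 116L)
  expect_true(pe$in_frame)
  expect_equal(pe$cds_nt_removed, 216L)
  tm2 <- pe$overlaps[pe$overlaps$domain == "TM2", ]
  expect_equal(tm2$overlap_start, 61L)
  expect_equal(tm2$overlap_end, 78L)
  expect_equal(tm2$overlap_aa, 18L)
})

test_that("deleted range 61-130 intersects TM2 (60-78) in 18 residues", {
  ov <- domain_overlaps(61, 130, fixture_protein_domains())
  tm2 <- ov[ov$domain == "TM2", ]
  expect_equal(unname(unlist(tm2[, c("overlap_start", "overlap_end",
                                     "overlap_aa")])),
               c(61, 78, 18))
})

test_that("protein effect interval arithmetic equals per-residue brute force", {
  fx <- simulate_gene_fixture(seed = 7)
  model <- fx$model
  for (k in 2:3) {
    pe <- protein_effect(model, k)
    cds_lo <- max(model$exons$tx_start[k], model$cds_start) -
      model$cds_start + 1
    cds_hi <- min(model$exons$tx_end[k], model$cds_end) -
      model$cds_start + 1
    deleted <- which(vapply(seq_len(pe$protein_length), function(aa) {
      nts <- (3 * aa - 2):(3 * aa)
      any(nts >= cds_lo & nts <= cds_hi)
    }, logical(1)))
    expect_equal(pe$deleted_start, min(deleted))
    expect_equal(pe$deleted_end, max(deleted))
  }
})

test_that("a 3n exon inside the CDS is flagged in frame, others frameshift", {
  fx <- simulate_gene_fixture(seed = 1)
  expect_true(protein_effect(fx$model, 2)$in_frame)       # 216 nt
  expect_true(protein_effect(fx$model, 3)$in_frame)       # 150 nt
  # a skipped exon with no coding sequence errors
  m <- gene_model("t", "chrT", "+",
                  tibble::tibble(gstart = c(1, 101, 201),
                                 gend = c(50, 160, 260)),
                  cds_start = 61, cds_end = 120)
  expect_error(protein_effect(m, 1), "no coding")
  # 60-nt CDS chunk of a 60-nt exon... build a frameshifting model
  m2 <- gene_model("t2", "chrT", "+",
                   tibble::tibble(gstart = c(1, 101, 201),
                                  gend = c(50, 150, 280)),
                   cds_start = 11, cds_end = 160)
  expect_false(protein_effect(m2, 2)$in_frame)   # 50-nt exon
})
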