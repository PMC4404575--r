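test_that("sim_config validates probabilities, counts and interval width", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(skip_fraction_het = 1.2), "probability")
  expect_error(sim_config(n_cases = 0), "positive")
  expect_error(sim_config(ibd_interval = 1), "interval")
  expect_error(sim_config(ibd_interval = 0), "interval")
  expect_error(sim_config(n_candidate_decoys = 10, n_decoy_variants = 5),
               "exceed")
  expect_error(sim_config(strand = "x"), "strand")
})

test_that("same seed reproduces the population byte-for-byte", {
  cfg <- sim_config(seed = 1, n_controls = 40, n_markers = 60,
                    n_decoy_variants = 50, n_candidate_decoys = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$pop$geno$geno, b$pop$geno$geno)
  expect_identical(a$calls$variants, b$calls$variants)
  expect_identical(a$junctions, b$junctions)
  d <- simulate_study(sim_config(seed = 2, n_controls = 40, n_markers = 60,
                                 n_decoy_variants = 50,
                                 n_candidate_decoys = 5))
  expect_false(identical(a$pop$geno$geno, d$pop$geno$geno))
})

test_that("all cases are homozygous for the founder haplotype across the interval", {
  study <- default_study()
  gm <- study$pop$geno
  iv <- study$truth$interval
  sel <- gm$map$pos >= iv$start & gm$map$pos <= iv$end
  hstar <- study$truth$founder_hap[sel]
  cases <- gm$geno[study$truth$case_ids, sel, drop = FALSE]
  for (i in seq_len(nrow(cases))) {
    expect_equal(unname(cases[i, ]), 2L * hstar)
  }
})

test_that("controls carry the risk haplotype at the configured rate, never homozygous", {
  study <- default_study()
  gm <- study$pop$geno
  iv <- study$truth$interval
  sel <- gm$map$pos >= iv$start & gm$map$pos <= iv$end
  hstar <- study$truth$founder_hap[sel]
  ctrl <- gm$geno[study$truth$control_ids, sel, drop = FALSE]
  hom_for_hstar <- apply(ctrl, 1, function(g) all(g == 2L * hstar))
  expect_false(any(hom_for_hstar))
  # carriers recorded in truth at ~6% of 275
  n_car <- length(study$truth$carrier_controls)
  expect_gt(n_car, 0)
  p <- 0.06
  se <- sqrt(p * (1 - p) * 275)
  expect_lt(abs(n_car - 275 * p), 4 * se)
})

test_that("zero carrier frequency yields no carrier controls", {
  cfg <- sim_config(carrier_freq_controls = 0, n_controls = 50,
                    n_markers = 40, seed = 5)
  pop <- simulate_population(cfg)
  expect_length(pop$truth$carrier_controls, 0)
})

test_that("simulated trios are Mendelian-consistent", {
  study <- default_study()
  gm <- study$pop$geno
  ped <- study$pop$pedigree
  trios <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  ok_marker <- function(child, p1, p2) {
    # allele counts: child must draw one allele from each parent
    half <- function(g) unique(c(floor(g / 2), ceiling(g / 2)))
    any(outer(half(p1), half(p2), `+`) == child)
  }
  for (r in seq_len(nrow(trios))) {
    child <- gm$geno[trios$id[r], ]
    p1 <- gm$geno[trios$sire[r], ]
    p2 <- gm$geno[trios$dam[r], ]
    viol <- sum(!mapply(ok_marker, child, p1, p2))
    expect_equal(viol, 0)
  }
})

test_that("variant simulation plants one causal record that survives by construction", {
  study <- default_study()
  v <- study$calls$variants
  causal <- v[v$id == study$truth$causal_id, ]
  expect_equal(nrow(causal), 1)
  iv <- study$truth$interval
  expect_true(causal$pos >= iv$start && causal$pos <= iv$end)
  expect_gt(causal$qual, 100)
  expect_false(causal$in_catalog)
  expect_true(all(unlist(causal[study$calls$case_ids]) == 2L))
  expect_true(all(unlist(causal[study$calls$control_ids]) == 0L))
})

test_that("with no decoys the callset holds exactly the causal record", {
  cfg <- sim_config(n_decoy_variants = 0, n_candidate_decoys = 0,
                    n_controls = 60, n_markers = 40, seed = 3)
  pop <- simulate_population(cfg)
  calls <- simulate_variant_calls(cfg, pop)
  expect_equal(nrow(calls$variants), 1)
  expect_equal(calls$variants$id, calls$truth$causal_id)
})

test_that("junction counts follow the configured genotype-dependent fractions", {
  cfg <- sim_config(seed = 9)
  fx <- simulate_gene_fixture(seed = 9)
  wt <- simulate_junction_reads(cfg, "ref", fx, "wt")
  # wild type: no skip junction at all
  skip_j <- junction_coords(fx$model, 1, 3)
  expect_equal(lookup_count(wt, "wt", skip_j$donor_end,
                            skip_j$acceptor_start), 0L)
  q <- exon_psi(wt, fx$model, 2, "wt")
  expect_equal(q$psi, 1.0)
  expect_error(simulate_junction_reads(cfg, "carrier", fx), "genotype label")

  # aggregate over seeds: het skip fraction ~0.5, hom ~1, cryptic ~0.25
  counts <- purrr::map_dfr(1:30, function(s) {
    cfg_s <- sim_config(seed = s)
    het <- simulate_junction_reads(cfg_s, "het", fx, "het")
    hom <- simulate_junction_reads(cfg_s, "hom", fx, "hom")
    cj <- junction_coords(fx$model, 1, 3, shift = 3)
    tibble::tibble(
      het_inc = lookup_count(het, "het", junction_coords(fx$model, 1, 2)$donor_end,
                             junction_coords(fx$model, 1, 2)$acceptor_start),
      het_skip = lookup_count(het, "het", skip_j$donor_end,
                              skip_j$acceptor_start) +
        lookup_count(het, "het", cj$donor_end, cj$acceptor_start),
      hom_inc = lookup_count(hom, "hom", junction_coords(fx$model, 1, 2)$donor_end,
                             junction_coords(fx$model, 1, 2)$acceptor_start),
      hom_skip_only = lookup_count(hom, "hom", skip_j$donor_end,
                                   skip_j$acceptor_start),
      hom_cryptic = lookup_count(hom, "hom", cj$donor_end, cj$acceptor_start))
  })
  expect_equal(mean(counts$het_skip / (counts$het_skip + counts$het_inc)),
               0.5, tolerance = 0.1)
  expect_equal(sum(counts$hom_inc), 0)
  expect_equal(sum(counts$hom_cryptic) /
                 (sum(counts$hom_cryptic) + sum(counts$hom_skip_only)),
               0.25, tolerance = 0.1)
})
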