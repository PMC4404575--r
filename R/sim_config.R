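#' Synthetic-study configuration
#'
#' Holds the design constants of the simulated mapping study: a half-sib
#' population in which one founder haplotype carries a recessive lethal
#' splice variant. Defaults reproduce the structure of the motivating study:
#' 15 affected calves and 275 AI-sire controls genotyped at 324 markers over a
#' 20 Mb chromosome-10-like region, an identity-by-descent interval covering
#' 11% of the region (2.2 Mb), a 6% carrier frequency among controls, ~50%
#' exon skipping in heterozygous carriers and ~100% in homozygotes with a
#' 75/25 split between skip-only and skip-plus-cryptic isoforms, and a mean
#' junction depth of 45 reads.
#'
#' @param n_cases,n_controls Numbers of affected and control animals.
#' @param n_markers SNP-array markers simulated across the region.
#' @param region_start,region_span 1-based start and width (bp) of the region.
#' @param ibd_interval Width of the shared autozygous interval as a fraction
#'   of `region_span` (must be in (0, 1)).
#' @param carrier_freq_controls Probability that a control carries one copy of
#'   the founder haplotype (controls are never homozygous for it).
#' @param n_decoy_variants Non-causal variants simulated across the region.
#' @param n_candidate_decoys Of these, how many are planted to survive the
#'   whole filter cascade (placed inside the interval, homozygous in cases,
#'   absent from controls and catalog, but far from any splice site).
#' @param skip_fraction_het,skip_fraction_hom Fraction of transcripts skipping
#'   the fixture's exon 2 in heterozygous / homozygous mutant samples.
#' @param cryptic_fraction Fraction of aberrant (skipping) transcripts that
#'   additionally use the cryptic acceptor 3 nt into exon 3.
#' @param read_depth Mean junction reads per splice site (Poisson).
#' @param strand Strand on which the fixture gene is generated.
#' @param seed Integer master seed; per-stage streams are derived from it.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_cases = 15, n_controls = 275, n_markers = 324,
                       region_start = 70e6, region_span = 20e6,
                       ibd_interval = 0.11, carrier_freq_controls = 0.06,
                       n_decoy_variants = 3000, n_candidate_decoys = 30,
                       skip_fraction_het = 0.5, skip_fraction_hom = 1.0,
                       cryptic_fraction = 0.25, read_depth = 45,
                       strand = "-", seed = 1) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_markers = n_markers, region_start = region_start,
              region_span = region_span, ibd_interval = ibd_interval,
              carrier_freq_controls = carrier_freq_controls,
              n_decoy_variants = n_decoy_variants,
              n_candidate_decoys = n_candidate_decoys,
              skip_fraction_het = skip_fraction_het,
              skip_fraction_hom = skip_fraction_hom,
              cryptic_fraction = cryptic_fraction,
              read_depth = read_depth, strand = strand,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  err <- function(...) stop("invalid sim_config: ", ..., call. = FALSE)
  probs <- c("ibd_interval", "carrier_freq_controls", "skip_fraction_het",
             "skip_fraction_hom", "cryptic_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      err(p, " must be a probability in [0, 1]")
  }
  counts <- c("n_cases", "n_controls", "n_markers", "region_span",
              "read_depth")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      err(p, " must be positive")
  }
  for (p in c("n_decoy_variants", "n_candidate_decoys")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      err(p, " must be non-negative")
  }
  if (cfg$n_candidate_decoys > cfg$n_decoy_variants)
    err("n_candidate_decoys cannot exceed n_decoy_variants")
  if (cfg$ibd_interval <= 0 || cfg$ibd_interval >= 1)
    err("ibd_interval must lie strictly inside (0, 1): the autozygous ",
        "interval cannot be empty or wider than the region")
  if (cfg$n_markers < 10)
    err("n_markers must be at least 10 to support a window scan")
  if (!cfg$strand %in% c("+", "-")) err("strand must be '+' or '-'")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Deterministically derive a per-stage RNG seed (< 2^31) from the master seed,
# so any stage can be re-run in isolation.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 +
                sum(utf8ToInt(stage)) * 2654435) %% 2147483647)
}
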