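#' Pipeline configuration
#'
#' Bundles every threshold of the pipeline with the simulation design, and
#' round-trips through YAML unchanged so a run is fully described by one
#' file. Thresholds: variant quality strictly above `qual_min`; junction
#' anchors of at least `anchor_min` nt; skip calls need `min_reads`
#' informative reads and PSI below `psi_max_normal`; cryptic acceptors are
#' searched within `max_shift` nt; an acceptor is disrupted at a score drop
#' of `disrupt_threshold`; candidates link to events within `max_link_bp`;
#' the haplotype scan uses `window_size` markers.
#'
#' @param sim A [sim_config()] (or a named list of its fields).
#' @param qual_min,anchor_min,min_reads,psi_max_normal,max_shift
#'   See description.
#' @param disrupt_threshold,max_link_bp,window_size See description.
#' @param seed Master seed (defaults to the simulation seed).
#' @param verbosity 0 = quiet, 1 = progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qual_min = 100,
                            anchor_min = 8, min_reads = 10,
                            psi_max_normal = 0.8, max_shift = 10,
                            disrupt_threshold = 1 / 24, max_link_bp = 50,
                            window_size = 20, seed = NULL,
                            verbosity = 1) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  cfg <- list(sim = sim, qual_min = qual_min, anchor_min = anchor_min,
              min_reads = min_reads, psi_max_normal = psi_max_normal,
              max_shift = max_shift, disrupt_threshold = disrupt_threshold,
              max_link_bp = max_link_bp, window_size = window_size,
              seed = as.integer(seed %||% sim$seed),
              verbosity = verbosity)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  err <- function(...) stop("invalid pipeline_config: ", ..., call. = FALSE)
  if (cfg$qual_min < 0) err("qual_min must be >= 0")
  if (cfg$anchor_min < 1) err("anchor_min must be >= 1")
  if (cfg$min_reads < 1) err("min_reads must be >= 1")
  if (cfg$psi_max_normal <= 0 || cfg$psi_max_normal > 1)
    err("psi_max_normal must be in (0, 1]")
  if (cfg$max_shift < 1) err("max_shift must be >= 1")
  if (cfg$disrupt_threshold <= 0 || cfg$disrupt_threshold > 1)
    err("disrupt_threshold must be in (0, 1]")
  if (cfg$max_link_bp < 0) err("max_link_bp must be >= 0")
  if (cfg$window_size < 2) err("window_size must be >= 2")
  invisible(cfg)
}

#' Write and read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), x))
}

#' Run the whole pipeline on a simulated study
#'
#' Executes the full discovery sequence: simulate the study, map the shared
#' homozygous interval among cases (plus the haplotype-sharing scan), filter
#' the variant calls through the candidate cascade, detect aberrant splicing
#' in the mutant RNA samples, score candidate effects on the acceptor, link
#' candidates to events and rank them, and compute the population assay
#' statistics. Fully deterministic for a given configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory: writes `summary.json`,
#'   `interval.bed`, `scan_track.tsv`, `events.json` and `ranked.tsv`.
#' @return A list of class `pipeline_result`: `interval`, `scan`, `filter`
#'   (a `filter_report`), `events`, `ranked`, `assay` (list: `concordance`,
#'   `carrier`, `deficit`), `top_candidate`, `truth`, `summary` (the
#'   JSON-ready list).
#' @export
run_all <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbosity > 0) message(...)

  say("simulating study ...")
  study <- simulate_study(config$sim)
  gm <- study$pop$geno
  cases <- gm_subset(gm, study$truth$case_ids)
  controls <- gm_subset(gm, study$truth$control_ids)

  say("mapping shared homozygous interval ...")
  interval <- find_shared_homozygous_segment(cases)
  if (nrow(interval) == 0L)
    stop("no shared homozygous segment found among cases", call. = FALSE)
  scan <- haplotype_sharing_scan(cases, controls,
                                 window_size = config$window_size)

  say("filtering variant calls ...")
  rep_ <- filter_cascade(study$calls$variants, interval,
                         case_ids = study$calls$case_ids,
                         control_ids = study$calls$control_ids,
                         qual_min = config$qual_min)

  say("detecting splice events ...")
  fixture <- study$fixture
  events <- dplyr::bind_rows(
    detect_events(study$junctions, fixture$model, "rna_case",
                  ref = fixture$ref, min_reads = config$min_reads,
                  psi_max_normal = config$psi_max_normal,
                  max_shift = config$max_shift),
    detect_events(study$junctions, fixture$model, "rna_carrier",
                  ref = fixture$ref, min_reads = config$min_reads,
                  psi_max_normal = config$psi_max_normal,
                  max_shift = config$max_shift))

  say("ranking candidates ...")
  ranked <- link_and_rank(rep_$candidates, events, fixture$model,
                          ref = fixture$ref,
                          max_link_bp = config$max_link_bp)
  top <- if (nrow(ranked)) ranked[1, ] else NULL

  say("computing assay statistics ...")
  assay_tbl <- simulate_assay_table(
    n_population = 10000,
    carrier_prob = config$sim$carrier_freq_controls,
    n_cases = config$sim$n_cases, n_parents = 21,
    seed = config$seed)
  conc <- concordance_check(assay_tbl)
  carr <- carrier_frequency(assay_tbl)
  defi <- deficit_homozygote_test(carr$n, carr$het, carr$hom)

  summary <- list(
    seed = config$seed,
    interval = list(chrom = interval$chrom, start = interval$start,
                    end = interval$end, length_mb = interval_length_mb(interval)),
    scan = list(best_start = scan$best$start, best_end = scan$best$end,
                best_p = scan$best$p, threshold = scan$threshold,
                significant = scan$significant),
    filter_stages = stats::setNames(as.list(rep_$stages$n),
                                    rep_$stages$stage),
    n_events = nrow(events),
    event_types = as.list(table(events$type)),
    top_candidate = if (is.null(top)) NULL else
      list(id = top$id, chrom = top$chrom, pos = top$pos,
           ref = top$ref, alt = top$alt, linked = top$linked,
           disrupts_acceptor = top$disrupts_acceptor),
    causal_recovered = !is.null(top) &&
      identical(top$id, study$truth$causal_id),
    assay = list(checked = conc$checked,
                 violations = nrow(conc$violations),
                 carrier_freq = carr$carrier_freq,
                 deficit_p = defi$p_value)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    interval_to_bed(interval, file.path(outdir, "interval.bed"))
    readr::write_tsv(scan$track, file.path(outdir, "scan_track.tsv"))
    jsonlite::write_json(events, file.path(outdir, "events.json"),
                         dataframe = "rows", pretty = TRUE, digits = NA)
    readr::write_tsv(ranked, file.path(outdir, "ranked.tsv"))
  }

  structure(list(interval = interval, scan = scan, filter = rep_,
                 events = events, ranked = ranked, fixture = fixture,
                 assay = list(concordance = conc, carrier = carr,
                              deficit = defi),
                 top_candidate = top, truth = study$truth,
                 summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  interval: %s:%s-%s (%.1f Mb)\n", s$interval$chrom,
              format(s$interval$start, scientific = FALSE),
              format(s$interval$end, scientific = FALSE),
              s$interval$length_mb))
  cat(sprintf("  candidates after cascade: %d\n",
              utils::tail(unlist(s$filter_stages), 1)))
  cat(sprintf("  splice events: %d\n", s$n_events))
  if (!is.null(s$top_candidate))
    cat(sprintf("  top candidate: %s at %s:%s\n", s$top_candidate$id,
                s$top_candidate$chrom,
                format(s$top_candidate$pos, scientific = FALSE)))
  cat(sprintf("  assay: carrier freq %.4f, deficit p %.3g\n",
              s$assay$carrier_freq, s$assay$deficit_p))
  invisible(x)
}
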