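#' Recessive-model concordance of a diagnostic assay
#'
#' Under a fully penetrant recessive model every affected animal must be
#' homozygous for the mutant allele and every parent of an affected animal an
#' obligate heterozygous carrier. Flags every case that is not `AA` and every
#' parent that is not `RA`.
#'
#' @param table Assay tibble: columns `id`, `role` (`case` / `parent` /
#'   `population`), `genotype` (`RR` / `RA` / `AA` / `missing`; R =
#'   reference, A = mutant allele).
#' @return A list of class `concordance_report`: `checked` (cases + parents
#'   with a genotype call), `n_cases`, `n_parents`, `violations` (tibble
#'   `id`, `role`, `genotype`, `expected`), `note`.
#' @export
concordance_check <- function(table) {
  table <- validate_assay_table(table)
  cases <- table[table$role == "case" & table$genotype != "missing", ]
  parents <- table[table$role == "parent" & table$genotype != "missing", ]
  bad_case <- cases[cases$genotype != "AA", ]
  bad_parent <- parents[parents$genotype != "RA", ]
  violations <- dplyr::bind_rows(
    if (nrow(bad_case))
      tibble::tibble(id = bad_case$id, role = "case",
                     genotype = bad_case$genotype, expected = "AA"),
    if (nrow(bad_parent))
      tibble::tibble(id = bad_parent$id, role = "parent",
                     genotype = bad_parent$genotype, expected = "RA")
  )
  if (is.null(violations))
    violations <- tibble::tibble(id = character(0), role = character(0),
                                 genotype = character(0),
                                 expected = character(0))
  checked <- nrow(cases) + nrow(parents)
  note <- if (checked == 0)
    "no case or parent genotypes to check" else NA_character_
  structure(list(checked = checked, n_cases = nrow(cases),
                 n_parents = nrow(parents), violations = violations,
                 note = note),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d genotypes checked (%d cases, %d parents), %d violation(s)\n",
              x$checked, x$n_cases, x$n_parents, nrow(x$violations)))
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

validate_assay_table <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("id", "role", "genotype") %in% names(table)))
  bad_role <- setdiff(unique(table$role), c("case", "parent", "population"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  bad_gt <- setdiff(unique(table$genotype), c("RR", "RA", "AA", "missing"))
  if (length(bad_gt))
    stop("unknown genotype(s): ", paste(bad_gt, collapse = ", "),
         call. = FALSE)
  table
}

#' Carrier frequency in the genotyped population
#'
#' Fraction of population samples heterozygous for the mutant allele
#' (homozygous mutants are not carriers). Missing genotypes are excluded
#' from the denominator.
#'
#' @param table Assay tibble (see [concordance_check()]).
#' @param population_role_only Restrict to `role == "population"` (default);
#'   otherwise all samples are used.
#' @return A one-row tibble: `n`, `het`, `hom`, `carrier_freq`.
#' @export
carrier_frequency <- function(table, population_role_only = TRUE) {
  table <- validate_assay_table(table)
  if (population_role_only) table <- table[table$role == "population", ]
  table <- table[table$genotype != "missing", ]
  if (nrow(table) == 0)
    stop("no genotyped population samples", call. = FALSE)
  het <- sum(table$genotype == "RA")
  hom <- sum(table$genotype == "AA")
  tibble::tibble(n = nrow(table), het = het, hom = hom,
                 carrier_freq = het / nrow(table))
}

#' Exact deficit-of-homozygotes test
#'
#' The signature of a recessive lethal in a healthy population is a deficit
#' of mutant homozygotes relative to Hardy-Weinberg expectation. With the
#' plug-in allele frequency `q = (het + 2 hom) / 2n`, the expected number of
#' homozygotes is `n q^2`; the test is the exact lower-tail binomial
#' probability `P(X <= hom)` with `X ~ Binomial(n, q^2)`. A mid-p variant
#' (`P(X < hom) + P(X = hom)/2`) is available behind a flag.
#'
#' @param n Population samples genotyped.
#' @param het,hom Observed heterozygote and mutant-homozygote counts.
#' @param midp Use the mid-p correction.
#' @return An object of class `hwe_deficit`: list with `n`, `het`, `hom`,
#'   `q_hat`, `expected_hom`, `p_value`.
#' @export
deficit_homozygote_test <- function(n, het, hom, midp = FALSE) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (het + hom > n) stop("het + hom cannot exceed n", call. = FALSE)
  q <- (het + 2 * hom) / (2 * n)
  p2 <- q^2
  p <- if (midp) {
    stats::pbinom(hom - 1, n, p2) + stats::dbinom(hom, n, p2) / 2
  } else {
    stats::pbinom(hom, n, p2)
  }
  structure(list(n = as.integer(n), het = as.integer(het),
                 hom = as.integer(hom), q_hat = q, expected_hom = n * p2,
                 p_value = p, midp = midp),
            class = "hwe_deficit")
}

#' @export
print.hwe_deficit <- function(x, ...) {
  cat(sprintf(
    "<hwe_deficit> n=%d het=%d hom=%d; q=%.4f, expected hom=%.2f, p=%.4g%s\n",
    x$n, x$het, x$hom, x$q_hat, x$expected_hom, x$p_value,
    if (x$midp) " (mid-p)" else ""))
  invisible(x)
}

#' @rdname deficit_homozygote_test
#' @param x A `hwe_deficit`.
#' @param ... Unused.
#' @export
tidy.hwe_deficit <- function(x, ...) {
  tibble::tibble(n = x$n, het = x$het, hom = x$hom, q_hat = x$q_hat,
                 expected_hom = x$expected_hom, p_value = x$p_value)
}

#' @rdname deficit_homozygote_test
#' @export
glance.hwe_deficit <- function(x, ...) tidy.hwe_deficit(x)

#' Simulate an assay table for a genotyped population
#'
#' Draws population genotypes with carrier probability `carrier_prob` (and no
#' mutant homozygotes, emulating a recessive lethal), plus optional fully
#' concordant cases and parents.
#'
#' @param n_population Population samples.
#' @param carrier_prob Per-sample probability of being a carrier.
#' @param n_cases,n_parents Concordant cases (`AA`) and parents (`RA`).
#' @param seed Integer seed.
#' @return An assay tibble `id`, `role`, `genotype`.
#' @export
simulate_assay_table <- function(n_population = 10000, carrier_prob = 0.06,
                                 n_cases = 25, n_parents = 21, seed = 1) {
  withr::with_seed(derive_seed(seed, "assay"), {
    pop_gt <- ifelse(stats::runif(n_population) < carrier_prob, "RA", "RR")
    dplyr::bind_rows(
      tibble::tibble(id = sprintf("case%02d", seq_len(n_cases)),
                     role = "case", genotype = "AA"),
      tibble::tibble(id = sprintf("parent%02d", seq_len(n_parents)),
                     role = "parent", genotype = "RA"),
      tibble::tibble(id = sprintf("pop%05d", seq_len(n_population)),
                     role = "population", genotype = pop_gt)
    )
  })
}
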