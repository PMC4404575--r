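# Shared test fixtures and independent oracles.

# Small plus-strand gene for hand-checkable coordinate arithmetic:
# exons chrT:101-150, 201-260, 301-340 (tx length 150), CDS tx 11-130.
tiny_model <- function(strand = "+") {
  if (strand == "+") {
    ex <- tibble::tibble(gstart = c(101, 201, 301),
                         gend = c(150, 260, 340))
  } else {
    ex <- tibble::tibble(gstart = c(301, 201, 101),
                         gend = c(340, 260, 150))
  }
  gene_model("tiny", "chrT", strand, ex, cds_start = 11, cds_end = 130)
}

# Deterministic reference for tiny_model: repeatable pseudo-random bases.
tiny_ref <- function(seed = 11) {
  withr::with_seed(seed, {
    ref_window("chrT", 1, paste(sample(c("A", "C", "G", "T"), 500,
                                       replace = TRUE), collapse = ""))
  })
}

# Genotype matrix from a literal sample-by-marker matrix on one chromosome,
# markers at 1 kb spacing.
make_gm <- function(m, chrom = "chr1", pos = NULL, role = "unknown") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(pos)) pos <- 1000 * seq_len(ncol(m))
  map <- tibble::tibble(marker_id = sprintf("m%03d", seq_len(ncol(m))),
                        chrom = chrom, pos = pos, ref = "A", alt = "B")
  genotype_matrix(m, map,
                  tibble::tibble(sample_id = rownames(m), role = role))
}

# Brute-force oracle for the shared-homozygous-segment finder: enumerate
# every marker run and keep the longest (leftmost on ties) where each marker
# has all cases homozygous for one shared allele (missing compatible, not
# all missing).
brute_shared_segment <- function(geno, pos, chrom = "chr1") {
  m <- ncol(geno)
  marker_ok <- function(j) {
    col <- geno[, j]
    obs <- col[!is.na(col)]
    length(obs) > 0 && all(obs %in% c(0, 2)) && length(unique(obs)) == 1
  }
  okv <- vapply(seq_len(m), marker_ok, logical(1))
  best <- NULL
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (all(okv[i:j])) {
        len <- j - i + 1
        if (is.null(best) || len > best$len) best <- list(i = i, j = j,
                                                          len = len)
      }
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_markers = integer(0)))
  }
  tibble::tibble(chrom = chrom, start = pos[best$i], end = pos[best$j],
                 n_markers = best$len)
}

# Brute-force CIGAR interpreter: walks the CIGAR base by base and reports
# every N gap with its flanking aligned-run lengths.
brute_cigar_junctions <- function(pos, cigar, anchor_min = 8) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ops <- substr(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substr(toks, 1, nchar(toks) - 1))
  ref <- pos
  runs <- c(0)           # aligned-run lengths between gaps
  gaps <- list()
  for (t in seq_along(ops)) {
    if (ops[t] %in% c("M", "=", "X")) {
      runs[length(runs)] <- runs[length(runs)] + lens[t]
      ref <- ref + lens[t]
    } else if (ops[t] == "D") {
      ref <- ref + lens[t]
    } else if (ops[t] == "N") {
      gaps[[length(gaps) + 1]] <- list(donor_end = ref - 1,
                                       acceptor_start = ref + lens[t],
                                       left = runs[length(runs)])
      runs <- c(runs, 0)
      ref <- ref + lens[t]
    }
  }
  out <- list()
  for (g in seq_along(gaps)) {
    right <- runs[g + 1]   # aligned run between gap g and the next gap/end
    if (gaps[[g]]$left >= anchor_min && right >= anchor_min) {
      out[[length(out) + 1]] <- tibble::tibble(
        donor_end = gaps[[g]]$donor_end,
        acceptor_start = gaps[[g]]$acceptor_start)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(donor_end = numeric(0), acceptor_start = numeric(0)))
  }
  dplyr::bind_rows(out)
}

# One cached default-scale simulated study shared across test files (built
# once per test run; generation is seeded and deterministic).
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 101))
    cache
  }
})
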