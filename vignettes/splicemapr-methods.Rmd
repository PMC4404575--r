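---
title: "Methods: mapping a recessive splice-disrupting variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a recessive splice-disrupting variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemapr)
```

`splicemapr` formalises, as a tested pipeline, the discovery chain for a
recessive lethal splice mutation segregating from an elite founder in a
closed livestock population. This vignette is the package's own account of
the models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where several conventions were defensible.

## The genetic model

Affected animals in such a population are *autozygous* at the causal locus:
both chromosomes descend from the founder's mutant haplotype, one directly
through the sire path and one through carrier dams that are themselves
daughters of the same sire. Two consequences drive the design:

* every case is homozygous for one shared marker haplotype across a
  megabase-scale interval around the mutation, while controls rarely are;
* healthy carriers are common (several percent), but mutant homozygotes are
  absent from the living population — a *deficit of homozygotes* relative
  to Hardy–Weinberg expectation.

## Stage 1 — autozygosity mapping

`find_shared_homozygous_segment()` returns the longest run of consecutive
markers at which every case is homozygous *and* all cases carry the same
homozygous allele. Unphased genotypes suffice: when all cases must be
homozygous, the shared haplotype is readable directly from the shared
homozygous allele, so no phasing step is required. Conventions, each chosen
for determinism and testability against a brute-force enumeration oracle:

* a missing call is treated as compatible with homozygosity, but a marker
  with no informative call does not qualify;
* ties in run length break to the leftmost start;
* the interval is reported at the outermost qualifying markers (not at
  midpoints between markers), so its measured width is shortened by up to a
  marker gap on each side relative to the underlying IBD segment. At the
  default marker density (324 markers / 20 Mb, mean gap ≈ 62 kb) the
  measured width of a 2.2 Mb segment typically rounds to 2.2 Mb but can
  lose a few hundred kb when a sparse gap abuts a boundary — visible in
  some seeds of the end-to-end suite, and a property of array resolution,
  not of the finder;
* interval lengths are quoted as `(end − start)/10^6` rounded to one
  decimal, the convention used when stating intervals like "2.2 Mb".

`haplotype_sharing_scan()` complements the finder with a significance
track. The population-scale analysis this substitutes for is a generalized
mixed-model score test; re-implementing that estimator is out of scope
here, and the scan instead tests, per sliding window of `window_size = 20`
markers, whether all cases are homozygous for one shared window haplotype,
and if so compares the case haplotype-homozygote count against the control
count with a one-sided Fisher exact test. Bonferroni adjustment over
windows matches the conservative "genome-wide significant" language of
array-era mapping. A window fails if more than 5% of its case calls are
missing. The null behaviour (no significant window in almost all null simulations)
is enforced by test, exploiting the conservativeness of Fisher +
Bonferroni.

## Stage 2 — the variant filter cascade

`filter_cascade()` applies five set-intersection filters in a fixed order
(the order affects per-stage counts, not the final set, which the tests
verify by permutation): interval membership; quality strictly greater than
`qual_min = 100` (strict, so a variant at exactly the threshold is
dropped); homozygous-alternate in every case; alternate allele absent from
every control genotype; absence from the known-variant catalog. Two
conventions deserve note:

* catalog matching requires chrom + pos + ref + alt identity — a novel
  allele at a known site is *not* filtered;
* a missing case genotype fails the homozygosity stage (an explicit
  hom-alt call is required — stricter than a low-coverage pooled analysis,
  where missingness at ~2.5× per genome is tolerated silently), while a
  missing control genotype is not an observation of the allele and passes.

`classify_consequence()` assigns the SNV taxonomy (missense / nonsense /
synonymous by codon comparison, UTR, intronic with signed distance to the
nearest junction — intronic side negative — and `canonical_splice_region`
within 3 bp on the intronic side). Indels are flagged as a distinct class
rather than forced into the SNV taxonomy.

### HGVS-style c. anchors

`parse_hgvs_c()` accepts `c.<pos>[±<offset>]<ref>><alt>` with the dot
optionally omitted, as such designations are often printed in assay
reports. Positions are numbered **along the spliced transcript** (the
packaged fixture carries a 30-nt 5'UTR, so c.1 is the transcription start,
not the ATG). This convention was chosen because the package's anchors are
resolved purely through the gene model's transcript coordinate map, and it
makes the fixture's causal designation `c.211-10C>G` anchor exactly at the
first base of exon 2 with a 10-bp intronic offset; strict HGVS numbering
from the translation start would be an alternative convention, differing by
the 5'UTR length. The parser validates that intronic offsets stay inside
the adjoining intron, and `format_hgvs_c()` inverts the mapping (the
round trip is property-tested across the gene span).

## Stage 3 — splice-event detection

Only junction reads are used — no exon-body coverage — because the
discriminating evidence for skipping is the gapped alignment itself.
`extract_junctions()` walks each CIGAR from POS; every `N` gap flanked by
aligned runs of at least `anchor_min = 8` nt contributes one count to the
junction `(donor_end, acceptor_start)`, both 1-based flanking exonic bases
on the forward genome axis (strand-agnostic, as alignments are).

For an internal exon, `exon_psi()` counts inclusion as the *average* of the
two flanking inclusion junctions, rounded half up — each included
transcript produces two inclusion junctions, so summing would double-count
it; averaging keeps the 25-inclusion / 20-skip worked example exact. The
skip count sums junctions joining the neighbouring exons directly,
*including* acceptor-shifted variants of the skip junction within
`max_shift = 10` nt, since those isoforms also omit the exon. PSI is
inclusion / (inclusion + skip).

`detect_events()` reports an exon-skip when PSI falls below
`psi_max_normal = 0.8` with at least `min_reads = 10` informative reads,
and a cryptic acceptor for any junction sharing an annotated donor whose
acceptor is shifted by up to `max_shift` nt, supported by at least
`min_cryptic_reads = 2` reads (a lower bar than the skip call, because a
minor isoform at ~25% of ~50% of depth may carry only a handful of reads;
single-read junctions are ignored as likely alignment noise). Each cryptic
call is annotated with a strand-aware sequence check that the transcribed
strand carries `AG` immediately 5' of the new acceptor.

`insilico_rtpcr()` predicts what a primer pair amplifies from an isoform's
cDNA: the distance between primer outer ends along the isoform transcript,
with an explicit no-product result when a primer site is skipped or
trimmed. On the packaged fixture the wild-type, exon-2-skip and
skip-plus-cryptic products are 593, 377 and 374 bp.

## Stage 4 — acceptor scoring and conservation

The acceptor window spans positions −20…+3 on the transcribed strand
(+1 = first exonic base). The score is deliberately transparent rather than
a trained position-weight or maximum-entropy model (no training data ships
with the package, and trained splice models are out of scope): the fraction
of pyrimidines across tract positions −16…−5, multiplied by a hard gate on
the invariant `AG` at −2/−1, with `N` counted as a purine. The design makes
effects exact and monotone: any single tract pyrimidine→purine substitution
changes the score by exactly −1/12, substitutions outside the tract and the
AG change nothing, and AG loss zeroes the score. `variant_acceptor_delta()`
flags disruption at `delta ≤ −disrupt_threshold` (default 1/24, half a
tract position — any real tract hit exceeds it) or AG loss.

`conservation_fraction()` counts species matching the reference base at an
alignment column; gaps are excluded from the denominator by default (a
documented `gap_as_mismatch` flag counts them against conservation). The
packaged 27-taxon alignment under `inst/extdata/` is synthetic — built to
exhibit the 26-of-27 conservation pattern at the −10 tract column that
motivates the causal call — and is labelled as such in its filename; it
replicates the count, not any real species set.

## Stage 5 — prioritization and protein effect

No single rule in the source analysis links DNA candidates to RNA events —
that step was expert inspection. `link_and_rank()` formalises it as a
deterministic lexicographic order: linked (within `max_link_bp = 50` of a
splice site of an event's affected exon) before unlinked; acceptor-
disrupting before not; smaller distance; genomic position as final
tie-break. A lexicographic order was preferred over a weighted score
because every comparison is testable and no weights need justification.

`protein_effect()` maps the skipped exon's coding nucleotides to deleted
residues with explicit codon phase: a residue is deleted when any of its
codon's nucleotides are removed. The fixture is phased so exon 2 (216 nt,
coding positions 181–396, codon-aligned) deletes residues 61–132 — 72
residues of the 188-residue protein, 116 remaining — an in-frame deletion
that removes the second transmembrane helix entirely (18-residue overlap
with TM2 at 60–78) plus the start of the cytoplasmic tail. Note that a
216-nt in-frame deletion removes 71 or 72 codons whatever the phase;
published descriptions of comparable events sometimes quote a slightly
smaller range, which cannot arise from this arithmetic and is reproduced
here only in its anchor (deletion starting at residue 61).

## Stage 6 — assay statistics

`deficit_homozygote_test()` uses the plug-in allele frequency
`q̂ = (het + 2·hom)/2n` and the exact lower-tail binomial probability
`P(X ≤ hom)`, `X ~ Bin(n, q̂²)`. It is simple, stated, and reproducible
from published counts; a mid-p variant sits behind a flag. At the package's
default population scale (n = 10,000, 6% carriers, zero homozygotes) the
closed form `(1 − q̂²)^n` gives p ≈ 1.2 × 10⁻⁴. Null super-uniformity at
the 5% level and monotonicity in `n` are enforced by test.

## The synthetic-data generator

`simulate_study()` generates every input the pipeline consumes, from one
seed, under the study design the pipeline assumes:

* **Population**: one carrier sire; each case is produced by the sire and
  one of his carrier daughters, so the founder haplotype reaches the case
  on both paths. 15 cases, 275 unrelated controls carrying the haplotype
  with probability 0.06 and never homozygous. 324 markers over a 20 Mb
  region with the 2.2 Mb IBD interval centred in it (fraction 0.11).
* **Haplotype model**: markers are fully linked inside the IBD segment;
  recombination occurs only at segment boundaries, with uniform overhangs
  of at most 2% of the region per transmission, so the intersection of the
  cases' homozygous segments closely matches the configured interval.
  Founder haplotypes are independent Bernoulli draws per marker (allele
  frequencies uniform on 0.1–0.9) — deliberately free of background
  linkage disequilibrium.
* **Variant calls**: 3,000 decoys across the region (random genotypes,
  20% at quality ≤ 100, 30% in the synthetic catalog), of which 30 planted
  "candidate decoys" survive the whole cascade but sit > 1 kb from the
  gene — so the cascade leaves 31 candidates including the causal variant,
  the load the downstream linking step must disambiguate. One causal
  variant: the fixture's intron-1 C>G at acceptor offset −10 (on the
  genomic plus strand of the default minus-strand fixture: G>C).
* **Junctions**: Poisson counts at mean depth 45 per junction; mutant
  transcripts skip exon 2 with fraction 0.5 (het) or 1.0 (hom); skipping
  transcripts use the +3 cryptic acceptor with fraction 0.25. An optional
  SAM emitter writes one 20M-gap-20M alignment per read for the junction
  extractor to consume.
* **Gene fixture**: four exons (210/216/150/200 nt) on the minus strand by
  default (a plus-strand flag mirrors the whole construction, and the test
  suite asserts strand symmetry), introns 400/300/350 nt, 30-nt 5'UTR,
  567-nt CDS; exon 3 starts with the lysine codon AAG whose 3' AG acts as
  the cryptic acceptor; all acceptors carry an all-pyrimidine −16…−5 tract;
  primers at transcript 21–40 and 594–613 give the 593/377/374 bp products.
  Exon-1/3/4 lengths, intron lengths and the decoy quality mix are free
  parameters fixed once at values typical for a compact mammalian gene.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: background LD and realistic allele-frequency
spectra, recombination maps, genotyping and sequencing error, base-level
read simulation, multi-gene transcriptomes, and partial penetrance. The
recovery suites show the pipeline is correct under its own model, not that
the model captures every failure mode of array and short-read data.

## Reference sequence convention

Sequence is exchanged as a *region FASTA*: a single record named
`chrom:start-end` (the `samtools faidx` region convention), wrapped as a
`ref_window` object carrying its genomic offset. This lets a ~2 kb gene at
a ~80 Mb coordinate travel without a chromosome-length file; all sequence
lookups are strand-aware through this window.

## Seeds and determinism

Every stochastic stage derives its own RNG stream from the master seed
(`derive_seed()`), so any stage can be re-run in isolation and a
configuration fully determines every output, byte for byte. All seeds stay
below 2³¹.

## Problem sizes in the test suite

The suite runs the full default-scale study (324 markers × 321 individuals,
3,001 variants) for the worked-example checks; oracle equivalence for the
segment finder uses randomized instances up to 200 markers × 20 samples;
the null-scan suite runs 100 seeds at 100 markers (12 cases / 80 controls);
PSI monotonicity uses 50 planted skip fractions; truth recovery runs the
complete pipeline over 20 seeds; the deficit-test null uses 1,000
simulations at n = 400. These sizes were chosen so each property is
exercised well past its edge cases while the whole suite stays comfortably
interactive.

## Known limitations

* The haplotype-sharing scan is a conservative substitute for a mixed-model
  score test; its p-values are not comparable to published mixed-model
  peaks, only its qualitative output (a single significant interval) is.
* The acceptor score is untrained; it orders variants within the tract
  correctly by construction but does not predict splicing efficiency.
* Junction-based PSI ignores exon-body and paired-end evidence; transcript
  assembly and quantification are out of scope.
* The consequence classifier handles single-nucleotide substitutions;
  indels are flagged, not interpreted.
* BAM/CRAM, tabix indexing and dbSNP-scale catalogs are out of scope; the
  SAM dialect is the minimal text form the junction extractor needs.
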