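---
title: "Mapping HERV-K (HML-2) integration sites from LTR-targeted enrichment reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping HERV-K (HML-2) integration sites from LTR-targeted enrichment reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrmapr)
library(dplyr)
```

## The problem

HERV-K (HML-2) is the youngest and best-preserved group of human
endogenous retroviruses. Its elements persist either as proviruses
(5'LTR–gag/pol/env–3'LTR) or as solo LTRs left behind by
inter-LTR recombination, and a subset of integrations is insertionally
polymorphic: present in some individuals and absent (pre-integration
state) in others. Because the elements are highly similar to one another,
mapping *which* genomic locus a sequencing read comes from is the central
difficulty.

`ltrmapr` implements the bioinformatic workflow of a PCR-based
LTR-targeted enrichment protocol. Libraries are built by random
fragmentation, linker ligation, and suppression + nested PCR with primers
anchored near the LTR termini, so that sequenced molecules span an
LTR/host-genome junction. The pipeline recovers those junctions, assigns
them to a catalog of known integration loci, discovers novel loci, and
tests for insertional polymorphism between individuals. A full protocol
simulator generates synthetic genomes, genotypes and reads with ground
truth, so every stage is testable at desk scale without any download.

## Pipeline model

Per sample the stages are:

1. **Read preparation** — sliding-window quality trimming, sequence-level
   PCR-duplicate removal, and overlap merging of read pairs. The stage
   order (deduplicate, then merge) follows the enrichment protocol's
   published pipeline; a `dedup_first = FALSE` switch provides the more
   common merge-first order. Duplicates are defined by exact sequence
   identity of the pair because deduplication happens before any
   alignment exists.
2. **Chimera detection** — each read is screened against 20-bp "baits"
   (the first and last 20 bases of each LTR subtype consensus, forward
   and reverse complement) by ungapped sliding-window identity with a 90%
   acceptance threshold: at 20 bp this admits at most 2 mismatches, and
   an `N` never matches. The host flank is cut at the bait boundary,
   normalised to read 5'→3' *away* from the junction (so a read and its
   reverse complement give the same flank, and the ligated linker is
   always a flank suffix), the linker remnant is stripped (longest
   suffix/prefix overlap of at least 6 nt with ≤ 10% mismatches), and
   flanks shorter than 10 nt are abandoned. Finally, flanks with a local
   match to any catalogued HML-2 sequence at ≥ 90% identity over ≥ 20 nt
   are removed — these are the LTR–gag / LTR–env amplicons that arise
   because a provirus's inner LTR ends also carry primer sites.
3. **Flank mapping** — an exact-k-mer-seeded (k = 15), ungapped aligner
   enumerates all placements within a 6% mismatch allowance and keeps a
   flank only when exactly one best-scoring placement exists. Uniqueness
   is strict: a second placement at the same score disqualifies the
   flank. Real-genome runs can bypass the internal aligner entirely and
   import SAM produced by any external aligner; there, MAPQ > 0 plus
   not-secondary is the documented uniqueness proxy.
4. **Locus calling** — the junction coordinate (the flank edge adjacent
   to the LTR) is compared against the catalog: a junction within 10 nt
   of a record's interval increments that locus (nearest edge wins; exact
   ties go deterministically to the lower-coordinate locus and are
   counted). Per-locus abundance is reported as counts per million (CPM)
   with the library size defined as the number of uniquely mapped flanks
   after all filters, which makes CPM invariant to raw sequencing depth;
   a locus is "detected" with one read and passes the stringent filter at
   CPM ≥ 50 (a locus at exactly 50 passes). Unassigned junctions are
   clustered (single linkage, 50-nt gap); clusters of ≥ 2 reads farther
   than 2 kb from every catalog record are novel-locus candidates, while
   clusters between 10 nt and 2 kb stay ambiguous.
5. **Novel-locus classification** — a candidate supported on both flank
   sides whose right-of-flank and left-of-flank junctions differ by 1–10
   bases records that interval as the target-site duplication (TSD) and
   is a non-reference insertion; the TSD is reported 1-based inclusive to
   match how such footprints are printed. A candidate that instead
   overlaps an annotated-but-uncatalogued LTR interval (when a track is
   supplied) is a novel reference locus, and the two single-ended
   clusters at the ends of one element merge into a single call. Anything
   else remains ambiguous.
6. **Polymorphism calling** — for each pair of individuals and each
   locus, replicate counts are summed and tested with a conditional
   binomial exact test: conditional on the total `t = ya + yb`, `ya` is
   Binomial(t, Na/(Na+Nb)) under the null of equal relative abundance,
   and the two-sided p sums all outcomes no more likely than the observed
   one. This is the dispersion-to-zero limit of the negative-binomial
   exact tests used by count-based differential-abundance packages; at
   the extreme significance threshold used here the two agree on
   presence/absence calls, which is the use case. A locus is polymorphic
   when the CPM fold change (max/min of per-individual means) exceeds 20
   **and** p < 1e-10. No multiple-testing correction is applied: the
   method uses fixed thresholds, not an FDR procedure. A pseudocount of
   0.5 per replicate count keeps fold changes finite — absent loci
   attract a few stray reads rather than none in real data, but that
   finiteness must be structural in a simulation.

## What the simulator emulates

`sim_insertions()`, `design_experiment()`, `build_genome()` and
`simulate_reads()` model the wet-lab phase:

* diploid individuals with per-locus genotypes (fixed loci homozygous in
  everyone; polymorphic loci drawn from an allele frequency with at least
  one discordant pair guaranteed);
* insertion structure: each present element is planted with a
  target-site duplication (6 bp by default), proviruses as
  LTR–internal–LTR, both LTR copies accumulating independent point
  mutations at `ltr_mutation_rate_per_mya × age`;
* the three LTR subtypes as divergent copies of one ancestral consensus
  (LTR5_Hs 1%, LTR5A 6%, LTR5B 12% divergence), which is the mechanism
  behind the observed detection bias toward recent integrations: the
  suppression-PCR primers are taken from the ancestral consensus, so
  older and more diverged elements accumulate primer-site mismatches and
  are down-weighted by a logistic amplification curve
  `w = 1/(1 + exp(k(m - m0)))` with defaults `k = 2`, `m0 = 3`;
* library construction: on-target molecules are
  `[42 terminal LTR bases][host or internal flank][25-mer linker]`,
  size-selected to 250–450 bp and read as a PE150 pair; a provirus emits
  both host-junction and internal (LTR–gag / LTR–env) amplicons; 20% of
  molecules are off-target background fragments; a configurable fraction
  of emitted pairs are PCR re-emissions of the same molecule; sequencing
  errors are flat-rate substitutions at constant quality;
* repeat-embedded insertions: the 4-kb flank context of designated loci
  is copied to two other genomic locations, so their junction flanks
  cannot map uniquely — reproducing the known failure mode that elements
  inside repeats are lost at the unique-mapping filter.

Read names carry truth tags after a reserved `::` separator, so every
simulated read is traceable to its (insertion, LTR end) of origin without
side-channel files.

What the simulator does **not** model: indels and structural variation
(the internal aligner is ungapped; on real data indel-bearing flanks are
simply lost as unmapped, and users who care take the SAM-import route),
base-quality realism beyond a flat error rate, thermodynamic PCR
chemistry, and the real nucleotide content of the elements — sequences
are synthetic, only their relationships (terminal repeats, subtype
divergence, age-dependent mutation load) are emulated. Passing tests
therefore demonstrate the correctness of the pipeline's logic and its
statistical behaviour under the modelled error processes, not performance
on any particular human genome.

A count-level companion, `simulate_quant_tables()`, skips reads entirely
for statistical experiments: per-locus abundances are log-normal
(mirroring the tens-fold CPM spread between real loci), present loci draw
Poisson counts, and absent loci draw a small Poisson "leak" (0.2 expected
stray reads per replicate in a 100,000-read library — the same order as
the few mis-mapped reads per library observed at absent loci in real
data). The leak magnitude matters: with substantially more leak the
fold-change gate can no longer separate presence from absence for
low-abundance loci, so the stated power property (loci with ≥ 30 expected
reads per carrier sample are essentially always called) holds under this
calibration and is tested under it.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bait_len`, `min_identity` | 20, 0.90 | bp, fraction | terminal-LTR bait recognition; 2 mismatches of 20 pass, 3 fail |
| `min_flank` | 10 | nt | flanks shorter than this after linker removal are unmappable noise |
| `window_nt` | 10 | nt | catalog assignment window around each record; a junction at exactly edge + 10 is assigned |
| `min_novel_dist` | 2000 | nt | junction clusters farther than this from every record are novel |
| `cluster_gap`, `min_reads` | 50, 2 | nt, reads | single-linkage junction clustering; 2 supporting reads curb false novels while staying overridable to 1 |
| `max_tsd` | 10 | bp | maximal target-site-duplication footprint |
| `cpm_min` | 50 | CPM | stringent detection filter; ≥ is a pass |
| `fc_min`, `p_max` | 20, 1e-10 | fold, p | polymorphism rule: both gates must pass |
| `max_mismatch_frac`, `index_k` | 0.06, 15 | fraction, bp | aligner mismatch allowance and seed length |
| `size_select_min/max`, `read_len` | 250/450, 150 | bp | simulated library geometry |

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; table-style listings
  are declared 1-based inclusive and converted on load; TSDs are reported
  1-based inclusive. Contigs are normalised to lower-case `chr` prefixes,
  unplaced-scaffold names kept verbatim.
* **Tie-breaks** are deterministic everywhere: bait ties go to fewer
  mismatches, then the smaller offset, then declaration order; merge
  overlaps minimise the mismatch ratio with ties to the longer overlap;
  equidistant catalog records go to the lower coordinate (and are
  counted); the aligner reports the first best placement in
  (orientation, contig, position) order, though multi-best flanks are
  discarded anyway.
* **Seeding of the aligner** requires one clean k-mer; a placement whose
  mismatches break every 15-mer would be missed in seeded mode, so an
  `exhaustive = TRUE` mode evaluates every placement and is used to
  verify seed-mode equivalence on small genomes.
* **Degenerate inputs**: empty catalogs, header-only files, zero-insertion
  genomes, empty read sets and zero-variance CPM vectors all return
  well-typed empty or `NA` results rather than errors; a library size of
  zero and a requested depth of zero are errors.
* **Exact-test ties** use the customary `1 + 1e-7` relative slack when
  collecting outcomes no more likely than the observed one, and the
  p-value is exactly 1 whenever every outcome qualifies.
* **Problem sizes**: the packaged experiments run at desk scale — a
  1.2-Mb three-contig genome with 120 insertions, 3 individuals × 3
  replicates at 100,000 read pairs per sample for end-to-end recovery,
  and a subsampling ladder of 1,000–150,000 pairs (the published
  100,000–15,000,000 ladder scaled by 100). These sizes were chosen so
  every per-locus expectation stays high enough that recovery properties
  are structural rather than lucky, while a full run remains a
  few-minute computation.

## Known limitations

* The internal aligner is ungapped and intended for synthetic or small
  genomes; human-scale runs should align the exported flank FASTA
  externally and use `import_alignments()`.
* Uniqueness on import uses the MAPQ > 0 proxy, which is
  aligner-dependent; the internal aligner's "exactly one best placement"
  definition is the strict reference behaviour.
* The chi-square comparison of detection counts across replicates is a
  2 × k detected/undetected contingency table by default; a
  goodness-of-fit reading (equal proportions of the detected counts) is
  also provided because either construction is defensible.
* Classification of a novel *reference* locus requires an annotated LTR
  interval track; without one, single-ended candidates stay ambiguous by
  design rather than being guessed.
* The bait set accepts ≥ 90% identity per subtype consensus, so an
  element whose terminal 20 bp have drifted by 3+ substitutions from
  every bait is invisible to the chimera stage — the same sensitivity
  cliff the real protocol has.

## A minimal session

```{r mini, eval = FALSE}
specs <- sim_insertions(n_loci = 30, n_contigs = 2, contig_len = 2e5,
                        seed = 11)
design <- design_experiment(specs, n_individuals = 3, n_replicates = 2,
                            polymorphic_fraction = 0.2, seed = 11)
truth <- build_genome(specs, design,
                      params = default_protocol(seq_error_rate = 0),
                      seed = 11)
pairs <- simulate_reads(truth, depth = 4000, seed = 11)

run <- run_pipeline(pairs, truth$catalog, truth$reference,
                    samples = truth$design$samples)
run$quant                      # per-sample locus x count/CPM table
run$novel                      # novel-locus calls with TSD footprints
glance(run$scan)               # polymorphic-locus summary
autoplot(run$scan)             # volcano plot per individual pair
```
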