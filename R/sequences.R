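# Synthetic HML-2 element sequences and protocol oligo defaults.
#
# Desk-scale stand-ins for the real LTR consensus, retrovirus-internal
# sequence, suppression-PCR primers and GAPS-style linker. The three LTR
# subtypes are modelled as divergent copies of one ancestral consensus:
# LTR5_Hs closest to it (youngest), LTR5B most diverged (oldest), which is
# what drives the amplification bias toward recent integrations.

LTR_SUBTYPE_DIVERGENCE <- c(LTR5_Hs = 0.01, LTR5A = 0.06, LTR5B = 0.12)

#' Synthetic HML-2 element sequence set
#'
#' Deterministically generates an ancestral LTR consensus, per-subtype LTR
#' consensus sequences (divergent copies of the ancestor), and a
#' retrovirus-internal segment (the gag/pol/env stand-in used for proviral
#' elements and the internal-homology filter). All sequences are synthetic:
#' the generator emulates the sequence relationships (subtype divergence,
#' terminal-repeat structure) rather than the real nucleotide content.
#'
#' @param ltr_len LTR length in bp.
#' @param internal_len Internal-segment length in bp.
#' @param divergence Named per-subtype divergence from the ancestral
#'   consensus (substitution probability per site).
#' @param seed Integer seed fixing the sequence set.
#' @return List with elements `ancestral`, `ltr` (named character vector per
#'   subtype), `internal`.
#' @export
hml2_elements <- function(ltr_len = 968L, internal_len = 1500L,
                          divergence = LTR_SUBTYPE_DIVERGENCE,
                          seed = 104729L) {
  with_seed(seed, {
    ancestral <- random_dna(ltr_len)
    ltr <- vapply(names(divergence), function(s) {
      mutate_seq(ancestral, divergence[[s]])
    }, character(1))
    internal <- random_dna(internal_len)
    list(ancestral = ancestral, ltr = ltr, internal = internal)
  })
}

#' Enrichment protocol parameters
#'
#' Parameters of the simulated wet-lab phase: random fragmentation,
#' GAPS-style linker ligation, suppression + nested PCR selecting
#' LTR-end-containing fragments, 250-450 bp size selection and PE150
#' sequencing. The nested primers anneal inside the LTR at a fixed offset
#' from the terminus; mismatches between a locus's (aged) LTR and the
#' primer reduce its amplification weight through a logistic curve
#' `1 / (1 + exp(amp_k * (m - amp_m0)))`.
#'
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution (bp).
#' @param size_select_min,size_select_max Size-selection bounds (bp).
#' @param read_len Read length (PE150 default).
#' @param seq_error_rate Flat per-base substitution error rate.
#' @param pcr_duplicate_rate Fraction of emitted read pairs that are PCR
#'   duplicates of another molecule, in `[0, 1)`.
#' @param linker_seq Linker (adapter) sequence ligated at the genomic end of
#'   each fragment. The default is a synthetic 25-mer; the real protocol's
#'   oligos are configurable here.
#' @param primer_offset Distance (bp) from the LTR terminus to the inner end
#'   of the nested primer site; the amplified molecule carries this many
#'   terminal LTR bases.
#' @param primer_len Primer length (bp); the primer site spans
#'   `[bait_len, primer_offset)` from the LTR terminus.
#' @param ltr_mutation_rate_per_mya Per-site substitution rate accumulated by
#'   an element per million years since integration.
#' @param off_target_fraction Fraction of molecules that are background
#'   (non-LTR) fragments escaping suppression.
#' @param amp_k,amp_m0 Logistic slope and midpoint (in primer mismatches) of
#'   the amplification-weight curve.
#' @param depth_reads Default read pairs per sample.
#' @return A validated `ltr_protocol` list.
#' @export
default_protocol <- function(fragment_len_mean = 350L,
                             fragment_len_sd = 120L,
                             size_select_min = 250L,
                             size_select_max = 450L,
                             read_len = 150L,
                             seq_error_rate = 0.001,
                             pcr_duplicate_rate = 0.10,
                             linker_seq = "GTAATACGACTCACTATAGGGCACG",
                             primer_offset = 42L,
                             primer_len = 22L,
                             ltr_mutation_rate_per_mya = 0.001,
                             off_target_fraction = 0.20,
                             amp_k = 2,
                             amp_m0 = 3,
                             depth_reads = 100000L) {
  p <- list(fragment_len_mean = fragment_len_mean,
            fragment_len_sd = fragment_len_sd,
            size_select_min = as.integer(size_select_min),
            size_select_max = as.integer(size_select_max),
            read_len = as.integer(read_len),
            seq_error_rate = seq_error_rate,
            pcr_duplicate_rate = pcr_duplicate_rate,
            linker_seq = linker_seq,
            primer_offset = as.integer(primer_offset),
            primer_len = as.integer(primer_len),
            ltr_mutation_rate_per_mya = ltr_mutation_rate_per_mya,
            off_target_fraction = off_target_fraction,
            amp_k = amp_k, amp_m0 = amp_m0,
            depth_reads = as.integer(depth_reads))
  if (p$size_select_min >= p$size_select_max)
    abort("size_select_min must be < size_select_max")
  if (p$read_len > p$size_select_max)
    abort("read_len must be <= size_select_max")
  if (p$pcr_duplicate_rate < 0 || p$pcr_duplicate_rate >= 1)
    abort("pcr_duplicate_rate must be in [0, 1)")
  if (nchar(p$linker_seq) < 8) abort("linker_seq must be >= 8 nt")
  if (p$off_target_fraction < 0 || p$off_target_fraction > 1)
    abort("off_target_fraction must be in [0, 1]")
  structure(p, class = "ltr_protocol")
}

# Amplification weight from primer mismatch count.
amp_weight <- function(m, k, m0) 1 / (1 + exp(k * (m - m0)))
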