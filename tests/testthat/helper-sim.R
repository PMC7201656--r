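# Shared simulation fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# A small error-free 3-individual x 2-replicate experiment.
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    specs <- sim_insertions(n_loci = 30, n_contigs = 2, contig_len = 2e5,
                            n_repeat = 2, seed = 11)
    des <- design_experiment(specs, n_individuals = 3, n_replicates = 2,
                             polymorphic_fraction = 0.2, seed = 11)
    truth <- build_genome(specs, des, seed = 11)
    truth$params <- default_protocol(seq_error_rate = 0,
                                     pcr_duplicate_rate = 0.1)
    pairs <- suppressWarnings(simulate_reads(truth, depth = 4000, seed = 11))
    .fixtures$small <- list(specs = specs, truth = truth, pairs = pairs)
  }
  .fixtures$small
}

# One processed sample of the small experiment.
small_run <- function() {
  if (is.null(.fixtures$small_run)) {
    s <- small_sim()
    idx <- build_index(s$truth$reference)
    run <- run_pipeline(s$pairs, s$truth$catalog, idx,
                        samples = s$truth$design$samples)
    .fixtures$small_run <- list(sim = s, index = idx, run = run)
  }
  .fixtures$small_run
}
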