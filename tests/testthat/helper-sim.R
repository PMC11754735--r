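# The default scenario run is shared between test files through a
# session-local cache so the full pipeline is only executed once.
.sim_cache <- new.env(parent = emptyenv())

get_s1_run <- function() {
  if (is.null(.sim_cache$s1))
    .sim_cache$s1 <- run_pipeline(pipeline_config(scenario = scenario_s1(1),
                                                  compute_metrics = FALSE))
  .sim_cache$s1
}

small_scenario <- function(seed = 1, n_genes = 20)
  sim_scenario(seed = seed, n_contigs = 1, contig_length_bp = 400000L,
               n_genes = n_genes)
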