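# One shared end-to-end pipeline run (the default fixture spec, seed 1),
# reused by the pipeline and acceptance tests so the suite pays the cost
# once.

tr_pipeline_result <- function() {
  if (!exists("pipeline", .tr_mol_env)) {
    dir <- file.path(tempdir(), "trscreen_e2e")
    res <- suppressMessages(
      run_pipeline(run_config(seed = 1, out_dir = dir)))
    assign("pipeline", res, .tr_mol_env)
  }
  get("pipeline", .tr_mol_env)
}
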