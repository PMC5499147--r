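#!/usr/bin/env Rscript
# Thin command-line wrapper over oscimmune::run_experiment().
#
#   Rscript scripts/run_experiment.R --experiment sweep --outdir out --seed 1
#   Rscript scripts/run_experiment.R --experiment simulate --V0 25 \
#       --config model.json --outdir out

suppressMessages({
  library(optparse)
  library(oscimmune)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--experiment", type = "character", default = "simulate",
              help = "simulate | sweep | pathway | diffuse | screen"),
  make_option("--config", type = "character", default = NULL,
              help = "optional model JSON (default: built-in fixture)"),
  make_option("--outdir", type = "character", default = "out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--V0", type = "double", default = 10),
  make_option("--paper-literal", action = "store_true", default = FALSE,
              dest = "paper_literal")
)))

model <- if (is.null(opts$config)) default_model() else
  read_model_config(opts$config)

res <- run_experiment(opts$experiment, outdir = opts$outdir, model = model,
                      seed = opts$seed, V0 = opts$V0,
                      paper_literal = opts$paper_literal)
cat("wrote:\n")
cat(paste(" ", res$files), sep = "\n")
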