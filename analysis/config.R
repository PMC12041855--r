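# Shared configuration for the numbered analysis scripts.
# Override the seed with RG4DYN_SEED in the environment if desired.
library(rg4dyn)

SEED <- as.integer(Sys.getenv("RG4DYN_SEED", "1"))
OUT <- "results/analysis"
CFG <- sim_config(seed = SEED)            # default study conditions
PARAMS <- pipeline_params()
CONDITIONS <- names(CFG$foldedness)       # GV, MII_DMSO, MII_BYBX
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)
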