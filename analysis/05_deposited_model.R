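#!/usr/bin/env Rscript
# Full-scale run on the deposited Spn-GEM, when a copy is available
# locally. The model is an external input (github.com/Shuliu97/Spn_GEM)
# and is not redistributed here; place the SBML file at the path below.
# Note: the bundled dense simplex targets desk-scale models — a
# genome-scale run is slow and is why this driver is separate.

library(fluxscan)

path <- "scratch/Spn_GEM.xml"
if (!file.exists(path)) {
  cat("Deposited model not found at", path, "-",
      "download it to reproduce the published 36 up / 20 down counts.\n")
  quit(status = 0)
}

model <- read_model(path, "sbml")
print(model)
cat("checksum:", unname(tools::md5sum(path)), "\n")
manifest <- run_pipeline(list(
  model = path, model_format = "sbml",
  scan = list(biomass_reaction_id = model$biomass_reaction_id,
              target_reaction_id = model$objective_reaction_id),
  out_dir = "results/spn_gem"))
targets <- utils::read.delim("results/spn_gem/targets.tsv")
cat(sum(targets$direction == "up"), "up,",
    sum(targets$direction == "down"), "down targets\n")
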