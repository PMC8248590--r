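#!/usr/bin/env Rscript
# Stage 2: derive the ICD-10-CM side of the AMI algorithm by
# forward-backward crosswalk.
#
# Starting from the ICD-9-CM families 410.x0 / 410.x1, the packaged toy
# GEM tables are walked forward (ICD-9 -> ICD-10) and backward to surface
# candidate ICD-10-CM codes and any related ICD-9-CM codes the seed list
# missed. On real GEM releases the same call reproduces the published
# candidate-generation step; the toys keep the repository self-contained.

library(amiclaims)

dir.create("results", showWarnings = FALSE)

fwd <- parse_gem(system.file("extdata", "gem_toy_9to10.txt", package = "amiclaims"),
                 "icd9_to_icd10")
bwd <- parse_gem(system.file("extdata", "gem_toy_10to9.txt", package = "amiclaims"),
                 "icd10_to_icd9")

universe <- fwd$entries$source
seed <- union(expand_pattern("410.x0", universe),
              expand_pattern("410.x1", universe))
message("Seed (ICD-9-CM 410.x0 / 410.x1 expansion): ",
        paste(seed, collapse = ", "))

report <- forward_backward(seed, fwd, bwd)
print(report)

message("Forward set (ICD-10-CM candidates): ",
        paste(report$forward_set, collapse = ", "))
message("Newly discovered ICD-9-CM codes (for clinical review): ",
        paste(report$newly_discovered, collapse = ", "),
        " - subsequent-episode codes like these were reviewed and excluded",
        " from the final algorithm.")

write_mapping_report(report, "results/02_mapping")
message("Mapping report written to results/02_mapping/")
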