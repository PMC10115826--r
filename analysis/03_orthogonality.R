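#!/usr/bin/env Rscript
# Stage 3: orthogonality screening and best-combination sweep.
#
# From the measured fold-change matrix we compute all pairwise centered
# cosine distances, then search for the most orthogonal combination of
# each size N = 3..16: once in restricted-profile mode (profiles limited
# to the switches inside the combination; exhaustive search) and once in
# full-profile mode (optimized threshold/max-clique search). Combinations
# with distance below 0.7 are flagged as crosstalking.

suppressPackageStartupMessages(library(orthocircuit))

fc <- read_matrix("results/fc_matrix.tsv")

pairwise <- pairwise_cosine_distances(fc)
write_matrix(pairwise, "results/pairwise_distances.tsv")

sweep_restricted <- sweep_best_combinations(fc, 3:16,
                                            profile_mode = "restricted")
sweep_full <- sweep_best_combinations(fc, 3:16, profile_mode = "full")
sweep_restricted$profile_mode <- "restricted"
sweep_full$profile_mode <- "full"
both <- rbind(sweep_restricted, sweep_full)
write.table(both, "results/best_combinations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

largest_ok <- max(sweep_restricted$N[sweep_restricted$orthogonal])
best <- attr(sweep_restricted, "scores")[[match(largest_ok,
                                                sweep_restricted$N)]]
message(sprintf("largest orthogonal set at the 0.7 threshold: N = %d", largest_ok))
message(sprintf("  members: %s",
                paste(rownames(fc)[best$combination], collapse = ", ")))
message(sprintf("  min pairwise distance: %.3f (pair %s-%s)", best$distance,
                rownames(fc)[best$argmin_pair[1]],
                rownames(fc)[best$argmin_pair[2]]))
flagged <- sweep_restricted$N[!sweep_restricted$orthogonal]
message(sprintf("set sizes flagged as crosstalking: %s",
                if (length(flagged)) paste(flagged, collapse = ", ") else "none"))
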