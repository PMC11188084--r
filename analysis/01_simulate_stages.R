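#!/usr/bin/env Rscript
# Simulate the two reference stages used throughout the analysis - a
# germline-interphase-like map (typical ~100 kb loops, genome-wide A/B
# checkerboard) and a pachytene-like map (extended ~800 kb loop array,
# no long-range compartment signal) - balance them, and write the
# matrices plus ground-truth annotations under results/stages/.

library(meioc)

out <- "results/stages"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L
N <- 5e6
# 10 kb bins so the interphase-like ~100 kb loop hump is resolvable in P(s)

for (stage in c("interphase", "pachytene")) {
  p <- stage_preset(stage, chrom_lengths = c(chr1 = 50e6), bin_size = 10e3,
                    n_dots = 30, n_contacts = N, seed = seed)
  tr <- simulate_features(p, seed = seed)
  m <- balance_matrix(sample_map(tr, p, N = N, seed = seed + 1L))
  write_matrix(m, file.path(out, stage))
  write_bed(anchor_set(data.frame(chrom = tr$ctcf$chrom, pos = tr$ctcf$pos,
                                  orientation = tr$ctcf$orientation,
                                  strength = tr$ctcf$strength,
                                  class = "CTCF")),
            file.path(out, paste0(stage, ".ctcf.bed")))
  utils::write.table(tr$dot_pairs, file.path(out, paste0(stage, ".dots.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d bins, %s contacts, %d loop anchors, %d dot pairs\n",
              stage, nrow(m$bins), format(total_contacts(m), big.mark = ","),
              length(tr$anchors$chr1),
              nrow(tr$dot_pairs)))
  seed <- seed + 100L
}
cat("stage maps written to", out, "\n")
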