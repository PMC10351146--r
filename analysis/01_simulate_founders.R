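#!/usr/bin/env Rscript
# Step 1: historical population and base cohort.
#
# Simulates the Wright-Fisher history at the working scale (set SCALE = 1 for
# the full design; that run takes hours), partitions loci into markers / QTL /
# neutral loci, assigns gamma-distributed QTL effects, and writes the locus
# map plus a short summary under results/.  The founder population itself is
# regenerated from its seed wherever needed, so nothing large is stored.

library(kinocs)

SCALE <- as.numeric(Sys.getenv("KINOCS_SCALE", "0.1"))
SEED <- as.integer(Sys.getenv("KINOCS_SEED", "20260923"))
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- program_config(scale = SCALE)
cat(sprintf("genome: %d chromosomes x %d loci, cohort %d + %d\n",
            cfg$genome$n_chromosomes, cfg$genome$loci_per_chromosome,
            cfg$genome$base_males, cfg$genome$base_females))

founders <- make_founders(cfg, seed_stream(SEED, "founders", 1))
print(founders)

write.csv(founders$map[, c("chrom", "id", "pos", "class")],
          file.path(out_dir, "locus_map.csv"), row.names = FALSE)

maf <- pmin(founders$freq, 1 - founders$freq)
summary_df <- data.frame(
  n_markers = sum(founders$map$class == "MARKER"),
  n_qtl = sum(founders$map$class == "QTL"),
  n_neutral = sum(founders$map$class == "NEUTRAL"),
  n_discarded = sum(founders$map$class == "DISCARDED"),
  mean_maf_markers = mean(maf[founders$map$class == "MARKER"]),
  mean_maf_all_segregating = mean(maf[founders$freq > 0 & founders$freq < 1]),
  sigma2_a0 = founders$arch$sigma2_a0,
  sigma2_e = founders$arch$sigma2_e
)
write.csv(summary_df, file.path(out_dir, "founder_summary.csv"),
          row.names = FALSE)
cat("markers:", summary_df$n_markers,
    "| mean marker MAF:", round(summary_df$mean_maf_markers, 3),
    "(ascertainment flattens the spectrum vs",
    round(summary_df$mean_maf_all_segregating, 3), "overall)\n")
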