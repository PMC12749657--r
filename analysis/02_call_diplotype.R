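#!/usr/bin/env Rscript
# Re-run the full inference on the simulated locus from 01: PSV table via
# paralog alignment, per-read voting and switch detection, allele
# clustering, depth segmentation and CN integration. Writes allele calls,
# the diplotype table and symbolic SV VCF records to results/call/.

library(psvtyper)

cfg <- pipeline_config(
  seed = 20250919L,
  alleles = list(allele_spec("hybrid", "intron1"),
                 allele_spec("hybrid", "utr3")))

# regenerate in memory (bit-identical to 01 by seed)
pair <- generate_paralog_pair(cfg$pair_spec)
dip <- build_diplotype_sequences(cfg$alleles[[1]], cfg$alleles[[2]], pair)
reads <- simulate_long_reads(dip, mean_len = cfg$mean_len,
                             len_sd = cfg$len_sd,
                             per_base_error = cfg$per_base_error,
                             depth = cfg$depth, seed = cfg$seed)
profile <- simulate_depth_profile(dip, seed = cfg$seed + 1L)
sim <- list(pair = pair, diplotype = dip, reads = reads, profile = profile)

d <- run_call(sim, cfg, out_dir = file.path("results", "call"))
print(d)
print(attr(d, "clusters"))
cl <- attr(d, "clusters")
for (cand in cl$candidates)
  cat(sprintf("candidate %s: SP interval (%d, %d], support %d reads\n",
              cand$switch_segment, cand$sp_interval[1], cand$sp_interval[2],
              cand$support))
cat("truth junctions:",
    paste(vapply(dip$structures, function(s)
      sprintf("%s@%s", s$switch_segment, s$junction), ""), collapse = ", "),
    "\n")
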