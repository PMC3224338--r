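#!/usr/bin/env Rscript
# Simulate the survey's sequencing libraries: one shared transcriptome with
# allelic/paralogous variation and skewed expression, sampled into two
# normalized GS20 libraries, one normalized GS FLX library, and one
# non-normalized GS20 library. A fraction of reads carries a lowercase
# primer prefix so the clean-up stage has real work to do. All ground
# truth is written alongside the FASTA.

suppressMessages(library(estsurvey))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L

cfg <- sim_config(n_reads = 80000, primer_mask_rate = 0.15, seed = seed)
tx <- build_transcriptome(cfg)
wts <- draw_weights(tx, cfg)
write_tsv(wts, file.path(out, "weights.tsv"))
write_tsv(sim_category_map(tx, seed = seed + 7L),
          file.path(out, "category_map.tsv"))

manifest <- data.frame(
  label = c("LVN.1", "LVN.2", "LVN.5", "LVR.1"),
  platform = c("GS20", "GS20", "GSFLX", "GS20"),
  normalized = c(TRUE, TRUE, TRUE, FALSE))
write_tsv(manifest, file.path(out, "manifest.tsv"))

for (i in seq_len(nrow(manifest))) {
  m <- manifest[i, ]
  libcfg <- sim_config(n_reads = cfg$n_reads, platform = m$platform,
                       primer_mask_rate = cfg$primer_mask_rate, seed = seed)
  w <- if (m$normalized) wts$norm_weight else wts$raw_weight
  names(w) <- wts$gene_id
  lib <- generate_reads(tx, w, libcfg, library = m$label,
                        seed = seed + 101L * i)
  write_library(lib, out)
  cat(sprintf("%s: %d reads (%s, %s), %d genes with >= 1 read\n",
              m$label, nrow(lib$reads), m$platform,
              if (m$normalized) "normalized" else "non-normalized",
              sum(lib$truth$genes$count > 0)))
}
cat("transcriptome:", length(tx$sequences), "genes (incl. paralog copies)\n")
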