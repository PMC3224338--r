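#!/usr/bin/env Rscript
# Clean every simulated library: clip lowercase/X-masked contamination,
# drop reads shorter than 50 nt, and tabulate counts and mean lengths
# before and after -- the survey's pre-processing bookkeeping.

suppressMessages(library(estsurvey))

sim <- "results/sim"
manifest <- read_tsv(file.path(sim, "manifest.tsv"))
cfg <- trim_config(min_length = 50)

rows <- list()
for (lab in manifest$label) {
  seqs <- read_fasta(file.path(sim, paste0(lab, "_reads.fasta")))
  f <- filter_library(seqs, cfg)
  rows[[lab]] <- cbind(library = lab, f$summary)
  clean <- f$kept$sequence
  names(clean) <- f$kept$id
  write_fasta(clean, file.path(sim, paste0(lab, "_clean.fasta")))
}
summary <- do.call(rbind, rows)
write_tsv(summary, "results/prep_summary.tsv")
print(summary, row.names = FALSE)
cat(sprintf("dropped %d of %d reads overall\n",
            sum(summary$n_in) - sum(summary$n_kept), sum(summary$n_in)))
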