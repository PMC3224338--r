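#!/usr/bin/env Rscript
# Rarefaction of gene discovery and hyperbolic saturation fits: subsample
# each library's read pool (and the union pool) at geometrically spaced
# depths, count genes tagged at least 1/5/10 times, fit y = ax/(b+x), and
# lay the results out as a completeness table (asymptote a, half-saturation
# b, R^2, total detections, slope at the final read count).

suppressMessages(library(estsurvey))

profiles <- read_tsv("results/profiles.tsv")
labs <- unique(profiles$library)
seed <- 42L

pools <- lapply(labs, function(l) read_pool(profiles[profiles$library == l, ]))
names(pools) <- labs
pools$all <- read_pool(stats::setNames(
  tapply(profiles$count, profiles$gene_id, sum) |> as.integer(),
  names(tapply(profiles$count, profiles$gene_id, sum))))

curves <- list()
fits <- list()
for (l in names(pools)) {
  pool <- pools[[l]]
  grid <- unique(round(exp(seq(log(100), log(pool$N), length.out = 15))))
  cur <- build_curves(pool, grid, thresholds = c(1, 5, 10), reps = 5,
                      seed = seed)
  curves[[l]] <- cbind(library = l, cur)
  fits[[l]] <- fit_table(cur, final_x = pool$N, library = l)
}
write_tsv(do.call(rbind, curves), "results/rarefaction.tsv")
fit_tab <- do.call(rbind, fits)
write_tsv(fit_tab, "results/fit_table.tsv")

print(within(fit_tab, {a <- round(a); b <- round(b)
                       r_squared <- round(r_squared, 4)
                       slope_final <- round(slope_final, 4)}),
      row.names = FALSE)
k1 <- fit_tab[fit_tab$k == 1, ]
cat(sprintf("\nnon-normalized asymptote is %.0f%% of the normalized one\n",
            100 * k1$a[k1$library == "LVR.1"] / k1$a[k1$library == "LVN.1"]))
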