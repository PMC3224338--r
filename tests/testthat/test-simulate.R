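test_that("transcriptome variation structure follows the configuration", {
  # no variation: single haplotype, singleton paralog groups
  cfg <- sim_config(n_genes = 30, p_allelic = 0, p_paralog = 0, seed = 1)
  tx <- build_transcriptome(cfg)
  expect_length(tx$sequences, 30)
  expect_true(all(lengths(tx$sequences) == 1))
  expect_true(all(tx$paralog_group == names(tx$sequences)))

  # zero divergence: second haplotypes identical to the first
  cfg0 <- sim_config(n_genes = 20, p_allelic = 1, allelic_div = 0,
                     p_paralog = 0, seed = 2)
  tx0 <- build_transcriptome(cfg0)
  expect_true(all(lengths(tx0$sequences) == 2))
  expect_true(all(vapply(tx0$sequences, function(s) s[1] == s[2], TRUE)))

  # paralogs are separate genes sharing the group id
  cfgp <- sim_config(n_genes = 50, p_allelic = 0, p_paralog = 1, seed = 3)
  txp <- build_transcriptome(cfgp)
  expect_length(txp$sequences, 100)
  expect_equal(sum(table(txp$paralog_group) == 2), 50)
})

test_that("haplotype divergence matches its binomial expectation", {
  cfg <- sim_config(n_genes = 100, p_allelic = 1, allelic_div = 0.01,
                    p_paralog = 0, seed = 7)
  tx <- build_transcriptome(cfg)
  diffs <- vapply(tx$sequences, function(s) {
    a <- strsplit(s[1], "")[[1]]; b <- strsplit(s[2], "")[[1]]
    sum(a != b)
  }, numeric(1))
  total_bases <- sum(vapply(tx$sequences, function(s) nchar(s[1]),
                            numeric(1)))
  expected <- 0.01 * total_bases
  se <- sqrt(total_bases * 0.01 * 0.99)
  expect_lt(abs(sum(diffs) - expected), 3 * se)
})

test_that("weight flattening is exponentiation with renormalization", {
  raw <- c(0.8, 0.15, 0.05)
  expect_equal(normalize_weights(raw, 1), raw / sum(raw))
  expect_equal(normalize_weights(raw, 0), rep(1 / 3, 3))
  manual <- sqrt(raw) / sum(sqrt(raw))  # (0.894, 0.387, 0.224) renormalized
  expect_equal(normalize_weights(raw, 0.5), manual, tolerance = 1e-12)

  s <- tiny_sim(seed = 4)
  expect_equal(sum(s$w$raw_weight), 1)
  expect_equal(sum(s$w$norm_weight), 1)
  # flattening shrinks the spread of weights
  expect_lt(max(s$norm) / min(s$norm), max(s$raw) / min(s$raw))
})

test_that("error-free reads are exact substrings and counts match truth", {
  s <- tiny_sim(seed = 5, sub_rate = 0, hp_indel_rate = 0)
  lib <- generate_reads(s$tx, s$raw, s$cfg)
  expect_equal(nrow(lib$reads), s$cfg$n_reads)
  expect_equal(sum(lib$truth$genes$count), s$cfg$n_reads)
  ok <- vapply(seq_len(nrow(lib$reads)), function(i) {
    tr <- lib$truth$reads[i, ]
    src <- s$tx$sequences[[tr$gene_id]][tr$haplotype]
    substr(src, tr$start, tr$end) == lib$reads$sequence[i]
  }, logical(1))
  expect_true(all(ok))
  # realized counts equal the truth table by construction
  expect_equal(as.vector(table(factor(lib$truth$reads$gene_id,
                                      levels = lib$truth$genes$gene_id))),
               lib$truth$genes$count)
})

test_that("planted substitution load matches the configured rate", {
  s <- tiny_sim(seed = 6, n_genes = 100, n_reads = 10000,
                sub_rate = 0.01, hp_indel_rate = 0)
  lib <- generate_reads(s$tx, s$raw, s$cfg)
  total_bases <- sum(lib$truth$reads$end - lib$truth$reads$start + 1)
  observed <- sum(lib$truth$reads$n_sub)
  expected <- 0.01 * total_bases
  se <- sqrt(total_bases * 0.01 * 0.99)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("start positions are uniform when the 3' bias is off", {
  cfg <- sim_config(n_genes = 1, length_range = c(1000, 1000),
                    read_length_mean = 100, read_length_sd = 0,
                    sub_rate = 0, hp_indel_rate = 0,
                    three_prime_lambda = 0, p_allelic = 0, p_paralog = 0,
                    n_reads = 10000, seed = 8)
  tx <- build_transcriptome(cfg)
  lib <- generate_reads(tx, c(g0001 = 1), cfg)
  # 901 feasible starts; bin into 10 equal classes for a chi-square GOF
  bins <- cut(lib$truth$reads$start, breaks = seq(0.5, 901.5, length.out = 11))
  gof <- chisq.test(table(bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("3' bias shifts read starts toward the transcript end", {
  cfg <- sim_config(n_genes = 1, length_range = c(1000, 1000),
                    read_length_mean = 100, read_length_sd = 0,
                    sub_rate = 0, hp_indel_rate = 0,
                    three_prime_lambda = 0.01, p_allelic = 0, p_paralog = 0,
                    n_reads = 5000, seed = 9)
  tx <- build_transcriptome(cfg)
  lib <- generate_reads(tx, c(g0001 = 1), cfg)
  expect_gt(mean(lib$truth$reads$start), 901 / 2 + 50)
})

test_that("generation is deterministic given the seed", {
  s <- tiny_sim(seed = 10)
  a <- generate_reads(s$tx, s$raw, s$cfg)
  b <- generate_reads(s$tx, s$raw, s$cfg)
  expect_identical(a, b)
  d <- withr::with_tempdir({
    p1 <- write_library(a, "one")
    p2 <- write_library(b, "two")
    identical(readLines(p1[1]), readLines(p2[1]))
  })
  expect_true(d)
})

test_that("normalization increases the number of genes tagged", {
  # expectation over seeds, at equal depth on a skewed expression vector
  wins <- vapply(1:20, function(s) {
    sim <- tiny_sim(seed = s, n_genes = 200, n_reads = 2000,
                    sub_rate = 0, hp_indel_rate = 0)
    ln <- generate_reads(sim$tx, sim$norm, sim$cfg, "N", seed = s * 2 + 1)
    lr <- generate_reads(sim$tx, sim$raw, sim$cfg, "R", seed = s * 2 + 2)
    sum(ln$truth$genes$count > 0) - sum(lr$truth$genes$count > 0)
  }, numeric(1))
  expect_gt(mean(wins), 0)
  expect_gt(mean(wins > 0), 0.8)
})

test_that("primer-masked prefixes are lowercase and clip off cleanly", {
  s <- tiny_sim(seed = 11, sub_rate = 0, hp_indel_rate = 0,
                primer_mask_rate = 1)
  lib <- generate_reads(s$tx, s$raw, s$cfg)
  expect_true(all(grepl("^[acgt]{20}[ACGT]+$", lib$reads$sequence)))
  f <- filter_library(lib$reads)
  tr <- lib$truth$reads[lib$reads$id %in% f$kept$id, ]
  src <- vapply(seq_len(nrow(tr)), function(i)
    substr(s$tx$sequences[[tr$gene_id[i]]][tr$haplotype[i]],
           tr$start[i], tr$end[i]), character(1))
  expect_identical(f$kept$sequence, src)
})
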