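hit_row <- function(q, s, evalue, bits, sstart = 1, send = 50) {
  data.frame(qseqid = q, sseqid = s, pident = 95, length = 50, mismatch = 2,
             gapopen = 0, qstart = 1, qend = 50, sstart = sstart,
             send = send, evalue = evalue, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("best-hit assignment applies the e-value cutoff and max-score rule", {
  h <- rbind(hit_row("r1", "AT1G01010.1", 1e-5, 60),
             hit_row("r2", "AT1G01020.1", 1e-3, 90),
             hit_row("r3", "AT1G01030.1", 1e-9, 80),
             hit_row("r3", "AT1G01040.1", 1e-9, 75))
  a <- assign_best_hit(h)
  expect_equal(sort(a$query_id), c("r1", "r3"))      # r2 fails the cutoff
  expect_equal(a$subject_id[a$query_id == "r3"], "AT1G01030")
  # boundary: e-value exactly at the cutoff passes
  expect_equal(nrow(assign_best_hit(hit_row("r", "s", 1e-4, 50))), 1)

  # ties: equal bit score -> lower e-value, then smaller subject id
  t1 <- rbind(hit_row("q", "AT2G02020.1", 1e-6, 80),
              hit_row("q", "AT2G02010.1", 1e-8, 80))
  expect_equal(assign_best_hit(t1)$subject_id, "AT2G02010")
  t2 <- rbind(hit_row("q", "AT2G02020.1", 1e-8, 80),
              hit_row("q", "AT2G02010.1", 1e-8, 80))
  expect_equal(assign_best_hit(t2)$subject_id, "AT2G02010")

  # isoform collapsing is a toggle
  expect_equal(assign_best_hit(hit_row("q", "AT3G01010.2", 1e-6, 55),
                               collapse_isoforms = FALSE)$subject_id,
               "AT3G01010.2")
})

test_that("hit files round-trip and malformed rows are located", {
  h <- rbind(hit_row("r1", "AT1G01010.1", 1e-5, 60),
             hit_row("r2", "AT1G01020.1", 1e-6, 70, sstart = 80, send = 31))
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(h, tf, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  rt <- read_hits(tf)
  expect_equal(nrow(rt), 2)
  # minus-strand subject coordinates are normalized
  expect_equal(rt$sstart[2], 31)
  expect_equal(rt$send[2], 80)
  expect_true(rt$minus[2])

  writeLines(c("a\tb\tc"), tf)
  expect_error(read_hits(tf), "line 1")
})

test_that("profiles count assigned reads per gene", {
  a <- data.frame(query_id = paste0("r", 1:4),
                  subject_id = c("A", "A", "A", "B"))
  p <- build_profile(a, "L1")
  expect_equal(p$count[p$gene_id == "A"], 3)
  expect_equal(p$count[p$gene_id == "B"], 1)
  expect_equal(sum(p$count), nrow(a))
  expect_equal(nrow(build_profile(a[0, ])), 0)
})

test_that("profiles from simulated truth match realized counts exactly", {
  s <- tiny_sim(seed = 21, sub_rate = 0, hp_indel_rate = 0)
  lib <- generate_reads(s$tx, s$raw, s$cfg)
  p <- build_profile(lib$truth$reads, "sim")
  expect_equal(sum(p$count), s$cfg$n_reads)
  tg <- lib$truth$genes[lib$truth$genes$count > 0, ]
  expect_equal(stats::setNames(p$count, p$gene_id)[tg$gene_id],
               stats::setNames(tg$count, tg$gene_id))
})

test_that("proteome coverage unions hit intervals per subject", {
  lens <- c(S1 = 200, S2 = 100)
  h <- rbind(hit_row("q1", "S1", 1e-6, 50, 1, 50),
             hit_row("q2", "S1", 1e-6, 50, 41, 100),
             hit_row("q3", "S2", 1e-6, 50, 1, 100))
  cv <- proteome_coverage(h, lens)
  expect_equal(cv$per_subject$covered[cv$per_subject$subject_id == "S1"], 100)
  expect_equal(cv$per_subject$fraction[cv$per_subject$subject_id == "S1"], 0.5)
  expect_equal(cv$per_subject$fraction[cv$per_subject$subject_id == "S2"], 1)
  expect_equal(cv$aggregate, 200 / 300)
  # no hits
  expect_equal(proteome_coverage(h[0, ], lens)$aggregate, 0)
  # interval beyond the subject end is clipped with a warning
  expect_warning(cv2 <- proteome_coverage(hit_row("q", "S2", 1e-6, 50, 90, 150),
                                          lens), "clipped")
  expect_equal(cv2$per_subject$covered, 11)
})

test_that("terminal windows classify hit locations", {
  lens <- c(P = 400)
  h5 <- hit_row("q1", "P", 1e-6, 50, 1, 30)
  hm <- hit_row("q2", "P", 1e-6, 50, 150, 250)
  h3 <- hit_row("q3", "P", 1e-6, 50, 320, 390)
  b <- terminal_window_bias(rbind(h5, hm, h3), lens, window = 100)
  expect_equal(b$n_queries, 3)
  expect_equal(b$n_five_prime, 1)
  expect_equal(b$n_three_prime, 1)
  # short subject: the whole protein is both windows
  ball <- terminal_window_bias(hit_row("q", "S", 1e-6, 50, 10, 40),
                               c(S = 80), window = 100)
  expect_equal(ball$n_five_prime, 1)
  expect_equal(ball$n_three_prime, 1)
})

test_that("3'-biased simulated reads hit the 3' window more often", {
  cfg <- sim_config(n_genes = 5, length_range = c(1500, 2000),
                    three_prime_lambda = 0.01, sub_rate = 0,
                    hp_indel_rate = 0, p_allelic = 0, p_paralog = 0,
                    n_reads = 3000, seed = 22)
  tx <- build_transcriptome(cfg)
  w <- rep(1 / 5, 5)
  names(w) <- names(tx$sequences)
  lib <- generate_reads(tx, w, cfg)
  tr <- lib$truth$reads
  # recast truth intervals as hits against the source transcript
  h <- data.frame(qseqid = tr$read_id, sseqid = tr$gene_id, pident = 100,
                  length = tr$end - tr$start + 1, mismatch = 0, gapopen = 0,
                  qstart = 1, qend = tr$end - tr$start + 1,
                  sstart = tr$start, send = tr$end, evalue = 0,
                  bitscore = 100)
  lens <- vapply(tx$sequences, function(s) nchar(s[1]), numeric(1))
  b <- terminal_window_bias(h, lens, window = 300)
  expect_gt(b$n_three_prime, b$n_five_prime)
})
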