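#' Configuration for an end-to-end simulated survey run
#'
#' Bundles the per-stage parameters of [run_survey()]: the simulator
#' configuration, the library manifest (label, platform, normalized flag,
#' reads), trimming, rarefaction and classification settings. One master
#' seed drives every stochastic stage through derived substreams.
#'
#' @param sim a [sim_config()]; its `n_reads` is overridden per library by
#'   the manifest.
#' @param libraries data frame manifest with columns `label`, `platform`,
#'   `normalized` (logical), `n_reads`.
#' @param trim a [trim_config()].
#' @param thresholds rarefaction detection thresholds.
#' @param reps rarefaction replicates per grid point.
#' @param grid_size number of geometric grid points per curve.
#' @param classifier a [classifier_thresholds()].
#' @param seed master seed.
#' @return list of class `survey_config`.
#' @export
survey_config <- function(sim = sim_config(),
                          libraries = data.frame(
                            label = c("NORM.1", "NORM.2", "RAW.1"),
                            platform = "GS20",
                            normalized = c(TRUE, TRUE, FALSE),
                            n_reads = 20000L),
                          trim = trim_config(),
                          thresholds = c(1, 5, 10),
                          reps = 5,
                          grid_size = 15,
                          classifier = classifier_thresholds(),
                          seed = 1L) {
  stopifnot(all(c("label", "platform", "normalized", "n_reads") %in%
                  names(libraries)), nrow(libraries) >= 1)
  structure(list(sim = sim, libraries = libraries, trim = trim,
                 thresholds = thresholds, reps = reps,
                 grid_size = grid_size, classifier = classifier,
                 seed = as.integer(seed)),
            class = "survey_config")
}

config_fingerprint <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  codes <- utf8ToInt(txt)
  sprintf("%08x",
          sum((codes * (seq_along(codes) %% 97 + 1)) %% 2147483647) %%
            4294967296)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("survey stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulated survey diagnostic pipeline
#'
#' Simulates one transcriptome and a manifest of libraries (normalized and
#' non-normalized), cleans the reads, builds truth-based expression
#' profiles, rarefies each library and the combined pool, fits the
#' hyperbolic saturation model, classifies unigene redundancy on a
#' simulated haplotype mixture, compares library profiles by Spearman
#' correlation, computes the annotation-retention chimera proxy on
#' progressively stricter detection sets, and tests category enrichment of
#' each library against the union background. Every table is stamped with
#' the configuration fingerprint and seed; two runs with identical
#' configuration are identical.
#'
#' @param config a [survey_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as TSVs there.
#' @return list of class `survey_report`: `prep_summary`, `profiles`,
#'   `rarefaction` (long format), `fit_table`, `redundancy_table`,
#'   `correlation_matrix`, `retention`, `enrichment_z`, `truth`, `stamp`.
#' @export
run_survey <- function(config = survey_config(), out_dir = NULL) {
  stopifnot(inherits(config, "survey_config"))
  stamp <- data.frame(fingerprint = config_fingerprint(config),
                      seed = config$seed)

  tx <- stage("simulate", build_transcriptome(config$sim))
  wts <- stage("simulate", draw_weights(tx, config$sim))
  raw_w <- stats::setNames(wts$raw_weight, wts$gene_id)
  norm_w <- stats::setNames(wts$norm_weight, wts$gene_id)

  libs <- list()
  for (i in seq_len(nrow(config$libraries))) {
    mf <- config$libraries[i, ]
    cfg <- config$sim
    cfg$platform <- mf$platform
    defaults <- list(GS20 = c(100, 10), GSFLX = c(230, 20))[[mf$platform]]
    cfg$read_length_mean <- defaults[1]
    cfg$read_length_sd <- defaults[2]
    cfg$n_reads <- as.integer(mf$n_reads)
    w <- if (mf$normalized) norm_w else raw_w
    libs[[mf$label]] <- stage("simulate",
      generate_reads(tx, w, cfg, library = mf$label,
                     seed = config$seed + 101L * i))
  }

  prep <- stage("prep", {
    rows <- lapply(names(libs), function(lab) {
      f <- filter_library(libs[[lab]]$reads, config$trim)
      cbind(library = lab, f$summary)
    })
    do.call(rbind, rows)
  })

  profiles <- stage("tag", {
    lapply(libs, function(l) {
      build_profile(l$truth$reads, library = l$reads$library[1])
    })
  })

  rare <- stage("rarefy", {
    rows <- lapply(names(profiles), function(lab) {
      pool <- read_pool(profiles[[lab]])
      grid <- unique(round(exp(seq(log(min(100, pool$N)), log(pool$N),
                                   length.out = config$grid_size))))
      cbind(library = lab,
            build_curves(pool, grid, config$thresholds, config$reps,
                         seed = config$seed + 7L))
    })
    all_pool <- read_pool(unlist(lapply(libs, function(l)
      l$truth$reads$gene_id)))
    grid <- unique(round(exp(seq(log(min(100, all_pool$N)), log(all_pool$N),
                                 length.out = config$grid_size))))
    rows$all <- cbind(library = "all",
                      build_curves(all_pool, grid, config$thresholds,
                                   config$reps, seed = config$seed + 7L))
    do.call(rbind, rows)
  })

  fits <- stage("fit", {
    rows <- lapply(unique(rare$library), function(lab) {
      cc <- rare[rare$library == lab, ]
      fit_table(cc[, c("k", "n", "rep", "detections")],
                final_x = max(cc$n), library = lab)
    })
    do.call(rbind, rows)
  })

  redundancy <- stage("redundancy", {
    # pick a long gene and build a haplotype-mixture unigene alignment
    lens <- vapply(tx$sequences, function(s) nchar(s[1]), numeric(1))
    gene <- names(which.max(lens))
    ref <- tx$sequences[[gene]][1]
    set.seed(config$seed + 13L)
    vpos <- sort(sample.int(nchar(ref), 3))
    sim <- simulate_unigene_alignment(ref, n_unigenes = 60,
                                      variant_positions = vpos,
                                      p_hap2 = 0.5, error_rate = 0.005,
                                      seed = config$seed + 17L)
    pu <- pileup_columns(sim$sam, "ref", ref)
    cls <- classify_positions(pu, config$classifier)
    summarize_table(list(cls))
  })

  corr <- stage("compare", compare_matrix(profiles))

  retention <- stage("compare", {
    all_genes <- unique(unlist(lapply(profiles, function(p) p$gene_id)))
    combined <- do.call(rbind, profiles)
    tot <- tapply(combined$count, combined$gene_id, sum)
    annotation_retention(all_genes,
                         pass1 = names(tot)[tot >= 2],
                         pass2 = names(tot)[tot >= 3])
  })

  enr <- stage("enrich", {
    cmap <- sim_category_map(tx, seed = config$seed + 23L)
    sets <- lapply(profiles, function(p) p$gene_id)
    background <- unique(unlist(sets))
    enrichment_matrix(sets, background, cmap)
  })

  report <- structure(list(
    prep_summary = prep, profiles = profiles, rarefaction = rare,
    fit_table = fits, redundancy_table = redundancy,
    correlation_matrix = corr, retention = retention,
    enrichment_z = enr,
    truth = list(weights = wts,
                 counts = lapply(libs, function(l) l$truth$genes)),
    stamp = stamp
  ), class = "survey_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(cbind(prep, stamp), file.path(out_dir, "prep_summary.tsv"))
    write_tsv(cbind(do.call(rbind, profiles), stamp),
              file.path(out_dir, "profiles.tsv"))
    write_tsv(cbind(rare, stamp), file.path(out_dir, "rarefaction.tsv"))
    write_tsv(cbind(fits, stamp), file.path(out_dir, "fit_table.tsv"))
    write_tsv(cbind(redundancy, stamp),
              file.path(out_dir, "redundancy_table.tsv"))
    write_tsv(data.frame(library = rownames(corr), corr,
                         check.names = FALSE),
              file.path(out_dir, "correlation_matrix.tsv"))
    write_tsv(cbind(retention, stamp), file.path(out_dir, "retention.tsv"))
    write_tsv(data.frame(category = rownames(enr), enr,
                         check.names = FALSE),
              file.path(out_dir, "enrichment_z.tsv"))
  }
  report
}
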