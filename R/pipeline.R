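## Pipeline orchestration: scenario configuration, stage execution with a
## manifest (resumable, deterministic), and report writers.

STAGES <- c("simulate", "fingerprint", "assemble_fpc", "map_bes",
            "assemble_comparative", "detect_rearrangements", "stats")

#' Default desk-scale scenario configuration
#'
#' A two-chromosome ~10 Mb reference with three planted inversions (0.2,
#' 0.5 and 2 Mb) on chr1, sampled by two BAC libraries mirroring the
#' classic two-library design: a 190 kb EcoRI library and a 160 kb
#' MboI library (about 12.7x combined clone coverage, so roughly 10x
#' coverage in anchored clones), 600 bp end reads at 0.5% error, and
#' evenly spaced overgo probes.  Sized to run the full pipeline in minutes
#' on one CPU while exercising every stage.
#'
#' @param seed master RNG seed.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
desk_scenario <- function(seed = 101) {
  list(
    seed = as.integer(seed),
    genome = list(n_chroms = 2, lengths = c(6e6, 4e6), gc = 0.36,
                  repeat_density = 0, repeat_length = 500),
    events = list(
      list(kind = "inversion", chrom = "chr1", start = 8e5, end = 1e6),
      list(kind = "inversion", chrom = "chr1", start = 2e6, end = 2.5e6),
      list(kind = "inversion", chrom = "chr1", start = 3.2e6, end = 5.2e6)),
    libraries = list(
      list(name = "CHA", enzyme_motif = "GAATTC", insert_mean = 190,
           insert_sd = 25, clone_count = 340, empty_rate = 0),
      list(name = "TKB", enzyme_motif = "GATC", insert_mean = 160,
           insert_sd = 20, clone_count = 390, empty_rate = 0.03)),
    spans = list(CHA = 200e3, TKB = 150e3),
    bes = list(read_len = 600, err_rate = 0.005),
    probes = list(n = 120, spacing = 6e4, probe_len = 40),
    digest = list(),
    sulston = list(tolerance = 7, gel_states = 4651, cutoff = 1e-08),
    alignment = list(),
    detection = list(cluster_gap = 5e4, min_support = 3,
                     min_segment = 5e4, segment_gap = 1e6,
                     major_threshold = 1e5),
    genome_size_kb = 1e4)
}

config_keys <- c("seed", "genome", "events", "libraries", "spans", "bes",
                 "probes", "digest", "sulston", "alignment", "detection",
                 "genome_size_kb")

validate_config <- function(config) {
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown))
    stopf("unknown configuration key(s): %s",
          paste(unknown, collapse = ", "))
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    stopf("seed must be an integer")
  invisible(config)
}

as_events <- function(evs) {
  lapply(evs, function(e) {
    if (inherits(e, "rearrangement_event")) return(e)
    do.call(switch(e$kind,
                   inversion = inversion,
                   centric_fission = centric_fission,
                   segmental_duplication = segmental_duplication,
                   transposition = transposition,
                   stopf("unknown event kind '%s'", e$kind)),
            e[setdiff(names(e), "kind")])
  })
}

#' Read / write a pipeline configuration file (JSON)
#'
#' @param path configuration file path.
#' @param config configuration list.
#' @return the configuration list (read) or `path` (write), invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(cfg$events))
    cfg$events <- lapply(seq_len(nrow(cfg$events)), function(i)
      as.list(cfg$events[i, !is.na(cfg$events[i, ])]))
  if (is.data.frame(cfg$libraries))
    cfg$libraries <- lapply(seq_len(nrow(cfg$libraries)), function(i)
      as.list(cfg$libraries[i, ]))
  validate_config(cfg)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- report writers -----------------------------------------------------

## report TSVs are 1-based inclusive; `coord_cols` name the 0-based
## half-open start columns to shift
write_report_tsv <- function(df, path, start_cols = character(0)) {
  df <- as.data.frame(df)
  for (cc in intersect(start_cols, colnames(df)))
    df[[cc]] <- df[[cc]] + 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

## BED stays 0-based half-open
write_bed <- function(df, path, chrom = "chrom", start = "start",
                      end = "end", name = NULL, score = NULL,
                      strand = NULL) {
  n <- nrow(df)
  out <- data.frame(
    chrom = df[[chrom]], start = as.integer(df[[start]]),
    end = as.integer(df[[end]]),
    name = if (is.null(name)) rep(".", n) else df[[name]],
    score = if (is.null(score)) rep(0, n) else df[[score]],
    strand = if (is.null(strand)) rep(".", n) else df[[strand]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

cfg_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a detection scenario in memory
#'
#' Convenience wrapper for simulation studies: simulates the scenario
#' (reference, derived genome, libraries, reads), maps and classifies the
#' mate pairs, builds orientation segments and discordant clusters, calls
#' inversions and scores them against the planted truth.  No files are
#' written; fingerprinting stages are not run.
#'
#' @param config configuration list (see [desk_scenario()]).
#' @param seed overrides `config$seed` when given.
#' @return list with statuses, anchored placements, segments, clusters,
#'   calls and the `recovery_report` (NULL when no inversions are
#'   planted).
#' @export
run_detection_scenario <- function(config = desk_scenario(),
                                   seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  s <- derive_seed(as.integer(config$seed), 1)
  g <- config$genome
  ref <- simulate_reference(g$n_chroms, g$lengths, g$gc,
                            g$repeat_density %||% 0,
                            g$repeat_length %||% 500, seed = s)
  dg <- apply_rearrangements(ref, as_events(config$events))
  clones <- do.call(rbind, lapply(seq_along(config$libraries),
                                  function(i) {
    lb <- config$libraries[[i]]
    sample_bac_library(dg, do.call(bac_library_params, lb),
                       seed = derive_seed(s, i))
  }))
  bes <- suppressMessages(
    extract_bes(dg, clones, config$bes$read_len, config$bes$err_rate,
                seed = derive_seed(s, 90)))
  ap <- do.call(alignment_params, config$alignment)
  aln <- align_bes_reads(bes, ref_index(ref), ap)
  st <- classify_mate_pairs(aln, clones, ap)
  st <- place_single_end(st, clones, unlist(config$spans),
                         genome_lengths(ref))
  dt <- config$detection
  cl <- cluster_discordant(st, dt$cluster_gap, dt$min_support)
  anch <- add_test_order(anchor_bacs(st), clones)
  segs <- orientation_segments(anch, dt$min_segment, dt$segment_gap)
  calls <- call_inversions(cl, segs, params = ap,
                           major_threshold = dt$major_threshold)
  calls <- annotate_centromeres(calls, dt$centromeres)
  truth <- do.call(rbind, lapply(config$events, function(e)
    if (e$kind == "inversion")
      data.frame(chrom = e$chrom, start = e$start, end = e$end)))
  rec <- if (!is.null(truth)) {
    tol <- mean(vapply(config$libraries, function(l) l$insert_mean,
                       numeric(1))) * 1000
    score_recovery(calls, truth, tol, dt$major_threshold)
  } else NULL
  list(clones = clones, statuses = st, anchored = anch, segments = segs,
       clusters = cl, calls = calls, recovery = rec)
}

## ---- pipeline -----------------------------------------------------------

#' Run the full mapping pipeline
#'
#' Executes simulate -> fingerprint -> assemble-fpc -> map-bes ->
#' assemble-comparative -> detect-rearrangements -> stats, writing each
#' stage's reports plus a manifest (stage hashes, seeds, outputs) under
#' `outdir`.  A rerun with the same configuration and seed skips completed
#' stages (their manifest entries and outputs are left untouched), so the
#' pipeline is resumable per stage; `force = TRUE` recomputes everything.
#' All randomness derives from the configuration seed, making reruns
#' byte-identical.
#'
#' @param config configuration list, see [desk_scenario()].
#' @param outdir output directory (created if needed).
#' @param stages run this ordered prefix of stages (default: all).
#' @param force recompute even when manifest and outputs are current.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the principal stage results.
#' @export
run_pipeline <- function(config = desk_scenario(), outdir,
                         stages = STAGES, force = FALSE, quiet = FALSE) {
  validate_config(config)
  stages <- match.arg(stages, STAGES, several.ok = TRUE)
  stages <- STAGES[STAGES %in% stages]
  upto <- max(match(stages, STAGES))
  stages <- STAGES[seq_len(upto)]   # dependencies always run (or resume)
  dir.create(file.path(outdir, "state"), recursive = TRUE,
             showWarnings = FALSE)
  man_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path) else list(stages = list())
  seed <- as.integer(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  ## `expr` is a promise: it is only evaluated when the stage actually runs
  run_stage <- function(name, outputs, expr) {
    h <- cfg_hash(list(config = config, stage = name))
    paths <- file.path(outdir, outputs)
    spath <- file.path(outdir, "state", paste0(name, ".rds"))
    entry <- manifest$stages[[name]]
    if (!force && !is.null(entry) && identical(entry$hash, h) &&
        all(file.exists(c(paths, spath)))) {
      say("[%s] up to date, skipping", name)
      return(readRDS(spath))
    }
    say("[%s] running", name)
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s (earlier stage outputs preserved)",
            name, conditionMessage(e)))
    saveRDS(res, spath)
    manifest$stages[[name]] <<- list(
      hash = h, outputs = as.list(outputs),
      seed = derive_seed(seed, match(name, STAGES)),
      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                         pretty = TRUE)
    res
  }

  res <- list()

  if ("simulate" %in% stages) res$sim <- run_stage("simulate", c(
    "reference.fasta", "derived.fasta", "bes.fasta", "clones.tsv",
    "probes.tsv", "probe_hits.tsv", "events.json", "liftover.tsv"), {
      s <- derive_seed(seed, 1)
      g <- config$genome
      ref <- simulate_reference(g$n_chroms, g$lengths, g$gc,
                                g$repeat_density %||% 0,
                                g$repeat_length %||% 500, seed = s)
      dg <- apply_rearrangements(ref, as_events(config$events))
      clones <- do.call(rbind, lapply(seq_along(config$libraries),
                                      function(i) {
        lb <- config$libraries[[i]]
        sample_bac_library(dg, do.call(bac_library_params, lb),
                           seed = derive_seed(s, i))
      }))
      bes <- extract_bes(dg, clones, config$bes$read_len,
                         config$bes$err_rate, seed = derive_seed(s, 90))
      probes <- design_overgos(ref, config$probes$n,
                               config$probes$spacing,
                               config$probes$probe_len %||% 40,
                               seed = derive_seed(s, 91))
      hits <- hybridize(probes, clones, dg, seed = derive_seed(s, 92))
      Biostrings::writeXStringSet(ref, file.path(outdir,
                                                 "reference.fasta"))
      Biostrings::writeXStringSet(dg$seq, file.path(outdir,
                                                    "derived.fasta"))
      bs <- Biostrings::DNAStringSet(setNames(bes$seq, bes$id))
      Biostrings::writeXStringSet(bs, file.path(outdir, "bes.fasta"))
      write_report_tsv(clones, file.path(outdir, "clones.tsv"), "start")
      write_report_tsv(probes, file.path(outdir, "probes.tsv"), "pos")
      write_report_tsv(hits, file.path(outdir, "probe_hits.tsv"))
      jsonlite::write_json(config$events, file.path(outdir,
                                                    "events.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_report_tsv(dg$liftover, file.path(outdir, "liftover.tsv"),
                       c("der_start", "ref_start"))
      list(ref = ref, dg = dg, clones = clones, bes = bes,
           probes = probes, hits = hits)
  })

  if ("fingerprint" %in% stages) res$fp <- run_stage("fingerprint",
                                                     "bands.txt", {
      dp <- do.call(digest_params, config$digest)
      fps <- fingerprint_clones(res$sim$dg, res$sim$clones, dp,
                                seed = derive_seed(seed, 2))
      qf <- quality_filter(fps)
      write_bands_file(qf$valid, file.path(outdir, "bands.txt"))
      list(fps = fps, valid = qf$valid, params = dp)
  })

  if ("assemble_fpc" %in% stages) res$fpc <- run_stage("assemble_fpc", c(
    "fpc_contigs.tsv", "fpc_summary.tsv"), {
      sp <- do.call(sulston_params, config$sulston)
      map <- build_contigs(res$fp$valid, sp)
      map <- dq_pass(map, res$fp$valid)
      map <- end_merge(map, res$fp$valid)
      map <- incorporate_markers(map, res$sim$hits, res$fp$valid)
      map <- add_singletons(map, res$fp$valid)
      rows <- do.call(rbind, lapply(map$contigs, function(ct)
        data.frame(contig = ct$id, clone = ct$members,
                   offset = unname(ct$offsets[ct$members]),
                   q = ct$members %in% ct$q_clones)))
      write_report_tsv(rows, file.path(outdir, "fpc_contigs.tsv"))
      kb_band <- calibrate_kb_per_band(
        mean(vapply(config$libraries, function(l) l$insert_mean,
                    numeric(1))), res$fp$valid)
      summ <- summarize_physical_map(map, res$fp$valid, kb_band)
      write_report_tsv(data.frame(statistic = names(summ),
                                  value = unlist(summ)),
                       file.path(outdir, "fpc_summary.tsv"))
      list(map = map, summary = summ, kb_per_band = kb_band)
  })

  if ("map_bes" %in% stages) res$bes <- run_stage("map_bes", c(
    "mate_status.tsv", "placements.bed"), {
      ap <- do.call(alignment_params, config$alignment)
      idx <- ref_index(res$sim$ref)
      aln <- align_bes_reads(res$sim$bes, idx, ap)
      st <- classify_mate_pairs(aln, res$sim$clones, ap)
      st <- place_single_end(st, res$sim$clones,
                             unlist(config$spans),
                             genome_lengths(res$sim$ref))
      write_report_tsv(st, file.path(outdir, "mate_status.tsv"),
                       c("start", "a1_start", "a2_start"))
      placed <- st[st$status %in% c("consistent", "single_end") &
                     !is.na(st$start), , drop = FALSE]
      write_bed(placed, file.path(outdir, "placements.bed"),
                name = "clone", strand = "orientation")
      list(aln = aln, statuses = st, params = ap)
  })

  if ("assemble_comparative" %in% stages)
    res$cmp <- run_stage("assemble_comparative", c(
      "comparative_contigs.bed", "comparative_stats.tsv",
      "merge_evidence.tsv"), {
        anchored <- anchor_bacs(res$bes$statuses, res$sim$hits,
                                res$sim$probes, res$bes$params)
        cmap <- build_comparative_contigs(anchored)
        mg <- merge_contigs(cmap, res$fpc$map, res$sim$hits,
                            res$sim$probes)
        cmap <- mg$map
        bed <- do.call(rbind, lapply(cmap$contigs, function(ct)
          data.frame(chrom = ct$chrom, start = ct$start, end = ct$end,
                     id = ct$id, n = nrow(ct$members))))
        write_bed(bed, file.path(outdir, "comparative_contigs.bed"),
                  name = "id", score = "n")
        cs <- contig_stats(cmap)
        write_report_tsv(cs$table,
                         file.path(outdir, "comparative_stats.tsv"))
        write_report_tsv(mg$evidence,
                         file.path(outdir, "merge_evidence.tsv"))
        list(anchored = anchored, map = cmap, stats = cs,
             evidence = mg$evidence)
    })

  if ("detect_rearrangements" %in% stages)
    res$det <- run_stage("detect_rearrangements", c(
      "clusters.tsv", "segments.tsv", "inversions.bed",
      "recovery.json"), {
        dt <- config$detection
        cl <- cluster_discordant(res$bes$statuses, dt$cluster_gap,
                                 dt$min_support)
        anch <- add_test_order(res$cmp$anchored, res$sim$clones)
        segs <- orientation_segments(anch, dt$min_segment,
                                     dt$segment_gap)
        calls <- call_inversions(cl, segs, res$sim$hits,
                                 res$sim$probes, anch,
                                 res$bes$params, dt$major_threshold)
        calls <- annotate_centromeres(calls, dt$centromeres)
        write_report_tsv(cl, file.path(outdir, "clusters.tsv"),
                         c("left_start", "right_start"))
        write_report_tsv(segs, file.path(outdir, "segments.tsv"),
                         "ref_start")
        write_bed(calls, file.path(outdir, "inversions.bed"),
                  score = "support_bes")
        truth <- do.call(rbind, lapply(config$events, function(e)
          if (e$kind == "inversion")
            data.frame(chrom = e$chrom, start = e$start, end = e$end)))
        rec <- if (!is.null(truth)) {
          tol <- mean(vapply(config$libraries, function(l)
            l$insert_mean, numeric(1))) * 1000
          score_recovery(calls, truth, tol, dt$major_threshold)
        } else NULL
        if (!is.null(rec))
          jsonlite::write_json(
            list(precision = rec$precision, recall = rec$recall,
                 events = rec$events),
            file.path(outdir, "recovery.json"), auto_unbox = TRUE,
            digits = NA, pretty = TRUE)
        else writeLines("{}", file.path(outdir, "recovery.json"))
        list(clusters = cl, segments = segs, calls = calls,
             recovery = rec)
    })

  if ("stats" %in% stages) res$stats <- run_stage("stats", c(
    "coverage.tsv", "summary.tsv"), {
      cov <- do.call(rbind, lapply(config$libraries, function(l)
        data.frame(library = l$name, clones = l$clone_count,
                   mean_insert_kb = l$insert_mean,
                   coverage = coverage_fold(l$clone_count,
                                            l$insert_mean,
                                            config$genome_size_kb))))
      write_report_tsv(cov, file.path(outdir, "coverage.tsv"))
      summ <- data.frame(
        statistic = c("n_major_calls", "n_comparative_contigs",
                      "comparative_n50", "comparative_n90"),
        value = c(count_major(res$det$calls,
                              config$detection$major_threshold),
                  length(res$cmp$map$contigs),
                  res$cmp$stats$n50, res$cmp$stats$n90))
      write_report_tsv(summ, file.path(outdir, "summary.tsv"))
      list(coverage = cov, summary = summ)
  })

  invisible(res)
}
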