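# end-to-end properties of the fingerprint-contig assembly passes

test_that("overlapping clones contig together; disjoint chromosomes never do", {
  # two noise-free clones overlapping ~80%
  w <- fp_world(len = 4e5, n_clones = 30, noise = FALSE, seed = 45)
  cl <- w$clones[order(w$clones$start), ]
  ov <- which(cl$start[-1] < cl$end[-nrow(cl)] -
                0.7 * cl$insert_len[-1])[1]
  pair <- w$fps[c(cl$id[ov], cl$id[ov + 1])]
  map2 <- build_contigs(pair)
  expect_length(map2$contigs, 1)
  expect_length(map2$contigs[[1]]$members, 2)

  # clones from two chromosomes, several seeds: never co-contiged
  for (seed in 1:5) {
    ref <- simulate_reference(2, c(3e5, 3e5), gc = 0.36, seed = 50 + seed)
    cl2 <- sample_bac_library(
      ref, bac_library_params("T", "GATC", 160, 20, clone_count = 40),
      seed = 60 + seed)
    fps <- suppressMessages(
      quality_filter(fingerprint_clones(ref, cl2, seed = 70 + seed)))$valid
    m <- build_contigs(fps)
    for (ct in m$contigs)
      expect_length(unique(cl2$chrom[match(ct$members, cl2$id)]), 1)
  }
})

test_that("contig ordering recovers true clone order and islands", {
  w <- fp_world(len = 1e6, n_clones = 65, seed = 21)   # ~10x coverage
  map <- build_contigs(w$fps)
  big <- map$contigs[[which.max(vapply(map$contigs, function(c)
    length(c$members), integer(1)))]]
  truth <- w$clones$start[match(big$members, w$clones$id)]
  expect_gte(abs(cor(seq_along(truth), truth, method = "spearman")), 0.95)

  # noise-free, no repeats: contig count equals true coverage islands
  wn <- fp_world(len = 8e5, n_clones = 40, noise = FALSE, seed = 81)
  mapn <- build_contigs(wn$fps)
  memb <- wn$clones[match(names(wn$fps), wn$clones$id), ]
  isl <- coverage_islands(memb$start, memb$end)
  # islands of a single clone stay singletons, not contigs
  single <- sum(vapply(mapn$contigs, function(c)
    length(c$members), integer(1)) >= 2)
  expect_equal(length(mapn$contigs), isl$n - length(mapn$singletons))

  # clone conservation through every assembly pass
  hits <- data.frame(probe = character(0), clone = character(0),
                     grade = character(0))
  m1 <- dq_pass(mapn, wn$fps)
  m2 <- end_merge(m1, wn$fps)
  m3 <- suppressMessages(incorporate_markers(m2, hits, wn$fps))
  m4 <- add_singletons(m3, wn$fps)
  all_ids <- c(unlist(lapply(m4$contigs, `[[`, "members")), m4$singletons)
  expect_setequal(all_ids, names(wn$fps))
  expect_length(all_ids, length(wn$fps))
})

test_that("assembly is deterministic for fixed input", {
  w <- fp_world(len = 5e5, n_clones = 35, seed = 83)
  a <- build_contigs(w$fps)
  b <- build_contigs(w$fps)
  expect_identical(a, b)
})

test_that("DQ re-assembly splits a planted chimera and conserves clones", {
  w <- fp_world(len = 1e6, n_clones = 55, seed = 61)
  clA <- w$clones[w$clones$end < 4e5, ]
  clB <- w$clones[w$clones$start > 6e5, ]
  fpsA <- w$fps[intersect(names(w$fps), clA$id)]
  fpsB <- w$fps[intersect(names(w$fps), clB$id)]
  set.seed(1)
  chim <- sort(c(sample(fpsA[[3]], length(fpsA[[3]]) %/% 2),
                 sample(fpsB[[3]], length(fpsB[[3]]) %/% 2)))
  fps2 <- c(fpsA, fpsB, list(CHIM = as.integer(chim)))
  map <- build_contigs(fps2)
  joined <- vapply(map$contigs, function(ct)
    any(ct$members %in% clA$id) && any(ct$members %in% clB$id),
    logical(1))
  expect_true(any(joined))   # the chimera fused two distant regions
  ct <- map$contigs[[which(joined)[1]]]
  # force re-clustering regardless of the questionable fraction: the
  # stepped-stringency split behaviour is what is under test here
  pieces <- dq_reassemble(ct, fps2, q_threshold = -1)
  expect_gte(sum(vapply(pieces, function(p)
    length(p$members) >= 2, logical(1))), 2)
  # no piece mixes the two source regions
  for (p in pieces) {
    m <- setdiff(p$members, "CHIM")
    expect_false(any(m %in% clA$id) && any(m %in% clB$id))
  }
  # conservation
  expect_setequal(unlist(lapply(pieces, `[[`, "members")), ct$members)
  # a clean contig is returned unchanged
  clean <- build_contigs(fpsA)$contigs[[1]]
  expect_identical(dq_reassemble(clean, fpsA), list(clean))
})

test_that("end merging rejoins contigs split at high stringency", {
  w <- fp_world(len = 1e6, n_clones = 55, seed = 61)
  strict <- build_contigs(w$fps, sulston_params(cutoff = 1e-25))
  expect_gt(length(strict$contigs), 2)
  merged <- end_merge(strict, w$fps)
  default <- build_contigs(w$fps)
  expect_lte(length(merged$contigs), length(default$contigs) + 1)
  expect_lt(length(merged$contigs), length(strict$contigs))
  # clone conservation
  expect_setequal(
    c(unlist(lapply(merged$contigs, `[[`, "members"), use.names = FALSE),
      merged$singletons),
    c(unlist(lapply(strict$contigs, `[[`, "members"), use.names = FALSE),
      strict$singletons))
  # the shared-band floor vetoes merges: demanding more shared terminal
  # bands than any terminal pair has leaves the map untouched
  frozen <- end_merge(strict, w$fps, min_shared = 1000)
  expect_length(frozen$contigs, length(strict$contigs))
})

test_that("marker incorporation merges only score-supported contig pairs", {
  w <- fp_world(len = 1e6, n_clones = 55, seed = 61)
  strict <- build_contigs(w$fps, sulston_params(cutoff = 1e-20))
  expect_gte(length(strict$contigs), 3)
  # adjacent contigs on the genome: their nearest clones truly overlap
  spans <- t(vapply(strict$contigs, function(ct) {
    iv <- w$clones[match(ct$members, w$clones$id), ]
    c(min(iv$start), max(iv$end))
  }, numeric(2)))
  ord <- order(spans[, 1])
  a <- names(strict$contigs)[ord[1]]; b <- names(strict$contigs)[ord[2]]
  hits <- data.frame(
    probe = "ovX",
    clone = c(tail(strict$contigs[[a]]$members, 1),
              head(strict$contigs[[b]]$members, 1)),
    grade = "P")
  m <- incorporate_markers(strict, hits, w$fps)
  c2 <- vapply(m$contigs, function(ct)
    all(hits$clone %in% ct$members), logical(1))
  expect_true(any(c2))          # merged into one contig
  expect_true(all(c("probe", "contig", "n_clones") %in%
                    colnames(m$marker_index)))
  # a promiscuous probe touching too many contigs is excluded
  many <- build_contigs(w$fps, sulston_params(cutoff = 1e-30))
  expect_gt(length(many$contigs), 6)
  hitsP <- data.frame(
    probe = "ovBAD",
    clone = vapply(many$contigs[1:7], function(ct) ct$members[1],
                   character(1)),
    grade = "P")
  expect_message(mP <- incorporate_markers(many, hitsP, w$fps),
                 "promiscuous")
  expect_identical(mP$promiscuous_probes, "ovBAD")
  expect_length(mP$contigs, length(many$contigs))
})

test_that("singleton adoption attaches overlapping clones and never merges contigs", {
  w <- fp_world(len = 1e6, n_clones = 55, seed = 61)
  strict <- build_contigs(w$fps, sulston_params(cutoff = 1e-30))
  expect_gt(length(strict$singletons), 0)
  out <- add_singletons(strict, w$fps)
  expect_equal(length(out$contigs), length(strict$contigs))
  expect_lte(length(out$singletons), length(strict$singletons))
  # a hopeless singleton (random bands) stays a singleton
  set.seed(2)
  fps3 <- c(w$fps, list(RAND = sort(sample.int(4651, 50))))
  m3 <- build_contigs(fps3)
  expect_true("RAND" %in% m3$singletons)
  m4 <- add_singletons(m3, fps3)
  expect_true("RAND" %in% m4$singletons)
})

test_that("physical length estimation matches worked arithmetic and truth", {
  # whole-map worked example: 575,144 consensus bands at 2.9 kb/band
  expect_equal(round_half_up(estimate_physical_length(575144, 2.9) / 1000),
               1668)
  expect_equal(estimate_physical_length(0), 0)
  # calibration against the generator's known region length
  w <- fp_world(len = 1.2e6, n_clones = 90, seed = 101)
  map <- build_contigs(w$fps)
  kb <- calibrate_kb_per_band(160, w$fps)
  est <- estimate_physical_length(map, kb)
  true_kb <- sum(vapply(map$contigs, function(ct) {
    m <- w$clones[match(ct$members, w$clones$id), ]
    (max(m$end) - min(m$start)) / 1000
  }, numeric(1)))
  expect_lt(abs(est - true_kb) / true_kb, 0.15)
})

test_that("parameter sweep tabulates the stringency grid consistently", {
  w <- fp_world(len = 6e5, n_clones = 40, seed = 91)
  grid <- parameter_sweep(w$fps, tolerances = c(5, 7),
                          cutoffs = c(1e-30, 1e-20, 1e-08))
  expect_equal(nrow(grid), 6)
  # stricter cutoffs never decrease the singleton count
  for (t in c(5, 7)) {
    g <- grid[grid$tolerance == t, ]
    g <- g[order(g$cutoff), ]   # ascending = strictest first
    expect_true(all(diff(g$n_singletons) <= 0))
  }
  # a single-point sweep equals a direct build
  one <- parameter_sweep(w$fps, 7, 1e-08)
  direct <- build_contigs(w$fps, sulston_params())
  expect_equal(one$n_contigs, length(direct$contigs))
  expect_equal(one$n_singletons, length(direct$singletons))
})

test_that("a clone with random bands is flagged questionable", {
  w <- fp_world(len = 4e5, n_clones = 25, noise = FALSE, seed = 93)
  base <- build_contigs(w$fps)
  good <- base$contigs[[which.max(vapply(base$contigs, function(c)
    length(c$members), integer(1)))]]
  set.seed(3)
  fps <- c(w$fps, list(RAND = sort(sample.int(4651, 54))))
  # force the random clone into the contig's member set
  ct <- bacmap:::make_contig(c(good$members, "RAND"), fps,
                             sulston_params(), "forced")
  expect_true("RAND" %in% ct$q_clones)
  # noise-free genuine members are not questionable
  expect_false(any(good$members %in% ct$q_clones))
})

test_that("questionable-clone fraction rises with sizing noise", {
  ref <- simulate_reference(1, 8e5, gc = 0.36, seed = 95)
  cl <- sample_bac_library(
    ref, bac_library_params("T", "GATC", 160, 20, clone_count = 50),
    seed = 96)
  qfrac <- vapply(c(0.2, 0.6), function(sd) {
    fps <- suppressMessages(quality_filter(fingerprint_clones(
      ref, cl, digest_params(sizing_sd = sd), seed = 97)))$valid
    m <- build_contigs(fps)
    nq <- sum(vapply(m$contigs, function(c) length(c$q_clones),
                     integer(1)))
    nq / length(fps)
  }, numeric(1))
  expect_lte(qfrac[1], qfrac[2])
})
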