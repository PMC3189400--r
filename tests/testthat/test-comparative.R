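test_that("anchoring requires two consistent placements", {
  ap <- alignment_params()
  st <- rbind(
    bacmap:::status_row("c1", "consistent", "green", "chr1", 1e5,
                        2.8e5, "+"),
    bacmap:::status_row("c2", "single_end", "blue", "chr1", 5e5,
                        7e5, "+", "T7"),
    bacmap:::status_row("c3", "single_end", "blue", "chr1", 9e5,
                        1.1e6, "+", "T7"),
    bacmap:::status_row("c4", "unmapped", NA))
  probes <- data.frame(id = c("p1", "p2"), chrom = "chr1",
                       pos = c(6.2e5, 2e6), seq = "x", length = 40)
  hits <- data.frame(probe = c("p1", "p2"), clone = c("c2", "c4"),
                     grade = "P")
  anch <- anchor_bacs(st, hits, probes, ap)
  # c1 by mate pair, c2 by BES + in-span overgo; c3 has no probe; c4 is
  # overgo-only and recorded but not anchored
  expect_setequal(anch$clone, c("c1", "c2"))
  expect_equal(anch$anchors[anch$clone == "c1"], "bes,bes")
  expect_equal(anch$anchors[anch$clone == "c2"], "bes,overgo")
  expect_identical(attr(anch, "overgo_only"), "c4")
})

test_that("interval chaining reproduces the worked example", {
  anch <- data.frame(clone = c("a", "b", "c"), chrom = "chr1",
                     start = c(0, 150e3, 400e3),
                     end = c(200e3, 350e3, 600e3),
                     orientation = "+", anchors = "bes,bes")
  cmap <- build_comparative_contigs(anch)
  expect_length(cmap$contigs, 2)
  expect_equal(cmap$contigs[[1]]$start, 0)
  expect_equal(cmap$contigs[[1]]$end, 350e3)
  expect_equal(cmap$contigs[[2]]$start, 400e3)
  expect_equal(cmap$gaps$width, 50e3)
  one <- build_comparative_contigs(anch[1, ])
  expect_length(one$contigs, 1)
  expect_equal(nrow(one$contigs[[1]]$members), 1)
})

test_that("contig count equals anchored coverage islands on simulation", {
  w <- bes_world(lengths = c(1.2e6, 8e5), n_a = 45, n_b = 50, seed = 231)
  anch <- anchor_bacs(w$statuses)
  cmap <- build_comparative_contigs(anch)
  n_isl <- 0L
  for (ch in unique(anch$chrom)) {
    a <- anch[anch$chrom == ch, ]
    n_isl <- n_isl + coverage_islands(a$start, a$end)$n
  }
  expect_equal(length(cmap$contigs), n_isl)
  # every anchored clone appears in exactly one contig
  mem <- unlist(lapply(cmap$contigs, function(ct) ct$members$clone))
  expect_setequal(mem, anch$clone)
  expect_length(mem, nrow(anch))
})

test_that("evidence-based merging bridges gaps, respects chromosomes, and is idempotent", {
  # two contigs on chr1 with a small gap, one contig on chr2
  anch <- data.frame(
    clone = c("a1", "a2", "b1", "b2", "z1"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(0, 100e3, 450e3, 550e3, 0),
    end = c(200e3, 300e3, 650e3, 750e3, 150e3),
    orientation = "+", anchors = "bes,bes")
  cmap <- build_comparative_contigs(anch)
  expect_length(cmap$contigs, 3)
  # fingerprint contig containing terminals of both chr1 contigs
  fmap <- structure(list(contigs = list(ctg0001 = structure(list(
    id = "ctg0001", members = c("a2", "b1")), class = "fingerprint_contig"))),
    class = "fpc_map")
  mg <- merge_contigs(cmap, fpc_map = fmap)
  expect_length(mg$map$contigs, 2)
  expect_equal(mg$evidence$kind, "fingerprint_contig")
  # second pass adds nothing
  mg2 <- merge_contigs(mg$map, fpc_map = fmap)
  expect_length(mg2$map$contigs, 2)
  expect_equal(nrow(mg2$evidence), 0)
  # shared probes never merge across chromosomes
  hits <- data.frame(probe = "pX", clone = c("b2", "z1"), grade = "P")
  mg3 <- merge_contigs(cmap, hits = hits)
  expect_length(mg3$map$contigs, 3)
  # but do merge adjacent contigs on one chromosome
  hits2 <- data.frame(probe = "pY", clone = c("a2", "b1"), grade = "P")
  mg4 <- merge_contigs(cmap, hits = hits2)
  expect_length(mg4$map$contigs, 2)
  expect_equal(mg4$evidence$kind, "shared_overgo")
})

test_that("bridged coverage gaps merge in most seeded replicates", {
  hits_ok <- 0L
  n_rep <- 12
  for (seed in seq_len(n_rep)) {
    w <- fp_world(len = 9e5, n_clones = 55, seed = 300 + seed)
    # comparative contigs from two halves with a forced anchored gap
    anch <- data.frame(clone = w$clones$id, chrom = "chr1",
                       start = w$clones$start, end = w$clones$end,
                       orientation = "+", anchors = "bes,bes")
    # unanchor every clone overlapping the middle 250 kb so a genuine
    # anchored-coverage gap arises; the fingerprint map still sees them
    mid <- (anch$start + anch$end) / 2
    bridge <- which(mid > 3.25e5 & mid < 5.75e5)
    anch2 <- anch[-c(bridge), , drop = FALSE]
    if (!nrow(anch2)) next
    cmap <- build_comparative_contigs(anch2)
    if (length(cmap$contigs) < 2) next  # no gap arose; uninformative seed
    fmap <- build_contigs(w$fps)        # fingerprint map knows the bridge
    mg <- merge_contigs(cmap, fpc_map = fmap)
    if (length(mg$map$contigs) < length(cmap$contigs)) hits_ok <- hits_ok + 1L
  }
  expect_gte(hits_ok / n_rep, 0.5)
})

test_that("contig statistics reproduce worked N50/N90 and totals arithmetic", {
  expect_equal(n_stat(c(10, 20, 30, 40), 0.5), 30)  # brute-force by hand:
  # sorted desc 40,30,... cumsum 40,70 >= 50 at the 30-length contig
  expect_equal(n_stat(c(10, 20, 30, 40), 0.9), 20)
  expect_equal(n_stat(42, 0.5), 42)
  expect_equal(n_stat(42, 0.9), 42)
  expect_equal(n_stat(numeric(0)), 0)

  # totals row from per-chromosome inputs: 31 orthologue pairs, 74 contigs
  per <- data.frame(
    chrom = paste0("T", 1:31),
    n = c(9, 1, 1, 3, 2, 1, 5, 2, 1, 2, 2, 1, 1, 2, 2, 1, 1, 1, 1, 1, 1,
          3, 1, 3, 2, 1, 5, 2, 3, 2, 11),
    total = c(198141542, 111826550, 100502741, 72769490, 60352001,
              51981596, 36281918, 34867379, 19188313, 29163447, 23514388,
              22321123, 21290332, 19602960, 17856723, 15894242, 12928248,
              68068, 10577421, 10507821, 9897437, 13624242, 6854714,
              3657921, 5832856, 6430646, 2143571, 4831899, 4641426,
              4439785, 72157792))
  contigs <- list()
  for (i in seq_len(nrow(per))) {
    n <- per$n[i]
    lens <- rep(per$total[i] %/% n, n)
    lens[1] <- lens[1] + per$total[i] - sum(lens)
    for (l in lens)
      contigs[[length(contigs) + 1L]] <- list(
        id = sprintf("cc%03d", length(contigs) + 1L), chrom = per$chrom[i],
        start = 0, end = l, members = data.frame())
  }
  cmap <- structure(list(contigs = contigs,
                         gaps = data.frame()), class = "comparative_map")
  cs <- contig_stats(cmap)
  tot <- cs$table[cs$table$chrom == "TOTALS", ]
  expect_equal(tot$n_contigs, 74)
  expect_equal(tot$total_length, 1004148592)
  expect_equal(tot$avg_length, 13569576)
})
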