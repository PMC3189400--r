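mk_inconsistent <- function(clone, chrom, lpos, rpos, lstrand, rstrand) {
  bacmap:::status_row(clone, "inconsistent", "yellow",
                      a1 = list(chrom = chrom, start = lpos,
                                end = lpos + 600, strand = lstrand),
                      a2 = list(chrom = chrom, start = rpos,
                                end = rpos + 600, strand = rstrand))
}

test_that("discordant pairs cluster by signature and proximity", {
  # seven same-strand pairs spanning one breakpoint -> one cluster of 7
  st <- do.call(rbind, lapply(1:7, function(i)
    mk_inconsistent(paste0("c", i), "chr1", 1e6 + i * 5e3,
                    2e6 + i * 5e3, "+", "+")))
  cl <- cluster_discordant(st, cluster_gap = 5e4, min_support = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 7)
  expect_equal(cl$signature, "same_strand")
  # two isolated pairs 5 Mb apart never reach min_support
  st2 <- rbind(mk_inconsistent("a", "chr1", 1e6, 1.5e6, "+", "+"),
               mk_inconsistent("b", "chr1", 6e6, 6.5e6, "+", "+"))
  expect_equal(nrow(cluster_discordant(st2)), 0)
  expect_equal(nrow(attr(cluster_discordant(st2), "minor")), 2)
  # no discordance at all
  st3 <- bacmap:::status_row("z", "consistent", "green", "chr1", 0, 2e5,
                             "+")
  expect_equal(nrow(cluster_discordant(st3)), 0)
})

test_that("orientation segments recover planted inversion and fission structure", {
  # colinear: one plus segment per chromosome
  w0 <- bes_world(lengths = c(8e5, 5e5), n_a = 30, n_b = 35, seed = 401)
  anch0 <- add_test_order(anchor_bacs(w0$statuses), w0$clones)
  seg0 <- orientation_segments(anch0)
  expect_equal(nrow(seg0), 2)
  expect_true(all(seg0$orientation == "+"))

  # a planted 800 kb inversion gives (+, -, +) with the middle matching
  # truth to within one insert length per edge
  ev <- list(inversion("chr1", 6e5, 1.4e6))
  w1 <- bes_world(lengths = 2e6, events = ev, n_a = 60, n_b = 70,
                  seed = 403)
  anch1 <- add_test_order(anchor_bacs(w1$statuses), w1$clones)
  seg1 <- orientation_segments(anch1)
  s1 <- seg1[seg1$test_chrom == "chr1", ]
  expect_equal(s1$orientation, c("+", "-", "+"))
  minus <- s1[s1$orientation == "-", ]
  expect_lt(abs(minus$ref_start - 6e5), 190e3)
  expect_lt(abs(minus$ref_end - 1.4e6), 190e3)

  # a centric fission yields two test chromosomes partitioning one
  # reference chromosome
  w2 <- bes_world(lengths = 1.6e6,
                  events = list(centric_fission("chr1", 7e5)),
                  n_a = 50, n_b = 55, seed = 405)
  anch2 <- add_test_order(anchor_bacs(w2$statuses), w2$clones)
  seg2 <- orientation_segments(anch2)
  expect_setequal(unique(seg2$test_chrom), c("chr1_f1", "chr1_f2"))
  expect_true(all(seg2$ref_chrom == "chr1"))
  i1 <- seg2[seg2$test_chrom == "chr1_f1", ]
  i2 <- seg2[seg2$test_chrom == "chr1_f2", ]
  # disjoint reference intervals on either side of the fission point
  expect_lte(max(i1$ref_end), min(i2$ref_start))
  expect_lt(abs(max(i1$ref_end) - 7e5), 190e3)
})

test_that("major-event counting is a simple monotone threshold", {
  calls <- data.frame(chrom = "chr1", start = c(0, 1e6, 5e6),
                      end = c(5e4, 1.15e6, 7e6))
  calls$size <- calls$end - calls$start
  expect_equal(count_major(calls, 1e5), 2)
  expect_equal(count_major(calls[0, ], 1e5), 0)
  # monotone non-increasing in the threshold
  th <- c(1e4, 1e5, 1e6, 5e6)
  expect_true(all(diff(vapply(th, count_major, integer(1),
                              calls = calls)) <= 0))
})

test_that("four planted inversions on one chromosome yield four major calls", {
  ev <- list(inversion("chr1", 4e5, 6e5),
             inversion("chr1", 1.2e6, 1.5e6),
             inversion("chr1", 2.2e6, 2.7e6),
             inversion("chr1", 3.4e6, 3.55e6))
  w <- bes_world(lengths = 4.2e6, events = ev, n_a = 130, n_b = 150,
                 err_rate = 0.005, seed = 407)
  anch <- add_test_order(anchor_bacs(w$statuses), w$clones)
  segs <- orientation_segments(anch)
  cls <- cluster_discordant(w$statuses)
  calls <- call_inversions(cls, segs)
  expect_equal(count_major(calls, 1e5), 4)
  truth <- data.frame(chrom = "chr1",
                      start = c(4e5, 1.2e6, 2.2e6, 3.4e6),
                      end = c(6e5, 1.5e6, 2.7e6, 3.55e6))
  rec <- score_recovery(calls, truth, tol = 175e3)
  expect_equal(rec$recall, 1)
  expect_equal(rec$precision, 1)
})

test_that("declared centromeres annotate nearby calls only", {
  calls <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1e6, 5e6, 1e6),
                      end = c(1.4e6, 5.5e6, 1.2e6))
  calls$size <- calls$end - calls$start
  out <- annotate_centromeres(calls, list(chr1 = 1.6e6), dist = 5e5)
  expect_identical(out$centromere_adjacent, c(TRUE, FALSE, FALSE))
  # no declared positions: nothing annotated
  out2 <- annotate_centromeres(calls, NULL)
  expect_false(any(out2$centromere_adjacent))
})

test_that("recovery scoring handles perfect, missing and spurious calls", {
  truth <- data.frame(chrom = "chr1", start = c(1e6, 4e6),
                      end = c(1.5e6, 6e6))
  calls <- data.frame(chrom = "chr1", start = truth$start,
                      end = truth$end)
  calls$size <- calls$end - calls$start
  rec <- score_recovery(calls, truth, tol = 1e5)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_true(all(rec$events$err_left == 0))
  rec0 <- score_recovery(calls[0, ], truth, tol = 1e5)
  expect_equal(rec0$recall, 0)
  spur <- rbind(calls, data.frame(chrom = "chr1", start = 8e6,
                                  end = 9e6, size = 1e6))
  rec2 <- score_recovery(spur, truth, tol = 1e5)
  expect_equal(rec2$recall, 1)
  expect_lt(rec2$precision, 1)
  expect_equal(nrow(rec2$spurious), 1)
})
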