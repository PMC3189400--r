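test_that("error-free reads align uniquely at their truth loci", {
  w <- bes_world(lengths = c(4e5, 3e5), n_a = 15, n_b = 15, seed = 201)
  expect_gt(nrow(w$aln), 0)
  expect_true(all(w$aln$identity == 1))
  expect_true(all(w$aln$unique))
  # alignments land exactly on the truth coordinates (ref == derived here)
  tr <- w$bes[match(w$aln$id, w$bes$id), ]
  plus <- w$aln$strand == "+"
  expect_true(all(w$aln$start[plus] == tr$true_pos[plus]))
  expect_true(all(w$aln$end[!plus] == tr$true_pos[!plus]))
  # raw genome instead of an index is a state error
  expect_error(align_bes_reads(w$bes, w$ref, w$params), "indexed")
})

test_that("short reads and unplaced reference names are rejected", {
  ref <- simulate_reference(1, 1e5, seed = 205)
  idx <- ref_index(ref)
  s <- as.character(ref)[[1]]
  r49 <- data.frame(id = "r49", seq = substr(s, 1001, 1049))
  expect_equal(nrow(align_bes_reads(r49, idx, alignment_params())), 0)
  r80 <- data.frame(id = "r80", seq = substr(s, 1001, 1080))
  expect_equal(nrow(align_bes_reads(r80, idx, alignment_params())), 1)
  # hits on unplaced names are treated as failed matches
  p2 <- alignment_params(unplaced_names = "chr1")
  expect_equal(nrow(align_bes_reads(r80, idx, p2)), 0)
})

test_that("reads inside a planted two-copy repeat are repetitive", {
  ref <- simulate_reference(1, 3e5, gc = 0.36, repeat_density = 0.01,
                            repeat_length = 1500, seed = 207)
  reps <- S4Vectors::metadata(ref)$repeats
  expect_gte(nrow(reps), 2)
  s <- as.character(ref)[[1]]
  inside <- data.frame(id = "rep_read",
                       seq = substr(s, reps$start[1] + 101,
                                    reps$start[1] + 700))
  aln <- align_bes_reads(inside, ref_index(ref), alignment_params())
  expect_gte(nrow(aln), 2)
  expect_false(any(aln$unique))
})

test_that("mate-pair classification follows the consistency rules", {
  ap <- alignment_params()
  mk <- function(chrom, start, end, strand, score = 600)
    data.frame(id = "x", chrom = chrom, start = start, end = end,
               strand = strand, identity = 1, length = 600,
               score = score, unique = TRUE, n_hits = 1L)
  # 150 kb apart, opposite strands, facing inward -> consistent
  st <- classify_mate_pair(mk("chr1", 1e6, 1e6 + 600, "+"),
                           mk("chr1", 1.15e6, 1.15e6 + 600, "-"), ap)
  expect_equal(st$status, "consistent")
  expect_equal(st$color, "green")
  expect_equal(c(st$start, st$end), c(1e6, 1.15e6 + 600))
  # 2.45 Mb apart -> inconsistent (rearrangement candidate)
  st2 <- classify_mate_pair(mk("chr1", 1e6, 1e6 + 600, "+"),
                            mk("chr1", 3.45e6, 3.45e6 + 600, "-"), ap)
  expect_equal(st2$status, "inconsistent")
  expect_equal(st2$color, "yellow")
  # 200 kb apart on the same strand -> inconsistent (inversion signature)
  st3 <- classify_mate_pair(mk("chr1", 1e6, 1e6 + 600, "+"),
                            mk("chr1", 1.2e6, 1.2e6 + 600, "+"), ap)
  expect_equal(st3$status, "inconsistent")
  # below the minimum span -> inconsistent
  st4 <- classify_mate_pair(mk("chr1", 1e6, 1e6 + 600, "+"),
                            mk("chr1", 1.005e6, 1.005e6 + 600, "-"), ap)
  expect_equal(st4$status, "inconsistent")
  # facing outward -> inconsistent
  st5 <- classify_mate_pair(mk("chr1", 1.15e6, 1.15e6 + 600, "+"),
                            mk("chr1", 1e6, 1e6 + 600, "-"), ap)
  expect_equal(st5$status, "inconsistent")
  # single end
  st6 <- classify_mate_pair(mk("chr1", 1e6, 1e6 + 600, "+"), NULL, ap)
  expect_equal(st6$status, "single_end")
  expect_equal(st6$color, "blue")
  # nothing aligned
  st7 <- classify_mate_pair(NULL, NULL, ap)
  expect_equal(st7$status, "unmapped")
})

test_that("repetitive sides resolve when exactly one combination is consistent", {
  ap <- alignment_params()
  uniq <- data.frame(id = "t", chrom = "chr1", start = 1e6,
                     end = 1e6 + 600, strand = "+", identity = 1,
                     length = 600, score = 600, unique = TRUE,
                     n_hits = 1L)
  multi <- data.frame(id = "s", chrom = "chr1",
                      start = c(1.15e6, 2.5e6, 9e6),
                      end = c(1.15e6, 2.5e6, 9e6) + 600,
                      strand = c("-", "-", "+"), identity = 1,
                      length = 600, score = 600, unique = FALSE,
                      n_hits = 3L)
  st <- classify_mate_pair(uniq, multi, ap)
  expect_equal(st$status, "consistent")
  expect_equal(st$color, "tan")
  expect_equal(st$end, 1.15e6 + 600)
  # two consistent combinations -> ambiguity preserved
  multi2 <- multi
  multi2$start[2] <- 1.2e6; multi2$end[2] <- 1.2e6 + 600
  st2 <- classify_mate_pair(uniq, multi2, ap)
  expect_equal(st2$status, "repetitive")
  # resolution recovers truth in planted-repeat simulations
  ref <- simulate_reference(1, 8e5, gc = 0.36, repeat_density = 0.004,
                            repeat_length = 1500, seed = 211)
  reps <- S4Vectors::metadata(ref)$repeats
  cl <- sample_bac_library(
    ref, bac_library_params("T", "GATC", 160, 20, clone_count = 60),
    seed = 212)
  bes <- extract_bes(ref, cl, 600, 0, seed = 213)
  aln <- align_bes_reads(bes, ref_index(ref), alignment_params())
  st3 <- classify_mate_pairs(aln, cl, alignment_params())
  tan <- st3[st3$color == "tan" & st3$status == "consistent", ,
             drop = FALSE]
  if (nrow(tan)) {
    tru <- cl[match(tan$clone, cl$id), ]
    expect_true(all(abs(tan$start - tru$start) < 1e3 &
                      abs(tan$end - tru$end) < 1e3))
  }
})

test_that("single-end placement uses library spans and clips at bounds", {
  cl <- data.frame(id = c("a", "b", "c"),
                   library = c("CHA", "TKB", "CHA"))
  st <- rbind(
    bacmap:::status_row("a", "single_end", "blue", "chr1", 1e6,
                        1e6 + 600, "+", "T7"),
    bacmap:::status_row("b", "single_end", "blue", "chr1", 5e5,
                        5e5 + 600, "-", "SP6"),
    bacmap:::status_row("c", "single_end", "blue", "chr1", 1.45e6,
                        1.45e6 + 600, "+", "T7"))
  out <- place_single_end(st, cl, c(CHA = 200e3, TKB = 150e3),
                          c(chr1 = 1.5e6))
  expect_equal(c(out$start[1], out$end[1]), c(1e6, 1.2e6))
  expect_equal(c(out$start[2], out$end[2]), c(5e5 + 600 - 150e3,
                                              5e5 + 600))
  # placement near the chromosome end is clipped and flagged
  expect_equal(out$end[3], 1.5e6)
  expect_true(out$clipped[3])
  expect_error(place_single_end(st, data.frame(id = "a", library = "XX"),
                                c(CHA = 2e5), c(chr1 = 1.5e6)),
               "span")
})

test_that("external tabular alignments import with thresholds applied", {
  path <- withr::local_tempfile()
  rows <- c(
    "r1.T7\tchr1\t98.5\t600\t9\t0\t1\t600\t1001\t1600\t1e-120\t1100",
    "r1.SP6\tchr1\t99.0\t600\t6\t0\t1\t600\t151600\t151001\t1e-130\t1150",
    "bad\tchr1\t80.0\t600\t120\t0\t1\t600\t5000\t5599\t1e-20\t300",
    "short\tchr1\t99.0\t40\t0\t0\t1\t40\t9000\t9039\t1e-9\t80")
  writeLines(rows, path)
  aln <- read_alignment_table(path)
  expect_setequal(aln$id, c("r1.T7", "r1.SP6"))
  expect_equal(aln$strand[aln$id == "r1.SP6"], "-")
  expect_true(all(aln$unique))
})
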