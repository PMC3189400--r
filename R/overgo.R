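## Overgo probe design on the reference and in-silico hybridization against
## clones of the derived genome.

#' Design overgo probes on the reference genome
#'
#' Probes (~40 bp) are drawn at roughly even spacing along each chromosome.
#' Each candidate must occur exactly once in the reference (counting both
#' strands); non-unique candidates are replaced by scanning nearby positions
#' up to half the spacing away.
#'
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param n number of probes.
#' @param spacing target spacing in bp between design loci (must be at least
#'   the probe length).
#' @param probe_len probe length in bp (bounds 36-44 by convention).
#' @param seed integer RNG seed (used only to jitter starting offsets).
#' @return data.frame: id, chrom, pos (design locus, 0-based), seq, length.
#' @export
design_overgos <- function(ref, n, spacing, probe_len = 40, seed = 1) {
  if (n < 1) stopf("n must be >= 1")
  if (spacing < probe_len) stopf("spacing must be >= probe length")
  set.seed(as.integer(seed))
  lens <- genome_lengths(ref)
  ## allocate loci per chromosome proportional to length, evenly spaced
  alloc <- diff(round(cumsum(c(0, lens)) / sum(lens) * n))
  names(alloc) <- names(lens)
  full <- as.character(ref)
  occurs_once <- function(p) {
    fwd <- sum(Biostrings::vcountPattern(p, ref, fixed = TRUE))
    rc <- revcomp_chr(p)
    rev <- if (rc == p) 0 else
      sum(Biostrings::vcountPattern(rc, ref, fixed = TRUE))
    (fwd + rev) == 1
  }
  rows <- list()
  shortfall <- 0L
  for (ci in names(lens)) {
    k <- alloc[[ci]]
    if (k < 1) next
    step <- lens[[ci]] / k
    anchors <- as.integer(floor(step / 2 + step * (seq_len(k) - 1)))
    for (a in anchors) {
      found <- FALSE
      ## replacement candidates stay within a quarter-spacing so design
      ## loci keep at least half the spacing between them
      for (off in unique(c(0, as.integer(outer(
        seq_len(max(1, floor(spacing / 4 / probe_len))) * probe_len,
        c(1, -1)))))) {
        pos <- a + off
        if (pos < 0 || pos + probe_len > lens[[ci]]) next
        cand <- substr(full[[ci]], pos + 1L, pos + probe_len)
        if (grepl("[^ACGT]", cand)) next
        if (occurs_once(cand)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ci, pos = pos, seq = cand, length = probe_len,
            stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
      if (!found) shortfall <- shortfall + 1L
    }
  }
  if (shortfall > 0)
    stopf("could not find %d unique probe(s) of %d requested",
          shortfall, n)
  out <- do.call(rbind, rows)
  out <- data.frame(id = sprintf("ov%04d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hybridize overgo probes against BAC clones
#'
#' A probe hits a clone iff the probe sequence or its reverse complement
#' occurs within the clone's derived-genome interval (full containment).
#' Matching is done by exact search of the derived chromosomes followed by
#' interval containment, which is equivalent to searching every clone
#' sequence directly.  Optional noise downgrades a fraction of hits to
#' T/W grades and adds false-positive hits.
#'
#' @param probes probe table from [design_overgos()].
#' @param clones clone table from [sample_bac_library()].
#' @param genome the derived genome the clones were sampled from.
#' @param downgrade_frac fraction of true hits downgraded to grade T or W.
#' @param fp_rate false-positive rate per (probe, clone) pair.
#' @param seed RNG seed for the noise model.
#' @return data.frame of hits: probe, clone, grade (`P`/`T`/`W`).
#' @export
hybridize <- function(probes, clones, genome, downgrade_frac = 0,
                      fp_rate = 0, seed = 1) {
  seqs <- genome_seqs(genome)
  clones <- clones[!is.na(clones$start), , drop = FALSE]
  hits <- list()
  for (ci in names(seqs)) {
    cl <- clones[clones$chrom == ci, , drop = FALSE]
    if (nrow(cl) == 0) next
    subj <- seqs[[ci]]
    for (pi in seq_len(nrow(probes))) {
      p <- probes$seq[pi]
      occ <- Biostrings::start(Biostrings::matchPattern(p, subj)) - 1L
      rc <- revcomp_chr(p)
      if (rc != p)
        occ <- c(occ, Biostrings::start(
          Biostrings::matchPattern(rc, subj)) - 1L)
      if (length(occ) == 0) next
      plen <- probes$length[pi]
      for (o in occ) {
        inside <- cl$start <= o & cl$end >= o + plen
        if (any(inside))
          hits[[length(hits) + 1L]] <- data.frame(
            probe = probes$id[pi], clone = cl$id[inside],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    out <- data.frame(probe = character(0), clone = character(0),
                      grade = character(0))
  } else {
    out <- unique(do.call(rbind, hits))
    out$grade <- "P"
  }
  set.seed(as.integer(seed))
  if (downgrade_frac > 0 && nrow(out) > 0) {
    k <- rbinom(1, nrow(out), downgrade_frac)
    if (k > 0) {
      idx <- sample.int(nrow(out), k)
      out$grade[idx] <- sample(c("T", "W"), k, replace = TRUE)
    }
  }
  if (fp_rate > 0) {
    k <- rbinom(1, nrow(probes) * nrow(clones), fp_rate)
    if (k > 0) {
      fp <- data.frame(probe = sample(probes$id, k, replace = TRUE),
                       clone = sample(clones$id, k, replace = TRUE),
                       grade = "W", stringsAsFactors = FALSE)
      out <- rbind(out, fp)
      out <- out[!duplicated(out[, c("probe", "clone")]), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}
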