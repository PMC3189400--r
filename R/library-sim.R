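## BAC library sampling (partial-digest model) and BAC-end read extraction.

#' BAC library parameters
#'
#' @param name library name (used as clone-id prefix and span lookup key).
#' @param enzyme_motif recognition sequence whose occurrences bound clone
#'   inserts (e.g. `"GATC"` for an MboI-type library, `"GAATTC"` for an
#'   EcoRI-type library).
#' @param insert_mean,insert_sd insert size distribution in kb.
#' @param clone_count number of clones to sample.
#' @param empty_rate fraction of insert-free clones.
#' @param insert_min,insert_max truncation bounds of the insert-size
#'   distribution in kb; default mean +/- 3 sd.
#' @return list of class `bac_library_params`.
#' @export
bac_library_params <- function(name, enzyme_motif = "GATC",
                               insert_mean = 160, insert_sd = 20,
                               clone_count = 100, empty_rate = 0,
                               insert_min = NULL, insert_max = NULL) {
  if (insert_mean <= 0) stopf("insert_mean must be positive")
  if (empty_rate < 0 || empty_rate >= 1) stopf("empty_rate must be in [0,1)")
  structure(list(
    name = name, enzyme_motif = toupper(enzyme_motif),
    insert_mean = insert_mean, insert_sd = insert_sd,
    clone_count = as.integer(clone_count), empty_rate = empty_rate,
    insert_min = insert_min %||% max(1, insert_mean - 3 * insert_sd),
    insert_max = insert_max %||% (insert_mean + 3 * insert_sd)),
    class = "bac_library_params")
}

#' Sample a BAC library from a (derived) genome
#'
#' Partial-digest model: a clone starts at a uniformly chosen occurrence of
#' the library's restriction motif and ends at the motif occurrence whose
#' distance best matches a draw from the truncated Normal insert-size
#' distribution.  Both clone boundaries therefore sit on motif sites.  Empty
#' clones (fraction `empty_rate`) carry NA intervals.
#'
#' @param genome a `derived_genome` or [Biostrings::DNAStringSet].
#' @param params [bac_library_params()].
#' @param seed integer RNG seed.
#' @return data.frame of clones: id, library, chrom, start, end, insert_len
#'   (0-based half-open derived-genome coordinates; NA for empty clones).
#' @export
sample_bac_library <- function(genome, params, seed = 1) {
  stopifnot(inherits(params, "bac_library_params"))
  seqs <- genome_seqs(genome)
  if (params$clone_count == 0)
    return(data.frame(id = character(0), library = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), insert_len = integer(0)))
  set.seed(as.integer(seed))
  motif <- Biostrings::DNAString(params$enzyme_motif)
  sites <- lapply(seq_along(seqs), function(i)
    Biostrings::start(Biostrings::matchPattern(motif, seqs[[i]])) - 1L)
  names(sites) <- names(seqs)
  if (all(lengths(sites) == 0))
    stopf("enzyme motif %s not found in the genome", params$enzyme_motif)
  lens <- genome_lengths(seqs)
  mean_bp <- params$insert_mean * 1000
  sd_bp <- params$insert_sd * 1000
  min_bp <- params$insert_min * 1000
  max_bp <- params$insert_max * 1000

  n <- params$clone_count
  empty <- runif(n) < params$empty_rate
  chrom <- character(n); st <- rep(NA_integer_, n); en <- rep(NA_integer_, n)
  p_chrom <- lens / sum(lens)
  n_fail <- 0L
  for (i in seq_len(n)) {
    if (empty[i]) { chrom[i] <- NA_character_; next }
    ok <- FALSE
    for (try in 1:50) {
      ci <- sample(names(seqs), 1, prob = p_chrom)
      ss <- sites[[ci]]
      if (length(ss) < 2) next
      a <- sample(ss, 1)
      target <- rnorm(1, mean_bp, sd_bp)
      while (target < min_bp || target > max_bp)
        target <- rnorm(1, mean_bp, sd_bp)
      ## end site whose distance from a best matches the draw (either side)
      b <- ss[which.min(abs(abs(ss - a) - target))]
      len <- abs(b - a)
      if (len >= min_bp && len <= max_bp) {
        chrom[i] <- ci; st[i] <- min(a, b); en[i] <- max(a, b)
        ok <- TRUE
        break
      }
    }
    if (!ok) n_fail <- n_fail + 1L
  }
  if (n_fail == n)
    stopf("library %s: no motif pair within the insert-size window",
          params$name)
  if (n_fail > 0)
    message(sprintf("library %s: %d clone draws failed, emitted as empty",
                    params$name, n_fail))
  data.frame(id = sprintf("%s_%05d", params$name, seq_len(n)),
             library = params$name, chrom = chrom, start = st, end = en,
             insert_len = en - st, stringsAsFactors = FALSE)
}

#' Extract clone insert sequences
#'
#' @param genome a `derived_genome` or `DNAStringSet`.
#' @param clones clone table from [sample_bac_library()] (empty clones are
#'   dropped).
#' @return named [Biostrings::DNAStringSet] of insert sequences.
#' @export
clone_sequences <- function(genome, clones) {
  seqs <- genome_seqs(genome)
  clones <- clones[!is.na(clones$start), , drop = FALSE]
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(clones)), function(i)
    as.character(Biostrings::subseq(seqs[[clones$chrom[i]]],
                                    clones$start[i] + 1L, clones$end[i])),
    character(1)))
  names(out) <- clones$id
  out
}

#' Extract paired BAC-end sequences
#'
#' The T7 read is the first `read_len` bases of the insert on the forward
#' strand; the SP6 read is the last `read_len` bases reverse-complemented, so
#' the two reads of a clone face inward.  Independent per-base substitution
#' errors are applied at `err_rate`.  Empty clones are skipped with a notice.
#'
#' @param genome a `derived_genome` or `DNAStringSet`.
#' @param clones clone table from [sample_bac_library()].
#' @param read_len read length in bp (must not exceed any insert length).
#' @param err_rate per-base substitution error rate in `[0, 0.2)`.
#' @param seed integer RNG seed.
#' @return data.frame of reads: id (`<clone>.T7` / `<clone>.SP6`), clone,
#'   end_label, seq, read_len, true_chrom, true_pos, true_strand.  The truth
#'   coordinate is the outer clone boundary the read starts from (derived
#'   genome, 0-based).
#' @export
extract_bes <- function(genome, clones, read_len = 600, err_rate = 0,
                        seed = 1) {
  if (err_rate < 0 || err_rate >= 0.2) stopf("err_rate must be in [0, 0.2)")
  empty <- is.na(clones$start)
  if (any(empty))
    message(sprintf("skipping %d empty clone(s) with no insert", sum(empty)))
  clones <- clones[!empty, , drop = FALSE]
  if (any(clones$insert_len < read_len))
    stopf("read_len %d exceeds the shortest insert (%d bp)",
          read_len, min(clones$insert_len))
  set.seed(as.integer(seed))
  ins <- clone_sequences(genome, clones)
  t7 <- as.character(Biostrings::subseq(ins, 1L, read_len))
  sp6 <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(ins, Biostrings::width(ins) - read_len + 1L)))
  out <- data.frame(
    id = c(paste0(clones$id, ".T7"), paste0(clones$id, ".SP6")),
    clone = rep(clones$id, 2),
    end_label = rep(c("T7", "SP6"), each = nrow(clones)),
    seq = c(t7, sp6), read_len = read_len,
    true_chrom = rep(clones$chrom, 2),
    true_pos = c(clones$start, clones$end),
    true_strand = rep(c("+", "-"), each = nrow(clones)),
    stringsAsFactors = FALSE)
  if (err_rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(out))) {
      ne <- rbinom(1, read_len, err_rate)
      if (ne == 0) next
      pos <- sample.int(read_len, ne)
      s <- out$seq[i]
      for (p in pos) {
        cur <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(bases, cur), 1)
      }
      out$seq[i] <- s
    }
  }
  rownames(out) <- NULL
  out
}
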