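# shared fixture builders; everything is generated in code at test time

# small single-chromosome world with clones and (optionally noisy)
# fingerprints
fp_world <- function(len = 1e6, n_clones = 65, insert_mean = 160,
                     insert_sd = 20, gc = 0.36, noise = TRUE,
                     seed = 1) {
  ref <- simulate_reference(1, len, gc = gc, seed = seed)
  cl <- sample_bac_library(
    ref, bac_library_params("T", "GATC", insert_mean, insert_sd,
                            clone_count = n_clones),
    seed = seed + 1000)
  fps <- suppressMessages(
    quality_filter(fingerprint_clones(ref, cl, noise = noise,
                                      seed = seed + 2000)))$valid
  list(ref = ref, clones = cl, fps = fps)
}

# mate-pair world: reference, derived genome with given events, clones of
# two libraries, reads, alignments and statuses
bes_world <- function(lengths = c(1e6, 6e5), events = list(),
                      n_a = 40, n_b = 45, err_rate = 0, seed = 1,
                      repeat_density = 0) {
  ref <- simulate_reference(length(lengths), lengths, gc = 0.36,
                            repeat_density = repeat_density, seed = seed)
  dg <- apply_rearrangements(ref, events)
  cl <- rbind(
    sample_bac_library(dg, bac_library_params(
      "CHA", "GAATTC", 190, 25, clone_count = n_a), seed = seed + 1),
    sample_bac_library(dg, bac_library_params(
      "TKB", "GATC", 160, 20, clone_count = n_b), seed = seed + 2))
  bes <- suppressMessages(extract_bes(dg, cl, 600, err_rate,
                                      seed = seed + 3))
  ap <- alignment_params()
  aln <- align_bes_reads(bes, ref_index(ref), ap)
  st <- classify_mate_pairs(aln, cl, ap)
  list(ref = ref, dg = dg, clones = cl, bes = bes, aln = aln,
       statuses = st, params = ap)
}

# brute-force string count of probe occurrences (both strands)
count_occurrences <- function(genome_chars, probe) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  cnt <- 0L
  for (s in genome_chars) {
    for (p in unique(c(probe, rc))) {
      g <- gregexpr(p, s, fixed = TRUE)[[1]]
      cnt <- cnt + if (g[1] == -1) 0L else length(g)
    }
  }
  cnt
}

# maximum bipartite matching size between two band lists under tolerance,
# via igraph (independent oracle for the greedy matcher)
max_matching_bands <- function(a, b, t) {
  na <- length(a); nb <- length(b)
  edges <- integer(0)
  for (i in seq_len(na)) {
    js <- which(abs(b - a[i]) <= t)
    if (length(js)) edges <- c(edges, rbind(i, na + js))
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    edges)
  igraph::max_bipartite_match(g)$matching_size
}

# greedy interval-union oracle: number of coverage islands and spanned bp
coverage_islands <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  n_isl <- 0L; spanned <- 0
  cur_s <- NULL
  for (i in seq_along(starts)) {
    if (is.null(cur_s) || starts[i] > cur_e) {
      if (!is.null(cur_s)) spanned <- spanned + (cur_e - cur_s)
      n_isl <- n_isl + 1L
      cur_s <- starts[i]; cur_e <- ends[i]
    } else cur_e <- max(cur_e, ends[i])
  }
  spanned <- spanned + (cur_e - cur_s)
  list(n = n_isl, spanned = spanned)
}
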