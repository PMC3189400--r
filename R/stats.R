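## Coverage arithmetic and physical-map summary tables.

#' Genome coverage fold of a clone library
#'
#' Fold coverage = clones x mean insert / genome size, reported half-up to
#' one decimal (the convention of published library summary tables).
#'
#' @param n_clones number of clones.
#' @param mean_insert_kb mean insert size in kb.
#' @param genome_size_kb haploid genome size in kb.
#' @return fold coverage, one decimal.
#' @export
coverage_fold <- function(n_clones, mean_insert_kb, genome_size_kb) {
  if (n_clones <= 0 || mean_insert_kb <= 0 || genome_size_kb <= 0)
    stopf("all coverage inputs must be positive")
  round_half_up(n_clones * mean_insert_kb / genome_size_kb, 1)
}

#' Physical-map summary statistics
#'
#' Computes the standard whole-genome physical map summary (contig and
#' singleton counts, questionable-clone fraction, consensus bands, mean
#' bands per clone, mean clones per contig, per-clone length contribution,
#' mean/largest contig size, total physical length) either from an
#' assembled `fpc_map` plus its fingerprints, or from bare counts via
#' [physical_map_arithmetic()].
#'
#' @param map an `fpc_map`.
#' @param fps the validated fingerprint list that entered assembly.
#' @param kb_per_band physical length per consensus band, kb.
#' @return named list of summary statistics.
#' @export
summarize_physical_map <- function(map, fps, kb_per_band = 2.9) {
  sizes <- vapply(map$contigs, function(c) length(c$members), integer(1))
  cons <- vapply(map$contigs, `[[`, integer(1), "n_consensus")
  nq <- sum(vapply(map$contigs, function(c) length(c$q_clones),
                   integer(1)))
  physical_map_arithmetic(
    validated = length(fps),
    clones_in_contigs = sum(sizes),
    n_contigs = length(map$contigs),
    consensus_bands = sum(cons),
    q_clones = nq,
    mean_bands_per_clone = round_half_up(mean(lengths(fps)), 1),
    largest_contig_kb = if (length(cons))
      round_half_up(max(cons) * kb_per_band) else 0,
    kb_per_band = kb_per_band)
}

#' @rdname summarize_physical_map
#' @param validated number of validated clones that entered assembly.
#' @param clones_in_contigs clones placed in contigs.
#' @param n_contigs contig count.
#' @param consensus_bands total consensus bands across contigs.
#' @param q_clones questionable clones in contigs.
#' @param mean_bands_per_clone optional, carried through when known.
#' @param largest_contig_kb optional, carried through when known.
#' @export
physical_map_arithmetic <- function(validated, clones_in_contigs,
                                    n_contigs, consensus_bands,
                                    q_clones = NA,
                                    mean_bands_per_clone = NA,
                                    largest_contig_kb = NA,
                                    kb_per_band = 2.9) {
  total_kb <- consensus_bands * kb_per_band
  list(
    validated = validated,
    n_contigs = n_contigs,
    n_singletons = validated - clones_in_contigs,
    clones_in_contigs = clones_in_contigs,
    q_clones = q_clones,
    q_fraction_pct = if (is.na(q_clones) || validated == 0) NA
    else round_half_up(100 * q_clones / validated, 1),
    consensus_bands = consensus_bands,
    mean_bands_per_clone = mean_bands_per_clone,
    mean_clones_per_contig = if (n_contigs == 0) 0
    else round_half_up(clones_in_contigs / n_contigs, 1),
    kb_per_clone = if (clones_in_contigs == 0) 0
    else round_half_up(total_kb / clones_in_contigs, 1),
    mean_contig_kb = if (n_contigs == 0) 0
    else round_half_up(total_kb / n_contigs),
    largest_contig_kb = largest_contig_kb,
    total_length_kb = total_kb,
    total_length_mb = round_half_up(total_kb / 1000, 1))
}
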