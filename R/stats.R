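#' Per-sample capture enrichment statistics
#'
#' Classifies each unique read pair into exactly one of three categories:
#' on-target (any mate's primary or SA alignment touches the vector
#' scaffold, entirely or split), genome-only, or unmapped. Duplicates are
#' excluded first, mirroring upstream duplicate removal, so "unique read
#' pairs" is the post-dedup library size. The enrichment ratio is
#' vector-mapped over not-vector-mapped; because the literature is loose
#' about reads vs pairs, both a pair-based and a read-based version are
#' reported.
#'
#' @param records record data frame from [read_sam()].
#' @param refs a [reference_set()].
#' @return a `capture_stats` list: `unique_read_pairs`, `vector_pairs`,
#'   `genome_only_pairs`, `unmapped_pairs`, `pct_on_target`,
#'   `enrichment_ratio` (pair-based; `Inf` when nothing maps off the
#'   vector), read-level counterparts (`vector_reads`, `nonvector_reads`,
#'   `pct_on_target_reads`, `enrichment_ratio_reads`), and `no_pairs`
#'   (TRUE when the input was empty, in which case percentages are
#'   reported as 0).
#' @export
compute_capture_stats <- function(records, refs) {
  prim <- records[!records$is_secondary & !records$is_supplementary &
                    !records$is_duplicate, , drop = FALSE]
  if (nrow(prim) == 0L) {
    return(structure(list(
      unique_read_pairs = 0L, vector_pairs = 0L, genome_only_pairs = 0L,
      unmapped_pairs = 0L, pct_on_target = 0, enrichment_ratio = 0,
      vector_reads = 0L, nonvector_reads = 0L, pct_on_target_reads = 0,
      enrichment_ratio_reads = 0, no_pairs = TRUE
    ), class = "capture_stats"))
  }
  touches_vector <- function(rname, sa) {
    (!is.na(rname) & rname == refs$vector_name) |
      (!is.na(sa) & grepl(paste0("(^|;)", refs$vector_name, ","), sa))
  }
  vec_read <- touches_vector(prim$rname, prim$sa)

  by_pair <- split(seq_len(nrow(prim)), prim$qname)
  n_mates <- lengths(by_pair)
  orphan <- prim$is_paired[vapply(by_pair, `[`, 1L, 1L)] & n_mates == 1L
  if (any(orphan)) {
    warning(sum(orphan), " paired read(s) present as a single mate; ",
            "counted as single-read pairs")
  }
  pair_vec <- vapply(by_pair, function(idx) any(vec_read[idx]), TRUE)
  pair_unmapped <- vapply(by_pair, function(idx) all(prim$is_unmapped[idx]),
                          TRUE)
  n_pairs <- length(by_pair)
  vector_pairs <- sum(pair_vec)
  unmapped_pairs <- sum(!pair_vec & pair_unmapped)
  genome_only_pairs <- n_pairs - vector_pairs - unmapped_pairs

  nonvec_pairs <- n_pairs - vector_pairs
  vector_reads <- sum(vec_read)
  nonvector_reads <- nrow(prim) - vector_reads
  structure(list(
    unique_read_pairs = n_pairs,
    vector_pairs = as.integer(vector_pairs),
    genome_only_pairs = as.integer(genome_only_pairs),
    unmapped_pairs = as.integer(unmapped_pairs),
    pct_on_target = 100 * vector_pairs / n_pairs,
    enrichment_ratio = if (nonvec_pairs == 0L) Inf
                       else vector_pairs / nonvec_pairs,
    vector_reads = as.integer(vector_reads),
    nonvector_reads = as.integer(nonvector_reads),
    pct_on_target_reads = 100 * vector_reads / nrow(prim),
    enrichment_ratio_reads = if (nonvector_reads == 0L) Inf
                             else vector_reads / nonvector_reads,
    no_pairs = FALSE
  ), class = "capture_stats")
}

#' @export
print.capture_stats <- function(x, ...) {
  cat(sprintf(
    "capture stats: %d unique pairs | %d on-target (%.1f%%) | %d genome-only | %d unmapped | enrichment %.2fx\n",
    x$unique_read_pairs, x$vector_pairs, x$pct_on_target,
    x$genome_only_pairs, x$unmapped_pairs, x$enrichment_ratio))
  invisible(x)
}
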