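#' Read and write integration-site tables
#'
#' The site table is TSV with columns `sample`, `scaffold`, `genome_pos`,
#' `vector_pos`, `vector_end`, `strand`, `support`. All coordinates are
#' 1-based inclusive (SAM convention); this is stated in a comment header
#' line. A multi-sample table is the concatenation of per-sample tables.
#'
#' @param sites integration-site data frame from [call_sites()].
#' @param path file path.
#' @return `path` (writers, invisibly) or the site data frame (reader).
#' @export
write_site_table <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# integration sites; coordinates are 1-based inclusive", con)
  utils::write.table(sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @rdname write_site_table
#' @details `write_site_bed()` converts to BED's 0-based half-open
#'   intervals at write time (start = genome_pos - 1, end = genome_pos) and
#'   says so in the track header.
#' @export
write_site_bed <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0('track name="integration_sites" ',
                    'description="vector-genome junctions ',
                    '(0-based half-open; converted from 1-based calls)"'),
             con)
  if (nrow(sites) > 0L) {
    bed <- data.frame(sites$scaffold, sites$genome_pos - 1L,
                      sites$genome_pos,
                      paste0(sites$sample, "_", sites$vector_end),
                      sites$support,
                      ifelse(sites$strand %in% c("+", "-"), sites$strand,
                             "."))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a capture-stats block or a clonality report as JSON
#'
#' @param x a `capture_stats` or `clonality_report` object.
#' @param path output path.
#' @export
write_stats_json <- function(x, path) {
  y <- unclass(x)
  y$enrichment_ratio <- unbox_inf(y$enrichment_ratio)
  y$enrichment_ratio_reads <- unbox_inf(y$enrichment_ratio_reads)
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# JSON has no Inf; report the degenerate all-on-target denominator as a string
unbox_inf <- function(v) if (is.infinite(v)) "Inf" else v

#' @rdname write_stats_json
#' @export
write_clonality_json <- function(x, path) {
  y <- list(
    samples = x$samples,
    n_groups = x$n_groups,
    groups = x$groups,
    relations = as.data.frame(x$relations),
    jaccard = as.data.frame(x$jaccard),
    loci = as.list(x$loci),
    linked = x$linked,
    tolerance = x$tolerance,
    min_shared = x$min_shared
  )
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_stats_json
#' @details `write_relation_tsv()` writes the pairwise relation matrix as a
#'   human-readable TSV with sample ids on both axes.
#' @export
write_relation_tsv <- function(x, path) {
  utils::write.table(x$relations, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
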