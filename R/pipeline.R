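#' Call integration sites from a SAM file and write the outputs
#'
#' The `call` stage of the workflow: parse the alignments, extract split
#' reads spanning the vector-genome junction, filter, tabulate support,
#' threshold, and write a deterministic sorted site table plus a capture
#' statistics block. The per-stage filter funnel is logged via `message()`.
#'
#' @param sam_path input SAM file; its header must contain the vector
#'   scaffold named in `config`.
#' @param config a [caller_config()].
#' @param out_dir output directory (created if needed); files are
#'   `<sample>.sites.tsv`, `<sample>.sites.bed`, `<sample>.stats.json`.
#' @param sample sample label; defaults to the SAM file stem.
#' @return invisibly, `list(sites, stats)`.
#' @export
cmd_call <- function(sam_path, config = caller_config(), out_dir = ".",
                     sample = NULL) {
  if (!file.exists(sam_path)) stop("input not found: ", sam_path)
  if (is.null(sample)) sample <- sub("\\.sam$", "", basename(sam_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- read_sam(sam_path, vector_name = config$vector_name)
  if (nrow(x$records) == 0L) warning("no alignment records in ", sam_path)
  sites <- call_integration_sites(x$records, x$refs, config, sample = sample)
  stats <- compute_capture_stats(x$records, x$refs)
  funnel <- attr(sites, "funnel")
  message(sprintf(
    "[%s] records=%d dup_skipped=%d evidence=%d junctions=%d called=%d",
    sample, funnel["records"], funnel["duplicates_skipped"],
    funnel["evidence"], funnel["junctions"], funnel["called"]))
  write_site_table(sites, file.path(out_dir, paste0(sample, ".sites.tsv")))
  write_site_bed(sites, file.path(out_dir, paste0(sample, ".sites.bed")))
  write_stats_json(stats, file.path(out_dir, paste0(sample, ".stats.json")))
  invisible(list(sites = sites, stats = stats))
}

#' @rdname cmd_call
#' @details `cmd_stats()` computes and writes only the capture statistics.
#' @export
cmd_stats <- function(sam_path, config = caller_config(), out_dir = ".",
                      sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.sam$", "", basename(sam_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- read_sam(sam_path, vector_name = config$vector_name)
  stats <- compute_capture_stats(x$records, x$refs)
  write_stats_json(stats, file.path(out_dir, paste0(sample, ".stats.json")))
  invisible(stats)
}

#' Cross-sample clonality verification from site tables
#'
#' Reads one or more site tables (single- or multi-sample), groups samples
#' into lineages by shared integration sites, and writes the clonality
#' report. When `expect_single_lineage` is set the return value's
#' `verified` field says whether all samples grouped as one lineage — the
#' CI-style yes/no clonality check.
#'
#' @param site_tables paths of site-table TSVs, or a single multi-sample
#'   site data frame.
#' @param out_dir output directory for `clonality.json` and
#'   `relations.tsv`.
#' @param tolerance,min_shared,link_distance,end_pair_distance see
#'   [clonality_report()].
#' @param expect_single_lineage declare that all input samples should form
#'   one lineage.
#' @return invisibly, the [clonality_report()] with an added `verified`
#'   logical (`NA` when no expectation was declared).
#' @export
cmd_clonality <- function(site_tables, out_dir = ".", tolerance = 0L,
                          min_shared = 1L, link_distance = 10000L,
                          end_pair_distance = 500L,
                          expect_single_lineage = FALSE) {
  sites <- if (is.data.frame(site_tables)) site_tables
           else do.call(rbind, lapply(site_tables, read_site_table))
  if (anyDuplicated(sites[c("sample", "scaffold", "genome_pos",
                            "vector_end")])) {
    sites <- unique(sites)
  }
  ids <- unique(sites$sample)
  if (length(ids) < 2L) stop("clonality comparison needs >= 2 samples")
  samples <- split(sites, sites$sample)
  rep <- clonality_report(samples, tolerance = tolerance,
                          min_shared = min_shared,
                          link_distance = link_distance,
                          end_pair_distance = end_pair_distance)
  rep$verified <- if (expect_single_lineage) rep$n_groups == 1L else NA
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_clonality_json(rep, file.path(out_dir, "clonality.json"))
  write_relation_tsv(rep, file.path(out_dir, "relations.tsv"))
  invisible(rep)
}

#' Simulate a preset and write its reference, alignments and truth table
#'
#' @param preset a [sim_preset()] name.
#' @param out_dir output directory; writes `reference.fasta`,
#'   `<preset>.sam` and `<preset>.truth.tsv`.
#' @param seed RNG seed (drives both the reference and the reads).
#' @return invisibly, the simulated `list(records, truth)`.
#' @export
cmd_simulate <- function(preset, out_dir = ".", seed = 1L) {
  p <- sim_preset(preset, seed = seed)
  reference <- preset_reference(seed = seed)
  sim <- simulate_sam(p$truths, p$config, reference, sample = preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_fasta(reference, file.path(out_dir, "reference.fasta"))
  write_sam(sim$records, reference$refs,
            file.path(out_dir, paste0(preset, ".sam")))
  utils::write.table(sim$truth,
                     file.path(out_dir, paste0(preset, ".truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Simulate the full 32-sample cohort and call sites per sample
#'
#' Convenience wrapper used by the worked examples: simulates every cohort
#' sample from [cohort_presets()] against one shared reference and runs the
#' caller on each, returning the combined multi-sample site table.
#'
#' @param seed base RNG seed.
#' @param config a [caller_config()]; the multiplex preset by default.
#' @return a list with `sites` (combined site table) and `per_sample`
#'   (named list of per-sample site tables).
#' @export
run_cohort <- function(seed = 1L, config = caller_config()) {
  reference <- preset_reference(seed = seed)
  presets <- cohort_presets(seed = seed)
  per_sample <- lapply(names(presets), function(id) {
    p <- presets[[id]]
    sim <- simulate_sam(p$truths, p$config, reference, sample = id)
    call_integration_sites(sim$records, reference$refs, config, sample = id)
  })
  names(per_sample) <- names(presets)
  sites <- do.call(rbind, per_sample)
  rownames(sites) <- NULL
  list(sites = sites, per_sample = per_sample)
}
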