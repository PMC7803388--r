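test_that("make_reference is deterministic and validates arguments", {
  r1 <- make_reference(2, 50000, 8000, seed = 7)
  r2 <- make_reference(2, 50000, 8000, seed = 7)
  expect_identical(r1$sequences, r2$sequences)
  expect_equal(length(r1$sequences), 3L)
  expect_equal(names(r1$sequences), c("scaffold_1", "scaffold_2", "vector"))
  expect_equal(nchar(r1$sequences[["vector"]]), 8000L)
  r3 <- make_reference(2, 50000, 8000, seed = 8)
  expect_false(identical(r1$sequences, r3$sequences))
  expect_error(make_reference(0, 50000, 8000), "n_scaffolds")
  expect_error(make_reference(2, 500, 8000), "degenerate")

  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(r1, path)
  fa <- Biostrings::readDNAStringSet(path)
  expect_equal(length(fa), 3L)
  expect_equal(as.character(fa[["vector"]]), r1$sequences[["vector"]])
})

test_that("planted junctions yield exactly the configured number of unique split pairs", {
  reference <- preset_reference(seed = 2)
  tr <- integration_truth("scaffold_1", 20000L, "left", 150L, support = 20L)
  cfg <- sim_config(support_per_junction = 20L, seed = 9L,
                    flank_pairs_per_junction = 5L, vector_only_pairs = 5L,
                    genome_only_pairs = 5L, unmapped_pairs = 2L)
  sim <- simulate_sam(tr, cfg, reference, sample = "T")
  ev <- find_split_reads(sim$records, reference$refs, caller_config())
  expect_equal(length(unique(ev$qname)), 20L)
  expect_true(all(ev$genome_pos == 20000L))
  expect_true(all(ev$vector_pos == 150L))
  expect_true(all(ev$vector_end == "left"))
})

test_that("emitted split alignments are internally consistent SAM", {
  reference <- preset_reference(seed = 4)
  p <- sim_preset("sh87", seed = 4)
  sim <- simulate_sam(p$truths, p$config, reference, sample = "V")
  recs <- sim$records
  mapped <- recs[!recs$is_unmapped, ]
  # positions inside their scaffold
  for (i in seq_len(nrow(mapped))) {
    len <- if (mapped$rname[i] == "vector") reference$refs$vector_length
           else reference$refs$lengths[[mapped$rname[i]]]
    expect_lte(mapped$pos[i] + reference_span(mapped$cigar[i]) - 1L, len)
    expect_gte(mapped$pos[i], 1L)
  }
  # primary and SA halves account for the same read length, with
  # complementary clip/aligned structure
  with_sa <- mapped[!is.na(mapped$sa), ]
  expect_gt(nrow(with_sa), 0L)
  aligned_len <- function(cg) query_span(cg) - sum(clip_lengths(cg))
  for (i in seq_len(nrow(with_sa))) {
    sa <- parse_sa_tag(with_sa$sa[i])
    expect_equal(query_span(with_sa$cigar[i]), query_span(sa$cigar[1]))
    # the two halves tile the read: aligned portions are complementary
    expect_equal(aligned_len(with_sa$cigar[i]) + aligned_len(sa$cigar[1]),
                 query_span(with_sa$cigar[i]))
  }
  # read sequences match the declared read length
  expect_true(all(nchar(mapped$seq) == p$config$read_len))
})

test_that("fixed seed reproduces byte-identical SAM; seeds differ otherwise", {
  reference <- preset_reference(seed = 2)
  p <- sim_preset("lineage_A", seed = 11)
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(simulate_sam(p$truths, p$config, reference, "A")$records,
            reference$refs, f1)
  write_sam(simulate_sam(p$truths, p$config, reference, "A")$records,
            reference$refs, f2)
  expect_identical(readLines(f1), readLines(f2))
  p2 <- sim_preset("lineage_A", seed = 12)
  f3 <- withr::local_tempfile(fileext = ".sam")
  write_sam(simulate_sam(p2$truths, p2$config, reference, "A")$records,
            reference$refs, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("duplicate-flagged copies change nothing after dedup", {
  reference <- preset_reference(seed = 2)
  tr <- integration_truth("scaffold_1", 20000L, "left", 150L, support = 10L)
  cfg0 <- sim_config(seed = 5L, dup_rate = 0, flank_pairs_per_junction = 2L,
                     vector_only_pairs = 2L, genome_only_pairs = 2L,
                     unmapped_pairs = 0L)
  cfg5 <- sim_config(seed = 5L, dup_rate = 0.5, flank_pairs_per_junction = 2L,
                     vector_only_pairs = 2L, genome_only_pairs = 2L,
                     unmapped_pairs = 0L)
  s0 <- simulate_sam(tr, cfg0, reference, "D")
  s5 <- simulate_sam(tr, cfg5, reference, "D")
  expect_gt(nrow(s5$records), nrow(s0$records))
  expect_true(any(s5$records$is_duplicate))
  call0 <- call_integration_sites(s0$records, reference$refs,
                                  caller_config(), "D")
  call5 <- call_integration_sites(s5$records, reference$refs,
                                  caller_config(), "D")
  expect_equal(call0$support, call5$support)
  expect_equal(call0$genome_pos, call5$genome_pos)
})

test_that("low-MAPQ decoy chimeras are filtered out of the calls", {
  reference <- preset_reference(seed = 2)
  tr <- integration_truth("scaffold_1", 20000L, "left", 150L, support = 12L)
  cfg <- sim_config(seed = 6L, decoy_n = 3L, decoy_mapq = 10L,
                    decoy_support = 8L, flank_pairs_per_junction = 2L,
                    vector_only_pairs = 2L, genome_only_pairs = 2L,
                    unmapped_pairs = 0L)
  sim <- simulate_sam(tr, cfg, reference, "D")
  sites <- call_integration_sites(sim$records, reference$refs,
                                  caller_config(), "D")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$genome_pos, 20000L)
  # the decoys are present in the alignment stream, just rejected
  expect_gt(sum(grepl("_dc", sim$records$qname)), 0L)
})

test_that("suppressed-SA junctions produce genome-only reads and no call", {
  reference <- preset_reference(seed = 2)
  tr <- integration_truth("scaffold_3", 30045L, "right", 7850L,
                          support = 10L, suppress_sa = TRUE)
  cfg <- sim_config(seed = 7L, flank_pairs_per_junction = 0L,
                    vector_only_pairs = 0L, genome_only_pairs = 0L,
                    unmapped_pairs = 0L)
  sim <- simulate_sam(tr, cfg, reference, "C")
  expect_true(all(is.na(sim$records$sa)))
  sites <- call_integration_sites(sim$records, reference$refs,
                                  caller_config(), "C")
  expect_equal(nrow(sites), 0L)
})

test_that("a junction too close to a sequence edge is a placement error", {
  reference <- preset_reference(seed = 2)
  tr <- integration_truth("scaffold_1", 10L, "left", 150L, support = 2L)
  cfg <- sim_config(seed = 1L)
  expect_error(simulate_sam(tr, cfg, reference, "X"), "placement error")
})

test_that("read depth decays with distance from the junction", {
  reference <- preset_reference(seed = 2)
  tr <- integration_truth("scaffold_1", 40000L, "right", 7800L,
                          support = 30L)
  cfg <- sim_config(seed = 8L, flank_pairs_per_junction = 400L,
                    capture_decay = 0.005, vector_only_pairs = 0L,
                    genome_only_pairs = 0L, unmapped_pairs = 0L)
  sim <- simulate_sam(tr, cfg, reference, "W")
  recs <- sim$records[sim$records$rname == "scaffold_1" &
                        !sim$records$is_unmapped, ]
  starts <- recs$pos - 40000L
  win <- cut(starts, breaks = c(0, 400, 800, 1200, 1600), right = FALSE)
  counts <- as.integer(table(win))
  expect_true(all(diff(counts) <= 0))
})

test_that("presets encode the expected junction structures", {
  expect_equal(nrow(sim_preset("sh87")$truths), 6L)
  a <- sim_preset("lineage_A")$truths
  expect_equal(nrow(a), 2L)
  expect_setequal(a$vector_end, c("left", "right"))
  expect_equal(abs(diff(a$genome_pos)), 30L)
  e <- sim_preset("lineage_E")$truths
  expect_equal(length(unique(e$scaffold)), 3L)
  expect_equal(nrow(e), 4L)
  expect_error(sim_preset("lineage_Z"))
})
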