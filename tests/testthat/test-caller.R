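test_that("junction_position applies the leading-match / leading-clip rules", {
  expect_equal(junction_position(1000, "60M40S", "right"), 1060L)
  expect_equal(junction_position(5000, "40S60M", "left"), 5000L)
  # deletion inside the aligned block shifts the junction; oracle-checked
  expect_equal(ref_span_oracle("30M2D30M40S"), 62L)
  expect_equal(junction_position(200, "30M2D30M40S", "right"), 262L)
  # side inferred from the CIGAR when not given
  expect_equal(junction_position(1000, "60M40S"), 1060L)
  expect_equal(junction_position(5000, "40S60M"), 5000L)
  expect_error(junction_position(1000, "100M", "right"),
               "inconsistent evidence")
  expect_error(junction_position(1000, "60M40S", "left"),
               "inconsistent evidence")
})

test_that("extract_split_evidence pairs a genome half with its vector SA entry", {
  refs <- test_refs()
  rec <- parse_sam_line(split_sam_line())  # 1000 60M40S + vector,1,+,60S40M
  ev <- extract_split_evidence(rec, refs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$scaffold, "scaffold_1")
  expect_equal(ev$genome_pos, 1060L)
  expect_equal(ev$vector_pos, 1L)
  expect_equal(ev$vector_end, "left")

  # direction reversed: primary on the vector, SA on the genome
  rec2 <- parse_sam_line(split_sam_line(
    rname = "vector", pos = 7900L, cigar = "60M40S",
    sa = "scaffold_1,5000,+,60S40M,60,0;"))
  ev2 <- extract_split_evidence(rec2, refs)
  expect_equal(ev2$scaffold, "scaffold_1")
  expect_equal(ev2$genome_pos, 5000L)
  expect_equal(ev2$vector_pos, 7960L)
  expect_equal(ev2$vector_end, "right")
})

test_that("non-junction and filtered records yield no evidence", {
  refs <- test_refs()
  cfg <- caller_config()
  none <- function(line) {
    nrow(extract_split_evidence(parse_sam_line(line), refs, cfg))
  }
  # genome-genome chimera
  expect_equal(none(split_sam_line(sa = "scaffold_2,500,+,60S40M,60,0;")), 0L)
  # vector-side MAPQ at the floor (30 is not > 30)
  expect_equal(none(split_sam_line(sa = "vector,1,+,60S40M,30,0;")), 0L)
  expect_equal(none(split_sam_line(sa = "vector,1,+,60S40M,20,0;")), 0L)
  # genome-side MAPQ at the floor
  expect_equal(none(split_sam_line(mapq = 30L)), 0L)
  # NM at the ceiling (4 is not < 4), either half
  expect_equal(none(split_sam_line(nm = 4L)), 0L)
  expect_equal(none(split_sam_line(sa = "vector,1,+,60S40M,60,4;")), 0L)
  # absent NM on the primary fails the filter
  expect_equal(none(split_sam_line(nm = NA)), 0L)
  # duplicates and secondaries are skipped
  expect_equal(none(split_sam_line(flag = 99L + 0x400L)), 0L)
  expect_equal(none(split_sam_line(flag = 99L + 0x100L)), 0L)
  # unknown SA scaffold is a reference mismatch, not silence
  expect_error(
    extract_split_evidence(
      parse_sam_line(split_sam_line(sa = "chrX,1,+,60S40M,60,0;")),
      refs, cfg),
    "reference mismatch")
})

test_that("tabulate_junctions counts a read pair once and distinct reads separately", {
  refs <- test_refs()
  # both mates of one pair support the same junction -> one count
  pair <- records_from_lines(c(
    split_sam_line("p1", flag = 99L),
    split_sam_line("p1", flag = 147L)))
  cand <- tabulate_junctions(find_split_reads(pair, refs, caller_config()))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$support, 1L)

  two <- records_from_lines(c(split_sam_line("p1"), split_sam_line("p2")))
  cand2 <- tabulate_junctions(find_split_reads(two, refs, caller_config()))
  expect_equal(cand2$support, 2L)

  expect_equal(nrow(tabulate_junctions(find_split_reads(
    pair[0, ], refs, caller_config()))), 0L)
})

test_that("a supplementary record never double-counts its primary's SA evidence", {
  refs <- test_refs()
  recs <- records_from_lines(c(
    split_sam_line("p1", flag = 99L),
    # the corresponding supplementary record (0x800), SA points back
    split_sam_line("p1", flag = 99L + 0x800L, rname = "vector", pos = 1L,
                   cigar = "60S40M",
                   sa = "scaffold_1,1000,+,60M40S,60,0;")))
  cand <- tabulate_junctions(find_split_reads(recs, refs, caller_config()))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$support, 1L)
})

test_that("call_sites thresholds at min_support and merges within the window", {
  cfg15 <- caller_config(preset = "deep")
  mk <- function(pos, n, qprefix) {
    ev <- do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      qname = paste0(qprefix, i), mate = 1L, scaffold = "scaffold_1",
      genome_pos = pos, genome_strand = "+", genome_mapq = 60L,
      genome_nm = 0L, vector_pos = 1L, vector_end = "left",
      vector_mapq = 60L, vector_nm = 0L, stringsAsFactors = FALSE)))
    ev
  }
  expect_equal(nrow(call_sites(tabulate_junctions(mk(100, 20, "a")), cfg15)),
               1L)
  expect_equal(nrow(call_sites(tabulate_junctions(mk(100, 15, "a")), cfg15)),
               1L)
  expect_equal(nrow(call_sites(tabulate_junctions(mk(100, 14, "a")), cfg15)),
               0L)

  # merge-then-threshold: 4 @ 5000 and 3 @ 5002, window 5, min_support 5
  cand <- tabulate_junctions(rbind(mk(5000, 4, "a"), mk(5002, 3, "b")))
  cfg_m <- caller_config(min_support = 5L, merge_window = 5L)
  merged <- call_sites(cand, cfg_m)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$support, 7L)
  expect_equal(merged$genome_pos, 5000L)
  # without merging, neither survives
  expect_equal(nrow(call_sites(cand, caller_config(min_support = 5L))), 0L)
})

test_that("tightening any filter never adds a called site (monotonicity)", {
  refs <- test_refs()
  set.seed(11)
  lines <- unlist(lapply(1:6, function(k) {
    support_lines(sample(3:12, 1), qprefix = sprintf("j%d_", k),
                  genome_pos_cigar_start = 1000L * k,
                  mapq = sample(c(25L, 35L, 60L), 1),
                  nm = sample(0:5, 1))
  }))
  recs <- records_from_lines(lines, refs)
  base_cfg <- caller_config(min_support = 3L, min_mapq = 20L, max_nm = 6L)
  base <- call_integration_sites(recs, refs, base_cfg)
  key <- function(s) paste(s$scaffold, s$genome_pos, s$vector_end)
  for (cfg in list(caller_config(min_support = 8L, min_mapq = 20L, max_nm = 6L),
                   caller_config(min_support = 3L, min_mapq = 30L, max_nm = 6L),
                   caller_config(min_support = 3L, min_mapq = 20L, max_nm = 2L))) {
    tighter <- call_integration_sites(recs, refs, cfg)
    expect_true(all(key(tighter) %in% key(base)))
    expect_lte(nrow(tighter), nrow(base))
  }
})

test_that("support is conserved: total support <= distinct contributing reads", {
  refs <- test_refs()
  set.seed(13)
  lines <- unlist(lapply(1:5, function(k) {
    support_lines(sample(2:9, 1), qprefix = sprintf("q%d_", k),
                  genome_pos_cigar_start = 500L * k)
  }))
  recs <- records_from_lines(lines, refs)
  ev <- find_split_reads(recs, refs, caller_config())
  cand <- tabulate_junctions(ev)
  expect_lte(sum(cand$support), length(unique(ev$qname)))
  expect_equal(sum(cand$support), length(unique(ev$qname)))  # disjoint junctions
})

test_that("call_sites is idempotent over already-called candidates", {
  cfg <- caller_config(min_support = 5L)
  ev <- do.call(rbind, lapply(1:8, function(i) data.frame(
    qname = paste0("r", i), mate = 1L, scaffold = "scaffold_1",
    genome_pos = 1060L, genome_strand = "+", genome_mapq = 60L,
    genome_nm = 0L, vector_pos = 1L, vector_end = "left",
    vector_mapq = 60L, vector_nm = 0L, stringsAsFactors = FALSE)))
  cand <- tabulate_junctions(ev)
  once <- call_sites(cand, cfg)
  again <- call_sites(cand[cand$support >= cfg$min_support, , drop = FALSE],
                      cfg)
  expect_equal(once, again)
})

test_that("called sites never fall on the vector scaffold", {
  reference <- preset_reference(seed = 5)
  p <- sim_preset("lineage_E", seed = 5)
  sim <- simulate_sam(p$truths, p$config, reference, sample = "E")
  sites <- call_integration_sites(sim$records, reference$refs,
                                  caller_config(), sample = "E")
  expect_gt(nrow(sites), 0L)
  expect_false(any(sites$scaffold == reference$refs$vector_name))
})
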