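# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a random reference: genome scaffolds plus an appended vector
#'
#' Emulates the alignment reference used by the pipeline: a genome assembly
#' with the linearized vector sequence added as one extra named scaffold.
#' Sequences are i.i.d. uniform bases (no repeat structure).
#'
#' @param n_scaffolds number of genome scaffolds (>= 1).
#' @param scaffold_len length of each genome scaffold, bp.
#' @param vector_len length of the vector scaffold, bp.
#' @param seed RNG seed; the same seed reproduces the reference exactly.
#' @param vector_name name for the vector scaffold.
#' @return a list with `refs` (a [reference_set()]) and `sequences`
#'   (named character vector of scaffold sequences, vector included).
#' @export
make_reference <- function(n_scaffolds, scaffold_len, vector_len, seed = 1L,
                           vector_name = "vector") {
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  if (scaffold_len < 1000L || vector_len < 1000L) {
    stop("degenerate reference lengths (need >= 10 read lengths)")
  }
  scaffolds <- sprintf("scaffold_%d", seq_len(n_scaffolds))
  sequences <- with_seed(seed, {
    v <- vapply(c(rep(scaffold_len, n_scaffolds), vector_len), function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
    names(v) <- c(scaffolds, vector_name)
    v
  })
  lens <- rep(as.integer(scaffold_len), n_scaffolds)
  names(lens) <- scaffolds
  list(refs = reference_set(scaffolds, vector_name, vector_len,
                            lengths = lens),
       sequences = sequences)
}

#' @rdname make_reference
#' @param reference the list returned by `make_reference()`.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$sequences), path)
  invisible(path)
}

#' Planted integration-junction ground truth
#'
#' @param scaffold genome scaffold of the junction.
#' @param genome_pos 1-based planted junction coordinate.
#' @param vector_end which vector terminus abuts the genome
#'   (`"left"`/`"right"`).
#' @param vector_pos 1-based junction coordinate on the vector.
#' @param support number of unique junction-spanning pairs to emit
#'   (`NA` uses the configuration default).
#' @param suppress_sa emit the genome half only, with no SA tag — models a
#'   junction whose vector side maps ambiguously (e.g. into a duplicated
#'   vector element) so the aligner reports no chimeric alignment.
#' @return a one-row data frame; rbind rows to build a truth set.
#' @export
integration_truth <- function(scaffold, genome_pos, vector_end, vector_pos,
                              support = NA_integer_, suppress_sa = FALSE) {
  stopifnot(vector_end %in% c("left", "right"))
  data.frame(scaffold = scaffold, genome_pos = as.integer(genome_pos),
             vector_end = vector_end, vector_pos = as.integer(vector_pos),
             support = as.integer(support), suppress_sa = suppress_sa,
             stringsAsFactors = FALSE)
}

#' Simulator configuration
#'
#' Defaults emulate the multiplexed clonality runs: 100 bp paired-end reads
#' from fragments averaging 250 bp; the deep-capture preset in
#' [sim_preset()] switches to 250 bp reads from 500 bp fragments. Capture
#' probability decays with distance from the junction, so genome-only
#' background pairs are placed at exponentially distributed distances.
#'
#' @param read_len read length, bp.
#' @param fragment_mean,fragment_sd fragment length distribution, bp.
#' @param support_per_junction default unique junction-spanning pairs per
#'   planted junction.
#' @param capture_decay rate (per bp) of the exponential fall-off of
#'   capture probability with distance from a junction.
#' @param flank_pairs_per_junction genome-only pairs emitted near each
#'   junction (the decaying pileup flank).
#' @param vector_only_pairs,genome_only_pairs,unmapped_pairs background
#'   pair counts per sample.
#' @param dup_rate fraction of emitted pairs re-emitted as duplicate-flagged
#'   copies (flag 0x400); in `[0, 1]`.
#' @param decoy_n,decoy_mapq,decoy_support spurious vector-genome chimeras:
#'   how many decoy junctions, their mapping quality, and their support.
#' @param nm_value NM tag value assigned to planted split reads (0 =
#'   error-free mode; sequences are not altered).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(read_len = 100L, fragment_mean = 250L,
                       fragment_sd = 30L, support_per_junction = 20L,
                       capture_decay = 0.01, flank_pairs_per_junction = 20L,
                       vector_only_pairs = 40L, genome_only_pairs = 40L,
                       unmapped_pairs = 4L, dup_rate = 0,
                       decoy_n = 0L, decoy_mapq = 10L, decoy_support = 3L,
                       nm_value = 0L, seed = 1L) {
  stopifnot(dup_rate >= 0, dup_rate <= 1, capture_decay > 0,
            read_len >= 50L, support_per_junction >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

# One SAM record as a one-row data frame (seq filled in later).
sim_record <- function(qname, flag, rname, pos, mapq, cigar,
                       rnext = "*", pnext = 0L, tlen = 0L,
                       nm = NA_integer_, sa = NA_character_) {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext),
             tlen = as.integer(tlen), nm = nm, sa = sa,
             stringsAsFactors = FALSE)
}

# Extract the read sequence implied by an alignment geometry.
seq_for <- function(sequences, rname, pos, len) {
  if (is.null(sequences) || is.na(rname)) return(NA_character_)
  substr(sequences[[rname]], pos, pos + len - 1L)
}

#' Simulate aligned reads over planted integration junctions
#'
#' Emits, per junction, the configured number of unique junction-spanning
#' read pairs as primary alignments with SA tags whose CIGARs, positions
#' and clip lengths are mutually consistent (error-free mode: MAPQ 60,
#' NM 0), plus genome-only flanking pairs at exponentially decaying
#' distances from the junction, vector-only / genome-only / unmapped
#' background pairs, optional duplicate-flagged copies, and optional
#' low-quality decoy chimeras. Reads are emitted directly as alignments
#' (SAM), not as FASTQ through an aligner, which keeps tests hermetic.
#'
#' @param truths truth data frame built from [integration_truth()] rows.
#' @param config a [sim_config()].
#' @param reference a reference from [make_reference()] (its `refs` and
#'   `sequences`; pass a bare [reference_set()] to omit sequences).
#' @param sample sample label used in read names.
#' @return a list with `records` (data frame in [read_sam()] layout, with
#'   `seq` when sequences are available) and `truth` (the input truths with
#'   the realized `planted_support` column).
#' @export
simulate_sam <- function(truths, config, reference, sample = "S") {
  refs <- if (inherits(reference, "reference_set")) reference else reference$refs
  sequences <- if (inherits(reference, "reference_set")) NULL else reference$sequences
  L <- config$read_len
  bad <- !truths$scaffold %in% refs$scaffolds
  if (any(bad)) stop("truth scaffold not in reference: ",
                     truths$scaffold[which(bad)[1]])

  scaffold_len <- function(sc) {
    if (is.null(refs$lengths)) .Machine$integer.max else refs$lengths[[sc]]
  }

  with_seed(config$seed, {
    out <- list()
    planted <- integer(nrow(truths))

    split_pair <- function(qname, sc, g, end, v, mapq, nm, suppress_sa) {
      k <- sample(seq(25L, L - 25L), 1L)  # genome-side aligned length
      m <- L - k
      if (end == "left") {
        gpos <- g - k; gcig <- sprintf("%dM%dS", k, m)
        vpos <- v; vcig <- sprintf("%dS%dM", k, m)
        if (gpos < 1L || v + m - 1L > refs$vector_length) {
          stop("placement error: junction ", sc, ":", g,
               " too close to a sequence edge")
        }
      } else {
        gpos <- g; gcig <- sprintf("%dS%dM", m, k)
        vpos <- v - m; vcig <- sprintf("%dM%dS", m, k)
        if (g + k - 1L > scaffold_len(sc) || vpos < 1L) {
          stop("placement error: junction ", sc, ":", g,
               " too close to a sequence edge")
        }
      }
      gseq <- seq_for(sequences, sc, gpos, k)
      vseq <- seq_for(sequences, refs$vector_name, vpos, m)
      rseq <- if (is.na(gseq)) NA_character_
              else if (end == "left") paste0(gseq, vseq) else paste0(vseq, gseq)
      if (suppress_sa) {
        r1 <- sim_record(qname, 99L, sc, gpos, mapq, gcig,
                         rnext = sc, pnext = gpos, nm = nm)
        r1$seq <- rseq
        mpos <- max(1L, gpos - L)
        r2 <- sim_record(qname, 147L, sc, mpos, mapq, sprintf("%dM", L),
                         rnext = sc, pnext = gpos, nm = nm)
        r2$seq <- seq_for(sequences, sc, mpos, L)
        return(rbind(r1, r2))
      }
      genome_primary <- k >= m  # aligner keeps the longer half primary
      sa_g <- sprintf("%s,%d,+,%s,%d,%d;", sc, gpos, gcig, mapq, nm)
      sa_v <- sprintf("%s,%d,+,%s,%d,%d;", refs$vector_name, vpos, vcig,
                      mapq, nm)
      if (genome_primary) {
        r1 <- sim_record(qname, 99L, sc, gpos, mapq, gcig,
                         rnext = refs$vector_name, pnext = vpos,
                         nm = nm, sa = sa_v)
      } else {
        r1 <- sim_record(qname, 99L, refs$vector_name, vpos, mapq, vcig,
                         rnext = refs$vector_name, pnext = vpos,
                         nm = nm, sa = sa_g)
      }
      r1$seq <- rseq
      # mate maps fully inside the vector near the junction (captured side)
      mpos <- if (end == "left") min(v + 5L, refs$vector_length - L + 1L)
              else max(1L, v - m - L - 5L)
      r2 <- sim_record(qname, 147L, refs$vector_name, mpos, mapq,
                       sprintf("%dM", L), rnext = refs$vector_name,
                       pnext = mpos, nm = nm)
      r2$seq <- seq_for(sequences, refs$vector_name, mpos, L)
      rbind(r1, r2)
    }

    for (ti in seq_len(nrow(truths))) {
      t <- truths[ti, ]
      s <- if (is.na(t$support)) config$support_per_junction else t$support
      planted[ti] <- s
      for (j in seq_len(s)) {
        qn <- sprintf("%s_jx%02d_%04d", sample, ti, j)
        out[[length(out) + 1L]] <-
          split_pair(qn, t$scaffold, t$genome_pos, t$vector_end,
                     t$vector_pos, 60L, config$nm_value, t$suppress_sa)
      }
      # genome-only flank pairs: capture probability decays with distance
      for (j in seq_len(config$flank_pairs_per_junction)) {
        d <- ceiling(stats::rexp(1, config$capture_decay))
        frag <- max(2L * L,
                    round(stats::rnorm(1, config$fragment_mean,
                                       config$fragment_sd)))
        if (t$vector_end == "left") {
          start <- t$genome_pos - d - frag
          if (start < 1L) next
          p1 <- start; p2 <- start + frag - L
        } else {
          start <- t$genome_pos + d
          if (start + frag - 1L > scaffold_len(t$scaffold)) next
          p1 <- start; p2 <- start + frag - L
        }
        qn <- sprintf("%s_fl%02d_%04d", sample, ti, j)
        r1 <- sim_record(qn, 99L, t$scaffold, p1, 60L, sprintf("%dM", L),
                         rnext = t$scaffold, pnext = p2, nm = 0L)
        r1$seq <- seq_for(sequences, t$scaffold, p1, L)
        r2 <- sim_record(qn, 147L, t$scaffold, p2, 60L, sprintf("%dM", L),
                         rnext = t$scaffold, pnext = p1, nm = 0L)
        r2$seq <- seq_for(sequences, t$scaffold, p2, L)
        out[[length(out) + 1L]] <- rbind(r1, r2)
      }
    }

    # decoy chimeras: spurious junctions with configurable (low) MAPQ
    if (config$decoy_n > 0L) {
      for (di in seq_len(config$decoy_n)) {
        sc <- sample(refs$scaffolds, 1L)
        g <- sample(seq(5L * L, scaffold_len(sc) - 5L * L), 1L)
        v <- sample(seq(2L * L, refs$vector_length - 2L * L), 1L)
        end <- sample(c("left", "right"), 1L)
        for (j in seq_len(config$decoy_support)) {
          qn <- sprintf("%s_dc%02d_%04d", sample, di, j)
          out[[length(out) + 1L]] <-
            split_pair(qn, sc, g, end, v, config$decoy_mapq,
                       config$nm_value, FALSE)
        }
      }
    }

    for (j in seq_len(config$vector_only_pairs)) {
      p1 <- sample(seq_len(refs$vector_length - 3L * L), 1L)
      p2 <- p1 + L + 20L
      qn <- sprintf("%s_vo_%04d", sample, j)
      r1 <- sim_record(qn, 99L, refs$vector_name, p1, 60L,
                       sprintf("%dM", L), rnext = refs$vector_name,
                       pnext = p2, nm = 0L)
      r1$seq <- seq_for(sequences, refs$vector_name, p1, L)
      r2 <- sim_record(qn, 147L, refs$vector_name, p2, 60L,
                       sprintf("%dM", L), rnext = refs$vector_name,
                       pnext = p1, nm = 0L)
      r2$seq <- seq_for(sequences, refs$vector_name, p2, L)
      out[[length(out) + 1L]] <- rbind(r1, r2)
    }
    for (j in seq_len(config$genome_only_pairs)) {
      sc <- sample(refs$scaffolds, 1L)
      p1 <- sample(seq(1L, scaffold_len(sc) - 3L * L), 1L)
      p2 <- p1 + L + 20L
      qn <- sprintf("%s_go_%04d", sample, j)
      r1 <- sim_record(qn, 99L, sc, p1, 60L, sprintf("%dM", L),
                       rnext = sc, pnext = p2, nm = 0L)
      r1$seq <- seq_for(sequences, sc, p1, L)
      r2 <- sim_record(qn, 147L, sc, p2, 60L, sprintf("%dM", L),
                       rnext = sc, pnext = p1, nm = 0L)
      r2$seq <- seq_for(sequences, sc, p2, L)
      out[[length(out) + 1L]] <- rbind(r1, r2)
    }
    for (j in seq_len(config$unmapped_pairs)) {
      qn <- sprintf("%s_um_%04d", sample, j)
      r1 <- sim_record(qn, 77L, NA_character_, NA_integer_, 0L,
                       NA_character_)
      r2 <- sim_record(qn, 141L, NA_character_, NA_integer_, 0L,
                       NA_character_)
      r1$seq <- if (is.null(sequences)) NA_character_
                else paste(rep("N", L), collapse = "")
      r2$seq <- r1$seq
      out[[length(out) + 1L]] <- rbind(r1, r2)
    }

    records <- do.call(rbind, out)

    # PCR duplicates: re-emit a fraction of pairs, duplicate-flagged, under
    # fresh read names (upstream marking flags the copy, not the original)
    if (config$dup_rate > 0) {
      qnames <- unique(records$qname)
      n_dup <- floor(config$dup_rate * length(qnames))
      if (n_dup > 0L) {
        pick <- sample(qnames, n_dup)
        dup <- records[records$qname %in% pick, , drop = FALSE]
        dup$flag <- bitwOr(dup$flag, 0x400L)
        dup$qname <- paste0(dup$qname, "_dup")
        records <- rbind(records, dup)
      }
    }

    if (is.null(sequences)) records$seq <- NULL
    records <- cbind(records, decode_flag(records$flag))
    rownames(records) <- NULL
    truth <- truths
    truth$planted_support <- planted
    list(records = records, truth = truth)
  })
}

#' Named simulation presets emulating the study's integration structures
#'
#' * `sh87` — the deep-capture validation cell line: three integration loci,
#'   each with both vector ends recovered, i.e. six vector-genome junctions;
#'   250 bp reads from 500 bp fragments, support 25 per junction (called
#'   under the deep threshold of 15).
#' * `lineage_A` — one locus with both vector ends 30 bp apart.
#' * `lineage_B`, `lineage_D` — one junction (a single vector end) each.
#' * `lineage_C` — one called junction plus a second end ~45 bp away whose
#'   vector side is unmappable (`suppress_sa`), so only one end is called.
#' * `lineage_E` — three loci on three scaffolds; one locus with both ends
#'   100 bp apart (four junctions total).
#'
#' Lineage presets use 100 bp reads from 250 bp fragments and ~10 supporting
#' pairs per junction (called under the multiplex threshold of 5). All
#' presets place each lineage's sites on distinct scaffolds of the default
#' 7-scaffold reference from [preset_reference()].
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned configuration.
#' @return a list with `truths` and `config`, ready for [simulate_sam()].
#' @export
sim_preset <- function(name = c("sh87", "lineage_A", "lineage_B",
                                "lineage_C", "lineage_D", "lineage_E"),
                       seed = 1L) {
  name <- match.arg(name)
  lin_cfg <- sim_config(read_len = 100L, fragment_mean = 250L,
                        support_per_junction = 10L,
                        flank_pairs_per_junction = 8L,
                        vector_only_pairs = 30L, genome_only_pairs = 15L,
                        unmapped_pairs = 2L, seed = seed)
  tr <- switch(
    name,
    sh87 = rbind(
      integration_truth("scaffold_1", 15000L, "left", 120L),
      integration_truth("scaffold_1", 15040L, "right", 7880L),
      integration_truth("scaffold_2", 25000L, "left", 120L),
      integration_truth("scaffold_2", 25040L, "right", 7880L),
      integration_truth("scaffold_3", 35000L, "left", 120L),
      integration_truth("scaffold_3", 35040L, "right", 7880L)
    ),
    lineage_A = rbind(
      integration_truth("scaffold_1", 18000L, "left", 120L),
      integration_truth("scaffold_1", 18030L, "right", 7880L)
    ),
    lineage_B = integration_truth("scaffold_2", 22000L, "left", 150L),
    lineage_C = rbind(
      integration_truth("scaffold_3", 30000L, "left", 200L),
      integration_truth("scaffold_3", 30045L, "right", 7850L,
                        suppress_sa = TRUE)
    ),
    lineage_D = integration_truth("scaffold_4", 40000L, "right", 7800L),
    lineage_E = rbind(
      integration_truth("scaffold_5", 12000L, "left", 130L),
      integration_truth("scaffold_6", 20000L, "left", 140L),
      integration_truth("scaffold_6", 20100L, "right", 7870L),
      integration_truth("scaffold_7", 33000L, "left", 160L)
    )
  )
  cfg <- if (name == "sh87") {
    sim_config(read_len = 250L, fragment_mean = 500L, fragment_sd = 60L,
               support_per_junction = 25L, flank_pairs_per_junction = 20L,
               vector_only_pairs = 60L, genome_only_pairs = 40L,
               unmapped_pairs = 4L, seed = seed)
  } else lin_cfg
  list(truths = tr, config = cfg)
}

#' @rdname sim_preset
#' @return `preset_reference()` returns the 7-scaffold reference (60 kb
#'   scaffolds, 8 kb vector) the presets are laid out on.
#' @export
preset_reference <- function(seed = 1L) {
  make_reference(n_scaffolds = 7L, scaffold_len = 60000L,
                 vector_len = 8000L, seed = seed)
}

#' The multiplexed clonality cohort: 32 samples from five lineages
#'
#' Thirty-one cell lines — 13 from lineage A (A-1 additionally run in
#' duplicate as A-1D), 3 from B, unrelated singletons C-1 and D-1, and 13
#' from E — for 32 samples total. Sample-specific deviations mirror the
#' observed structures: A-2 carries an extra junction 1 kbp downstream of
#' its locus; E-2 and E-10 carry an extra junction 4.7 kbp downstream of
#' one locus; in E-1 one junction's support falls below the multiplex
#' calling threshold (so its called set is a proper subset of its
#' lineage's).
#'
#' @param seed base RNG seed; each sample derives its own sub-seed.
#' @return a named list (one element per sample) of `list(truths, config)`
#'   ready for [simulate_sam()].
#' @export
cohort_presets <- function(seed = 1L) {
  samples <- c(sprintf("A-%d", 1:13), "A-1D", sprintf("B-%d", 1:3),
               "C-1", "D-1", sprintf("E-%d", 1:13))
  out <- vector("list", length(samples))
  names(out) <- samples
  for (i in seq_along(samples)) {
    id <- samples[i]
    lineage <- substr(id, 1, 1)
    p <- sim_preset(paste0("lineage_", lineage),
                    seed = (seed %% 10000L) * 100L + i)
    tr <- p$truths
    tr$support <- rep(8L + (i %% 5L), nrow(tr))  # per-sample depth jitter
    if (id == "A-2") {
      tr <- rbind(tr, integration_truth("scaffold_1", 19000L, "left", 120L,
                                        support = 7L))
    }
    if (id %in% c("E-2", "E-10")) {
      tr <- rbind(tr, integration_truth("scaffold_6", 24700L, "left", 140L,
                                        support = 7L))
    }
    if (id == "E-1") {
      tr$support[tr$genome_pos == 20100L] <- 3L  # below the threshold of 5
    }
    out[[i]] <- list(truths = tr, config = p$config)
  }
  out
}
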