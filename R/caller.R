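#' Configuration for the integration-site caller
#'
#' Defaults reproduce the published operating point for multiplexed
#' clonality runs: split alignments are kept when both halves have
#' `MAPQ > 30` and `NM < 4`, and a junction becomes an integration site at
#' five or more unique supporting reads or pairs. The deep single-sample
#' preset raises the support floor to fifteen, appropriate when one library
#' receives the full sequencing depth.
#'
#' @param min_support minimum unique read/pair support for a called site
#'   (a candidate is called when `support >= min_support`).
#' @param min_mapq mapping-quality floor; an alignment half passes when
#'   `mapq > min_mapq` (strict).
#' @param max_nm edit-distance ceiling; a half passes when `nm < max_nm`
#'   (strict). A record with no NM tag fails the filter.
#' @param vector_name scaffold name of the appended vector.
#' @param merge_window bp window for merging near-identical junction
#'   positions before thresholding; 0 (default) tabulates exact positions
#'   only.
#' @param skip_duplicates drop records flagged as PCR/optical duplicates
#'   (0x400); duplicate marking is an upstream contract, not recomputed here.
#' @param preset `"multiplex"` (min_support 5) or `"deep"` (min_support 15);
#'   an explicit `min_support` overrides the preset.
#' @return a `caller_config` list.
#' @export
caller_config <- function(min_support = NULL, min_mapq = 30L, max_nm = 4L,
                          vector_name = "vector", merge_window = 0L,
                          skip_duplicates = TRUE,
                          preset = c("multiplex", "deep")) {
  preset <- match.arg(preset)
  if (is.null(min_support)) {
    min_support <- if (preset == "deep") 15L else 5L
  }
  stopifnot(min_support >= 1L, min_mapq >= 0L, max_nm >= 1L,
            merge_window >= 0L)
  structure(
    list(min_support = as.integer(min_support),
         min_mapq = as.integer(min_mapq), max_nm = as.integer(max_nm),
         vector_name = vector_name, merge_window = as.integer(merge_window),
         skip_duplicates = isTRUE(skip_duplicates), preset = preset),
    class = "caller_config"
  )
}

#' Junction coordinate from an alignment's position and CIGAR
#'
#' The SAM position is the leftmost aligned base. When the CIGAR begins
#' with aligned bases, the reference span is added to the position to land
#' on the junction; when it begins with a clip (the clipped bases align to
#' the partner reference), the reported position itself is the junction.
#' Deletions and reference skips inside the aligned block shift the
#' reference coordinate and are counted in the span.
#'
#' @param pos 1-based leftmost aligned position.
#' @param cigar CIGAR string or parsed CIGAR data frame.
#' @param junction_side which end of the alignment abuts the junction:
#'   `"left"` (CIGAR begins with a clip) or `"right"` (CIGAR begins with
#'   aligned bases, clip at the end). If omitted, inferred from the CIGAR.
#' @return the 1-based junction coordinate.
#' @examples
#' junction_position(1000, "60M40S", "right")  # 1060
#' junction_position(5000, "40S60M", "left")   # 5000
#' @export
junction_position <- function(pos, cigar, junction_side = NULL) {
  ops <- parse_cigar(cigar)
  clips <- clip_lengths(ops)
  if (is.null(junction_side)) {
    junction_side <- if (ops$op[1] %in% c("S", "H")) "left" else "right"
  }
  junction_side <- match.arg(junction_side, c("left", "right"))
  need <- if (junction_side == "left") clips[["left"]] else clips[["right"]]
  if (need == 0L) {
    stop("inconsistent evidence: no clip on the ", junction_side,
         " side of CIGAR '", cigar_string(ops), "'")
  }
  if (junction_side == "left") as.integer(pos)
  else as.integer(pos) + reference_span(ops)
}

# Which vector terminus a vector-side junction belongs to.
vector_end_of <- function(vector_junction, vector_length) {
  ifelse(vector_junction <= vector_length / 2, "left", "right")
}

# One alignment half passes the quality filter: MAPQ strictly above the
# floor AND NM strictly below the ceiling; absent NM fails.
half_passes <- function(mapq, nm, config) {
  !is.na(mapq) && mapq > config$min_mapq &&
    !is.na(nm) && nm < config$max_nm
}

empty_evidence <- function() {
  data.frame(qname = character(), mate = integer(), scaffold = character(),
             genome_pos = integer(), genome_strand = character(),
             genome_mapq = integer(), genome_nm = integer(),
             vector_pos = integer(), vector_end = character(),
             vector_mapq = integer(), vector_nm = integer(),
             stringsAsFactors = FALSE)
}

#' Extract split-read evidence for a vector-genome junction from one record
#'
#' A record contributes evidence when it and one of its SA entries map to
#' the vector scaffold and a genome scaffold (in either direction), both
#' halves pass the MAPQ/NM filter, and both CIGARs carry the clip that marks
#' the junction. Secondary alignments never contribute; duplicates are
#' skipped when the configuration says so.
#'
#' @param record a one-row record data frame (see [parse_sam_line()]).
#' @param refs a [reference_set()].
#' @param config a [caller_config()].
#' @return a data frame of evidence rows (usually one), or a zero-row frame
#'   when the record yields none. Columns: `qname`, `mate`, `scaffold`,
#'   `genome_pos`, `genome_strand`, `genome_mapq`, `genome_nm`,
#'   `vector_pos`, `vector_end`, `vector_mapq`, `vector_nm`.
#' @export
extract_split_evidence <- function(record, refs, config = caller_config()) {
  out <- empty_evidence()
  if (record$is_unmapped || record$is_secondary) return(out)
  if (config$skip_duplicates && record$is_duplicate) return(out)
  if (is.na(record$sa)) return(out)
  sa <- parse_sa_tag(record$sa)
  unknown <- setdiff(sa$rname, all_ref_names(refs))
  if (length(unknown)) {
    stop("reference mismatch: SA scaffold '", unknown[1],
         "' not in reference (read ", record$qname, ")")
  }
  primary_on_vector <- identical(record$rname, refs$vector_name)
  for (i in seq_len(nrow(sa))) {
    sa_on_vector <- sa$rname[i] == refs$vector_name
    if (primary_on_vector == sa_on_vector) next  # genome-genome or vector-vector
    if (primary_on_vector) {
      g <- list(rname = sa$rname[i], pos = sa$pos[i],
                strand = sa$strand[i], cigar = sa$cigar[i],
                mapq = sa$mapq[i], nm = sa$nm[i])
      v <- list(pos = record$pos, cigar = record$cigar,
                mapq = record$mapq, nm = record$nm)
    } else {
      g <- list(rname = record$rname, pos = record$pos,
                strand = if (record$is_reverse) "-" else "+",
                cigar = record$cigar, mapq = record$mapq, nm = record$nm)
      v <- list(pos = sa$pos[i], cigar = sa$cigar[i],
                mapq = sa$mapq[i], nm = sa$nm[i])
    }
    if (!half_passes(g$mapq, g$nm, config)) next
    if (!half_passes(v$mapq, v$nm, config)) next
    gj <- tryCatch(junction_position(g$pos, g$cigar),
                   error = function(e) NULL)
    vj <- tryCatch(junction_position(v$pos, v$cigar),
                   error = function(e) NULL)
    if (is.null(gj) || is.null(vj)) next  # a half with no clip: not split here
    out <- rbind(out, data.frame(
      qname = record$qname, mate = record$mate, scaffold = g$rname,
      genome_pos = gj, genome_strand = g$strand,
      genome_mapq = g$mapq, genome_nm = g$nm,
      vector_pos = vj,
      vector_end = vector_end_of(vj, refs$vector_length),
      vector_mapq = v$mapq, vector_nm = v$nm,
      stringsAsFactors = FALSE
    ))
  }
  out
}

#' Scan a record table for split reads spanning the vector-genome junction
#'
#' Applies [extract_split_evidence()] across all records. Supplementary
#' records (0x800) describe the same chimera as their primary's SA tag, so
#' evidence is deduplicated by (read, mate, junction) and each physical
#' read contributes at most once per junction.
#'
#' @inheritParams extract_split_evidence
#' @param records record data frame from [read_sam()].
#' @return evidence data frame (see [extract_split_evidence()]).
#' @export
find_split_reads <- function(records, refs, config = caller_config()) {
  if (nrow(records) == 0L) return(empty_evidence())
  keep <- !records$is_unmapped & !records$is_secondary & !is.na(records$sa)
  if (config$skip_duplicates) keep <- keep & !records$is_duplicate
  rows <- which(keep)
  ev <- lapply(rows, function(i) {
    extract_split_evidence(records[i, , drop = FALSE], refs, config)
  })
  ev <- do.call(rbind, c(list(empty_evidence()), ev))
  key <- paste(ev$qname, ev$mate, ev$scaffold, ev$genome_pos,
               ev$vector_pos, ev$vector_end, sep = "\r")
  ev[!duplicated(key), , drop = FALSE]
}

#' Tabulate unique junctions and their read/pair support
#'
#' Candidates are keyed by (scaffold, genome position, vector position,
#' vector end); supporters are distinct read names, so when both mates of a
#' pair span the same junction the pair counts once.
#'
#' @param evidence evidence data frame from [find_split_reads()].
#' @return a data frame of junction candidates sorted by
#'   (scaffold, genome_pos, vector_end): columns `scaffold`, `genome_pos`,
#'   `vector_pos`, `vector_end`, `strand` (modal genome strand), `support`,
#'   and a list-column `supporters` of read names.
#' @export
tabulate_junctions <- function(evidence) {
  empty <- data.frame(scaffold = character(), genome_pos = integer(),
                      vector_pos = integer(), vector_end = character(),
                      strand = character(), support = integer(),
                      stringsAsFactors = FALSE)
  empty$supporters <- list()
  if (nrow(evidence) == 0L) return(empty)
  key <- paste(evidence$scaffold, evidence$genome_pos,
               evidence$vector_pos, evidence$vector_end, sep = "\r")
  groups <- split(seq_len(nrow(evidence)), key)
  rows <- lapply(groups, function(idx) {
    e <- evidence[idx, , drop = FALSE]
    supp <- sort(unique(e$qname))
    strands <- table(e$genome_strand)
    out <- data.frame(
      scaffold = e$scaffold[1], genome_pos = e$genome_pos[1],
      vector_pos = e$vector_pos[1], vector_end = e$vector_end[1],
      strand = names(strands)[which.max(strands)],
      support = length(supp), stringsAsFactors = FALSE
    )
    out$supporters <- list(supp)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$genome_pos, out$vector_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge candidates on one scaffold/vector_end whose positions chain within
# merge_window bp: supporters unioned, position = support-weighted mode
# (ties -> smallest coordinate).
merge_candidates <- function(candidates, merge_window) {
  if (merge_window <= 0L || nrow(candidates) < 2L) return(candidates)
  key <- paste(candidates$scaffold, candidates$vector_end, sep = "\r")
  groups <- split(seq_len(nrow(candidates)), key)
  rows <- lapply(groups, function(idx) {
    cc <- candidates[idx, , drop = FALSE]
    cc <- cc[order(cc$genome_pos), , drop = FALSE]
    gap_new <- c(TRUE, diff(cc$genome_pos) > merge_window)
    cluster <- cumsum(gap_new)
    do.call(rbind, lapply(split(seq_len(nrow(cc)), cluster), function(ci) {
      m <- cc[ci, , drop = FALSE]
      if (nrow(m) == 1L) return(m)
      best <- which(m$support == max(m$support))
      best <- best[which.min(m$genome_pos[best])]
      supp <- sort(unique(unlist(m$supporters)))
      out <- m[best, , drop = FALSE]
      out$support <- length(supp)
      out$supporters <- list(supp)
      out
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call integration sites from tabulated junction candidates
#'
#' Optionally merges near-identical positions (within `merge_window` bp on
#' one scaffold and vector end), then keeps candidates whose unique support
#' meets the configured minimum. Output is deterministically sorted.
#'
#' @param candidates candidate data frame from [tabulate_junctions()].
#' @param config a [caller_config()].
#' @param sample optional sample label attached to the output.
#' @return an integration-site data frame: `sample`, `scaffold`,
#'   `genome_pos`, `vector_pos`, `vector_end`, `strand`, `support`.
#'   Coordinates are 1-based.
#' @export
call_sites <- function(candidates, config = caller_config(), sample = NA) {
  merged <- merge_candidates(candidates, config$merge_window)
  called <- merged[merged$support >= config$min_support, , drop = FALSE]
  called <- called[order(called$scaffold, called$genome_pos,
                         called$vector_end), , drop = FALSE]
  out <- data.frame(
    sample = rep(as.character(sample), nrow(called)),
    scaffold = called$scaffold, genome_pos = called$genome_pos,
    vector_pos = called$vector_pos, vector_end = called$vector_end,
    strand = called$strand, support = called$support,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' End-to-end integration-site calling on a record table
#'
#' Convenience wrapper chaining [find_split_reads()],
#' [tabulate_junctions()] and [call_sites()], with a per-stage count funnel
#' attached so the filtering can be audited.
#'
#' @inheritParams find_split_reads
#' @param sample sample label for the output table.
#' @return integration-site data frame (see [call_sites()]) with a `funnel`
#'   attribute: named counts of records parsed, duplicates skipped, split
#'   evidence rows, unique junctions, and called sites.
#' @export
call_integration_sites <- function(records, refs,
                                   config = caller_config(), sample = NA) {
  n_dup <- sum(records$is_duplicate)
  evidence <- find_split_reads(records, refs, config)
  candidates <- tabulate_junctions(evidence)
  sites <- call_sites(candidates, config, sample = sample)
  attr(sites, "funnel") <- c(
    records = nrow(records), duplicates_skipped = n_dup,
    evidence = nrow(evidence), junctions = nrow(candidates),
    called = nrow(sites)
  )
  sites
}
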