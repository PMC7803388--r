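# Independent oracles and small fixture builders shared across tests.

# Per-base CIGAR walk: expand the string one op-letter at a time and count
# reference positions. Deliberately naive and independent of parse_cigar().
ref_span_oracle <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  expanded <- unlist(lapply(toks, function(tk) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", tk))
    rep(sub("^[0-9]+", "", tk), n)
  }))
  sum(expanded %in% c("M", "D", "N", "=", "X"))
}

# Oracle for clip lengths: expand and count leading/trailing S/H letters.
clip_oracle <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  expanded <- unlist(lapply(toks, function(tk) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", tk))
    rep(sub("^[0-9]+", "", tk), n)
  }))
  is_clip <- expanded %in% c("S", "H")
  left <- match(FALSE, is_clip, nomatch = length(expanded) + 1L) - 1L
  right <- match(FALSE, rev(is_clip), nomatch = length(expanded) + 1L) - 1L
  c(left = left, right = if (left == length(expanded)) 0L else right)
}

# Random well-formed CIGAR: optional clip run at each end, interior ops
# from {M, I, D}, always at least one M.
random_cigar <- function() {
  n_mid <- sample(1:5, 1)
  ops <- sample(c("M", "I", "D"), n_mid, replace = TRUE, prob = c(.6, .2, .2))
  ops[sample(n_mid, 1)] <- "M"
  lens <- sample(1:80, n_mid, replace = TRUE)
  left <- if (runif(1) < .5) sprintf("%d%s", sample(1:40, 1),
                                     sample(c("S", "H"), 1)) else ""
  right <- if (runif(1) < .5) sprintf("%d%s", sample(1:40, 1),
                                      sample(c("S", "H"), 1)) else ""
  paste0(left, paste0(lens, ops, collapse = ""), right)
}

test_refs <- function() {
  reference_set(c("scaffold_1", "scaffold_2"), "vector", 8000L,
                lengths = c(scaffold_1 = 50000L, scaffold_2 = 50000L))
}

# A primary split-read SAM line: genome part with an SA entry on the vector.
split_sam_line <- function(qname = "r1", flag = 99L, rname = "scaffold_1",
                           pos = 1000L, mapq = 60L, cigar = "60M40S",
                           nm = 0L,
                           sa = "vector,1,+,60S40M,60,0;") {
  tags <- character()
  if (!is.na(nm)) tags <- c(tags, sprintf("NM:i:%d", nm))
  if (!is.na(sa)) tags <- c(tags, paste0("SA:Z:", sa))
  paste(c(qname, flag, rname, pos, mapq, cigar, "=", pos, 0, "*", "*",
          tags), collapse = "\t")
}

records_from_lines <- function(lines, refs = NULL) {
  do.call(rbind, lapply(lines, parse_sam_line, refs = refs))
}

# n otherwise-identical supporting split reads for one junction.
support_lines <- function(n, genome_pos_cigar_start = 1000L,
                          mapq = 60L, nm = 0L, qprefix = "r",
                          sa = "vector,1,+,60S40M,60,0;") {
  vapply(seq_len(n), function(i) {
    split_sam_line(qname = paste0(qprefix, i), pos = genome_pos_cigar_start,
                   mapq = mapq, nm = nm, sa = sa)
  }, "")
}
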