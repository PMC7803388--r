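#' CIGAR string parsing and coordinate arithmetic
#'
#' A CIGAR string encodes how a read's bases align to the reference:
#' `M`/`=`/`X` aligned bases, `I` insertions, `D` deletions, `N` skips,
#' `S`/`H` soft/hard clips, `P` padding. In a split (chimeric) read the
#' clipped portion is the part that aligns elsewhere, so clip lengths and
#' reference spans carry the junction geometry.
#'
#' @param cigar a CIGAR string such as `"60M40S"`, or a parsed CIGAR
#'   data frame as returned by `parse_cigar()`.
#' @return `parse_cigar()` returns a data frame with columns `op`
#'   (character, one of `M I D N S H P = X`) and `len` (positive integer),
#'   one row per operation in order.
#' @examples
#' parse_cigar("30M2D30M40S")
#' reference_span("30M2D30M40S")  # 62: deletions consume the reference
#' clip_lengths("10H30S60M")      # c(left = 40, right = 0)
#' @export
parse_cigar <- function(cigar) {
  if (is.data.frame(cigar)) return(cigar)
  stopifnot(is.character(cigar), length(cigar) == 1L)
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    stop("malformed CIGAR: '", cigar, "'")
  }
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: '", cigar, "'")
  }
  ops <- data.frame(
    op  = sub("^[0-9]+", "", toks),
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    stringsAsFactors = FALSE
  )
  if (any(ops$len < 1L)) stop("malformed CIGAR (zero-length op): '", cigar, "'")
  validate_cigar(ops, cigar)
  ops
}

# Clip ops must form at most one run at each end, H outermost within a run.
validate_cigar <- function(ops, label = NULL) {
  is_clip <- ops$op %in% c("S", "H")
  if (!any(is_clip)) return(invisible(ops))
  runs <- rle(is_clip)
  clip_runs <- which(runs$values)
  n_runs <- length(runs$values)
  if (any(clip_runs != 1L & clip_runs != n_runs)) {
    stop("malformed CIGAR (interior clip): '",
         if (is.null(label)) cigar_string(ops) else label, "'")
  }
  # H only outermost: within a leading run H before S; trailing run S before H
  h_pos <- which(ops$op == "H")
  for (i in h_pos) {
    if (i != 1L && i != nrow(ops)) {
      stop("malformed CIGAR (interior hard clip): '",
           if (is.null(label)) cigar_string(ops) else label, "'")
    }
  }
  invisible(ops)
}

#' @rdname parse_cigar
#' @export
cigar_string <- function(cigar) {
  ops <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  paste0(ops$len, ops$op, collapse = "")
}

#' @rdname parse_cigar
#' @return `reference_span()` returns the number of reference bases the
#'   alignment consumes (sum over `M D N = X`); clips, insertions and padding
#'   contribute nothing.
#' @export
reference_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' @rdname parse_cigar
#' @return `query_span()` returns the number of read bases the CIGAR accounts
#'   for including soft clips (`M I S = X`); with hard clips added this is the
#'   full read length.
#' @export
query_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

#' @rdname parse_cigar
#' @return `clip_lengths()` returns a named integer vector
#'   `c(left = , right = )` of summed soft+hard clip lengths at each end.
#' @export
clip_lengths <- function(cigar) {
  ops <- parse_cigar(cigar)
  n <- nrow(ops)
  left <- 0L
  i <- 1L
  while (i <= n && ops$op[i] %in% c("S", "H")) {
    left <- left + ops$len[i]
    i <- i + 1L
  }
  right <- 0L
  j <- n
  while (j >= i && ops$op[j] %in% c("S", "H")) {
    right <- right + ops$len[j]
    j <- j - 1L
  }
  c(left = left, right = right)
}
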