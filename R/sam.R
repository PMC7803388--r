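#' Decode a SAM FLAG field
#'
#' @param flag integer vector of SAM FLAG values.
#' @return a data frame with one logical column per decoded bit
#'   (`is_paired`, `is_proper`, `is_unmapped`, `mate_unmapped`, `is_reverse`,
#'   `mate_reverse`, `is_first`, `is_second`, `is_secondary`, `is_qcfail`,
#'   `is_duplicate`, `is_supplementary`) and an integer `mate` column
#'   (1 or 2; 1 for unpaired reads).
#' @export
decode_flag <- function(flag) {
  flag <- as.integer(flag)
  if (any(is.na(flag) | flag < 0L)) stop("malformed FLAG")
  bit <- function(b) bitwAnd(flag, b) != 0L
  out <- data.frame(
    is_paired        = bit(0x1),
    is_proper        = bit(0x2),
    is_unmapped      = bit(0x4),
    mate_unmapped    = bit(0x8),
    is_reverse       = bit(0x10),
    mate_reverse     = bit(0x20),
    is_first         = bit(0x40),
    is_second        = bit(0x80),
    is_secondary     = bit(0x100),
    is_qcfail        = bit(0x200),
    is_duplicate     = bit(0x400),
    is_supplementary = bit(0x800)
  )
  out$mate <- ifelse(out$is_second, 2L, 1L)
  out
}

#' Describe the reference the reads were aligned to
#'
#' The caller's contract is that the linearized vector was appended to the
#' genome assembly as one extra named scaffold before alignment; this object
#' records which scaffold that is and how long it is.
#'
#' @param scaffolds character vector of genome scaffold names (the vector
#'   scaffold excluded).
#' @param vector_name name of the appended vector scaffold.
#' @param vector_length length of the vector scaffold in bases.
#' @param lengths optional named integer vector of genome scaffold lengths.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(scaffolds, vector_name, vector_length,
                          lengths = NULL) {
  scaffolds <- as.character(scaffolds)
  if (vector_name %in% scaffolds) {
    stop("vector scaffold '", vector_name,
         "' must not also be a genome scaffold")
  }
  if (!is.null(lengths)) {
    stopifnot(!is.null(names(lengths)), all(scaffolds %in% names(lengths)))
    lengths <- as.integer(lengths)[match(scaffolds, names(lengths))]
    names(lengths) <- scaffolds
  }
  structure(
    list(scaffolds = scaffolds, vector_name = vector_name,
         vector_length = as.integer(vector_length), lengths = lengths),
    class = "reference_set"
  )
}

all_ref_names <- function(refs) c(refs$scaffolds, refs$vector_name)

#' Parse an SA:Z tag (supplementary alignments of a chimeric read)
#'
#' BWA-MEM records a split read's other alignments in the primary record's
#' SA tag as semicolon-terminated `rname,pos,strand,CIGAR,mapQ,NM` entries.
#'
#' @param sa the SA:Z tag value (without the `SA:Z:` prefix), or `NA`.
#' @return a data frame with columns `rname`, `pos`, `strand`, `cigar`,
#'   `mapq`, `nm`; zero rows when `sa` is `NA` or empty.
#' @export
parse_sa_tag <- function(sa) {
  empty <- data.frame(rname = character(), pos = integer(),
                      strand = character(), cigar = character(),
                      mapq = integer(), nm = integer(),
                      stringsAsFactors = FALSE)
  if (length(sa) != 1L || is.na(sa) || sa == "") return(empty)
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0L) return(empty)
  parts <- strsplit(entries, ",", fixed = TRUE)
  if (any(lengths(parts) != 6L)) stop("malformed SA tag: '", sa, "'")
  out <- data.frame(
    rname  = vapply(parts, `[`, "", 1L),
    pos    = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    cigar  = vapply(parts, `[`, "", 4L),
    mapq   = as.integer(vapply(parts, `[`, "", 5L)),
    nm     = as.integer(vapply(parts, `[`, "", 6L)),
    stringsAsFactors = FALSE
  )
  if (any(!out$strand %in% c("+", "-")) || any(is.na(out$pos)) ||
      any(out$pos < 1L)) {
    stop("malformed SA tag: '", sa, "'")
  }
  out
}

#' Parse one SAM alignment line
#'
#' Decodes the eleven mandatory fields plus the two optional tags the
#' pipeline consumes: `NM:i` (edit distance) and `SA:Z` (supplementary
#' alignments). A missing NM tag is kept as `NA`, never coerced to zero,
#' because the quality filter treats absent edit distance as unassessable.
#'
#' @param line a non-header SAM record line.
#' @param refs optional [reference_set()]; when given, a mapped record whose
#'   RNAME is not in the reference raises a reference-mismatch error.
#' @param line_num optional line number used in error messages.
#' @return a one-row data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `nm`, `sa` plus the decoded
#'   flag columns of [decode_flag()]. Coordinates are 1-based (SAM
#'   convention); for unmapped records `rname`, `pos` and `cigar` are `NA`.
#' @export
parse_sam_line <- function(line, refs = NULL, line_num = NA) {
  where <- if (is.na(line_num)) "" else paste0(" at line ", line_num)
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L) stop("malformed SAM record", where,
                            ": fewer than 11 fields")
  flag <- suppressWarnings(as.integer(f[2]))
  if (is.na(flag)) stop("malformed FLAG", where, ": '", f[2], "'")
  bits <- decode_flag(flag)
  rec <- data.frame(
    qname = f[1], flag = flag, rname = f[3],
    pos   = suppressWarnings(as.integer(f[4])),
    mapq  = suppressWarnings(as.integer(f[5])),
    cigar = f[6], rnext = f[7],
    pnext = suppressWarnings(as.integer(f[8])),
    tlen  = suppressWarnings(as.integer(f[9])),
    stringsAsFactors = FALSE
  )
  tags <- f[-(1:11)]
  nm_tag <- grep("^NM:i:", tags, value = TRUE)
  sa_tag <- grep("^SA:Z:", tags, value = TRUE)
  rec$nm <- if (length(nm_tag)) as.integer(sub("^NM:i:", "", nm_tag[1])) else NA_integer_
  rec$sa <- if (length(sa_tag)) sub("^SA:Z:", "", sa_tag[1]) else NA_character_
  rec <- cbind(rec, bits)
  if (rec$is_unmapped || rec$rname == "*") {
    rec$rname <- NA_character_
    rec$pos <- NA_integer_
    rec$cigar <- NA_character_
  } else {
    if (is.na(rec$pos) || rec$pos < 1L) {
      stop("malformed POS", where, ": '", f[4], "'")
    }
    tryCatch(parse_cigar(rec$cigar),
             error = function(e) stop(conditionMessage(e), where, call. = FALSE))
    if (!is.null(refs) && !rec$rname %in% all_ref_names(refs)) {
      stop("reference mismatch", where, ": scaffold '", rec$rname,
           "' not in reference")
    }
  }
  rec
}

#' Read a SAM file into a record table
#'
#' Text SAM v1 is the canonical input surface: the pipeline consumes the
#' aligner's output after upstream trimming, mapping and duplicate marking.
#' `@SQ` header lines are used to build the reference dictionary.
#'
#' @param path path to a SAM text file.
#' @param vector_name name of the appended vector scaffold; when given, a
#'   [reference_set()] is built from the header and attached, and its absence
#'   from the header is a configuration error.
#' @return a list with elements `records` (data frame, one row per alignment
#'   record, columns as in [parse_sam_line()]) and `refs` (a
#'   [reference_set()] or `NULL`).
#' @export
read_sam <- function(path, vector_name = NULL) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  body <- lines[!is_header]
  body <- body[nzchar(body)]

  sq <- header[startsWith(header, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- suppressWarnings(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)))
  refs <- NULL
  if (!is.null(vector_name)) {
    if (!vector_name %in% sn) {
      stop("vector scaffold '", vector_name, "' not in SAM header; ",
           "scaffolds present: ", paste(sn, collapse = ", "))
    }
    genome <- setdiff(sn, vector_name)
    lens <- ln[match(genome, sn)]
    names(lens) <- genome
    refs <- reference_set(genome, vector_name, ln[match(vector_name, sn)],
                          lengths = lens)
  }
  if (length(body) == 0L) {
    rec <- parse_sam_line("q\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")[0, ]
    return(list(records = rec, refs = refs))
  }
  recs <- lapply(seq_along(body), function(i) {
    parse_sam_line(body[i], refs = refs,
                   line_num = which(!is_header)[i])
  })
  list(records = do.call(rbind, recs), refs = refs)
}

#' Write a record table back to SAM text
#'
#' Emits an `@HD` line, one `@SQ` line per reference scaffold, and the
#' records with their NM and SA tags. Round-trips every field the pipeline
#' consumes.
#'
#' @param records a record data frame (as from [read_sam()] or the
#'   simulator); may carry `seq`/`qual` columns, otherwise `*` is written.
#' @param refs a [reference_set()] with scaffold `lengths` set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, refs, path) {
  sq <- c(
    sprintf("@SQ\tSN:%s\tLN:%d", refs$scaffolds,
            if (is.null(refs$lengths)) rep(0L, length(refs$scaffolds))
            else refs$lengths),
    sprintf("@SQ\tSN:%s\tLN:%d", refs$vector_name, refs$vector_length)
  )
  n <- nrow(records)
  seq <- if ("seq" %in% names(records)) records$seq else rep("*", n)
  qual <- if ("qual" %in% names(records)) records$qual else rep("*", n)
  rname <- ifelse(is.na(records$rname), "*", records$rname)
  pos <- ifelse(is.na(records$pos), 0L, records$pos)
  cig <- ifelse(is.na(records$cigar), "*", records$cigar)
  rnext <- if ("rnext" %in% names(records)) records$rnext else rep("*", n)
  pnext <- if ("pnext" %in% names(records)) records$pnext else rep(0L, n)
  tlen <- if ("tlen" %in% names(records)) records$tlen else rep(0L, n)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                   records$qname, records$flag, rname, pos,
                   ifelse(is.na(records$mapq), 0L, records$mapq),
                   cig, ifelse(is.na(rnext), "*", rnext),
                   ifelse(is.na(pnext), 0L, pnext),
                   ifelse(is.na(tlen), 0L, tlen), seq, qual)
  has_nm <- !is.na(records$nm)
  lines[has_nm] <- paste0(lines[has_nm], "\tNM:i:", records$nm[has_nm])
  has_sa <- !is.na(records$sa)
  lines[has_sa] <- paste0(lines[has_sa], "\tSA:Z:", records$sa[has_sa])
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, lines), path)
  invisible(path)
}
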