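#' Match two samples' integration-site sets
#'
#' Two sites match when they lie on the same scaffold, carry the same
#' vector end, and their genome positions differ by at most `tolerance` bp.
#' The default tolerance is 0: in practice junctions from the same lineage
#' are identical at the base level. Matching is one-to-one (greedy by
#' distance), so a site can support at most one match.
#'
#' @param a,b integration-site data frames (columns `scaffold`,
#'   `genome_pos`, `vector_end` at minimum).
#' @param tolerance maximum genome-position difference, in bp, for two
#'   sites to be considered the same junction.
#' @return `match_site_sets()` returns the number of matched sites.
#' @export
match_site_sets <- function(a, b, tolerance = 0L) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  matched <- 0L
  for (key in unique(paste(a$scaffold, a$vector_end, sep = "\r"))) {
    ka <- paste(a$scaffold, a$vector_end, sep = "\r") == key
    kb <- paste(b$scaffold, b$vector_end, sep = "\r") == key
    pa <- sort(a$genome_pos[ka])
    pb <- sort(b$genome_pos[kb])
    if (length(pb) == 0L) next
    pairs <- expand.grid(i = seq_along(pa), j = seq_along(pb))
    pairs$d <- abs(pa[pairs$i] - pb[pairs$j])
    pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
    used_a <- logical(length(pa)); used_b <- logical(length(pb))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  matched
}

#' @rdname match_site_sets
#' @return `compare_site_sets()` returns a list with the match count `n_matched`,
#'   the Jaccard index `matched / (|a| + |b| - matched)`, and `relation`:
#'   `"identical"` (all sites matched on both sides), `"subset"` (one side
#'   fully matched — consistent with clonality, a locus possibly missed below
#'   the support threshold in the smaller sample), `"partial"` (some but not
#'   all matched on either side) or `"disjoint"`.
#' @export
compare_site_sets <- function(a, b, tolerance = 0L) {
  na <- nrow(a); nb <- nrow(b)
  m <- match_site_sets(a, b, tolerance)
  relation <-
    if (m == na && m == nb) "identical"
    else if (m > 0L && (m == na || m == nb)) "subset"
    else if (m > 0L) "partial"
    else "disjoint"
  list(n_matched = m,
       jaccard = if (na + nb - m == 0L) 1 else m / (na + nb - m),
       relation = relation)
}

#' Group samples into lineages by shared integration sites
#'
#' A single shared junction is strong evidence of common ancestry, because
#' independent random integrations essentially never collide at the same
#' base. Samples sharing at least `min_shared` matched sites are linked and
#' lineage groups are the connected components of that link graph — so a
#' subline whose set is a subset of its parent's (one locus under the
#' support threshold) still groups with its lineage.
#'
#' @param samples named list of integration-site data frames, one per
#'   sample; names are sample identifiers.
#' @param tolerance bp tolerance for site matching (default 0).
#' @param min_shared minimum matched sites to link two samples (default 1).
#' @return a data frame `sample`, `group` (integer lineage index; groups
#'   are numbered by their first sample in sorted order), sorted by sample.
#' @export
group_lineages <- function(samples, tolerance = 0L, min_shared = 1L) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  ids <- sort(names(samples))
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      m <- match_site_sets(samples[[ids[i]]], samples[[ids[j]]], tolerance)
      adj[i, j] <- adj[j, i] <- m >= min_shared
    }
  }
  comp <- integer(n)
  next_grp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    next_grp <- next_grp + 1L
    queue <- i
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      if (comp[k] != 0L) next
      comp[k] <- next_grp
      queue <- c(queue, which(adj[k, ] & comp == 0L))
    }
  }
  data.frame(sample = ids, group = comp, stringsAsFactors = FALSE)
}

#' Flag linked junctions and paired vector ends within a sample
#'
#' One insertion exposes up to two junctions — its left and right vector
#' ends — typically tens of bp apart on the genome; these are paired and
#' counted as a single locus. An extra junction on the same scaffold within
#' `link_distance` of a locus (observed around 1-4.7 kbp downstream) is
#' flagged as linked, i.e. a likely local rearrangement or duplication
#' rather than an independent integration event, and excluded from the
#' count of independent loci while staying in the site table.
#'
#' @param sites one sample's integration-site data frame.
#' @param link_distance bp window for flagging same-scaffold junctions as
#'   rearrangement-linked (default 10000, covering the observed 1 and
#'   4.7 kbp cases).
#' @param end_pair_distance bp window for pairing opposite vector ends of
#'   one insertion (default 500, covering the observed ~30 and ~100 bp
#'   separations with margin).
#' @return a data frame of flagged pairs: `scaffold`, `pos1`, `pos2`,
#'   `end1`, `end2`, `distance`, `type` (`"end_pair"` or `"linked"`).
#' @export
annotate_linked_junctions <- function(sites, link_distance = 10000L,
                                      end_pair_distance = 500L) {
  out <- data.frame(scaffold = character(), pos1 = integer(),
                    pos2 = integer(), end1 = character(),
                    end2 = character(), distance = integer(),
                    type = character(), stringsAsFactors = FALSE)
  n <- nrow(sites)
  if (n < 2L) return(out)
  ord <- order(sites$scaffold, sites$genome_pos)
  s <- sites[ord, , drop = FALSE]
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (s$scaffold[i] != s$scaffold[j]) next
    d <- abs(s$genome_pos[j] - s$genome_pos[i])
    type <-
      if (s$vector_end[i] != s$vector_end[j] && d <= end_pair_distance)
        "end_pair"
      else if (d <= link_distance) "linked"
      else NA_character_
    if (is.na(type)) next
    out <- rbind(out, data.frame(
      scaffold = s$scaffold[i], pos1 = s$genome_pos[i],
      pos2 = s$genome_pos[j], end1 = s$vector_end[i],
      end2 = s$vector_end[j], distance = d, type = type,
      stringsAsFactors = FALSE
    ))
  }
  out
}

#' @rdname annotate_linked_junctions
#' @return `count_independent_loci()` returns the number of independent
#'   integration loci: connected components of the sites under end-pair and
#'   linked relations (an end pair is one locus; a linked extra junction
#'   does not add a locus).
#' @export
count_independent_loci <- function(sites, link_distance = 10000L,
                                   end_pair_distance = 500L) {
  n <- nrow(sites)
  if (n == 0L) return(0L)
  pairs <- annotate_linked_junctions(sites, link_distance, end_pair_distance)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(pairs))) {
    i <- which(sites$scaffold == pairs$scaffold[r] &
                 sites$genome_pos == pairs$pos1[r] &
                 sites$vector_end == pairs$end1[r])[1]
    j <- which(sites$scaffold == pairs$scaffold[r] &
                 sites$genome_pos == pairs$pos2[r] &
                 sites$vector_end == pairs$end2[r])[1]
    parent[find(i)] <- find(j)
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

#' Full clonality report across samples
#'
#' Computes pairwise relations and Jaccard indices, lineage groups, and
#' per-sample linked-junction annotations and locus counts.
#'
#' @inheritParams group_lineages
#' @inheritParams annotate_linked_junctions
#' @return a `clonality_report` list: `samples` (ids), `groups`
#'   (data frame from [group_lineages()]), `n_groups`, `relations` and
#'   `jaccard` (sample x sample matrices), `linked` (named list of
#'   per-sample linked-pair tables), `loci` (named integer vector of
#'   independent locus counts).
#' @export
clonality_report <- function(samples, tolerance = 0L, min_shared = 1L,
                             link_distance = 10000L,
                             end_pair_distance = 500L) {
  ids <- sort(names(samples))
  n <- length(ids)
  rel <- matrix("", n, n, dimnames = list(ids, ids))
  jac <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cmp <- compare_site_sets(samples[[ids[i]]], samples[[ids[j]]], tolerance)
    rel[i, j] <- cmp$relation
    jac[i, j] <- cmp$jaccard
  }
  groups <- group_lineages(samples, tolerance, min_shared)
  linked <- lapply(samples[ids], annotate_linked_junctions,
                   link_distance = link_distance,
                   end_pair_distance = end_pair_distance)
  loci <- vapply(samples[ids], count_independent_loci, 1L,
                 link_distance = link_distance,
                 end_pair_distance = end_pair_distance)
  structure(
    list(samples = ids, groups = groups, n_groups = max(groups$group),
         relations = rel, jaccard = jac, linked = linked, loci = loci,
         tolerance = tolerance, min_shared = min_shared),
    class = "clonality_report"
  )
}

#' @export
print.clonality_report <- function(x, ...) {
  cat(sprintf("clonality report: %d samples in %d lineage group(s)\n",
              length(x$samples), x$n_groups))
  for (g in sort(unique(x$groups$group))) {
    cat(sprintf("  group %d: %s\n", g,
                paste(x$groups$sample[x$groups$group == g], collapse = ", ")))
  }
  invisible(x)
}
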