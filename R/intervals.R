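# Genomic intervals are plain tibbles with columns chrom / start / end in
# 0-based half-open coordinates (BED convention). Every reader in the package
# normalizes to this convention, and every overlap decision is made under it:
# two intervals overlap iff they share at least one base pair, so bookended
# intervals ([100,200) and [200,300)) do NOT overlap.

#' Validate a tibble of genomic intervals
#'
#' Checks the 0-based half-open interval invariants: `chrom` non-empty,
#' `start >= 0`, `end > start`. Called by every function that consumes
#' intervals; exported because fixture and pipeline code finds it useful too.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly usable in pipes.
#' @export
validate_intervals <- function(x, what = "interval") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(paste0(what, ": chromosome names must be non-empty"))
  }
  if (any(x$start < 0)) {
    abort(paste0(what, ": start coordinates must be >= 0"))
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(paste0(what, " row ", bad[1], ": end (", x$end[bad[1]],
                 ") must be > start (", x$start[bad[1]],
                 ") under half-open coordinates"))
  }
  x
}

# Convert 0-based half-open intervals to a GRanges (1-based closed). The +1
# shift makes GRanges overlap semantics coincide with shared-base overlap of
# half-open intervals.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tibble0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Find overlapping interval pairs
#'
#' Returns every (query, subject) index pair whose intervals share at least
#' one base on the same chromosome. Zero-length overlap (bookended intervals)
#' does not count. Results are ordered query-major, then by subject index, so
#' output is deterministic.
#'
#' @param query,subject Interval tibbles (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @return A tibble with integer columns `query` and `subject` (1-based row
#'   indices into the inputs).
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' s <- tibble::tibble(chrom = "chr1", start = c(5, 10), end = c(6, 20))
#' find_overlaps(q, s) # only the first subject hits; [10,20) is bookended
#' @export
find_overlaps <- function(query, subject) {
  query <- validate_intervals(query, "query")
  subject <- validate_intervals(subject, "subject")
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query = integer(), subject = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  out <- tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
  arrange(out, .data$query, .data$subject)
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into the minimal set of maximal intervals such
#' that any two overlapping inputs end up in the same output interval.
#' Bookended intervals are kept separate (strict half-open overlap).
#'
#' @param x Interval tibble.
#' @return Tibble of merged intervals sorted by (`chrom`, `start`).
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  # min.gapwidth = 0 so adjacency alone (gap of zero bases) never merges
  merged <- GenomicRanges::reduce(as_granges0(x), min.gapwidth = 0L)
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
  out <- granges_to_tibble0(merged)
  arrange(out, .data$chrom, .data$start)
}

#' Strip or add the "chr" prefix of chromosome names
#'
#' Chromosome names are compared as exact strings everywhere in the package
#' ("chr1" is not "1"); this helper converts between the two common styles
#' explicitly rather than coercing silently.
#'
#' @param x A data frame; every column named `chrom`, `chrom1` or `chrom2` is
#'   rewritten.
#' @param style `"strip"` removes a leading "chr", `"add"` prepends it where
#'   absent, `"asis"` is a no-op.
#' @return The data frame with rewritten chromosome columns.
#' @export
normalize_chroms <- function(x, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  if (style == "asis") return(x)
  fix <- function(v) {
    if (style == "strip") sub("^chr", "", v) else ifelse(grepl("^chr", v), v, paste0("chr", v))
  }
  for (col in intersect(c("chrom", "chrom1", "chrom2"), names(x))) {
    x[[col]] <- fix(x[[col]])
  }
  x
}

# compact "chr1:100-200" labels, used for node labels and feature ids
interval_label <- function(chrom, start, end) {
  paste0(chrom, ":", start, "-", end)
}
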