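# Readers for the flat-file formats the package consumes. All coordinates are
# normalized to 0-based half-open on the way in.

# Read a tab-delimited text file into a list of character vectors, skipping
# blank lines, "#" comments and browser/track header lines, but remembering
# the original line number of every data row for error messages.
read_tab_lines <- function(path, what = "file") {
  if (!file.exists(path)) abort(paste0(what, " not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^#", lines) &
    !grepl("^(track|browser)\\b", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

parse_int <- function(x, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0) {
    abort(paste0("line ", lineno[bad[1]], ": cannot parse ", what,
                 " ('", x[bad[1]], "') as an integer"))
  }
  v
}

#' Read paired-anchor chromatin interactions
#'
#' Parses a BEDPE-dialect interaction file: tab-separated
#' `chrom1 start1 end1 chrom2 start2 end2 pet_count [score]`, coordinates
#' 0-based half-open. This is the format emitted (up to column naming) by
#' ChIA-PET pre-processing pipelines; the `chiapet_tool` dialect is read as
#' the same 7-column BEDPE superset. Anchors are canonically ordered so that
#' anchor 1 is never after anchor 2 by (chrom, start), and inter-chromosomal
#' pairs are retained and flagged `trans`.
#'
#' A missing 7th column defaults the PET count to 1 with a warning, since some
#' BEDPE emitters omit it.
#'
#' @param path Path to the interaction file.
#' @param dialect `"bedpe"` or `"chiapet_tool"` (currently parsed
#'   identically; the distinction is kept for forward compatibility).
#' @param chrom_style Passed to [normalize_chroms()].
#' @return A tibble with columns `chrom1,start1,end1,chrom2,start2,end2`,
#'   `pet_count` (integer >= 1), `score` (double, `NA` when absent) and
#'   `trans` (logical, inter-chromosomal).
#' @export
read_interactions <- function(path, dialect = c("bedpe", "chiapet_tool"),
                              chrom_style = c("asis", "strip", "add")) {
  dialect <- match.arg(dialect)
  chrom_style <- match.arg(chrom_style)
  parsed <- read_tab_lines(path, "interaction file")
  if (length(parsed$fields) == 0) {
    return(empty_interactions())
  }
  ncols <- lengths(parsed$fields)
  if (any(ncols < 6)) {
    bad <- which(ncols < 6)[1]
    abort(paste0("line ", parsed$lineno[bad], ": expected at least 6 ",
                 "tab-separated columns, found ", ncols[bad]))
  }
  get_col <- function(i) vapply(parsed$fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, character(1))
  ln <- parsed$lineno
  x <- tibble(
    chrom1 = get_col(1),
    start1 = parse_int(get_col(2), ln, "start1"),
    end1 = parse_int(get_col(3), ln, "end1"),
    chrom2 = get_col(4),
    start2 = parse_int(get_col(5), ln, "start2"),
    end2 = parse_int(get_col(6), ln, "end2")
  )
  pet_raw <- get_col(7)
  if (all(is.na(pet_raw))) {
    warn("no 7th column: defaulting pet_count to 1 for all interactions")
    x$pet_count <- 1L
  } else {
    if (any(is.na(pet_raw))) {
      abad <- which(is.na(pet_raw))[1]
      abort(paste0("line ", ln[abad], ": missing PET-count column"))
    }
    x$pet_count <- parse_int(pet_raw, ln, "pet_count")
  }
  score_raw <- get_col(8)
  x$score <- suppressWarnings(as.double(score_raw))
  # per-anchor interval validation with file line numbers
  for (side in 1:2) {
    s <- x[[paste0("start", side)]]; e <- x[[paste0("end", side)]]
    if (any(s < 0)) {
      abort(paste0("line ", ln[which(s < 0)[1]], ": negative start coordinate"))
    }
    bad <- which(e <= s)
    if (length(bad) > 0) {
      abort(paste0("line ", ln[bad[1]], ": anchor ", side, " has end <= start (",
                   s[bad[1]], ", ", e[bad[1]], "); zero-length and inverted ",
                   "anchors are not valid half-open intervals"))
    }
  }
  bad <- which(x$pet_count < 1L)
  if (length(bad) > 0) {
    abort(paste0("line ", ln[bad[1]], ": pet_count must be >= 1, found ",
                 x$pet_count[bad[1]]))
  }
  x <- normalize_chroms(x, chrom_style)
  canonicalize_interactions(x)
}

empty_interactions <- function() {
  tibble(chrom1 = character(), start1 = integer(), end1 = integer(),
         chrom2 = character(), start2 = integer(), end2 = integer(),
         pet_count = integer(), score = double(), trans = logical())
}

# order the two anchors of each interaction by (chrom, start, end)
canonicalize_interactions <- function(x) {
  swap <- (x$chrom2 < x$chrom1) |
    (x$chrom2 == x$chrom1 & (x$start2 < x$start1 |
                               (x$start2 == x$start1 & x$end2 < x$end1)))
  if (any(swap)) {
    tmp <- x[swap, c("chrom1", "start1", "end1")]
    x[swap, c("chrom1", "start1", "end1")] <-
      setNames(x[swap, c("chrom2", "start2", "end2")], c("chrom1", "start1", "end1"))
    x[swap, c("chrom2", "start2", "end2")] <-
      setNames(tmp, c("chrom2", "start2", "end2"))
  }
  x$trans <- x$chrom1 != x$chrom2
  x
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3+ (track/browser/comment lines skipped) into a 0-based half-open
#' interval tibble. A 4th column, when present, is kept as `name`.
#'
#' @param path Path to the BED file.
#' @param chrom_style Passed to [normalize_chroms()].
#' @return Tibble with columns `chrom`, `start`, `end` (and `name` if the
#'   file has one); empty files give an empty tibble.
#' @export
read_bed <- function(path, chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  parsed <- read_tab_lines(path, "BED file")
  if (length(parsed$fields) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  ncols <- lengths(parsed$fields)
  if (any(ncols < 3)) {
    bad <- which(ncols < 3)[1]
    abort(paste0("line ", parsed$lineno[bad],
                 ": BED requires at least 3 columns"))
  }
  ln <- parsed$lineno
  x <- tibble(
    chrom = vapply(parsed$fields, `[[`, character(1), 1),
    start = parse_int(vapply(parsed$fields, `[[`, character(1), 2), ln, "start"),
    end = parse_int(vapply(parsed$fields, `[[`, character(1), 3), ln, "end")
  )
  if (any(ncols >= 4)) {
    x$name <- vapply(parsed$fields, function(f) {
      if (length(f) >= 4) f[[4]] else NA_character_
    }, character(1))
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(paste0("line ", ln[bad[1]], ": end <= start (", x$start[bad[1]],
                 ", ", x$end[bad[1]], ")"))
  }
  if (any(x$start < 0)) {
    abort(paste0("line ", ln[which(x$start < 0)[1]], ": negative start"))
  }
  normalize_chroms(x, chrom_style)
}

#' Read a variant table
#'
#' Tab-separated `chrom pos [id]`, positions 0-based. Variants are treated as
#' 1-bp intervals `[pos, pos + 1)` wherever they are overlapped with nodes.
#'
#' @param path Path to the variant file.
#' @param chrom_style Passed to [normalize_chroms()].
#' @return Tibble with columns `chrom`, `pos`, `id`.
#' @export
read_variants <- function(path, chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  parsed <- read_tab_lines(path, "variant file")
  if (length(parsed$fields) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character()))
  }
  ncols <- lengths(parsed$fields)
  if (any(ncols < 2)) {
    abort(paste0("line ", parsed$lineno[which(ncols < 2)[1]],
                 ": variant rows need at least chrom and pos"))
  }
  ln <- parsed$lineno
  x <- tibble(
    chrom = vapply(parsed$fields, `[[`, character(1), 1),
    pos = parse_int(vapply(parsed$fields, `[[`, character(1), 2), ln, "pos"),
    id = vapply(parsed$fields, function(f) {
      if (length(f) >= 3) f[[3]] else NA_character_
    }, character(1))
  )
  if (any(x$pos < 0)) {
    abort(paste0("line ", ln[which(x$pos < 0)[1]], ": negative position"))
  }
  x$id <- ifelse(is.na(x$id), paste0(x$chrom, ":", x$pos), x$id)
  normalize_chroms(x, chrom_style)
}

#' Read a refGene-style gene model table
#'
#' Expects a tab-separated file with a header naming (at least) the columns
#' `name`, `chrom`, `strand`, `txStart`, `txEnd` (snake_case variants are also
#' accepted). Coordinates are 0-based half-open; the TSS is `txStart` on the
#' `+` strand and `txEnd - 1` on the `-` strand. Duplicate
#' (name, chrom, tx_start) rows are collapsed.
#'
#' @param path Path to the gene table.
#' @param chrom_style Passed to [normalize_chroms()].
#' @return Tibble with columns `name`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `tss`.
#' @export
read_gene_table <- function(path, chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  nm <- tolower(gsub("[_.]", "", names(x)))
  pick <- function(key) {
    i <- match(key, nm)
    if (is.na(i)) abort(paste0("gene table lacks a '", key, "' column"))
    x[[i]]
  }
  g <- tibble(
    name = as.character(pick("name")),
    chrom = as.character(pick("chrom")),
    strand = as.character(pick("strand")),
    tx_start = as.integer(pick("txstart")),
    tx_end = as.integer(pick("txend"))
  )
  validate_genes(g, chrom_style)
}

#' Validate (and finish) a gene model tibble
#'
#' @param genes Tibble with `name`, `chrom`, `strand`, `tx_start`, `tx_end`.
#' @param chrom_style Passed to [normalize_chroms()].
#' @return The tibble with a `tss` column added, deduplicated.
#' @export
validate_genes <- function(genes, chrom_style = "asis") {
  g <- as_tibble(genes)
  need <- c("name", "chrom", "strand", "tx_start", "tx_end")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!g$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(paste0("gene table row ", bad[1], ": unknown strand symbol '",
                 g$strand[bad[1]], "' (must be + or -)"))
  }
  bad <- which(g$tx_end <= g$tx_start)
  if (length(bad) > 0) {
    abort(paste0("gene table row ", bad[1], ": txEnd must be > txStart"))
  }
  g <- distinct(g, .data$name, .data$chrom, .data$tx_start, .keep_all = TRUE)
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
  normalize_chroms(g, chrom_style)
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path Path to the list file.
#' @return Character vector of unique, non-empty gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("gene list not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !grepl("^#", x)])
}

#' Read a two-column gene-pair list
#'
#' Tab-separated `gene1 gene2` rows, e.g. protein-protein interaction pairs to
#' superimpose on a chromatin network.
#'
#' @param path Path to the pair file.
#' @return Tibble with columns `gene1`, `gene2`.
#' @export
read_gene_pairs <- function(path) {
  parsed <- read_tab_lines(path, "gene-pair file")
  if (length(parsed$fields) == 0) {
    return(tibble(gene1 = character(), gene2 = character()))
  }
  if (any(lengths(parsed$fields) < 2)) {
    abort(paste0("line ",
                 parsed$lineno[which(lengths(parsed$fields) < 2)[1]],
                 ": gene pairs need two columns"))
  }
  tibble(
    gene1 = vapply(parsed$fields, `[[`, character(1), 1),
    gene2 = vapply(parsed$fields, `[[`, character(1), 2)
  )
}
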