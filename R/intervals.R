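#' Construct a genomic interval table
#'
#' The atom of all region arithmetic in this package: a plain data.frame with
#' BED semantics, i.e. 0-based half-open `[start, end)` coordinates. Optional
#' columns carry a record id, a score, and the ChIP tag count supporting a
#' peak (used by the mitochondrial tag-density filter, where density = N/l
#' with N the tag count and l the site length).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open; `0 <= start < end`.
#' @param id optional character vector of record identifiers.
#' @param score optional numeric score.
#' @param tag_count optional non-negative integer tag counts.
#' @return a data.frame of class `genomic_intervals` with columns
#'   `chrom,start,end` and any of `id,score,tag_count` supplied.
#' @examples
#' genomic_intervals("chr1", 100, 250, id = "peak1")
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, score = NULL,
                              tag_count = NULL) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(id)) x$id <- as.character(id)
  if (!is.null(score)) x$score <- as.numeric(score)
  if (!is.null(tag_count)) x$tag_count <- as.integer(tag_count)
  class(x) <- c("genomic_intervals", "data.frame")
  validate_intervals(x)
  x
}

#' Validate a genomic interval table
#'
#' Checks the container invariants: required columns, `0 <= start < end`, and,
#' when a chromosome-size table is supplied, that every interval lies within
#' its declared chromosome.
#'
#' @param x data.frame with columns `chrom,start,end`.
#' @param chrom_sizes optional named vector of chromosome lengths (bp).
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop("non-finite interval coordinates")
  if (any(x$start < 0)) stop("negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("start >= end for record(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) absent from size table: ", paste(unknown, collapse = ", "))
    over <- which(x$end > chrom_sizes[x$chrom])
    if (length(over))
      stop("interval end beyond chromosome length for record(s): ",
           paste(utils::head(over, 5), collapse = ", "))
  }
  if ("tag_count" %in% names(x) && any(!is.na(x$tag_count) & x$tag_count < 0))
    stop("negative tag_count")
  invisible(x)
}

# 0-based half-open -> IRanges (1-based closed), per chromosome.
# Returns list(ranges = IRanges, chrom = split factor keys, idx = original rows)
.split_iranges <- function(x) {
  f <- factor(x$chrom, levels = unique(x$chrom))
  idx <- split(seq_len(nrow(x)), f)
  rng <- lapply(idx, function(i)
    IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
  list(ranges = rng, idx = idx, chroms = names(idx))
}

# For each row of q, TRUE iff it shares >= 1 bp with some row of s.
# Book-ended intervals (q$end == s$start) do NOT count as overlapping.
.overlaps_any <- function(q, s) {
  out <- logical(nrow(q))
  if (nrow(q) == 0 || nrow(s) == 0) return(out)
  sq <- .split_iranges(q)
  ss <- .split_iranges(s)
  for (ch in intersect(sq$chroms, ss$chroms)) {
    hit <- IRanges::overlapsAny(sq$ranges[[ch]], ss$ranges[[ch]], minoverlap = 1L)
    out[sq$idx[[ch]]] <- hit
  }
  out
}

#' Read a two-column chromosome size table
#'
#' @param path tab-separated file with columns chromosome name and length.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(tab$length, tab$chrom)
}
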