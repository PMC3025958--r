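#' Read a BED file into a genomic interval table
#'
#' Reads BED3+ records as 0-based half-open intervals. Column 4 becomes `id`,
#' column 5 becomes `score`; when `score_is_tag_count = TRUE` column 5 is
#' additionally interpreted as the ChIP tag count supporting the site, which
#' is how deposited site lists carry the N of the tag-density filter.
#' `track`, `browser` and `#` comment lines are skipped.
#'
#' @param path path to a BED file.
#' @param score_is_tag_count also copy column 5 into `tag_count`.
#' @return a `genomic_intervals` data.frame.
#' @export
read_bed <- function(path, score_is_tag_count = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": start >= end")
  x <- data.frame(chrom = chrom, start = start, end = end,
                  stringsAsFactors = FALSE)
  if (any(nf >= 4))
    x$id <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (any(nf >= 5)) {
    sc <- vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")
    x$score <- suppressWarnings(as.numeric(sc))
    if (score_is_tag_count) x$tag_count <- as.integer(round(x$score))
  }
  class(x) <- c("genomic_intervals", "data.frame")
  validate_intervals(x)
  x
}

#' Write a genomic interval table as BED
#'
#' Records are written sorted by (chrom, start). The score column is taken
#' from `tag_count` when present, else from `score`; `read_bed()` of the
#' output round-trips chrom/start/end/id losslessly.
#'
#' @param x a `genomic_intervals` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  o <- order(x$chrom, x$start, x$end)
  x <- x[o, , drop = FALSE]
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  has_score <- "tag_count" %in% names(x) || "score" %in% names(x)
  if ("id" %in% names(x) || has_score) {
    id <- if ("id" %in% names(x)) ifelse(is.na(x$id), ".", x$id)
          else rep(".", nrow(x))
    cols <- c(cols, list(id))
  }
  if (has_score) {
    sc <- if ("tag_count" %in% names(x)) x$tag_count else x$score
    cols <- c(cols, list(ifelse(is.na(sc), "0", as.character(sc))))
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a BED12 file or a simple gene table
#'
#' BED12 input: standard UCSC 12-column records; blocks become exons. Simple
#' table input (detected by a header line starting with `gene_id`):
#' tab-separated columns `gene_id chrom strand tx_start tx_end exon_starts
#' exon_ends` with comma-separated absolute exon coordinates.
#'
#' The transcription start site (TSS) is strand-aware: `tx_start` on `+`,
#' `tx_end - 1` on `-`. Exons must be sorted, non-overlapping and contained
#' in the transcription unit.
#'
#' @param path input path.
#' @return data.frame of class `gene_models` with columns `gene_id, chrom,
#'   strand, tx_start, tx_end, tss` and a list-column `exons` of two-column
#'   (start, end) matrices.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) && grepl("^gene_id\\b", lines[1])) {
    return(.parse_simple_gene_table(lines))
  }
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("BED12 line ", i, ": fewer than 12 columns")
    tx_start <- as.numeric(f[2]); tx_end <- as.numeric(f[3])
    n_blocks <- as.integer(f[10])
    sizes <- as.numeric(strsplit(f[11], ",")[[1]])[seq_len(n_blocks)]
    offs <- as.numeric(strsplit(f[12], ",")[[1]])[seq_len(n_blocks)]
    exons <- cbind(start = tx_start + offs, end = tx_start + offs + sizes)
    list(gene_id = f[4], chrom = f[1], strand = f[6],
         tx_start = tx_start, tx_end = tx_end, exons = exons)
  })
  .build_gene_models(recs)
}

.parse_simple_gene_table <- function(lines) {
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  recs <- lapply(lines[-1], function(l) {
    f <- stats::setNames(strsplit(l, "\t", fixed = TRUE)[[1]], header)
    es <- as.numeric(strsplit(f[["exon_starts"]], ",")[[1]])
    ee <- as.numeric(strsplit(f[["exon_ends"]], ",")[[1]])
    list(gene_id = f[["gene_id"]], chrom = f[["chrom"]], strand = f[["strand"]],
         tx_start = as.numeric(f[["tx_start"]]), tx_end = as.numeric(f[["tx_end"]]),
         exons = cbind(start = es, end = ee))
  })
  .build_gene_models(recs)
}

.build_gene_models <- function(recs) {
  for (r in recs) {
    ex <- r$exons
    if (!nrow(ex)) stop("gene ", r$gene_id, ": no exons")
    if (any(ex[, 1] >= ex[, 2]))
      stop("gene ", r$gene_id, ": empty exon block")
    if (is.unsorted(ex[, 1], strictly = FALSE))
      stop("gene ", r$gene_id, ": exon blocks not sorted")
    if (nrow(ex) > 1 && any(ex[-nrow(ex), 2] > ex[-1, 1]))
      stop("gene ", r$gene_id, ": overlapping exon blocks")
    if (ex[1, 1] < r$tx_start || ex[nrow(ex), 2] > r$tx_end)
      stop("gene ", r$gene_id, ": exon outside transcription unit")
    if (!r$strand %in% c("+", "-"))
      stop("gene ", r$gene_id, ": strand must be + or -")
  }
  g <- data.frame(
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    tx_start = vapply(recs, `[[`, 0, "tx_start"),
    tx_end = vapply(recs, `[[`, 0, "tx_end"),
    stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1)
  g$exons <- lapply(recs, `[[`, "exons")
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Extract site sequences from a FASTA file
#'
#' Subsequences are taken at each interval's coordinates from the named
#' chromosome records of `fasta`, returned as an uppercase character vector
#' named by interval id (or `chrom:start-end` when ids are absent).
#'
#' @param fasta path to a (plain-text) FASTA file of chromosome sequences.
#' @param intervals a `genomic_intervals` data.frame.
#' @return named character vector of sequences.
#' @export
site_sequences <- function(fasta, intervals) {
  validate_intervals(intervals)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(intervals$chrom), names(seqs))
  if (length(missing))
    stop("chromosome(s) absent from FASTA: ", paste(missing, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  validate_intervals(intervals, chrom_sizes = lens)
  out <- as.character(Biostrings::subseq(
    seqs[intervals$chrom], start = intervals$start + 1L, end = intervals$end))
  names(out) <- if ("id" %in% names(intervals) && !anyNA(intervals$id))
    intervals$id else paste0(intervals$chrom, ":", intervals$start, "-", intervals$end)
  toupper(out)
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(unname(seqs), names(seqs))), path)
  invisible(path)
}

#' Read a JSON analysis configuration
#'
#' Thresholds and flags for the pipeline (flank, window, boot_reps, seed,
#' core_thresh, mat_thresh, z_min, fold_min, diffscore_min, density_min).
#' JSON stands in for YAML so that no extra parser dependency is needed;
#' unknown keys are rejected to catch typos.
#'
#' @param path JSON file; may be `NULL` for all defaults.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(flank = 1000, window = 10000, boot_reps = 1000, seed = 1L,
                   core_thresh = 0.75, mat_thresh = 0.80, z_min = 3.0,
                   fold_min = 4.0, diffscore_min = 40, density_min = 0.5,
                   promoter_bp = 1000, detection_p = 0.01)
  if (is.null(path)) return(defaults)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

# Stage-boundary logging: input counts, parameters, output counts.
log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unlist(lapply(kv, format)), sep = "=",
                      collapse = " "))
  message(msg)
  invisible(msg)
}
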