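# merged, sorted, per-chromosome interval index for fast gap queries
.merge_index <- function(x) {
  sp <- split(x[c("start", "end")], x$chrom)
  lapply(sp, function(d) {
    o <- order(d$start)
    s <- d$start[o]; e <- d$end[o]
    # merge strictly overlapping spans (book-ended spans may stay split;
    # irrelevant for any-overlap queries)
    keep_s <- numeric(0); keep_e <- numeric(0)
    cs <- s[1]; ce <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] < ce) ce <- max(ce, e[i])
      else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce); cs <- s[i]; ce <- e[i] }
    }
    list(start = c(keep_s, cs), end = cummax(c(keep_e, ce)))
  })
}

# for each query interval, TRUE iff gap to nearest subject interval <= window
# (overlap = gap 0). Subject is a .merge_index().
.near_any <- function(q, index, window) {
  out <- logical(nrow(q))
  if (nrow(q) == 0) return(out)
  for (ch in unique(q$chrom)) {
    idx <- index[[ch]]
    rows <- which(q$chrom == ch)
    if (is.null(idx)) next
    a <- q$start[rows] - window
    b <- q$end[rows] + window
    # gap <= window iff some subject has start <= b AND end >= a
    # (book-ended extended spans count: gap exactly == window).
    # j = number of subjects with start <= b; idx$end is nondecreasing.
    j <- findInterval(b + 0.5, idx$start)
    out[rows] <- j >= 1 & idx$end[pmax(j, 1)] >= a
  }
  out
}

#' Proximity statistics between binding sites and pre-miRNA loci
#'
#' "Within `window_bp`" is edge-to-edge distance: the gap between closest
#' interval ends is at most `window_bp`, an overlap counting as distance 0.
#' Reports the number of sites near at least one locus, the number of loci
#' near at least one site, their ratio, and the total number of
#' (site, locus) pairs within the window.
#'
#' @param sites,loci interval tables.
#' @param window_bp proximity window, default 10 kb.
#' @return list `n_sites_near, n_loci_near, ratio, n_pairs` (`ratio` is `NA`
#'   when no locus is near a site).
#' @export
proximity_stats <- function(sites, loci, window_bp = 10000) {
  validate_intervals(sites); validate_intervals(loci)
  if (nrow(loci) == 0 || nrow(sites) == 0)
    return(list(n_sites_near = 0L, n_loci_near = 0L, ratio = NA_real_,
                n_pairs = 0L))
  li <- .merge_index(loci)
  si <- .merge_index(sites)
  n_sites_near <- sum(.near_any(sites, li, window_bp))
  n_loci_near <- sum(.near_any(loci, si, window_bp))
  n_pairs <- 0L
  for (ch in intersect(unique(sites$chrom), unique(loci$chrom))) {
    s <- sites[sites$chrom == ch, ]
    l <- loci[loci$chrom == ch, ]
    # closed-coordinate window widened by one so gap == window_bp still pairs
    ir_s <- IRanges::IRanges(s$start - window_bp, s$end + window_bp + 1)
    ir_l <- IRanges::IRanges(l$start + 1, l$end)
    n_pairs <- n_pairs + length(IRanges::findOverlaps(ir_s, ir_l, minoverlap = 1L))
  }
  list(n_sites_near = n_sites_near, n_loci_near = n_loci_near,
       ratio = if (n_loci_near > 0) n_sites_near / n_loci_near else NA_real_,
       n_pairs = n_pairs)
}

#' Resample a site set preserving composition
#'
#' Draws a random site set matched to the input: per chromosome, the same
#' number of sites with the exact original length multiset (lengths permuted
#' within the chromosome) and starts uniform on `[0, chrom_len - length]`.
#' Random sites may overlap each other; `no_self_overlap = TRUE` redraws
#' colliding sites (rejection) for sensitivity analysis.
#'
#' @param sites interval table.
#' @param chrom_sizes named chromosome lengths covering all site chromosomes.
#' @param no_self_overlap forbid overlaps within the resampled set.
#' @param max_tries rejection-sampling cap per chromosome.
#' @return interval table of the same size and per-chromosome composition.
#' @export
resample_sites <- function(sites, chrom_sizes, no_self_overlap = FALSE,
                           max_tries = 1000) {
  validate_intervals(sites, chrom_sizes)
  pieces <- lapply(split(sites, sites$chrom), function(d) {
    ch <- d$chrom[1]
    # permute lengths within chromosome (explicit index: sample(x) on a
    # length-1 numeric would expand to 1:x)
    len <- (d$end - d$start)[sample.int(nrow(d))]
    clen <- chrom_sizes[[ch]]
    if (any(len > clen)) stop("site longer than chromosome ", ch)
    draw <- function(l) floor(stats::runif(length(l), 0, clen - l + 1))
    start <- draw(len)
    if (no_self_overlap) {
      for (t in seq_len(max_tries)) {
        o <- order(start)
        bad_sorted <- which(start[o][-1] < (start + len)[o][-length(o)]) + 1L
        if (!length(bad_sorted)) break
        redo <- o[bad_sorted]
        start[redo] <- draw(len[redo])
        if (t == max_tries) stop("no_self_overlap: rejection cap reached")
      }
    }
    data.frame(chrom = ch, start = start, end = start + len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Matched bootstrap null for site-locus proximity
#'
#' Tests whether binding sites sit near pre-miRNA loci more often than
#' expected by chance: `B` resampled site sets matched in count, length
#' distribution and chromosome composition ([resample_sites()]) are scored
#' with [proximity_stats()], and each observed statistic gets an empirical
#' upper-tail p-value with the add-one rule,
#' `p = (1 + #\{replicates >= observed\}) / (B + 1)` (never exactly 0).
#' The raw exceedance fraction `#\{replicates >= observed\} / B` is also
#' reported, along with the replicate ratio range.
#'
#' @param sites,loci interval tables.
#' @param chrom_sizes named chromosome lengths.
#' @param B number of bootstrap replicates, default 1000.
#' @param window_bp proximity window, default 10 kb.
#' @param seed integer seed; same seed, same result.
#' @param no_self_overlap passed to [resample_sites()].
#' @return object of class `bootstrap_result`: list with `observed`,
#'   `replicates` (B-row data.frame), `p` and `p_raw` (named vectors for
#'   `n_sites_near` and `n_loci_near`), `ratio_range`, `B`, `window_bp`,
#'   `seed`.
#' @export
mirna_bootstrap <- function(sites, loci, chrom_sizes, B = 1000,
                            window_bp = 10000, seed = 1,
                            no_self_overlap = FALSE) {
  stopifnot(B >= 1)
  set.seed(seed)
  observed <- proximity_stats(sites, loci, window_bp)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    r <- resample_sites(sites, chrom_sizes, no_self_overlap)
    reps[[b]] <- proximity_stats(r, loci, window_bp)
  }
  replicates <- data.frame(
    n_sites_near = vapply(reps, `[[`, 0L, "n_sites_near"),
    n_loci_near = vapply(reps, `[[`, 0L, "n_loci_near"),
    ratio = vapply(reps, function(x) as.numeric(x$ratio), 0))
  p_of <- function(stat) {
    ge <- sum(replicates[[stat]] >= observed[[stat]])
    c(p = (1 + ge) / (B + 1), raw = ge / B)
  }
  ps <- cbind(n_sites_near = p_of("n_sites_near"),
              n_loci_near = p_of("n_loci_near"))
  structure(list(observed = observed, replicates = replicates,
                 p = ps["p", ], p_raw = ps["raw", ],
                 ratio_range = if (all(is.na(replicates$ratio)))
                   c(NA_real_, NA_real_) else range(replicates$ratio, na.rm = TRUE),
                 B = B, window_bp = window_bp, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Matched bootstrap (B =", x$B, ", window =", x$window_bp, "bp)\n")
  cat("observed: sites near =", x$observed$n_sites_near,
      "loci near =", x$observed$n_loci_near,
      "ratio =", format(x$observed$ratio, digits = 3), "\n")
  cat("empirical p: sites =", format(x$p[["n_sites_near"]], digits = 3),
      "loci =", format(x$p[["n_loci_near"]], digits = 3), "\n")
  cat("replicate ratio range:",
      paste(format(x$ratio_range, digits = 3), collapse = " - "), "\n")
  invisible(x)
}

#' Serialize a bootstrap result as JSON
#' @param x a `bootstrap_result`.
#' @param path output path.
#' @param replicates_tsv optional path for a TSV of all replicate statistics.
#' @return `path`, invisibly.
#' @export
write_bootstrap_json <- function(x, path, replicates_tsv = NULL) {
  obj <- list(observed = x$observed, p = as.list(x$p), p_raw = as.list(x$p_raw),
              ratio_range = x$ratio_range, B = x$B, window_bp = x$window_bp,
              seed = x$seed,
              replicate_summary = lapply(x$replicates, function(v)
                list(mean = mean(v, na.rm = TRUE),
                     min = suppressWarnings(min(v, na.rm = TRUE)),
                     max = suppressWarnings(max(v, na.rm = TRUE)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(replicates_tsv))
    utils::write.table(x$replicates, replicates_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
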