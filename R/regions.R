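#' Extend peaks symmetrically, clipping at chromosome bounds
#'
#' Each binding peak is elongated by `flank_bp` in both directions (the
#' "cartographic" step that groups nearby sites before merging); the result
#' is clipped to `[0, chromosome length)`.
#'
#' @param x `genomic_intervals` data.frame.
#' @param flank_bp non-negative flank, default 1000 bp.
#' @param chrom_sizes named vector of chromosome lengths; every chromosome in
#'   `x` must be declared.
#' @return extended intervals; ids and other columns preserved.
#' @export
extend_intervals <- function(x, flank_bp = 1000, chrom_sizes) {
  validate_intervals(x)
  stopifnot(flank_bp >= 0)
  unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome(s) absent from size table: ", paste(unknown, collapse = ", "))
  x$start <- pmax(0, x$start - flank_bp)
  x$end <- pmin(unname(chrom_sizes[x$chrom]), x$end + flank_bp)
  validate_intervals(x, chrom_sizes)
  x
}

#' Merge overlapping intervals into binding regions
#'
#' Regions are the connected components of the overlap graph: intervals
#' sharing at least 1 bp end up in the same region. Book-ended intervals
#' (end of one equals start of the next, zero shared bases) are NOT merged,
#' per strict half-open semantics. Member ids of the original records are
#' carried in a list-column.
#'
#' @param x `genomic_intervals` data.frame (typically extended peaks).
#' @return data.frame of class `binding_regions` with columns `chrom, start,
#'   end, region_id, n_members` and list-column `member_ids`.
#' @export
merge_regions <- function(x) {
  validate_intervals(x)
  ids <- if ("id" %in% names(x)) x$id else as.character(seq_len(nrow(x)))
  if (nrow(x) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      region_id = character(0), n_members = integer(0))
    out$member_ids <- list()
    class(out) <- c("binding_regions", "data.frame")
    return(out)
  }
  sp <- .split_iranges(x)
  pieces <- lapply(sp$chroms, function(ch) {
    red <- IRanges::reduce(sp$ranges[[ch]], min.gapwidth = 0L, with.revmap = TRUE)
    members <- lapply(S4Vectors::mcols(red)$revmap, function(i) ids[sp$idx[[ch]][i]])
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), n_members = lengths(members),
               stringsAsFactors = FALSE, row.names = NULL) |>
      transform(member_ids = I(members))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- sprintf("region_%05d", seq_len(nrow(out)))
  out <- out[, c("chrom", "start", "end", "region_id", "n_members", "member_ids")]
  class(out) <- c("binding_regions", "data.frame")
  out
}

# regions within one set must be pairwise non-overlapping
.check_disjoint <- function(x, label) {
  if (nrow(x) < 2) return(invisible(TRUE))
  o <- order(x$chrom, x$start)
  s <- x[o, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (any(same & s$start[-1] < s$end[-nrow(s)]))
    stop("overlapping regions within ", label, " set")
  invisible(TRUE)
}

#' Partition binding regions by receptor subtype
#'
#' Intersects the ERbeta and ERalpha region sets: a beta region overlapping
#' (>= 1 bp) at least one alpha region is a heterodimer (alpha+beta) region;
#' beta regions overlapping none are beta-homodimer; alpha regions
#' overlapping no beta region are alpha-homodimer.
#'
#' @param beta_regions,alpha_regions `binding_regions` (each internally
#'   non-overlapping).
#' @return list with elements `heterodimer`, `homodimer_beta`,
#'   `homodimer_alpha` (subsets of the inputs) and `n_alpha_partners`, the
#'   number of alpha regions overlapping some beta region (so that
#'   `n_alpha_partners + nrow(homodimer_alpha) == nrow(alpha_regions)`).
#' @export
partition_subtypes <- function(beta_regions, alpha_regions) {
  .check_disjoint(beta_regions, "beta")
  .check_disjoint(alpha_regions, "alpha")
  b_hit <- .overlaps_any(beta_regions, alpha_regions)
  a_hit <- .overlaps_any(alpha_regions, beta_regions)
  out <- list(heterodimer = beta_regions[b_hit, , drop = FALSE],
              homodimer_beta = beta_regions[!b_hit, , drop = FALSE],
              homodimer_alpha = alpha_regions[!a_hit, , drop = FALSE],
              n_alpha_partners = sum(a_hit))
  log_stage("partition_subtypes", beta = nrow(beta_regions),
            alpha = nrow(alpha_regions), het = nrow(out$heterodimer),
            homo_beta = nrow(out$homodimer_beta),
            homo_alpha = nrow(out$homodimer_alpha))
  out
}

# map each peak to the (single) region of its set that it overlaps;
# errors when a peak matches no region (provenance mismatch).
.peak_region_index <- function(peaks, regions, label) {
  if (nrow(peaks) == 0) return(integer(0))
  idx <- rep(NA_integer_, nrow(peaks))
  sq <- .split_iranges(peaks)
  sr <- .split_iranges(regions)
  for (ch in sq$chroms) {
    if (!ch %in% sr$chroms) next
    hits <- IRanges::findOverlaps(sq$ranges[[ch]], sr$ranges[[ch]], minoverlap = 1L,
                                  select = "first")
    idx[sq$idx[[ch]]] <- sr$idx[[ch]][hits]
  }
  if (anyNA(idx))
    stop("peak(s) not contained in any ", label,
         " region: peak/region provenance mismatch")
  idx
}

#' Extract subtype-prevalent binding sites
#'
#' A beta peak is a beta-only ("prevalent") site when its containing beta
#' region overlaps no alpha region; symmetric for alpha peaks. These are the
#' sites with no nearby binding of the other receptor subtype.
#'
#' @param beta_peaks,alpha_peaks raw (unextended) peaks.
#' @param beta_regions,alpha_regions region sets built from the same peaks by
#'   [extend_intervals()] + [merge_regions()].
#' @return list with `beta_only` and `alpha_only` interval tables.
#' @export
prevalent_sites <- function(beta_peaks, alpha_peaks, beta_regions, alpha_regions) {
  bi <- .peak_region_index(beta_peaks, beta_regions, "beta")
  ai <- .peak_region_index(alpha_peaks, alpha_regions, "alpha")
  b_region_hit <- .overlaps_any(beta_regions, alpha_regions)
  a_region_hit <- .overlaps_any(alpha_regions, beta_regions)
  out <- list(beta_only = beta_peaks[!b_region_hit[bi], , drop = FALSE],
              alpha_only = alpha_peaks[!a_region_hit[ai], , drop = FALSE])
  log_stage("prevalent_sites", beta_peaks = nrow(beta_peaks),
            alpha_peaks = nrow(alpha_peaks),
            beta_only = nrow(out$beta_only), alpha_only = nrow(out$alpha_only))
  out
}

#' Six-class ER co-binding taxonomy levels
#' @export
site_class_levels <- c("class1_competition", "class2_beta_plus_alpha",
                       "class3_beta_specific", "class4_heterodimer_specific",
                       "class5_alpha_displacement", "class6_alpha_specific")

#' Classify binding sites into the six ER co-binding classes
#'
#' Each ERbeta peak (from ERbeta-expressing cells) is labeled by whether its
#' binding region overlaps the wild-type ERalpha region set and/or the
#' ERalpha-in-ERbeta-cells (TAP) region set:
#' \describe{
#'   \item{class1_competition}{alpha-wt yes, alpha-TAP no: ERalpha binds in
#'     wild-type cells, only ERbeta in ERbeta+ cells.}
#'   \item{class2_beta_plus_alpha}{both: ERalpha binds in wild-type cells and
#'     both receptors in ERbeta+ cells.}
#'   \item{class3_beta_specific}{neither: only ERbeta, ever.}
#'   \item{class4_heterodimer_specific}{alpha-TAP only: both receptors in
#'     ERbeta+ cells, nothing in wild-type.}
#' }
#' ERalpha-TAP peaks whose region contains no ERbeta binding are
#' `class5_alpha_displacement` when the region also misses every wild-type
#' alpha region (alpha binds only in ERbeta+ cells) and
#' `class6_alpha_specific` when wild-type alpha binds too. Alpha-TAP peaks
#' sharing a region with ERbeta inherit class 2 or 4 from the region so the
#' labeling is exhaustive and disjoint over both peak universes.
#'
#' @param beta_peaks,alpha_tap_peaks raw peaks.
#' @param beta_regions,alpha_tap_regions,alpha_wt_regions region sets built
#'   with the same extend/merge procedure.
#' @return data.frame with columns `id, set, chrom, start, end, class`
#'   (factor with [site_class_levels]).
#' @export
classify_six <- function(beta_peaks, beta_regions, alpha_tap_regions,
                         alpha_wt_regions, alpha_tap_peaks) {
  bi <- .peak_region_index(beta_peaks, beta_regions, "beta")
  ai <- .peak_region_index(alpha_tap_peaks, alpha_tap_regions, "alpha-TAP")

  b_vs_wt <- .overlaps_any(beta_regions, alpha_wt_regions)
  b_vs_tap <- .overlaps_any(beta_regions, alpha_tap_regions)
  beta_class <- ifelse(b_vs_wt[bi] & !b_vs_tap[bi], site_class_levels[1],
                ifelse(b_vs_wt[bi] & b_vs_tap[bi], site_class_levels[2],
                ifelse(!b_vs_wt[bi] & !b_vs_tap[bi], site_class_levels[3],
                       site_class_levels[4])))

  a_vs_beta <- .overlaps_any(alpha_tap_regions, beta_regions)
  a_vs_wt <- .overlaps_any(alpha_tap_regions, alpha_wt_regions)
  alpha_class <- ifelse(!a_vs_beta[ai] & !a_vs_wt[ai], site_class_levels[5],
                 ifelse(!a_vs_beta[ai] & a_vs_wt[ai], site_class_levels[6],
                 # region shared with beta: same site as a class-2/4 beta site
                 ifelse(a_vs_wt[ai], site_class_levels[2], site_class_levels[4])))

  ids_of <- function(p) if ("id" %in% names(p)) p$id else as.character(seq_len(nrow(p)))
  out <- rbind(
    data.frame(id = ids_of(beta_peaks),
               set = rep("beta", nrow(beta_peaks)),
               chrom = beta_peaks$chrom, start = beta_peaks$start,
               end = beta_peaks$end, class = beta_class,
               stringsAsFactors = FALSE),
    data.frame(id = ids_of(alpha_tap_peaks),
               set = rep("alpha_tap", nrow(alpha_tap_peaks)),
               chrom = alpha_tap_peaks$chrom, start = alpha_tap_peaks$start,
               end = alpha_tap_peaks$end, class = alpha_class,
               stringsAsFactors = FALSE))
  out$class <- factor(out$class, levels = site_class_levels)
  counts <- table(out$class[out$set == "beta"])
  log_stage("classify_six", beta_peaks = nrow(beta_peaks),
            alpha_tap_peaks = nrow(alpha_tap_peaks),
            class1 = counts[[1]], class2 = counts[[2]], class3 = counts[[3]],
            class4 = counts[[4]])
  out
}

#' Filter sites by ChIP tag density
#'
#' Tag density is N/l: the number of sequence tags supporting a site divided
#' by its length. Sites with density strictly below `min_density` are
#' dropped (a site exactly at the threshold is kept). Intended for
#' mitochondrial-genome peaks, where copy-number noise inflates spurious
#' calls.
#'
#' @param x intervals with a `tag_count` column.
#' @param min_density threshold, default 0.5 tags/bp.
#' @return the retained intervals.
#' @export
tag_density_filter <- function(x, min_density = 0.5) {
  validate_intervals(x)
  if (!"tag_count" %in% names(x) || anyNA(x$tag_count))
    stop("tag_density_filter requires a complete tag_count column")
  density <- x$tag_count / (x$end - x$start)
  out <- x[density >= min_density, , drop = FALSE]
  log_stage("tag_density_filter", input = nrow(x), kept = nrow(out),
            min_density = min_density)
  out
}

#' Reproduce the headline region/partition counts from deposited site lists
#'
#' Runs the full cartographic procedure on two deposited BED site lists:
#' parse, extend by `flank_bp`, merge, partition by subtype, and extract
#' prevalent sites. Returns all counts in one list for comparison with
#' published figures.
#'
#' @param beta_bed,alpha_bed paths to the ERbeta and ERalpha site BEDs.
#' @param chrom_sizes named chromosome lengths; defaults to per-chromosome
#'   max end + flank so arbitrary assemblies parse.
#' @param flank_bp extension, default 1000.
#' @return list of counts: `n_beta_sites, n_alpha_sites, n_beta_regions,
#'   n_alpha_regions, n_heterodimer, n_homodimer_beta, n_homodimer_alpha,
#'   n_beta_only, n_alpha_only`.
#' @export
reproduce_region_counts <- function(beta_bed, alpha_bed, chrom_sizes = NULL,
                                    flank_bp = 1000) {
  beta <- read_bed(beta_bed)
  alpha <- read_bed(alpha_bed)
  if (is.null(chrom_sizes)) {
    both <- rbind(beta[c("chrom", "start", "end")], alpha[c("chrom", "start", "end")])
    chrom_sizes <- tapply(both$end, both$chrom, max) + flank_bp
  }
  br <- merge_regions(extend_intervals(beta, flank_bp, chrom_sizes))
  ar <- merge_regions(extend_intervals(alpha, flank_bp, chrom_sizes))
  part <- partition_subtypes(br, ar)
  prev <- prevalent_sites(beta, alpha, br, ar)
  list(n_beta_sites = nrow(beta), n_alpha_sites = nrow(alpha),
       n_beta_regions = nrow(br), n_alpha_regions = nrow(ar),
       n_heterodimer = nrow(part$heterodimer),
       n_homodimer_beta = nrow(part$homodimer_beta),
       n_homodimer_alpha = nrow(part$homodimer_alpha),
       n_beta_only = nrow(prev$beta_only),
       n_alpha_only = nrow(prev$alpha_only))
}
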