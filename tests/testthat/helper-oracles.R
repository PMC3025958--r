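# Brute-force oracles, deliberately independent of the package's code paths.

# per-basepair boolean-mask merge at doubled resolution: base b maps to mask
# position 2b+1 and the boundary between b and b+1 to 2b+2, so book-ended
# half-open intervals (zero shared bases) leave an unmarked boundary and stay
# in separate runs, while any 1-bp overlap fuses them.
oracle_merge_spans <- function(x, chrom_sizes) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    mask <- logical(2 * chrom_sizes[[ch]])
    d <- x[x$chrom == ch, ]
    for (i in seq_len(nrow(d)))
      mask[(2 * d$start[i] + 1):(2 * d$end[i] - 1)] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based run starts in doubled coords
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] / 2,
                              end = (ends[keep] + 1) / 2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# O(n*m) pairwise: does each row of q share >= 1 bp with any row of s?
oracle_overlaps_any <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] & s$start < q$end[i] & s$end > q$start[i])
  }, logical(1))
}

# edge-to-edge gap between two half-open intervals on the same chromosome
oracle_gap <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) 0 else max(s2 - e1, s1 - e2)
}

# all-pairs proximity statistics
oracle_proximity <- function(sites, loci, w) {
  near_s <- logical(nrow(sites))
  near_l <- logical(nrow(loci))
  pairs <- 0L
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(loci))) {
    if (sites$chrom[i] != loci$chrom[j]) next
    if (oracle_gap(sites$start[i], sites$end[i],
                   loci$start[j], loci$end[j]) <= w) {
      near_s[i] <- TRUE; near_l[j] <- TRUE; pairs <- pairs + 1L
    }
  }
  list(n_sites_near = sum(near_s), n_loci_near = sum(near_l),
       ratio = if (sum(near_l)) sum(near_s) / sum(near_l) else NA_real_,
       n_pairs = pairs)
}

# six-class labels by exhaustive pairwise overlap, straight from definitions
oracle_classify_six <- function(beta_peaks, beta_regions, atap_regions,
                                awt_regions, atap_peaks) {
  ov <- function(a_chrom, a_start, a_end, set) {
    any(set$chrom == a_chrom & set$start < a_end & set$end > a_start)
  }
  region_of <- function(p, i, regions) {
    hit <- which(regions$chrom == p$chrom[i] & regions$start < p$end[i] &
                   regions$end > p$start[i])
    stopifnot(length(hit) >= 1)
    regions[hit[1], ]
  }
  beta_cls <- vapply(seq_len(nrow(beta_peaks)), function(i) {
    r <- region_of(beta_peaks, i, beta_regions)
    wt <- ov(r$chrom, r$start, r$end, awt_regions)
    tap <- ov(r$chrom, r$start, r$end, atap_regions)
    if (wt && !tap) "class1_competition"
    else if (wt && tap) "class2_beta_plus_alpha"
    else if (!wt && !tap) "class3_beta_specific"
    else "class4_heterodimer_specific"
  }, character(1))
  alpha_cls <- vapply(seq_len(nrow(atap_peaks)), function(i) {
    r <- region_of(atap_peaks, i, atap_regions)
    b <- ov(r$chrom, r$start, r$end, beta_regions)
    wt <- ov(r$chrom, r$start, r$end, awt_regions)
    if (!b && !wt) "class5_alpha_displacement"
    else if (!b && wt) "class6_alpha_specific"
    else if (wt) "class2_beta_plus_alpha"
    else "class4_heterodimer_specific"
  }, character(1))
  list(beta = beta_cls, alpha = alpha_cls)
}

# exhaustive PWM scan: per-offset scoring computed from the frequency matrix
# alone (own information vector, own core search, own reverse complement)
oracle_scan <- function(seq, freq, core_min, mat_min) {
  ci <- apply(freq, 1, function(f) {
    (100 / log(4)) * sum(ifelse(f > 0, f * log(f), 0)) + 100
  })
  L <- nrow(freq)
  core_sums <- sapply(1:(L - 3), function(i) sum(ci[i:(i + 3)]))
  core <- which.max(core_sums):(which.max(core_sums) + 3)
  fmax <- apply(freq, 1, max)
  score_window <- function(chars, positions) {
    num <- 0
    for (l in positions) {
      b <- match(chars[l], c("A", "C", "G", "T"))
      if (!is.na(b)) num <- num + ci[l] * freq[l, b]
    }
    num / sum(ci[positions] * fmax[positions])
  }
  one_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < L) return(data.frame(offset = integer(0)))
    res <- lapply(0:(n - L), function(o) {
      win <- chars[(o + 1):(o + L)]
      data.frame(offset = o, core = score_window(win, core),
                 mat = score_window(win, 1:L))
    })
    do.call(rbind, res)
  }
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  n <- nchar(seq)
  fwd <- one_strand(toupper(seq)); fwd$strand <- "+"
  bwd <- one_strand(rc(toupper(seq)))
  if (nrow(bwd)) bwd$offset <- n - L - bwd$offset
  bwd$strand <- "-"
  hits <- rbind(fwd, bwd)
  hits <- hits[hits$core >= core_min - 1e-12 & hits$mat >= mat_min - 1e-12, ]
  hits[order(hits$offset, hits$strand), c("offset", "strand", "core", "mat")]
}

# random interval set on a toy genome
random_intervals <- function(n, chrom_sizes, max_len = 500) {
  ch <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_sizes[ch] - len))
  genomic_intervals(ch, start, start + len, id = paste0("iv", seq_len(n)))
}
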