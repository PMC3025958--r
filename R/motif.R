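#' Build a position weight matrix object
#'
#' A PWM here is a per-position base-frequency matrix in the MatInspector
#' tradition: each position holds frequencies of A, C, G, T summing to 1.
#' Two derived quantities drive scoring: the information vector `ci`
#' (0 at a uniform position, 100 at a fully conserved one) and the core,
#' the 4 consecutive positions with maximal summed information (ties broken
#' leftmost).
#'
#' @param freq L x 4 numeric matrix with columns A, C, G, T; rows sum to 1.
#' @param name matrix name.
#' @return object of class `pwm`: list with `name`, `freq`, `ci`,
#'   `core_positions`, `length`, `consensus`.
#' @export
new_pwm <- function(freq, name = "pwm") {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4) stop("PWM must have 4 base columns")
  colnames(freq) <- c("A", "C", "G", "T")
  if (any(freq < 0)) stop("negative frequencies in PWM")
  if (any(abs(rowSums(freq) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  if (nrow(freq) < 4) stop("PWM shorter than the 4-position core")
  ci <- information_vector(freq)
  core_sums <- vapply(seq_len(nrow(freq) - 3L),
                      function(i) sum(ci[i:(i + 3L)]), 0)
  core_start <- which.max(core_sums)  # which.max takes the leftmost tie
  cons <- colnames(freq)[apply(freq, 1, which.max)]
  structure(list(name = name, freq = freq, ci = ci,
                 core_positions = core_start:(core_start + 3L),
                 length = nrow(freq), consensus = paste(cons, collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- length", x$length,
      "core", paste(range(x$core_positions), collapse = "-"),
      "consensus", x$consensus, "\n")
  invisible(x)
}

#' Per-position information vector of a frequency matrix
#'
#' `ci(l) = (100/ln 4) * sum_b f(l,b) ln f(l,b) + 100`, with `0*ln 0 = 0`:
#' 0 for a uniform position, 100 for a perfectly conserved one.
#'
#' @param freq L x 4 row-stochastic matrix.
#' @return numeric vector of length L in [0, 100].
#' @export
information_vector <- function(freq) {
  freq <- as.matrix(freq)
  if (any(freq < 0)) stop("negative frequencies")
  plogp <- ifelse(freq > 0, freq * log(freq), 0)
  (100 / log(4)) * rowSums(plogp) + 100
}

.BASE_IDX <- stats::setNames(1:4, c("A", "C", "G", "T"))

# sequence string -> integer codes (A=1 C=2 G=3 T=4, other/N = NA)
.seq_codes <- function(seq) {
  unname(.BASE_IDX[strsplit(toupper(seq), "", fixed = TRUE)[[1]]])
}

# shared numerator/denominator machinery; positions = subset of 1..L
.similarity <- function(codes, pwm, positions) {
  ci <- pwm$ci[positions]
  f <- pwm$freq[positions, , drop = FALSE]
  fmax <- apply(f, 1, max)
  b <- codes[positions]
  contrib <- ifelse(is.na(b), 0, ci * f[cbind(seq_along(positions), b)])
  denom <- sum(ci * fmax)
  if (denom == 0) return(0)
  sum(contrib) / denom
}

#' Matrix similarity of a sequence window to a PWM
#'
#' `sum_l ci(l) f(l, b_l) / sum_l ci(l) max_b f(l, b)`; an `N` base
#' contributes 0 to the numerator. 1.0 for the per-position argmax
#' consensus, 0 for all-N.
#'
#' @param window string of length `pwm$length` over A,C,G,T,N.
#' @param pwm a [new_pwm()] object.
#' @return score in [0, 1].
#' @export
matrix_similarity <- function(window, pwm) {
  codes <- .seq_codes(window)
  if (length(codes) != pwm$length)
    stop("window length ", length(codes), " != PWM length ", pwm$length)
  .similarity(codes, pwm, seq_len(pwm$length))
}

#' Core similarity of a sequence window to a PWM
#'
#' The same similarity ratio restricted to the PWM's core: the 4 consecutive
#' positions with maximal summed information.
#'
#' @inheritParams matrix_similarity
#' @return score in [0, 1].
#' @export
core_similarity <- function(window, pwm) {
  codes <- .seq_codes(window)
  if (length(codes) != pwm$length)
    stop("window length ", length(codes), " != PWM length ", pwm$length)
  .similarity(codes, pwm, pwm$core_positions)
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

# vectorized all-offsets similarity scan of one strand; returns data.frame
.scan_strand <- function(codes, pwm) {
  L <- pwm$length
  n <- length(codes)
  n_off <- n - L + 1L
  if (n_off < 1) return(data.frame(offset = integer(0), core = numeric(0),
                                   mat = numeric(0)))
  ci <- pwm$ci
  fmax <- apply(pwm$freq, 1, max)
  num_all <- numeric(n_off)
  num_core <- numeric(n_off)
  core <- pwm$core_positions
  for (l in seq_len(L)) {
    b <- codes[l:(l + n_off - 1L)]
    w <- ifelse(is.na(b), 0, ci[l] * pwm$freq[l, ][b])
    w[is.na(w)] <- 0
    num_all <- num_all + w
    if (l %in% core) num_core <- num_core + w
  }
  data.frame(offset = 0:(n_off - 1L),
             core = num_core / sum(ci[core] * fmax[core]),
             mat = num_all / sum(ci * fmax))
}

#' Scan a sequence for PWM matches on both strands
#'
#' A hit requires core similarity >= `core_min` AND matrix similarity >=
#' `mat_min`. The reverse strand is scanned as the reverse complement with
#' hit offsets mapped back to forward coordinates; overlapping hits are all
#' reported.
#'
#' @param sequence DNA string (A,C,G,T,N).
#' @param pwm a [new_pwm()] object.
#' @param core_min core similarity threshold, default 0.75.
#' @param mat_min matrix similarity threshold, default 0.80.
#' @return data.frame with columns `offset` (0-based, forward strand),
#'   `strand` (+/-), `core_similarity`, `matrix_similarity`, `match`
#'   (forward-strand text under the window).
#' @export
scan_pwm <- function(sequence, pwm, core_min = 0.75, mat_min = 0.80) {
  stopifnot(core_min >= 0, core_min <= 1, mat_min >= 0, mat_min <= 1)
  seq <- toupper(sequence)
  n <- nchar(seq)
  fwd <- .scan_strand(.seq_codes(seq), pwm)
  rev <- .scan_strand(.seq_codes(.revcomp(seq)), pwm)
  fwd$strand <- "+"
  if (nrow(rev)) rev$offset <- n - pwm$length - rev$offset
  rev$strand <- "-"
  hits <- rbind(fwd, rev)
  hits <- hits[hits$core >= core_min & hits$mat >= mat_min, , drop = FALSE]
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  matched <- if (nrow(hits)) substring(seq, hits$offset + 1L,
                                       hits$offset + pwm$length)
             else character(0)
  data.frame(offset = hits$offset, strand = hits$strand,
             core_similarity = hits$core, matrix_similarity = hits$mat,
             match = matched, stringsAsFactors = FALSE, row.names = NULL)
}

#' Find hemi-palindromic ERE half-sites (RGGTCA)
#'
#' Exact matches to the half-ERE consensus PuGGTCA: `[AG]GGTCA` on the
#' forward strand; a reverse-strand half-site appears as `TGACC[CT]` in the
#' forward text. Overlapping matches are all reported.
#'
#' @param sequence DNA string.
#' @return data.frame with `offset` (0-based, forward coordinates of the
#'   6-mer) and `strand`.
#' @export
scan_half_site <- function(sequence) {
  seq <- toupper(sequence)
  find_all <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  fwd <- find_all("[AG]GGTCA")
  rev <- find_all("TGACC[CT]")
  out <- rbind(
    data.frame(offset = fwd, strand = rep("+", length(fwd))),
    data.frame(offset = rev, strand = rep("-", length(rev))))
  out[order(out$offset), , drop = FALSE]
}

#' Default open full-ERE frequency matrix
#'
#' Built from the 13-bp palindromic consensus GGTCAnnnTGACC: consensus
#' positions get `consensus_freq` on the consensus base and the remainder
#' split evenly; the 3-bp spacer is uniform (information 0, so it never
#' contributes to similarity). An open, documented stand-in for proprietary
#' ER matrices; it preserves the palindrome structure but not any vendor's
#' exact percentages.
#'
#' @param consensus_freq frequency of the consensus base, default 0.85.
#' @return a `pwm` object named "ERE_consensus".
#' @export
default_ere_pwm <- function(consensus_freq = 0.85) {
  consensus <- strsplit("GGTCANNNTGACC", "")[[1]]
  off <- (1 - consensus_freq) / 3
  freq <- t(vapply(consensus, function(b) {
    if (b == "N") rep(0.25, 4)
    else {
      v <- rep(off, 4)
      v[.BASE_IDX[[b]]] <- consensus_freq
      v
    }
  }, numeric(4)))
  rownames(freq) <- NULL
  new_pwm(freq, name = "ERE_consensus")
}

#' Read / write PWM frequency tables
#'
#' Plain-text format: a header line `# name <matrix name>` followed by a
#' tab-separated table with columns `A C G T`, one row per position.
#'
#' @param path file path.
#' @return `read_pwm`: a `pwm` object.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- "pwm"
  hdr <- grep("^# *name", lines, value = TRUE)
  if (length(hdr)) name <- trimws(sub("^# *name", "", hdr[1]))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  new_pwm(as.matrix(tab[, c("A", "C", "G", "T")]), name = name)
}

#' @rdname read_pwm
#' @param pwm a `pwm` object to write.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# name", pwm$name), con)
  utils::write.table(as.data.frame(pwm$freq), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' ERE classes
#' @export
ere_class_levels <- c("ERE_PLUS", "HERE_PLUS", "NONE")

#' Classify binding-site sequences by ERE content
#'
#' A site is `ERE_PLUS` when any of the supplied full-ERE matrices hits it
#' (core and matrix similarity thresholds on either strand); the remaining
#' sites are `HERE_PLUS` when they carry a perfect RGGTCA half-site on
#' either strand; the rest are `NONE`. Full-ERE precedence is absolute:
#' half-sites inside ERE_PLUS sites are not counted, matching the
#' search-the-remaining-sites procedure.
#'
#' @param site_sequences named character vector, one sequence per site.
#' @param ere_pwms list of `pwm` objects (default: [default_ere_pwm()]).
#' @param core_min,mat_min scan thresholds.
#' @return factor of site classes (levels [ere_class_levels]) named by site;
#'   attribute `fractions` holds the per-class proportions.
#' @export
classify_ere <- function(site_sequences, ere_pwms = list(default_ere_pwm()),
                         core_min = 0.75, mat_min = 0.80) {
  if (is.null(names(site_sequences)))
    names(site_sequences) <- paste0("site_", seq_along(site_sequences))
  if (anyNA(site_sequences)) stop("missing sequence for some site(s)")
  if (inherits(ere_pwms, "pwm")) ere_pwms <- list(ere_pwms)
  cls <- vapply(site_sequences, function(s) {
    full <- any(vapply(ere_pwms, function(p)
      nrow(scan_pwm(s, p, core_min, mat_min)) > 0, logical(1)))
    if (full) return("ERE_PLUS")
    if (nrow(scan_half_site(s)) > 0) return("HERE_PLUS")
    "NONE"
  }, character(1))
  out <- factor(cls, levels = ere_class_levels)
  names(out) <- names(site_sequences)
  attr(out, "fractions") <- prop.table(table(out))
  out
}

#' Per-group ERE class fractions
#'
#' @param classes factor from [classify_ere()].
#' @param groups grouping factor/vector aligned with `classes` (e.g. the
#'   heterodimer / beta-only / alpha-only site groups).
#' @return data.frame of fractions per group; rows sum to 1.
#' @export
ere_class_summary <- function(classes, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(classes))
  tab <- prop.table(table(group = groups, class = classes), margin = 1)
  as.data.frame.matrix(tab)
}
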