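#' Default simulated genome
#'
#' Three 5-Mb autosome surrogates plus a 16,569-bp mitochondrial surrogate
#' (the human mtDNA length).
#'
#' @param n_autosomes number of autosome surrogates.
#' @param autosome_bp length of each autosome surrogate.
#' @return named numeric vector of chromosome lengths.
#' @export
sim_chrom_sizes <- function(n_autosomes = 3, autosome_bp = 5e6) {
  c(stats::setNames(rep(autosome_bp, n_autosomes),
                    paste0("sim", seq_len(n_autosomes))),
    chrM = 16569)
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults emulate the
#' study's data shapes at reduced scale: peak counts in the published
#' beta/alpha-only proportion, class proportions echoing the published
#' six-class split, log-normal peak lengths around a 400-bp median.
#'
#' @param chrom_sizes genome, default [sim_chrom_sizes()].
#' @param n_beta number of ERbeta peaks.
#' @param n_alpha_only number of alpha-only clusters (classes 5/6).
#' @param class_props proportions of beta peaks intended as classes 1-4
#'   (sums to 1); default echoes the published split 2126/4340/2707/529.
#' @param class5_frac fraction of alpha-only clusters intended as class 5
#'   (rest class 6); default echoes 617/1390.
#' @param peak_len_meanlog,peak_len_sdlog log-normal length parameters
#'   (median 400 bp); lengths are clipped to `[100, 2000]` bp.
#' @param companion_max_gap maximal edge-to-edge gap between a beta peak and
#'   a planted companion alpha peak; must stay below twice the extension
#'   flank so companion regions always merge/overlap.
#' @param flank extension used downstream, default 1000.
#' @param n_genes,exons_per_gene gene-model generator shape.
#' @param n_mirna,mirna_f,mirna_locus_len pre-miRNA locus generator shape:
#'   locus count, planted proximity fraction, locus length.
#' @param expr_props regulated-group proportions (wt-only, both, beta-only,
#'   opposite) echoing the published 234/154/516/17 split; remainder (if
#'   any) unregulated.
#' @param expr_sigma DiffScore noise SD, default 0 (noise off).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = sim_chrom_sizes(),
                       n_beta = 300, n_alpha_only = 45,
                       class_props = c(class1 = 2126, class2 = 4340,
                                       class3 = 2707, class4 = 529) / 9702,
                       class5_frac = 617 / 1390,
                       peak_len_meanlog = log(400), peak_len_sdlog = 0.4,
                       companion_max_gap = 800, flank = 1000,
                       n_genes = 100, exons_per_gene = 4,
                       n_mirna = 50, mirna_f = 0.3, mirna_locus_len = 80,
                       expr_props = c(wt_only = 0.25, both = 0.17,
                                      beta_only = 0.56, opposite = 0.02),
                       expr_sigma = 0) {
  stopifnot(all(class_props >= 0), abs(sum(class_props) - 1) < 1e-9,
            class5_frac >= 0, class5_frac <= 1,
            all(expr_props >= 0), sum(expr_props) <= 1 + 1e-9,
            companion_max_gap < 2 * flank)
  structure(as.list(environment()), class = "sim_config")
}

.rpeak_len <- function(n, cfg) {
  pmin(2000, pmax(100, round(stats::rlnorm(n, cfg$peak_len_meanlog,
                                           cfg$peak_len_sdlog))))
}

# deterministic class assignment honoring exact proportions
.assign_counts <- function(n, props) {
  k <- floor(n * props)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(n * props - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  k
}

#' Simulate three ChIP-Seq peak sets with a planted co-binding design
#'
#' Peaks are laid out in well-separated genomic slots (one cluster per
#' slot) so that the intended six-class label of every cluster is
#' recoverable after extension and merging: companion alpha peaks sit
#' within `companion_max_gap` bp of their beta peak, and slot spacing keeps
#' extended regions of different clusters disjoint. Errors when the genome
#' cannot host the requested counts at that spacing (infeasible design).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with interval tables `beta`, `alpha_tap`, `alpha_wt`, a
#'   `truth` data.frame (id, set, class), and `chrom_sizes`.
#' @export
simulate_peaks <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  chroms <- setdiff(names(cfg$chrom_sizes), "chrM")
  sizes <- cfg$chrom_sizes[chroms]
  n_slots <- cfg$n_beta + cfg$n_alpha_only
  # influence radius: peak half-length + companion gap + companion length
  # + extension flank; x2 between neighboring cluster centers
  radius <- 2000 / 2 + cfg$companion_max_gap + 2000 + cfg$flank
  per_chrom <- .assign_counts(n_slots, sizes / sum(sizes))
  slot_w <- floor(sizes / pmax(per_chrom, 1))
  if (any(per_chrom > 0 & slot_w < 2 * radius + 1))
    stop("infeasible design: genome too small for ", n_slots,
         " well-separated clusters (need slot width >= ", 2 * radius + 1, ")")
  centers <- unlist(lapply(seq_along(chroms), function(i) {
    k <- per_chrom[i]
    if (k == 0) return(numeric(0))
    base <- (seq_len(k) - 0.5) * slot_w[i]
    jit <- stats::runif(k, -(slot_w[i] / 2 - radius), slot_w[i] / 2 - radius)
    base + jit
  }))
  slot_chrom <- rep(chroms, per_chrom)
  ord <- sample(n_slots)  # shuffle which slot hosts which cluster type
  centers <- centers[ord]
  slot_chrom <- slot_chrom[ord]

  beta_classes <- rep(names(cfg$class_props),
                      .assign_counts(cfg$n_beta, cfg$class_props))
  n5 <- .assign_counts(cfg$n_alpha_only,
                       c(cfg$class5_frac, 1 - cfg$class5_frac))
  alpha_only_classes <- rep(c("class5", "class6"), n5)

  mk <- function(chrom, center, len)
    data.frame(chrom = chrom, start = round(center - len / 2),
               end = round(center - len / 2) + len, stringsAsFactors = FALSE)
  companion <- function(anchor, cfg) {
    len <- .rpeak_len(1, cfg)
    gap <- stats::runif(1, 0, cfg$companion_max_gap)
    if (stats::runif(1) < 0.5)
      data.frame(chrom = anchor$chrom, start = anchor$end + gap,
                 end = anchor$end + gap + len)
    else
      data.frame(chrom = anchor$chrom, start = anchor$start - gap - len,
                 end = anchor$start - gap)
  }

  beta <- alpha_tap <- alpha_wt <- list()
  truth <- list()
  for (i in seq_len(cfg$n_beta)) {
    cls <- beta_classes[i]
    b <- mk(slot_chrom[i], centers[i], .rpeak_len(1, cfg))
    beta[[length(beta) + 1]] <- b
    truth[[length(truth) + 1]] <-
      data.frame(id = paste0("beta_", i), set = "beta", class = cls)
    if (cls %in% c("class1", "class2"))
      alpha_wt[[length(alpha_wt) + 1]] <- companion(b, cfg)
    if (cls %in% c("class2", "class4"))
      alpha_tap[[length(alpha_tap) + 1]] <- companion(b, cfg)
  }
  for (j in seq_len(cfg$n_alpha_only)) {
    i <- cfg$n_beta + j
    cls <- alpha_only_classes[j]
    a <- mk(slot_chrom[i], centers[i], .rpeak_len(1, cfg))
    alpha_tap[[length(alpha_tap) + 1]] <- a
    truth[[length(truth) + 1]] <-
      data.frame(id = paste0("alphaonly_", j), set = "alpha_tap", class = cls)
    if (cls == "class6") alpha_wt[[length(alpha_wt) + 1]] <- companion(a, cfg)
  }

  finish <- function(lst, prefix) {
    x <- do.call(rbind, lst)
    if (is.null(x)) x <- data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0))
    x$start <- pmax(0, round(x$start)); x$end <- round(x$end)
    x$id <- if (nrow(x)) paste0(prefix, "_", seq_len(nrow(x))) else character(0)
    class(x) <- c("genomic_intervals", "data.frame")
    validate_intervals(x, cfg$chrom_sizes)
    x
  }
  beta <- finish(beta, "beta")
  out <- list(beta = beta,
              alpha_tap = finish(alpha_tap, "atap"),
              alpha_wt = finish(alpha_wt, "awt"),
              truth = do.call(rbind, truth),
              chrom_sizes = cfg$chrom_sizes)
  log_stage("simulate_peaks", beta = nrow(out$beta),
            alpha_tap = nrow(out$alpha_tap), alpha_wt = nrow(out$alpha_wt))
  out
}

.random_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.random_seq <- function(len, gc = 0.5) paste(.random_bases(len, gc), collapse = "")

# plant a motif string at a random offset inside a background sequence
.plant <- function(background, motif) {
  n <- nchar(background); L <- nchar(motif)
  off <- sample.int(n - L + 1, 1)
  paste0(substring(background, 1, off - 1), motif,
         substring(background, off + L, n))
}

.full_ere_instance <- function(k_mismatch) {
  cons <- strsplit("GGTCANNNTGACC", "")[[1]]
  info <- which(cons != "N")
  cons[cons == "N"] <- .random_bases(3)
  if (k_mismatch > 0) {
    pos <- sample(info, k_mismatch)
    for (p in pos) cons[p] <- sample(setdiff(c("A", "C", "G", "T"), cons[p]), 1)
  }
  paste(cons, collapse = "")
}

#' Simulate binding-site sequences with planted ERE content
#'
#' Generates one sequence per site with a designated class mix: a fraction
#' carries a full palindromic ERE (consensus with `k_mismatch` substitutions
#' among the informative positions), a second fraction carries only an
#' RGGTCA half-site, and the rest is background (i.i.d. bases at the
#' requested GC content). With `clean = TRUE` (default) background segments
#' are rejection-sampled so each emitted sequence classifies exactly as
#' intended by [classify_ere()] at the supplied thresholds, making the
#' truth table exact; `clean = FALSE` plants into raw background, so chance
#' motif hits can upgrade a site's realized class.
#'
#' @param n number of sites.
#' @param site_len sequence length (>= 13), default 200.
#' @param fractions named proportions `c(ere=, here=, none=)` summing to 1.
#' @param k_mismatch substitutions applied to planted full EREs, default 1
#'   (still above default thresholds).
#' @param gc background GC content, default 0.5 (0.4 mimics the GC-rich
#'   context of several ERE-less tethering motifs).
#' @param core_min,mat_min thresholds used for cleaning.
#' @param clean reject chance motifs in background segments.
#' @param seed integer seed.
#' @return list with named character vector `sequences` and data.frame
#'   `truth` (site, class).
#' @export
simulate_sequences <- function(n, site_len = 200,
                               fractions = c(ere = 0.5, here = 0.3, none = 0.2),
                               k_mismatch = 1, gc = 0.5,
                               core_min = 0.75, mat_min = 0.80,
                               clean = TRUE, seed = 1) {
  stopifnot(site_len >= 13, abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  counts <- .assign_counts(n, fractions[c("ere", "here", "none")])
  classes <- rep(c("ERE_PLUS", "HERE_PLUS", "NONE"), counts)
  pwm <- default_ere_pwm()
  has_full <- function(s) nrow(scan_pwm(s, pwm, core_min, mat_min)) > 0
  has_half <- function(s) nrow(scan_half_site(s)) > 0
  gen_one <- function(cls) {
    repeat {
      bg <- .random_seq(site_len, gc)
      s <- switch(cls,
                  ERE_PLUS = .plant(bg, .full_ere_instance(k_mismatch)),
                  HERE_PLUS = .plant(bg, paste0(sample(c("A", "G"), 1), "GGTCA")),
                  NONE = bg)
      if (!clean) return(s)
      ok <- switch(cls,
                   ERE_PLUS = has_full(s),
                   HERE_PLUS = !has_full(s) && has_half(s),
                   NONE = !has_full(s) && !has_half(s))
      if (ok) return(s)
    }
  }
  seqs <- vapply(classes, gen_one, character(1))
  names(seqs) <- paste0("site_", seq_len(n))
  list(sequences = seqs,
       truth = data.frame(site = names(seqs), class = classes,
                          stringsAsFactors = FALSE))
}

#' Simulate gene models on the synthetic genome
#'
#' Genes are placed on a regular grid with random strand; each gene gets
#' `exons_per_gene` equal exons separated by introns.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return `gene_models` data.frame.
#' @export
simulate_genes <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  chroms <- setdiff(names(cfg$chrom_sizes), "chrM")
  sizes <- cfg$chrom_sizes[chroms]
  per_chrom <- .assign_counts(cfg$n_genes, sizes / sum(sizes))
  recs <- list()
  g <- 0
  for (i in seq_along(chroms)) {
    if (per_chrom[i] == 0) next
    slot <- floor(sizes[i] / per_chrom[i])
    for (k in seq_len(per_chrom[i])) {
      g <- g + 1
      tx_len <- round(stats::runif(1, 5000, min(40000, slot * 0.6)))
      tx_start <- (k - 1) * slot + round(stats::runif(1, 0, slot - tx_len - 1))
      exon_len <- max(50, floor(tx_len / (2 * cfg$exons_per_gene)))
      gaplen <- floor((tx_len - cfg$exons_per_gene * exon_len) /
                        max(1, cfg$exons_per_gene - 1))
      es <- tx_start + (seq_len(cfg$exons_per_gene) - 1) * (exon_len + gaplen)
      recs[[g]] <- list(gene_id = sprintf("gene_%04d", g), chrom = chroms[i],
                        strand = sample(c("+", "-"), 1),
                        tx_start = tx_start, tx_end = tx_start + tx_len,
                        exons = cbind(start = es, end = es + exon_len))
    }
  }
  .build_gene_models(recs)
}

#' Simulate a differential-expression table with planted regulation groups
#'
#' Two cell lines (`wt`, `beta`) at 0/2/4/8 h. Regulated gene-lines ramp
#' their |DiffScore| to 60 at 8 h (above the 40 threshold only at 8 h, as in
#' the real design where group calls use the 8-h data); unregulated
#' gene-lines stay flat. `OPPOSITE` genes are repressed in wt and activated
#' in beta cells. Gaussian noise of SD `expr_sigma` is added to DiffScores
#' (and proportionally to log2 fold-changes); at `expr_sigma = 0` the
#' planted groups are recovered exactly by [classify_regulation()].
#'
#' @param gene_ids character vector of gene ids.
#' @param config a [sim_config()] (uses `expr_props`, `expr_sigma`).
#' @param seed integer seed.
#' @return list with the long-format `table` (gene_id, line, time, log2fc,
#'   diffscore, detection_p) and `truth` (gene_id, group; `UNREGULATED` for
#'   the remainder).
#' @export
simulate_expression <- function(gene_ids, config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  n <- length(gene_ids)
  props <- c(cfg$expr_props, unreg = max(0, 1 - sum(cfg$expr_props)))
  counts <- .assign_counts(n, props)
  groups <- sample(rep(c("WT_ONLY", "BOTH_CONCORDANT", "BETA_ONLY",
                         "OPPOSITE", "UNREGULATED"), counts))
  times <- c(0, 2, 4, 8)
  ramp <- c(0, 15, 30, 60)   # |DiffScore| trajectory when regulated
  flat <- c(0, 2, 4, 6)
  rows <- list()
  for (i in seq_len(n)) {
    grp <- groups[i]
    dir_wt <- switch(grp, WT_ONLY = sample(c(-1, 1), 1),
                     BOTH_CONCORDANT = sample(c(-1, 1), 1),
                     OPPOSITE = -1, 0)
    dir_beta <- switch(grp, BETA_ONLY = sample(c(-1, 1), 1),
                       BOTH_CONCORDANT = dir_wt, OPPOSITE = 1, 0)
    for (line in c("wt", "beta")) {
      dir <- if (line == "wt") dir_wt else dir_beta
      ds <- if (dir != 0) dir * ramp else sample(c(-1, 1), 1) * flat
      ds <- ds + c(0, stats::rnorm(3, 0, cfg$expr_sigma))
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene_ids[i], line = line, time = times,
        log2fc = ds / 30, diffscore = ds, detection_p = 0.001,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows),
       truth = data.frame(gene_id = gene_ids, group = groups,
                          stringsAsFactors = FALSE))
}

#' Simulate pre-miRNA loci with planted proximity to sites
#'
#' A fraction `f` of loci is placed within `window_bp` (edge-to-edge) of a
#' randomly chosen site; the rest land uniformly on the genome. Truth
#' records the intent; un-planted loci can still fall near a site by
#' chance.
#'
#' @param sites interval table the planted loci attach to.
#' @param chrom_sizes named chromosome lengths.
#' @param n_loci number of loci.
#' @param f planted proximity fraction in [0, 1].
#' @param window_bp proximity window used for planting, default 10 kb.
#' @param locus_len locus length, default 80 bp (pre-miRNA hairpin scale).
#' @param seed integer seed.
#' @return list with `loci` (interval table) and `truth` (locus id,
#'   planted flag).
#' @export
simulate_mirna <- function(sites, chrom_sizes, n_loci = 50, f = 0.3,
                           window_bp = 10000, locus_len = 80, seed = 1) {
  stopifnot(f >= 0, f <= 1, n_loci >= 0)
  set.seed(seed)
  n_planted <- round(f * n_loci)
  rows <- list()
  if (n_planted > 0) {
    anchors <- sites[sample.int(nrow(sites), n_planted, replace = TRUE), ]
    for (i in seq_len(n_planted)) {
      gap <- stats::runif(1, 0, max(0, window_bp - 1))
      start <- if (stats::runif(1) < 0.5) anchors$end[i] + gap
               else anchors$start[i] - gap - locus_len
      start <- max(0, min(start, chrom_sizes[[anchors$chrom[i]]] - locus_len))
      rows[[i]] <- data.frame(chrom = anchors$chrom[i], start = floor(start),
                              end = floor(start) + locus_len)
    }
  }
  chroms <- names(chrom_sizes)
  for (j in seq_len(n_loci - n_planted)) {
    ch <- sample(chroms, 1, prob = chrom_sizes / sum(chrom_sizes))
    start <- floor(stats::runif(1, 0, chrom_sizes[[ch]] - locus_len))
    rows[[n_planted + j]] <- data.frame(chrom = ch, start = start,
                                        end = start + locus_len)
  }
  loci <- do.call(rbind, rows)
  loci$id <- sprintf("mir_%03d", seq_len(nrow(loci)))
  class(loci) <- c("genomic_intervals", "data.frame")
  validate_intervals(loci, chrom_sizes)
  list(loci = loci,
       truth = data.frame(id = loci$id,
                          planted = rep(c(TRUE, FALSE),
                                        c(n_planted, n_loci - n_planted))))
}
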