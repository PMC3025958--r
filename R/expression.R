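#' Quantile-normalize an intensity matrix
#'
#' Forces every sample (column) onto the identical distribution: the
#' across-sample mean of order statistics. Ties within a sample receive the
#' mean of the tied target values (average ranks).
#'
#' @param m numeric matrix, probes in rows, samples in columns; no missing
#'   values (impute upstream).
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(m)) stop("missing values: impute upstream")
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (target[floor(r)] + target[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Convert an Illumina DiffScore to a p-value and back
#'
#' `p = 10^(-|ds|/10)`; the anchor is |DiffScore| = 40 <-> p = 1e-4. The
#' inverse restores the magnitude with the requested sign.
#'
#' @param ds numeric DiffScore(s).
#' @return p-value(s) in (0, 1].
#' @export
diffscore_to_p <- function(ds) {
  stopifnot(all(is.finite(ds)))
  10^(-abs(ds) / 10)
}

#' @rdname diffscore_to_p
#' @param p p-value(s).
#' @param direction sign of the expression change (+1 up, -1 down).
#' @export
p_to_diffscore <- function(p, direction = 1) {
  sign(direction) * 10 * log10(1 / p)
}

#' Call regulated genes per cell line
#'
#' Input is a long-format expression table with one row per gene x cell line
#' x timepoint. A gene is regulated in a cell line at a timepoint iff it is
#' detected (`detection_p < detection_p_max`) AND `|DiffScore| >=
#' diffscore_min`; the gene-level flag is regulation at any timepoint.
#' Direction is taken from the final (8 h) timepoint, the one the published
#' group analysis was performed on; if the final timepoint is flat, the
#' direction of the largest-|DiffScore| regulated timepoint is used.
#'
#' @param tbl data.frame with columns `gene_id, line, time, log2fc,
#'   diffscore, detection_p`.
#' @param diffscore_min significance threshold, default 40 (p = 1e-4).
#' @param detection_p_max detection threshold, default 0.01.
#' @return data.frame, one row per gene x line: `gene_id, line, regulated,
#'   direction` (+1/-1/NA).
#' @export
call_regulated <- function(tbl, diffscore_min = 40, detection_p_max = 0.01) {
  need <- c("gene_id", "line", "time", "diffscore", "detection_p")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("expression table lacks: ", paste(miss, collapse = ", "))
  tbl$hit <- tbl$detection_p < detection_p_max & abs(tbl$diffscore) >= diffscore_min
  per <- split(tbl, list(tbl$gene_id, tbl$line), drop = TRUE)
  rows <- lapply(per, function(d) {
    reg <- any(d$hit)
    dir <- NA_real_
    if (reg) {
      d8 <- d[d$time == max(d$time), , drop = FALSE]
      if (nrow(d8) && d8$hit[1] && d8$diffscore[1] != 0) dir <- sign(d8$diffscore[1])
      else {
        dh <- d[d$hit, , drop = FALSE]
        dir <- sign(dh$diffscore[which.max(abs(dh$diffscore))])
      }
    }
    data.frame(gene_id = d$gene_id[1], line = d$line[1], regulated = reg,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id, out$line), , drop = FALSE]
}

#' Regulation groups
#' @export
regulation_group_levels <- c("WT_ONLY", "BOTH_CONCORDANT", "BETA_ONLY", "OPPOSITE")

#' Assign regulation groups across the two cell lines
#'
#' Genes regulated in exactly one line are `WT_ONLY` / `BETA_ONLY`; genes
#' regulated in both lines are `BOTH_CONCORDANT` when the directions agree
#' and `OPPOSITE` otherwise. Genes regulated in neither line are excluded.
#'
#' @param calls output of [call_regulated()], with `line` values `"wt"` and
#'   `"beta"`.
#' @return data.frame `gene_id, group` (factor over
#'   [regulation_group_levels]); attribute `counts` holds the group tally.
#' @export
classify_regulation <- function(calls) {
  stopifnot(all(c("gene_id", "line", "regulated", "direction") %in% names(calls)))
  wide <- merge(calls[calls$line == "wt", c("gene_id", "regulated", "direction")],
                calls[calls$line == "beta", c("gene_id", "regulated", "direction")],
                by = "gene_id", all = TRUE, suffixes = c("_wt", "_beta"))
  wide$regulated_wt[is.na(wide$regulated_wt)] <- FALSE
  wide$regulated_beta[is.na(wide$regulated_beta)] <- FALSE
  wide <- wide[wide$regulated_wt | wide$regulated_beta, , drop = FALSE]
  grp <- ifelse(wide$regulated_wt & !wide$regulated_beta, "WT_ONLY",
         ifelse(!wide$regulated_wt & wide$regulated_beta, "BETA_ONLY",
         ifelse(wide$direction_wt == wide$direction_beta,
                "BOTH_CONCORDANT", "OPPOSITE")))
  out <- data.frame(gene_id = wide$gene_id,
                    group = factor(grp, levels = regulation_group_levels),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- table(out$group)
  log_stage("classify_regulation", regulated = nrow(out),
            wt_only = sum(grp == "WT_ONLY"), both = sum(grp == "BOTH_CONCORDANT"),
            beta_only = sum(grp == "BETA_ONLY"), opposite = sum(grp == "OPPOSITE"))
  out
}

#' Read a long-format expression table
#'
#' Tab-separated columns `gene_id line time log2fc diffscore detection_p`
#' with a header line.
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "line", "time", "log2fc", "diffscore", "detection_p")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("expression table lacks: ", paste(miss, collapse = ", "))
  tbl
}
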