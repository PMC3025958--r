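#' Background hit rate of a matrix
#'
#' The per-basepair probability of a matrix hit in the genomic background,
#' either looked up in a precomputed per-matrix rate table (avoids
#' whole-genome scans) or estimated by scanning background sequences:
#' total hits on both strands divided by total forward-strand basepairs.
#'
#' @param sequences character vector of background sequences, or `NULL` when
#'   `rate_table` is used.
#' @param pwm `pwm` object to scan with; ignored with `rate_table`.
#' @param core_min,mat_min scan thresholds.
#' @param rate_table optional named numeric vector of per-matrix rates.
#' @param matrix_name name to look up in `rate_table`.
#' @return per-bp hit probability.
#' @export
background_rate <- function(sequences = NULL, pwm = NULL,
                            core_min = 0.75, mat_min = 0.80,
                            rate_table = NULL, matrix_name = NULL) {
  if (!is.null(rate_table)) {
    if (is.null(matrix_name) || !matrix_name %in% names(rate_table))
      stop("matrix_name absent from rate table")
    return(unname(rate_table[matrix_name]))
  }
  if (is.null(sequences) || length(sequences) == 0 ||
      sum(nchar(sequences)) == 0)
    stop("empty background")
  hits <- sum(vapply(sequences, function(s)
    nrow(scan_pwm(s, pwm, core_min, mat_min)), 0L))
  hits / sum(nchar(sequences))
}

#' Over-representation record for one matrix in one site group
#'
#' Compares the observed match count `O` in `T` scanned basepairs with the
#' expectation `E = p_bg * T` under the genomic background rate. Fold is
#' `O/E`; significance is a continuity-corrected normal approximation to the
#' binomial: `z = (O - E - 0.5) / sqrt(E (1 - p_bg))`.
#'
#' @param O observed hit count (non-negative integer).
#' @param T_bp total scanned basepairs (> 0).
#' @param p_bg background per-bp hit probability.
#' @param matrix_name label carried into the record.
#' @return one-row data.frame: `matrix, O, E, p_bg, T_bp, fold, z`. When
#'   `E = 0` with `O > 0`, fold is `Inf` and z is `NA` (flagged infinite
#'   enrichment).
#' @export
enrichment <- function(O, T_bp, p_bg, matrix_name = "matrix") {
  stopifnot(T_bp > 0, O >= 0, p_bg >= 0, p_bg <= 1)
  E <- p_bg * T_bp
  if (E == 0) {
    fold <- if (O > 0) Inf else NA_real_
    z <- NA_real_
  } else {
    fold <- O / E
    z <- (O - E - 0.5) / sqrt(E * (1 - p_bg))
  }
  data.frame(matrix = matrix_name, O = O, E = E, p_bg = p_bg, T_bp = T_bp,
             fold = fold, z = z, stringsAsFactors = FALSE)
}

#' Filter over-representation records
#'
#' Keeps matrices that are both statistically significant (`z >= z_min`) and
#' highly enriched (`fold >= fold_min`); both bounds inclusive. Defaults
#' follow the published screen: Z >= 3.0 and >= 4-fold.
#'
#' @param records data.frame of [enrichment()] rows.
#' @param z_min,fold_min thresholds.
#' @return the retained rows.
#' @export
filter_enriched <- function(records, z_min = 3.0, fold_min = 4.0) {
  if (nrow(records) == 0) return(records)
  keep <- !is.na(records$z) & records$z >= z_min &
    !is.na(records$fold) & records$fold >= fold_min
  records[keep, , drop = FALSE]
}

#' Fold-enrichment grid over site groups with z-gating
#'
#' The heat-grid report: one row per site group, one column per matrix.
#' Cells hold the fold value when `z >= z_min`, the sentinel `"low-z"` when
#' the matrix is present but not significant, and `"absent"` when `O = 0`.
#'
#' @param records_by_group named list of [enrichment()] data.frames (one per
#'   site group, each with one row per matrix).
#' @param z_min significance gate, default 3.
#' @return character matrix (groups x matrices); attribute `fold` carries
#'   the ungated numeric folds.
#' @export
enrichment_grid <- function(records_by_group, z_min = 3.0) {
  matrices <- unique(unlist(lapply(records_by_group, `[[`, "matrix")))
  groups <- names(records_by_group)
  grid <- matrix("absent", nrow = length(groups), ncol = length(matrices),
                 dimnames = list(groups, matrices))
  fold <- matrix(NA_real_, nrow = length(groups), ncol = length(matrices),
                 dimnames = list(groups, matrices))
  for (g in groups) {
    rec <- records_by_group[[g]]
    for (i in seq_len(nrow(rec))) {
      m <- rec$matrix[i]
      fold[g, m] <- rec$fold[i]
      grid[g, m] <-
        if (rec$O[i] == 0) "absent"
        else if (is.na(rec$z[i]) || rec$z[i] < z_min) "low-z"
        else format(rec$fold[i], digits = 4)
    }
  }
  attr(grid, "fold") <- fold
  grid
}

#' Write an enrichment report / grid as TSV
#' @param records data.frame of enrichment rows (with pass flag added).
#' @param path output path.
#' @param z_min,fold_min thresholds used for the pass column.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(records, path, z_min = 3.0, fold_min = 4.0) {
  records$pass <- !is.na(records$z) & records$z >= z_min &
    !is.na(records$fold) & records$fold >= fold_min
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
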