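#' Link binding regions to genes within a window of the transcription unit
#'
#' A region is linked to a gene when it overlaps the transcription unit
#' extended by `window_bp` on both sides, i.e. `[tx_start - window, tx_end +
#' window)`. A region may link to several genes; genes with at least one
#' link are "primary" targets.
#'
#' @param genes a `gene_models` data.frame ([read_gene_table()]).
#' @param regions `binding_regions` (or any interval table with region ids).
#' @param window_bp linking window, default 10 kb.
#' @return data.frame of links: `gene_id, region_id` plus region
#'   coordinates.
#' @export
link_targets <- function(genes, regions, window_bp = 10000) {
  stopifnot(window_bp >= 0)
  rid <- if ("region_id" %in% names(regions)) regions$region_id
         else if ("id" %in% names(regions)) regions$id
         else as.character(seq_len(nrow(regions)))
  gx <- data.frame(chrom = genes$chrom,
                   start = pmax(0, genes$tx_start - window_bp),
                   end = genes$tx_end + window_bp)
  links <- list()
  sq <- .split_iranges(gx)
  sr <- .split_iranges(regions)
  for (ch in intersect(sq$chroms, sr$chroms)) {
    h <- IRanges::findOverlaps(sq$ranges[[ch]], sr$ranges[[ch]], minoverlap = 1L)
    if (length(h) == 0) next
    gi <- sq$idx[[ch]][S4Vectors::queryHits(h)]
    ri <- sr$idx[[ch]][S4Vectors::subjectHits(h)]
    links[[ch]] <- data.frame(gene_id = genes$gene_id[gi], region_id = rid[ri],
                              chrom = ch, region_start = regions$start[ri],
                              region_end = regions$end[ri],
                              stringsAsFactors = FALSE)
  }
  out <- if (length(links)) do.call(rbind, links)
         else data.frame(gene_id = character(0), region_id = character(0),
                         chrom = character(0), region_start = numeric(0),
                         region_end = numeric(0))
  out <- out[order(out$gene_id, out$region_start), , drop = FALSE]
  rownames(out) <- NULL
  log_stage("link_targets", genes = nrow(genes), regions = nrow(regions),
            window_bp = window_bp, links = nrow(out),
            primary_genes = length(unique(out$gene_id)))
  out
}

#' Site location labels
#' @export
site_location_levels <- c("promoter", "exon", "intron", "upstream", "downstream")

#' Annotate a linked site's position relative to a gene
#'
#' Strand-aware labeling by site midpoint: `promoter` covers the
#' `promoter_bp` bases immediately 5' of the TSS; `exon`/`intron` by
#' containment in the transcription unit; `upstream` lies 5' beyond the
#' promoter; `downstream` lies 3' of the transcription unit. At boundary
#' ambiguities the precedence is promoter > exon > intron. With
#' `by = "containment"` a site overlapping any exon is `exon`, any part of
#' the promoter window `promoter`, etc., evaluated in the same precedence.
#'
#' @param site one-row interval (chrom, start, end).
#' @param gene one row of a `gene_models` data.frame.
#' @param promoter_bp promoter extent 5' of the TSS, default 1000.
#' @param by `"midpoint"` (default) or `"containment"`.
#' @return one of [site_location_levels].
#' @export
annotate_location <- function(site, gene, promoter_bp = 1000, by = "midpoint") {
  if (site$chrom != gene$chrom) stop("site not linked to gene (chromosome mismatch)")
  exons <- gene$exons[[1]]
  plus <- gene$strand == "+"
  promoter <- if (plus) c(max(0, gene$tss - promoter_bp), gene$tss)
              else c(gene$tss + 1, gene$tss + 1 + promoter_bp)  # half-open
  spans_hit <- function(a, b) {  # does the site (or midpoint) intersect [a, b)?
    if (by == "midpoint") {
      mid <- floor((site$start + site$end) / 2)
      mid >= a && mid < b
    } else site$start < b && site$end > a
  }
  if (spans_hit(promoter[1], promoter[2])) return("promoter")
  in_exon <- any(apply(exons, 1, function(e) spans_hit(e[1], e[2])))
  if (in_exon) return("exon")
  if (spans_hit(gene$tx_start, gene$tx_end)) return("intron")
  mid <- floor((site$start + site$end) / 2)
  five_prime <- if (plus) mid < gene$tx_start else mid >= gene$tx_end
  if (five_prime) "upstream" else "downstream"
}

#' Collapse a gene's linked site classes into a gene class
#'
#' A gene whose linked sites all share one co-binding class keeps that
#' class (however many sites there are); genes with sites of different
#' classes are labeled `"combination"`.
#'
#' @param classes character/factor vector of site classes (>= 1).
#' @return single class label or `"combination"`.
#' @export
assign_gene_class <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) == 0) stop("assign_gene_class needs >= 1 linked site")
  u <- unique(classes)
  if (length(u) == 1) u else "combination"
}

#' Build the primary-target table
#'
#' Combines linking, per-site location annotation and gene-class assignment
#' into one table mirroring a supplementary-table layout: gene, gene class,
#' TU coordinates, site coordinates, site class, site location.
#'
#' @param genes `gene_models`.
#' @param regions `binding_regions` linked to `genes`.
#' @param site_classes optional named vector mapping region id -> co-binding
#'   class; when `NULL`, gene classes are omitted.
#' @param window_bp linking window, default 10 kb.
#' @param promoter_bp promoter extent, default 1000.
#' @return data.frame with one row per (gene, linked region).
#' @export
primary_targets <- function(genes, regions, site_classes = NULL,
                            window_bp = 10000, promoter_bp = 1000) {
  links <- link_targets(genes, regions, window_bp)
  if (nrow(links) == 0) {
    links$location <- character(0)
    links$site_class <- character(0)
    links$gene_class <- character(0)
    return(links)
  }
  gidx <- match(links$gene_id, genes$gene_id)
  links$location <- vapply(seq_len(nrow(links)), function(i) {
    site <- data.frame(chrom = links$chrom[i], start = links$region_start[i],
                       end = links$region_end[i])
    annotate_location(site, genes[gidx[i], , drop = FALSE], promoter_bp)
  }, character(1))
  if (!is.null(site_classes)) {
    links$site_class <- as.character(site_classes[links$region_id])
    gene_cls <- tapply(links$site_class, links$gene_id, assign_gene_class)
    links$gene_class <- as.character(gene_cls[links$gene_id])
  }
  links
}
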