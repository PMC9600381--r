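## Cobalamin riboswitch hit filtering and genomic-context assignment.

#' Filter riboswitch hits by E-value
#'
#' Keeps covariance-model hits at or below the E-value cutoff. Counts are
#' reported as raw per-model tallies without model-length normalization:
#' read lengths and covariance-model lengths are similar, so length
#' normalization is unnecessary for riboswitches.
#'
#' @param hits data.frame from [read_cmsearch_tblout()].
#' @param evalue_max E-value cutoff (default 1e-6).
#' @return The filtered hit data.frame.
#' @export
filter_riboswitch_hits <- function(hits, evalue_max = 1e-6) {
  out <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-model raw riboswitch counts
#'
#' @param hits (Filtered) riboswitch hit data.frame.
#' @return Named integer vector model -> raw hit count.
#' @export
riboswitch_model_counts <- function(hits) {
  tab <- table(hits$model_name)
  setNames(as.integer(tab), names(tab))
}

.gff_gene_table <- function(annotations) {
  if (is.character(annotations))
    annotations <- rtracklayer::import(annotations, format = "gff3")
  stopifnot(methods::is(annotations, "GRanges"))
  types <- as.character(annotations$type %||% "gene")
  keep <- types %in% c("gene", "CDS")
  if (any(keep)) annotations <- annotations[keep]
  md <- S4Vectors::mcols(annotations)
  gene_id <- if ("Name" %in% names(md) && !all(is.na(md$Name)))
    ifelse(is.na(md$Name), as.character(md$ID %||% NA), as.character(md$Name))
  else as.character(md$ID %||% seq_along(annotations))
  product <- if ("product" %in% names(md)) as.character(md$product)
             else rep(NA_character_, length(annotations))
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(annotations)),
    start = GenomicRanges::start(annotations),
    end = GenomicRanges::end(annotations),
    strand = as.character(GenomicRanges::strand(annotations)),
    gene_id = gene_id, product = product, stringsAsFactors = FALSE)
}

#' Assign genomic context to riboswitches
#'
#' For each riboswitch interval, lists the genes overlapping it or lying
#' within \code{window_bp} on either side, with their distance and strand
#' orientation relative to the riboswitch, and assigns a functional
#' category: the category (per \code{function_map}) of the nearest
#' same-strand downstream gene, falling back to \code{"hypothetical"} when
#' that gene has no product annotation and \code{"other"} when it is not in
#' the map or no downstream gene exists. Upstream/downstream are defined on
#' the riboswitch's strand, matching the 5' regulatory placement of
#' riboswitches.
#'
#' @param riboswitch_intervals data.frame with columns \code{seqid},
#'   \code{start}, \code{end}, \code{strand} (1-based inclusive) and
#'   optionally \code{riboswitch_id}.
#' @param annotations GFF3 path or a \code{GRanges} of gene features.
#' @param window_bp Search window on each side (default 5000).
#' @param function_map Named character vector gene_id -> category (one of
#'   cobamide_biosynthesis, abc_transport, cobalt_transport,
#'   cobamide_dependent, cobamide_independent_isozyme, hypothetical,
#'   other).
#' @return List of contexts, one per riboswitch: list(riboswitch,
#'   upstream, downstream, functional_category), the gene lists sorted by
#'   distance.
#' @export
assign_context <- function(riboswitch_intervals, annotations,
                           window_bp = 5000L, function_map = character()) {
  assert_cols(riboswitch_intervals, c("seqid", "start", "end", "strand"),
              "riboswitch intervals")
  genes <- .gff_gene_table(annotations)
  miss <- setdiff(unique(riboswitch_intervals$seqid), unique(genes$seqid))
  if (length(miss))
    stopf("sequence id(s) absent from annotations: %s",
          paste(miss, collapse = ", "))
  lapply(seq_len(nrow(riboswitch_intervals)), function(i) {
    rs <- riboswitch_intervals[i, ]
    g <- genes[genes$seqid == rs$seqid, , drop = FALSE]
    # signed genomic offset: >0 right of the riboswitch, 0 if overlapping
    dist_right <- pmax(0L, g$start - rs$end)
    dist_left <- pmax(0L, rs$start - g$end)
    overlapping <- g$start <= rs$end & g$end >= rs$start
    dist <- ifelse(overlapping, 0L, pmax(dist_right, dist_left))
    side_right <- !overlapping & g$start > rs$end
    within <- dist <= window_bp
    g <- g[within, , drop = FALSE]
    dist <- dist[within]; side_right <- side_right[within]
    overlapping <- overlapping[within]
    downstream_side <- if (rs$strand == "+") side_right else
      (!side_right & !overlapping)
    rel_strand <- ifelse(g$strand == rs$strand, "same", "opposite")
    mk <- function(sel) {
      df <- data.frame(gene_id = g$gene_id[sel], product = g$product[sel],
                       strand = g$strand[sel], rel_strand = rel_strand[sel],
                       distance = dist[sel], stringsAsFactors = FALSE)
      df[order(df$distance, df$gene_id), , drop = FALSE]
    }
    down <- mk(downstream_side | overlapping)
    up <- mk(!downstream_side | overlapping)
    cand <- down[down$rel_strand == "same", , drop = FALSE]
    category <- "other"
    if (nrow(cand)) {
      nearest <- cand[1L, ]
      if (nearest$gene_id %in% names(function_map))
        category <- unname(function_map[nearest$gene_id])
      else if (is.na(nearest$product)) category <- "hypothetical"
    }
    list(riboswitch = rs, upstream = up, downstream = down,
         functional_category = category)
  })
}
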