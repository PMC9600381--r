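## Read-based functional profiling: hit filtering, coverage-based presence,
## normalization, cross-dataset rare-pair filtering and derived profiles.

#' Profiling parameters
#'
#' Filtering and normalization settings for metagenomic read profiling.
#'
#' @param evalue_max Maximum independent E-value for a hit to be retained
#'   (default 1e-6).
#' @param min_coverage Minimum fraction of the HMM length that must be
#'   covered by read envelopes for a gene to be called present in a sample
#'   (default 0.20, inclusive).
#' @param min_samples,min_datasets A (gene, taxon) pairing must appear in at
#'   least \code{min_samples} samples spanning at least \code{min_datasets}
#'   distinct studies to survive rare-pair filtering (defaults 5 and 2).
#' @param depth_scale Depth-normalized counts are hits per
#'   \code{depth_scale} post-QC reads (default 1e6, i.e. hits per million).
#' @param producer_min_markers Minimum number of distinct marker genes a
#'   taxon must show reads for to be called a de novo producer (default 5).
#' @param producer_marker_genes Marker gene set for producer calls; defaults
#'   to the 10 biosynthesis markers of [default_pathway_model()] (the
#'   11-marker panel minus \code{bluB}, which some producers lack).
#' @return A list of class \code{profiling_params}.
#' @export
profiling_params <- function(evalue_max = 1e-6, min_coverage = 0.20,
                             min_samples = 5L, min_datasets = 2L,
                             depth_scale = 1e6, producer_min_markers = 5L,
                             producer_marker_genes = NULL) {
  if (min_coverage <= 0 || min_coverage > 1)
    stopf("min_coverage must be in (0, 1]")
  if (is.null(producer_marker_genes))
    producer_marker_genes <- default_pathway_model()$marker_genes
  if (producer_min_markers > length(producer_marker_genes))
    stopf("producer_min_markers exceeds the number of marker genes")
  structure(list(evalue_max = evalue_max, min_coverage = min_coverage,
                 min_samples = as.integer(min_samples),
                 min_datasets = as.integer(min_datasets),
                 depth_scale = depth_scale,
                 producer_min_markers = as.integer(producer_min_markers),
                 producer_marker_genes = producer_marker_genes),
            class = "profiling_params")
}

#' Six-frame translation of a nucleotide read
#'
#' Translates a DNA string in all six reading frames with the standard
#' genetic code: frames +1..+3 from the forward strand, -1..-3 from the
#' reverse complement. Stop codons are rendered \code{*}, codons containing
#' \code{N} become \code{X}, and trailing partial codons are dropped.
#'
#' @param dna A single string over the alphabet A, C, G, T, N.
#' @return Named character vector of length 6 (\code{"+1"}..\code{"-3"}).
#' @export
six_frame_translate <- function(dna) {
  if (!is.character(dna) || length(dna) != 1L)
    stopf("dna must be a single string")
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) stopf("alphabet must be A, C, G, T, N")
  if (nchar(dna) < 3L) stopf("sequence shorter than one codon")
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = n),
      if.fuzzy.codon = "X"))
  }
  c("+1" = one(fwd, 0L), "+2" = one(fwd, 1L), "+3" = one(fwd, 2L),
    "-1" = one(rev, 0L), "-2" = one(rev, 1L), "-3" = one(rev, 2L))
}

#' Best-hit selection across models
#'
#' Drops hits above the E-value cutoff, then keeps exactly one hit per read:
#' the one with the lowest E-value, ties broken by the highest bit score,
#' residual ties by the lexicographically smallest model name. Reads are
#' identified by \code{read_id} after frame-suffix stripping, so the six
#' frame translations of one read compete with each other.
#'
#' @param hits Hit data.frame (see [read_domtblout()]); an optional
#'   \code{sample_id} column scopes deduplication per sample.
#' @param params [profiling_params()].
#' @return The filtered, deduplicated hit data.frame.
#' @export
select_best_hits <- function(hits, params = profiling_params()) {
  hits <- hits[hits$evalue <= params$evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  key <- if ("sample_id" %in% names(hits))
    paste(hits$sample_id, hits$read_id, sep = "\r") else hits$read_id
  ord <- order(key, hits$evalue, -hits$bitscore, hits$hmm_name)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Coverage-based gene presence call
#'
#' A gene is present in a sample when the union of its hit envelopes covers
#' at least \code{min_coverage} of the HMM length (inclusive boundary).
#' Coverage is computed jointly over all taxa in the sample.
#'
#' @param hmm_from,hmm_to Envelope coordinates (1-based inclusive) of the
#'   hits to one gene in one sample.
#' @param hmm_length Model length.
#' @param params [profiling_params()].
#' @return list(present = logical, coverage = fraction).
#' @export
gene_presence <- function(hmm_from, hmm_to, hmm_length,
                          params = profiling_params()) {
  if (hmm_length <= 0) stopf("hmm_length must be positive")
  if (length(hmm_from) == 0L)
    return(list(present = FALSE, coverage = 0))
  cov <- interval_union_length(hmm_from, hmm_to) / hmm_length
  list(present = cov >= params$min_coverage, coverage = cov)
}

#' Build the normalized gene-by-taxon table
#'
#' Counts best-hit reads per (sample, gene, taxon), applying the per-sample
#' coverage gate first: genes whose envelope union covers less than
#' \code{min_coverage} of the model in a sample contribute no entries for
#' that sample. Counts are normalized to HMM length (\code{norm_length},
#' for within-sample comparisons) and additionally to sequencing depth
#' (\code{norm_length_depth}, hits per HMM-length-unit per
#' \code{depth_scale} post-QC reads, for cross-sample comparisons). Reads
#' without a species-level classification are aggregated under the reserved
#' taxon \code{"unclassified"}.
#'
#' @param hits Best-hit-deduplicated hit data.frame with a \code{sample_id}
#'   column.
#' @param assignments Read taxonomy (see [read_taxonomy()]).
#' @param metadata Sample metadata with columns \code{sample_id},
#'   \code{study_id}, \code{total_reads} (post-QC read count).
#' @param params [profiling_params()].
#' @return data.frame of class \code{gene_taxon_table} with columns
#'   \code{sample_id}, \code{gene}, \code{taxon}, \code{raw_hits},
#'   \code{norm_length}, \code{norm_length_depth}.
#' @export
build_gene_taxon_table <- function(hits, assignments, metadata,
                                   params = profiling_params()) {
  assert_cols(hits, c("sample_id", "read_id", "hmm_name", "hmm_from",
                      "hmm_to", "hmm_length"), "hits")
  assert_cols(metadata, c("sample_id", "study_id", "total_reads"), "metadata")
  missing_s <- setdiff(unique(hits$sample_id), metadata$sample_id)
  if (length(missing_s))
    stopf("sample(s) missing from metadata: %s",
          paste(missing_s, collapse = ", "))
  if (nrow(hits) == 0L) return(empty_gene_taxon_table())

  # presence gate per (sample, gene) across all taxa jointly
  sg <- paste(hits$sample_id, hits$hmm_name, sep = "\r")
  keep_sg <- vapply(split(seq_len(nrow(hits)), sg), function(ix) {
    gene_presence(hits$hmm_from[ix], hits$hmm_to[ix],
                  hits$hmm_length[ix][1L], params)$present
  }, logical(1))
  hits <- hits[keep_sg[sg], , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_gene_taxon_table())

  ix <- match(hits$read_id, assignments$read_id)
  taxon <- ifelse(is.na(ix) | assignments$rank[ix] == "unclassified",
                  "unclassified", assignments$taxon_name[ix])
  agg <- stats::aggregate(
    list(raw_hits = rep(1L, nrow(hits))),
    by = list(sample_id = hits$sample_id, gene = hits$hmm_name,
              taxon = taxon, hmm_length = hits$hmm_length),
    FUN = sum)
  agg$norm_length <- agg$raw_hits / agg$hmm_length
  depth <- metadata$total_reads[match(agg$sample_id, metadata$sample_id)]
  agg$norm_length_depth <- agg$norm_length / depth * params$depth_scale
  out <- agg[order(agg$sample_id, agg$gene, agg$taxon),
             c("sample_id", "gene", "taxon", "raw_hits", "norm_length",
               "norm_length_depth")]
  rownames(out) <- NULL
  class(out) <- c("gene_taxon_table", "data.frame")
  out
}

empty_gene_taxon_table <- function() {
  out <- data.frame(sample_id = character(), gene = character(),
                    taxon = character(), raw_hits = integer(),
                    norm_length = numeric(), norm_length_depth = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_taxon_table", "data.frame")
  out
}

#' Cross-dataset rare-pair filter
#'
#' Removes (gene, taxon) pairings that do not appear (>= 1 retained read) in
#' at least \code{min_samples} samples spanning at least \code{min_datasets}
#' distinct studies. This suppresses rare and singleton hits that are not
#' conserved across individuals and cohorts. Idempotent.
#'
#' @param table A \code{gene_taxon_table}.
#' @param metadata Sample metadata mapping \code{sample_id} to
#'   \code{study_id}.
#' @param params [profiling_params()].
#' @return The filtered \code{gene_taxon_table}.
#' @export
filter_rare_pairs <- function(table, metadata, params = profiling_params()) {
  if (nrow(table) == 0L) return(table)
  study <- metadata$study_id[match(table$sample_id, metadata$sample_id)]
  if (anyNA(study)) stopf("sample(s) missing from metadata")
  pair <- paste(table$gene, table$taxon, sep = "\r")
  n_samples <- tapply(table$sample_id, pair,
                      function(s) length(unique(s)))
  n_studies <- tapply(study, pair, function(s) length(unique(s)))
  ok <- names(n_samples)[n_samples >= params$min_samples &
                           n_studies >= params$min_datasets]
  out <- table[pair %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove contaminant taxa
#'
#' Deletes every entry whose taxon is on the supplied contaminant list
#' (e.g. from a negative-control decontamination step) and reports how many
#' entries were removed.
#'
#' @param table A \code{gene_taxon_table}.
#' @param contaminant_taxa Character vector of taxa to drop.
#' @return The filtered table; the number of removed entries is attached as
#'   attribute \code{"removed"} and reported via \code{message()}.
#' @export
remove_contaminants <- function(table, contaminant_taxa) {
  drop <- table$taxon %in% contaminant_taxa
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  if (sum(drop) > 0)
    message(sprintf("removed %d contaminant entr%s", sum(drop),
                    if (sum(drop) == 1L) "y" else "ies"))
  out
}

#' Per-sample taxon contributions
#'
#' Fraction of a sample's (length-normalized) biosynthesis gene hits
#' assigned to each taxon, over a chosen gene subset. Contributions sum
#' to 1.
#'
#' @param table A \code{gene_taxon_table}.
#' @param sample_id Sample to profile.
#' @param gene_subset Genes to include (default: all genes in the table).
#' @return Named numeric vector taxon -> fraction.
#' @export
taxon_contribution <- function(table, sample_id,
                               gene_subset = unique(table$gene)) {
  sub <- table[table$sample_id == sample_id & table$gene %in% gene_subset, ,
               drop = FALSE]
  tot <- sum(sub$norm_length)
  if (nrow(sub) == 0L || tot <= 0)
    stopf("no hits in sample '%s' for gene subset", sample_id)
  out <- tapply(sub$norm_length, sub$taxon, sum) / tot
  setNames(as.numeric(out), names(out))
}

#' Per-gene taxonomic frequency profile
#'
#' Fraction of a gene's length- and depth-normalized hits assigned to each
#' taxon, summed across samples. Fractions sum to 1.
#'
#' @param table A \code{gene_taxon_table}.
#' @param gene Gene to profile.
#' @return Named numeric vector taxon -> fraction.
#' @export
gene_frequency_profile <- function(table, gene) {
  sub <- table[table$gene == gene, , drop = FALSE]
  tot <- sum(sub$norm_length_depth)
  if (nrow(sub) == 0L || tot <= 0)
    stopf("gene '%s' absent from table", gene)
  out <- tapply(sub$norm_length_depth, sub$taxon, sum) / tot
  setNames(as.numeric(out), names(out))
}

#' Call de novo producers from metagenomic profiles
#'
#' A taxon is called a de novo cobamide producer when, after all filtering,
#' it retains reads for at least \code{producer_min_markers} distinct genes
#' of the marker panel (default: at least 5 of the 10 biosynthesis markers).
#'
#' @param table A filtered \code{gene_taxon_table}.
#' @param params [profiling_params()].
#' @return Sorted character vector of producer taxa.
#' @export
call_metagenomic_producers <- function(table, params = profiling_params()) {
  sub <- table[table$gene %in% params$producer_marker_genes &
                 table$taxon != "unclassified", , drop = FALSE]
  if (nrow(sub) == 0L) return(character(0))
  n_markers <- tapply(sub$gene, sub$taxon, function(g) length(unique(g)))
  sort(names(n_markers)[n_markers >= params$producer_min_markers])
}

#' Mock-community false-positive rate
#'
#' Fraction of raw hits in a mock-community sample assigned to taxa that
#' were not put into the mock community. Unclassified reads are excluded
#' from both numerator and denominator.
#'
#' @param table \code{gene_taxon_table} built from a single mock sample.
#' @param expected_taxa Taxa truly present in the mock community.
#' @return The false-positive fraction.
#' @export
mock_false_positive_rate <- function(table, expected_taxa) {
  sub <- table[table$taxon != "unclassified", , drop = FALSE]
  tot <- sum(sub$raw_hits)
  if (tot == 0) stopf("no classified hits in table")
  sum(sub$raw_hits[!sub$taxon %in% expected_taxa]) / tot
}

#' Run the full profiling chain
#'
#' Convenience wrapper: best-hit selection, gene-taxon table construction,
#' contaminant removal and rare-pair filtering, in the pipeline's order.
#'
#' @inheritParams build_gene_taxon_table
#' @param contaminant_taxa Optional contaminant list.
#' @return A filtered \code{gene_taxon_table}.
#' @export
run_profiling <- function(hits, assignments, metadata,
                          params = profiling_params(),
                          contaminant_taxa = character(0)) {
  hits <- select_best_hits(hits, params)
  tab <- build_gene_taxon_table(hits, assignments, metadata, params)
  tab <- remove_contaminants(tab, contaminant_taxa)
  filter_rare_pairs(tab, metadata, params)
}
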