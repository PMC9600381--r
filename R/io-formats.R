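## Readers/writers for the external dialects the pipeline touches.
## All tables are UTF-8, tab- or whitespace-delimited, '#'-prefixed comments.
## Coordinates are 1-based inclusive on disk (domtblout, GFF3 convention).

# Split the "_frameK" suffix (K in 1..6; 4..6 = reverse frames) off a
# translated-read identifier. Returns list(read_id, frame) where frame is
# +1..+3 / -1..-3.
strip_frame_suffix <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_frame([1-6])$", ids))
  ok <- lengths(m) == 3L
  read_id <- ids
  frame <- rep(NA_integer_, length(ids))
  read_id[ok] <- vapply(m[ok], `[`, "", 2L)
  k <- as.integer(vapply(m[ok], `[`, "", 3L))
  frame[ok] <- ifelse(k <= 3L, k, -(k - 3L))
  list(read_id = read_id, frame = frame)
}

.read_commented <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.num_or_stop <- function(x, field, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad))
    stopf("malformed %s at line %d: '%s'", field, lineno[bad][1L], x[bad][1L])
  v
}

#' Read an hmmsearch per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain tabular output of
#' \command{hmmsearch} into a hit table. One row per domain hit is returned
#' with the domain's independent E-value, bit score and HMM-coordinate
#' envelope. Translated reads are expected to carry a \code{_frameK} suffix
#' (K in 1..6, 4-6 meaning reverse-strand frames), which is stripped to
#' recover the nucleotide read identifier.
#'
#' @param path Path to a domtblout file ('#' comment lines are skipped).
#' @param hmm_lengths Named integer vector mapping every HMM/gene name that
#'   may occur in the file to its model length. An unregistered model is an
#'   error.
#' @return A data.frame with columns \code{read_id}, \code{frame},
#'   \code{hmm_name}, \code{hmm_accession}, \code{evalue}, \code{bitscore},
#'   \code{hmm_from}, \code{hmm_to}, \code{hmm_length}.
#' @export
read_domtblout <- function(path, hmm_lengths) {
  if (is.null(names(hmm_lengths)) || any(!nzchar(names(hmm_lengths))))
    stopf("hmm_lengths must be a named vector")
  cc <- .read_commented(path)
  if (length(cc$lines) == 0L) return(empty_hits())
  toks <- strsplit(cc$lines, "[ \t]+")
  n_tok <- lengths(toks)
  if (any(n_tok < 22L))
    stopf("truncated domtblout row at line %d (%d fields, expected >= 22)",
          cc$lineno[n_tok < 22L][1L], min(n_tok))
  get <- function(i) vapply(toks, `[`, "", i)
  target <- get(1L)
  fr <- strip_frame_suffix(target)
  hmm_name <- get(4L)
  unknown <- setdiff(unique(hmm_name), names(hmm_lengths))
  if (length(unknown))
    stopf("unregistered model: %s", paste(unknown, collapse = ", "))
  hits <- data.frame(
    read_id = fr$read_id,
    frame = fr$frame,
    hmm_name = hmm_name,
    hmm_accession = get(5L),
    evalue = .num_or_stop(get(13L), "i-Evalue", cc$lineno),
    bitscore = .num_or_stop(get(14L), "bit score", cc$lineno),
    hmm_from = as.integer(.num_or_stop(get(16L), "hmm_from", cc$lineno)),
    hmm_to = as.integer(.num_or_stop(get(17L), "hmm_to", cc$lineno)),
    stringsAsFactors = FALSE
  )
  hits$hmm_length <- unname(hmm_lengths[hits$hmm_name])
  validate_hits(hits, lineno = cc$lineno)
}

empty_hits <- function() {
  data.frame(read_id = character(), frame = integer(), hmm_name = character(),
             hmm_accession = character(), evalue = numeric(),
             bitscore = numeric(), hmm_from = integer(), hmm_to = integer(),
             hmm_length = integer(), stringsAsFactors = FALSE)
}

validate_hits <- function(hits, lineno = NULL) {
  bad <- which(hits$hmm_to < hits$hmm_from | hits$hmm_from < 1L |
                 hits$hmm_to > hits$hmm_length | hits$evalue <= 0)
  if (length(bad)) {
    where <- if (is.null(lineno)) sprintf("row %d", bad[1L])
             else sprintf("line %d", lineno[bad[1L]])
    stopf("invalid hit envelope or E-value at %s", where)
  }
  hits
}

#' Write hits back out in domtblout layout
#'
#' Emits the 22-column per-domain layout that [read_domtblout()] parses, so
#' synthetic hit tables round-trip through the same dialect as real
#' \command{hmmsearch} output. Fields the pipeline does not model (alignment
#' coordinates, biases) are written as placeholders.
#'
#' @param hits Hit data.frame as returned by [read_domtblout()].
#' @param path Output path.
#' @export
write_domtblout <- function(hits, path) {
  k <- ifelse(hits$frame > 0, hits$frame, 3L - hits$frame)
  target <- sprintf("%s_frame%d", hits$read_id, k)
  rows <- sprintf(
    "%s - 120 %s %s %d %.3g %.1f 0.0 1 1 %.3g %.3g %.1f 0.0 %d %d 1 100 1 100 0.90 -",
    target, hits$hmm_name, hits$hmm_accession, hits$hmm_length,
    hits$evalue, hits$bitscore, hits$evalue, hits$evalue, hits$bitscore,
    hits$hmm_from, hits$hmm_to)
  writeLines(c("# domain hits table", "#", rows), path)
  invisible(path)
}

#' Read read-level taxonomic assignments
#'
#' Supports two dialects: the Kraken2 per-read output (columns
#' C/U, read id, taxon, read length, LCA mapping) and a generic TSV with a
#' header \code{read_id, taxon_id, taxon_name, rank}. Unclassified reads are
#' returned with \code{rank = "unclassified"}. When a read appears more than
#' once the last assignment wins and a warning reports the number of
#' duplicates.
#'
#' @param path Input file.
#' @param dialect \code{"kraken2"} or \code{"tsv"}.
#' @param taxa Optional data.frame (\code{taxon_id}, \code{taxon_name},
#'   \code{rank}) used to resolve names/ranks for the kraken2 dialect, whose
#'   native output carries only taxon ids.
#' @return data.frame with columns \code{read_id}, \code{taxon_id},
#'   \code{taxon_name}, \code{rank}.
#' @export
read_taxonomy <- function(path, dialect = c("kraken2", "tsv"), taxa = NULL) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "kraken2") .read_taxonomy_kraken2(path, taxa)
         else .read_taxonomy_tsv(path)
  dup <- duplicated(out$read_id, fromLast = TRUE)
  if (any(dup)) {
    warnf("%d duplicate read assignment(s); keeping the last per read", sum(dup))
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.read_taxonomy_kraken2 <- function(path, taxa) {
  cc <- .read_commented(path)
  if (length(cc$lines) == 0L)
    return(data.frame(read_id = character(), taxon_id = integer(),
                      taxon_name = character(), rank = character(),
                      stringsAsFactors = FALSE))
  toks <- strsplit(cc$lines, "\t")
  if (any(lengths(toks) < 4L))
    stopf("kraken2 line %d has fewer than 4 tab-separated fields",
          cc$lineno[lengths(toks) < 4L][1L])
  flag <- vapply(toks, `[`, "", 1L)
  if (!all(flag %in% c("C", "U")))
    stopf("kraken2 classification flag must be 'C' or 'U'")
  read_id <- vapply(toks, `[`, "", 2L)
  taxfield <- vapply(toks, `[`, "", 3L)
  # field 3 is either a bare taxid or "Name (taxid 123)"
  in_paren <- regmatches(taxfield, regexec("\\(taxid ([0-9]+)\\)", taxfield))
  taxon_id <- ifelse(lengths(in_paren) == 2L,
                     vapply(in_paren, function(x) x[2L] %||% NA_character_, ""),
                     taxfield)
  taxon_id <- suppressWarnings(as.integer(taxon_id))
  if (any(is.na(taxon_id)))
    stopf("unparseable taxon field at line %d", cc$lineno[is.na(taxon_id)][1L])
  name <- sub(" *\\(taxid [0-9]+\\)$", "", taxfield)
  name[name == taxfield & grepl("^[0-9]+$", taxfield)] <- NA_character_
  rank <- rep("species", length(read_id))
  if (!is.null(taxa)) {
    assert_cols(taxa, c("taxon_id", "taxon_name", "rank"), "taxa map")
    ix <- match(taxon_id, taxa$taxon_id)
    name <- ifelse(is.na(ix), name, taxa$taxon_name[ix])
    rank <- ifelse(is.na(ix), rank, taxa$rank[ix])
  }
  name[is.na(name)] <- as.character(taxon_id[is.na(name)])
  uncl <- flag == "U"
  rank[uncl] <- "unclassified"
  name[uncl] <- "unclassified"
  taxon_id[uncl] <- 0L
  data.frame(read_id = read_id, taxon_id = taxon_id, taxon_name = name,
             rank = rank, stringsAsFactors = FALSE)
}

.read_taxonomy_tsv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    return(data.frame(read_id = character(), taxon_id = integer(),
                      taxon_name = character(), rank = character(),
                      stringsAsFactors = FALSE))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  assert_cols(df, c("read_id", "taxon_id", "taxon_name", "rank"),
              "taxonomy TSV")
  ranks <- c("species", "genus", "family", "phylum", "unclassified")
  if (!all(df$rank %in% ranks))
    stopf("unknown rank value(s): %s",
          paste(setdiff(unique(df$rank), ranks), collapse = ", "))
  df[, c("read_id", "taxon_id", "taxon_name", "rank")]
}

#' Write taxonomy in the Kraken2 per-read dialect
#' @param assignments data.frame as returned by [read_taxonomy()].
#' @param path Output path.
#' @export
write_taxonomy_kraken2 <- function(assignments, path) {
  uncl <- assignments$rank == "unclassified"
  flag <- ifelse(uncl, "U", "C")
  tax <- ifelse(uncl, "0",
                sprintf("%s (taxid %d)", assignments$taxon_name,
                        assignments$taxon_id))
  writeLines(paste(flag, assignments$read_id, tax, "100", "0:66",
                   sep = "\t"), path)
  invisible(path)
}

#' Read an Infernal cmsearch --tblout table
#'
#' One row per covariance-model hit with its E-value and strand. No E-value
#' threshold is applied here; see [filter_riboswitch_hits()].
#'
#' @param path Path to a cmsearch \code{--tblout} file.
#' @return data.frame with columns \code{read_id}, \code{model_name},
#'   \code{evalue}, \code{strand}.
#' @export
read_cmsearch_tblout <- function(path) {
  cc <- .read_commented(path)
  if (length(cc$lines) == 0L)
    return(data.frame(read_id = character(), model_name = character(),
                      evalue = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  toks <- strsplit(cc$lines, "[ \t]+")
  if (any(lengths(toks) < 16L))
    stopf("truncated tblout row at line %d",
          cc$lineno[lengths(toks) < 16L][1L])
  get <- function(i) vapply(toks, `[`, "", i)
  strand <- get(10L)
  if (!all(strand %in% c("+", "-")))
    stopf("invalid strand value at line %d",
          cc$lineno[!strand %in% c("+", "-")][1L])
  ev <- .num_or_stop(get(16L), "E-value", cc$lineno)
  if (any(ev <= 0)) stopf("non-positive E-value at line %d",
                          cc$lineno[ev <= 0][1L])
  data.frame(read_id = get(1L), model_name = get(3L), evalue = ev,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a per-genome gene presence table
#'
#' TSV with columns \code{genome_id} and \code{gene}, one row per present
#' gene. Gene symbols are matched case-insensitively against a registered
#' vocabulary; unknown symbols are kept verbatim with a warning.
#'
#' @param path Input TSV.
#' @param vocabulary Optional character vector of known gene symbols used to
#'   normalize case.
#' @param roster Optional character vector of genome ids that must appear in
#'   the result even with zero rows (mapped to empty sets).
#' @return Named list mapping genome_id to a character vector (set) of genes.
#' @export
read_gene_table <- function(path, vocabulary = NULL, roster = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  assert_cols(df, c("genome_id", "gene"), "gene table")
  if (!is.null(vocabulary)) {
    ix <- match(tolower(df$gene), tolower(vocabulary))
    unknown <- unique(df$gene[is.na(ix)])
    if (length(unknown))
      warnf("unknown gene symbol(s) kept verbatim: %s",
            paste(unknown, collapse = ", "))
    df$gene[!is.na(ix)] <- vocabulary[ix[!is.na(ix)]]
  }
  sets <- lapply(split(df$gene, df$genome_id), function(g) sort(unique(g)))
  for (g in setdiff(roster, names(sets))) sets[[g]] <- character(0)
  sets
}

#' Write / read internal tables as commented TSV
#'
#' All internal tables (gene-taxon tables, edge tables, rosters) are written
#' as UTF-8 tab-separated files with '#' comment headers, and round-trip
#' exactly.
#'
#' @param df data.frame to write.
#' @param path File path.
#' @param comments Character vector of comment lines (written '#'-prefixed).
#' @export
write_tsv_table <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, quote = "")
}
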