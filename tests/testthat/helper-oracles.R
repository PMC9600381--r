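# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops, bitmaps and closed forms.

# exhaustive per-read scan: lowest E, then highest bit, then lex model name
oracle_best_hits <- function(hits, evalue_max) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  out <- NULL
  for (r in unique(hits$read_id)) {
    sub <- hits[hits$read_id == r, , drop = FALSE]
    best <- sub[1L, , drop = FALSE]
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      cand <- sub[i, , drop = FALSE]
      better <- cand$evalue < best$evalue ||
        (cand$evalue == best$evalue && cand$bitscore > best$bitscore) ||
        (cand$evalue == best$evalue && cand$bitscore == best$bitscore &&
           cand$hmm_name < best$hmm_name)
      if (better) best <- cand
    }
    out <- rbind(out, best)
  }
  out[order(out$read_id), , drop = FALSE]
}

# per-position bitmap coverage
oracle_coverage <- function(from, to, L) {
  pos <- logical(L)
  for (i in seq_along(from)) pos[from[i]:to[i]] <- TRUE
  sum(pos) / L
}

# enumerate (gene, taxon) support sets sample by sample
oracle_rare_pairs <- function(table, metadata, min_samples, min_datasets) {
  keep <- rep(FALSE, nrow(table))
  pairs <- unique(table[, c("gene", "taxon")])
  for (k in seq_len(nrow(pairs))) {
    sel <- table$gene == pairs$gene[k] & table$taxon == pairs$taxon[k]
    samples <- unique(table$sample_id[sel])
    studies <- unique(metadata$study_id[match(samples,
                                              metadata$sample_id)])
    if (length(samples) >= min_samples && length(studies) >= min_datasets)
      keep[sel] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# enumerate edges over all networks: identical-sign support count
oracle_consensus <- function(networks, min_support) {
  tally <- list()
  for (nw in networks) {
    e <- nw$edges
    for (i in seq_len(nrow(e))) {
      k <- paste(min(e$a[i], e$b[i]), max(e$a[i], e$b[i]), e$sign[i])
      tally[[k]] <- c(tally[[k]], e$weight[i])
    }
  }
  kept <- names(tally)[vapply(tally, length, 1L) >= min_support]
  sort(kept)
}

# cyclic coordinate descent lasso on standardized data:
# min (1/2n)||y - Xb||^2 + lambda ||b||_1
oracle_lasso <- function(X, y, lambda, tol = 1e-10, max_iter = 1e5) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p)
  xx <- colSums(X^2) / n
  r <- y
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- b[j]
      z <- sum(X[, j] * r) / n + xx[j] * bj_old
      b[j] <- soft(z, lambda) / xx[j]
      if (b[j] != bj_old) {
        r <- r - X[, j] * (b[j] - bj_old)
        delta <- max(delta, abs(b[j] - bj_old))
      }
    }
    if (delta < tol) break
  }
  b
}

oracle_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

# random hit table generator used by several rule-exactness tests
random_hits <- function(n, n_reads = 40, genes = paste0("g", 1:6),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    read_id = sprintf("r%03d", sample.int(n_reads, n, replace = TRUE)),
    frame = sample(c(1:3, -(1:3)), n, replace = TRUE),
    hmm_name = sample(genes, n, replace = TRUE),
    hmm_accession = "ACC",
    evalue = 10^sample(seq(-12, -4, by = 1), n, replace = TRUE),
    bitscore = sample(seq(50, 70, by = 5), n, replace = TRUE) / 1,
    hmm_from = 1L, hmm_to = 50L, hmm_length = 100L,
    stringsAsFactors = FALSE)
}

random_gene_taxon_table <- function(n_samples = 12, n_genes = 4,
                                    n_taxa = 6, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(sample_id = sprintf("s%02d", 1:n_samples),
                      gene = paste0("g", 1:n_genes),
                      taxon = paste0("t", 1:n_taxa),
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < 0.3, , drop = FALSE]
  grid$raw_hits <- rpois(nrow(grid), 3) + 1L
  grid$norm_length <- grid$raw_hits / 200
  grid$norm_length_depth <- grid$norm_length / 1e4 * 1e6
  rownames(grid) <- NULL
  class(grid) <- c("gene_taxon_table", "data.frame")
  grid
}

meta_for <- function(table_or_samples, n_studies = 3) {
  s <- if (is.data.frame(table_or_samples))
    sort(unique(table_or_samples$sample_id)) else table_or_samples
  data.frame(sample_id = s,
             study_id = rep(sprintf("study_%d", seq_len(n_studies)),
                            length.out = length(s)),
             total_reads = 1e4, stringsAsFactors = FALSE)
}
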