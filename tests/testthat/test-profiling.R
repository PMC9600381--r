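test_that("six-frame translation follows the standard code and drops partial codons", {
  tr <- six_frame_translate("ATGTAA")
  expect_equal(unname(tr["+1"]), "M*")
  expect_equal(unname(six_frame_translate("ATG")["-1"]), "H")
  expect_equal(unname(six_frame_translate("ATGNAA")["+1"]), "MX")
  expect_error(six_frame_translate("AT"), "shorter")
  expect_error(six_frame_translate("ATGZ"), "alphabet")
  # frame-length law on random sequences
  set.seed(42)
  for (i in 1:20) {
    L <- sample(3:40, 1)
    dna <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    tr <- six_frame_translate(dna)
    for (off in 0:2) {
      expect_equal(nchar(tr[[paste0("+", off + 1)]]), (L - off) %/% 3)
      expect_equal(nchar(tr[[paste0("-", off + 1)]]), (L - off) %/% 3)
    }
  }
})

test_that("best-hit selection applies the E-value cutoff and the tie ladder", {
  two <- rbind(
    data.frame(read_id = "r1", frame = 1L, hmm_name = "geneA",
               hmm_accession = "A", evalue = 1e-8, bitscore = 50,
               hmm_from = 1L, hmm_to = 50L, hmm_length = 100L),
    data.frame(read_id = "r1", frame = 2L, hmm_name = "geneB",
               hmm_accession = "B", evalue = 1e-7, bitscore = 80,
               hmm_from = 1L, hmm_to = 50L, hmm_length = 100L))
  kept <- select_best_hits(two)
  expect_equal(kept$hmm_name, "geneA")  # lowest E wins over higher bitscore
  one <- two[2, ]; one$evalue <- 1e-5
  expect_equal(nrow(select_best_hits(one)), 0L)  # above the 1e-6 cutoff
  # tie on E-value: bitscore decides; full tie: lexicographic model name
  tie <- two; tie$evalue <- c(1e-8, 1e-8)
  expect_equal(select_best_hits(tie)$hmm_name, "geneB")
  tie$bitscore <- c(60, 60)
  expect_equal(select_best_hits(tie)$hmm_name, "geneA")
})

test_that("coverage presence uses the interval union with an inclusive 20% boundary", {
  p <- gene_presence(c(1, 5), c(10, 15), 100)
  expect_equal(p$coverage, 0.15)
  expect_false(p$present)
  p <- gene_presence(c(1, 11), c(10, 20), 100)
  expect_equal(p$coverage, 0.20)
  expect_true(p$present)
  expect_equal(gene_presence(integer(0), integer(0), 100),
               list(present = FALSE, coverage = 0))
  # bitmap oracle on random envelope sets
  set.seed(3)
  for (i in 1:25) {
    L <- sample(50:200, 1)
    n <- sample(1:50, 1)
    from <- sample(L, n, replace = TRUE)
    to <- pmin(L, from + sample(0:30, n, replace = TRUE))
    expect_equal(gene_presence(from, to, L)$coverage,
                 oracle_coverage(from, to, L))
  }
})

test_that("presence is monotone under hit addition", {
  set.seed(8)
  L <- 100
  from <- sample(L, 10, replace = TRUE)
  to <- pmin(L, from + 20)
  cov <- vapply(1:10, function(k)
    gene_presence(from[1:k], to[1:k], L)$coverage, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("gene-taxon table normalizations follow their definitions", {
  hits <- data.frame(
    sample_id = "s1", read_id = sprintf("r%d", 1:4), frame = 1L,
    hmm_name = "cobT", hmm_accession = "A", evalue = 1e-8, bitscore = 50,
    hmm_from = c(1L, 40L, 80L, 120L), hmm_to = c(45L, 85L, 125L, 165L),
    hmm_length = 200L, stringsAsFactors = FALSE)
  assign <- data.frame(read_id = sprintf("r%d", 1:4), taxon_id = 1L,
                       taxon_name = "t1", rank = "species",
                       stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = "s1", study_id = "study_1",
                     total_reads = 1e6, stringsAsFactors = FALSE)
  tab <- build_gene_taxon_table(hits, assign, meta)
  expect_equal(tab$raw_hits, 4L)
  expect_equal(tab$norm_length, 4 / 200)
  expect_equal(tab$norm_length_depth, 4 / 200 / 1e6 * 1e6)
  # a gene below 20% coverage contributes no entries
  low <- hits; low$hmm_from <- 1L; low$hmm_to <- 30L  # union 30/200 = 15%
  expect_equal(nrow(build_gene_taxon_table(low, assign, meta)), 0L)
  # unknown sample errors
  expect_error(build_gene_taxon_table(hits, assign, meta[0, ]),
               "missing from metadata")
  # unclassified reads aggregate under the reserved taxon
  assign$rank[1:2] <- "unclassified"
  tab <- build_gene_taxon_table(hits, assign, meta)
  expect_setequal(tab$taxon, c("t1", "unclassified"))
  expect_equal(sum(tab$raw_hits), 4L)
})

test_that("gene-taxon counting matches an independent group-by on synthetic data", {
  comm <- make_community(12, 4, 2, 0.5, seed = 2)
  sim <- simulate_hit_table(comm, n_samples = 6, n_studies = 2,
                            hits_per_sample = 400, trace_per_sample = 0,
                            unclassified_rate = 0, seed = 3)
  tab <- build_gene_taxon_table(sim$hits, sim$assignments, sim$metadata)
  # every envelope spans 100 of <= 450 positions, so every gene passes the
  # gate and the table must equal a plain count aggregation
  taxon <- sim$assignments$taxon_name[match(sim$hits$read_id,
                                            sim$assignments$read_id)]
  key <- paste(sim$hits$sample_id, sim$hits$hmm_name, taxon)
  counts <- table(key)
  expect_equal(nrow(tab), length(counts))
  expect_equal(tab$raw_hits[match(names(counts),
                                  paste(tab$sample_id, tab$gene,
                                        tab$taxon))],
               as.integer(counts))
})

test_that("rare-pair filtering enforces >= min_samples across >= min_datasets and is idempotent", {
  mk <- function(samples, gene = "g1", taxon = "t1") {
    data.frame(sample_id = samples, gene = gene, taxon = taxon,
               raw_hits = 1L, norm_length = 0.01,
               norm_length_depth = 1, stringsAsFactors = FALSE)
  }
  meta <- data.frame(sample_id = sprintf("s%02d", 1:12),
                     study_id = rep(c("A", "B"), each = 6),
                     total_reads = 1e4, stringsAsFactors = FALSE)
  # 6 samples all in one study: removed
  expect_equal(nrow(filter_rare_pairs(mk(sprintf("s%02d", 1:6)), meta)), 0L)
  # 5 samples across 2 studies: kept (boundary)
  kept <- filter_rare_pairs(mk(sprintf("s%02d", 4:8)), meta)
  expect_equal(nrow(kept), 5L)
  # random tables match the enumeration oracle; filter is idempotent
  for (seed in 1:5) {
    tab <- random_gene_taxon_table(seed = seed)
    meta2 <- meta_for(tab)
    p <- profiling_params(min_samples = 3, min_datasets = 2)
    got <- filter_rare_pairs(tab, meta2, p)
    want <- oracle_rare_pairs(tab, meta2, 3, 2)
    expect_equal(got[order(got$sample_id, got$gene, got$taxon), ],
                 want[order(want$sample_id, want$gene, want$taxon), ],
                 ignore_attr = TRUE)
    expect_equal(filter_rare_pairs(got, meta2, p), got)
  }
})

test_that("contaminant removal is an exact set difference", {
  tab <- random_gene_taxon_table(seed = 11)
  expect_equal(nrow(remove_contaminants(tab, character(0))), nrow(tab))
  expect_equal(nrow(suppressMessages(
    remove_contaminants(tab, unique(tab$taxon)))), 0L)
  drop <- c("t1", "t4")
  out <- suppressMessages(remove_contaminants(tab, drop))
  expect_equal(as.data.frame(out),
               as.data.frame(tab[!tab$taxon %in% drop, ]),
               ignore_attr = TRUE)
  expect_equal(attr(out, "removed"), sum(tab$taxon %in% drop))
})

test_that("taxon contributions and gene profiles are probability vectors", {
  tab <- data.frame(sample_id = "s1", gene = c("g1", "g1"),
                    taxon = c("A", "B"), raw_hits = c(3L, 1L),
                    norm_length = c(3, 1), norm_length_depth = c(30, 10),
                    stringsAsFactors = FALSE)
  expect_equal(taxon_contribution(tab, "s1"), c(A = 0.75, B = 0.25))
  expect_equal(gene_frequency_profile(tab, "g1"), c(A = 0.75, B = 0.25))
  expect_error(taxon_contribution(tab, "s1", gene_subset = "gX"), "no hits")
  expect_error(gene_frequency_profile(tab, "gX"), "absent")
  for (seed in 1:5) {
    rt <- random_gene_taxon_table(seed = seed)
    s <- rt$sample_id[1]
    tc <- taxon_contribution(rt, s)
    expect_true(all(tc >= 0))
    expect_lt(abs(sum(tc) - 1), 1e-12)
    g <- rt$gene[1]
    gp <- gene_frequency_profile(rt, g)
    expect_lt(abs(sum(gp) - 1), 1e-12)
    # manual ratio oracle
    sub <- rt[rt$gene == g, ]
    want <- tapply(sub$norm_length_depth, sub$taxon, sum)
    want <- want / sum(want)
    expect_equal(gp[names(want)], setNames(as.numeric(want), names(want)))
  }
})

test_that("producer calls need >= 5 distinct markers; boundary at exactly 5", {
  markers <- profiling_params()$producer_marker_genes
  mk <- function(taxon, genes) {
    data.frame(sample_id = "s1", gene = genes, taxon = taxon, raw_hits = 1L,
               norm_length = 0.01, norm_length_depth = 1,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mk("five", markers[1:5]), mk("four", markers[1:4]))
  expect_equal(call_metagenomic_producers(tab), "five")
})

test_that("mock false-positive accounting excludes unclassified reads", {
  tab <- data.frame(sample_id = "m", gene = "g",
                    taxon = c("in1", "out1", "unclassified"),
                    raw_hits = c(998L, 2L, 50L), norm_length = 1,
                    norm_length_depth = 1, stringsAsFactors = FALSE)
  expect_equal(mock_false_positive_rate(tab, "in1"), 2 / 1000)
  expect_equal(mock_false_positive_rate(tab, c("in1", "out1")), 0)
  expect_error(mock_false_positive_rate(tab[0, ], "in1"), "no classified")
})

test_that("normalizations are linear: doubling raw counts doubles both norms", {
  comm <- make_community(10, 3, 2, 0.5, seed = 6)
  sim <- simulate_hit_table(comm, n_samples = 4, n_studies = 2,
                            hits_per_sample = 300, seed = 6)
  tab <- build_gene_taxon_table(select_best_hits(sim$hits),
                                sim$assignments, sim$metadata)
  doubled <- tab
  doubled$raw_hits <- 2L * tab$raw_hits
  doubled$norm_length <- doubled$raw_hits / (tab$raw_hits / tab$norm_length)
  expect_equal(doubled$norm_length, 2 * tab$norm_length)
  # contributions are invariant under the doubling
  s <- tab$sample_id[1]
  doubled$norm_length_depth <- 2 * tab$norm_length_depth
  expect_equal(taxon_contribution(tab, s), taxon_contribution(doubled, s))
})
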