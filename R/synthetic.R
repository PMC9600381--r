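## Synthetic-data generator: communities with planted cobamide categories,
## hit tables with planted false positives, and multi-study count matrices
## drawn from a known sparse association graph. Every output is
## reproducible bit-for-bit from (parameters, seed), and ground truth is
## returned alongside the data.

#' Default HMM length registry for synthetic hit tables
#'
#' Deterministic model lengths for the marker, salvage and dependence
#' panels. Lengths are spread over 180-450 positions, the typical span of
#' the cobamide-gene profile HMMs; the generator's read envelopes cover 100
#' positions, so a single read always covers more than 20\% of any model.
#'
#' @param model Pathway model supplying the gene vocabulary.
#' @return Named integer vector gene -> model length.
#' @export
default_hmm_lengths <- function(model = default_pathway_model()) {
  genes <- unique(c(model$all_markers,
                    unlist(model$salvage_genes, use.names = FALSE),
                    model$dependent_enzymes, "rpoB"))
  setNames(180L + (seq_along(genes) - 1L) * 270L %/%
             max(1L, length(genes) - 1L), genes)
}

#' Plant a synthetic community roster
#'
#' Species receive a cobamide biosynthesis category (producers carry the
#' full pathway gene complement, salvagers only the salvage set,
#' nonproducers neither), a dependence flag (dependent species carry at
#' least one of the seven dependent enzyme families), and a phylum assigned
#' round-robin over the four major skin phyla.
#'
#' @param n_species Total species.
#' @param n_producers,n_salvagers Planted category counts (the rest are
#'   nonproducers).
#' @param frac_dependent Fraction of species that are cobamide dependent.
#' @param seed RNG seed.
#' @param model Pathway model.
#' @return list of class \code{synthetic_community}: \code{roster}
#'   (data.frame species/phylum/category/dependent), \code{gene_sets}
#'   (named list), \code{model}, \code{params}.
#' @export
make_community <- function(n_species, n_producers, n_salvagers,
                           frac_dependent, seed = 1L,
                           model = default_pathway_model()) {
  if (n_producers + n_salvagers > n_species)
    stopf("n_producers + n_salvagers exceeds n_species")
  with_seed(seed, {
    species <- sprintf("sp_%03d", seq_len(n_species))
    phyla <- rep(c("Actinobacteria", "Firmicutes", "Proteobacteria",
                   "Bacteroidetes"), length.out = n_species)
    category <- rep("nonproducer", n_species)
    picked <- sample.int(n_species, n_producers + n_salvagers)
    category[picked[seq_len(n_producers)]] <- "producer"
    if (n_salvagers > 0)
      category[picked[n_producers + seq_len(n_salvagers)]] <- "salvager"
    n_dep <- round(frac_dependent * n_species)
    dependent <- rep(FALSE, n_species)
    if (n_dep > 0) dependent[sample.int(n_species, n_dep)] <- TRUE
    producer_genes <- unique(c(
      model$subsections$tetrapyrrole_precursor,
      model$subsections$corrin_ring_aerobic,
      c("cobO", "cobQ", "cobD", "cobP", "cobU", "cobS", "cobC"),
      "cobT"))
    salvage_canon <- c("cobQ", "cobD", "cobP", "cobS")
    gene_sets <- lapply(seq_len(n_species), function(i) {
      g <- switch(category[i],
                  producer = c(producer_genes,
                               if (runif(1) < 0.7) "bluB"),
                  salvager = salvage_canon,
                  character(0))
      if (dependent[i])
        g <- c(g, sample(model$dependent_enzymes,
                         1L + rbinom(1L, 2L, 0.5)))
      sort(unique(g))
    })
    names(gene_sets) <- species
    structure(list(
      roster = data.frame(species = species, phylum = phyla,
                          category = category, dependent = dependent,
                          stringsAsFactors = FALSE),
      gene_sets = gene_sets, model = model,
      params = list(n_species = n_species, n_producers = n_producers,
                    n_salvagers = n_salvagers,
                    frac_dependent = frac_dependent, seed = seed)),
      class = "synthetic_community")
  })
}

#' Simulate multi-study metagenomic hit tables
#'
#' Emulates the output of a profile-HMM search plus read classification on
#' a community with known ground truth. Per sample, species relative
#' abundances are log-normal; hit counts per (species, gene) cell are
#' multinomial with probability proportional to abundance times model
#' length; envelopes span 100 HMM positions at uniform positions, so every
#' truly expressed gene passes the 20\% coverage gate, while planted
#' "trace" genes get envelopes confined to the first 15\% of the model and
#' are guaranteed to fail it. A Bernoulli(\code{fp_rate}) fraction of reads
#' is reassigned to out-of-roster taxa, emulating classifier false
#' positives.
#'
#' @param truth A [make_community()] result.
#' @param n_samples Total samples, split evenly across studies.
#' @param n_studies Number of studies.
#' @param hits_per_sample Expected cobamide-gene hits per sample
#'   (default 2000).
#' @param reads_per_sample Post-QC sequencing depth recorded in the
#'   metadata (default 2e4).
#' @param fp_rate Planted false-positive classification rate in [0, 0.5).
#' @param sigma Log-normal abundance sd (default 1).
#' @param trace_per_sample Planted below-coverage trace genes per sample
#'   (default 1).
#' @param unclassified_rate Fraction of reads left unclassified
#'   (default 0.02).
#' @param seed RNG seed.
#' @param hmm_lengths Named model lengths (default
#'   [default_hmm_lengths()]).
#' @return list of class \code{synthetic_hit_table}: \code{hits} (with
#'   \code{sample_id}), \code{assignments}, \code{metadata},
#'   \code{truth} (planted abundances, fp counts, roster, parameters).
#' @export
simulate_hit_table <- function(truth, n_samples, n_studies,
                               hits_per_sample = 2000L,
                               reads_per_sample = 2e4, fp_rate = 0,
                               sigma = 1, trace_per_sample = 1L,
                               unclassified_rate = 0.02, seed = 1L,
                               hmm_lengths = default_hmm_lengths(truth$model)) {
  if (fp_rate < 0 || fp_rate >= 0.5) stopf("fp_rate must be in [0, 0.5)")
  roster <- truth$roster
  env_len <- 100L
  if (any(hmm_lengths > env_len / 0.22) || any(hmm_lengths < env_len))
    stopf("model lengths must lie in [%d, %d] so one read envelope covers more than 20%% of the model",
          env_len, as.integer(floor(env_len / 0.22)))
  # cells: species x gene combinations that truly generate reads
  cells <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    genes <- intersect(truth$gene_sets[[roster$species[i]]],
                       names(hmm_lengths))
    if (!length(genes)) return(NULL)
    data.frame(species = roster$species[i], gene = genes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cells)) stopf("no species carries a registered gene")
  fp_pool <- sprintf("fp_taxon_%02d", 1:5)
  with_seed(seed, {
    study <- rep(sprintf("study_%d", seq_len(n_studies)),
                 length.out = n_samples)
    micro <- rep(c("sebaceous", "moist", "dry", "foot"),
                 length.out = n_samples)
    metadata <- data.frame(
      sample_id = sprintf("s%03d", seq_len(n_samples)),
      study_id = sort(study),
      subject_id = sprintf("subj%03d", seq_len(n_samples)),
      site = micro, microenvironment = micro,
      total_reads = as.integer(round(reads_per_sample *
                                       runif(n_samples, 0.9, 1.1))),
      stringsAsFactors = FALSE)
    abund <- matrix(rlnorm(n_samples * nrow(roster), 0, sigma),
                    nrow = n_samples)
    abund <- abund / rowSums(abund)
    dimnames(abund) <- list(metadata$sample_id, roster$species)
    all_hits <- vector("list", n_samples)
    all_assign <- vector("list", n_samples)
    fp_planted <- integer(n_samples)
    trace_planted <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      w <- abund[s, cells$species] * hmm_lengths[cells$gene]
      counts <- as.integer(rmultinom(1L, hits_per_sample, w))
      idx <- rep(seq_len(nrow(cells)), counts)
      n_reads <- length(idx)
      L <- unname(hmm_lengths[cells$gene[idx]])
      from <- 1L + floor(runif(n_reads) * (L - env_len + 1L))
      to <- from + env_len - 1L
      gene <- cells$gene[idx]
      taxon <- cells$species[idx]
      # planted trace genes: envelopes confined to the first 15% of the
      # model, guaranteed below the 20% coverage gate
      trace_genes <- character(0)
      if (trace_per_sample > 0L) {
        pool <- setdiff(names(hmm_lengths), unique(gene))
        for (k in seq_len(min(trace_per_sample, length(pool)))) {
          tg <- pool[k]
          trace_genes <- c(trace_genes, tg)
          tL <- unname(hmm_lengths[tg])
          lim <- floor(0.15 * tL)
          t_n <- 3L
          t_from <- 1L + floor(runif(t_n) * max(1L, lim - 30L))
          t_to <- pmin(t_from + 29L, lim)
          gene <- c(gene, rep(tg, t_n))
          taxon <- c(taxon, rep(sample(roster$species, 1L), t_n))
          from <- c(from, t_from); to <- c(to, t_to)
          L <- c(L, rep(tL, t_n))
        }
        n_reads <- length(gene)
      }
      trace_planted[[s]] <- trace_genes
      read_id <- sprintf("%s_r%05d", metadata$sample_id[s],
                         seq_len(n_reads))
      flip <- runif(n_reads) < fp_rate
      fp_planted[s] <- sum(flip)
      taxon[flip] <- sample(fp_pool, sum(flip), replace = TRUE)
      uncl <- runif(n_reads) < unclassified_rate
      all_hits[[s]] <- data.frame(
        sample_id = metadata$sample_id[s], read_id = read_id,
        frame = sample(c(1:3, -(1:3)), n_reads, replace = TRUE),
        hmm_name = gene, hmm_accession = paste0("SYN", gene),
        evalue = signif(10^runif(n_reads, -20, -7), 3),
        bitscore = round(runif(n_reads, 30, 300), 1),
        hmm_from = as.integer(from), hmm_to = as.integer(to),
        hmm_length = as.integer(L), stringsAsFactors = FALSE)
      all_assign[[s]] <- data.frame(
        read_id = read_id,
        taxon_id = ifelse(uncl, 0L,
                          1000L + match(taxon, c(roster$species, fp_pool))),
        taxon_name = ifelse(uncl, "unclassified", taxon),
        rank = ifelse(uncl, "unclassified", "species"),
        stringsAsFactors = FALSE)
    }
    structure(list(
      hits = do.call(rbind, all_hits),
      assignments = do.call(rbind, all_assign),
      metadata = metadata,
      truth = list(roster = roster, abundances = abund,
                   fp_rate = fp_rate, fp_planted = fp_planted,
                   fp_taxa = fp_pool, trace_planted = trace_planted,
                   hmm_lengths = hmm_lengths, seed = seed)),
      class = "synthetic_hit_table")
  })
}

#' Band graph over p nodes
#'
#' Edges join nodes at index distance 1..\code{width} with alternating
#' signs; at the default width 1 every interior node is linked to its two
#' chain neighbours.
#'
#' @param p Number of nodes.
#' @param width Band width (default 1).
#' @return data.frame(a, b, sign) of integer node indices.
#' @export
band_graph <- function(p, width = 1L) {
  edges <- do.call(rbind, lapply(seq_len(width), function(w) {
    a <- seq_len(p - w)
    data.frame(a = a, b = a + w)
  }))
  edges$sign <- ifelse(seq_len(nrow(edges)) %% 2L == 1L, 1L, -1L)
  edges
}

#' Simulate count matrices from a known association graph
#'
#' Normal-to-anything copula construction: the signed graph defines a
#' sparse precision matrix (unit diagonal, off-diagonal
#' \code{-sign * edge_magnitude}, ridge-inflated until the smallest
#' eigenvalue reaches 0.01); latent Gaussian samples from the implied
#' correlation matrix are pushed through the Gaussian CDF and the
#' marginal's inverse CDF. Studies share the graph and marginals but use
#' independent draws, so rank correlations mirror the planted partial
#' correlation structure.
#'
#' @param graph data.frame(a, b, sign) of 1-based node indices (e.g.
#'   [band_graph()]).
#' @param p Number of species (default: largest node index in
#'   \code{graph}).
#' @param n_samples Samples per study.
#' @param n_studies Number of studies (default 1).
#' @param marginal \code{"negative_binomial"} (default) or
#'   \code{"poisson"}.
#' @param edge_magnitude Absolute off-diagonal precision entry
#'   (default 0.35).
#' @param mu_range Range of per-species marginal means, spread
#'   log-uniformly (default c(20, 200)).
#' @param nb_size Negative-binomial dispersion parameter (default 5).
#' @param seed RNG seed.
#' @return list of class \code{synthetic_counts}: \code{matrices} (list of
#'   sample x species integer matrices), \code{truth} (graph, precision,
#'   correlation, marginal parameters, seed).
#' @export
simulate_count_matrices <- function(graph, p = max(graph$a, graph$b),
                                    n_samples, n_studies = 1L,
                                    marginal = c("negative_binomial",
                                                 "poisson"),
                                    edge_magnitude = 0.35,
                                    mu_range = c(20, 200), nb_size = 5,
                                    seed = 1L) {
  marginal <- match.arg(marginal)
  omega <- diag(p)
  if (nrow(graph)) {
    for (k in seq_len(nrow(graph))) {
      v <- -graph$sign[k] * edge_magnitude
      omega[graph$a[k], graph$b[k]] <- v
      omega[graph$b[k], graph$a[k]] <- v
    }
  }
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.01) omega <- omega + (0.01 - ev) * diag(p)
  ev2 <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev2 < 0.01 - 1e-8)
    stopf("precision matrix not positive definite after ridge loading")
  R <- stats::cov2cor(solve(omega))
  ch <- chol(R)
  species <- sprintf("sp_%03d", seq_len(p))
  with_seed(seed, {
    mu <- exp(runif(p, log(mu_range[1L]), log(mu_range[2L])))
    matrices <- lapply(seq_len(n_studies), function(st) {
      z <- matrix(rnorm(n_samples * p), n_samples, p) %*% ch
      u <- pnorm(z)
      counts <- if (marginal == "negative_binomial")
        qnbinom(u, mu = rep(mu, each = n_samples), size = nb_size)
      else qpois(u, lambda = rep(mu, each = n_samples))
      counts <- matrix(as.integer(counts), n_samples, p,
                       dimnames = list(sprintf("st%d_s%03d", st,
                                               seq_len(n_samples)),
                                       species))
      counts
    })
    names(matrices) <- sprintf("study_%d", seq_len(n_studies))
    structure(list(
      matrices = matrices,
      truth = list(graph = graph, species = species, precision = omega,
                   correlation = R, marginal = marginal, mu = mu,
                   nb_size = nb_size, edge_magnitude = edge_magnitude,
                   seed = seed)),
      class = "synthetic_counts")
  })
}

#' Edge precision/recall against a planted graph
#'
#' @param net An [association_network()] whose node names follow the
#'   synthetic \code{sp_NNN} convention (or any names matching
#'   \code{species}).
#' @param graph Planted data.frame(a, b) of node indices.
#' @param species Character vector mapping indices to names.
#' @return list(precision, recall, tp, n_estimated, n_true).
#' @export
edge_recovery <- function(net, graph, species) {
  true_keys <- paste(pmin(graph$a, graph$b), pmax(graph$a, graph$b))
  ea <- match(net$edges$a, species)
  eb <- match(net$edges$b, species)
  est_keys <- paste(pmin(ea, eb), pmax(ea, eb))
  tp <- length(intersect(est_keys, true_keys))
  list(precision = if (length(est_keys)) tp / length(est_keys) else NA_real_,
       recall = tp / length(true_keys), tp = tp,
       n_estimated = length(est_keys), n_true = length(true_keys))
}
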