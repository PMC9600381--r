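## Compositional sparse association networks: CLR transform, per-node lasso
## neighborhood selection over a shared lambda path, StARS stability
## selection, multi-study sign-consistent consensus, topology metrics and
## cobamide edge accounting.

#' Network inference parameters
#'
#' @param pseudocount Added to every count before closure (default 1).
#' @param n_lambda Number of penalties on the log-spaced path (default 20).
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param stars_subsamples Number of StARS subsamples (default 50).
#' @param stars_instability_threshold Target edge instability (default 0.05).
#' @param symmetrization \code{"or"} (edge if either directed regression
#'   selects it; default) or \code{"and"}.
#' @param seed Seed for subsampling.
#' @param min_mean_abundance Species filter: minimum mean relative abundance
#'   over pooled samples (default 0.00015, i.e. 0.015\%; strict inequality).
#' @param min_prevalence Species filter: minimum fraction of pooled samples
#'   in which the species is detected (default 0.55).
#' @param consensus_min_support Minimum number of per-study networks an edge
#'   must appear in, with identical sign, to enter the consensus (default 2).
#' @return A list of class \code{network_params}.
#' @export
network_params <- function(pseudocount = 1, n_lambda = 20L,
                           lambda_min_ratio = 0.01, stars_subsamples = 50L,
                           stars_instability_threshold = 0.05,
                           symmetrization = c("or", "and"), seed = NULL,
                           min_mean_abundance = 0.00015,
                           min_prevalence = 0.55,
                           consensus_min_support = 2L) {
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stopf("lambda_min_ratio must be in (0, 1)")
  structure(list(pseudocount = pseudocount, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 stars_subsamples = as.integer(stars_subsamples),
                 stars_instability_threshold = stars_instability_threshold,
                 symmetrization = match.arg(symmetrization), seed = seed,
                 min_mean_abundance = min_mean_abundance,
                 min_prevalence = min_prevalence,
                 consensus_min_support = as.integer(consensus_min_support)),
            class = "network_params")
}

## StARS subsample size rule: min(floor(10 sqrt(n)), floor(0.8 n)).
stars_subsample_size <- function(n) min(floor(10 * sqrt(n)), floor(0.8 * n))

#' Species roster filter
#'
#' Pools the samples of all studies and keeps species whose mean relative
#' abundance exceeds \code{min_mean_abundance} and whose prevalence
#' (fraction of samples with a nonzero count) is at least
#' \code{min_prevalence}. One shared roster is produced for all studies.
#'
#' @param matrices List of sample x species count matrices sharing a species
#'   vocabulary (column names).
#' @param params [network_params()].
#' @return Character vector of retained species.
#' @export
filter_species <- function(matrices, params = network_params()) {
  if (!length(matrices)) stopf("no count matrices supplied")
  species <- colnames(matrices[[1L]])
  if (any(!vapply(matrices, function(m) identical(colnames(m), species),
                  logical(1))))
    stopf("count matrices must share a species vocabulary")
  pooled <- do.call(rbind, matrices)
  if (nrow(pooled) == 0L) stopf("empty sample pool")
  rel <- pooled / rowSums(pooled)
  keep <- colMeans(rel) > params$min_mean_abundance &
    colMeans(pooled > 0) >= params$min_prevalence
  species[keep]
}

#' Centered log-ratio transform
#'
#' Per sample: add the pseudocount, close to proportions, take logs and
#' subtract the sample's mean log. Each output row sums to zero.
#'
#' @param counts Sample x species matrix of non-negative counts.
#' @param pseudocount Added before closure (default 1).
#' @return Real matrix of the same shape.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  x <- counts + pseudocount
  if (any(rowSums(x) <= 0))
    stopf("sample with zero total; use a positive pseudocount")
  lp <- log(x / rowSums(x))
  lp - rowMeans(lp)
}

#' Lasso neighborhood selection along a penalty path
#'
#' Regresses each node's CLR abundance on all other nodes with an
#' L1-penalized linear model at every penalty of a log-spaced path. The
#' path runs from \code{lambda_max} (the largest absolute off-diagonal
#' correlation of the CLR columns, above which every neighborhood is empty)
#' down to \code{lambda_max * lambda_min_ratio}. Directed selections are
#' symmetrized by the OR (default) or AND rule; an edge's weight is the
#' mean of the two directed coefficients and its sign the sign of that
#' mean (exact zeros after symmetrization are dropped).
#'
#' @param clr CLR-transformed sample x species matrix.
#' @param params [network_params()].
#' @param lambda Optional fixed penalty path (used by StARS so subsamples
#'   share the full-data path).
#' @return List of class \code{nbhd_path}: \code{lambda}, \code{species},
#'   per-lambda lists \code{adjacency} (logical p x p) and \code{weight}
#'   (numeric p x p, symmetrized means), and \code{directed}, the raw
#'   p x p x n_lambda array of directed regression coefficients
#'   (\code{directed[j, k, l]} is the coefficient of node k in node j's
#'   regression at the l-th penalty).
#' @export
neighborhood_path <- function(clr, params = network_params(), lambda = NULL) {
  n <- nrow(clr); p <- ncol(clr)
  if (n < 10L) stopf("need at least 10 samples")
  if (p < 3L) stopf("need at least 3 species")
  species <- colnames(clr) %||% paste0("V", seq_len(p))
  z <- scale(clr)
  if (any(!is.finite(z))) stopf("constant CLR column; filter species first")
  if (is.null(lambda)) {
    r <- cor(z)
    lmax <- max(abs(r[upper.tri(r)]))
    lambda <- exp(seq(log(lmax), log(lmax * params$lambda_min_ratio),
                      length.out = params$n_lambda))
  }
  nl <- length(lambda)
  beta <- array(0, dim = c(p, p, nl))  # beta[j, k, l]: coef of k in model j
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(z[, -j, drop = FALSE], z[, j], family = "gaussian",
                          lambda = lambda, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    b <- as.matrix(fit$beta)  # (p-1) x nl', may be shorter if path truncated
    cols <- match(signif(fit$lambda, 10), signif(lambda, 10))
    beta[j, -j, cols[!is.na(cols)]] <- b[, !is.na(cols), drop = FALSE]
  }
  adjacency <- vector("list", nl)
  weight <- vector("list", nl)
  for (l in seq_len(nl)) {
    B <- beta[, , l]
    sel <- B != 0
    A <- if (params$symmetrization == "or") (sel | t(sel)) else (sel & t(sel))
    W <- (B + t(B)) / 2
    W[!A] <- 0
    A[W == 0] <- FALSE  # exact zeros after symmetrization carry no edge
    diag(A) <- FALSE; diag(W) <- 0
    dimnames(A) <- dimnames(W) <- list(species, species)
    adjacency[[l]] <- A
    weight[[l]] <- W
  }
  structure(list(lambda = lambda, species = species, adjacency = adjacency,
                 weight = weight, directed = beta),
            class = "nbhd_path")
}

#' StARS penalty selection
#'
#' Stability approach to regularization selection: draws
#' \code{stars_subsamples} subsamples without replacement of size
#' \code{min(floor(10 sqrt(n)), floor(0.8 n))}, reruns neighborhood
#' selection on each over the full-data penalty path, and computes the
#' per-penalty edge instability (mean over node pairs of
#' \eqn{2\xi(1-\xi)}, where \eqn{\xi} is the edge's selection frequency).
#' The chosen penalty is the smallest (densest graph) whose monotonized
#' instability stays at or below the threshold; the final network is refit
#' on the full data at that penalty.
#'
#' @param clr CLR-transformed matrix.
#' @param params [network_params()]; \code{params$seed} drives subsampling.
#' @param node_meta Optional node metadata data.frame (column
#'   \code{species} plus any of \code{phylum}, \code{category},
#'   \code{dependent}, \code{mean_abundance}) attached to the network.
#' @return list(lambda_opt, lambda_index, instability, stability,
#'   network) where \code{stability} is the p x p edge selection-frequency
#'   matrix at the chosen penalty and \code{network} an
#'   [association_network()].
#' @export
stars_select <- function(clr, params = network_params(), node_meta = NULL) {
  n <- nrow(clr)
  full <- neighborhood_path(clr, params)
  lambda <- full$lambda
  nl <- length(lambda)
  p <- length(full$species)
  b <- stars_subsample_size(n)
  freq <- array(0, dim = c(p, p, nl))
  with_seed(params$seed, {
    for (s in seq_len(params$stars_subsamples)) {
      idx <- sample.int(n, b)
      sub <- neighborhood_path(clr[idx, , drop = FALSE], params,
                               lambda = lambda)
      for (l in seq_len(nl))
        freq[, , l] <- freq[, , l] + sub$adjacency[[l]]
    }
  })
  freq <- freq / params$stars_subsamples
  ut <- upper.tri(matrix(0, p, p))
  instability <- vapply(seq_len(nl), function(l) {
    xi <- freq[, , l][ut]
    mean(2 * xi * (1 - xi))
  }, numeric(1))
  mono <- cummax(instability)  # lambda is decreasing: density grows with index
  ok <- which(mono <= params$stars_instability_threshold)
  if (length(ok) == 0L) {
    warnf("no penalty met the instability threshold; returning the sparsest")
    opt <- 1L
  } else opt <- max(ok)
  net <- .network_at(full, opt, node_meta)
  list(lambda_opt = lambda[opt], lambda_index = opt,
       instability = instability,
       stability = structure(freq[, , opt],
                             dimnames = list(full$species, full$species)),
       network = net)
}

.network_at <- function(path, l, node_meta = NULL) {
  A <- path$adjacency[[l]]
  W <- path$weight[[l]]
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  edges <- data.frame(
    a = path$species[idx[, 1L]], b = path$species[idx[, 2L]],
    sign = ifelse(W[idx] > 0, 1L, -1L), weight = W[idx],
    stringsAsFactors = FALSE)
  nodes <- data.frame(species = path$species, stringsAsFactors = FALSE)
  if (!is.null(node_meta)) {
    assert_cols(node_meta, "species", "node_meta")
    nodes <- merge(nodes, node_meta, by = "species", all.x = TRUE,
                   sort = TRUE)
  }
  association_network(nodes, edges)
}

#' Signed association network
#'
#' Container for a species association graph: a node table and an edge
#' table of unordered species pairs with sign and weight. Validates that
#' there are no self-edges, at most one edge per pair, and that every edge
#' endpoint is a node.
#'
#' @param nodes data.frame with at least a \code{species} column; optional
#'   \code{phylum}, \code{category}, \code{dependent},
#'   \code{mean_abundance}.
#' @param edges data.frame with columns \code{a}, \code{b}, \code{sign}
#'   (+1/-1) and \code{weight}.
#' @return list of class \code{assoc_network}.
#' @export
association_network <- function(nodes, edges) {
  assert_cols(nodes, "species", "nodes")
  assert_cols(edges, c("a", "b", "sign", "weight"), "edges")
  if (nrow(edges)) {
    if (any(edges$a == edges$b)) stopf("self-edges are not allowed")
    if (!all(edges$sign %in% c(-1L, 1L)))
      stopf("edge sign must be +1 or -1")
    swap <- edges$a > edges$b
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
    key <- paste(edges$a, edges$b, sep = "\r")
    if (anyDuplicated(key)) stopf("duplicate edge(s) for a species pair")
    bad <- setdiff(c(edges$a, edges$b), nodes$species)
    if (length(bad))
      stopf("edge endpoint(s) not in node table: %s",
            paste(bad, collapse = ", "))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign > 0),
              sum(x$edges$sign < 0)))
  invisible(x)
}

#' Sign-consistent consensus of per-study networks
#'
#' An edge enters the consensus when it appears with identical sign in at
#' least \code{consensus_min_support} of the input networks; its weight is
#' the mean of the contributing weights and its support count is recorded.
#' Nodes not touched by any kept edge are dropped.
#'
#' @param networks List of [association_network()]s over a shared species
#'   vocabulary.
#' @param params [network_params()].
#' @return An [association_network()] whose edge table carries a
#'   \code{support} column.
#' @export
consensus_merge <- function(networks, params = network_params()) {
  if (length(networks) < 2L) stopf("need at least 2 networks")
  all_edges <- do.call(rbind, lapply(networks, function(nw) {
    e <- nw$edges
    e[, c("a", "b", "sign", "weight")]
  }))
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    nodes <- data.frame(species = character(), stringsAsFactors = FALSE)
    return(association_network(nodes, data.frame(
      a = character(), b = character(), sign = integer(),
      weight = numeric(), support = integer(), stringsAsFactors = FALSE)))
  }
  key <- paste(all_edges$a, all_edges$b, all_edges$sign, sep = "\r")
  support <- tapply(rep(1L, nrow(all_edges)), key, sum)
  wmean <- tapply(all_edges$weight, key, mean)
  keep <- names(support)[support >= params$consensus_min_support]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  edges <- data.frame(
    a = vapply(parts, `[`, "", 1L), b = vapply(parts, `[`, "", 2L),
    sign = as.integer(vapply(parts, `[`, "", 3L)),
    weight = unname(wmean[keep]), support = unname(as.integer(support[keep])),
    stringsAsFactors = FALSE)
  # the same pair could reach support with both signs only when
  # consensus_min_support * 2 <= length(networks); keep the better-supported
  # sign, ties by larger mean |weight|
  pair <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(pair)) {
    ord <- order(pair, -edges$support, -abs(edges$weight))
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(pair[ord]), , drop = FALSE]
  }
  node_tabs <- do.call(rbind, lapply(networks, `[[`, "nodes"))
  node_tabs <- node_tabs[!duplicated(node_tabs$species), , drop = FALSE]
  touched <- unique(c(edges$a, edges$b))
  nodes <- node_tabs[node_tabs$species %in% touched, , drop = FALSE]
  nodes <- nodes[order(nodes$species), , drop = FALSE]
  rownames(nodes) <- NULL
  association_network(nodes, edges)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = net$nodes$species)
  if (nrow(net$edges)) {
    igraph::E(g)$sign <- net$edges$sign
    igraph::E(g)$weight <- abs(net$edges$weight)
  }
  g
}

#' Topology metrics of an association network
#'
#' Degree distribution, density, global transitivity, modularity of a
#' greedy agglomerative community partition of the unsigned graph, and
#' Newman nominal assortativity over phylum labels (when the node table
#' carries a \code{phylum} column).
#'
#' @param net An [association_network()].
#' @return list of class \code{network_metrics}.
#' @export
network_metrics <- function(net) {
  if (nrow(net$nodes) < 2L) stopf("need at least 2 nodes")
  g <- as_igraph(net)
  gu <- igraph::delete_edge_attr(g, "weight")
  comm <- igraph::cluster_fast_greedy(gu)
  assort <- NA_real_
  if ("phylum" %in% names(net$nodes) && !anyNA(net$nodes$phylum) &&
      nrow(net$edges) > 0L) {
    lab <- factor(net$nodes$phylum)
    assort <- igraph::assortativity_nominal(
      g, types = as.integer(lab)[match(igraph::V(g)$name,
                                       net$nodes$species)])
  }
  structure(list(
    degree = igraph::degree(g),
    density = igraph::edge_density(g),
    transitivity = igraph::transitivity(g, type = "global"),
    modularity = igraph::modularity(comm),
    membership = setNames(igraph::membership(comm), igraph::V(g)$name),
    phylum_assortativity = assort
  ), class = "network_metrics")
}

#' Cobamide edge categories
#'
#' Classifies every edge by the cobamide biosynthesis categories of its
#' endpoints (producer P, salvager S, nonproducer NP) and reports counts
#' and percentages per unordered category pair, plus the percentage of
#' edges joining a producer to a cobamide-dependent nonproducer or
#' salvager (the putative sharing edges).
#'
#' @param net An [association_network()].
#' @param annotations data.frame with columns \code{species} (or
#'   \code{genome_id}), \code{category}, \code{dependent}.
#' @return list(counts, percentages, sharing_pct, n_edges).
#' @export
categorize_edges <- function(net, annotations) {
  if ("genome_id" %in% names(annotations) &&
      !"species" %in% names(annotations))
    names(annotations)[names(annotations) == "genome_id"] <- "species"
  assert_cols(annotations, c("species", "category", "dependent"),
              "annotations")
  miss <- setdiff(net$nodes$species, annotations$species)
  if (length(miss))
    stopf("unannotated node(s): %s", paste(miss, collapse = ", "))
  abbrev <- c(producer = "P", salvager = "S", nonproducer = "NP")
  cat_of <- setNames(abbrev[annotations$category], annotations$species)
  dep_of <- setNames(annotations$dependent, annotations$species)
  levels <- c("P-P", "P-S", "P-NP", "S-S", "S-NP", "NP-NP")
  if (nrow(net$edges) == 0L)
    return(list(counts = setNames(rep(0L, 6L), levels),
                percentages = setNames(rep(NA_real_, 6L), levels),
                sharing_pct = NA_real_, n_edges = 0L))
  ca <- cat_of[net$edges$a]; cb <- cat_of[net$edges$b]
  rank <- c(P = 1L, S = 2L, NP = 3L)
  lab <- ifelse(rank[ca] <= rank[cb], paste(ca, cb, sep = "-"),
                paste(cb, ca, sep = "-"))
  counts <- setNames(tabulate(factor(lab, levels = levels), 6L), levels)
  n <- nrow(net$edges)
  sharing <- (ca == "P" & cb != "P" & dep_of[net$edges$b]) |
    (cb == "P" & ca != "P" & dep_of[net$edges$a])
  list(counts = counts, percentages = 100 * counts / n,
       sharing_pct = 100 * sum(sharing) / n, n_edges = n)
}
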