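## Community diversity statistics: rarefaction, Shannon, square-root
## Bray-Curtis, cumulative producer abundance, quartile grouping, rank tests.

#' Community analysis parameters
#'
#' @param rarefaction_depth Reads to subsample each metagenome to
#'   (default 1,500,000); shallower samples are discarded.
#' @param sqrt_transform Square-root transform abundances before Bray-Curtis
#'   (default TRUE), giving more weight to low-abundance taxa.
#' @param quartile_low,quartile_high Bounds for Low/High grouping of
#'   cumulative producer abundance (defaults 0.0005 and 0.0075, i.e. the
#'   0.05\% and 0.75\% quartile values; strict inequalities).
#' @param alpha Significance level for reporting (default 0.05).
#' @param seed Seed for rarefaction draws.
#' @return A list of class \code{community_params}.
#' @export
community_params <- function(rarefaction_depth = 1500000L,
                             sqrt_transform = TRUE,
                             quartile_low = 0.0005, quartile_high = 0.0075,
                             alpha = 0.05, seed = NULL) {
  if (quartile_low > quartile_high)
    stopf("quartile_low must not exceed quartile_high")
  structure(list(rarefaction_depth = as.integer(rarefaction_depth),
                 sqrt_transform = sqrt_transform,
                 quartile_low = quartile_low, quartile_high = quartile_high,
                 alpha = alpha, seed = seed),
            class = "community_params")
}

#' Rarefy a species count vector
#'
#' Draws exactly \code{depth} reads without replacement (multivariate
#' hypergeometric) from the observed counts. A sample with fewer than
#' \code{depth} total reads raises an error condition of class
#' \code{"sample_discarded"} that callers can catch.
#'
#' @param counts Non-negative integer vector (named by species).
#' @param depth Target depth.
#' @param seed Optional seed.
#' @return Integer vector summing to \code{depth}.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  total <- sum(counts)
  if (total < depth)
    stop(errorCondition(
      sprintf("sample discarded: %d reads < depth %d", total, depth),
      class = c("sample_discarded", "error", "condition")))
  with_seed(seed, {
    out <- integer(length(counts))
    remaining <- depth
    left <- total
    for (i in seq_along(counts)) {
      left <- left - counts[i]
      out[i] <- rhyper(1L, counts[i], left, remaining)
      remaining <- remaining - out[i]
      if (remaining == 0L) break
    }
    names(out) <- names(counts)
    out
  })
}

#' Rarefy a sample x species matrix, discarding shallow samples
#'
#' @param mat Sample x species count matrix.
#' @param params [community_params()].
#' @return Rarefied matrix; discarded samples are dropped with a message.
#' @export
rarefy_matrix <- function(mat, params = community_params()) {
  with_seed(params$seed, {
    rows <- lapply(rownames(mat) %||% as.character(seq_len(nrow(mat))),
                   function(s) {
      tryCatch(rarefy(mat[s, ], params$rarefaction_depth),
               sample_discarded = function(e) NULL)
    })
    keep <- !vapply(rows, is.null, logical(1))
    if (any(!keep))
      message(sprintf("discarded %d sample(s) below rarefaction depth",
                      sum(!keep)))
    out <- do.call(rbind, rows[keep])
    rownames(out) <- (rownames(mat) %||% as.character(seq_len(nrow(mat))))[keep]
    colnames(out) <- colnames(mat)
    out
  })
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log p_i} over the positive entries of a relative
#' abundance vector, natural log by default.
#'
#' @param rel_abund Probability vector (non-negative, sums to 1).
#' @param base Logarithm base (default \code{exp(1)}).
#' @return The Shannon index.
#' @export
shannon <- function(rel_abund, base = exp(1)) {
  if (any(rel_abund < 0)) stopf("negative abundance")
  if (abs(sum(rel_abund) - 1) > 1e-9)
    stopf("rel_abund must sum to 1")
  p <- rel_abund[rel_abund > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' Optionally square-root transforms abundances, then computes
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} for every
#' sample pair. Pairs of all-zero samples are undefined and returned as
#' \code{NA} with a warning.
#'
#' @param mat Sample x species abundance matrix (non-negative).
#' @param sqrt_transform Apply the square-root transform first
#'   (default TRUE).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(mat, sqrt_transform = TRUE) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stopf("abundances must be non-negative")
  if (sqrt_transform) mat <- sqrt(mat)
  d <- as.matrix(suppressWarnings(vegan::vegdist(mat, method = "bray")))
  diag(d) <- 0
  if (any(is.nan(d))) {
    warnf("all-zero sample pair(s): dissimilarity undefined, set to NA")
    d[is.nan(d)] <- NA_real_
  }
  d
}

#' Cumulative producer abundance
#'
#' Sum of the relative abundances of the given producer species in one
#' sample (e.g. the cumulative relative abundance of cobamide-producing
#' corynebacteria, CPC).
#'
#' @param rel_abund Named relative abundance vector.
#' @param producer_species Character vector of producer species.
#' @return The cumulative fraction.
#' @export
cpc_abundance <- function(rel_abund, producer_species) {
  sum(rel_abund[names(rel_abund) %in% producer_species])
}

#' Quartile grouping of producer abundance
#'
#' Labels values strictly below the low bound \code{"Low"}, strictly above
#' the high bound \code{"High"}, and everything else \code{"Mid"}. Bounds
#' default to the parameters' fixed quartile values; when \code{compute}
#' is TRUE they are instead the first and third type-7 quartiles of the
#' supplied values.
#'
#' @param values Numeric vector (e.g. per-sample CPC abundance).
#' @param params [community_params()].
#' @param compute Compute bounds from \code{values} (default FALSE).
#' @return Character vector of labels.
#' @export
quartile_grouping <- function(values, params = community_params(),
                              compute = FALSE) {
  if (compute) {
    q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1L]; hi <- q[2L]
  } else {
    lo <- params$quartile_low; hi <- params$quartile_high
  }
  ifelse(values < lo, "Low", ifelse(values > hi, "High", "Mid"))
}

## Tie-corrected Dunn z post hoc tests with Bonferroni multiplication.
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = NA_real_, p.unadj = NA_real_, p.adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    p <- 2 * pnorm(-abs(z))
    out$z[k] <- z
    out$p.unadj[k] <- p
    out$p.adj[k] <- min(1, p * m)
  }
  out
}

#' Rank-based group tests
#'
#' The pipeline's nonparametric tests: a Kruskal-Wallis test followed by
#' Dunn's post hoc test with Bonferroni correction
#' (\code{"kruskal_dunn_bonferroni"}), a two-sided Mann-Whitney U test
#' (\code{"mann_whitney"}), or a Spearman rank correlation computed as the
#' Pearson correlation of average ranks (\code{"spearman"}). All
#' statistics are tie-corrected.
#'
#' @param values Numeric vector (for \code{"spearman"}, the first
#'   variable).
#' @param groups Group labels (for \code{"spearman"}, the paired second
#'   numeric vector).
#' @param design Which test to run.
#' @return A list with the statistic(s) and p-value(s); for the
#'   Kruskal-Wallis design, the Dunn pairwise table is included.
#' @export
rank_tests <- function(values, groups,
                       design = c("kruskal_dunn_bonferroni", "mann_whitney",
                                  "spearman")) {
  design <- match.arg(design)
  if (design == "spearman") {
    x <- values; y <- groups
    if (length(x) != length(y)) stopf("paired vectors must match in length")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    return(list(design = design, rho = unname(ct$estimate),
                p.value = ct$p.value))
  }
  groups <- factor(groups)
  if (any(tabulate(groups) == 0L) || nlevels(groups) < 2L)
    stopf("need at least 2 non-empty groups")
  if (design == "mann_whitney") {
    if (nlevels(groups) != 2L) stopf("mann_whitney needs exactly 2 groups")
    sp <- split(values, groups)
    wt <- suppressWarnings(wilcox.test(sp[[1L]], sp[[2L]],
                                       alternative = "two.sided"))
    return(list(design = design, U = unname(wt$statistic),
                p.value = wt$p.value))
  }
  kw <- kruskal.test(values, groups)
  list(design = design, H = unname(kw$statistic),
       df = unname(kw$parameter), p.value = kw$p.value,
       dunn = dunn_posthoc(values, groups))
}
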