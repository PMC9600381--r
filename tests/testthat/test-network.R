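test_that("species filtering applies the abundance and prevalence thresholds on the pooled samples", {
  # species at 0.02% mean abundance and 60% prevalence is kept; one seen in
  # a single sample is removed
  n <- 100
  m <- matrix(1000L, n, 3, dimnames = list(NULL, c("common", "low", "rare")))
  m[, "low"] <- 0L
  m[1:60, "low"] <- 1L   # mean rel abundance ~ 0.6 * 1/2000 = 0.03% > 0.015%
  m[, "rare"] <- 0L
  m[1, "rare"] <- 500L
  roster <- filter_species(list(m))
  expect_true(all(c("common", "low") %in% roster))
  expect_false("rare" %in% roster)
  # brute-force oracle on random matrices
  set.seed(21)
  for (i in 1:5) {
    mats <- lapply(1:2, function(k)
      matrix(rpois(40 * 8, 20) * rbinom(40 * 8, 1, 0.6), 40, 8,
             dimnames = list(NULL, paste0("sp", 1:8))))
    pooled <- do.call(rbind, mats)
    rel <- pooled / rowSums(pooled)
    want <- colnames(pooled)[colMeans(rel) > 0.00015 &
                               colMeans(pooled > 0) >= 0.55]
    expect_equal(filter_species(mats), want)
  }
})

test_that("CLR rows sum to zero and the transform matches its formula", {
  expect_equal(as.numeric(clr_transform(matrix(c(1, 1, 1, 1), 1))),
               rep(0, 4))
  set.seed(2)
  counts <- matrix(rpois(60, 10), 6, 10)
  out <- clr_transform(counts, pseudocount = 1)
  expect_true(all(abs(rowSums(out)) < 1e-9))
  x <- counts[3, ] + 1
  expect_equal(out[3, ], log(x / sum(x)) - mean(log(x / sum(x))))
  # scale invariance of compositions at pseudocount zero
  c2 <- counts + 1
  expect_equal(clr_transform(c2 * 5L, pseudocount = 0),
               clr_transform(c2, pseudocount = 0))
  expect_error(clr_transform(rbind(c(0, 0, 0)), pseudocount = 0), "zero")
})

test_that("per-node neighborhoods match an independent coordinate-descent lasso", {
  set.seed(31)
  n <- 200; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  x[, 2] <- x[, 1] * 0.9 + rnorm(n, sd = 0.2)
  x[, 5] <- -0.7 * x[, 4] + rnorm(n, sd = 0.4)
  colnames(x) <- paste0("sp", 1:p)
  path <- neighborhood_path(x, network_params(n_lambda = 8))
  z <- scale(x)  # the path standardizes internally; mirror it
  for (l in c(3, 6, 8)) {
    lam <- path$lambda[l]
    for (j in seq_len(p)) {
      want <- numeric(p)
      want[-j] <- oracle_lasso(z[, -j, drop = FALSE], z[, j], lam)
      got <- path$directed[j, , l]
      expect_lt(max(abs(got - want)), 1e-4)
    }
  }
})

test_that("the penalty path starts empty and finds the correlated pair first", {
  set.seed(33)
  n <- 400
  a <- rnorm(n)
  x <- cbind(a, a + rnorm(n, sd = 0.05), rnorm(n))
  colnames(x) <- c("u", "v", "w")
  path <- neighborhood_path(x, network_params(n_lambda = 10))
  expect_equal(sum(path$adjacency[[1]]), 0)  # lambda_max: empty graph
  dense <- path$adjacency[[10]]
  expect_true(dense["u", "v"])
  w_uv <- path$weight[[10]]["u", "v"]
  expect_gt(w_uv, 0)  # positive association
})

test_that("StARS is reproducible, stable for duplicated signal, near-empty on null data", {
  set.seed(41)
  x <- matrix(rpois(500 * 10, 50), 500, 10,
              dimnames = list(NULL, paste0("sp", 1:10)))
  clr <- clr_transform(x)
  p1 <- network_params(seed = 1, stars_subsamples = 20)
  s1 <- suppressWarnings(stars_select(clr, p1))
  s2 <- suppressWarnings(stars_select(clr, p1))
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(s1$instability, s2$instability)
  expect_lte(nrow(s1$network$edges), 1)  # independent variables
  # duplicated columns are always selected together at dense penalties
  y <- x; y[, 2] <- y[, 1]
  sdup <- suppressWarnings(stars_select(clr_transform(y), p1))
  dense_l <- length(sdup$instability)
  expect_true(sdup$stability["sp1", "sp2"] == 1 ||
                nrow(sdup$network$edges) >= 1)
})

test_that("consensus keeps sign-consistent edges in >= 2 studies and matches enumeration", {
  nodes <- data.frame(species = letters[1:5], stringsAsFactors = FALSE)
  mk <- function(a, b, sign, w) association_network(
    nodes, data.frame(a = a, b = b, sign = sign, weight = w,
                      stringsAsFactors = FALSE))
  n1 <- mk(c("a", "a", "b"), c("b", "c", "d"), c(1L, 1L, -1L),
           c(0.5, 0.3, -0.2))
  n2 <- mk(c("a", "b"), c("b", "d"), c(1L, -1L), c(0.4, -0.4))
  n3 <- mk(c("a"), c("c"), c(-1L), c(-0.1))
  cons <- consensus_merge(list(n1, n2, n3))
  expect_equal(cons$edges$a, c("a", "b"))
  expect_equal(cons$edges$b, c("b", "d"))
  expect_equal(cons$edges$sign, c(1L, -1L))
  expect_equal(cons$edges$weight, c(0.45, -0.3))
  expect_equal(cons$edges$support, c(2L, 2L))
  # sign conflict drops the edge: a-c is + in n1 and - in n3
  expect_false(any(cons$edges$a == "a" & cons$edges$b == "c"))
  # isolated nodes dropped
  expect_setequal(cons$nodes$species, c("a", "b", "d"))
  # consensus is a subset of the union of input edges; idempotent at support 1
  again <- consensus_merge(list(cons, cons),
                           network_params(consensus_min_support = 1))
  expect_equal(again$edges[, c("a", "b", "sign")],
               cons$edges[, c("a", "b", "sign")])
  # random networks against the enumeration oracle
  set.seed(17)
  for (i in 1:10) {
    nets <- lapply(1:3, function(k) {
      e <- expand.grid(a = letters[1:5], b = letters[1:5],
                       stringsAsFactors = FALSE)
      e <- e[e$a < e$b & runif(nrow(e)) < 0.4, , drop = FALSE]
      e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
      e$weight <- round(runif(nrow(e), -1, 1), 2)
      association_network(nodes, e)
    })
    got <- consensus_merge(nets)
    want <- oracle_consensus(nets, 2)
    expect_equal(sort(paste(got$edges$a, got$edges$b, got$edges$sign)),
                 want)
  }
})

test_that("topology metrics match closed forms on canonical graphs", {
  nodes4 <- data.frame(species = letters[1:4],
                       phylum = c("X", "X", "Y", "Y"),
                       stringsAsFactors = FALSE)
  k4 <- expand.grid(a = letters[1:4], b = letters[1:4],
                    stringsAsFactors = FALSE)
  k4 <- k4[k4$a < k4$b, ]
  k4$sign <- 1L; k4$weight <- 1
  m <- network_metrics(association_network(nodes4, k4))
  expect_equal(m$density, 1)
  expect_equal(m$transitivity, 1)
  # two disjoint triangles: modularity of the 2-community split is 1/2 - 1/4...
  # Q = sum(e_ii - a_i^2) = 2 * (3/6 - (6/12)^2) = 0.5
  nodes6 <- data.frame(species = letters[1:6],
                       phylum = rep(c("X", "Y"), each = 3),
                       stringsAsFactors = FALSE)
  tri2 <- data.frame(a = c("a", "a", "b", "d", "d", "e"),
                     b = c("b", "c", "c", "e", "f", "f"),
                     sign = 1L, weight = 1, stringsAsFactors = FALSE)
  m2 <- network_metrics(association_network(nodes6, tri2))
  expect_equal(m2$modularity, 0.5)
  expect_equal(m2$phylum_assortativity, 1)  # edges never cross phyla
  # cross-phylum star: nominal assortativity -1
  star_nodes <- data.frame(species = c("hub", "l1", "l2", "l3"),
                           phylum = c("X", "Y", "Y", "Y"),
                           stringsAsFactors = FALSE)
  star <- data.frame(a = "hub", b = c("l1", "l2", "l3"), sign = 1L,
                     weight = 1, stringsAsFactors = FALSE)
  m3 <- network_metrics(association_network(star_nodes, star))
  expect_equal(m3$phylum_assortativity, -1)
  expect_error(network_metrics(association_network(
    data.frame(species = "a"), star[0, ])), "at least 2")
})

test_that("metrics are invariant under node relabeling", {
  set.seed(23)
  nodes <- data.frame(species = sprintf("n%02d", 1:12),
                      phylum = sample(c("X", "Y", "Z"), 12, replace = TRUE),
                      stringsAsFactors = FALSE)
  e <- expand.grid(a = nodes$species, b = nodes$species,
                   stringsAsFactors = FALSE)
  e <- e[e$a < e$b & runif(nrow(e)) < 0.3, ]
  e$sign <- 1L; e$weight <- 1
  base <- network_metrics(association_network(nodes, e))
  for (i in 1:20) {
    perm <- setNames(sample(nodes$species), nodes$species)
    nodes2 <- nodes; nodes2$species <- unname(perm[nodes$species])
    e2 <- e; e2$a <- unname(perm[e$a]); e2$b <- unname(perm[e$b])
    m2 <- network_metrics(association_network(nodes2, e2))
    expect_equal(m2$density, base$density)
    expect_equal(m2$transitivity, base$transitivity)
    expect_equal(m2$modularity, base$modularity)
    expect_equal(m2$phylum_assortativity, base$phylum_assortativity)
    expect_equal(sort(unname(m2$degree)), sort(unname(base$degree)))
  }
})

test_that("edge categories enumerate unordered pairs and sum to 100%", {
  nodes <- data.frame(species = c("p", "n1", "n2"), stringsAsFactors = FALSE)
  tri <- data.frame(a = c("p", "p", "n1"), b = c("n1", "n2", "n2"),
                    sign = 1L, weight = 1, stringsAsFactors = FALSE)
  ann <- data.frame(species = c("p", "n1", "n2"),
                    category = c("producer", "nonproducer", "nonproducer"),
                    dependent = c(FALSE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  ce <- categorize_edges(association_network(nodes, tri), ann)
  expect_equal(unname(ce$counts[c("P-NP", "NP-NP")]), c(2L, 1L))
  expect_equal(sum(ce$percentages), 100, tolerance = 1e-12)
  expect_equal(ce$sharing_pct, 100 / 3)  # only p-n1 joins P to a dependent NP
  ann$category <- "producer"
  ce2 <- categorize_edges(association_network(nodes, tri), ann)
  expect_equal(unname(ce2$percentages["P-P"]), 100)
  expect_error(categorize_edges(association_network(nodes, tri),
                                ann[1:2, ]), "unannotated")
  # brute-force scan on a random annotated graph
  set.seed(27)
  nodes <- data.frame(species = sprintf("n%02d", 1:10),
                      stringsAsFactors = FALSE)
  e <- expand.grid(a = nodes$species, b = nodes$species,
                   stringsAsFactors = FALSE)
  e <- e[e$a < e$b & runif(nrow(e)) < 0.4, ]
  e$sign <- 1L; e$weight <- 1
  ann <- data.frame(species = nodes$species,
                    category = sample(c("producer", "salvager",
                                        "nonproducer"), 10, replace = TRUE),
                    dependent = sample(c(TRUE, FALSE), 10, replace = TRUE),
                    stringsAsFactors = FALSE)
  ce <- categorize_edges(association_network(nodes, e), ann)
  lab <- setNames(c(P = "P", S = "S", NP = "NP")[
    c(producer = "P", salvager = "S", nonproducer = "NP")[ann$category]],
    ann$species)
  cnt <- integer(0)
  for (i in seq_len(nrow(e))) {
    pair <- sort(factor(c(lab[e$a[i]], lab[e$b[i]]),
                        levels = c("P", "S", "NP")))
    k <- paste(pair, collapse = "-")
    cnt[k] <- (if (is.na(cnt[k])) 0L else cnt[k]) + 1L
  }
  for (k in names(cnt)) expect_equal(unname(ce$counts[k]), unname(cnt[k]))
  expect_equal(sum(ce$counts), nrow(e))
})
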