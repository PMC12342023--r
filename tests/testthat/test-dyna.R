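makeWindowDataset <- function(values) {
  # values: named list mediator -> numeric vector over (subject x 2 times)
  n <- length(values[[1]])
  stopifnot(n %% 2 == 0)
  rows <- do.call(rbind, lapply(names(values), function(med) {
    data.frame(subject = rep(sprintf("s%d", seq_len(n / 2)), each = 2),
               subgroup = "G", time = rep(0:1, n / 2), mediator = med,
               value = values[[med]], stringsAsFactors = FALSE)
  }))
  MediatorDataset(rows, timeGrid = 0:1)
}

test_that("window correlations reproduce hand-computed Pearson values", {
  # hand evaluation of the sums formula: cov = 10.25, ss = 8.75 and 14.75,
  # r = 10.25 / sqrt(8.75 * 14.75) = 0.902244
  ds <- makeWindowDataset(list(A = c(1, 2, 3, 5), B = c(2, 1, 4, 6)))
  cc <- intervalCorrelations(ds, "G", 1, minPairs = 4)
  expect_equal(cc$r["A", "B"], 0.902244, tolerance = 5e-6)
  # exact linear dependence
  ds2 <- makeWindowDataset(list(A = c(1, 2, 3, 4), B = 2 * c(1, 2, 3, 4)))
  expect_equal(intervalCorrelations(ds2, "G", 1)$r["A", "B"], 1.0)
})

test_that("zero-variance mediators are excluded with a reason, never edges", {
  ds <- makeWindowDataset(list(A = c(1, 2, 3, 4), C = rep(7, 4)))
  cc <- intervalCorrelations(ds, "G", 1)
  expect_true(is.na(cc$r["A", "C"]))
  expect_equal(cc$excluded$reason[cc$excluded$mediator == "C"],
               "zero variance")
  nets <- buildNetworks(ds, "G")
  expect_equal(nrow(networkEdges(nets)), 0)
  expect_equal(nrow(nets@excluded), 1)
})

test_that("the stringency threshold is inclusive at the boundary", {
  # engineer r very close to target values via direct construction
  ds <- makeWindowDataset(list(A = c(1, 2, 3, 5), B = c(2, 1, 4, 6)))
  cc <- intervalCorrelations(ds, "G", 1)
  r <- cc$r["A", "B"]  # ~0.8616
  nets_at <- buildNetworks(ds, "G", threshold = r)         # == r: edge
  nets_above <- buildNetworks(ds, "G", threshold = r + 1e-6)
  expect_equal(nrow(networkEdges(nets_at)), 1)
  expect_equal(nrow(networkEdges(nets_above)), 0)
  # negative correlations yield negative edges (hand r = -0.8620)
  dsn <- makeWindowDataset(list(A = c(1, 2, 3, 5), B = c(6, 7, 2, 1)))
  e <- networkEdges(buildNetworks(dsn, "G", threshold = 0.85))
  expect_equal(e$sign, "negative")
  expect_error(buildNetworks(ds, "G", threshold = 1.2), "threshold")
  expect_error(buildNetworks(ds, "G", threshold = 0), "threshold")
})

test_that("pairs below the minimum complete-pair count stay undefined", {
  ds <- makeWindowDataset(list(A = c(1, 2, 3, 5), B = c(2, 1, 4, 6)))
  cc <- intervalCorrelations(ds, "G", 1, minPairs = 5)
  expect_true(is.na(cc$r["A", "B"]))
})

test_that("differences mode correlates per-subject changes across the window", {
  A <- c(1, 3, 2, 6, 5, 4)  # subjects s1..s3 at times 0,1
  B <- c(2, 6, 1, 9, 8, 2)
  ds <- makeWindowDataset(list(A = A, B = B))
  cc <- intervalCorrelations(ds, "G", 1, mode = "differences", minPairs = 3)
  dA <- A[c(2, 4, 6)] - A[c(1, 3, 5)]
  dB <- B[c(2, 4, 6)] - B[c(1, 3, 5)]
  expect_equal(cc$r["A", "B"], cor(dA, dB))
  nets <- buildNetworks(ds, "G", mode = "differences", minPairs = 3)
  expect_equal(nets@mode, "differences")
})

test_that("edge sets match a brute-force oracle on random datasets", {
  set.seed(21)
  for (rep in 1:12) {
    ds <- randomDataset(sample(3:6, 1), sample(2:4, 1), sample(10:30, 1),
                        missing = 0.1)
    nets <- buildNetworks(ds, "G", threshold = 0.5)  # low threshold: edges
    expect_identical(edgeKey(networkEdges(nets)),
                     edgeKey(bfEdges(ds, "G", threshold = 0.5)))
  }
})

test_that("no self-edges and symmetric treatment of pairs", {
  set.seed(3)
  ds <- randomDataset(5, 3, 12)
  nets <- buildNetworks(ds, "G", threshold = 0.3)
  e <- networkEdges(nets)
  expect_false(any(e$mediator_a == e$mediator_b))
  expect_false(any(duplicated(paste(e$interval, pmin(e$mediator_a, e$mediator_b),
                                    pmax(e$mediator_a, e$mediator_b)))))
})

test_that("raising the threshold never adds edges and complexity is monotone", {
  set.seed(8)
  ds <- randomDataset(6, 3, 10)
  th <- c(0.3, 0.5, 0.7, 0.85, 0.95)
  sets <- lapply(th, function(t) buildNetworks(ds, "G", threshold = t))
  for (i in seq_along(th)[-1]) {
    expect_true(all(edgeKey(networkEdges(sets[[i]])) %in%
                      edgeKey(networkEdges(sets[[i - 1]]))))
    expect_lte(sum(networkComplexity(sets[[i]])$complexity),
               sum(networkComplexity(sets[[i - 1]])$complexity))
  }
})

test_that("complexity follows the degree-sum formula", {
  set.seed(13)
  ds <- randomDataset(5, 4, 10)
  nets <- buildNetworks(ds, "G", threshold = 0.4)
  cx <- networkComplexity(nets)
  for (k in nets@intervals$index) {
    E <- sum(networkEdges(nets)$interval == k)
    expect_equal(cx$complexity[cx$interval == k], 2 * E / (5 - 1))
  }
  expect_equal(attr(cx, "totalConnections"), nrow(networkEdges(nets)))
  expect_equal(totalConnections(nets), nrow(networkEdges(nets)))
  # closed forms: one edge on a 23-panel; complete graph on 5 nodes
  empty <- methods::new("DynamicNetworkSet",
    edges = data.frame(interval = 1L, mediator_a = "A", mediator_b = "B",
                       r = 0.9, sign = "positive", n_pairs = 10L),
    intervals = data.frame(index = 1L, start = 0, end = 1, label = "0-1"),
    mediators = paste0("m", 1:23), threshold = 0.85, mode = "levels",
    subgroup = "G",
    excluded = data.frame(interval = integer(), mediator = character(),
                          reason = character()))
  expect_equal(networkComplexity(empty)$complexity, 2 / 22)
  pairs <- t(combn(paste0("m", 1:5), 2))
  complete5 <- methods::new("DynamicNetworkSet",
    edges = data.frame(interval = 1L, mediator_a = pairs[, 1],
                       mediator_b = pairs[, 2], r = 0.9, sign = "positive",
                       n_pairs = 10L),
    intervals = data.frame(index = 1L, start = 0, end = 1, label = "0-1"),
    mediators = paste0("m", 1:5), threshold = 0.85, mode = "levels",
    subgroup = "G",
    excluded = data.frame(interval = integer(), mediator = character(),
                          reason = character()))
  expect_equal(networkComplexity(complete5)$complexity, 5.0)
  expect_error(networkComplexity(complete5, nMediators = 1), "at least 2")
})

test_that("mediator connectivity sums per-interval degrees", {
  set.seed(2)
  ds <- randomDataset(5, 4, 12)
  nets <- buildNetworks(ds, "G", threshold = 0.4)
  e <- networkEdges(nets)
  for (med in mediators(ds)) {
    conn <- mediatorConnectivity(nets, med)
    expect_equal(conn$total,
                 sum(e$mediator_a == med) + sum(e$mediator_b == med))
    expect_equal(sum(conn$perInterval$degree), conn$total)
  }
  ct <- connectivityTable(nets)
  expect_equal(sum(ct$total_degree), 2 * nrow(e))
  expect_error(mediatorConnectivity(nets, "nope"), "unknown mediator")
})

test_that("a planted hub carries the highest total connectivity", {
  hub_wins <- 0
  for (sd in 1:10) {
    # hub edges in non-adjacent intervals: a same-window star with
    # independent spokes at high r would not be a valid correlation matrix
    pe <- data.frame(
      mediator_a = "M1", mediator_b = c("M2", "M3", "M4"),
      interval = c(1L, 3L, 5L), r = 0.9)
    spec <- SyntheticSpec(6, c(G = 20L), timeGrid = 0:5, plantedEdges = pe,
                          latentLogSd = 0.3, noiseLogSd = 0.05)
    g <- generateDataset(spec, seed = sd)
    ct <- connectivityTable(buildNetworks(g$dataset, "G"))
    if (ct$mediator[1] == "M1") hub_wins <- hub_wins + 1
  }
  expect_gte(hub_wins, 9)
})

test_that("networks serialize to edge list, complexity, connectivity, GraphML", {
  set.seed(6)
  ds <- randomDataset(4, 3, 8)
  nets <- buildNetworks(ds, "G", threshold = 0.4)
  dir <- tempfile()
  paths <- writeNetworks(nets, dir)
  expect_true(file.exists(file.path(dir, "edges.csv")))
  expect_true(file.exists(file.path(dir, "complexity.csv")))
  g <- asIgraph(nets, 1)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), sum(networkEdges(nets)$interval == 1))
})
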