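# build a TransitionTable directly from latent matrices (bypasses the
# dataset layer so score tests control their inputs exactly)
makeTT <- function(x0, x1, timeIndex = rep(1L, nrow(x0)),
                   nTime = max(timeIndex) + 1L) {
  med <- colnames(x0)
  structure(list(x0 = x0, x1 = x1, timeIndex = as.integer(timeIndex),
                 subject = rep("s", nrow(x0)), mediators = med,
                 nTime = as.integer(nTime)),
            class = "TransitionTable")
}

test_that("transition pooling counts subjects x consecutive pairs", {
  spec <- SyntheticSpec(3, c(S = 14L), timeGrid = 0:7)
  g <- generateDataset(spec, seed = 1)
  tt <- buildTransitions(g$dataset, "S")
  expect_equal(nrow(tt$x0), 14 * 7)
  expect_equal(sort(unique(tt$timeIndex)), 1:7)
})

test_that("gaps break the transition chain under the strict-consecutive policy", {
  meas <- expand.grid(subject = "a", time = c(0, 1, 3),
                      mediator = c("X", "Y"), stringsAsFactors = FALSE)
  meas$subgroup <- "G"
  set.seed(2); meas$value <- exp(rnorm(nrow(meas)))
  ds <- MediatorDataset(meas, timeGrid = 0:3)
  expect_warning(tt <- buildTransitions(ds, "G"), "prior-dominated")
  expect_equal(nrow(tt$x0), 1)         # only (0,1); (1,3) is a gap
  expect_equal(tt$timeIndex, 1L)
})

test_that("an empty subgroup yields a no-transitions error", {
  ds <- randomDataset(2, 3, 4)
  expect_error(buildTransitions(ds, "H"), "unknown subgroup")
  one <- measurements(ds)
  one <- one[one$time == 0, ]
  ds1 <- MediatorDataset(one, timeGrid = timeGrid(ds))
  expect_error(buildTransitions(ds1, "G"), "no transitions")
})

test_that("the closed-form marginal matches numerical quadrature (1-D)", {
  h <- bgeHyperparams(3)
  for (x in list(c(0, 1, -1), c(0.3, 0.1), c(2, -1, 0.5, 0.2, -0.7))) {
    expect_equal(bgeMarginalLikelihood(matrix(x), h),
                 quadMarginal1D(x, h), tolerance = 1e-6)
  }
})

test_that("family scores match the importance-sampling oracle (<= 2 parents)", {
  h <- bgeHyperparams(3)
  set.seed(7)
  x0 <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  x1 <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  tt <- makeTT(x0, x1)
  for (pa in list(character(), "A", c("A", "B"), c("B", "C"))) {
    fam <- cbind(x1[, "C", drop = FALSE], x0[, pa, drop = FALSE])
    oracle <- isMarginal(fam, h, nDraws = 3e4) -
      (if (length(pa)) isMarginal(x0[, pa, drop = FALSE], h, nDraws = 3e4)
       else 0)
    expect_equal(bgeFamilyScore(tt, "C", pa, hyper = h), oracle,
                 tolerance = 1e-3)
  }
})

test_that("the score is equivalent across Markov-equivalent complete families", {
  set.seed(9)
  for (rep in 1:5) {
    h2 <- bgeHyperparams(2)
    Z <- matrix(rnorm(16), 8, 2)
    sXY <- bgeMarginalLikelihood(Z[, 1, drop = FALSE], h2) +
      (bgeMarginalLikelihood(Z, h2) -
         bgeMarginalLikelihood(Z[, 1, drop = FALSE], h2))
    sYX <- bgeMarginalLikelihood(Z[, 2, drop = FALSE], h2) +
      (bgeMarginalLikelihood(Z, h2) -
         bgeMarginalLikelihood(Z[, 2, drop = FALSE], h2))
    expect_equal(sXY, sYX, tolerance = 1e-10)
    # 3-variable complete DAGs: all orderings give the joint marginal
    h3 <- bgeHyperparams(3)
    Z3 <- matrix(rnorm(24), 8, 3)
    scoreOrder <- function(ord) {
      s <- 0
      for (i in seq_along(ord)) {
        fam <- Z3[, ord[seq_len(i)], drop = FALSE]
        pa <- Z3[, ord[seq_len(i - 1)], drop = FALSE]
        s <- s + bgeMarginalLikelihood(fam, h3) -
          (if (i > 1) bgeMarginalLikelihood(pa, h3) else 0)
      }
      s
    }
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                  c(3, 2, 1))
    ss <- vapply(perms, scoreOrder, numeric(1))
    expect_lt(max(ss) - min(ss), 1e-10)
  }
})

test_that("empty segments and empty transition sets score exactly zero", {
  set.seed(1)
  x <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("A", "B", "C")))
  tt <- makeTT(x, x)
  expect_identical(bgeFamilyScore(tt, "A", rows = integer()), 0)
})

test_that("the network score is additive and invariant to relabeling", {
  set.seed(12)
  spec <- SyntheticSpec(3, c(G = 10L), timeGrid = 0:4,
                        arSelf = c(M1 = 0.6))
  g <- generateDataset(spec, seed = 3)
  tt <- buildTransitions(g$dataset, "G")
  h <- bgeHyperparams(3)
  cpc <- cpConfig(kMax = 0)
  strEmpty <- setNames(rep(list(character()), 3), tt$mediators)
  total <- networkLogScore(strEmpty, NULL, tt, h, cpc, fanIn = 2)
  bySum <- sum(vapply(tt$mediators, function(m)
    bgeFamilyScore(tt, m, hyper = h), numeric(1))) -
    3 * log(1 + 3 + 3)                # uniform prior over 7 parent sets
  expect_equal(total, bySum, tolerance = 1e-10)
  # relabel mediators: permuting the panel leaves the score unchanged
  perm <- c(2, 3, 1)
  tt2 <- tt
  tt2$x0 <- tt$x0[, perm]; tt2$x1 <- tt$x1[, perm]
  tt2$mediators <- tt$mediators[perm]
  str2 <- strEmpty[tt2$mediators]
  expect_equal(networkLogScore(str2, NULL, tt2, h, cpc, fanIn = 2), total,
               tolerance = 1e-10)
})

test_that("a changepoint splitting a homogeneous series lowers the score", {
  spec <- SyntheticSpec(2, c(G = 15L), timeGrid = 0:7,
                        arSelf = c(M1 = 0.6, M2 = 0.6))
  g <- generateDataset(spec, seed = 21)
  tt <- buildTransitions(g$dataset, "G")
  h <- bgeHyperparams(2)
  cpc <- cpConfig(kMax = 1, lambda = 0.1)
  strSelf <- list(M1 = "M1", M2 = "M2")
  noCp <- networkLogScore(strSelf, NULL, tt, h, cpc)
  withCp <- networkLogScore(strSelf, list(M1 = 4L, M2 = integer()), tt, h,
                            cpc)
  expect_lt(withCp, noCp)
})

test_that("segmentations violating the minimum length are rejected", {
  spec <- SyntheticSpec(2, c(G = 1L), timeGrid = 0:7)
  g <- generateDataset(spec, seed = 2)
  tt <- buildTransitions(g$dataset, "G")
  # one subject: a boundary at index 2 leaves a single-transition segment
  expect_error(
    networkLogScore(list(M1 = character(), M2 = character()),
                    list(M1 = 2L, M2 = integer()), tt,
                    bgeHyperparams(2), cpConfig(kMax = 1, minSegment = 2)),
    "minimum segment length")
})

test_that("MCMC agrees with exact enumeration and is seed-deterministic", {
  spec <- SyntheticSpec(3, c(G = 20L), timeGrid = 0:7,
                        arSelf = c(M1 = 0.8), latentLogSd = 0.4,
                        noiseLogSd = 0.05)
  g <- generateDataset(spec, seed = 11)
  tt <- buildTransitions(g$dataset, "G")
  ex <- dybnExact(tt, fanIn = 2)
  p1 <- dybnSample(tt, cp = cpConfig(kMax = 0), iterations = 20000,
                   burnIn = 4000, fanIn = 2, seed = 5)
  p2 <- dybnSample(tt, cp = cpConfig(kMax = 0), iterations = 20000,
                   burnIn = 4000, fanIn = 2, seed = 5)
  expect_identical(edgeProbabilities(p1), edgeProbabilities(p2))
  expect_lt(max(abs(edgeProbabilities(p1) - ex)), 0.05)
  expect_error(dybnSample(tt, iterations = 10, burnIn = 10), "config error")
})

test_that("self-loop posterior grows with the planted AR coefficient", {
  means <- vapply(c(0, 0.4, 0.8), function(a) {
    post <- vapply(1:4, function(sd) {
      ar <- if (a == 0) numeric() else c(M1 = a)
      spec <- SyntheticSpec(3, c(G = 21L), timeGrid = 0:7, arSelf = ar,
                            latentLogSd = 0.4, noiseLogSd = 0.05)
      g <- generateDataset(spec, seed = 50 + sd)
      tt <- buildTransitions(g$dataset, "G")
      p <- dybnSample(tt, cp = cpConfig(kMax = 0), iterations = 4000,
                      burnIn = 1000, fanIn = 2, seed = sd)
      edgeProbabilities(p)["M1", "M1"]
    }, numeric(1))
    mean(post)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_lt(means[1], 0.5)
  expect_gt(means[3], 0.8)
})

test_that("consensus thresholding extracts self-feedback and central nodes", {
  P <- matrix(0.1, 3, 3, dimnames = list(c("GDF-15", "MIG", "IL-6"),
                                         c("GDF-15", "MIG", "IL-6")))
  P["GDF-15", "GDF-15"] <- 0.9   # self-loop
  P["GDF-15", "MIG"] <- 0.7      # GDF-15 -> MIG (MIG is connected too)
  P["IL-6", "IL-6"] <- 0.6       # isolated self-loop: not central
  post <- methods::new("DybnPosterior", edgeProb = P,
                       mediators = rownames(P), changepoints = list(),
                       diagnostics = list(), config = list(),
                       nSamples = 100L)
  cg <- consensusGraph(post, threshold = 0.5)
  expect_setequal(selfFeedback(cg), c("GDF-15", "IL-6"))
  expect_equal(centralNodes(cg), "GDF-15")  # IL-6 lacks other connections
  expect_equal(nrow(cg@edges), 3)
  empty <- consensusGraph(post, threshold = 0.95)
  expect_equal(nrow(empty@edges), 0)
  expect_error(consensusGraph(post, threshold = 0), "between 0 and 1")
  expect_error(consensusGraph(post, threshold = 1), "between 0 and 1")
})

test_that("with kMax = 0 the sampler reduces to the homogeneous model", {
  spec <- SyntheticSpec(2, c(G = 12L), timeGrid = 0:5,
                        arSelf = c(M1 = 0.7))
  g <- generateDataset(spec, seed = 8)
  tt <- buildTransitions(g$dataset, "G")
  p <- dybnSample(tt, cp = cpConfig(kMax = 0), iterations = 3000,
                  burnIn = 500, seed = 2)
  # no changepoints ever sampled
  for (m in tt$mediators)
    expect_equal(unname(p@changepoints[[m]]$countDist["0"]), 1)
})
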