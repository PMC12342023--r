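test_that("Mann-Whitney exact p matches full enumeration on small samples", {
  # the canonical worked case: complete separation at n = 2 vs 2
  res <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  expect_true(res$exact)
  expect_equal(res$p.value, 1 / 3, tolerance = 1e-12)
  # all sample-size combinations up to 5, tie-free random data
  set.seed(31)
  for (n1 in 1:5) for (n2 in 1:5) {
    z <- sample(seq_len(50), n1 + n2)   # distinct values: no ties
    x <- z[seq_len(n1)]; y <- z[-seq_len(n1)]
    expect_equal(mannWhitney(x, y)$p.value, bfMannWhitneyP(x, y),
                 tolerance = 1e-12,
                 label = sprintf("exact p at n1=%d n2=%d", n1, n2))
  }
})

test_that("Mann-Whitney handles identical samples and midrank ties", {
  x <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  res <- mannWhitney(x, x)
  expect_equal(unname(res$statistic), length(x)^2 / 2)
  expect_equal(res$p.value, 1)
  # U by direct pair counting (wins + half-ties)
  a <- c(1, 1, 2); b <- c(1, 2, 2)
  expect_equal(unname(mannWhitney(a, b)$statistic), bfU(a, b))
  # large-sample path agrees with the reference implementation
  set.seed(4)
  x <- round(rlnorm(30), 1); y <- round(rlnorm(25) * 1.5, 1)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(mannWhitney(x, y)$p.value, ref$p.value, tolerance = 1e-9)
  expect_error(mannWhitney(numeric(), 1:3), "at least one")
})

test_that("Spearman rho follows the rank-difference formula and monotone limits", {
  expect_equal(unname(spearmanTest(1:6, c(2, 4, 5, 7, 10, 20))$statistic), 1)
  expect_equal(unname(spearmanTest(1:6, -(1:6)^3)$statistic), -1)
  # d^2 = (1,1,1,1): rho = 1 - 6*4/(4*15) = 0.6
  res <- spearmanTest(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(unname(res$statistic), 0.6, tolerance = 1e-12)
  expect_true(res$exact)
  # exact permutation p agrees with the reference implementation
  ref <- suppressWarnings(cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3),
                                   method = "spearman"))
  expect_equal(unname(res$statistic), unname(ref$estimate))
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
  expect_error(spearmanTest(1:2, 2:3), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(17)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    r0 <- spearmanTest(x, y)
    r1 <- spearmanTest(exp(x), y)
    r2 <- spearmanTest(x, qlogis(plogis(y)))
    expect_equal(unname(r0$statistic), unname(r1$statistic), tolerance = 1e-12)
    expect_equal(r0$p.value, r1$p.value, tolerance = 1e-12)
    expect_equal(unname(r0$statistic), unname(r2$statistic), tolerance = 1e-9)
  }
})

test_that("ROC curve is monotone, anchored, and AUC equals normalized U", {
  # perfect separation
  res <- rocAnalysis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
                     positive = "b")
  expect_equal(res$auc, 1.0)
  expect_equal(res$roc$fpr[1], 0); expect_equal(res$roc$tpr[1], 0)
  expect_equal(tail(res$roc$fpr, 1), 1); expect_equal(tail(res$roc$tpr, 1), 1)
  # AUC / U identity on random inputs, including ties
  set.seed(23)
  for (rep in 1:25) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    v <- c(round(rlnorm(n1), 1), round(rlnorm(n2) * runif(1, 0.5, 2), 1))
    lab <- rep(c("ctl", "case"), c(n1, n2))
    r <- rocAnalysis(v, lab, positive = "case")
    u <- unname(mannWhitney(v[lab == "case"], v[lab == "ctl"])$statistic)
    expect_equal(r$auc, u / (n1 * n2), tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
})

test_that("ROC orientation and Youden cutoff behave as documented", {
  v <- c(1, 2, 3, 4, 10, 11, 12, 13)
  lab <- rep(c("low", "high"), each = 4)
  auto <- rocAnalysis(v, lab)            # auto-orients to AUC >= 0.5
  expect_gte(auto$auc, 0.5)
  expect_true(auto$auto_oriented)
  forced <- rocAnalysis(v, lab, positive = "low")
  expect_equal(forced$auc, 1 - auto$auc, tolerance = 1e-12)
  expect_equal(auto$cutoff, 10)          # lowest cutoff maximizing J
  expect_error(rocAnalysis(v, rep("x", 8)), "two groups")
  # null: shuffled labels give AUC near 1/2
  set.seed(41)
  v <- rlnorm(400); lab <- sample(rep(c("a", "b"), 200))
  expect_lt(abs(rocAnalysis(v, lab, positive = "b")$auc - 0.5), 0.08)
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  v <- round(rlnorm(40), 1)
  lab <- rep(c("a", "b"), 20)
  ours <- rocAnalysis(v, lab, positive = "b")
  ref <- suppressMessages(pROC::roc(response = lab, predictor = v,
                                    levels = c("a", "b"),
                                    direction = "<"))
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("volcano classification applies inclusive fold-change and p gates", {
  ge <- data.frame(mediator = c("M1", "M2"), subgroup = "B",
                   fold = c(4, 0.2))
  spec <- SyntheticSpec(3, c(A = 14L, B = 7L), timeGrid = 0:3,
                        groupEffects = ge, latentLogSd = 0.2,
                        noiseLogSd = 0.1)
  g <- generateDataset(spec, seed = 2)
  v <- volcanoAnalysis(g$dataset, "A", "B")
  expect_equal(v$class[v$mediator == "M1"], "up")
  expect_equal(v$class[v$mediator == "M2"], "down")
  expect_equal(v$class[v$mediator == "M3"], "not-significant")
  expect_equal(v$p.value, sort(v$p.value))  # sorted by p
  # identical groups: nothing significant
  mm <- measurements(g$dataset)
  mm$subgroup <- rep(c("A", "B"), length.out = nrow(mm))
  mm$subject <- paste0(mm$subgroup, mm$subject)
  ds2 <- MediatorDataset(mm)
  v2 <- volcanoAnalysis(ds2, "A", "B")
  expect_true(all(v2$class == "not-significant"))
})

test_that("a planted 4-fold shift is classified up in almost all replicates", {
  ge <- data.frame(mediator = "M1", subgroup = "B", fold = 4)
  spec <- SyntheticSpec(1, c(A = 14L, B = 7L), timeGrid = 0:1,
                        groupEffects = ge, latentLogSd = 0,
                        noiseLogSd = 0.2)
  up <- vapply(1:60, function(sd) {
    g <- generateDataset(spec, seed = sd)
    volcanoAnalysis(g$dataset, "A", "B")$class[1] == "up"
  }, logical(1))
  expect_gte(mean(up), 0.95)
})

test_that("the fold-change boundary is inclusive", {
  # construct groups with geometric-mean ratio exactly 2 and a real shift
  a <- rep(c(10, 20), 8)
  b <- rep(c(20, 40), 8)
  ds <- MediatorDataset(data.frame(
    subject = sprintf("s%02d", seq_len(32)),
    subgroup = rep(c("A", "B"), each = 16), time = 0, mediator = "M",
    value = c(a, b)))
  v <- volcanoAnalysis(ds, "A", "B")
  expect_equal(v$fold_change, 2, tolerance = 1e-12)
  expect_lt(v$p.value, 0.05)
  expect_equal(v$class, "up")
})

test_that("mediators absent from one group are excluded with a reason", {
  ds <- MediatorDataset(data.frame(
    subject = c("a1", "a2", "b1", "b2", "a3"),
    subgroup = c("A", "A", "B", "B", "A"),
    time = 0, mediator = c("M1", "M1", "M1", "M1", "M2"),
    value = c(1, 2, 3, 4, 5)))
  v <- volcanoAnalysis(ds, "A", "B")
  expect_false("M2" %in% v$mediator)
  expect_match(attr(v, "excluded")$reason, "no data in group B")
})

test_that("per-subject covariate correlations recover a planted age trend", {
  set.seed(77)
  nsub <- 20
  age <- runif(nsub, 1, 17)
  subj <- sprintf("s%02d", seq_len(nsub))
  rows <- expand.grid(subject = subj, time = 0:2, stringsAsFactors = FALSE)
  rows$subgroup <- "G"
  rows$mediator <- "M1"
  rows$value <- exp(0.2 * age[match(rows$subject, subj)] +
                      rnorm(nrow(rows), 0, 0.1))
  ds <- MediatorDataset(rows)
  res <- covariateCorrelation(ds, setNames(age, subj))
  expect_gt(res$rho[res$mediator == "M1"], 0.8)
  expect_lt(res$p.value[res$mediator == "M1"], 0.001)
})
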