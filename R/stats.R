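#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test with midrank tie handling. The statistic is
#' U for the first sample (number of (x, y) pairs with x > y, counting ties
#' as one half). The p-value is exact (from the null distribution of U) when
#' the smaller sample has at most 8 observations and there are no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y numeric samples (each non-empty; NAs dropped)
#' @return list of class \code{"StatResult"}: \code{method},
#'   \code{statistic} (U), \code{p.value}, \code{n} (per-group sizes),
#'   \code{exact}, \code{tie_correction}
#' @export
mannWhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1)
    stop("both samples must contain at least one observation", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)
  exact <- !hasTies && min(n1, n2) <= 8
  if (exact) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieAdj)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  structure(list(method = "Mann-Whitney rank-sum", statistic = c(U = U),
                 p.value = p, n = c(n1 = n1, n2 = n2), exact = exact,
                 tie_correction = hasTies && !exact),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %s%s)\n", x$method,
              names(x$statistic)[1], x$statistic[1], x$p.value,
              paste(x$n, collapse = "/"),
              if (isTRUE(x$exact)) ", exact" else ""))
  invisible(x)
}

## all permutations of 1..n (n small), one per row
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Spearman's rho computed as the Pearson correlation of midranks on
#' complete pairs. The two-sided p-value is exact (full enumeration of the
#' permutation null) for n <= 8 complete pairs and a t-distribution
#' approximation with n - 2 degrees of freedom otherwise.
#'
#' @param x,y paired numeric samples; at least 3 complete pairs required
#' @return list of class \code{"StatResult"} with \code{statistic} = rho
#' @export
spearmanTest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("spearman correlation requires at least 3 complete pairs",
         call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant sample: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rx, ry)
  exact <- n <= 8
  if (exact) {
    perms <- .permutations(n)
    rhoNull <- as.vector(stats::cor(rx, t(matrix(ry[perms], nrow(perms)))))
    p <- mean(abs(rhoNull) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  structure(list(method = "Spearman rank correlation",
                 statistic = c(rho = rho), p.value = p, n = c(n = n),
                 exact = exact, tie_correction = anyDuplicated(x) > 0 ||
                   anyDuplicated(y) > 0),
            class = "StatResult")
}

#' ROC curve and AUC for a two-group biomarker
#'
#' Builds the full ROC curve over all observed thresholds (classifying a
#' sample as positive when its value is >= the cutoff), computes the area
#' under the curve by the trapezoid rule -- which equals the normalized
#' Mann-Whitney U statistic with ties counted as one half -- and reports the
#' cutoff maximizing Youden's J = TPR - FPR (ties broken toward the lowest
#' cutoff). If no positive group is specified, orientation is chosen
#' automatically so that AUC >= 0.5 and recorded.
#'
#' @param values numeric biomarker measurements
#' @param labels group label per value (exactly two levels present)
#' @param positive label treated as the positive (case) group; default
#'   auto-oriented
#' @return list of class \code{"RocResult"}: \code{auc}, \code{roc}
#'   (data.frame cutoff/fpr/tpr), \code{cutoff}, \code{positive},
#'   \code{auto_oriented}
#' @export
rocAnalysis <- function(values, labels, positive = NULL) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("ROC requires exactly two groups, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  auto <- is.null(positive)
  if (auto) positive <- lev[1]
  if (!positive %in% lev) stop("unknown positive label", call. = FALSE)
  build <- function(pos) {
    isPos <- labels == pos
    nP <- sum(isPos); nN <- sum(!isPos)
    cuts <- sort(unique(values), decreasing = TRUE)
    tpr <- vapply(cuts, function(c) sum(values[isPos] >= c) / nP, numeric(1))
    fpr <- vapply(cuts, function(c) sum(values[!isPos] >= c) / nN, numeric(1))
    roc <- data.frame(cutoff = c(Inf, cuts), fpr = c(0, fpr),
                      tpr = c(0, tpr))
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
    list(roc = roc, auc = auc)
  }
  b <- build(positive)
  if (auto && b$auc < 0.5) {
    positive <- setdiff(lev, positive)
    b <- build(positive)
  }
  j <- b$roc$tpr - b$roc$fpr
  best <- which(j == max(j))
  cutoff <- min(b$roc$cutoff[best])
  structure(list(auc = b$auc, roc = b$roc, cutoff = cutoff,
                 positive = positive, auto_oriented = auto),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positive = %s%s), optimal cutoff = %.4g\n",
              x$auc, x$positive,
              if (x$auto_oriented) ", auto-oriented" else "", x$cutoff))
  invisible(x)
}

#' Volcano classification of mediators between two groups
#'
#' Per mediator, the fold change is the ratio of geometric means (group B
#' over group A, positive values only, all time points pooled) and the
#' p-value comes from the Mann-Whitney rank-sum test on the pooled values.
#' A mediator is classified \code{"up"} when the fold change is >= the
#' threshold (inclusive) with p < alpha, \code{"down"} when the fold change
#' is <= 1/threshold with p < alpha, and \code{"not-significant"} otherwise.
#' No multiple-testing correction is applied. Pooling time points treats
#' repeated measures of one subject as independent samples; results carry a
#' \code{pooled_time_points} flag to make that pseudo-replication explicit.
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param groupA,groupB subgroup labels (fold change is B over A)
#' @param fcThreshold fold-change threshold, default 2.0
#' @param alpha significance level, default 0.05
#' @return data.frame(mediator, log2fc, fold_change, p.value, class) of
#'   class \code{"VolcanoResult"}, sorted by p-value; attribute
#'   \code{"excluded"} lists mediators absent from one group.
#' @export
volcanoAnalysis <- function(ds, groupA, groupB, fcThreshold = 2.0,
                            alpha = 0.05) {
  .checkSubgroup(ds, groupA); .checkSubgroup(ds, groupB)
  m <- ds@measurements
  out <- list(); excl <- list()
  for (med in ds@mediators) {
    a <- m$value[m$subgroup == groupA & m$mediator == med]
    b <- m$value[m$subgroup == groupB & m$mediator == med]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      excl[[length(excl) + 1]] <- data.frame(
        mediator = med,
        reason = paste0("no data in group ",
                        if (length(a) == 0) groupA else groupB))
      next
    }
    ga <- exp(mean(log(a[a > 0]))); gb <- exp(mean(log(b[b > 0])))
    fc <- gb / ga
    p <- mannWhitney(b, a)$p.value
    ## inclusive threshold, with a relative guard so that a fold change
    ## equal to the threshold up to floating error still classifies
    eps <- 1e-9
    cls <- if (fc >= fcThreshold * (1 - eps) && p < alpha) "up"
           else if (fc <= 1 / fcThreshold * (1 + eps) && p < alpha) "down"
           else "not-significant"
    out[[length(out) + 1]] <- data.frame(
      mediator = med, log2fc = log2(fc), fold_change = fc, p.value = p,
      class = cls, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mediator = character(), log2fc = numeric(),
               fold_change = numeric(), p.value = numeric(),
               class = character(), stringsAsFactors = FALSE)
  res <- res[order(res$p.value), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  attr(res, "groups") <- c(A = groupA, B = groupB)
  attr(res, "pooled_time_points") <- TRUE
  class(res) <- c("VolcanoResult", "data.frame")
  res
}

#' Spearman correlation of each mediator against a subject covariate
#'
#' Correlates per-subject mediator summaries (the median over time by
#' default) against a numeric covariate such as age, one mediator at a time.
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param covariate named numeric vector, names = subject ids
#' @param subgroup optional subgroup restriction
#' @param summary per-subject summary function over time (default median)
#' @return data.frame(mediator, rho, p.value, n)
#' @export
covariateCorrelation <- function(ds, covariate, subgroup = NULL,
                                 summary = stats::median) {
  m <- ds@measurements
  if (!is.null(subgroup)) {
    .checkSubgroup(ds, subgroup)
    m <- m[m$subgroup == subgroup, , drop = FALSE]
  }
  out <- list()
  for (med in ds@mediators) {
    mm <- m[m$mediator == med & !is.na(m$value), , drop = FALSE]
    if (nrow(mm) == 0) next
    per <- tapply(mm$value, mm$subject, summary)
    subj <- intersect(names(per), names(covariate))
    if (length(subj) < 3) next
    st <- spearmanTest(covariate[subj], unname(per[subj]))
    out[[length(out) + 1]] <- data.frame(
      mediator = med, rho = unname(st$statistic), p.value = st$p.value,
      n = length(subj), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mediator = character(), rho = numeric(),
               p.value = numeric(), n = integer())
}
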