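# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: correlations by explicit sums, rank
# statistics by pair enumeration, marginal likelihoods by numerical
# integration / importance sampling over the Normal-Wishart prior.

# --- tiny random dataset builder -------------------------------------------

randomDataset <- function(nMediators, nTimes, nSubjects, subgroup = "G",
                          missing = 0) {
  med <- paste0("X", seq_len(nMediators))
  rows <- expand.grid(subject = sprintf("s%02d", seq_len(nSubjects)),
                      time = seq_len(nTimes) - 1, mediator = med,
                      stringsAsFactors = FALSE)
  rows$subgroup <- subgroup
  rows$value <- exp(rnorm(nrow(rows), mean = 3, sd = 0.6))
  if (missing > 0) rows$value[runif(nrow(rows)) < missing] <- NA
  rows <- rows[!is.na(rows$value), ]
  MediatorDataset(rows, mediators = med, timeGrid = seq_len(nTimes) - 1)
}

# --- brute-force DyNA -------------------------------------------------------

# Pearson r by the textbook sums formula
bfPearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) return(NA_real_)
  num / den
}

# edge set for one subgroup, by direct filtering of the long table
bfEdges <- function(ds, subgroup, threshold = 0.85, minPairs = 4) {
  m <- measurements(ds)
  tg <- timeGrid(ds)
  med <- mediators(ds)
  out <- list()
  for (k in seq_len(length(tg) - 1)) {
    for (i in seq_along(med)) for (j in seq_along(med)) {
      if (j <= i) next
      get <- function(mm) {
        rows <- m[m$subgroup == subgroup & m$mediator == mm &
                    m$time %in% c(tg[k], tg[k + 1]), ]
        setNames(rows$value, paste(rows$subject, rows$time))
      }
      a <- get(med[i]); b <- get(med[j])
      key <- intersect(names(a), names(b))
      a <- a[key]; b <- b[key]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < minPairs) next
      r <- bfPearson(a[ok], b[ok])
      if (!is.na(r) && abs(r) >= threshold)
        out[[length(out) + 1]] <- data.frame(
          interval = k, mediator_a = med[i], mediator_b = med[j], r = r)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(interval = integer(), mediator_a = character(),
               mediator_b = character(), r = numeric())
}

edgeKey <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$interval, pmin(df$mediator_a, df$mediator_b),
             pmax(df$mediator_a, df$mediator_b)))
}

# --- rank-statistic oracles -------------------------------------------------

# exact Mann-Whitney p by enumerating all group assignments
bfMannWhitneyP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  uStat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u0 <- uStat(seq_len(n1))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, uStat)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u0 - mu) - 1e-9)
}

# U by direct pair counting (wins + half-ties)
bfU <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

# --- Normal-Wishart marginal-likelihood oracles -----------------------------

# 1-D case by nested quadrature over (mean, precision)
quadMarginal1D <- function(x, hyper) {
  al <- hyper$alphaW - hyper$d + 1   # subset dof for l = 1
  am <- hyper$alphaMu
  t0 <- hyper$t0
  # w ~ Gamma(al/2, rate = t0/2); mu | w ~ N(0, 1/(am w))
  inner <- function(w) {
    f <- function(mu) {
      exp(sum(dnorm(x, mu, 1 / sqrt(w), log = TRUE)) +
            dnorm(mu, 0, 1 / sqrt(am * w), log = TRUE))
    }
    integrate(Vectorize(f), -Inf, Inf, rel.tol = 1e-10)$value
  }
  f_w <- function(w)
    vapply(w, function(wi) inner(wi) * dgamma(wi, al / 2, rate = t0 / 2),
           numeric(1))
  log(integrate(f_w, 0, Inf, rel.tol = 1e-10)$value)
}

logIWishart <- function(S, Psi, nu) {
  p <- ncol(S)
  lmv <- p * (p - 1) / 4 * log(pi) +
    sum(lgamma(nu / 2 + (1 - seq_len(p)) / 2))
  nu / 2 * determinant(Psi)$modulus - (nu * p / 2) * log(2) - lmv -
    (nu + p + 1) / 2 * determinant(S)$modulus -
    0.5 * sum(diag(solve(S, Psi)))
}

logMvn <- function(x, mu, Sigma) {
  p <- length(mu)
  ch <- chol(Sigma)
  d <- backsolve(ch, x - mu, transpose = TRUE)
  -p / 2 * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(d^2)
}

# Marginal likelihood of an N x l data matrix under the subset-adjusted
# Normal-Wishart prior, by importance sampling with a conjugate
# normal-inverse-Wishart proposal. The proposal parameters come from the
# textbook conjugate update; the estimate itself is pure numerical
# integration of prior x likelihood, so it is an independent check of any
# closed-form expression.
isMarginal <- function(Z, hyper, nDraws = 4e4, seed = 42) {
  set.seed(seed)
  Z <- as.matrix(Z)
  N <- nrow(Z); l <- ncol(Z)
  al <- hyper$alphaW - hyper$d + l
  am <- hyper$alphaMu
  Psi0 <- diag(hyper$t0, l)
  xbar <- colMeans(Z)
  S <- crossprod(sweep(Z, 2, xbar))
  kN <- am + N
  mN <- N * xbar / kN
  nuN <- al + N
  PsiN <- Psi0 + S + am * N / kN * tcrossprod(xbar)
  # draw Sigma ~ IW(PsiN, nuN) via Wishart on the precision
  Ws <- stats::rWishart(nDraws, df = nuN, Sigma = solve(PsiN))
  logw <- vapply(seq_len(nDraws), function(i) {
    Sigma <- solve(Ws[, , i])
    Sigma <- (Sigma + t(Sigma)) / 2
    mu <- drop(mN + t(chol(Sigma / kN)) %*% rnorm(l))
    loglik <- sum(vapply(seq_len(N), function(r)
      logMvn(Z[r, ], mu, Sigma), numeric(1)))
    lprior <- logIWishart(Sigma, Psi0, al) + logMvn(mu, rep(0, l), Sigma / am)
    lprop <- logIWishart(Sigma, PsiN, nuN) + logMvn(mu, mN, Sigma / kN)
    loglik + lprior - lprop
  }, numeric(1))
  mx <- max(logw)
  mx + log(mean(exp(logw - mx)))
}
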