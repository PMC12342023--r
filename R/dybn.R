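#' BGe hyperparameters
#'
#' Normal-Wishart prior for the Bayesian Gaussian equivalent (BGe) score on
#' z-scored data: prior mean zero with precision scale \code{alphaMu},
#' Wishart degrees of freedom \code{alphaW} and diagonal prior scale matrix
#' \code{t0 * I}. Subsets of size l are scored with degrees of freedom
#' \code{alphaW - d + l} (the adjustment that makes the per-family
#' decomposition score-equivalent across Markov-equivalent structures).
#'
#' @param d panel dimension (number of mediators)
#' @param alphaMu prior precision on the mean (> 0); default 1
#' @param alphaW Wishart degrees of freedom (>= d); default d + 2
#' @param t0 diagonal entry of the prior scale matrix; default 0.5
#' @return list of class \code{"BgeHyperparams"}
#' @export
bgeHyperparams <- function(d, alphaMu = 1, alphaW = d + 2, t0 = 0.5) {
  stopifnot(alphaMu > 0, alphaW >= d, t0 > 0)
  structure(list(d = as.integer(d), alphaMu = alphaMu, alphaW = alphaW,
                 t0 = t0), class = "BgeHyperparams")
}

#' Changepoint configuration
#'
#' Node-specific changepoints split a node's transitions by source time
#' index; the network structure is held fixed across segments and only the
#' Gaussian parameters change. The number of changepoints per node carries a
#' truncated Poisson prior and locations are uniform over admissible subsets.
#'
#' @param kMax maximum changepoints per node (>= 0); default 1 (mediator
#'   series have 5-8 time points and cannot support many segments)
#' @param minSegment minimum transitions per segment; default 2
#' @param lambda Poisson rate of the changepoint-count prior; default 1
#' @return list of class \code{"ChangepointConfig"}
#' @export
cpConfig <- function(kMax = 1, minSegment = 2, lambda = 1) {
  stopifnot(kMax >= 0, minSegment >= 1, lambda > 0)
  structure(list(kMax = as.integer(kMax), minSegment = as.integer(minSegment),
                 lambda = lambda), class = "ChangepointConfig")
}

#' Build the pooled transition table for one subgroup
#'
#' Z-scores each mediator (natural-log transform then standardization, via
#' \code{\link{zscoreByMediator}}) over the subgroup, then forms lag-1
#' transitions (x_t, x_{t+1}) from strictly consecutive sampled time-grid
#' points per subject; a gap in a subject's series breaks the chain rather
#' than bridging it. Transitions are pooled across subjects; rows with
#' missing values are retained and dropped per family at scoring time.
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param subgroup subgroup label
#' @param log log-transform before standardizing (default TRUE)
#' @return list of class \code{"TransitionTable"}: \code{x0}, \code{x1}
#'   (transition matrices, columns = mediators), \code{timeIndex} (source
#'   grid index per transition), \code{subject}, \code{mediators},
#'   \code{nTime} (grid length)
#' @export
buildTransitions <- function(ds, subgroup, log = TRUE) {
  .checkSubgroup(ds, subgroup)
  z <- zscoreByMediator(ds, subgroup, log = log)
  info <- attr(z, "sampleInfo")
  if (nrow(z) == 0 || length(unique(info$time)) < 2)
    stop("no transitions: subgroup '", subgroup,
         "' has fewer than 2 time points with data", call. = FALSE)
  tg <- ds@timeGrid
  gi <- match(info$time, tg)
  x0 <- list(); x1 <- list(); tix <- integer(); subj <- character()
  for (s in unique(info$subject)) {
    rows <- which(info$subject == s)
    rows <- rows[order(gi[rows])]
    g <- gi[rows]
    for (j in seq_along(rows)[-length(rows)]) {
      if (g[j + 1] == g[j] + 1) {  # strictly consecutive grid points
        x0[[length(x0) + 1]] <- z[rows[j], ]
        x1[[length(x1) + 1]] <- z[rows[j + 1], ]
        tix <- c(tix, g[j])
        subj <- c(subj, s)
      }
    }
  }
  if (length(x0) == 0)
    stop("no transitions: no consecutive sampled time points in subgroup '",
         subgroup, "'", call. = FALSE)
  x0 <- do.call(rbind, x0); x1 <- do.call(rbind, x1)
  med <- colnames(z)
  if (nrow(x0) < length(med) + 2)
    warning("only ", nrow(x0), " transitions for ", length(med),
            " mediators: posterior will be prior-dominated", call. = FALSE)
  structure(list(x0 = x0, x1 = x1, timeIndex = tix, subject = subj,
                 mediators = med, nTime = length(tg)),
            class = "TransitionTable")
}

## log multivariate gamma function
.lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Log marginal likelihood of a variable subset under the Normal-Wishart prior
#'
#' Closed-form marginal of N iid l-dimensional Gaussian observations with
#' zero prior mean (precision scale alphaMu), Wishart degrees of freedom
#' alphaW - d + l and scale t0*I. Internal building block of the BGe family
#' score.
#' @noRd
.logSubsetMarginal <- function(Z, hyper) {
  l <- ncol(Z)
  if (l == 0L) return(0)
  N <- nrow(Z)
  if (N == 0L) return(0)
  al <- hyper$alphaW - hyper$d + l
  am <- hyper$alphaMu
  xbar <- colMeans(Z)
  Zc <- sweep(Z, 2, xbar)
  S <- crossprod(Zc)
  TN <- diag(hyper$t0, l) + S + (am * N / (am + N)) * tcrossprod(xbar)
  ch <- tryCatch(chol(TN), error = function(e) NULL)
  if (is.null(ch))
    stop("singular posterior scale matrix (condition number ",
         format(kappa(TN), digits = 3), ")", call. = FALSE)
  ldTN <- 2 * sum(log(diag(ch)))
  ldT0 <- l * log(hyper$t0)
  -l * N / 2 * log(pi) + l / 2 * (log(am) - log(am + N)) +
    .lmvgamma((al + N) / 2, l) - .lmvgamma(al / 2, l) +
    al / 2 * ldT0 - (al + N) / 2 * ldTN
}

#' Normal-Wishart marginal likelihood of a data matrix
#'
#' Closed-form log marginal likelihood of N observations of an l-variable
#' Gaussian under the package's Normal-Wishart prior (zero prior mean with
#' precision scale \code{alphaMu}; Wishart degrees of freedom
#' \code{alphaW - d + l} and scale \code{t0 * I} for an l-column subset of a
#' d-variable panel). This is the building block of the BGe score: the score
#' of a child with parents is the marginal of the family columns minus the
#' marginal of the parent columns, which makes Markov-equivalent structures
#' over the same variables score identically (e.g. for a complete two-node
#' family, score(X) + score(Y|X) = score(Y) + score(X|Y) exactly).
#'
#' @param Z numeric matrix (rows = observations, columns = variables)
#' @param hyper \code{\link{bgeHyperparams}} for the full panel
#' @return log marginal likelihood (0 for zero rows or zero columns)
#' @export
bgeMarginalLikelihood <- function(Z, hyper) {
  Z <- as.matrix(Z)
  .logSubsetMarginal(Z, hyper)
}

#' BGe family score
#'
#' Log marginal likelihood contribution of one child given a parent set over
#' a subset of transitions, under the Normal-Wishart prior: the score of the
#' family {child(t+1)} with parents(t) minus the score of the parents alone
#' (the Geiger-Heckerman family decomposition). Transitions with a missing
#' value in any family column are dropped. An empty segment scores exactly 0.
#'
#' @param tt a \code{TransitionTable} from \code{\link{buildTransitions}}
#' @param child child mediator name
#' @param parents character vector of parent names (may include the child
#'   itself: a self-loop) or empty
#' @param rows transition indices forming the segment; default all
#' @param hyper \code{\link{bgeHyperparams}}; default for the panel
#' @return log marginal likelihood contribution (numeric scalar)
#' @export
bgeFamilyScore <- function(tt, child, parents = character(),
                           rows = seq_len(nrow(tt$x0)),
                           hyper = bgeHyperparams(length(tt$mediators))) {
  ci <- match(child, tt$mediators)
  pi_ <- match(parents, tt$mediators)
  if (anyNA(c(ci, pi_))) stop("unknown mediator in family", call. = FALSE)
  if (length(rows) == 0) return(0)
  Y <- tt$x1[rows, ci, drop = FALSE]
  X <- tt$x0[rows, pi_, drop = FALSE]
  ok <- stats::complete.cases(cbind(Y, X))
  Zfam <- cbind(Y[ok, , drop = FALSE], X[ok, , drop = FALSE])
  if (nrow(Zfam) == 0) return(0)
  .logSubsetMarginal(Zfam, hyper) -
    .logSubsetMarginal(X[ok, , drop = FALSE], hyper)
}

## segment row indices from sorted changepoint locations (source-time grid
## indices in 2..nTime-1); boundaries partition transitions by timeIndex
.segmentRows <- function(tt, cps) {
  bounds <- c(1L, sort(cps), tt$nTime)  # timeIndex ranges over 1..nTime-1
  lapply(seq_len(length(bounds) - 1L), function(j) {
    which(tt$timeIndex >= bounds[j] & tt$timeIndex < bounds[j + 1L])
  })
}

.cpAdmissible <- function(tt, cps, cp) {
  segs <- .segmentRows(tt, cps)
  all(vapply(segs, length, 1L) >= cp$minSegment)
}

## log prior of a node's changepoint configuration: truncated Poisson count,
## uniform locations
.cpLogPrior <- function(k, nLoc, cp) {
  if (cp$kMax == 0) return(0)
  lp <- stats::dpois(0:cp$kMax, cp$lambda, log = TRUE)
  lognorm <- max(lp) + log(sum(exp(lp - max(lp))))
  stats::dpois(k, cp$lambda, log = TRUE) - lognorm - lchoose(nLoc, k)
}

## number of parent sets of size <= fanIn from M candidates (uniform
## structure prior normalizer)
.nParentSets <- function(M, fanIn) {
  sum(choose(M, 0:min(fanIn, M)))
}

#' Total log score of a network with node-specific changepoints
#'
#' Sum over nodes and their segments of \code{\link{bgeFamilyScore}}, plus
#' the log structure prior (uniform over parent sets within the fan-in
#' limit) and the log changepoint prior (truncated Poisson count, uniform
#' locations).
#'
#' @param structure named list mapping each mediator to its parent names
#' @param changepoints named list mapping each mediator to a (possibly
#'   empty) vector of changepoint grid indices in \code{2..nTime-1}
#' @param tt a \code{TransitionTable}
#' @param hyper \code{\link{bgeHyperparams}}
#' @param cp \code{\link{cpConfig}}
#' @param fanIn fan-in limit used by the structure prior
#' @return total log score (numeric scalar)
#' @export
networkLogScore <- function(structure, changepoints = NULL, tt,
                            hyper = bgeHyperparams(length(tt$mediators)),
                            cp = cpConfig(), fanIn = 3) {
  med <- tt$mediators
  if (is.null(changepoints))
    changepoints <- stats::setNames(rep(list(integer()), length(med)), med)
  nLoc <- max(0L, tt$nTime - 2L)
  total <- 0
  for (m in med) {
    pars <- structure[[m]]
    if (length(pars) > fanIn)
      stop("parent set of ", m, " exceeds fan-in ", fanIn, call. = FALSE)
    cps <- as.integer(changepoints[[m]])
    if (length(cps) > cp$kMax)
      stop("changepoint count of ", m, " exceeds kMax", call. = FALSE)
    segs <- .segmentRows(tt, cps)
    if (any(vapply(segs, length, 1L) < cp$minSegment) && length(cps) > 0)
      stop("segmentation of ", m, " violates the minimum segment length",
           call. = FALSE)
    for (rows in segs)
      total <- total + bgeFamilyScore(tt, m, pars, rows, hyper)
    total <- total - log(.nParentSets(length(med), fanIn)) +
      .cpLogPrior(length(cps), nLoc, cp)
  }
  total
}

#' Exact posterior edge probabilities by exhaustive enumeration
#'
#' For the homogeneous model (no changepoints) the families are independent,
#' so the posterior over each child's parent set is a softmax of BGe family
#' scores over all sets within the fan-in limit. Feasible for small panels;
#' used to validate the MCMC sampler.
#'
#' @param tt a \code{TransitionTable}
#' @param fanIn fan-in limit
#' @param hyper \code{\link{bgeHyperparams}}
#' @return matrix of posterior probabilities, rows = parents, cols = children
#' @export
dybnExact <- function(tt, fanIn = 2,
                      hyper = bgeHyperparams(length(tt$mediators))) {
  med <- tt$mediators
  M <- length(med)
  sets <- list(integer())
  for (k in seq_len(min(fanIn, M)))
    sets <- c(sets, utils::combn(M, k, simplify = FALSE))
  P <- matrix(0, M, M, dimnames = list(med, med))
  for (ci in seq_len(M)) {
    sc <- vapply(sets, function(s)
      bgeFamilyScore(tt, med[ci], med[s], hyper = hyper), numeric(1))
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (j in seq_along(sets)) P[sets[[j]], ci] <- P[sets[[j]], ci] + w[j]
  }
  P
}

#' MCMC over network structures and node-specific changepoints
#'
#' Metropolis-Hastings sampler for a first-order dynamic Bayesian network
#' with BGe scoring and node-specific changepoints. Structure moves
#' add/remove/swap one parent of a uniformly chosen node; changepoint moves
#' are birth/death/relocation of one changepoint; proposal ratios preserve
#' detailed balance. Structures are not subject to an acyclicity constraint
#' (edges point from t to t+1), so self-loops are admissible parents and
#' families are independent given the segmentation. Edge posteriors are
#' inclusion frequencies over retained samples.
#'
#' @param tt a \code{TransitionTable} from \code{\link{buildTransitions}}
#' @param hyper \code{\link{bgeHyperparams}}
#' @param cp \code{\link{cpConfig}}
#' @param iterations total MCMC sweeps; must exceed \code{burnIn}
#' @param burnIn discarded initial sweeps
#' @param thinning keep every \code{thinning}-th sweep after burn-in
#' @param fanIn maximum parents per node (default 3)
#' @param seed RNG seed (the sampler is deterministic given the seed)
#' @return a \linkS4class{DybnPosterior}
#' @export
dybnSample <- function(tt, hyper = bgeHyperparams(length(tt$mediators)),
                       cp = cpConfig(), iterations = 20000, burnIn = 5000,
                       thinning = 1, fanIn = 3, seed = 1) {
  if (iterations <= burnIn)
    stop("config error: iterations must exceed burnIn", call. = FALSE)
  if (fanIn < 1) stop("config error: fanIn must be >= 1", call. = FALSE)
  med <- tt$mediators
  M <- length(med)
  nLoc <- max(0L, tt$nTime - 2L)
  set.seed(seed)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  nhit <- 0L; nmiss <- 0L
  dataScore <- function(ci, pars, cps) {
    key <- paste(ci, paste(pars, collapse = ","),
                 paste(cps, collapse = "-"), sep = "|")
    v <- cache[[key]]
    if (!is.null(v)) { nhit <<- nhit + 1L; return(v) }
    nmiss <<- nmiss + 1L
    s <- 0
    for (rows in .segmentRows(tt, cps))
      s <- s + bgeFamilyScore(tt, med[ci], med[pars], rows, hyper)
    cache[[key]] <- s
    s
  }

  parents <- rep(list(integer()), M)
  cps <- rep(list(integer()), M)
  nodeScore <- vapply(seq_len(M), function(ci)
    dataScore(ci, integer(), integer()), numeric(1))
  nodeCpPrior <- rep(.cpLogPrior(0L, nLoc, cp), M)

  edgeCount <- matrix(0, M, M, dimnames = list(med, med))
  cpCount <- matrix(0, cp$kMax + 1L, M,
                    dimnames = list(0:cp$kMax, med))
  locFreq <- matrix(0, max(nLoc, 1L), M)
  acc <- c(structure = 0, cp = 0); prop <- c(structure = 0, cp = 0)
  accBurn <- 0; propBurn <- 0
  nkeep <- 0L
  trace <- numeric()
  structPriorConst <- -M * log(.nParentSets(M, fanIn))
  pStruct <- if (cp$kMax > 0 && nLoc > 0) 0.65 else 1

  for (it in seq_len(iterations)) {
    ci <- sample.int(M, 1)
    if (stats::runif(1) < pStruct) {
      ## -------- structure move --------
      prop["structure"] <- prop["structure"] + 1
      P <- parents[[ci]]
      out <- setdiff(seq_len(M), P)
      types <- c(if (length(P) < fanIn && length(out) > 0) "add",
                 if (length(P) > 0) "remove",
                 if (length(P) > 0 && length(out) > 0) "swap")
      if (length(types) == 0) next
      type <- if (length(types) == 1) types else sample(types, 1)
      if (type == "add") {
        p <- if (length(out) == 1) out else sample(out, 1)
        Pn <- sort(c(P, p))
        nChoiceF <- length(out)
        newOut <- M - length(Pn)
        typesN <- c(if (length(Pn) < fanIn && newOut > 0) "add", "remove",
                    if (newOut > 0) "swap")
        nChoiceR <- length(Pn)          # reverse = remove
      } else if (type == "remove") {
        p <- if (length(P) == 1) P else sample(P, 1)
        Pn <- setdiff(P, p)
        nChoiceF <- length(P)
        newOut <- M - length(Pn)
        typesN <- c(if (length(Pn) < fanIn && newOut > 0) "add",
                    if (length(Pn) > 0) "remove",
                    if (length(Pn) > 0 && newOut > 0) "swap")
        nChoiceR <- newOut              # reverse = add
      } else {
        p <- if (length(P) == 1) P else sample(P, 1)
        q <- if (length(out) == 1) out else sample(out, 1)
        Pn <- sort(c(setdiff(P, p), q))
        nChoiceF <- length(P) * length(out)
        typesN <- types                 # same sizes either side
        nChoiceR <- nChoiceF            # reverse = swap back
      }
      newScore <- dataScore(ci, Pn, cps[[ci]])
      logA <- (newScore - nodeScore[ci]) +
        log(length(types)) + log(nChoiceF) -
        log(length(typesN)) - log(nChoiceR)
      if (is.finite(logA) && log(stats::runif(1)) < logA) {
        parents[[ci]] <- Pn
        nodeScore[ci] <- newScore
        acc["structure"] <- acc["structure"] + 1
        if (it <= burnIn) accBurn <- accBurn + 1
      }
      if (it <= burnIn) propBurn <- propBurn + 1
    } else {
      ## -------- changepoint move --------
      prop["cp"] <- prop["cp"] + 1
      cc <- cps[[ci]]
      k <- length(cc)
      locs <- 2:(tt$nTime - 1)
      free <- setdiff(locs, cc)
      types <- c(if (k < cp$kMax && length(free) > 0) "birth",
                 if (k > 0) "death",
                 if (k > 0 && length(free) > 0) "move")
      if (length(types) == 0) next
      type <- if (length(types) == 1) types else sample(types, 1)
      if (type == "birth") {
        loc <- if (length(free) == 1) free else sample(free, 1)
        ccn <- sort(c(cc, loc))
        qf <- -log(length(types)) - log(length(free))
        typesN <- c(if (k + 1 < cp$kMax && length(free) > 1) "birth",
                    "death", if (length(free) > 1) "move")
        qr <- -log(length(typesN)) - log(k + 1)
      } else if (type == "death") {
        loc <- if (k == 1) cc else sample(cc, 1)
        ccn <- setdiff(cc, loc)
        qf <- -log(length(types)) - log(k)
        freeN <- length(free) + 1
        typesN <- c(if (k - 1 < cp$kMax && freeN > 0) "birth",
                    if (k > 1) "death", if (k > 1 && freeN > 0) "move")
        qr <- -log(length(typesN)) - log(freeN)
      } else {
        old <- if (k == 1) cc else sample(cc, 1)
        loc <- if (length(free) == 1) free else sample(free, 1)
        ccn <- sort(c(setdiff(cc, old), loc))
        qf <- -log(length(types)) - log(k) - log(length(free))
        qr <- qf                         # same counts after relocation
      }
      if (!.cpAdmissible(tt, ccn, cp)) { if (it <= burnIn) propBurn <- propBurn + 1; next }
      newScore <- dataScore(ci, parents[[ci]], ccn)
      newPrior <- .cpLogPrior(length(ccn), nLoc, cp)
      logA <- (newScore + newPrior) - (nodeScore[ci] + nodeCpPrior[ci]) +
        qr - qf
      if (is.finite(logA) && log(stats::runif(1)) < logA) {
        cps[[ci]] <- ccn
        nodeScore[ci] <- newScore
        nodeCpPrior[ci] <- newPrior
        acc["cp"] <- acc["cp"] + 1
        if (it <= burnIn) accBurn <- accBurn + 1
      }
      if (it <= burnIn) propBurn <- propBurn + 1
    }

    if (it > burnIn && (it - burnIn) %% thinning == 0) {
      nkeep <- nkeep + 1L
      for (j in seq_len(M)) {
        Pj <- parents[[j]]
        if (length(Pj)) edgeCount[Pj, j] <- edgeCount[Pj, j] + 1
        kj <- length(cps[[j]])
        cpCount[kj + 1L, j] <- cpCount[kj + 1L, j] + 1
        if (kj > 0) locFreq[cps[[j]] - 1L, j] <- locFreq[cps[[j]] - 1L, j] + 1
      }
      if (nkeep %% 50 == 1)
        trace <- c(trace, sum(nodeScore) + sum(nodeCpPrior) + structPriorConst)
    }
  }

  if (propBurn > 0 && accBurn / propBurn < 0.01)
    warning("MCMC acceptance rate below 1% during burn-in; ",
            "check scaling and proposal settings", call. = FALSE)

  cpl <- lapply(seq_len(M), function(j) {
    list(countDist = stats::setNames(cpCount[, j] / max(nkeep, 1L),
                                     rownames(cpCount)),
         locationFreq = if (nLoc > 0)
           stats::setNames(locFreq[seq_len(nLoc), j] / max(nkeep, 1L),
                           2:(tt$nTime - 1)) else numeric())
  })
  names(cpl) <- med
  methods::new("DybnPosterior",
    edgeProb = edgeCount / max(nkeep, 1L),
    mediators = med,
    changepoints = cpl,
    diagnostics = list(
      acceptanceRate = ifelse(prop > 0, acc / prop, NA_real_),
      logScoreTrace = trace,
      cache = c(hits = nhit, misses = nmiss),
      nTransitions = nrow(tt$x0)),
    config = list(hyper = unclass(hyper), cp = unclass(cp),
                  mcmc = list(iterations = iterations, burnIn = burnIn,
                              thinning = thinning, fanIn = fanIn,
                              seed = seed)),
    nSamples = nkeep)
}

setMethod("show", "DybnPosterior", function(object) {
  cat("DybnPosterior\n")
  cat(sprintf("  %d mediators | %d retained samples | seed %s\n",
              length(object@mediators), object@nSamples,
              object@config$mcmc$seed))
  sl <- diag(object@edgeProb)
  top <- order(-sl)[seq_len(min(3, length(sl)))]
  cat(sprintf("  top self-loop posteriors: %s\n",
              paste(sprintf("%s=%.2f", object@mediators[top], sl[top]),
                    collapse = ", ")))
})

#' @rdname DybnPosterior-class
#' @param x a \linkS4class{DybnPosterior}
#' @export
setMethod("edgeProbabilities", "DybnPosterior", function(x) x@edgeProb)

#' Threshold a posterior into a consensus graph
#'
#' Keeps directed edges whose posterior probability reaches the threshold.
#' Nodes whose self-loop passes form the self-feedback set; self-feedback
#' nodes that are additionally connected to at least one other node (in
#' either direction) are labelled central/high-feedback nodes.
#'
#' @param x a \linkS4class{DybnPosterior}
#' @param threshold posterior threshold in the open interval (0, 1);
#'   default 0.5
#' @return a \linkS4class{ConsensusGraph}
#' @export
setMethod("consensusGraph", "DybnPosterior", function(x, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("consensus threshold must lie strictly between 0 and 1",
         call. = FALSE)
  P <- x@edgeProb
  med <- x@mediators
  hit <- which(P >= threshold, arr.ind = TRUE)
  edges <- data.frame(parent = med[hit[, 1]], child = med[hit[, 2]],
                      prob = P[hit], stringsAsFactors = FALSE)
  selfFb <- med[diag(P) >= threshold]
  hasOther <- vapply(med, function(m) {
    any(edges$parent == m & edges$child != m) ||
      any(edges$child == m & edges$parent != m)
  }, logical(1))
  central <- intersect(selfFb, med[hasOther])
  methods::new("ConsensusGraph", edges = edges, selfFeedback = selfFb,
               central = central, threshold = threshold, mediators = med)
})

setMethod("show", "ConsensusGraph", function(object) {
  cat("ConsensusGraph\n")
  cat(sprintf("  %d edges at threshold %.2f | self-feedback: %s | central: %s\n",
              nrow(object@edges), object@threshold,
              if (length(object@selfFeedback))
                paste(object@selfFeedback, collapse = ", ") else "none",
              if (length(object@central))
                paste(object@central, collapse = ", ") else "none"))
})

#' @rdname ConsensusGraph-class
#' @param x a \linkS4class{ConsensusGraph}
#' @export
setMethod("selfFeedback", "ConsensusGraph", function(x) x@selfFeedback)

#' @rdname ConsensusGraph-class
#' @export
setMethod("centralNodes", "ConsensusGraph", function(x) x@central)
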