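#' MediatorDataset: long-format repository of mediator concentration measurements
#'
#' Central container for a longitudinal mediator panel. Measurements are kept
#' in long format, keyed by (subject, time, mediator), with the mediator
#' panel, the sampling time grid and the subgroup labels held as registries
#' so that every downstream module shares one coordinate convention. Time
#' positions are numeric (days for serum panels, hours for culture
#' supernatants); display labels are kept alongside.
#'
#' @slot measurements data.frame with columns \code{subject}, \code{subgroup},
#'   \code{time} (numeric grid position), \code{mediator}, \code{value}
#'   (non-negative concentration or \code{NA}), \code{censored} (logical;
#'   \code{TRUE} when a below-detection value was substituted).
#' @slot mediators character, ordered panel of canonical mediator names.
#' @slot timeGrid numeric, strictly increasing sampling positions.
#' @slot timeLabels character, display labels parallel to \code{timeGrid}.
#' @slot subgroups character, subgroup labels present in the design.
#'
#' @aliases mediators timeGrid timeLabels subgroups measurements
#' @export
setClass("MediatorDataset",
  representation(
    measurements = "data.frame",
    mediators    = "character",
    timeGrid     = "numeric",
    timeLabels   = "character",
    subgroups    = "character"
  )
)

setValidity("MediatorDataset", function(object) {
  msg <- character()
  m <- object@measurements
  need <- c("subject", "subgroup", "time", "mediator", "value", "censored")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("measurements must have columns:", paste(need, collapse = ", ")))
  tg <- object@timeGrid
  if (length(tg) > 1 && any(diff(tg) <= 0))
    msg <- c(msg, "timeGrid must be strictly increasing")
  if (length(object@timeLabels) != length(tg))
    msg <- c(msg, "timeLabels must be parallel to timeGrid")
  if (length(msg) == 0 && nrow(m) > 0) {
    if (!all(m$mediator %in% object@mediators))
      msg <- c(msg, "measurement mediator not in panel registry")
    if (!all(m$time %in% tg))
      msg <- c(msg, "measurement time not on the time grid")
    if (!all(m$subgroup %in% object@subgroups))
      msg <- c(msg, "measurement subgroup not in subgroup registry")
    bad <- !is.na(m$value) & m$value < 0
    if (any(bad))
      msg <- c(msg, sprintf("negative concentration at row(s) %s",
                            paste(utils::head(which(bad), 5), collapse = ", ")))
    key <- paste(m$subject, m$time, m$mediator, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
      msg <- c(msg, sprintf("duplicate (subject, time, mediator) keys at rows %s",
                            paste(utils::head(d, 6), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: full parameterization of the synthetic mediator-panel generator
#'
#' Describes a generative model for multi-subject mediator time series with
#' known ground truth: per-mediator lognormal baselines, subgroup fold
#' changes, AR(1) self-feedback with optional changepoints, cross-mediator
#' lag-1 couplings, interval-local planted correlations, measurement noise
#' and missingness. See \code{\link{generateDataset}} for the model.
#'
#' @slot mediators character panel.
#' @slot subgroupSizes named integer, subjects per subgroup.
#' @slot timeGrid numeric positions; \code{timeLabels} parallel labels.
#' @slot timeLabels character.
#' @slot baselineLogMean named numeric, log-scale baseline per mediator.
#' @slot baselineLogSd numeric scalar, sd used to draw baselines for
#'   mediators without an explicit entry.
#' @slot latentLogSd numeric scalar, stationary sd of the latent log-scale
#'   process per mediator.
#' @slot groupEffects data.frame(mediator, subgroup, fold): multiplicative
#'   fold change applied on the concentration scale.
#' @slot plantedEdges data.frame(mediator_a, mediator_b, interval, r,
#'   subgroup): target observed Pearson correlation within the interval's
#'   window; \code{subgroup = NA} applies to all subgroups.
#' @slot arSelf named numeric, AR(1) coefficient per mediator (absent = 0).
#' @slot crossEdges data.frame(from, to, coef): lag-1 cross couplings.
#' @slot changepoints data.frame(mediator, time_index, new_coef): the AR
#'   coefficient switches to \code{new_coef} from that grid index onward.
#' @slot noiseLogSd numeric scalar, log-scale measurement noise sd.
#' @slot missingRate numeric in [0,1], per-measurement Bernoulli drop rate.
#' @slot seed integer default RNG seed.
#' @slot meta list of free-form metadata (e.g. \code{stylized = TRUE}).
#'
#' @export
setClass("SyntheticSpec",
  representation(
    mediators      = "character",
    subgroupSizes  = "integer",
    timeGrid       = "numeric",
    timeLabels     = "character",
    baselineLogMean = "numeric",
    baselineLogSd  = "numeric",
    latentLogSd    = "numeric",
    groupEffects   = "data.frame",
    plantedEdges   = "data.frame",
    arSelf         = "numeric",
    crossEdges     = "data.frame",
    changepoints   = "data.frame",
    noiseLogSd     = "numeric",
    missingRate    = "numeric",
    seed           = "integer",
    meta           = "list"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (length(object@timeGrid) < 2 || any(diff(object@timeGrid) <= 0))
    msg <- c(msg, "timeGrid must be strictly increasing with >= 2 points")
  if (is.null(names(object@subgroupSizes)) || any(object@subgroupSizes < 1))
    msg <- c(msg, "subgroupSizes must be a named vector of positive counts")
  if (nrow(object@plantedEdges) > 0) {
    if (any(abs(object@plantedEdges$r) > 1))
      msg <- c(msg, "planted |r| must be <= 1")
    ok <- object@plantedEdges$interval >= 1 &
          object@plantedEdges$interval <= length(object@timeGrid) - 1
    if (!all(ok)) msg <- c(msg, "planted interval index out of range")
  }
  if (length(object@arSelf) && any(abs(object@arSelf) >= 1))
    msg <- c(msg, "|AR coefficients| must be < 1")
  if (nrow(object@changepoints) > 0 && any(abs(object@changepoints$new_coef) >= 1))
    msg <- c(msg, "|changepoint AR coefficients| must be < 1")
  if (object@missingRate < 0 || object@missingRate > 1)
    msg <- c(msg, "missingRate must be in [0, 1]")
  if (object@latentLogSd < 0 || object@noiseLogSd < 0 || object@baselineLogSd < 0)
    msg <- c(msg, "log-scale sds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DynamicNetworkSet: interval-wise signed correlation networks
#'
#' Result of dynamic network analysis (DyNA): one signed undirected graph per
#' consecutive time interval over a fixed mediator panel. Edges connect
#' mediator pairs whose Pearson correlation within the interval window
#' reaches the stringency threshold in absolute value; the sign records
#' whether the pair moves in parallel (positive) or anti-parallel (negative).
#'
#' @slot edges data.frame(interval, mediator_a, mediator_b, r, sign, n_pairs).
#' @slot intervals data.frame(index, start, end, label).
#' @slot mediators character, the full analyzed panel (denominator of the
#'   complexity formula).
#' @slot threshold numeric stringency in (0, 1].
#' @slot mode \code{"levels"} (pool boundary-time samples) or
#'   \code{"differences"} (per-subject change across the interval).
#' @slot subgroup character label the networks describe.
#' @slot excluded data.frame(interval, mediator, reason) of mediators
#'   undefined in a window (zero variance, too few pairs).
#'
#' @aliases networkEdges
#' @export
setClass("DynamicNetworkSet",
  representation(
    edges     = "data.frame",
    intervals = "data.frame",
    mediators = "character",
    threshold = "numeric",
    mode      = "character",
    subgroup  = "character",
    excluded  = "data.frame"
  )
)

setValidity("DynamicNetworkSet", function(object) {
  msg <- character()
  if (length(object@threshold) != 1 || object@threshold <= 0 || object@threshold > 1)
    msg <- c(msg, "threshold must be in (0, 1]")
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(e$mediator_a == e$mediator_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(abs(e$r) < object@threshold - 1e-12))
      msg <- c(msg, "edge |r| below threshold")
    if (!all(e$sign == ifelse(e$r >= 0, "positive", "negative")))
      msg <- c(msg, "edge sign inconsistent with r")
  }
  if (length(msg)) msg else TRUE
})

#' DybnPosterior: posterior summaries from dynamic Bayesian network MCMC
#'
#' Holds per-(parent, child) posterior edge probabilities (including
#' self-loops), changepoint posterior summaries per node, sampler
#' diagnostics, and an echo of the configuration and seed so that every
#' result is reproducible.
#'
#' @slot edgeProb numeric matrix, rows = parents, cols = children, entries
#'   in [0, 1]; \code{edgeProb[i, i]} is the self-loop posterior.
#' @slot mediators character node names.
#' @slot changepoints list per node: \code{countDist} (posterior over the
#'   number of changepoints) and \code{locationFreq} (posterior inclusion
#'   frequency per candidate grid index).
#' @slot diagnostics list: acceptance rates by move type, thinned log-score
#'   trace, cache statistics.
#' @slot config list: BGe hyperparameters, changepoint configuration, MCMC
#'   settings and seed.
#' @slot nSamples integer, number of retained posterior samples.
#'
#' @aliases edgeProbabilities
#' @export
setClass("DybnPosterior",
  representation(
    edgeProb     = "matrix",
    mediators    = "character",
    changepoints = "list",
    diagnostics  = "list",
    config       = "list",
    nSamples     = "integer"
  )
)

setValidity("DybnPosterior", function(object) {
  msg <- character()
  p <- object@edgeProb
  if (nrow(p) != ncol(p) || nrow(p) != length(object@mediators))
    msg <- c(msg, "edgeProb must be square over the mediator panel")
  if (any(p < -1e-12 | p > 1 + 1e-12))
    msg <- c(msg, "edge probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConsensusGraph: thresholded directed consensus network
#'
#' Directed graph of lag-1 influences whose posterior probability reaches the
#' consensus threshold. Nodes whose self-loop passes the threshold form the
#' self-feedback set; self-feedback nodes that are additionally connected to
#' at least one other node are labelled central (high-feedback) nodes.
#'
#' @slot edges data.frame(parent, child, prob), self-loops included.
#' @slot selfFeedback character, nodes with self-loop posterior >= threshold.
#' @slot central character, self-feedback nodes with >= 1 connection to
#'   another node.
#' @slot threshold numeric in (0, 1).
#' @slot mediators character panel.
#'
#' @aliases selfFeedback centralNodes
#' @export
setClass("ConsensusGraph",
  representation(
    edges        = "data.frame",
    selfFeedback = "character",
    central      = "character",
    threshold    = "numeric",
    mediators    = "character"
  )
)

setValidity("ConsensusGraph", function(object) {
  if (length(object@threshold) != 1 ||
      object@threshold <= 0 || object@threshold >= 1)
    return("threshold must be in the open interval (0, 1)")
  TRUE
})
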