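#' Built-in mediator panels
#'
#' Canonical panels for the two study designs the generator emulates: a
#' 28-mediator human serum panel (26 multiplex analytes plus HMGB1 and
#' NO2-/NO3-) and a 23-mediator mouse hepatocyte-supernatant panel
#' (20 multiplex analytes plus HMGB1, NO2-/NO3- and GDF-15).
#'
#' @param panel \code{"human"} or \code{"mouse"}
#' @return character vector of canonical mediator names
#' @export
mediatorPanel <- function(panel = c("human", "mouse")) {
  panel <- match.arg(panel)
  human26 <- c("Eotaxin", "GDF-15", "GM-CSF", "IFN-a2", "IFN-g", "IL-1b",
               "IL-1RA", "IL-2", "sIL-2Ra", "IL-4", "IL-5", "IL-6", "IL-7",
               "IL-8", "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-15",
               "IL-17A", "IP-10", "MCP-1", "MIG", "MIP-1a", "MIP-1b",
               "TNF-a")
  mouse20 <- c("GM-CSF", "IFN-g", "IL-1a", "IL-1b", "IL-2", "IL-4", "IL-5",
               "IL-6", "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-17",
               "IP-10", "KC", "MCP-1", "MIG", "MIP-1a", "TNF-a", "VEGF")
  switch(panel,
         human = c(human26, "HMGB1", "NO2-/NO3-"),
         mouse = c(mouse20, "HMGB1", "NO2-/NO3-", "GDF-15"))
}

#' Construct a SyntheticSpec
#'
#' See \linkS4class{SyntheticSpec} for slot semantics and
#' \code{\link{generateDataset}} for the generative model.
#'
#' @param mediators character panel (or a count, which names mediators
#'   \code{M1..Mk}).
#' @param subgroupSizes named vector of subject counts per subgroup.
#' @param timeGrid numeric sampling positions.
#' @param timeLabels display labels; default derived from \code{timeGrid}.
#' @param baselineLogMean named numeric of log-scale baselines; mediators
#'   without an entry are drawn from N(meanDefault, baselineLogSd^2).
#' @param baselineLogSd sd for drawn baselines (a fixed property of the
#'   panel, drawn once from the spec seed).
#' @param latentLogSd stationary sd of the latent log-scale process.
#' @param groupEffects data.frame(mediator, subgroup, fold).
#' @param plantedEdges data.frame(mediator_a, mediator_b, interval, r) with
#'   optional \code{subgroup} column (NA = all subgroups).
#' @param arSelf named numeric AR(1) coefficients.
#' @param crossEdges data.frame(from, to, coef) lag-1 couplings.
#' @param changepoints data.frame(mediator, time_index, new_coef).
#' @param noiseLogSd log-scale measurement noise sd.
#' @param missingRate per-measurement Bernoulli drop probability.
#' @param seed default RNG seed.
#' @param meta metadata list.
#' @return a validated \linkS4class{SyntheticSpec}
#' @export
SyntheticSpec <- function(mediators, subgroupSizes, timeGrid,
                          timeLabels = NULL, baselineLogMean = numeric(),
                          baselineLogSd = 0.5, latentLogSd = 0.4,
                          groupEffects = NULL, plantedEdges = NULL,
                          arSelf = numeric(), crossEdges = NULL,
                          changepoints = NULL, noiseLogSd = 0.1,
                          missingRate = 0, seed = 1L, meta = list()) {
  if (is.numeric(mediators) && length(mediators) == 1)
    mediators <- paste0("M", seq_len(mediators))
  if (is.null(timeLabels)) timeLabels <- as.character(timeGrid)
  empty_ge <- data.frame(mediator = character(), subgroup = character(),
                         fold = numeric(), stringsAsFactors = FALSE)
  empty_pe <- data.frame(mediator_a = character(), mediator_b = character(),
                         interval = integer(), r = numeric(),
                         subgroup = character(), stringsAsFactors = FALSE)
  empty_ce <- data.frame(from = character(), to = character(),
                         coef = numeric(), stringsAsFactors = FALSE)
  empty_cp <- data.frame(mediator = character(), time_index = integer(),
                         new_coef = numeric(), stringsAsFactors = FALSE)
  if (is.null(groupEffects)) groupEffects <- empty_ge
  if (is.null(plantedEdges)) plantedEdges <- empty_pe else {
    if (!"subgroup" %in% names(plantedEdges)) plantedEdges$subgroup <- NA_character_
  }
  if (is.null(crossEdges)) crossEdges <- empty_ce
  if (is.null(changepoints)) changepoints <- empty_cp
  methods::new("SyntheticSpec",
    mediators = as.character(mediators),
    subgroupSizes = stats::setNames(as.integer(subgroupSizes),
                                    names(subgroupSizes)),
    timeGrid = as.numeric(timeGrid), timeLabels = as.character(timeLabels),
    baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
    latentLogSd = latentLogSd, groupEffects = as.data.frame(groupEffects),
    plantedEdges = as.data.frame(plantedEdges), arSelf = arSelf,
    crossEdges = as.data.frame(crossEdges),
    changepoints = as.data.frame(changepoints), noiseLogSd = noiseLogSd,
    missingRate = missingRate, seed = as.integer(seed), meta = meta)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec\n")
  cat(sprintf("  %d mediators | %d time points | subgroups: %s\n",
              length(object@mediators), length(object@timeGrid),
              paste(sprintf("%s(n=%d)", names(object@subgroupSizes),
                            object@subgroupSizes), collapse = ", ")))
  cat(sprintf("  planted pair-windows: %d | AR self-feedback nodes: %d | cross edges: %d\n",
              nrow(object@plantedEdges), sum(object@arSelf != 0),
              nrow(object@crossEdges)))
  cat(sprintf("  latent sd %.2f, noise sd %.2f (log scale) | missing rate %.2f | seed %d\n",
              object@latentLogSd, object@noiseLogSd, object@missingRate,
              object@seed))
})

#' Latent correlation needed to realize a target observed Pearson r
#'
#' Observed concentrations are lognormal: value = exp(baseline + x + noise)
#' with latent x of sd \code{sdLat} and noise of sd \code{sdNoise} on the
#' log scale. A log-scale correlation rho between two latent values induces
#' linear-scale Pearson (exp(rho_log s^2) - 1)/(exp(s^2) - 1) with
#' s^2 = sdLat^2 + sdNoise^2. This inverts that relation so the generator
#' can hit a target on the scale the correlation networks actually use.
#'
#' @param r target observed (linear-scale) Pearson correlation
#' @param sdLat latent log-scale sd
#' @param sdNoise measurement-noise log-scale sd
#' @return latent correlation in [-1, 1]
#' @export
latentCorrelationFor <- function(r, sdLat, sdNoise) {
  s2 <- sdLat^2 + sdNoise^2
  arg <- 1 + r * (exp(s2) - 1)
  if (arg <= 0)
    stop("target correlation ", r, " is unattainable at these noise levels",
         call. = FALSE)
  rho <- log(arg) / sdLat^2
  if (abs(rho) > 1 + 1e-9)
    stop("target correlation ", r, " is unattainable: required latent ",
         "correlation ", round(rho, 3), " exceeds 1; reduce noise or target",
         call. = FALSE)
  max(-1, min(1, rho))
}

#' Generate a synthetic mediator dataset with known ground truth
#'
#' Simulates, per subject, a latent log-scale process
#' \code{x[t+1, i] = a_i(t) x[t, i] + sum_j b_ij x[t, j] + eta} with
#' stationary per-mediator sd \code{latentLogSd}; node-specific changepoints
#' switch \code{a_i} at a grid index. Within each planted interval the
#' involved mediators' boundary-time values are drawn jointly from a
#' correlation matrix whose entries are chosen (via
#' \code{\link{latentCorrelationFor}}) so that the observed linear-scale
#' Pearson correlation matches the planted target; the matrix is checked for
#' positive semi-definiteness before any sampling. Observed concentrations
#' are \code{exp(baseline + log fold + x + noise)}; missingness is
#' missing-completely-at-random.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param seed RNG seed; defaults to the spec's own seed
#' @return list with elements \code{dataset} (a
#'   \linkS4class{MediatorDataset}) and \code{truth} (ground truth: planted
#'   edges per interval and subgroup, true parent sets incl. self-loops,
#'   changepoint locations, group fold changes, resolved baselines).
#' @export
generateDataset <- function(spec, seed = spec@seed) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  med <- spec@mediators
  M <- length(med)
  tg <- spec@timeGrid
  Tn <- length(tg)

  ## resolve planted correlation matrices per (subgroup, interval) and
  ## validate PSD before any sampling
  pe <- spec@plantedEdges
  if (nrow(pe) > 0) {
    unknown <- setdiff(c(pe$mediator_a, pe$mediator_b), med)
    if (length(unknown))
      stop("planted edge names not in panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  sgs <- names(spec@subgroupSizes)
  plantPlan <- list()
  for (sg in sgs) {
    rows <- pe[is.na(pe$subgroup) | pe$subgroup == sg, , drop = FALSE]
    if (nrow(rows) == 0) next
    for (k in unique(rows$interval)) {
      rk <- rows[rows$interval == k, , drop = FALSE]
      nodes <- unique(c(rk$mediator_a, rk$mediator_b))
      C <- diag(length(nodes))
      dimnames(C) <- list(nodes, nodes)
      for (j in seq_len(nrow(rk))) {
        rho <- latentCorrelationFor(rk$r[j], spec@latentLogSd, spec@noiseLogSd)
        C[rk$mediator_a[j], rk$mediator_b[j]] <- rho
        C[rk$mediator_b[j], rk$mediator_a[j]] <- rho
      }
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8)
        stop("planted correlation structure for subgroup '", sg,
             "', interval ", k, " is not positive semi-definite", call. = FALSE)
      L <- t(chol(C + diag(1e-10, nrow(C))))
      plantPlan[[sg]][[as.character(k)]] <- list(nodes = nodes, L = L)
    }
  }

  set.seed(seed)
  ## fixed panel properties: baselines
  base <- rep(NA_real_, M); names(base) <- med
  if (length(spec@baselineLogMean))
    base[names(spec@baselineLogMean)] <- spec@baselineLogMean
  nb <- sum(is.na(base))
  if (nb > 0)
    base[is.na(base)] <- stats::rnorm(nb, mean = log(50),
                                      sd = spec@baselineLogSd)

  ## AR coefficient schedule a_i(t), with changepoints
  ar0 <- rep(0, M); names(ar0) <- med
  if (length(spec@arSelf)) ar0[names(spec@arSelf)] <- spec@arSelf
  arSched <- matrix(rep(ar0, each = Tn - 1), Tn - 1, M,
                    dimnames = list(NULL, med))
  cp <- spec@changepoints
  if (nrow(cp) > 0)
    for (j in seq_len(nrow(cp))) {
      idx <- cp$time_index[j]
      if (idx < 2 || idx > Tn)
        stop("changepoint time_index out of range", call. = FALSE)
      arSched[seq(idx - 1, Tn - 1), cp$mediator[j]] <- cp$new_coef[j]
    }

  ## cross couplings
  B <- matrix(0, M, M, dimnames = list(med, med))  # B[from, to]
  ce <- spec@crossEdges
  if (nrow(ce) > 0)
    B[cbind(match(ce$from, med), match(ce$to, med))] <- ce$coef

  ## fold change lookup
  foldOf <- function(sg) {
    f <- rep(1, M); names(f) <- med
    ge <- spec@groupEffects
    ge <- ge[ge$subgroup == sg, , drop = FALSE]
    if (nrow(ge)) f[ge$mediator] <- ge$fold
    f
  }

  sLat <- spec@latentLogSd
  innSd <- sLat * sqrt(pmax(1 - arSched^2, 0))  # keeps stationary sd ~ sLat
  sch <- .intervalScheme(tg, spec@timeLabels)

  rows <- vector("list", sum(spec@subgroupSizes))
  ri <- 0
  for (sg in sgs) {
    fold <- foldOf(sg)
    plan <- plantPlan[[sg]]
    ## which (mediator, time) cells are claimed by a planted window; first
    ## interval claiming a shared boundary time wins
    claimed <- matrix(FALSE, Tn, M, dimnames = list(NULL, med))
    claims <- list()
    if (!is.null(plan))
      for (k in as.integer(names(plan))) {
        nodes <- plan[[as.character(k)]]$nodes
        for (tix in c(k, k + 1)) {
          free <- nodes[!claimed[tix, nodes]]
          if (length(free)) {
            claimed[tix, free] <- TRUE
            claims[[length(claims) + 1]] <- list(t = tix, nodes = free, k = k)
          }
        }
      }
    for (s in seq_len(spec@subgroupSizes[[sg]])) {
      ri <- ri + 1
      subj <- sprintf("%s_%02d", sg, s)
      x <- matrix(0, Tn, M, dimnames = list(NULL, med))
      x[1, ] <- stats::rnorm(M, 0, sLat)
      for (t in seq_len(Tn - 1))
        x[t + 1, ] <- arSched[t, ] * x[t, ] + drop(x[t, ] %*% B) +
          stats::rnorm(M, 0, innSd[t, ])
      ## override planted cells with factor-constructed correlated draws
      for (cl in claims) {
        Lk <- plan[[as.character(cl$k)]]$L
        z <- drop(Lk %*% stats::rnorm(nrow(Lk)))
        names(z) <- plan[[as.character(cl$k)]]$nodes
        x[cl$t, cl$nodes] <- sLat * z[cl$nodes]
      }
      logv <- sweep(x, 2, base + log(fold), "+") +
        matrix(stats::rnorm(Tn * M, 0, spec@noiseLogSd), Tn, M)
      val <- exp(logv)
      if (spec@missingRate > 0)
        val[stats::runif(Tn * M) < spec@missingRate] <- NA
      rows[[ri]] <- data.frame(subject = subj, subgroup = sg,
                               time = rep(tg, M),
                               mediator = rep(med, each = Tn),
                               value = as.vector(val), censored = FALSE,
                               stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)
  meas <- meas[!is.na(meas$value), , drop = FALSE]
  ds <- MediatorDataset(meas, mediators = med, timeGrid = tg,
                        timeLabels = spec@timeLabels, subgroups = sgs)

  ## ground truth
  parents <- lapply(stats::setNames(med, med), function(mm) {
    p <- character()
    if (!is.na(ar0[mm]) && ar0[mm] != 0) p <- mm
    if (nrow(ce) > 0) p <- c(p, ce$from[ce$to == mm])
    unique(p)
  })
  truth <- list(
    plantedEdges = pe,
    parents = parents,
    selfLoops = names(ar0)[ar0 != 0],
    changepoints = cp,
    groupFoldChanges = spec@groupEffects,
    baselines = base,
    intervals = sch,
    seed = seed
  )
  list(dataset = ds, truth = truth)
}

#' Stylized preset emulating a pediatric acute liver failure serum study
#'
#' 28 human serum mediators, two outcome subgroups (spontaneous survivors
#' S, n = 14; non-survivors NS, n = 7), daily sampling d0..d7. The preset
#' plants, as ground truth: GDF-15 elevated in NS (fold 3), MIG suppressed
#' in NS (fold 0.4), high HMGB1 baselines in both subgroups, AR(1)
#' self-feedback on HMGB1 and GDF-15, a denser set of interval-local
#' correlations in NS than in S, and an S-only motif in which MIG links
#' HMGB1 and GDF-15. Effect sizes are stylized
#' (\code{meta$stylized = TRUE}), not fitted to any cohort.
#'
#' @param seed default RNG seed stored in the spec
#' @return a \linkS4class{SyntheticSpec}
#' @export
palfPreset <- function(seed = 1L) {
  med <- mediatorPanel("human")
  base <- c("HMGB1" = log(3000), "GDF-15" = log(1500), "MIG" = log(300),
            "IL-6" = log(200), "IL-8" = log(150), "IL-10" = log(80),
            "NO2-/NO3-" = log(25))
  ge <- data.frame(
    mediator = c("GDF-15", "MIG", "IL-6", "sIL-2Ra"),
    subgroup = c("NS", "NS", "NS", "NS"),
    fold     = c(3.0, 0.4, 2.2, 2.0),
    stringsAsFactors = FALSE)
  ## denser planted structure in NS (r = 0.9 pair-windows) than in S;
  ## S carries the MIG-bridges-HMGB1/GDF-15 motif
  ## within an interval, planted pairs form cliques or are node-disjoint so
  ## the per-interval correlation matrix is positive semi-definite, and
  ## adjacent planted intervals use disjoint mediator sets so that windows
  ## sharing a boundary time do not dilute each other
  ns <- data.frame(
    mediator_a = c("GDF-15", "GDF-15", "IL-6",          # triangle, d0-d1
                   "MCP-1", "TNF-a",                    # disjoint, d1-d2
                   "GDF-15", "GDF-15", "IL-6",          # triangle, d2-d3
                   "MCP-1", "TNF-a",                    # disjoint, d3-d4
                   "GDF-15", "IL-8",                    # disjoint, d4-d5
                   "MCP-1",                             # d5-d6
                   "IL-6"),                             # d6-d7
    mediator_b = c("IL-6", "IL-8", "IL-8",
                   "IP-10", "IL-10",
                   "IL-6", "IL-8", "IL-8",
                   "IP-10", "IL-10",
                   "IL-6", "MIP-1a",
                   "TNF-a",
                   "IL-8"),
    interval   = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 7L),
    r = 0.9, subgroup = "NS", stringsAsFactors = FALSE)
  ## MIG bridges HMGB1 and GDF-15 in S; the weaker implied HMGB1/GDF-15
  ## correlation is planted too so the joint correlation matrix stays PSD
  s <- data.frame(
    mediator_a = c("HMGB1", "MIG",    "HMGB1",  "IL-6", "IP-10"),
    mediator_b = c("MIG",   "GDF-15", "GDF-15", "IL-8", "MCP-1"),
    interval   = c(2L, 2L, 2L, 4L, 6L),
    r = c(0.9, 0.9, 0.87, 0.9, 0.9), subgroup = "S",
    stringsAsFactors = FALSE)
  SyntheticSpec(
    mediators = med,
    subgroupSizes = c(S = 14L, NS = 7L),
    timeGrid = 0:7, timeLabels = paste0("d", 0:7),
    baselineLogMean = base, baselineLogSd = 0.6,
    latentLogSd = 0.4, noiseLogSd = 0.1,
    groupEffects = ge, plantedEdges = rbind(ns, s),
    arSelf = c("HMGB1" = 0.7, "GDF-15" = 0.7),
    missingRate = 0.03, seed = seed,
    meta = list(design = "palf_serum", stylized = TRUE))
}

#' Stylized preset emulating an APAP hepatocyte-supernatant experiment
#'
#' 23 mouse mediators, four arms (wild-type or HMGB1-knockout hepatocytes,
#' with or without acetaminophen), sampled at 1, 3, 6, 24 and 48 h with 3-5
#' independent cultures per arm. Knockout arms are generated with HMGB1 near
#' zero and an attenuated GDF-15 response; APAP arms carry denser planted
#' correlations in wild-type than in knockout cells. Stylized ground truth,
#' not fitted to measured concentrations.
#'
#' @param seed default RNG seed stored in the spec
#' @return a \linkS4class{SyntheticSpec}
#' @export
hepatocytePreset <- function(seed = 1L) {
  med <- mediatorPanel("mouse")
  base <- c("HMGB1" = log(800), "GDF-15" = log(400), "MIG" = log(120),
            "IL-6" = log(150), "KC" = log(200), "NO2-/NO3-" = log(15))
  ge <- data.frame(
    mediator = c("HMGB1", "HMGB1", "GDF-15", "GDF-15", "GDF-15",
                 "IL-6", "IL-6", "KC", "TNF-a"),
    subgroup = c("KO_ctrl", "KO_APAP", "WT_APAP", "KO_APAP", "KO_ctrl",
                 "WT_APAP", "KO_APAP", "WT_APAP", "WT_APAP"),
    fold     = c(0.02, 0.02, 4.0, 1.5, 0.6,
                 3.0, 1.4, 2.5, 2.0),
    stringsAsFactors = FALSE)
  ## same PSD/disjoint-adjacency discipline as the serum preset
  wt <- data.frame(
    mediator_a = c("GDF-15", "GDF-15", "IL-6",     # triangle, 1-3 h
                   "MCP-1", "TNF-a",               # disjoint, 3-6 h
                   "GDF-15", "KC",                 # disjoint, 6-24 h
                   "MCP-1"),                       # 24-48 h
    mediator_b = c("IL-6", "KC", "KC",
                   "MIG", "IP-10",
                   "IL-6", "VEGF",
                   "TNF-a"),
    interval   = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L),
    r = 0.9, subgroup = "WT_APAP", stringsAsFactors = FALSE)
  ko <- data.frame(
    mediator_a = c("IL-6", "MCP-1"),
    mediator_b = c("KC",   "MIG"),
    interval   = c(1L, 3L),
    r = 0.9, subgroup = "KO_APAP", stringsAsFactors = FALSE)
  SyntheticSpec(
    mediators = med,
    subgroupSizes = c(WT_ctrl = 4L, WT_APAP = 5L, KO_ctrl = 4L, KO_APAP = 5L),
    timeGrid = c(1, 3, 6, 24, 48),
    timeLabels = c("1h", "3h", "6h", "24h", "48h"),
    baselineLogMean = base, baselineLogSd = 0.6,
    latentLogSd = 0.4, noiseLogSd = 0.1,
    groupEffects = ge, plantedEdges = rbind(wt, ko),
    arSelf = c("HMGB1" = 0.6, "GDF-15" = 0.6),
    missingRate = 0.02, seed = seed,
    meta = list(design = "hepatocyte_apap", stylized = TRUE))
}
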