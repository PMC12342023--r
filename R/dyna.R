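#' Pairwise Pearson correlations within one interval window
#'
#' Computes the symmetric matrix of Pearson correlations between all
#' mediator pairs over one consecutive time interval. In \code{"levels"}
#' mode the samples at the two boundary time points are pooled (each
#' subject-by-time sample is one observation); in \code{"differences"} mode
#' each subject contributes its change across the interval (value at the end
#' minus value at the start), requiring both samples. Correlations use
#' complete pairs only (pairwise deletion); a pair with fewer than
#' \code{minPairs} complete observations, or a mediator with zero variance
#' in the window, is undefined (NA) and can never become an edge.
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param subgroup subgroup label
#' @param interval interval index or \code{c(start, end)} pair
#' @param mode \code{"levels"} or \code{"differences"}
#' @param minPairs minimum complete pairs for a defined correlation
#' @return list with \code{r} (correlation matrix), \code{n} (complete-pair
#'   counts), \code{excluded} (data.frame mediator/reason), and the
#'   resolved \code{interval}.
#' @export
intervalCorrelations <- function(ds, subgroup, interval,
                                 mode = c("levels", "differences"),
                                 minPairs = 4) {
  mode <- match.arg(mode)
  iv <- .resolveInterval(ds, interval)
  if (mode == "levels") {
    mat <- windowSlice(ds, subgroup, interval)
  } else {
    .checkSubgroup(ds, subgroup)
    m0 <- .wideMatrix(ds, subgroup, times = iv$start)
    m1 <- .wideMatrix(ds, subgroup, times = iv$end)
    s0 <- attr(m0, "sampleInfo")$subject
    s1 <- attr(m1, "sampleInfo")$subject
    common <- intersect(s0, s1)
    mat <- m1[match(common, s1), , drop = FALSE] -
           m0[match(common, s0), , drop = FALSE]
  }
  med <- colnames(mat)
  M <- length(med)
  rmat <- matrix(NA_real_, M, M, dimnames = list(med, med))
  nmat <- matrix(0L, M, M, dimnames = list(med, med))
  excl <- data.frame(mediator = character(), reason = character(),
                     stringsAsFactors = FALSE)
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  nob <- colSums(!is.na(mat))
  zero_var <- which(!is.na(sdv) & sdv == 0 & nob >= 2)
  if (length(zero_var))
    excl <- rbind(excl, data.frame(mediator = med[zero_var],
                                   reason = "zero variance"))
  if (M >= 2 && nrow(mat) >= 2) {
    for (i in seq_len(M - 1)) {
      for (j in seq(i + 1, M)) {
        ok <- stats::complete.cases(mat[, c(i, j), drop = FALSE])
        n <- sum(ok)
        nmat[i, j] <- nmat[j, i] <- n
        if (n < minPairs) next
        xi <- mat[ok, i]; xj <- mat[ok, j]
        if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
        r <- stats::cor(xi, xj)
        rmat[i, j] <- rmat[j, i] <- r
      }
    }
  }
  diag(rmat) <- 1
  list(r = rmat, n = nmat, excluded = excl, interval = iv)
}

#' Build dynamic correlation networks over consecutive intervals
#'
#' Runs \code{\link{intervalCorrelations}} over every interval of the
#' dataset's scheme and keeps, per interval, the mediator pairs whose
#' Pearson correlation reaches the stringency threshold in absolute value
#' (inclusive: \code{|r| >= threshold}). Edge signs record parallel
#' (positive) versus anti-parallel (negative) movement.
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param subgroup subgroup label
#' @param threshold stringency in (0, 1]; default 0.85
#' @param mode \code{"levels"} or \code{"differences"} (see
#'   \code{\link{intervalCorrelations}})
#' @param minPairs minimum complete pairs per correlation
#' @return a \linkS4class{DynamicNetworkSet}
#' @export
buildNetworks <- function(ds, subgroup, threshold = 0.85,
                          mode = c("levels", "differences"), minPairs = 4) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a number in (0, 1]", call. = FALSE)
  .checkSubgroup(ds, subgroup)
  sch <- intervalScheme(ds)
  edges <- list()
  excl <- list()
  for (k in sch$index) {
    cc <- intervalCorrelations(ds, subgroup, k, mode = mode,
                               minPairs = minPairs)
    r <- cc$r
    med <- rownames(r)
    ut <- which(upper.tri(r) & !is.na(r) & abs(r) >= threshold,
                arr.ind = TRUE)
    if (nrow(ut)) {
      rv <- r[ut]
      edges[[length(edges) + 1]] <- data.frame(
        interval = k, mediator_a = med[ut[, 1]], mediator_b = med[ut[, 2]],
        r = rv, sign = ifelse(rv >= 0, "positive", "negative"),
        n_pairs = cc$n[ut], stringsAsFactors = FALSE)
    }
    if (nrow(cc$excluded))
      excl[[length(excl) + 1]] <- cbind(interval = k, cc$excluded)
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(interval = integer(), mediator_a = character(),
               mediator_b = character(), r = numeric(), sign = character(),
               n_pairs = integer(), stringsAsFactors = FALSE)
  x <- if (length(excl)) do.call(rbind, excl) else
    data.frame(interval = integer(), mediator = character(),
               reason = character(), stringsAsFactors = FALSE)
  methods::new("DynamicNetworkSet", edges = e, intervals = sch,
               mediators = ds@mediators, threshold = threshold, mode = mode,
               subgroup = subgroup, excluded = x)
}

setMethod("show", "DynamicNetworkSet", function(object) {
  cat("DynamicNetworkSet\n")
  cat(sprintf("  subgroup %s | %d intervals | threshold %.2f | mode %s\n",
              object@subgroup, nrow(object@intervals), object@threshold,
              object@mode))
  tab <- table(factor(object@edges$interval, levels = object@intervals$index))
  cat(sprintf("  edges per interval: %s | total connections: %d\n",
              paste(as.integer(tab), collapse = ", "), nrow(object@edges)))
})

#' @rdname DynamicNetworkSet-class
#' @param x a \linkS4class{DynamicNetworkSet}
#' @param interval optional interval index to filter on
#' @export
setMethod("networkEdges", "DynamicNetworkSet", function(x, interval = NULL) {
  e <- x@edges
  if (!is.null(interval)) e <- e[e$interval %in% interval, , drop = FALSE]
  e
})

#' Network complexity and total connections
#'
#' Per interval, complexity is the sum of node degrees over the analyzed
#' panel divided by (n - 1), i.e. 2E/(n - 1) for E edges and a panel of n
#' mediators; unconnected (and window-excluded) mediators still count in n
#' because they are part of the analyzed panel. The total number of
#' connections is the sum of edge counts across all intervals.
#'
#' @param x a \linkS4class{DynamicNetworkSet}
#' @param nMediators panel size n; defaults to the set's own panel
#' @return data.frame(interval, label, n_edges, complexity) with attribute
#'   \code{"totalConnections"}
#' @export
setMethod("networkComplexity", "DynamicNetworkSet",
          function(x, nMediators = length(x@mediators)) {
  if (nMediators < 2)
    stop("complexity requires a panel of at least 2 mediators", call. = FALSE)
  sch <- x@intervals
  nE <- as.integer(table(factor(x@edges$interval, levels = sch$index)))
  out <- data.frame(interval = sch$index, label = sch$label, n_edges = nE,
                    complexity = 2 * nE / (nMediators - 1),
                    stringsAsFactors = FALSE)
  attr(out, "totalConnections") <- sum(nE)
  out
})

#' @rdname networkComplexity
#' @export
setMethod("totalConnections", "DynamicNetworkSet", function(x) {
  nrow(x@edges)
})

#' Per-mediator connectivity across intervals
#'
#' Degree of one mediator in each interval network, its partners with edge
#' signs, and the total connectivity (sum of degrees over intervals).
#'
#' @param x a \linkS4class{DynamicNetworkSet}
#' @param mediator mediator name
#' @return list with \code{perInterval} (data.frame interval/degree),
#'   \code{partners} (data.frame interval/partner/r/sign) and \code{total}
#' @export
setMethod("mediatorConnectivity", "DynamicNetworkSet",
          function(x, mediator, ...) {
  if (!mediator %in% x@mediators)
    stop("unknown mediator '", mediator, "'", call. = FALSE)
  e <- x@edges
  hit <- e$mediator_a == mediator | e$mediator_b == mediator
  eh <- e[hit, , drop = FALSE]
  partner <- ifelse(eh$mediator_a == mediator, eh$mediator_b, eh$mediator_a)
  partners <- data.frame(interval = eh$interval, partner = partner,
                         r = eh$r, sign = eh$sign, stringsAsFactors = FALSE)
  deg <- as.integer(table(factor(eh$interval, levels = x@intervals$index)))
  list(perInterval = data.frame(interval = x@intervals$index,
                                label = x@intervals$label, degree = deg,
                                stringsAsFactors = FALSE),
       partners = partners, total = sum(deg))
})

#' Total connectivity for every mediator in the panel
#'
#' @param nets a \linkS4class{DynamicNetworkSet}
#' @return data.frame(mediator, total_degree), sorted decreasing
#' @export
connectivityTable <- function(nets) {
  e <- nets@edges
  cnt <- table(factor(c(e$mediator_a, e$mediator_b),
                      levels = nets@mediators))
  out <- data.frame(mediator = names(cnt), total_degree = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out[order(-out$total_degree, out$mediator), , drop = FALSE]
}

#' Export one interval network as an igraph object
#'
#' @param nets a \linkS4class{DynamicNetworkSet}
#' @param interval interval index
#' @return an \code{igraph} graph with node attribute \code{degree} and edge
#'   attributes \code{r} and \code{sign}
#' @export
asIgraph <- function(nets, interval) {
  e <- networkEdges(nets, interval)
  g <- igraph::graph_from_data_frame(
    e[, c("mediator_a", "mediator_b", "r", "sign")], directed = FALSE,
    vertices = data.frame(name = nets@mediators))
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Write a DynamicNetworkSet to disk
#'
#' Writes the edge list and complexity profile as CSV and one GraphML file
#' per interval.
#'
#' @param nets a \linkS4class{DynamicNetworkSet}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeNetworks <- function(nets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "edges.csv")
  utils::write.csv(nets@edges, p, row.names = FALSE)
  paths <- c(paths, p)
  cx <- networkComplexity(nets)
  cx$total_connections <- attr(cx, "totalConnections")
  p <- file.path(dir, "complexity.csv")
  utils::write.csv(cx, p, row.names = FALSE)
  paths <- c(paths, p)
  ct <- connectivityTable(nets)
  p <- file.path(dir, "connectivity.csv")
  utils::write.csv(ct, p, row.names = FALSE)
  paths <- c(paths, p)
  for (k in nets@intervals$index) {
    p <- file.path(dir, sprintf("network_interval_%02d.graphml", k))
    igraph::write_graph(asIgraph(nets, k), p, format = "graphml")
    paths <- c(paths, p)
  }
  invisible(paths)
}
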