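#' Build a validated run configuration
#'
#' Assembles and checks the settings of an end-to-end analysis run:
#' simulate (or load) a dataset, then per-subgroup dynamic correlation
#' networks (DyNA), per-subgroup dynamic Bayesian network inference (DyBN)
#' and outcome-biomarker statistics. The configuration is fully
#' serializable and echoed into every result bundle.
#'
#' @param input a \linkS4class{MediatorDataset}, a
#'   \linkS4class{SyntheticSpec}, a preset name (\code{"palf"},
#'   \code{"hepatocyte"}) or a path to a long CSV
#' @param subgroups subgroups to analyze; default all in the dataset
#' @param dyna list: \code{threshold} (default 0.85), \code{mode}
#'   (\code{"levels"}), \code{minPairs} (4)
#' @param dybn list: \code{iterations} (4000), \code{burnIn} (1000),
#'   \code{thinning} (1), \code{fanIn} (3), \code{kMax} (1),
#'   \code{consensusThreshold} (0.5), plus optional \code{alphaMu},
#'   \code{alphaW}, \code{t0}
#' @param statsCfg list: \code{groups} = c(A, B) for volcano/ROC (default
#'   the first two subgroups), \code{fcThreshold} (2.0), \code{alpha}
#'   (0.05), \code{rocMediators} (mediators to run ROC on; default none)
#' @param seed global seed; stage seeds are derived from it
#' @return list of class \code{"RunConfig"}
#' @export
runConfig <- function(input = "palf", subgroups = NULL,
                      dyna = list(), dybn = list(), statsCfg = list(),
                      seed = 1L) {
  dynaDef <- list(threshold = 0.85, mode = "levels", minPairs = 4)
  dybnDef <- list(iterations = 4000, burnIn = 1000, thinning = 1,
                  fanIn = 3, kMax = 1, consensusThreshold = 0.5)
  statsDef <- list(groups = NULL, fcThreshold = 2.0, alpha = 0.05,
                   rocMediators = character())
  dyna <- utils::modifyList(dynaDef, dyna)
  dybn <- utils::modifyList(dybnDef, dybn)
  statsCfg <- utils::modifyList(statsDef, statsCfg)
  if (dyna$threshold <= 0 || dyna$threshold > 1)
    stop("dyna$threshold must be in (0, 1]", call. = FALSE)
  if (dybn$iterations <= dybn$burnIn)
    stop("dybn$iterations must exceed dybn$burnIn", call. = FALSE)
  structure(list(input = input, subgroups = subgroups, dyna = dyna,
                 dybn = dybn, stats = statsCfg, seed = as.integer(seed)),
            class = "RunConfig")
}

.resolveInput <- function(config) {
  input <- config$input
  if (methods::is(input, "MediatorDataset"))
    return(list(dataset = input, truth = NULL, source = "dataset"))
  if (methods::is(input, "SyntheticSpec")) {
    g <- generateDataset(input, seed = config$seed)
    return(list(dataset = g$dataset, truth = g$truth, source = "spec"))
  }
  if (is.character(input) && length(input) == 1) {
    if (input == "palf") {
      g <- generateDataset(palfPreset(), seed = config$seed)
      return(list(dataset = g$dataset, truth = g$truth, source = "preset:palf"))
    }
    if (input == "hepatocyte") {
      g <- generateDataset(hepatocytePreset(), seed = config$seed)
      return(list(dataset = g$dataset, truth = g$truth,
                  source = "preset:hepatocyte"))
    }
    if (file.exists(input))
      return(list(dataset = readMediatorCSV(input), truth = NULL,
                  source = input))
    stop("I/O error: input '", input, "' is neither a preset nor a file",
         call. = FALSE)
  }
  stop("unresolvable input", call. = FALSE)
}

.configHash <- function(config) {
  js <- jsonlite::toJSON(.serializableConfig(config), auto_unbox = TRUE,
                         digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

.serializableConfig <- function(config) {
  inp <- config$input
  config$input <- if (is.character(inp)) inp else class(inp)[1]
  unclass(config)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input resolution (simulation, file or
#' in-memory dataset), per-subgroup DyNA with complexity and connectivity
#' summaries, per-subgroup DyBN with consensus graph and self-feedback
#' detection, and the volcano (plus optional ROC) statistics contrasting
#' two subgroups. Stage warnings are collected into the report. The run is
#' deterministic given the configuration: stochastic stages draw their
#' seeds from the global seed.
#'
#' @param config a \code{\link{runConfig}}
#' @return list of class \code{"RunReport"}: \code{dataset}, \code{truth}
#'   (for synthetic inputs), \code{dyna} and \code{dybn} per subgroup,
#'   \code{volcano}, \code{roc}, \code{warnings}, \code{config},
#'   \code{configHash}, \code{version}
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  warnings_ <- list()
  grab <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_[[length(warnings_) + 1]] <<- c(stage = stage,
                                               message = conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  inp <- .resolveInput(config)
  ds <- inp$dataset
  sgs <- config$subgroups
  if (is.null(sgs)) sgs <- subgroups(ds)
  unknown <- setdiff(sgs, subgroups(ds))
  if (length(unknown))
    stop("validation error: unknown subgroup(s) ",
         paste(unknown, collapse = ", "), "; available: ",
         paste(subgroups(ds), collapse = ", "), call. = FALSE)

  dynaRes <- list(); dybnRes <- list()
  for (i in seq_along(sgs)) {
    sg <- sgs[i]
    nets <- grab("dyna", buildNetworks(ds, sg,
                                       threshold = config$dyna$threshold,
                                       mode = config$dyna$mode,
                                       minPairs = config$dyna$minPairs))
    dynaRes[[sg]] <- list(networks = nets,
                          complexity = networkComplexity(nets),
                          connectivity = connectivityTable(nets),
                          totalConnections = totalConnections(nets))
    tt <- grab("dybn", buildTransitions(ds, sg))
    hyper <- bgeHyperparams(length(tt$mediators),
                            alphaMu = config$dybn$alphaMu %||% 1,
                            alphaW = config$dybn$alphaW %||%
                              (length(tt$mediators) + 2),
                            t0 = config$dybn$t0 %||% 0.5)
    post <- grab("dybn", dybnSample(tt, hyper = hyper,
                       cp = cpConfig(kMax = config$dybn$kMax),
                       iterations = config$dybn$iterations,
                       burnIn = config$dybn$burnIn,
                       thinning = config$dybn$thinning,
                       fanIn = config$dybn$fanIn,
                       seed = (config$seed * 1009L + i) %% 2147483647L))
    dybnRes[[sg]] <- list(posterior = post,
                          consensus = consensusGraph(
                            post, config$dybn$consensusThreshold))
  }

  grp <- config$stats$groups
  if (is.null(grp)) grp <- utils::head(sgs, 2)
  volcano <- NULL; roc <- NULL
  if (length(grp) == 2) {
    volcano <- grab("stats", volcanoAnalysis(ds, grp[1], grp[2],
                                 fcThreshold = config$stats$fcThreshold,
                                 alpha = config$stats$alpha))
    rocMed <- config$stats$rocMediators
    if (length(rocMed)) {
      m <- measurements(ds)
      roc <- lapply(stats::setNames(rocMed, rocMed), function(md) {
        mm <- m[m$mediator == md & m$subgroup %in% grp & !is.na(m$value), ]
        rocAnalysis(mm$value, mm$subgroup, positive = grp[2])
      })
    }
  }

  structure(list(dataset = ds, truth = inp$truth, source = inp$source,
                 subgroups = sgs, dyna = dynaRes, dybn = dybnRes,
                 volcano = volcano, roc = roc, warnings = warnings_,
                 config = config, configHash = .configHash(config),
                 version = as.character(utils::packageVersion("dynamed"))),
            class = "RunReport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (dynamed ", x$version, ")\n", sep = "")
  cat("  source: ", x$source, " | config ", substr(x$configHash, 1, 8),
      " | seed ", x$config$seed, "\n", sep = "")
  for (sg in x$subgroups)
    cat(sprintf("  %s: total connections %d | consensus edges %d | self-feedback: %s\n",
                sg, x$dyna[[sg]]$totalConnections,
                nrow(x$dybn[[sg]]$consensus@edges),
                paste(selfFeedback(x$dybn[[sg]]$consensus),
                      collapse = ", ")))
  if (!is.null(x$volcano))
    cat(sprintf("  volcano: %d up, %d down of %d mediators\n",
                sum(x$volcano$class == "up"),
                sum(x$volcano$class == "down"), nrow(x$volcano)))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see $warnings)\n")
  invisible(x)
}

#' Compare two subgroups of a run report
#'
#' Side-by-side per-interval complexity, per-mediator total-connectivity
#' deltas, and consensus-graph edge-set differences.
#'
#' @param report a \code{"RunReport"} from \code{\link{runAll}}
#' @param a,b subgroup labels present in the report
#' @return list: \code{complexity} (per-interval, both subgroups),
#'   \code{connectivity} (per-mediator degrees and delta b - a),
#'   \code{consensusDiff} (edges with column \code{which} in
#'   \code{"a_only"}/\code{"b_only"}), \code{totalConnections}
#' @export
compareSubgroups <- function(report, a, b) {
  stopifnot(inherits(report, "RunReport"))
  for (sg in c(a, b))
    if (!sg %in% names(report$dyna))
      stop("subgroup '", sg, "' not in report; available: ",
           paste(names(report$dyna), collapse = ", "), call. = FALSE)
  ca <- report$dyna[[a]]$complexity
  cb <- report$dyna[[b]]$complexity
  cx <- data.frame(interval = ca$interval, label = ca$label,
                   stringsAsFactors = FALSE)
  cx[[paste0("complexity_", a)]] <- ca$complexity
  cx[[paste0("complexity_", b)]] <- cb$complexity
  ta <- report$dyna[[a]]$connectivity
  tb <- report$dyna[[b]]$connectivity
  sfx <- paste0("_", c(a, b))
  if (a == b) sfx[2] <- paste0(sfx[2], ".b")  # self-comparison stays valid
  conn <- merge(ta, tb, by = "mediator", suffixes = sfx)
  conn$delta <- conn[[paste0("total_degree", sfx[2])]] -
    conn[[paste0("total_degree", sfx[1])]]
  conn <- conn[order(-abs(conn$delta), conn$mediator), , drop = FALSE]
  ea <- report$dybn[[a]]$consensus@edges
  eb <- report$dybn[[b]]$consensus@edges
  ka <- paste(ea$parent, ea$child, sep = "->")
  kb <- paste(eb$parent, eb$child, sep = "->")
  onlyIn <- function(e, keep, tag) {
    e <- e[keep, c("parent", "child"), drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    cbind(e, which = tag)
  }
  diff <- rbind(onlyIn(ea, !ka %in% kb, "a_only"),
                onlyIn(eb, !kb %in% ka, "b_only"))
  list(subgroups = c(a = a, b = b), complexity = cx, connectivity = conn,
       consensusDiff = diff,
       totalConnections = c(stats::setNames(
         c(report$dyna[[a]]$totalConnections,
           report$dyna[[b]]$totalConnections), c(a, b))))
}

#' Write a run report bundle to disk
#'
#' One directory per subgroup per stage, CSV outputs, and a
#' machine-readable index JSON (config echo, hash, warnings) at the root.
#' Rerunning with an identical configuration reproduces identical files.
#'
#' @param report a \code{"RunReport"}
#' @param dir output directory
#' @return invisibly, the index path
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sg in report$subgroups) {
    writeNetworks(report$dyna[[sg]]$networks, file.path(dir, sg, "dyna"))
    dd <- file.path(dir, sg, "dybn")
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
    post <- report$dybn[[sg]]$posterior
    utils::write.csv(edgeProbabilities(post),
                     file.path(dd, "posterior_matrix.csv"))
    utils::write.csv(report$dybn[[sg]]$consensus@edges,
                     file.path(dd, "consensus_edges.csv"), row.names = FALSE)
    writeLines(selfFeedback(report$dybn[[sg]]$consensus),
               file.path(dd, "self_feedback.txt"))
    jsonlite::write_json(post@diagnostics, file.path(dd, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  if (!is.null(report$volcano))
    utils::write.csv(as.data.frame(report$volcano),
                     file.path(dir, "volcano.csv"), row.names = FALSE)
  writeMediatorCSV(report$dataset, file.path(dir, "dataset.csv"))
  idx <- list(source = report$source, subgroups = report$subgroups,
              config = .serializableConfig(report$config),
              configHash = report$configHash, version = report$version,
              warnings = report$warnings)
  p <- file.path(dir, "index.json")
  jsonlite::write_json(idx, p, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(p)
}
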