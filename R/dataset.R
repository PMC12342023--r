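#' Construct a MediatorDataset from a long-format measurement table
#'
#' @param measurements data.frame with (at least) columns \code{subject},
#'   \code{subgroup}, \code{time}, \code{mediator}, \code{value} and
#'   optionally \code{censored}.
#' @param mediators optional ordered panel; defaults to the mediators present.
#' @param timeGrid optional numeric grid; defaults to sorted unique times.
#' @param timeLabels optional display labels parallel to \code{timeGrid};
#'   defaults to the numeric positions.
#' @param subgroups optional subgroup registry; defaults to those present.
#' @return A validated \linkS4class{MediatorDataset}.
#' @export
MediatorDataset <- function(measurements, mediators = NULL, timeGrid = NULL,
                            timeLabels = NULL, subgroups = NULL) {
  measurements <- as.data.frame(measurements)
  if (!"censored" %in% names(measurements)) measurements$censored <- FALSE
  measurements$subject  <- as.character(measurements$subject)
  measurements$subgroup <- as.character(measurements$subgroup)
  measurements$mediator <- as.character(measurements$mediator)
  measurements$time     <- as.numeric(measurements$time)
  measurements$value    <- as.numeric(measurements$value)
  measurements$censored <- as.logical(measurements$censored)
  if (is.null(mediators)) mediators <- unique(measurements$mediator)
  if (is.null(timeGrid))  timeGrid  <- sort(unique(measurements$time))
  if (is.null(timeLabels)) timeLabels <- as.character(timeGrid)
  if (is.null(subgroups)) subgroups <- unique(measurements$subgroup)
  methods::new("MediatorDataset",
    measurements = measurements[, c("subject", "subgroup", "time",
                                    "mediator", "value", "censored")],
    mediators = as.character(mediators), timeGrid = as.numeric(timeGrid),
    timeLabels = as.character(timeLabels), subgroups = as.character(subgroups))
}

#' @rdname MediatorDataset-class
#' @param x a \linkS4class{MediatorDataset}
#' @export
setMethod("mediators", "MediatorDataset", function(x) x@mediators)

#' @rdname MediatorDataset-class
#' @export
setMethod("timeGrid", "MediatorDataset", function(x) x@timeGrid)

#' @rdname MediatorDataset-class
#' @export
setMethod("timeLabels", "MediatorDataset", function(x) x@timeLabels)

#' @rdname MediatorDataset-class
#' @export
setMethod("subgroups", "MediatorDataset", function(x) x@subgroups)

#' @rdname MediatorDataset-class
#' @export
setMethod("measurements", "MediatorDataset", function(x) x@measurements)

setMethod("show", "MediatorDataset", function(object) {
  m <- object@measurements
  cat("MediatorDataset\n")
  cat(sprintf("  %d measurements | %d mediators | %d time points | subgroups: %s\n",
              nrow(m), length(object@mediators), length(object@timeGrid),
              paste(object@subgroups, collapse = ", ")))
  cat(sprintf("  subjects: %d | censored values: %d | missing values: %d\n",
              length(unique(m$subject)), sum(m$censored, na.rm = TRUE),
              sum(is.na(m$value))))
})

#' Consecutive-interval scheme of a dataset
#'
#' Returns the ordered list of closed intervals between adjacent time-grid
#' points, the windows over which dynamic networks are built (e.g. d0-d1,
#' d1-d2, ... for a daily serum panel; 1-3, 3-6, 6-24, 24-48 h for a
#' hepatocyte time course).
#'
#' @param x a \linkS4class{MediatorDataset} or \linkS4class{SyntheticSpec}
#' @return data.frame(index, start, end, label)
#' @export
setMethod("intervalScheme", "MediatorDataset", function(x) {
  .intervalScheme(x@timeGrid, x@timeLabels)
})

#' @rdname intervalScheme
#' @export
setMethod("intervalScheme", "SyntheticSpec", function(x) {
  .intervalScheme(x@timeGrid, x@timeLabels)
})

.intervalScheme <- function(tg, labels) {
  k <- length(tg) - 1L
  data.frame(index = seq_len(k), start = tg[-length(tg)], end = tg[-1],
             label = paste(labels[-length(labels)], labels[-1], sep = "-"),
             stringsAsFactors = FALSE)
}

.resolveInterval <- function(ds, interval) {
  sch <- intervalScheme(ds)
  if (length(interval) == 1 && is.numeric(interval)) {
    if (!interval %in% sch$index)
      stop("unknown interval index ", interval, "; scheme has ",
           nrow(sch), " intervals", call. = FALSE)
    return(sch[sch$index == interval, ])
  }
  if (length(interval) == 2) {
    hit <- which(sch$start == interval[1] & sch$end == interval[2])
    if (length(hit) != 1)
      stop("interval (", interval[1], ", ", interval[2],
           ") is not a consecutive pair of grid points", call. = FALSE)
    return(sch[hit, ])
  }
  stop("interval must be an index or a (start, end) pair", call. = FALSE)
}

.checkSubgroup <- function(ds, subgroup) {
  if (!subgroup %in% ds@subgroups)
    stop("unknown subgroup '", subgroup, "'; available: ",
         paste(ds@subgroups, collapse = ", "), call. = FALSE)
  invisible(subgroup)
}

#' Read a long-format mediator CSV
#'
#' Parses and validates a long-format table of mediator concentrations. Cells
#' that match a below-detection code (\code{"ND"}, \code{"<LOD"} or empty)
#' are handled by the censoring policy: \code{"half-lod"} substitutes
#' \code{lod/2} and flags the measurement; \code{"drop"} stores \code{NA}.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical field names
#'   (\code{subject}, \code{subgroup}, \code{time}, \code{mediator},
#'   \code{value}) to the file's column names.
#' @param censor censoring policy, \code{"half-lod"} or \code{"drop"}.
#' @param lod limit of detection used by the \code{"half-lod"} policy; may be
#'   a single number or a named vector per mediator.
#' @param ndCodes character codes that denote a below-detection cell.
#' @param ... passed to \code{\link{MediatorDataset}} (e.g. a fixed panel).
#' @return A \linkS4class{MediatorDataset}.
#' @export
readMediatorCSV <- function(path,
                            schema = c(subject = "subject_id",
                                       subgroup = "subgroup", time = "time",
                                       mediator = "mediator", value = "value"),
                            censor = c("half-lod", "drop"), lod = NA_real_,
                            ndCodes = c("ND", "<LOD", "BLQ"), ...) {
  censor <- match.arg(censor)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("subject", "subgroup", "time", "mediator", "value")
  missing_cols <- setdiff(schema[need], names(raw))
  if (length(missing_cols))
    stop("schema error: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(subject = raw[[schema[["subject"]]]],
                   subgroup = raw[[schema[["subgroup"]]]],
                   time = raw[[schema[["time"]]]],
                   mediator = raw[[schema[["mediator"]]]],
                   value_raw = trimws(raw[[schema[["value"]]]]),
                   stringsAsFactors = FALSE)
  tm <- suppressWarnings(as.numeric(df$time))
  if (anyNA(tm))
    stop("parse error: non-numeric time at row(s) ",
         paste(utils::head(which(is.na(tm)), 5), collapse = ", "), call. = FALSE)
  df$time <- tm
  is_nd <- df$value_raw %in% ndCodes
  is_empty <- df$value_raw == "" | is.na(df$value_raw)
  val <- suppressWarnings(as.numeric(df$value_raw))
  bad <- is.na(val) & !is_nd & !is_empty
  if (any(bad))
    stop("parse error: non-numeric value '", df$value_raw[which(bad)[1]],
         "' at row ", which(bad)[1], call. = FALSE)
  censored <- rep(FALSE, nrow(df))
  if (any(is_nd)) {
    if (censor == "half-lod") {
      lodv <- if (length(lod) > 1) unname(lod[df$mediator[is_nd]]) else rep(lod, sum(is_nd))
      if (anyNA(lodv))
        stop("half-lod policy requires a LOD for every censored mediator", call. = FALSE)
      val[is_nd] <- lodv / 2
      censored[is_nd] <- TRUE
    } else {
      val[is_nd] <- NA_real_
      censored[is_nd] <- TRUE
    }
  }
  df$value <- val
  df$censored <- censored
  key <- paste(df$subject, df$time, df$mediator, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("integrity error: duplicate (subject, time, mediator) at rows ",
         paste(rows, collapse = ", "), call. = FALSE)
  }
  MediatorDataset(df[, c("subject", "subgroup", "time", "mediator",
                         "value", "censored")], ...)
}

#' Write a MediatorDataset as canonical long CSV
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
writeMediatorCSV <- function(ds, path) {
  m <- ds@measurements
  out <- data.frame(subject_id = m$subject, subgroup = m$subgroup,
                    time = m$time, mediator = m$mediator, value = m$value,
                    censored = m$censored)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a dataset as counts per subgroup and time
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @return list with per-(subgroup, time) sample counts and totals,
#'   serializable to JSON.
#' @export
datasetSummary <- function(ds) {
  m <- ds@measurements
  tab <- as.data.frame(table(subgroup = m$subgroup, time = m$time),
                       stringsAsFactors = FALSE)
  tab$time <- as.numeric(tab$time)
  list(n_measurements = nrow(m),
       n_subjects = length(unique(m$subject)),
       mediators = ds@mediators,
       time_grid = ds@timeGrid,
       subgroups = ds@subgroups,
       counts = tab[tab$Freq > 0, ],
       n_missing = sum(is.na(m$value)),
       n_censored = sum(m$censored, na.rm = TRUE))
}

#' Wide observation matrix for one subgroup
#'
#' Internal pivot: rows are (subject, time) samples, columns the mediator
#' panel; absent measurements are NA.
#' @noRd
.wideMatrix <- function(ds, subgroup, times = NULL) {
  m <- ds@measurements
  m <- m[m$subgroup == subgroup & (is.null(times) | m$time %in% times), ,
         drop = FALSE]
  if (!is.null(times)) m <- m[m$time %in% times, , drop = FALSE]
  med <- ds@mediators
  if (nrow(m) == 0) {
    mat <- matrix(NA_real_, 0, length(med), dimnames = list(NULL, med))
    attr(mat, "sampleInfo") <- data.frame(subject = character(),
                                          time = numeric())
    return(mat)
  }
  sk <- paste(m$subject, m$time, sep = "\r")
  samples <- unique(sk)
  mat <- matrix(NA_real_, length(samples), length(med),
                dimnames = list(NULL, med))
  mat[cbind(match(sk, samples), match(m$mediator, med))] <- m$value
  parts <- do.call(rbind, strsplit(samples, "\r", fixed = TRUE))
  info <- data.frame(subject = parts[, 1], time = as.numeric(parts[, 2]),
                     stringsAsFactors = FALSE)
  ord <- order(info$subject, info$time)
  mat <- mat[ord, , drop = FALSE]
  attr(mat, "sampleInfo") <- info[ord, , drop = FALSE]
  mat
}

#' Boundary-time observation table for one interval window
#'
#' Returns all samples of a subgroup at the two boundary time points of a
#' consecutive interval, stacked (one row per subject-by-time sample, one
#' column per mediator). Rows with no observed mediator are dropped;
#' per-pair completeness is left to the consumer (pairwise deletion).
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param subgroup subgroup label
#' @param interval interval index into \code{\link{intervalScheme}}, or a
#'   \code{c(start, end)} pair of adjacent grid positions
#' @return numeric matrix with a \code{"sampleInfo"} attribute
#'   (data.frame: subject, time).
#' @export
windowSlice <- function(ds, subgroup, interval) {
  .checkSubgroup(ds, subgroup)
  iv <- .resolveInterval(ds, interval)
  mat <- .wideMatrix(ds, subgroup, times = c(iv$start, iv$end))
  keep <- rowSums(!is.na(mat)) > 0
  info <- attr(mat, "sampleInfo")
  mat <- mat[keep, , drop = FALSE]
  attr(mat, "sampleInfo") <- info[keep, , drop = FALSE]
  attr(mat, "interval") <- iv
  mat
}

#' Per-mediator z-scoring within a subgroup
#'
#' Pivots a subgroup's measurements to a (subject, time) x mediator matrix
#' and standardizes each mediator to mean 0, sample sd 1 over its non-missing
#' entries. Mediators with fewer than two observed values or zero variance
#' are excluded with a warning (never silently); missing entries propagate.
#'
#' @param ds a \linkS4class{MediatorDataset}
#' @param subgroup subgroup label
#' @param log whether to log-transform (natural log) positive concentrations
#'   before standardizing; default \code{TRUE}, matching the lognormal
#'   character of mediator panels.
#' @return numeric matrix (samples x retained mediators) with attributes
#'   \code{"sampleInfo"} and \code{"excluded"}.
#' @export
zscoreByMediator <- function(ds, subgroup, log = TRUE) {
  .checkSubgroup(ds, subgroup)
  mat <- .wideMatrix(ds, subgroup)
  if (log) {
    bad <- !is.na(mat) & mat <= 0
    if (any(bad)) mat[bad] <- NA
    mat <- base::log(mat)
  }
  mu <- colMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  nobs <- colSums(!is.na(mat))
  drop <- nobs < 2 | is.na(sdv) | sdv == 0
  if (any(drop))
    warning("excluding zero-variance or under-observed mediator(s): ",
            paste(colnames(mat)[drop], collapse = ", "), call. = FALSE)
  keep <- which(!drop)
  z <- sweep(sweep(mat[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  attr(z, "sampleInfo") <- attr(mat, "sampleInfo")
  attr(z, "excluded") <- colnames(mat)[drop]
  z
}
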