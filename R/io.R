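## On-disk formats: long-format TSV for tensors (entity1, entity2, time,
## value), JSON for modules, ground truth, evaluation reports and run
## manifests.

#' @importFrom data.table fread fwrite data.table as.data.table
NULL

.usageStop <- function(...) {
    stop(errorCondition(paste0(...), class = c("tritvUsageError", "error")))
}

## order labels: numerically when every label parses as a number, otherwise
## lexicographically
.sortLabels <- function(x) {
    num <- suppressWarnings(as.numeric(x))
    if (!anyNA(num)) x[order(num)] else sort(x)
}

#' Read a tensor from long-format TSV
#'
#' Expects a tab-separated file with header columns \code{entity1},
#' \code{entity2}, \code{time}, \code{value}. Axes are built from the sorted
#' unique labels of each column (numeric ordering when a column is fully
#' numeric, so time grids like 10, 20, ..., 80 order correctly). The tensor
#' must be dense: duplicated triples are an error, and missing triples are an
#' error naming the first gaps unless \code{fillMissing = "interpolate"},
#' which fills each (entity1, entity2) time series by linear interpolation
#' between the two closest available time-points and replaces any value still
#' missing (leading/trailing gaps) with the average observed value at the
#' corresponding time-point.
#'
#' @param path file path
#' @param fillMissing \code{"none"} (default) or \code{"interpolate"}
#' @return an \linkS4class{InteractionTensor}
#' @export
readTensorTSV <- function(path, fillMissing = c("none", "interpolate")) {
    fillMissing <- match.arg(fillMissing)
    if (!file.exists(path)) .usageStop("input file not found: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1:3), data.table = TRUE)
    need <- c("entity1", "entity2", "time", "value")
    if (!all(need %in% names(dt)))
        .usageStop("TSV must have header columns entity1, entity2, time, ",
                   "value; found: ", paste(names(dt), collapse = ", "))
    val <- suppressWarnings(as.numeric(dt$value))
    bad <- which(!is.finite(val))
    if (length(bad))
        .usageStop("non-numeric or non-finite value(s) at data line(s) ",
                   paste(utils::head(bad, 10L), collapse = ", "))
    g <- .sortLabels(unique(dt$entity1))
    cc <- .sortLabels(unique(dt$entity2))
    tt <- .sortLabels(unique(dt$time))
    key <- paste(dt$entity1, dt$entity2, dt$time, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup))
        .usageStop("duplicated (entity1, entity2, time) triple(s) at data ",
                   "line(s) ", paste(utils::head(dup, 10L), collapse = ", "))
    a <- array(NA_real_, c(length(g), length(cc), length(tt)),
               dimnames = list(g, cc, tt))
    a[cbind(match(dt$entity1, g), match(dt$entity2, cc),
            match(dt$time, tt))] <- val
    if (anyNA(a)) {
        if (fillMissing == "none") {
            gaps <- which(is.na(a), arr.ind = TRUE)
            msg <- apply(utils::head(gaps, 10L), 1L, function(r)
                sprintf("(%s, %s, %s)", g[r[1]], cc[r[2]], tt[r[3]]))
            .usageStop("tensor is not dense: ", sum(is.na(a)),
                       " missing triple(s), first gaps: ",
                       paste(msg, collapse = " "),
                       "; use fillMissing = \"interpolate\" to impute")
        }
        a <- .fillMissing(a)
    }
    InteractionTensor(a)
}

.fillMissing <- function(a) {
    d <- dim(a)
    tidx <- seq_len(d[3])
    ## pass 1: per-series linear interpolation between the two closest
    ## available time-points (interior gaps only)
    for (r in seq_len(d[1])) for (s in seq_len(d[2])) {
        y <- a[r, s, ]
        obs <- !is.na(y)
        if (all(obs) || sum(obs) < 2L) next
        a[r, s, ] <- stats::approx(tidx[obs], y[obs], xout = tidx,
                                   method = "linear", rule = 1)$y
    }
    ## pass 2: whatever remains (edges, near-empty series) takes the mean
    ## observed value at its time-point
    for (t in tidx) {
        sl <- a[, , t]
        if (anyNA(sl)) {
            m <- mean(sl, na.rm = TRUE)
            if (is.nan(m)) m <- mean(a, na.rm = TRUE)
            sl[is.na(sl)] <- m
            a[, , t] <- sl
        }
    }
    if (anyNA(a)) .usageStop("could not impute all missing values")
    a
}

#' Write a tensor as long-format TSV
#'
#' Inverse of \code{\link{readTensorTSV}}: one row per cell, columns
#' \code{entity1}, \code{entity2}, \code{time}, \code{value}.
#'
#' @param tensor an \linkS4class{InteractionTensor}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeTensorTSV <- function(tensor, path) {
    stopifnot(is(tensor, "InteractionTensor"))
    a <- tensor@values
    d <- dim(a)
    dn <- dimnames(a)
    dt <- data.table::data.table(
        entity1 = rep(dn[[1]], times = d[2] * d[3]),
        entity2 = rep(rep(dn[[2]], each = d[1]), times = d[3]),
        time = rep(dn[[3]], each = d[1] * d[2]),
        value = as.vector(a))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Read a directory of per-condition gene x time matrices
#'
#' Convenience reader for data shipped as one TSV per condition: each file
#' has genes in rows (first column = gene label) and time-points in columns;
#' the condition label is the file name without extension. All files must
#' share the same genes and time grid.
#'
#' @param dir directory containing \code{*.tsv} files
#' @param fillMissing as in \code{\link{readTensorTSV}}
#' @return an \linkS4class{InteractionTensor}
#' @export
readConditionDir <- function(dir, fillMissing = c("none", "interpolate")) {
    fillMissing <- match.arg(fillMissing)
    files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) .usageStop("no .tsv files in ", dir)
    mats <- lapply(files, function(f) {
        m <- data.table::fread(f, sep = "\t", header = TRUE)
        genes <- as.character(m[[1]])
        v <- as.matrix(m[, -1, drop = FALSE])
        rownames(v) <- genes
        v
    })
    genes <- rownames(mats[[1]])
    times <- colnames(mats[[1]])
    for (m in mats)
        if (!identical(rownames(m), genes) || !identical(colnames(m), times))
            .usageStop("per-condition matrices disagree on genes or time grid")
    conds <- sub("\\.tsv$", "", basename(files))
    a <- array(NA_real_, c(length(genes), length(conds), length(times)),
               dimnames = list(genes, conds, times))
    for (j in seq_along(mats)) a[, j, ] <- mats[[j]]
    if (anyNA(a)) {
        if (fillMissing == "none")
            .usageStop("missing values present; use fillMissing = ",
                       "\"interpolate\"")
        a <- .fillMissing(a)
    }
    InteractionTensor(a)
}

.moduleToList <- function(m) {
    list(k = m@k, genes = m@genes, conditions = m@conditions,
         timepoints = m@timepoints, degenerate = m@degenerate,
         time_contiguous = m@timeContiguous)
}

#' Write modules to JSON
#'
#' One object per module: \code{k}, \code{genes}, \code{conditions},
#' \code{timepoints}, \code{degenerate} flags and whether the time set is
#' contiguous.
#'
#' @param modules list of \linkS4class{TriModule}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeModulesJSON <- function(modules, path) {
    jsonlite::write_json(lapply(modules, .moduleToList), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read modules from JSON
#'
#' @param path path written by \code{\link{writeModulesJSON}}
#' @return list of \linkS4class{TriModule}
#' @export
readModulesJSON <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    lapply(raw, function(m)
        new("TriModule", k = as.integer(m$k),
            genes = as.character(unlist(m$genes)),
            conditions = as.character(unlist(m$conditions)),
            timepoints = as.character(unlist(m$timepoints)),
            degenerate = as.character(unlist(m$degenerate)),
            timeContiguous = isTRUE(m$time_contiguous)))
}

#' Write module TSV (flat form)
#'
#' One row per (module, axis, label) membership, handy for joins in other
#' tools.
#'
#' @param modules list of \linkS4class{TriModule}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeModulesTSV <- function(modules, path) {
    rows <- do.call(rbind, lapply(modules, function(m) {
        data.frame(module_id = m@k,
                   axis = rep(c("gene", "condition", "time"),
                              c(length(m@genes), length(m@conditions),
                                length(m@timepoints))),
                   label = c(m@genes, m@conditions, m@timepoints))
    }))
    if (is.null(rows))
        rows <- data.frame(module_id = integer(0), axis = character(0),
                           label = character(0))
    data.table::fwrite(rows, path, sep = "\t")
    invisible(path)
}

#' Write ground truth to JSON
#'
#' @param truth a \linkS4class{GroundTruth}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGroundTruthJSON <- function(truth, path) {
    jsonlite::write_json(list(
        dims = truth@dims,
        noise_density = truth@noiseDensity,
        seed = truth@seed,
        axis_labels = truth@axisLabels,
        modules = lapply(truth@modules, function(m) list(
            genes = m@genes, conditions = m@conditions,
            time_start = m@timeStart, time_end = m@timeEnd,
            signal_low = m@signalLow, signal_high = m@signalHigh))),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path path written by \code{\link{writeGroundTruthJSON}}
#' @return a \linkS4class{GroundTruth}
#' @export
readGroundTruthJSON <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    new("GroundTruth",
        modules = lapply(raw$modules, function(m)
            new("PlantedModule", genes = as.integer(unlist(m$genes)),
                conditions = as.integer(unlist(m$conditions)),
                timeStart = as.integer(m$time_start),
                timeEnd = as.integer(m$time_end),
                signalLow = as.numeric(m$signal_low),
                signalHigh = as.numeric(m$signal_high))),
        noiseDensity = as.numeric(raw$noise_density),
        seed = as.integer(raw$seed),
        dims = as.integer(unlist(raw$dims)),
        axisLabels = lapply(raw$axis_labels, function(x)
            as.character(unlist(x))))
}

#' Write an evaluation report to JSON
#'
#' @param report list from \code{\link{evaluateModules}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEvaluationJSON <- function(report, path) {
    jsonlite::write_json(list(
        fscore = report$fscore, nmi = report$nmi,
        per_module_f1 = report$perModuleF1,
        matching = report$matching),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

## Run manifest: everything needed to reproduce a run bit-for-bit.
.writeManifest <- function(path, command, config, extra = list()) {
    manifest <- c(list(
        command = command,
        config = config,
        package = "TriTV",
        package_version = as.character(utils::packageVersion("TriTV")),
        r_version = R.version.string,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
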