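#' Read an ensemble from a long-format CSV file
#'
#' Continuous data use columns `sample_id,value` (one row per observation);
#' categorical data use `sample_id,category,count`. Comma-separated, UTF-8,
#' header required. An optional `label` column (as written by the
#' organised-noise generator) is carried through as the `labels` attribute.
#'
#' @param path CSV file path.
#' @param kind `"continuous"` or `"categorical"`.
#' @param ... Passed to [ensemble()] (e.g. `weighting`).
#' @return An [ensemble()].
#' @export
read_samples <- function(path, kind = c("continuous", "categorical"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  required <- if (kind == "continuous") c("sample_id", "value") else
    c("sample_id", "category", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s for kind '%s'", path,
                 paste(missing_cols, collapse = ", "), kind), call. = FALSE)
  }
  num_col <- if (kind == "continuous") "value" else "count"
  vals <- suppressWarnings(as.numeric(df[[num_col]]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("%s: line %d, column '%s': not a number (%s)", path,
                 bad + 1L, num_col, df[[num_col]][bad]), call. = FALSE)
  }
  df[[num_col]] <- vals
  ids <- unique(df$sample_id)
  samples <- lapply(ids, function(sid) {
    sub <- df[df$sample_id == sid, , drop = FALSE]
    if (kind == "continuous") {
      replicate_sample(sid, observations = sub$value)
    } else {
      replicate_sample(sid, counts = stats::setNames(sub$count, sub$category))
    }
  })
  ens <- ensemble(samples, ...)
  if ("label" %in% names(df)) {
    attr(ens, "labels") <- vapply(ids, function(sid) {
      df$label[df$sample_id == sid][1L]
    }, df$label[1L])
  }
  ens
}

#' Write an ensemble to long-format CSV
#'
#' @param ens An [ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  labels <- attr(ens, "labels")
  rows <- lapply(seq_along(ens$samples), function(i) {
    s <- ens$samples[[i]]
    d <- if (s$kind == "continuous") {
      data.frame(sample_id = s$id, value = s$observations)
    } else {
      data.frame(sample_id = s$id, category = names(s$counts),
                 count = as.numeric(s$counts))
    }
    if (!is.null(labels)) d$label <- labels[i]
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Provenance block embedded in every written report: the command name, the
#' full parameter set, the master seed and the package version. Re-running
#' the same manifest on deterministic paths reproduces the report.
#'
#' @param command Name of the producing command/function.
#' @param parameters Named list of parameters.
#' @param seed Master seed used (or `NULL`).
#' @return A list of class `run_manifest` (includes a timestamp, which is
#'   excluded from reproducibility comparisons).
#' @export
run_manifest <- function(command, parameters = list(), seed = NULL) {
  structure(list(
    command = command,
    parameters = parameters,
    seed = seed,
    version = as.character(utils::packageVersion("cohesr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write an ensemble report to JSON
#'
#' Serialises an [analyse_ensemble()] report (plus a [run_manifest()]) to a
#' JSON document with floats at full precision.
#'
#' @param report An `ensemble_report`.
#' @param path Output path.
#' @param manifest Optional [run_manifest()]; a minimal one is generated
#'   when omitted.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, manifest = NULL) {
  stopifnot(inherits(report, "ensemble_report"))
  if (is.null(manifest)) manifest <- run_manifest("analyse_ensemble")
  body <- unclass(report)
  body$pairs <- as.data.frame(body$pairs)
  body$manifest <- unclass(manifest)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON ensemble report
#'
#' @param path Path written by [write_report()].
#' @return An `ensemble_report` (manifest attached as attribute
#'   `manifest`).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  body <- jsonlite::read_json(path, simplifyVector = TRUE)
  manifest <- body$manifest
  body$manifest <- NULL
  body$H_k <- unlist(body$H_k)
  structure(body, manifest = manifest, class = "ensemble_report")
}
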