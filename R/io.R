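#' Read incubation times from a plain numeric CSV
#'
#' Reads a single numeric column (one value per row); a non-numeric first
#' line is treated as a header and skipped.
#'
#' @param path CSV file path.
#' @return Numeric vector of times.
#' @export
read_incubation_times <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no data in ", path, call. = FALSE)
  first <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(first)) lines <- lines[-1L]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) stop("non-numeric entries in ", path, call. = FALSE)
  x
}

#' Write a sample set as CSV with a JSON sidecar
#'
#' Writes the takeover times one per row to `<path>` (with a `time` header)
#' and the simulation provenance (spec fields and the number of rejected
#' extinct trials) to `<path>.json`.
#'
#' @param sample_set A `sample_set` from the ensemble runners.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(sample_set, path) {
  stopifnot(inherits(sample_set, "sample_set"))
  writeLines(c("time", format(sample_set$times, scientific = FALSE, trim = TRUE)), path)
  spec <- sample_set$spec
  meta <- if (inherits(spec, "simulation_spec")) {
    list(
      family = spec$network$family,
      n_nodes = spec$network$n_nodes,
      network_params = spec$network$params,
      rule = spec$rule,
      fitness = if (is.infinite(spec$fitness)) "Inf" else spec$fitness,
      dose = spec$dose,
      threshold = spec$threshold
    )
  } else {
    spec
  }
  meta$n_rejected <- sample_set$n_rejected
  meta$n_samples <- length(sample_set$times)
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a sample set written by [write_sample_set()]
#'
#' @param path CSV path (the `.json` sidecar is read if present).
#' @return A `sample_set` (spec is the plain metadata list from the sidecar).
#' @export
read_sample_set <- function(path) {
  times <- read_incubation_times(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  n_rej <- if (!is.null(meta$n_rejected)) meta$n_rejected else 0
  structure(
    list(times = times, spec = meta, n_rejected = n_rej),
    class = "sample_set"
  )
}
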