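#' Provenance records
#'
#' Every written map carries a JSON provenance record: an ordered list of
#' processing steps, each with the step name, the full parameter set used,
#' input identifiers, software version and a timestamp. Records round-trip
#' through JSON without loss.
#'
#' @param description free-text description of the run.
#' @return object of class `provenance_record`.
#' @export
provenance_record <- function(description = "") {
  structure(list(description = description,
                 software = "mpmmaps",
                 version = as.character(utils::packageVersion("mpmmaps")),
                 steps = list()),
            class = "provenance_record")
}

#' @rdname provenance_record
#' @param record a `provenance_record`.
#' @param step step name (character scalar).
#' @param params named list of all settings used by the step (scalars and
#'   numeric vectors).
#' @param inputs character vector of input identifiers.
#' @export
prov_add_step <- function(record, step, params = list(), inputs = character(0)) {
  stopifnot(inherits(record, "provenance_record"))
  record$steps[[length(record$steps) + 1L]] <-
    list(step = step, params = params, inputs = as.character(inputs),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  record
}

#' @rdname provenance_record
#' @param path JSON file path.
#' @export
write_provenance <- function(record, path) {
  stopifnot(inherits(record, "provenance_record"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname provenance_record
#' @export
read_provenance <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  structure(rec, class = "provenance_record")
}
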