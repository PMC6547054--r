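# Output naming conventions. Map files are written as
# <basename>_<suffix>.nii with a JSON provenance file alongside; the
# basename derives from the first echo of the PDw series. Supplementary
# products go to Results/Supplementary.

MAP_KINDS <- list(
  MTsat   = list(suffix = "_MTsat",   supplementary = FALSE),
  PD      = list(suffix = "_PD",      supplementary = FALSE),
  R1      = list(suffix = "_R1",      supplementary = FALSE),
  R2s_OLS = list(suffix = "_R2s_OLS", supplementary = FALSE),
  R2s     = list(suffix = "_R2s",     supplementary = TRUE),
  B1map   = list(suffix = "_B1map",   supplementary = TRUE),
  B1ref   = list(suffix = "_B1ref",   supplementary = TRUE),
  PDw_TEzero = list(suffix = "_PDw_OLSfit_TEzero", supplementary = TRUE),
  T1w_TEzero = list(suffix = "_T1w_OLSfit_TEzero", supplementary = TRUE),
  MTw_TEzero = list(suffix = "_MTw_OLSfit_TEzero", supplementary = TRUE)
)

#' Output file naming
#'
#' Pure function from (kind, basename source) to the output file name.
#'
#' @param kind one of `names(mpmmaps:::MAP_KINDS)`: `MTsat`, `PD`, `R1`,
#'   `R2s_OLS`, `R2s`, `B1map`, `B1ref`, `PDw_TEzero`, `T1w_TEzero`,
#'   `MTw_TEzero`.
#' @param basename_source file path or basename the output name derives
#'   from (conventionally the first PDw echo; the B1 input file for
#'   `B1map`/`B1ref`).
#' @return file name (no directory), `.nii`.
#' @export
map_filename <- function(kind, basename_source) {
  k <- MAP_KINDS[[kind]]
  if (is.null(k)) stop("unknown map kind: ", kind)
  base <- sub("\\.nii(\\.gz)?$", "", basename(basename_source))
  paste0(base, k$suffix, ".nii")
}

is_supplementary_kind <- function(kind) MAP_KINDS[[kind]]$supplementary

#' Resolve the Results directory for a run
#'
#' Outputs are never overwritten: when the Results directory already holds a
#' previous run (detected by the presence of any file), a fresh run
#' sub-folder `Results/run-NN` is used instead.
#'
#' @param out_dir parent directory for outputs.
#' @return path of the Results directory to write into (created).
#' @export
resolve_results_dir <- function(out_dir) {
  base <- file.path(out_dir, "Results")
  if (!dir.exists(base) ||
      length(list.files(base, recursive = TRUE)) == 0L) {
    dir.create(base, recursive = TRUE, showWarnings = FALSE)
    return(base)
  }
  k <- 2L
  repeat {
    cand <- file.path(base, sprintf("run-%02d", k))
    if (!dir.exists(cand)) {
      dir.create(cand, recursive = TRUE, showWarnings = FALSE)
      return(cand)
    }
    k <- k + 1L
  }
}

#' Write a parameter map with provenance
#'
#' Writes `<basename>_<suffix>.nii` plus a `.json` provenance file into the
#' `Results` directory (supplementary kinds into `Results/Supplementary`).
#' Existing outputs are never overwritten: a new run sub-folder is created.
#'
#' @param volume a [qvol].
#' @param kind map kind, see [map_filename()].
#' @param out_dir parent directory (the `Results` tree is created inside).
#' @param basename_source path or basename the output name derives from.
#' @param provenance a [provenance_record()].
#' @param results_dir already-resolved results directory (used by the
#'   pipeline so that one run shares one folder); default resolves from
#'   `out_dir`.
#' @return path of the written NIfTI file.
#' @export
write_map <- function(volume, kind, out_dir, basename_source,
                      provenance = provenance_record(),
                      results_dir = NULL) {
  fname <- map_filename(kind, basename_source)
  if (is.null(results_dir)) {
    results_dir <- file.path(out_dir, "Results")
    dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
    probe <- file.path(
      if (is_supplementary_kind(kind)) file.path(results_dir, "Supplementary")
      else results_dir, fname)
    if (file.exists(probe)) results_dir <- resolve_results_dir(out_dir)
  }
  dir <- if (is_supplementary_kind(kind))
    file.path(results_dir, "Supplementary") else results_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, fname)
  write_volume(volume, path)
  write_provenance(provenance, sub("\\.nii$", ".json", path))
  path
}

#' Write a parameter-log JSON into Results/Supplementary
#'
#' @param params named list of parameters.
#' @param name file name (e.g. `hMRI_map_creation_mpm_params.json`).
#' @param results_dir resolved Results directory.
#' @return written path.
#' @export
write_param_log <- function(params, name, results_dir) {
  dir <- file.path(results_dir, "Supplementary")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, name)
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
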