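#' Residual dispersion of the R2* fit (intra-scan quality proxy)
#'
#' Pooled standard deviation of the log-domain ESTATICS residuals of one
#' contrast over a mask: the root mean square of the per-voxel residuals
#' across all echoes. Motion (and noise) during an echo train inflates the
#' deviation of the measured decay from the mono-exponential model, so this
#' statistic serves as an intra-scan degradation proxy. It is invariant to
#' global scaling of the contrast's signals (a global scale shifts only the
#' log intercept).
#'
#' @param fit an [fit_estatics()] result.
#' @param contrast contrast label present in the fit.
#' @param mask logical/0-1 array or [qvol]; typically a white-matter-like
#'   region.
#' @return scalar SD (dimensionless log-signal units).
#' @export
residual_sd <- function(fit, contrast, mask) {
  stopifnot(is_estatics_fit(fit))
  rss <- fit$resid_rss[[contrast]]
  if (is.null(rss)) stop("residual_sd: no residuals for contrast ", contrast)
  m <- as_vol_array(mask) > 0 & fit$mask$data > 0
  if (!any(m)) stop("residual_sd: empty mask")
  sqrt(sum(rss$data[m]) / (sum(m) * fit$n_echoes[[contrast]]))
}

#' Inter-contrast consistency index
#'
#' For each pair of contrasts in the fit: the median absolute deviation of
#' the voxelwise log-intercept difference after removing its mask median.
#' Spatially uniform differences between contrasts (true contrast, global
#' scale) are removed by the median; spatially varying inconsistency --
#' e.g. a receive-sensitivity profile that moved with the head between
#' scans -- inflates the index.
#'
#' @inheritParams residual_sd
#' @return data.frame with columns `contrast_a`, `contrast_b`, `index`;
#'   zero rows when the fit holds a single contrast.
#' @export
inter_contrast_index <- function(fit, mask) {
  stopifnot(is_estatics_fit(fit))
  ctr <- names(fit$log_intercepts)
  m <- as_vol_array(mask) > 0 & fit$mask$data > 0
  if (!any(m)) stop("inter_contrast_index: empty mask")
  out <- data.frame(contrast_a = character(0), contrast_b = character(0),
                    index = numeric(0))
  if (length(ctr) < 2L) return(out)
  pairs <- utils::combn(ctr, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    d <- fit$log_intercepts[[a]]$data[m] - fit$log_intercepts[[b]]$data[m]
    out <- rbind(out, data.frame(contrast_a = a, contrast_b = b,
                                 index = stats::mad(d)))
  }
  out
}

#' Assemble and write the quality-assessment report
#'
#' The report is descriptive (no pass/fail thresholds): per-contrast
#' residual SDs, pairwise inter-contrast indices, and invalid/clipped voxel
#' counts. The residual statistics are proxies for intra-/inter-scan
#' degradation computed from the model fit itself, not a calibrated motion
#' measurement; the report labels them as such.
#'
#' @inheritParams residual_sd
#' @return object of class `qa_report` (a named list, JSON-serialisable).
#' @export
qa_report <- function(fit, mask) {
  stopifnot(is_estatics_fit(fit))
  ctr <- names(fit$intercepts)
  sds <- lapply(ctr, function(cc) residual_sd(fit, cc, mask))
  names(sds) <- ctr
  ici <- inter_contrast_index(fit, mask)
  inter <- if (nrow(ici) == 0L) "not applicable (single contrast)"
  else lapply(seq_len(nrow(ici)), function(k)
    list(pair = c(ici$contrast_a[k], ici$contrast_b[k]),
         index = ici$index[k]))
  structure(list(
    description = paste("Model-fit-based quality proxies: residual",
                        "dispersion (intra-scan) and inter-contrast",
                        "intercept consistency (inter-scan). Indicative,",
                        "not calibrated against measured motion."),
    residual_sd = sds,
    inter_contrast_index = inter,
    n_invalid_voxels = fit$n_invalid,
    n_clipped_r2s_voxels = fit$n_clipped,
    n_mask_voxels = sum(as_vol_array(mask) > 0 & fit$mask$data > 0)
  ), class = "qa_report")
}

#' @rdname qa_report
#' @param report a `qa_report`.
#' @param out_dir parent directory; the file is written to
#'   `Results/Supplementary` (created if needed).
#' @param results_dir already-resolved results directory (pipeline use).
#' @return written path.
#' @export
write_qa <- function(report, out_dir = NULL, results_dir = NULL) {
  stopifnot(inherits(report, "qa_report"))
  if (is.null(results_dir)) {
    if (is.null(out_dir)) stop("write_qa: out_dir or results_dir required")
    results_dir <- file.path(out_dir, "Results")
  }
  dir <- file.path(results_dir, "Supplementary")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "hMRI_map_creation_quality_assessment.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname qa_report
#' @param path a written QA JSON file.
#' @export
read_qa <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE),
            class = "qa_report")
}
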