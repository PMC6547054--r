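#' Map-creation pipeline configuration
#'
#' Bundles all inputs and settings of [create_maps()]. Inputs may be given
#' in memory (series/field objects) or as file paths; a path-based
#' configuration serialises to JSON inside the output provenance, which
#' allows bit-exact re-execution via [config_from_provenance()].
#'
#' @param series named list keyed by contrast (`PDw`, `T1w`, `MTw`); each
#'   element an [mpm_series] or a character vector of per-echo NIfTI paths.
#'   A PDw entry is required.
#' @param b1 B1-transmit option: `NULL` (none), a [transmit_field], an
#'   [afi_pair], or a path to a pre-computed map (percent units or
#'   fraction, auto-detected).
#' @param rfsens_mode receive-sensitivity option: `"none"`, `"single"` or
#'   `"per_contrast"`.
#' @param rfsens receive field(s): a [qvol]/[receive_from_pair()] result
#'   (single) or a named list per contrast (per_contrast); paths accepted.
#' @param spoiling [spoiling_coefficients()] or `NULL` (disabled, the
#'   default).
#' @param pd_mask calibration mask for [calibrate_pd()] (`NULL`: relative
#'   calibration over the validity mask).
#' @param pd_target calibration target in p.u. (default 69 with mask, 100
#'   without).
#' @param mt_c constant of [b1_correct_mt()]; applied only when a transmit
#'   field is available.
#' @param te_max optional echo-selection cap in ms (see [fit_estatics()]).
#' @param out_dir output directory; `NULL` computes maps without writing.
#' @param basename basename for output files; defaults to the PDw series
#'   source (first PDw echo file).
#' @return a `map_config` list.
#' @export
map_config <- function(series, b1 = NULL,
                       rfsens_mode = c("none", "single", "per_contrast"),
                       rfsens = NULL, spoiling = NULL,
                       pd_mask = NULL, pd_target = NULL, mt_c = 0.4,
                       te_max = NULL, out_dir = NULL, basename = NULL) {
  rfsens_mode <- match.arg(rfsens_mode)
  if (is.null(series$PDw))
    stop("configuration error: a PDw series is required (stage: input)")
  if (!is.null(series$MTw) && is.null(series$T1w))
    stop("configuration error: MT saturation requires a T1w series ",
         "in addition to MTw (stage: input)")
  if (rfsens_mode != "none" && is.null(rfsens))
    stop("configuration error: rfsens_mode '", rfsens_mode,
         "' but no receive field supplied (stage: receive_correction)")
  structure(list(series = series, b1 = b1, rfsens_mode = rfsens_mode,
                 rfsens = rfsens, spoiling = spoiling, pd_mask = pd_mask,
                 pd_target = pd_target, mt_c = mt_c, te_max = te_max,
                 out_dir = out_dir, basename = basename),
            class = "map_config")
}

# serialise what is path-based; in-memory objects are tagged as such
config_as_json_list <- function(config) {
  ser_series <- lapply(config$series, function(s)
    if (is.character(s)) s else "<in-memory>")
  b1 <- config$b1
  b1s <- if (is.null(b1)) NULL
  else if (is.character(b1)) list(type = "precomputed", path = b1)
  else if (inherits(b1, "afi_pair")) list(type = "afi", source = "<in-memory>")
  else list(type = "field", source = "<in-memory>")
  rf <- config$rfsens
  rfs <- if (is.null(rf)) NULL
  else if (is.character(rf)) rf
  else if (is.list(rf) && all(vapply(rf, is.character, logical(1)))) rf
  else "<in-memory>"
  list(series = ser_series, b1 = b1s, rfsens_mode = config$rfsens_mode,
       rfsens = rfs,
       spoiling = if (is.null(config$spoiling)) NULL else
         list(acoef = config$spoiling$acoef, bcoef = config$spoiling$bcoef,
              protocol = config$spoiling$protocol),
       pd_mask = if (is.null(config$pd_mask)) NULL else "<in-memory>",
       pd_target = config$pd_target, mt_c = config$mt_c,
       te_max = config$te_max, out_dir = config$out_dir,
       basename = config$basename)
}

#' Rebuild a pipeline configuration from a provenance JSON
#'
#' Re-reads the configuration embedded in a map's provenance record. Only
#' path-based configurations are fully recoverable; in-memory inputs are
#' rejected.
#'
#' @param path a provenance `.json` written by [create_maps()].
#' @param out_dir optionally override the output directory.
#' @return a [map_config()].
#' @export
config_from_provenance <- function(path, out_dir = NULL) {
  rec <- read_provenance(path)
  cj <- rec$config
  if (is.null(cj)) stop("config_from_provenance: no config in record")
  has_mem <- function(x) identical(x, "<in-memory>")
  if (any(vapply(cj$series, has_mem, logical(1))))
    stop("config_from_provenance: in-memory inputs cannot be re-executed")
  b1 <- if (is.null(cj$b1)) NULL
  else if (identical(cj$b1$type, "precomputed")) cj$b1$path
  else stop("config_from_provenance: non-path B1 input cannot be re-executed")
  map_config(series = lapply(cj$series, unlist),
             b1 = b1, rfsens_mode = cj$rfsens_mode,
             rfsens = if (is.null(cj$rfsens)) NULL else
               if (is.character(unlist(cj$rfsens)) &&
                   !has_mem(cj$rfsens)) cj$rfsens else
                 stop("config_from_provenance: in-memory receive field"),
             spoiling = if (is.null(cj$spoiling)) NULL else
               spoiling_coefficients(unlist(cj$spoiling$acoef),
                                     unlist(cj$spoiling$bcoef),
                                     cj$spoiling$protocol),
             pd_target = cj$pd_target, mt_c = cj$mt_c,
             te_max = cj$te_max,
             out_dir = if (is.null(out_dir)) cj$out_dir else out_dir,
             basename = cj$basename)
}

resolve_series <- function(x) {
  if (is_mpm_series(x)) x else read_series(unlist(x))
}

resolve_rfsens <- function(rf) {
  load1 <- function(f) {
    if (is.character(f)) read_volume(f)$volume
    else if (is.list(f) && !is_qvol(f) && !is.null(f$map)) f$map
    else if (is_qvol(f)) f
    else qvol(as_vol_array(f))
  }
  if (is.null(rf)) NULL
  else if (is.list(rf) && !is_qvol(rf) && is.null(rf$map))
    lapply(rf, load1)
  else load1(rf)
}

#' Run the map-creation workflow
#'
#' Orchestrates the full estimation: grid check, optional receive-bias
#' correction, joint R2* fit (ESTATICS), TE=0 extrapolation, optional
#' transmit-field handling, dual-angle R1 and amplitude computation,
#' optional imperfect-spoiling correction, MT saturation with optional B1
#' correction, PD calibration, quality assessment, and output writing.
#'
#' Input subsets degrade gracefully: PDw alone yields R2* only; PDw + T1w
#' adds R1 and PD; MTsat additionally needs MTw. Single-echo inputs skip
#' the decay fit and use the first echo directly; the resulting T2* bias is
#' flagged in provenance.
#'
#' @param config a [map_config()].
#' @return list with `maps` (named list of [qvol]: `R2s_OLS`, `R2s`, `R1`,
#'   `A`, `PD`, `MTsat` as available, plus `TEzero` per contrast), `fit`
#'   (the [fit_estatics()] result or `NULL` on the single-echo path), `qa`
#'   ([qa_report()]), `mask` (validity), `provenance`, and `paths` (written
#'   files; empty when `out_dir` is `NULL`).
#' @export
create_maps <- function(config) {
  stopifnot(inherits(config, "map_config"))
  prov <- provenance_record("multi-parameter map creation")
  prov$config <- config_as_json_list(config)

  series <- lapply(config$series, resolve_series)
  names(series) <- vapply(series, function(s) s$meta$contrast, character(1))
  if (is.null(series$PDw))
    stop("configuration error: a PDw series is required (stage: input)")
  basename <- config$basename
  if (is.null(basename))
    basename <- if (!is.null(series$PDw$source)) series$PDw$source else "mpm"

  # --- transmit field --------------------------------------------------
  b1 <- config$b1
  afi_result <- NULL
  ft <- NULL
  if (!is.null(b1)) {
    if (is.character(b1)) {
      ft <- load_precomputed_ft(b1)
    } else if (inherits(b1, "afi_pair")) {
      afi_result <- afi_to_ft(b1)
      ft <- afi_result
    } else if (inherits(b1, "transmit_field")) {
      ft <- b1
    } else {
      ft <- transmit_field(b1)
    }
    prov <- prov_add_step(prov, "b1_transmit",
                          params = list(source = ft$source))
  }

  # --- grid gate -------------------------------------------------------
  grid_inputs <- c(unname(series),
                   if (!is.null(ft)) list(ft$ft))
  do.call(assert_common_grid, grid_inputs)
  prov <- prov_add_step(prov, "assert_common_grid",
                        params = list(n_series = length(series)))

  # --- receive correction ---------------------------------------------
  if (config$rfsens_mode != "none") {
    rf <- resolve_rfsens(config$rfsens)
    series <- apply_receive_correction(
      series, rf,
      mode = if (config$rfsens_mode == "single") "single" else "per_contrast")
    prov <- prov_add_step(prov, "receive_correction",
                          params = list(
                            mode = config$rfsens_mode,
                            note = paste("body-coil reference used as",
                                         "measured; residual body-coil",
                                         "modulation is a known limitation")))
  } else {
    prov <- prov_add_step(prov, "receive_correction",
                          params = list(mode = "none"))
  }

  n_echoes <- vapply(series, function(s) length(s$volumes), integer(1))
  multi_echo <- all(n_echoes >= 2L)
  maps <- list()

  # --- decay fit / TE=0 intercepts ------------------------------------
  if (multi_echo) {
    fit <- fit_estatics(unname(series), te_max = config$te_max)
    prov <- prov_add_step(prov, "estatics_fit",
                          params = list(contrasts = names(series),
                                        n_echoes = unname(n_echoes),
                                        te_max = config$te_max,
                                        n_invalid = fit$n_invalid,
                                        n_clipped = fit$n_clipped))
    maps$R2s_OLS <- fit$r2s
    intercepts <- lapply(names(series), function(cc)
      extrapolate_te_zero(cc, fit))
    names(intercepts) <- names(series)
    for (cc in names(series))
      maps[[paste0(cc, "_TEzero")]] <- intercepts[[cc]]
    pd_single <- fit_r2s_single(series$PDw, te_max = config$te_max)
    maps$R2s <- pd_single$r2s
    mask <- fit$mask
  } else {
    fit <- NULL
    intercepts <- lapply(series, function(s) s$volumes[[1]])
    mask0 <- Reduce(`&`, lapply(intercepts, function(v) v$data > 0))
    mask <- vol_like(mask0 * 1, series$PDw$volumes[[1]])
    prov <- prov_add_step(prov, "single_echo_path",
                          params = list(
                            t2s_bias = paste("no multi-echo data: maps are",
                                             "biased by exp(-TE1 * R2*)"),
                            te1 = vapply(series, function(s)
                              s$meta$echo_times[1], numeric(1))))
  }

  # --- dual-angle maps -------------------------------------------------
  if (!is.null(series$T1w)) {
    r1 <- compute_r1(intercepts$PDw, intercepts$T1w,
                     series$PDw$meta, series$T1w$meta, ft = ft)
    amp <- compute_amplitude(intercepts$PDw, intercepts$T1w,
                             series$PDw$meta, series$T1w$meta, ft = ft)
    prov <- prov_add_step(prov, "dual_angle_maps",
                          params = list(b1_corrected = !is.null(ft)))
    sp <- apply_spoiling_correction(r1, ft = ft, coeffs = config$spoiling)
    prov <- prov_add_step(prov, "spoiling_correction",
                          params = if (sp$enabled)
                            list(enabled = TRUE,
                                 acoef = config$spoiling$acoef,
                                 bcoef = config$spoiling$bcoef)
                          else list(enabled = FALSE, note = "disabled"))
    maps$R1 <- sp$map
    maps$A <- amp$map
    mask <- vol_like((mask$data > 0) * (r1$mask$data > 0) *
                       (amp$mask$data > 0), mask)

    if (!is.null(series$MTw)) {
      mt <- compute_mt_sat(intercepts$MTw, amp$map, sp$map,
                           series$MTw$meta, ft = ft)
      prov <- prov_add_step(prov, "compute_mt_sat",
                            params = list(b1_corrected = !is.null(ft)))
      if (!is.null(ft)) {
        mtc <- b1_correct_mt(mt, ft, C = config$mt_c)
        prov <- prov_add_step(prov, "b1_correct_mt",
                              params = list(C = config$mt_c))
        maps$MTsat <- mtc$map
      } else {
        prov <- prov_add_step(prov, "b1_correct_mt",
                              params = list(enabled = FALSE,
                                            note = "no transmit field"))
        maps$MTsat <- mt$map
      }
      mask <- vol_like((mask$data > 0) * (mt$mask$data > 0), mask)
    }

    cal <- calibrate_pd(amp$map, mask = config$pd_mask,
                        target = config$pd_target)
    prov <- prov_add_step(prov, "calibrate_pd",
                          params = list(
                            target = cal$target,
                            calibrated = cal$calibrated,
                            note = if (cal$calibrated)
                              "receive-corrected A calibrated over mask"
                            else "uncalibrated-relative (mean set over validity mask)"))
    maps$PD <- cal$map
  }

  # --- QA --------------------------------------------------------------
  qa <- if (!is.null(fit)) qa_report(fit, mask) else NULL
  prov <- prov_add_step(prov, "qa", params = list(
    available = !is.null(fit)))

  # --- outputs ---------------------------------------------------------
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    rd <- resolve_results_dir(config$out_dir)
    wr <- function(kind, vol, src = basename) {
      p <- write_map(vol, kind, config$out_dir, src, provenance = prov,
                     results_dir = rd)
      paths <<- c(paths, p)
    }
    for (k in c("MTsat", "PD", "R1", "R2s_OLS", "R2s"))
      if (!is.null(maps[[k]])) wr(k, maps[[k]])
    for (cc in names(series)) {
      k <- paste0(cc, "_TEzero")
      if (!is.null(maps[[k]])) wr(k, maps[[k]])
    }
    if (!is.null(afi_result)) {
      wr("B1map", ft_as_pu(afi_result))
      wr("B1ref", afi_result$ref)
      paths <- c(paths, write_param_log(
        list(method = "AFI", fwhm_mm = 8,
             tr1 = config$b1$tr1, tr2 = config$b1$tr2,
             alpha_nominal = config$b1$alpha_nominal),
        "hMRI_map_creation_b1map_params.json", rd))
    } else if (!is.null(ft)) {
      paths <- c(paths, write_param_log(
        list(method = ft$source),
        "hMRI_map_creation_b1map_params.json", rd))
    }
    if (config$rfsens_mode != "none") {
      paths <- c(paths, write_param_log(
        list(mode = config$rfsens_mode),
        "hMRI_map_creation_rfsens_params.json", rd))
    }
    paths <- c(paths, write_param_log(
      config_as_json_list(config),
      "hMRI_map_creation_job_create_maps.json", rd))
    paths <- c(paths, write_param_log(
      lapply(series, function(s) sidecar_from_metadata(s$meta)),
      "hMRI_map_creation_mpm_params.json", rd))
    if (!is.null(qa)) paths <- c(paths, write_qa(qa, results_dir = rd))
  }

  list(maps = maps, fit = fit, qa = qa, mask = mask, provenance = prov,
       paths = paths, basename = basename)
}

#' Spatially process quantitative maps (tissue-weighted smoothing)
#'
#' Applies [vbq_smooth_per_tissue()] to each requested map and writes the
#' smoothed maps plus companion validity masks. Segmentation and spatial
#' registration are consumed as inputs (pre-computed weight maps), not
#' performed here.
#'
#' @param maps named list of [qvol] (or NIfTI paths).
#' @param weights list of [tissue_weight_map] (or paths; class labels from
#'   names).
#' @param fwhm kernel FWHM in mm.
#' @param mask_threshold see [vbq_smooth()].
#' @param out_dir output directory (`NULL`: no writing).
#' @return nested list: result of [vbq_smooth()] per map per tissue class;
#'   attribute `"paths"` lists written files.
#' @export
process_maps <- function(maps, weights, fwhm, mask_threshold = 0.05,
                         out_dir = NULL) {
  load_map <- function(m) if (is.character(m)) read_volume(m)$volume else m
  maps <- lapply(maps, load_map)
  weights <- lapply(seq_along(weights), function(i) {
    w <- weights[[i]]
    if (is.character(w)) w <- read_volume(w)$volume
    if (!inherits(w, "tissue_weight_map")) {
      lbl <- names(weights)[i]
      if (is.null(lbl) || !nzchar(lbl)) lbl <- paste0("class", i)
      w <- tissue_weight_map(w, tissue = lbl)
    }
    w
  })
  do.call(assert_common_grid,
          c(unname(maps), lapply(weights, function(w) w$w)))
  out <- lapply(maps, function(m)
    vbq_smooth_per_tissue(m, weights, fwhm, mask_threshold))
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mn in names(out)) for (tn in names(out[[mn]])) {
      res <- out[[mn]][[tn]]
      v <- res$map
      v$data[is.na(v$data)] <- 0  # sentinel for storage; mask is companion
      p <- file.path(out_dir, sprintf("ws%g_%s_%s.nii", fwhm, tn, mn))
      write_volume(v, p)
      pm <- file.path(out_dir, sprintf("ws%g_%s_%s_mask.nii", fwhm, tn, mn))
      write_volume(res$mask, pm)
      paths <- c(paths, p, pm)
    }
  }
  attr(out, "paths") <- paths
  out
}
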