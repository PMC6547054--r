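#' Digital multi-parameter phantom
#'
#' A `phantom_spec` bundles ground-truth parameter maps (R1, R2*, A, MT
#' saturation), transmit and per-contrast receive bias fields, a noise model
#' and a seed. [make_layered_phantom()] builds a deterministic phantom with
#' concentric tissue-like compartments; [simulate_contrast()] forward-models
#' the multi-echo FLASH signal from it.
#'
#' Default compartment values (inner to outer) emulate deep grey matter,
#' white matter and cortical grey matter at 3T:
#' deep GM `R1 = 0.9 /s, R2* = 30 /s, A = 750, delta = 1.3 p.u.`;
#' WM `R1 = 1.05, R2* = 21, A = 690, delta = 2.0`;
#' GM `R1 = 0.7, R2* = 16, A = 820, delta = 1.0`.
#' Long-T1 fluid compartments are deliberately absent: the small-TR
#' rational approximations used downstream degrade for R1 well below
#' 0.5/s, which is a documented limitation of the method, not of the
#' phantom.
#'
#' @param dimensions integer length-3 grid size, each >= 8.
#' @param voxdim voxel size in mm.
#' @param seed integer seed; the phantom is a deterministic function of its
#'   arguments.
#' @param ft_range peak deviation of the smooth transmit field fT from 1
#'   (default 0.2, i.e. +/-20%); 0 gives fT identically 1.
#' @param fr_range peak deviation of each per-contrast receive field from 1
#'   (default 0.1); 0 gives fR identically 1.
#' @param noise noise model applied by [simulate_contrast()].
#' @param sigma noise standard deviation (a.u.), required > 0 for
#'   `"gaussian"`/`"rician"`.
#' @param compartments data.frame with columns `name, R1, R2s, A, delta`
#'   (inner to outer); must have >= 1 row.
#' @return object of class `phantom_spec` with elements `R1`, `R2s`, `A`,
#'   `delta` (qvol ground-truth maps), `ft` (qvol), `fr` (named list of qvol
#'   per contrast), `foreground` and `labels` (qvol; 0 = background,
#'   compartments numbered inner to outer), `noise`, `sigma`, `seed`.
#' @export
make_layered_phantom <- function(dimensions = c(48, 48, 48),
                                 voxdim = c(1, 1, 1),
                                 seed = 1L,
                                 ft_range = 0.2,
                                 fr_range = 0.1,
                                 noise = c("none", "gaussian", "rician"),
                                 sigma = 0,
                                 compartments = default_compartments()) {
  dimensions <- as.integer(dimensions)
  if (length(dimensions) != 3L || any(dimensions < 8L))
    stop("make_layered_phantom: dimensions must be >= 8 per axis")
  noise <- match.arg(noise)
  if (noise != "none" && (!is.finite(sigma) || sigma <= 0))
    stop("make_layered_phantom: sigma must be > 0 for noise model '",
         noise, "'")
  nc <- nrow(compartments)
  if (is.null(nc) || nc < 1L) stop("make_layered_phantom: no compartments")

  # normalised coordinates in [-1, 1] per axis
  cx <- lapply(dimensions, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  X <- array(rep(cx[[1]], times = dimensions[2] * dimensions[3]), dimensions)
  Y <- array(rep(rep(cx[[2]], each = dimensions[1]), times = dimensions[3]),
             dimensions)
  Z <- array(rep(cx[[3]], each = dimensions[1] * dimensions[2]), dimensions)
  r <- sqrt(X^2 + Y^2 + Z^2)

  # concentric shells: foreground radius 0.9, equal-volume-ish shells
  r_out <- 0.9
  edges <- r_out * sqrt(seq_len(nc) / nc)  # inner to outer radii
  labels <- array(0L, dimensions)
  for (k in rev(seq_len(nc))) labels[r <= edges[k]] <- k
  fg <- labels > 0L

  pick <- function(col) {
    v <- array(0, dimensions)
    for (k in seq_len(nc)) v[labels == k] <- compartments[[col]][k]
    v
  }
  mk <- function(a) qvol(a, voxdim = voxdim)

  # smooth low-order polynomial bias fields; coefficients drawn from the
  # seeded RNG, then scaled so the peak deviation over the foreground
  # equals the requested range (coil profiles vary across the head, so the
  # stated range must be attained in-tissue, not at grid corners)
  poly_field <- function(range) {
    co <- stats::runif(6, -1, 1)  # always drawn: RNG stream layout is fixed
    if (range == 0) return(array(1, dimensions))
    f <- co[1] * X + co[2] * Y + co[3] * Z +
      co[4] * X * Y + co[5] * (X^2 - Z^2) + co[6] * (Y^2 - 0.3)
    f <- f / max(abs(f[fg]))
    # the polynomial can exceed the target range outside the head; keep the
    # field strictly positive everywhere (invariant fT, fR > 0)
    pmax(1 + range * f, 0.05)
  }
  set.seed(seed)
  ft <- poly_field(range = ft_range)
  fr <- list(PDw = poly_field(range = fr_range),
             T1w = poly_field(range = fr_range),
             MTw = poly_field(range = fr_range))

  structure(list(
    R1 = mk(pick("R1")), R2s = mk(pick("R2s")), A = mk(pick("A")),
    delta = mk(pick("delta")),
    ft = mk(ft), fr = lapply(fr, mk),
    foreground = mk(fg * 1), labels = mk(labels * 1),
    compartments = compartments,
    noise = noise, sigma = sigma, seed = as.integer(seed),
    dimensions = dimensions, voxdim = voxdim,
    ft_range = ft_range, fr_range = fr_range
  ), class = "phantom_spec")
}

#' @rdname make_layered_phantom
#' @export
default_compartments <- function() {
  data.frame(
    name = c("deep_gm", "wm", "gm"),
    R1 = c(0.9, 1.05, 0.7),        # 1/s
    R2s = c(30, 21, 16),           # 1/s
    A = c(750, 690, 820),          # a.u.; 690 ~ 69 p.u. white matter
    delta = c(1.3, 2.0, 1.0)       # p.u.
  )
}

is_phantom_spec <- function(x) inherits(x, "phantom_spec")

#' Default acquisition protocol
#'
#' A representative multi-parameter mapping protocol: PDw TR 25 ms / 6
#' degrees, T1w TR 25 ms / 21 degrees, MTw TR 25 ms / 6 degrees with MT
#' pulse; six echoes equally spaced from 2.3 to 14.8 ms.
#'
#' @param contrasts subset of `c("PDw","T1w","MTw")` to include.
#' @param n_echoes number of echoes.
#' @return named list of [acq_metadata], one per contrast.
#' @export
default_protocol <- function(contrasts = c("PDw", "T1w", "MTw"),
                             n_echoes = 6L) {
  te <- seq(2.3, 14.8, length.out = n_echoes)
  all <- list(
    PDw = acq_metadata("PDw", flip_angle = 6, tr = 25, echo_times = te),
    T1w = acq_metadata("T1w", flip_angle = 21, tr = 25, echo_times = te),
    MTw = acq_metadata("MTw", flip_angle = 6, tr = 25, echo_times = te)
  )
  all[match.arg(contrasts, names(all), several.ok = TRUE)]
}

# deterministic per-volume noise seed: independent draws per contrast/echo
volume_seed <- function(base_seed, contrast, echo) {
  cidx <- match(contrast, c("PDw", "T1w", "MTw"))
  as.integer((base_seed + 7919L * cidx + 101L * echo) %% .Machine$integer.max)
}

#' Forward-simulate one multi-echo contrast
#'
#' Per echo the signal is
#' `fR * steady_state(A, R1, fT * alpha_nominal, TR) * exp(-TE * R2s/1000)`
#' where the steady state is the exact Ernst equation ([ernst_signal()]) for
#' PDw/T1w and the small-angle MT steady state ([mt_flash_signal()]) for
#' MTw. Gaussian noise adds `N(0, sigma)`; Rician noise replaces the signal
#' by `|S + n1 + i n2|` with independent `N(0, sigma)` components. One
#' independent, seed-determined draw is made per volume.
#'
#' @param phantom a [make_layered_phantom()] spec.
#' @param meta an [acq_metadata] for the contrast to simulate.
#' @return an [mpm_series].
#' @export
simulate_contrast <- function(phantom, meta) {
  stopifnot(is_phantom_spec(phantom), is_acq_metadata(meta))
  alpha_loc <- phantom$ft$data * flip_rad(meta)
  s0 <- if (meta$mt_pulse) {
    mt_flash_signal(phantom$A$data, phantom$R1$data, alpha_loc, meta$tr,
                    phantom$delta$data)
  } else {
    ernst_signal(phantom$A$data, phantom$R1$data, alpha_loc, meta$tr)
  }
  fr <- phantom$fr[[meta$contrast]]$data
  vols <- vector("list", length(meta$echo_times))
  for (e in seq_along(meta$echo_times)) {
    s <- fr * s0 * exp(-meta$echo_times[e] * phantom$R2s$data / 1000)
    if (phantom$noise != "none") {
      set.seed(volume_seed(phantom$seed, meta$contrast, e))
      n <- length(s)
      if (phantom$noise == "gaussian") {
        s <- s + stats::rnorm(n, 0, phantom$sigma)
      } else {
        s <- sqrt((s + stats::rnorm(n, 0, phantom$sigma))^2 +
                    stats::rnorm(n, 0, phantom$sigma)^2)
      }
      dim(s) <- phantom$dimensions
    }
    vols[[e]] <- qvol(s, voxdim = phantom$voxdim)
  }
  mpm_series(meta, vols, source = paste0("phantom_", tolower(meta$contrast),
                                         "_e1"))
}

#' @rdname simulate_contrast
#' @param protocol named list of [acq_metadata] (see [default_protocol()]).
#' @return `simulate_mpm()`: named list of [mpm_series], one per contrast.
#' @export
simulate_mpm <- function(phantom, protocol = default_protocol()) {
  out <- lapply(protocol, function(m) simulate_contrast(phantom, m))
  names(out) <- vapply(protocol, function(m) m$contrast, character(1))
  out
}

#' Write a simulated dataset as a BIDS-like tree
#'
#' Writes one NIfTI + JSON sidecar per echo under `<out_dir>/anat/`, the
#' ground-truth maps and bias fields under `<out_dir>/truth/`, and the
#' phantom/protocol settings as `<out_dir>/simulation.json`.
#'
#' @param phantom a [make_layered_phantom()] spec.
#' @param protocol named list of [acq_metadata].
#' @param out_dir output directory (created).
#' @return named list of character vectors: the written echo paths per
#'   contrast.
#' @export
write_phantom_dataset <- function(phantom, protocol = default_protocol(),
                                  out_dir) {
  series <- simulate_mpm(phantom, protocol)
  anat <- file.path(out_dir, "anat")
  truth <- file.path(out_dir, "truth")
  dir.create(anat, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (ctr in names(series)) {
    s <- series[[ctr]]
    p <- character(length(s$volumes))
    for (e in seq_along(s$volumes)) {
      p[e] <- file.path(anat, sprintf("sub-01_acq-%s_echo-%d_MPM.nii",
                                      tolower(ctr), e))
      write_volume(s$volumes[[e]], p[e])
      jsonlite::write_json(sidecar_from_metadata(s$meta, echo = e),
                           sidecar_path(p[e]), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    paths[[ctr]] <- p
  }
  for (m in c("R1", "R2s", "A", "delta", "ft", "foreground", "labels"))
    write_volume(phantom[[m]], file.path(truth, paste0(m, ".nii")),
                 datatype = "double")
  for (ctr in names(phantom$fr))
    write_volume(phantom$fr[[ctr]],
                 file.path(truth, paste0("fr_", tolower(ctr), ".nii")),
                 datatype = "double")
  jsonlite::write_json(
    list(seed = phantom$seed, noise = phantom$noise, sigma = phantom$sigma,
         ft_range = phantom$ft_range, fr_range = phantom$fr_range,
         dimensions = phantom$dimensions, voxdim = phantom$voxdim,
         compartments = phantom$compartments,
         protocol = lapply(protocol, sidecar_from_metadata)),
    file.path(out_dir, "simulation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
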