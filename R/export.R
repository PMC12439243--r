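#' Export or import a simulated record
#'
#' Two formats are supported. `"container"` is the package's keyed JSON
#' container: all complex arrays (data, transients, every ground-truth
#' component) are base64-encoded IEEE-754 doubles, so the round-trip through
#' [import_record()] is bit-exact and the full ground truth — baseline,
#' residual water, noise realization, B0 map, model parameters — travels
#' with the data. `"nifti_mrs"` writes a standard-conformant NIfTI-MRS file:
#' NIfTI-2, complex-double time-domain data in dimension 4, dwell time in
#' `pixdim[5]`, and the JSON header extension (ecode 44) carrying
#' `SpectrometerFrequency`, `ResonantNucleus` and — for transient records —
#' the `dim_5` tag `DIM_COIL`. NIfTI-MRS carries the measured data and
#' acquisition metadata only, not the ground-truth components.
#'
#' @param record A `sim_record`.
#' @param path Output path (`.json` for container, `.nii` for NIfTI-MRS).
#' @param format `"container"` or `"nifti_mrs"`.
#' @return `export_record()` returns `path` invisibly. `import_record()`
#'   returns a `sim_record` (container) or a list with `fid`, `transients`,
#'   `axes` and `header` (NIfTI-MRS).
#' @export
export_record <- function(record, path, format = c("container", "nifti_mrs")) {
  abort_if(!inherits(record, "sim_record"), "`record` must be a `sim_record`")
  format <- match.arg(format)
  if (format == "container") {
    export_container(record, path)
  } else {
    export_nifti_mrs(record, path)
  }
  invisible(path)
}

#' @rdname export_record
#' @param format_hint Optional import format; inferred from the file
#'   extension when `NULL`.
#' @export
import_record <- function(path, format_hint = NULL) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti_mrs" else "container"
  }
  if (fmt == "container") import_container(path) else import_nifti_mrs(path)
}

#' @noRd
export_container <- function(record, path) {
  gt <- record$ground_truth
  p <- gt$params
  enc <- function(x) if (is.null(x)) NULL else encode_doubles(x)
  obj <- list(
    container = "mrsim_record", version = 1L,
    stage = record$stage,
    axes = list(spectral_width = record$axes$spectral_width,
                n_points = record$axes$n_points,
                f0 = record$axes$f0, ppm_ref = record$axes$ppm_ref),
    fid = enc(record$fid),
    spectrum = enc(record$spectrum),
    transients = if (is.null(record$transients)) NULL else
      list(C = nrow(record$transients), data = enc(t(record$transients))),
    ground_truth = list(
      metab_fid = enc(gt$metab_fid),
      baseline = enc(gt$baseline),
      water = enc(gt$water),
      nuisance_fid = enc(gt$nuisance_fid),
      noise_fid = enc(gt$noise_fid),
      noise_sigma = gt$noise_sigma,
      ref_peak_height = gt$ref_peak_height,
      ref_level = gt$ref_level,
      b0 = if (is.null(gt$b0)) NULL else list(
        shape = gt$b0$shape, dx = gt$b0$dx, dy = gt$b0$dy, dz = gt$b0$dz,
        mu = gt$b0$mu, profile = gt$b0$profile,
        grid = encode_doubles(as.vector(gt$b0$grid))),
      coil = if (is.null(gt$coil)) NULL else
        gt$coil[c("C", "sens", "snr_scale", "df", "dphi")],
      seed = gt$seed),
    params = serialize_params(p))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
}

#' @noRd
serialize_params <- function(p) {
  keep <- c("amplitude", "lorentz_d", "gauss_met", "gauss_mm", "fshift",
            "fshift_global_met", "fshift_global_nuis", "phi0", "phi1",
            "eddy_a0", "eddy_tc", "snr", "snr_ref", "noise_correlated")
  out <- p[keep]
  out$amplitude <- as.list(out$amplitude)
  out$lorentz_d <- as.list(out$lorentz_d)
  out$fshift <- as.list(out$fshift)
  for (fld in c("baseline_cfg", "water_cfg")) {
    if (!is.null(p[[fld]])) out[[fld]] <- unclass(p[[fld]])
  }
  out
}

#' @noRd
deserialize_params <- function(obj, b0 = NULL) {
  unlist_named <- function(x) {
    if (is.null(x)) return(0)
    out <- unlist(x)
    if (length(out) == 1 && is.null(names(x))) unname(out) else out
  }
  wc <- function(x) if (is.null(x)) NULL else do.call(walk_config, x)
  model_params(
    amplitude = unlist_named(obj$amplitude),
    lorentz_d = unlist_named(obj$lorentz_d),
    gauss_met = obj$gauss_met, gauss_mm = obj$gauss_mm,
    fshift = unlist_named(obj$fshift),
    fshift_global_met = obj$fshift_global_met,
    fshift_global_nuis = obj$fshift_global_nuis,
    phi0 = obj$phi0, phi1 = obj$phi1,
    eddy_a0 = obj$eddy_a0, eddy_tc = obj$eddy_tc,
    snr = obj$snr, snr_ref = obj$snr_ref,
    noise_correlated = isTRUE(obj$noise_correlated),
    b0 = b0,
    baseline_cfg = wc(obj$baseline_cfg), water_cfg = wc(obj$water_cfg))
}

#' @noRd
import_container <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("container", "stage", "axes", "fid", "params")
  missing <- setdiff(required, names(obj))
  abort_if(length(missing) > 0,
           sprintf("malformed record container: missing field(s) %s",
                   paste(missing, collapse = ", ")))
  abort_if(obj$container != "mrsim_record", "not an mrsim record container")
  ax <- obj$axes
  axes <- make_axes(as.numeric(ax$spectral_width), ax$n_points,
                    as.numeric(ax$f0), as.numeric(ax$ppm_ref))
  dec <- function(s) if (is.null(s)) NULL else decode_doubles(s, complex = TRUE)
  gt <- obj$ground_truth
  b0 <- NULL
  if (!is.null(gt$b0)) {
    b0 <- make_b0_map(gt$b0$shape, gt$b0$dx, gt$b0$dy, gt$b0$dz, gt$b0$mu,
                      gt$b0$profile)
    b0$grid <- array(decode_doubles(gt$b0$grid), dim = gt$b0$shape)
  }
  coil <- NULL
  if (!is.null(gt$coil)) {
    coil <- coil_params(gt$coil$C, sens = gt$coil$sens,
                        snr_scale = gt$coil$snr_scale, df = gt$coil$df,
                        dphi = gt$coil$dphi)
  }
  transients <- NULL
  if (!is.null(obj$transients)) {
    z <- dec(obj$transients$data)
    transients <- t(matrix(z, ncol = obj$transients$C))
  }
  structure(
    list(fid = dec(obj$fid), spectrum = dec(obj$spectrum),
         transients = transients, axes = axes, stage = obj$stage,
         ground_truth = list(
           metab_fid = dec(gt$metab_fid), baseline = dec(gt$baseline),
           water = dec(gt$water), nuisance_fid = dec(gt$nuisance_fid),
           noise_fid = dec(gt$noise_fid), noise_sigma = gt$noise_sigma,
           ref_peak_height = gt$ref_peak_height, ref_level = gt$ref_level,
           b0 = b0, params = deserialize_params(obj$params, b0 = b0),
           coil = coil, seed = gt$seed)),
    class = "sim_record")
}

#' @noRd
export_nifti_mrs <- function(record, path) {
  axes <- record$axes
  if (is.null(record$transients)) {
    arr <- array(record$fid, dim = c(1, 1, 1, axes$n_points))
    dim5 <- NULL
  } else {
    arr <- array(0i, dim = c(1, 1, 1, axes$n_points, nrow(record$transients)))
    for (cc in seq_len(nrow(record$transients))) {
      arr[1, 1, 1, , cc] <- record$transients[cc, ]
    }
    dim5 <- "DIM_COIL"
  }
  img <- RNifti::asNifti(arr, reference = list(
    pixdim = c(1, 1, 1, 1, 1 / axes$spectral_width, 1, 1, 1),
    intent_name = "mrs_v0_2"))
  hdr <- list(SpectrometerFrequency = axes$f0,
              ResonantNucleus = "1H",
              ppm_ref = axes$ppm_ref,
              # pixdim is single-precision in the NIfTI struct; keep the
              # exact dwell time in the sidecar as well
              DwellTime = 1 / axes$spectral_width)
  if (!is.null(dim5)) hdr$dim_5 <- dim5
  json <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  # set the extension last: rebuilding the image drops extensions
  RNifti::extension(img, 44L) <- charToRaw(as.character(json))
  RNifti::writeNifti(img, path, version = 2)
}

#' @noRd
import_nifti_mrs <- function(path) {
  img <- RNifti::readNifti(path)
  ext <- RNifti::extension(img, 44L)
  abort_if(is.null(ext), "NIfTI file carries no MRS header extension (ecode 44)")
  hdr <- jsonlite::fromJSON(rawToChar(ext))
  abort_if(is.null(hdr$SpectrometerFrequency),
           "MRS header extension lacks SpectrometerFrequency")
  d <- dim(img)
  n <- d[4]
  dwell <- if (!is.null(hdr$DwellTime)) hdr$DwellTime else
    RNifti::niftiHeader(img)$pixdim[5]
  sw <- 1 / dwell
  ppm_ref <- if (!is.null(hdr$ppm_ref)) hdr$ppm_ref else 4.65
  axes <- make_axes(sw, n, hdr$SpectrometerFrequency, ppm_ref)
  dat <- as.array(img)
  if (length(d) >= 5 && d[5] > 1) {
    transients <- t(matrix(dat, nrow = n, ncol = d[5]))
    fid <- combine_transients(transients)
  } else {
    transients <- NULL
    fid <- as.vector(dat)
  }
  list(fid = fid, transients = transients, axes = axes, header = hdr)
}
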