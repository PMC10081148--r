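#' Write a dynamic series to NIfTI
#'
#' Magnitude series are written as a single 3D volume (x, y, t). For a
#' complex series, `what = "complex"` writes two files with `_real` / `_imag`
#' suffixes so no information is lost.
#'
#' @param series A `dynamic_series`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param what `"magnitude"` (default) or `"complex"`.
#' @return Invisibly, the path(s) written.
#' @export
write_series_nifti <- function(series, path, what = c("magnitude", "complex")) {
  what <- match.arg(what)
  if (what == "magnitude") {
    RNifti::writeNifti(RNifti::asNifti(unclass(combine_norm(series))), path)
    return(invisible(path))
  }
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- substr(path, nchar(stem) + 1L, nchar(path))
  if (ext == "") ext <- ".nii.gz"
  paths <- paste0(stem, c("_real", "_imag"), ext)
  RNifti::writeNifti(RNifti::asNifti(array(Re(series), dim(series))), paths[1])
  RNifti::writeNifti(RNifti::asNifti(array(Im(series), dim(series))), paths[2])
  invisible(paths)
}

#' Serialise / restore a phantom specification as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `write_phantom_spec()`: the path, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- list(grid_size = spec$grid_size, n_frames = spec$n_frames,
              ellipses = lapply(seq_len(nrow(spec$ellipses)), function(i)
                as.list(spec$ellipses[i, ])),
              bolus = spec$bolus,
              noise_sigma = spec$noise_sigma,
              phase_amplitude = spec$phase_amplitude,
              seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @return `read_phantom_spec()`: the restored [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  ell <- do.call(rbind, lapply(obj$ellipses, function(e) {
    e$curve <- if (is.null(e$curve) || is.na(e$curve)) NA_character_ else e$curve
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
  phantom_spec(grid_size = obj$grid_size, n_frames = obj$n_frames,
               ellipses = ell, bolus = obj$bolus,
               noise_sigma = obj$noise_sigma,
               phase_amplitude = obj$phase_amplitude,
               seed = obj$seed)
}
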