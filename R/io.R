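# Disk formats: NIfTI-1 volumes (via RNifti), plain-text b-value/NSA
# sidecars, YAML configs and manifests.

#' Write a phantom to disk
#'
#' Writes the 4-D magnitude series (`phantom.nii.gz`), the integer class
#' label map (`labels.nii.gz`), the b-value/NSA sidecar (`btable.txt`) and
#' a YAML ground-truth manifest with the seed, noise level and per-class
#' generating parameters.
#'
#' @param phantom a `dwi_phantom` from [make_phantom()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    nifti = file.path(dir, "phantom.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    btable = file.path(dir, "btable.txt"),
    manifest = file.path(dir, "manifest.yaml"))
  RNifti::writeNifti(RNifti::asNifti(phantom$data), paths$nifti)
  RNifti::writeNifti(RNifti::asNifti(phantom$labels + 0), paths$labels)
  write_bvalue_table(phantom$scheme, paths$btable)
  manifest <- list(
    seed = phantom$spec$seed,
    sigma = phantom$spec$sigma,
    dim = dim(phantom$labels),
    n_directions = phantom$scheme$n_directions,
    classes = lapply(phantom$spec$classes, function(cl)
      c(list(name = cl$name, s0_mean = cl$s0_mean, s0_sd = cl$s0_sd),
        params_to_config(cl$params))))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

#' Read / write model parameters as YAML
#'
#' Flat key-value serialization of a parameter set (see
#' [params_to_config()] for the key convention).
#'
#' @param p a parameter object.
#' @param path file path.
#' @return [write_params_yaml()] returns `path` invisibly;
#'   [read_params_yaml()] returns a parameter object.
#' @export
write_params_yaml <- function(p, path) {
  yaml::write_yaml(params_to_config(p), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  params_from_config(yaml::read_yaml(path))
}
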