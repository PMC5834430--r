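# Parameter sets for the three decay models. ADCs are stored in mm^2/s
# throughout the package; the x1e-6 mm^2/s display unit appears only at the
# I/O boundary (maps, tables, configs). Implied fast fractions are computed,
# never stored.

MODEL_IDS <- c("biexp", "triexp", "modtriexp")

#' Bi-exponential model parameters
#'
#' Two freely diffusing compartments: a slow and a fast one, with fractions
#' summing to one (`f_fast = 1 - f_slow` is implied, never stored).
#'
#' @param f_slow fraction of the slow compartment, in `[0, 1]`.
#' @param adc_slow,adc_fast apparent diffusion coefficients (mm^2/s),
#'   `0 <= adc_slow <= adc_fast`.
#' @return An object of class `biexp_params`.
#' @export
biexp_params <- function(f_slow, adc_slow, adc_fast) {
  p <- structure(list(f_slow = f_slow, adc_slow = adc_slow,
                      adc_fast = adc_fast),
                 class = c("biexp_params", "dwi_params"))
  validate_params(p)
}

#' Conventional tri-exponential model parameters
#'
#' Three freely diffusing compartments (very slow, slow, fast); the fast
#' fraction is implied by the sum-to-one constraint.
#'
#' @param f_very_slow,f_slow compartment fractions, non-negative with
#'   `f_very_slow + f_slow <= 1`.
#' @param adc_very_slow,adc_slow,adc_fast ADCs (mm^2/s), non-negative and
#'   ordered `adc_very_slow <= adc_slow <= adc_fast`.
#' @return An object of class `triexp_params`.
#' @export
triexp_params <- function(f_very_slow, f_slow, adc_very_slow, adc_slow,
                          adc_fast) {
  p <- structure(list(f_very_slow = f_very_slow, f_slow = f_slow,
                      adc_very_slow = adc_very_slow, adc_slow = adc_slow,
                      adc_fast = adc_fast),
                 class = c("triexp_params", "dwi_params"))
  validate_params(p)
}

#' Modified tri-exponential model parameters
#'
#' Like the conventional tri-exponential model but with the very-slow
#' compartment's ADC fixed at exactly zero: a strictly diffusion-limited
#' pool whose fraction `f0` survives as a signal floor at any b-value.
#'
#' @param f0 fraction of the strictly diffusion-limited compartment.
#' @param f_slow fraction of the slow compartment; `f0 + f_slow <= 1`.
#' @param adc_slow,adc_fast ADCs (mm^2/s), `0 <= adc_slow <= adc_fast`.
#' @return An object of class `modtriexp_params`.
#' @export
modtriexp_params <- function(f0, f_slow, adc_slow, adc_fast) {
  p <- structure(list(f0 = f0, f_slow = f_slow, adc_slow = adc_slow,
                      adc_fast = adc_fast),
                 class = c("modtriexp_params", "dwi_params"))
  validate_params(p)
}

validate_params <- function(p) {
  UseMethod("validate_params")
}

#' @export
validate_params.biexp_params <- function(p) {
  with(p, {
    if (!is.finite(f_slow) || f_slow < 0 || f_slow > 1)
      stop("f_slow must lie in [0, 1]")
    if (!is.finite(adc_slow) || adc_slow < 0)
      stop("adc_slow must be >= 0")
    if (!is.finite(adc_fast) || adc_fast < adc_slow)
      stop("adc_fast must be >= adc_slow")
  })
  p
}

#' @export
validate_params.triexp_params <- function(p) {
  with(p, {
    if (any(!is.finite(c(f_very_slow, f_slow))) ||
        f_very_slow < 0 || f_slow < 0 || f_very_slow + f_slow > 1 + 1e-12)
      stop("fractions must be >= 0 with f_very_slow + f_slow <= 1")
    if (any(!is.finite(c(adc_very_slow, adc_slow, adc_fast))) ||
        adc_very_slow < 0 || adc_slow < adc_very_slow ||
        adc_fast < adc_slow)
      stop("ADCs must satisfy 0 <= adc_very_slow <= adc_slow <= adc_fast")
  })
  p
}

#' @export
validate_params.modtriexp_params <- function(p) {
  with(p, {
    if (any(!is.finite(c(f0, f_slow))) ||
        f0 < 0 || f_slow < 0 || f0 + f_slow > 1 + 1e-12)
      stop("fractions must be >= 0 with f0 + f_slow <= 1")
    if (any(!is.finite(c(adc_slow, adc_fast))) ||
        adc_slow < 0 || adc_fast < adc_slow)
      stop("ADCs must satisfy 0 <= adc_slow <= adc_fast")
  })
  p
}

#' Implied fast-compartment fraction
#'
#' @param p a parameter object.
#' @return `1 - f_slow` (biexp), `1 - f_very_slow - f_slow` (triexp) or
#'   `1 - f0 - f_slow` (modtriexp).
#' @export
f_fast <- function(p) {
  stopifnot(inherits(p, "dwi_params"))
  if (inherits(p, "biexp_params")) return(1 - p$f_slow)
  if (inherits(p, "triexp_params")) return(1 - p$f_very_slow - p$f_slow)
  1 - p$f0 - p$f_slow
}

model_id_of <- function(p) {
  if (inherits(p, "biexp_params")) return("biexp")
  if (inherits(p, "triexp_params")) return("triexp")
  if (inherits(p, "modtriexp_params")) return("modtriexp")
  stop("not a dwi_params object")
}

# free-parameter count per model (S0 excluded: signals are pre-normalized)
model_k <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
         biexp = 3L, triexp = 5L, modtriexp = 4L)
}

free_param_names <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
         biexp = c("f_slow", "adc_slow", "adc_fast"),
         triexp = c("f_very_slow", "f_slow", "adc_very_slow", "adc_slow",
                    "adc_fast"),
         modtriexp = c("f0", "f_slow", "adc_slow", "adc_fast"))
}

# names of all reported parameters (free + implied fast fraction)
report_param_names <- function(model_id) {
  c(free_param_names(model_id), "f_fast")
}

params_from_vector <- function(model_id, v) {
  model_id <- match.arg(model_id, MODEL_IDS)
  switch(model_id,
         biexp = biexp_params(v[[1L]], v[[2L]], v[[3L]]),
         triexp = triexp_params(v[[1L]], v[[2L]], v[[3L]], v[[4L]],
                                v[[5L]]),
         modtriexp = modtriexp_params(v[[1L]], v[[2L]], v[[3L]], v[[4L]]))
}

params_to_vector <- function(p) {
  unlist(p[free_param_names(model_id_of(p))], use.names = TRUE)
}

#' @export
print.dwi_params <- function(x, ...) {
  cat(model_id_of(x), "parameters\n")
  v <- params_to_vector(x)
  adc <- grepl("^adc", names(v))
  disp <- ifelse(adc, v * 1e6, v * 100)
  unit <- ifelse(adc, "x1e-6 mm^2/s", "%")
  for (i in seq_along(v))
    cat(sprintf("  %-14s %10.3f %s\n", names(v)[i], disp[i], unit[i]))
  cat(sprintf("  %-14s %10.3f %% (implied)\n", "f_fast", 100 * f_fast(x)))
  invisible(x)
}

#' Serialize parameters to / from a flat configuration list
#'
#' Keys follow the display convention: fractions as plain fractions
#' (`f0`, `f_slow`, `f_fast`), ADCs in 1e-6 mm^2/s with an `_e6` suffix
#' (`adc_slow_e6`, `adc_fast_e6`, `adc_very_slow_e6`). The implied fast
#' fraction is written for readability and checked, not trusted, on read.
#'
#' @param p a parameter object.
#' @return [params_to_config()]: a named list; [params_from_config()]: a
#'   parameter object.
#' @export
params_to_config <- function(p) {
  stopifnot(inherits(p, "dwi_params"))
  out <- list(model = model_id_of(p))
  for (nm in free_param_names(out$model)) {
    key <- if (grepl("^adc", nm)) paste0(nm, "_e6") else nm
    val <- if (grepl("^adc", nm)) p[[nm]] * 1e6 else p[[nm]]
    out[[key]] <- val
  }
  out$f_fast <- f_fast(p)
  out
}

#' @rdname params_to_config
#' @param config a named list as produced by [params_to_config()] (the
#'   `model` key may be omitted; it is then inferred from the keys present).
#' @export
params_from_config <- function(config) {
  model <- config$model
  if (is.null(model)) {
    model <- if (!is.null(config$adc_very_slow_e6)) "triexp"
             else if (!is.null(config$f0)) "modtriexp" else "biexp"
  }
  nms <- free_param_names(model)
  v <- vapply(nms, function(nm) {
    key <- if (grepl("^adc", nm)) paste0(nm, "_e6") else nm
    val <- config[[key]]
    if (is.null(val)) stop("missing key: ", key)
    if (grepl("^adc", nm)) val * 1e-6 else as.numeric(val)
  }, numeric(1))
  p <- params_from_vector(model, v)
  if (!is.null(config$f_fast) &&
      abs(config$f_fast - f_fast(p)) > 1e-6)
    stop("stored f_fast inconsistent with the other fractions")
  p
}
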