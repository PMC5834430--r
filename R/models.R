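# Forward evaluation of the decay models. All models return the normalized
# signal S/S0, exactly 1 at b = 0 because the compartment fractions sum to
# one by construction.

#' Mono-exponential signal attenuation
#'
#' The single-compartment primitive `exp(-adc * b)`. At b = 8000 s/mm^2 an
#' ADC of 500e-6 mm^2/s retains 1.8% of the signal while an ADC of
#' 10e-6 mm^2/s still retains 92.3% — the contrast that makes a very-slow
#' compartment visible at ultra-high b-values.
#'
#' @param adc apparent diffusion coefficient (mm^2/s), >= 0. Vectorized.
#' @param b diffusion weighting (s/mm^2), >= 0. Vectorized.
#' @return Remaining signal fraction in `[0, 1]`.
#' @export
mono_attenuation <- function(adc, b) {
  if (any(!is.finite(adc)) || any(adc < 0)) stop("adc must be >= 0")
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be >= 0")
  exp(-adc * b)
}

#' Evaluate a decay model at given b-values
#'
#' `eval_biexp()`, `eval_triexp()` and `eval_modtriexp()` evaluate the
#' bi-exponential, conventional tri-exponential and modified
#' tri-exponential models; `signal_model()` dispatches on the parameter
#' class. The modified model's very-slow term has ADC fixed at zero, so its
#' fraction `f0` contributes a constant floor and the model's b -> Inf
#' asymptote is `f0`.
#'
#' @param p a parameter object ([biexp_params()], [triexp_params()] or
#'   [modtriexp_params()]).
#' @param b b-values (s/mm^2), vectorized.
#' @return Normalized signal S/S0 at each `b`.
#' @export
eval_biexp <- function(p, b) {
  validate_params(p)
  stopifnot(inherits(p, "biexp_params"))
  p$f_slow * exp(-p$adc_slow * b) + (1 - p$f_slow) * exp(-p$adc_fast * b)
}

#' @rdname eval_biexp
#' @export
eval_triexp <- function(p, b) {
  validate_params(p)
  stopifnot(inherits(p, "triexp_params"))
  p$f_very_slow * exp(-p$adc_very_slow * b) +
    p$f_slow * exp(-p$adc_slow * b) + f_fast(p) * exp(-p$adc_fast * b)
}

#' @rdname eval_biexp
#' @export
eval_modtriexp <- function(p, b) {
  validate_params(p)
  stopifnot(inherits(p, "modtriexp_params"))
  p$f0 + p$f_slow * exp(-p$adc_slow * b) + f_fast(p) * exp(-p$adc_fast * b)
}

#' @rdname eval_biexp
#' @export
signal_model <- function(p, b) {
  if (inherits(p, "biexp_params")) return(eval_biexp(p, b))
  if (inherits(p, "triexp_params")) return(eval_triexp(p, b))
  if (inherits(p, "modtriexp_params")) return(eval_modtriexp(p, b))
  stop("p is not a dwi_params object")
}

#' Per-voxel normalized decay curve
#'
#' Holds the normalized signal S/S0 sampled at each b-value of a scheme,
#' plus the raw b = 0 signal used for normalization.
#'
#' @param scheme a [bvalue_scheme()].
#' @param s_over_s0 numeric vector of normalized signals, same length as
#'   the scheme; the first entry must be 1 and all entries positive.
#' @param s0 the raw signal at b = 0 (arbitrary units).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(scheme, s_over_s0, s0 = 1) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  s_over_s0 <- as.numeric(s_over_s0)
  if (length(s_over_s0) != length(scheme$b_values))
    stop("curve length must match the scheme")
  if (any(!is.finite(s_over_s0)) || any(s_over_s0 <= 0))
    stop_unfittable("curve contains non-positive or non-finite values")
  if (abs(s_over_s0[1L] - 1) > 1e-9)
    stop("first entry of a normalized curve must be 1")
  s_over_s0[1L] <- 1
  structure(list(scheme = scheme, s_over_s0 = s_over_s0, s0 = s0),
            class = "decay_curve")
}

#' Normalize a raw signal series to S/S0
#'
#' Divides each raw signal by the b = 0 signal, the normalization applied
#' before any model fitting. Voxels whose S0 is zero, negative or
#' non-finite cannot be fitted and raise an unfittable-voxel condition
#' (caught and recorded by [fit_volume()]).
#'
#' @param raw_signals raw magnitudes, one per b-value of `scheme`.
#' @param scheme a [bvalue_scheme()].
#' @return A [decay_curve()].
#' @export
normalize_signal <- function(raw_signals, scheme) {
  raw_signals <- as.numeric(raw_signals)
  if (length(raw_signals) != length(scheme$b_values))
    stop("signal length must match the scheme")
  if (!is.finite(raw_signals[1L]) || raw_signals[1L] <= 0)
    stop_unfittable("S0 is non-positive; voxel cannot be normalized")
  if (any(!is.finite(raw_signals)) || any(raw_signals <= 0))
    stop_unfittable("non-positive or non-finite signal values")
  decay_curve(scheme, raw_signals / raw_signals[1L], s0 = raw_signals[1L])
}

#' Noise-free predicted decay curve for a model
#'
#' Forward-evaluates a parameter set over every b-value of a scheme. The
#' b = 0 entry is exactly 1 (fractions sum to one by construction).
#'
#' @param params a parameter object.
#' @param scheme a [bvalue_scheme()].
#' @param model optional model id (`"biexp"`, `"triexp"`, `"modtriexp"`);
#'   when given it must match the class of `params`.
#' @return A [decay_curve()].
#' @export
predict_curve <- function(params, scheme, model = NULL) {
  if (!is.null(model) && !identical(model, model_id_of(params)))
    stop("model id does not match the parameter type")
  v <- signal_model(params, scheme$b_values)
  v[scheme$b_values == 0] <- 1
  decay_curve(scheme, v, s0 = 1)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("decay curve over", length(x$s_over_s0), "b-values (s0 =",
      format(x$s0), ")\n")
  print(data.frame(b = x$scheme$b_values, s_over_s0 = x$s_over_s0))
  invisible(x)
}
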