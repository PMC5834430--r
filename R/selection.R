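# Model-ranking statistics: RSS (from the fit), small-sample corrected AIC,
# leave-one-out PRESS, and the squared prediction error at a held-out
# ultra-high b-value.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2k + N ln(RSS/N) + 2k(k+1)/(N - k - 1)`, computed from the
#' residual sum of squares of a least-squares fit with `k` free parameters
#' on `n` points. Lower is better; the correction term penalizes model
#' complexity more sharply at small `n`.
#'
#' @param k number of free parameters (3 biexp, 5 triexp, 4 modtriexp).
#' @param n number of fitted points; must exceed `k + 1`.
#' @param rss residual sum of squares, strictly positive (callers fit to
#'   noise-free data must floor the RSS themselves; see [compare_models()]).
#' @return The AICc value.
#' @export
aicc <- function(k, n, rss) {
  if (any(n <= k + 1)) stop("AICc requires n > k + 1")
  if (any(!is.finite(rss)) || any(rss <= 0))
    stop("AICc requires rss > 0")
  2 * k + n * log(rss / n) + 2 * k * (k + 1) / (n - k - 1)
}

#' Squared prediction error at a held-out b-value
#'
#' `SPE = (S_m - S_p)^2` on the normalized S/S0 scale, where `S_m` is the
#' measured and `S_p` the model-predicted signal at the held-out b-value.
#'
#' @param s_measured,s_predicted normalized signals (finite).
#' @return The squared difference.
#' @export
spe <- function(s_measured, s_predicted) {
  if (any(!is.finite(s_measured)) || any(!is.finite(s_predicted)))
    stop("SPE requires finite signals")
  (s_measured - s_predicted)^2
}

#' Predict the signal at a held-out b-value
#'
#' Forward-evaluates a fitted model at a b-value that was excluded from
#' fitting. Requesting a b-value that was used in the fit is an error
#' (it would leak training data into the prediction assessment).
#'
#' @param fit a `dwi_fit` from [fit_voxel()] or [grid_oracle()].
#' @param scheme a [bvalue_scheme()] containing `b_heldout`.
#' @param b_heldout the held-out b-value (s/mm^2); default 8000.
#' @return Predicted normalized signal at `b_heldout`.
#' @export
predict_heldout <- function(fit, scheme, b_heldout = 8000) {
  stopifnot(inherits(fit, "dwi_fit"))
  if (!any(abs(scheme$b_values - b_heldout) < 1e-9))
    stop("b_heldout is not part of the scheme")
  if (any(abs(fit$b_values - b_heldout) < 1e-9))
    stop("b_heldout was used in fitting; prediction would leak information")
  signal_model(fit$params, b_heldout)
}

#' Leave-one-out predicted residual sum of squares (PRESS)
#'
#' For each fitting b-value in turn: drop it, refit the model from
#' [default_init()] on the remaining points, predict the dropped point,
#' and accumulate the squared prediction error. Each refit starts from the
#' default initialization (not the full-fit solution) so the folds are
#' independent. The b = 0 fold contributes exactly zero (every model
#' predicts 1 at b = 0) but is kept so the fold count matches the AICc
#' point count.
#'
#' @param model_id model identifier.
#' @param curve a [decay_curve()].
#' @param opts a [fit_options()] list.
#' @return The PRESS value, with the per-fold squared errors attached as
#'   attribute `"fold_errors"` (named by b-value).
#' @export
press <- function(model_id, curve, opts = fit_options()) {
  model_id <- match.arg(model_id, MODEL_IDS)
  idx <- fit_indices(curve$scheme, opts)
  b <- curve$scheme$b_values[idx]
  y <- curve$s_over_s0[idx]
  k <- model_k(model_id)
  if (length(b) < k + 2L)
    stop("PRESS needs at least k + 2 fitted b-values")
  init <- default_init(model_id)
  errs <- vapply(seq_along(b), function(i) {
    fit <- fit_curve_points(model_id, b[-i], y[-i], init, opts)
    (signal_model(fit$params, b[i]) - y[i])^2
  }, numeric(1))
  structure(sum(errs), fold_errors = stats::setNames(errs, b))
}

#' Fit and rank all models on one voxel
#'
#' Fits each model on the fitting b-values (default: all but the largest),
#' then computes per model: RSS, AICc (with `n` = number of fitted points
#' and model-specific `k`), PRESS, the predicted signal at the held-out
#' b-value and its SPE against the measured value. RSS values below
#' `1e-30` (noise-free data) are floored with a warning before the AICc
#' logarithm.
#'
#' @param curve a [decay_curve()] whose scheme includes at least one
#'   b-value above `opts$fit_b_max` (the held-out measurement).
#' @param opts a [fit_options()] list.
#' @param models character vector of model ids to compare.
#' @param with_press compute PRESS (16 refits per model); set `FALSE` to
#'   skip when only RSS/AICc/SPE are needed.
#' All fits (full and leave-one-out) start once from [default_init()], the
#' voxel-wise protocol used for in-vivo map production; see the vignette
#' for why the ranking deliberately reflects this single-start protocol
#' rather than the multi-start default of [fit_voxel()].
#'
#' @return An object of class `model_selection`: list with `scores` (a
#'   data.frame with columns `model`, `k`, `n_points`, `rss`, `aicc`,
#'   `press`, `spe`, `s_predicted`), `s_measured`, `b_heldout` and the
#'   per-model `fits`.
#' @export
compare_models <- function(curve, opts = fit_options(),
                           models = MODEL_IDS, with_press = TRUE) {
  stopifnot(inherits(curve, "decay_curve"))
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  bv <- curve$scheme$b_values
  heldout <- bv[bv > opts$fit_b_max + 1e-9]
  if (length(heldout) == 0L)
    stop("curve must include a held-out b-value above fit_b_max")
  b_heldout <- max(heldout)
  s_measured <- curve$s_over_s0[which.max(bv)]

  fits <- lapply(models, function(m)
    fit_voxel(m, curve, init = default_init(m), opts = opts))
  names(fits) <- models
  rows <- lapply(models, function(m) {
    fit <- fits[[m]]
    rss_val <- fit$rss
    if (rss_val < 1e-30) {
      warning("RSS below 1e-30 floored for AICc (noise-free fit?)")
      rss_val <- 1e-30
    }
    s_pred <- predict_heldout(fit, curve$scheme, b_heldout)
    data.frame(model = m, k = fit$k, n_points = fit$n_points,
               rss = fit$rss,
               aicc = aicc(fit$k, fit$n_points, rss_val),
               press = if (with_press) press(m, curve, opts) else NA_real_,
               spe = spe(s_measured, s_pred),
               s_predicted = s_pred)
  })
  structure(list(scores = do.call(rbind, rows), s_measured = s_measured,
                 b_heldout = b_heldout, fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model comparison (held-out b = %g, measured S/S0 = %.4f)\n",
              x$b_heldout, x$s_measured))
  print(x$scores, row.names = FALSE, digits = 4)
  invisible(x)
}
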