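# Constrained voxel-wise least-squares fitting. The optimizer is projected
# steepest descent with a backtracking line search (src/fit.cpp), run on
# internally rescaled variables: b in ms/um^2 and ADC in um^2/ms, so every
# free parameter is O(0.1-5). Correctness is anchored to the brute-force
# grid oracle rather than to optimizer internals.

B_SCALE <- 1e-3   # s/mm^2 -> ms/um^2
D_SCALE <- 1e3    # mm^2/s -> um^2/ms

model_code <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS), biexp = 1L, triexp = 2L,
         modtriexp = 3L)
}

#' Fitting options
#'
#' @param max_iterations maximum accepted descent iterations (>= 1).
#' @param rel_tol stop when the relative RSS decrease of an accepted step
#'   falls below this threshold.
#' @param step_init initial line-search step size on the rescaled
#'   parameters (fractions as-is, ADCs in um^2/ms).
#' @param fit_b_max highest b-value (s/mm^2) included in fitting; with the
#'   default scheme this keeps the first 16 b-values and holds out
#'   b = 8000 for prediction.
#' @param seed optional seed recorded for stochastic restarts.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 10000L, rel_tol = 1e-9,
                        step_init = 0.1, fit_b_max = 5000, seed = NULL) {
  stopifnot(max_iterations >= 1L, rel_tol > 0, step_init > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_tol = rel_tol, step_init = step_init,
                 fit_b_max = fit_b_max, seed = seed),
            class = "fit_options")
}

#' Default initial parameter values
#'
#' The empirical starting point used for every voxel: f_slow = 0.50,
#' ADC_slow = 600e-6 mm^2/s, ADC_fast = 2000e-6 mm^2/s for all models;
#' additionally f0 = 0.10 (modified tri-exponential) or f_very_slow = 0.10
#' with ADC_very_slow = 100e-6 mm^2/s (conventional tri-exponential).
#'
#' @param model_id one of `"biexp"`, `"triexp"`, `"modtriexp"`.
#' @return A parameter object.
#' @export
default_init <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
         biexp = biexp_params(0.50, 600e-6, 2000e-6),
         triexp = triexp_params(0.10, 0.50, 100e-6, 600e-6, 2000e-6),
         modtriexp = modtriexp_params(0.10, 0.50, 600e-6, 2000e-6))
}

# indices of the b-values used for fitting
fit_indices <- function(scheme, opts) {
  if (!any(abs(scheme$b_values - opts$fit_b_max) < 1e-9))
    stop("fit_b_max must be one of the scheme's b-values")
  which(scheme$b_values <= opts$fit_b_max + 1e-9)
}

# reorder fitted parameters so ADCs ascend, carrying fractions along
# (resolves label switching; the implied fast fraction rides along too)
label_swap <- function(model_id, v) {
  if (model_id == "biexp") {
    if (v[2L] > v[3L]) v <- c(1 - v[1L], v[3L], v[2L])
  } else if (model_id == "modtriexp") {
    if (v[3L] > v[4L]) v <- c(v[1L], 1 - v[1L] - v[2L], v[4L], v[3L])
  } else {
    f <- c(v[1L], v[2L], 1 - v[1L] - v[2L])
    d <- v[3:5]
    o <- order(d)
    f <- f[o]; d <- d[o]
    v <- c(f[1L], f[2L], d)
  }
  v
}

# core fit on explicit (b, y) points; b in s/mm^2, y normalized
fit_curve_points <- function(model_id, b, y, init, opts, trace = FALSE) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (any(!is.finite(y)))
    stop_unfittable("non-finite signal values")
  v0 <- params_to_vector(init)
  adc <- grepl("^adc", names(v0))
  v0[adc] <- v0[adc] * D_SCALE
  res <- .fit_descent_cpp(b * B_SCALE, y, model_code(model_id), unname(v0),
                          opts$max_iterations, opts$rel_tol,
                          opts$step_init, trace)
  v <- res$params
  v[adc] <- v[adc] / D_SCALE
  v <- label_swap(model_id, v)
  # guard against projection round-off before re-validating
  frac <- !adc
  v[frac] <- pmin(pmax(v[frac], 0), 1)
  out <- list(model_id = model_id,
              params = params_from_vector(model_id, v),
              rss = res$rss,
              n_points = length(b),
              k = model_k(model_id),
              converged = res$converged,
              iterations = res$iterations,
              b_values = b,
              degenerate = any(abs(diff(sort(v[adc]))) < 1e-12))
  if (trace) out$trace <- res$trace
  structure(out, class = "dwi_fit")
}

#' Fit one decay model to one voxel's curve
#'
#' Minimizes the residual sum of squares between the normalized curve and
#' the model over the fitting b-values (those `<= opts$fit_b_max`),
#' subject to non-negative fractions summing to at most one and
#' non-negative ADCs. Fitted ADCs are reordered ascending (with their
#' fractions) so that `adc_slow <= adc_fast` always holds on output.
#'
#' When `init` is not supplied, the fit is deterministic multi-start: a
#' descent from [default_init()] and one from the best point of the
#' [default_grid_spec()] lattice, keeping the better result. Supplying
#' `init` forces a single start from exactly that point (the behavior the
#' leave-one-out and stability protocols rely on).
#'
#' @param model_id one of `"biexp"`, `"triexp"`, `"modtriexp"`.
#' @param curve a [decay_curve()].
#' @param init starting parameters; `NULL` for the default multi-start.
#' @param opts a [fit_options()] list.
#' @param trace if `TRUE`, attach the accepted-iteration RSS trace.
#' @return An object of class `dwi_fit` with elements `params`, `rss`,
#'   `n_points`, `k`, `converged`, `iterations`, `b_values`.
#' @export
fit_voxel <- function(model_id, curve, init = NULL, opts = fit_options(),
                      trace = FALSE) {
  stopifnot(inherits(curve, "decay_curve"))
  model_id <- match.arg(model_id, MODEL_IDS)
  idx <- fit_indices(curve$scheme, opts)
  b <- curve$scheme$b_values[idx]
  y <- curve$s_over_s0[idx]
  if (!is.null(init)) {
    if (!identical(model_id, model_id_of(init)))
      stop("init parameter type does not match model_id")
    return(fit_curve_points(model_id, b, y, init, opts, trace))
  }
  fit <- fit_curve_points(model_id, b, y, default_init(model_id), opts,
                          trace)
  seed_pt <- grid_best_point(model_id, b, y, default_grid_spec(model_id))
  fit2 <- fit_curve_points(model_id, b, y,
                           params_from_vector(model_id, seed_pt$v), opts,
                           trace)
  if (fit2$rss < fit$rss) fit2 else fit
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat(sprintf("%s fit: rss = %.4g over %d points (k = %d, %s in %d iter)\n",
              x$model_id, x$rss, x$n_points, x$k,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  print(x$params)
  invisible(x)
}

#' Default parameter lattice for the grid oracle
#'
#' A modest rectangular lattice over the physiologically plausible region
#' (fractions up to ~0.9, ADCs up to 5000e-6 mm^2/s), dense enough that a
#' local polish from the best lattice point reaches the global optimum on
#' realistic curves.
#'
#' @param model_id model identifier.
#' @return A named list of per-parameter grid vectors.
#' @export
default_grid_spec <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
         biexp = list(f_slow = seq(0.05, 0.95, length.out = 11),
                      adc_slow = seq(50e-6, 1500e-6, length.out = 9),
                      adc_fast = seq(600e-6, 5000e-6, length.out = 9)),
         modtriexp = list(f0 = seq(0, 0.4, length.out = 7),
                          f_slow = seq(0.05, 0.9, length.out = 9),
                          adc_slow = seq(50e-6, 1500e-6, length.out = 8),
                          adc_fast = seq(600e-6, 5000e-6, length.out = 8)),
         triexp = list(f_very_slow = seq(0, 0.4, length.out = 5),
                       f_slow = seq(0.05, 0.85, length.out = 7),
                       adc_very_slow = seq(0, 300e-6, length.out = 4),
                       adc_slow = seq(100e-6, 1500e-6, length.out = 6),
                       adc_fast = seq(700e-6, 5000e-6, length.out = 6)))
}

# exhaustive RSS evaluation over a feasible parameter lattice; returns the
# best point and its RSS
grid_best_point <- function(model_id, b, y, grid_spec) {
  nms <- free_param_names(model_id)
  P <- as.matrix(expand.grid(grid_spec, KEEP.OUT.ATTRS = FALSE))
  frac_cols <- grep("^f", nms)
  adc_cols <- grep("^adc", nms)
  feasible <- rowSums(P[, frac_cols, drop = FALSE]) <= 1
  if (length(adc_cols) > 1L)
    for (j in seq_len(length(adc_cols) - 1L))
      feasible <- feasible & P[, adc_cols[j]] <= P[, adc_cols[j + 1L]]
  P <- P[feasible, , drop = FALSE]
  if (nrow(P) == 0L) stop("empty lattice after feasibility filtering")

  rss <- numeric(nrow(P))
  for (i in seq_along(b)) {
    m <- switch(model_id,
      biexp = P[, 1L] * exp(-P[, 2L] * b[i]) +
        (1 - P[, 1L]) * exp(-P[, 3L] * b[i]),
      triexp = P[, 1L] * exp(-P[, 3L] * b[i]) +
        P[, 2L] * exp(-P[, 4L] * b[i]) +
        (1 - P[, 1L] - P[, 2L]) * exp(-P[, 5L] * b[i]),
      modtriexp = P[, 1L] + P[, 2L] * exp(-P[, 3L] * b[i]) +
        (1 - P[, 1L] - P[, 2L]) * exp(-P[, 4L] * b[i]))
    rss <- rss + (m - y[i])^2
  }
  best <- which.min(rss)
  list(v = P[best, ], rss = rss[best])
}

#' Brute-force grid-search oracle
#'
#' Exhaustively evaluates the RSS at every point of a finite parameter
#' lattice, returns the best point, and (by default) polishes it with a
#' local descent. Used as the independent correctness anchor for
#' [fit_voxel()]: the descent fit must never end up meaningfully above the
#' oracle's RSS.
#'
#' @param model_id model identifier.
#' @param curve a [decay_curve()].
#' @param grid_spec named list of per-parameter grid vectors (in the
#'   model's free-parameter order); defaults to [default_grid_spec()].
#'   Infeasible lattice points (fraction sums > 1, unordered ADCs) are
#'   dropped.
#' @param opts a [fit_options()] list.
#' @param polish run a local descent from the best lattice point.
#' @return A `dwi_fit` object (with `method = "grid_oracle"`).
#' @export
grid_oracle <- function(model_id, curve, grid_spec = NULL,
                        opts = fit_options(), polish = TRUE) {
  model_id <- match.arg(model_id, MODEL_IDS)
  stopifnot(inherits(curve, "decay_curve"))
  if (is.null(grid_spec)) grid_spec <- default_grid_spec(model_id)
  nms <- free_param_names(model_id)
  if (!identical(names(grid_spec), nms))
    stop("grid_spec names must be exactly: ", paste(nms, collapse = ", "))
  if (any(lengths(grid_spec) == 0L)) stop("empty lattice")

  idx <- fit_indices(curve$scheme, opts)
  b <- curve$scheme$b_values[idx]
  y <- curve$s_over_s0[idx]

  best <- grid_best_point(model_id, b, y, grid_spec)
  v <- best$v
  best_rss <- best$rss
  res <- list(model_id = model_id,
              params = params_from_vector(model_id, label_swap(model_id, v)),
              rss = best_rss, n_points = length(b), k = model_k(model_id),
              converged = TRUE, iterations = 0L, b_values = b,
              method = "grid_oracle")
  class(res) <- "dwi_fit"
  if (polish) {
    pol <- fit_curve_points(model_id, b, y,
                            params_from_vector(model_id, v), opts)
    if (pol$rss < best_rss) {
      pol$method <- "grid_oracle"
      res <- pol
    }
  }
  res
}

#' Voxel-wise fitting of a 4-D volume
#'
#' Applies [fit_voxel()] to every voxel inside a mask and assembles 3-D
#' parametric maps plus an RSS map. Maps are emitted in display units:
#' fractions in percent, ADCs in 1e-6 mm^2/s. Voxels that cannot be
#' normalized or fitted (non-positive S0, non-finite signals) are set to
#' `NA` and counted.
#'
#' @param model_id model identifier.
#' @param data 4-D numeric array `[x, y, z, b]`; the 4th dimension must
#'   match the scheme length.
#' @param scheme a [bvalue_scheme()].
#' @param mask optional 3-D logical/0-1 array; default: all voxels.
#' @param opts a [fit_options()] list.
#' @return An object of class `dwi_param_maps`: a named list of 3-D maps
#'   (one per reported parameter, plus `rss`), with attributes `model_id`,
#'   `scheme` and `n_unfittable`.
#' @export
fit_volume <- function(model_id, data, scheme, mask = NULL,
                       opts = fit_options()) {
  model_id <- match.arg(model_id, MODEL_IDS)
  dims <- dim(data)
  if (length(dims) != 4L || dims[4L] != length(scheme$b_values))
    stop("data must be 4-D with the 4th dimension matching the scheme")
  vox_dims <- dims[1:3]
  if (is.null(mask)) mask <- array(TRUE, vox_dims)
  if (!identical(dim(mask), vox_dims))
    stop("mask shape does not match the data")
  mask <- array(as.logical(mask), vox_dims)

  par_names <- c(report_param_names(model_id), "rss")
  maps <- lapply(par_names, function(n) array(NA_real_, vox_dims))
  names(maps) <- par_names

  vox <- which(mask)
  if (length(vox) == 0L)
    warning("mask selects no voxels; returning empty maps")
  n_unfittable <- 0L
  nvol <- prod(vox_dims)
  for (v in vox) {
    raw <- data[v + (seq_len(dims[4L]) - 1L) * nvol]
    fit <- tryCatch({
      curve <- normalize_signal(raw, scheme)
      fit_voxel(model_id, curve, opts = opts)
    }, triexpdwi_unfittable = function(e) NULL)
    if (is.null(fit)) {
      n_unfittable <- n_unfittable + 1L
      next
    }
    vals <- display_values(fit$params)
    for (nm in names(vals)) maps[[nm]][v] <- vals[[nm]]
    maps[["rss"]][v] <- fit$rss
  }
  structure(maps, class = "dwi_param_maps", model_id = model_id,
            scheme = scheme, n_unfittable = n_unfittable)
}

# reported parameter values in display units (% and 1e-6 mm^2/s)
display_values <- function(p) {
  v <- params_to_vector(p)
  adc <- grepl("^adc", names(v))
  v[adc] <- v[adc] * 1e6
  v[!adc] <- v[!adc] * 100
  c(as.list(v), f_fast = 100 * f_fast(p))
}

#' @export
print.dwi_param_maps <- function(x, ...) {
  cat(attr(x, "model_id"), "parameter maps:",
      paste(names(x), collapse = ", "), "\n")
  cat("dimensions:", paste(dim(x[[1L]]), collapse = " x "),
      "| unfittable voxels:", attr(x, "n_unfittable"), "\n")
  invisible(x)
}

#' Default random-initialization ranges for the stability experiment
#'
#' For the modified tri-exponential model: f0 in `[0.05, 0.10]`, f_slow in
#' `[0.50, 0.60]`, ADC_slow in `[500, 800]`e-6 and ADC_fast in
#' `[1900, 2200]`e-6 mm^2/s. The other models reuse the shared ranges;
#' the conventional tri-exponential additionally draws f_very_slow from
#' `[0.05, 0.10]` and ADC_very_slow from `[50, 150]`e-6 mm^2/s.
#'
#' @param model_id model identifier.
#' @return Named list of `c(lower, upper)` ranges per free parameter.
#' @export
default_init_ranges <- function(model_id) {
  base <- list(f_slow = c(0.50, 0.60), adc_slow = c(500e-6, 800e-6),
               adc_fast = c(1900e-6, 2200e-6))
  switch(match.arg(model_id, MODEL_IDS),
         biexp = base,
         modtriexp = c(list(f0 = c(0.05, 0.10)), base),
         triexp = c(list(f_very_slow = c(0.05, 0.10)), base[1L],
                    list(adc_very_slow = c(50e-6, 150e-6)), base[2:3]))
}

#' Random-initialization stability experiment
#'
#' Draws `n_sets` random starting points uniformly from per-parameter
#' ranges, refits the model from each, and summarizes the distribution of
#' every fitted parameter (including the implied fast fraction) as
#' mean and SD in display units. A stable fit shows negligible SD: the
#' optimum does not depend on where the descent started.
#'
#' @param model_id model identifier.
#' @param curve a [decay_curve()].
#' @param ranges named list of `c(lower, upper)` per free parameter;
#'   defaults to [default_init_ranges()].
#' @param n_sets number of random initializations (>= 2).
#' @param seed RNG seed.
#' @param opts a [fit_options()] list.
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `unit`.
#' @export
stability_experiment <- function(model_id, curve, ranges = NULL,
                                 n_sets = 20L, seed = 1L,
                                 opts = fit_options()) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (n_sets < 2L) stop("n_sets must be >= 2 (SD undefined otherwise)")
  if (is.null(ranges)) ranges <- default_init_ranges(model_id)
  nms <- free_param_names(model_id)
  if (!all(names(ranges) %in% nms))
    stop("unknown parameter in ranges")
  for (r in ranges) if (r[1L] > r[2L]) stop("range lower bound > upper")

  defaults <- params_to_vector(default_init(model_id))
  set.seed(seed)
  fits <- matrix(NA_real_, n_sets, length(nms) + 1L,
                 dimnames = list(NULL, c(nms, "f_fast")))
  for (s in seq_len(n_sets)) {
    v <- defaults
    for (nm in names(ranges)) v[nm] <- runif(1L, ranges[[nm]][1L],
                                             ranges[[nm]][2L])
    init <- params_from_vector(model_id, v)
    fit <- fit_voxel(model_id, curve, init = init, opts = opts)
    fits[s, nms] <- params_to_vector(fit$params)
    fits[s, "f_fast"] <- f_fast(fit$params)
  }
  adc <- grepl("^adc", colnames(fits))
  disp <- fits
  disp[, adc] <- disp[, adc] * 1e6
  disp[, !adc] <- disp[, !adc] * 100
  data.frame(parameter = colnames(disp),
             mean = colMeans(disp),
             sd = apply(disp, 2L, sd),
             unit = ifelse(adc, "1e-6 mm^2/s", "%"),
             row.names = NULL)
}
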