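# End-to-end orchestration: voxel-wise fits and model comparison over a
# volume, ROI aggregation, paired Wilcoxon model comparisons, and CSV
# report tables. Quantiles use linear interpolation between order
# statistics (stats::quantile type 7) throughout.

#' ROI summary of parameter or score maps
#'
#' Parameter maps are summarized as mean and SD; model-ranking score maps
#' (RSS, AICc, PRESS, SPE) as median and quartiles. Voxels that failed to
#' fit (`NA`) are dropped; an ROI with no valid voxels is an error.
#'
#' @param maps a `dwi_param_maps` object (mean/SD summary) or a named list
#'   of 3-D score maps (median/quartile summary).
#' @param roi_mask logical/0-1 3-D array.
#' @return A data.frame: `parameter`, `mean`, `sd`, `n_voxels` for
#'   parameter maps; `statistic`, `median`, `q1`, `q3`, `n_voxels` for
#'   score maps.
#' @export
roi_summary <- function(maps, roi_mask) {
  UseMethod("roi_summary")
}

roi_values <- function(map, roi_mask) {
  if (!identical(dim(map), dim(roi_mask)))
    stop("map and ROI mask shapes differ")
  v <- map[as.logical(roi_mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("ROI contains no valid (fitted) voxels")
  v
}

#' @export
roi_summary.dwi_param_maps <- function(maps, roi_mask) {
  par_names <- setdiff(names(maps), "rss")
  rows <- lapply(par_names, function(nm) {
    v <- roi_values(maps[[nm]], roi_mask)
    data.frame(parameter = nm, mean = mean(v), sd = sd(v),
               n_voxels = length(v))
  })
  do.call(rbind, rows)
}

#' @export
roi_summary.list <- function(maps, roi_mask) {
  rows <- lapply(names(maps), function(nm) {
    v <- roi_values(maps[[nm]], roi_mask)
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(statistic = nm, median = q[2L], q1 = q[1L], q3 = q[3L],
               n_voxels = length(v))
  })
  do.call(rbind, rows)
}

#' @export
roi_summary.default <- function(maps, roi_mask) {
  v <- roi_values(as.array(maps), roi_mask)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(mean = mean(v), sd = sd(v), median = q[2L], q1 = q[1L],
             q3 = q[3L], n_voxels = length(v))
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares two paired samples (e.g. one score per voxel under two
#' models). Exact p-values are used for fewer than 26 pairs when there are
#' no zero differences or ties; otherwise the normal approximation with
#' continuity correction handles zeros and ties. If every difference is
#' zero the test is undefined and flagged as such rather than forced.
#'
#' @param paired_a,paired_b numeric vectors of equal length >= 6.
#' @return A list: `p_value` (NA when undefined), `defined`, `direction`
#'   (sign of the median difference `a - b`), `n`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired samples must have equal length")
  n <- length(paired_a)
  if (n < 6L) stop("at least 6 pairs required")
  d <- paired_a - paired_b
  if (all(d == 0))
    return(list(p_value = NA_real_, defined = FALSE, direction = 0L,
                n = n))
  use_exact <- n < 26L && !any(d == 0) && !any(duplicated(abs(d[d != 0])))
  p <- suppressWarnings(
    wilcox.test(paired_a, paired_b, paired = TRUE, exact = use_exact,
                correct = TRUE)$p.value)
  list(p_value = p, defined = TRUE,
       direction = as.integer(sign(median(d))), n = n)
}

# voxel-wise model comparison over a masked volume: per-model parameter
# maps plus per-model score maps (rss, aicc, press, spe, s_predicted)
analyze_volume <- function(data, scheme, mask, opts = fit_options(),
                           models = MODEL_IDS, with_press = TRUE) {
  dims <- dim(data)
  vox_dims <- dims[1:3]
  nvol <- prod(vox_dims)
  stat_names <- c("rss", "aicc", "press", "spe", "s_predicted")
  score_maps <- lapply(models, function(m) {
    out <- lapply(stat_names, function(s) array(NA_real_, vox_dims))
    names(out) <- stat_names
    out
  })
  names(score_maps) <- models
  param_maps <- lapply(models, function(m) {
    nm <- c(report_param_names(m), "rss")
    out <- lapply(nm, function(x) array(NA_real_, vox_dims))
    names(out) <- nm
    structure(out, class = "dwi_param_maps", model_id = m,
              scheme = scheme, n_unfittable = 0L)
  })
  names(param_maps) <- models
  s_measured_map <- array(NA_real_, vox_dims)

  n_unfittable <- 0L
  for (v in which(as.logical(mask))) {
    raw <- data[v + (seq_len(dims[4L]) - 1L) * nvol]
    cmp <- tryCatch({
      curve <- normalize_signal(raw, scheme)
      compare_models(curve, opts, models, with_press = with_press)
    }, triexpdwi_unfittable = function(e) NULL)
    if (is.null(cmp)) {
      n_unfittable <- n_unfittable + 1L
      next
    }
    s_measured_map[v] <- cmp$s_measured
    for (m in models) {
      row <- cmp$scores[cmp$scores$model == m, ]
      for (s in stat_names) score_maps[[m]][[s]][v] <- row[[s]]
      vals <- display_values(cmp$fits[[m]]$params)
      for (nm in names(vals)) param_maps[[m]][[nm]][v] <- vals[[nm]]
      param_maps[[m]][["rss"]][v] <- row$rss
    }
  }
  for (m in models) attr(param_maps[[m]], "n_unfittable") <- n_unfittable
  list(param_maps = param_maps, score_maps = score_maps,
       s_measured = s_measured_map, n_unfittable = n_unfittable)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a 4-D multi-b-value dataset, fits all three models
#' voxel-wise, computes the ranking statistics, aggregates them per ROI,
#' runs pairwise paired Wilcoxon tests between models for each statistic,
#' and writes report tables (CSV), parameter/score maps (NIfTI) and a run
#' log. Fully deterministic given the seed in the configuration.
#'
#' @param config a named list or path to a YAML file. Recognized fields:
#'   `seed`; either `phantom` (fields `dim`, `sigma`, or omitted for the
#'   default phantom) or `input` (list with `nifti` and `btable` paths and
#'   optionally `roi_masks`, a named list of NIfTI label mask paths);
#'   `fit` (fields of [fit_options()]); `with_press` (default `TRUE`);
#'   `models`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the report bundle: list with `tables` (named list of
#'   data.frames), `param_maps`, `score_maps`, `rois`, `scheme`, `paths`.
#' @export
run_full_analysis <- function(config = list(), out_dir = tempfile("dwi_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  models <- if (is.null(config$models)) MODEL_IDS else
    match.arg(config$models, MODEL_IDS, several.ok = TRUE)
  opts <- do.call(fit_options, config$fit %||% list())
  with_press <- config$with_press %||% TRUE

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map_dir <- file.path(out_dir, "maps")
  tab_dir <- file.path(out_dir, "tables")
  dir.create(map_dir, showWarnings = FALSE)
  dir.create(tab_dir, showWarnings = FALSE)

  if (!is.null(config$input)) {
    data <- as.array(RNifti::readNifti(config$input$nifti))
    scheme <- read_bvalue_table(config$input$btable)
    rois <- lapply(config$input$roi_masks, function(p)
      as.array(RNifti::readNifti(p)) > 0)
    if (length(rois) == 0L)
      rois <- list(all = array(TRUE, dim(data)[1:3]))
  } else {
    ph_cfg <- config$phantom %||% list()
    spec <- if (!is.null(ph_cfg$dim) || !is.null(ph_cfg$sigma)) {
      sp <- default_phantom_spec(dim = ph_cfg$dim %||% c(32L, 32L, 4L),
                                 seed = seed)
      if (!is.null(ph_cfg$sigma)) sp$sigma <- ph_cfg$sigma
      sp
    } else default_phantom_spec(seed = seed)
    phantom <- make_phantom(spec)
    data <- phantom$data
    scheme <- phantom$scheme
    rois <- lapply(seq_along(spec$classes), function(i)
      phantom$labels == i)
    names(rois) <- vapply(spec$classes, `[[`, "", "name")
    RNifti::writeNifti(RNifti::asNifti(phantom$labels + 0),
                       file.path(map_dir, "labels.nii.gz"))
  }

  mask <- Reduce(`|`, rois)
  res <- analyze_volume(data, scheme, mask, opts, models, with_press)

  # per-ROI score tables (one per statistic, rows = roi x model)
  stat_names <- c("rss", "aicc", if (with_press) "press", "spe")
  tables <- list()
  for (s in stat_names) {
    rows <- list()
    for (r in names(rois)) for (m in models) {
      sm <- roi_summary(res$score_maps[[m]][s], rois[[r]])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(roi = r, model = m), sm)
    }
    tables[[s]] <- do.call(rbind, rows)
  }

  # parameter table (mean +/- SD per ROI, model and parameter)
  rows <- list()
  for (r in names(rois)) for (m in models) {
    sm <- roi_summary(res$param_maps[[m]], rois[[r]])
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(roi = r, model = m), sm)
  }
  tables$parameters <- do.call(rbind, rows)

  # pairwise Wilcoxon per ROI and statistic (voxel-wise pairing)
  pairs <- if (length(models) >= 2L) utils::combn(models, 2L,
                                                  simplify = FALSE)
           else list()
  rows <- list()
  for (r in names(rois)) for (s in stat_names) for (pr in pairs) {
    a <- roi_values(res$score_maps[[pr[1L]]][[s]], rois[[r]])
    b <- roi_values(res$score_maps[[pr[2L]]][[s]], rois[[r]])
    w <- wilcoxon_signed_rank(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = r, statistic = s, model_a = pr[1L], model_b = pr[2L],
      p_value = w$p_value, direction = w$direction, n = w$n,
      pairing = "voxel")
  }
  tables$comparisons <- if (length(rows)) do.call(rbind, rows) else NULL

  # write outputs
  for (nm in names(tables))
    if (!is.null(tables[[nm]]))
      write.csv(tables[[nm]], file.path(tab_dir, paste0(nm, ".csv")),
                row.names = FALSE)
  for (m in models) {
    for (nm in names(res$param_maps[[m]]))
      RNifti::writeNifti(RNifti::asNifti(res$param_maps[[m]][[nm]]),
        file.path(map_dir, paste0(m, "_", nm, ".nii.gz")))
    for (s in c("aicc", if (with_press) "press", "spe"))
      RNifti::writeNifti(RNifti::asNifti(res$score_maps[[m]][[s]]),
        file.path(map_dir, paste0(m, "_", s, ".nii.gz")))
  }
  n_tests <- length(rows)
  writeLines(c(
    paste("triexpdwi run log"),
    paste("seed:", seed),
    paste("models:", paste(models, collapse = ", ")),
    paste("fit_b_max:", opts$fit_b_max),
    paste("max_iterations:", opts$max_iterations),
    paste("rel_tol:", format(opts$rel_tol)),
    paste("unfittable voxels:", res$n_unfittable),
    paste("wilcoxon pairing: voxel-wise within ROI"),
    paste("wilcoxon comparisons (uncorrected):", n_tests)),
    file.path(out_dir, "log.txt"))

  invisible(list(tables = tables, param_maps = res$param_maps,
                 score_maps = res$score_maps, rois = rois,
                 scheme = scheme,
                 paths = list(out_dir = out_dir, maps = map_dir,
                              tables = tab_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
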