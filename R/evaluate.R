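# End-to-end experiment runner and summary statistics: per-trial
# dissimilarities, cumulative distributions and percentiles, per-slant
# means, and pairwise slant correlations.

#' Summarize trial results
#'
#' For each condition (any combination of grouping columns present,
#' typically object_type x projection) computes the absolute-dissimilarity
#' cumulative distribution, its percentiles (50th = the median headline
#' number), per-true-slant mean dissimilarity, and the Pearson correlation
#' between slant sources.
#'
#' @param results data.frame with columns `slant_true_deg`,
#'   `slant_model_deg`, optionally `slant_response_deg`, and optional
#'   grouping columns `object_type`, `projection`
#' @param probs percentile probabilities for the cumulative summary
#' @return a list of class `summary_table`: one entry per condition with
#'   `n`, `median_abs_dissimilarity`, `percentiles`, `cumulative`
#'   (data.frame ad, proportion), `per_slant` (mean dissimilarity by true
#'   slant), `correlations`
#' @export
evaluate_trials <- function(results, probs = c(0.25, 0.5, 0.75, 0.9)) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  group_cols <- intersect(c("object_type", "projection"), names(results))
  key <- if (length(group_cols))
    interaction(results[group_cols], drop = TRUE, sep = " / ")
  else factor(rep("all", nrow(results)))
  out <- lapply(split(results, key), function(df) {
    diss <- mapply(shape_dissimilarity, df$slant_true_deg,
                   df$slant_model_deg)
    ad <- sort(abs(diss))
    cumulative <- data.frame(ad = ad,
                             proportion = seq_along(ad) / length(ad))
    per_slant <- tapply(diss, df$slant_true_deg, mean)
    cors <- list(model_vs_true = safe_cor(df$slant_model_deg,
                                          df$slant_true_deg))
    diss_resp <- NULL
    if ("slant_response_deg" %in% names(df) &&
        !anyNA(df$slant_response_deg)) {
      diss_resp <- mapply(shape_dissimilarity, df$slant_response_deg,
                          df$slant_model_deg)
      cors$model_vs_response <- safe_cor(df$slant_model_deg,
                                         df$slant_response_deg)
      cors$response_vs_true <- safe_cor(df$slant_response_deg,
                                        df$slant_true_deg)
    }
    list(n = nrow(df),
         median_abs_dissimilarity = stats::quantile(abs(diss), 0.5,
                                                    names = FALSE),
         percentiles = stats::quantile(abs(diss), probs),
         cumulative = cumulative,
         per_slant = per_slant,
         median_abs_model_vs_response =
           if (is.null(diss_resp)) NA_real_
           else stats::quantile(abs(diss_resp), 0.5, names = FALSE),
         correlations = cors)
  })
  structure(out, class = "summary_table")
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: a slant source is constant")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' @export
print.summary_table <- function(x, ...) {
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("%s: n = %d, median |dissimilarity| = %.4f, r(model, true) = %s\n",
                nm, s$n, s$median_abs_dissimilarity,
                formatC(s$correlations$model_vs_true, digits = 3,
                        format = "f")))
  }
  invisible(x)
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one list; [run_pipeline()]
#' accepts this list, a modified copy, or the path to a YAML file with the
#' same structure. Defaults reproduce the experimental geometry: viewing
#' distance 50.8 cm, target angular sizes ~7.2 (orthographic) and ~22.8
#' (perspective) degrees, 1-degree segment orientation noise, slant grid
#' 0.2..pi/2 - 0.2 rad in 0.01 rad steps.
#'
#' @return a named list
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    n_per_slant = 1L,
    object_type = "rectangular",
    projection = "perspective",
    viewing_distance = 50.8,
    target_gamma_deg = NULL,   # filled from projection when NULL
    noise_sd_deg = 1.0,
    ransac_iters = 600L,
    grid = list(lo = 0.2, hi = pi / 2 - 0.2, step = 0.01),
    observer = list(beta0 = 0, beta1 = 0.5, beta2 = 0.25, beta3 = 0.25,
                    t_deg = 75, response_noise_deg = 2),
    stimulus = list(edge_range = c(1, 4), width_range = c(1, 4),
                    size_ratio_range = c(0.3, 1.0))
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  base[names(config)] <- config
  if (is.null(base$target_gamma_deg))
    base$target_gamma_deg <-
      if (base$projection == "perspective") 22.8 else 7.2
  base
}

scale_for_gamma <- function(mesh, gamma_deg, distance) {
  ctr <- colMeans(mesh$vertices)
  r <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  target_r <- distance * tan(gamma_deg / 2 * pi / 180)
  s <- target_r / r
  mesh$vertices <- mesh$vertices * s
  mesh
}

#' Run the full model pipeline on simulated trials
#'
#' Generates a condition set, detects symmetry planes, projects and
#' perturbs pair images, corrects them, computes the four slant estimates
#' per trial, simulates an observer with the configured coefficients, fits
#' the model back to the simulated responses and summarizes
#' dissimilarities. Deterministic given the config seed.
#'
#' @param config a config list (see [default_pipeline_config()]) or path
#'   to a YAML file
#' @param outdir optional directory; when given, writes manifest.csv,
#'   estimates.csv, predictions.csv, fit.json and summary.json there
#' @return invisibly, a list with `manifest`, `estimates` (data.frame),
#'   `fit` (`model_coefficients`), `summary` (`summary_table`), `config`
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = NULL) {
  cfg <- load_pipeline_config(config)
  params <- do.call(stimulus_params, cfg$stimulus)
  cond <- generate_condition_set(cfg$n_per_slant, cfg$object_type,
                                 params, seed = cfg$seed)
  cam <- camera(cfg$projection, cfg$viewing_distance)
  grid_args <- cfg$grid
  rows <- vector("list", length(cond$trials))
  for (i in seq_along(cond$trials)) {
    tr <- cond$trials[[i]]
    mesh <- scale_for_gamma(tr$mesh, cfg$target_gamma_deg,
                            cfg$viewing_distance)
    ctr <- colMeans(mesh$vertices)
    pose <- view_pose(tr$view, distance = cfg$viewing_distance,
                      center = ctr)
    cands <- ransac_symmetry_planes(mesh, n_iters = cfg$ransac_iters,
                                    seed = cfg$seed + 7919L * i)
    sel <- tryCatch(select_primary_secondary(mesh, cands),
                    error = function(e) list(primary = cands[[1]],
                                             secondary = NULL))
    img1 <- project_pairs(mesh, sel$primary, pose, cam)
    img1 <- perturb_orientations(img1, cfg$noise_sd_deg,
                                 seed = cfg$seed + 2L * i)
    cor1 <- correct_to_orthographic(img1)
    fam2 <- NULL; shared <- NULL
    if (!is.null(sel$secondary) && nrow(sel$secondary$pairs) >= 2) {
      img2 <- project_pairs(mesh, sel$secondary, pose, cam)
      img2 <- perturb_orientations(img2, cfg$noise_sd_deg,
                                   seed = cfg$seed + 2L * i + 1L)
      fam2 <- do.call(family_grid,
                      c(list(correct_to_orthographic(img2)), grid_args))
      posed <- apply_pose(mesh, pose)
      shared <- shared_index_map(posed,
                                 pose_correspondences(sel$primary, pose),
                                 pose_correspondences(sel$secondary, pose))
      if (nrow(shared) == 0) { fam2 <- NULL; shared <- NULL }
    }
    est <- trial_slant_estimates(img1, corrected = cor1, fam2 = fam2,
                                 shared = shared, grid_args = grid_args)
    rows[[i]] <- data.frame(
      trial_id = i,
      object_type = cfg$object_type,
      projection = cfg$projection,
      slant_true_deg = tr$view$slant_deg,
      tilt_deg = tr$view$tilt_deg,
      gamma_deg = est$gamma_deg,
      theta_v2s3_deg = est$v2s3$value_deg,
      theta_s3v_deg = est$s3v$value_deg,
      theta_sym2_deg = est$sym2$value_deg,
      theta_persp_deg = est$persp$value_deg)
  }
  estimates <- do.call(rbind, rows)
  beta_true <- do.call(model_coefficients,
                       cfg$observer[c("beta0", "beta1", "beta2", "beta3",
                                      "t_deg")])
  if (anyNA(estimates$theta_sym2_deg) && beta_true$beta3 != 0) {
    # no secondary plane on some trials: the simulated observer cannot
    # weight the two-plane estimate; fold its weight into compactness
    beta_true$beta1 <- beta_true$beta1 + beta_true$beta3
    beta_true$beta3 <- 0
  }
  sim <- simulate_observer(estimates, beta_true,
                           cfg$observer$response_noise_deg,
                           seed = cfg$seed + 104729L)
  estimates$response_slant_deg <- sim$response_slant_deg
  fit <- tryCatch(fit_coefficients(estimates, t_deg = beta_true$t_deg),
                  error = function(e) {
                    warning("model fit failed: ", conditionMessage(e))
                    NULL
                  })
  beta_pred <- if (is.null(fit)) beta_true else fit
  estimates$slant_model_deg <- vapply(seq_len(nrow(estimates)),
    function(i) {
      est <- list(v2s3 = estimates$theta_v2s3_deg[i],
                  s3v = estimates$theta_s3v_deg[i],
                  sym2 = estimates$theta_sym2_deg[i],
                  persp = estimates$theta_persp_deg[i],
                  gamma_deg = estimates$gamma_deg[i])
      predict_slant(est, beta_pred)
    }, numeric(1))
  results <- data.frame(
    trial_id = estimates$trial_id,
    object_type = estimates$object_type,
    projection = estimates$projection,
    slant_true_deg = estimates$slant_true_deg,
    slant_model_deg = estimates$slant_model_deg,
    slant_response_deg = estimates$response_slant_deg)
  summary <- evaluate_trials(results)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cond$manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(estimates, file.path(outdir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(outdir, "predictions.csv"),
                     row.names = FALSE)
    if (!is.null(fit))
      jsonlite::write_json(unclass(fit), file.path(outdir, "fit.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(summary, function(s)
        list(n = s$n,
             median_abs_dissimilarity = s$median_abs_dissimilarity,
             correlations = s$correlations)),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(manifest = cond$manifest, estimates = estimates,
                 fit = fit, summary = summary, config = cfg))
}
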