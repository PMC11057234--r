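# Lambda-weighted combination of the four slant estimators and its
# least-squares fit to response data. The perspective estimate gets weight
# lambda (a function of the image's angular size), the linear combination
# of the three constraint-based estimates gets weight 1 - lambda:
#   theta_hat = lambda theta_persp + (1 - lambda) theta_LM
#   theta_LM  = beta0 + beta1 theta_v2s3 + beta2 theta_s3v +
#               beta3 theta_sym2

#' Perspective reliability weight lambda
#'
#' alpha = tan(gamma / 2); phi = 2 atan(alpha tan t); lambda =
#' (1 - cos phi) / 2. phi is the convergence angle between symmetry
#' segments for a reference surface rotated by t away from frontoparallel,
#' so lambda grows monotonically from 0 (vanishing image, no usable
#' perspective information) toward 1, weighting the vanishing-point
#' estimate more as angular size increases. t = 75 degrees gave the best
#' account of observers and is the default.
#'
#' @param gamma_deg angular size of the image in degrees, in [0, 180)
#' @param t_deg reference rotation parameter in degrees, in (0, 90)
#' @return lambda in [0, 1]
#' @export
lambda_weight <- function(gamma_deg, t_deg = 75) {
  stopifnot(gamma_deg >= 0, gamma_deg < 180, t_deg > 0, t_deg < 90)
  alpha <- tan(gamma_deg / 2 * pi / 180)
  phi <- 2 * atan(alpha * tan(t_deg * pi / 180))
  (1 - cos(phi)) / 2
}

#' Model coefficients
#' @param beta0,beta1,beta2,beta3 intercept and weights on theta_v2s3,
#'   theta_s3v, theta_sym2 (degrees scale)
#' @param t_deg lambda parameter, default 75
#' @return a list of class `model_coefficients`
#' @export
model_coefficients <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                               t_deg = 75) {
  stopifnot(is.finite(c(beta0, beta1, beta2, beta3)),
            t_deg > 0, t_deg < 90)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 beta3 = beta3, t_deg = t_deg),
            class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat(sprintf(
    "model_coefficients: beta = (%.4g, %.4g, %.4g, %.4g), t = %g deg\n",
    x$beta0, x$beta1, x$beta2, x$beta3, x$t_deg))
  invisible(x)
}

est_value <- function(e) if (inherits(e, "slant_estimate")) e$value_deg else e

#' Linear combination of the constraint-based slant estimates
#'
#' Single intercept: beta0 + beta1 theta_v2s3 + beta2 theta_s3v + beta3
#' theta_sym2. An NA theta_sym2 (no secondary plane) is only allowed when
#' beta3 = 0.
#'
#' @param est list with elements `v2s3`, `s3v`, `sym2` (numbers or
#'   `slant_estimate`s)
#' @param beta a `model_coefficients`
#' @return theta_LM in degrees
#' @export
theta_lm <- function(est, beta) {
  th3 <- est_value(est$sym2)
  if (is.na(th3)) {
    if (beta$beta3 != 0) stop("theta_sym2 is NA but beta3 != 0")
    th3 <- 0
  }
  beta$beta0 + beta$beta1 * est_value(est$v2s3) +
    beta$beta2 * est_value(est$s3v) + beta$beta3 * th3
}

#' Combined model slant prediction
#'
#' theta_hat = lambda theta_persp + (1 - lambda) theta_LM, with lambda
#' computed from the trial's angular size and the model's t. The
#' prediction is clamped to the adjustable slant range [0.2, pi/2 - 0.2]
#' radians when `clamp` is TRUE (the experiment's response range).
#'
#' @param est list with `v2s3`, `s3v`, `sym2`, `persp` and `gamma_deg`
#' @param beta a `model_coefficients`
#' @param clamp clamp to the adjustable range?
#' @return predicted slant in degrees
#' @export
predict_slant <- function(est, beta, clamp = TRUE) {
  lam <- lambda_weight(est$gamma_deg, beta$t_deg)
  th <- lam * est_value(est$persp) + (1 - lam) * theta_lm(est, beta)
  if (clamp) {
    lo <- 0.2 * 180 / pi
    hi <- (pi / 2 - 0.2) * 180 / pi
    th <- min(max(th, lo), hi)
  }
  th
}

records_frame <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(theta_v2s3_deg = est_value(r$v2s3),
               theta_s3v_deg = est_value(r$s3v),
               theta_sym2_deg = est_value(r$sym2),
               theta_persp_deg = est_value(r$persp),
               gamma_deg = r$gamma_deg,
               response_slant_deg =
                 if (is.null(r$response_slant_deg)) NA_real_
                 else r$response_slant_deg)
  }))
}

#' Fit the model coefficients to response data
#'
#' Minimizes the sum of squared errors between response slants and the
#' full model prediction theta_hat over beta0..beta3, with lambda and
#' theta_persp fixed per trial; after absorbing the (1 - lambda) factor
#' this is an ordinary least-squares problem. t stays fixed. Trials whose
#' theta_sym2 is NA are fit with beta3 forced to 0 (the whole group must
#' then lack a secondary plane).
#'
#' @param records data.frame with columns theta_v2s3_deg, theta_s3v_deg,
#'   theta_sym2_deg, theta_persp_deg, gamma_deg, response_slant_deg, and
#'   optionally grouping columns; or a list of per-trial lists
#' @param group_by optional character vector of grouping column names
#'   (e.g. c("object_type", "subject")); the model is fit separately per
#'   group
#' @param t_deg lambda parameter
#' @return a `model_coefficients` (plus fields `n_trials`, `rmse_deg`), or
#'   a named list of them when `group_by` is given
#' @export
fit_coefficients <- function(records, group_by = NULL, t_deg = 75) {
  df <- records_frame(records)
  if (!is.null(group_by)) {
    key <- interaction(df[group_by], drop = TRUE)
    return(lapply(split(df, key), fit_coefficients, t_deg = t_deg))
  }
  if (nrow(df) < 5) stop("need at least 5 records to fit")
  lam <- vapply(df$gamma_deg, lambda_weight, numeric(1), t_deg = t_deg)
  y <- df$response_slant_deg - lam * df$theta_persp_deg
  use_sym2 <- !anyNA(df$theta_sym2_deg)
  X <- cbind(1, df$theta_v2s3_deg, df$theta_s3v_deg,
             if (use_sym2) df$theta_sym2_deg)
  X <- X * (1 - lam)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cn <- c("intercept", "theta_v2s3", "theta_s3v",
            if (use_sym2) "theta_sym2")
    bad <- cn[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear estimator(s): ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qrX, y)
  beta <- model_coefficients(b[1], b[2], b[3],
                             if (use_sym2) b[4] else 0, t_deg = t_deg)
  resid <- df$response_slant_deg - (lam * df$theta_persp_deg + X %*% b)
  beta$n_trials <- nrow(df)
  beta$rmse_deg <- sqrt(mean(resid^2))
  beta
}

#' Simulate an observer with known coefficients
#'
#' Generates response slants sigma_r = clamp(theta_hat(beta) + noise) for
#' a set of trial estimates; the test surface for parameter-recovery
#' checks, standing in for human response files.
#'
#' @param trials data.frame (or list) of trial estimates as in
#'   [fit_coefficients()], response column ignored
#' @param beta true `model_coefficients`
#' @param response_noise_deg SD of the added Gaussian response noise
#' @param seed integer seed
#' @return the trials data.frame with `response_slant_deg` filled in
#' @export
simulate_observer <- function(trials, beta, response_noise_deg = 2,
                              seed = 1L) {
  df <- records_frame(trials)
  with_seed(seed, {
    noise <- stats::rnorm(nrow(df), 0, response_noise_deg)
    lo <- 0.2 * 180 / pi
    hi <- (pi / 2 - 0.2) * 180 / pi
    pred <- vapply(seq_len(nrow(df)), function(i) {
      est <- list(v2s3 = df$theta_v2s3_deg[i], s3v = df$theta_s3v_deg[i],
                  sym2 = df$theta_sym2_deg[i],
                  persp = df$theta_persp_deg[i],
                  gamma_deg = df$gamma_deg[i])
      predict_slant(est, beta, clamp = FALSE)
    }, numeric(1))
    df$response_slant_deg <- pmin(pmax(pred + noise, lo), hi)
    df
  })
}
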