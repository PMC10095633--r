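# Apparent-to-intrinsic affinity bias: closed-form prediction, inversion,
# and extraction of intrinsic constants from lipid-titration series.
#
# Dilute regime:       KeqApp / Keq = 1 / (1 + KP * alpha_lb)
# Concentrated media:  KeqApp / Keq = 1 / (alpha_w + KP * alpha_lb),
#                      alpha_w = 1 - alpha_lb - alpha_p
# The bias is independent of the protein concentration.

.bias_prediction <- function(ratio, regime) {
  structure(
    list(
      ratio = ratio,
      fold_decrease = 1 / ratio,
      orders_decrease = log10(1 / ratio),
      regime = regime
    ),
    class = "bias_prediction"
  )
}

#' @export
print.bias_prediction <- function(x, ...) {
  cat(sprintf(
    "<bias_prediction> (%s regime)\n  KeqApp/Keq = %.6g  (%.4g-fold, %.3g orders of magnitude decrease)\n",
    x$regime, x$ratio, x$fold_decrease, x$orders_decrease
  ))
  invisible(x)
}

#' Apparent/intrinsic affinity ratio, dilute regime
#'
#' When ligand sequestration by the lipid bilayer is ignored in the
#' analysis, the apparent binding constant underestimates the intrinsic one
#' by the factor `1 / (1 + kp_lb_lw * alpha_lb)`.  The bias depends only on
#' the ligand's lipophilicity and on the bilayer volume fraction — not on
#' the protein concentration.  Valid for `alpha_w >= 0.99`; see
#' [bias_general()] otherwise.
#'
#' @param kp_lb_lw Water -> bilayer partition coefficient (dimensionless,
#'   >= 0).
#' @param alpha_lb Bilayer volume fraction, in `[0, 1)`.
#' @return An object of class `bias_prediction` with fields `ratio`
#'   (`KeqApp/Keq`), `fold_decrease` (`1/ratio`), `orders_decrease`
#'   (`log10(fold_decrease)`) and `regime`.
#' @examples
#' bias_dilute(1e4, 0.01) # ~100-fold decrease
#' @export
bias_dilute <- function(kp_lb_lw, alpha_lb) {
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  .check_scalar(alpha_lb, "alpha_lb", nonneg = TRUE)
  if (alpha_lb >= 1) stop("`alpha_lb` must be < 1", call. = FALSE)
  .bias_prediction(1 / (1 + kp_lb_lw * alpha_lb), "dilute")
}

#' Apparent/intrinsic affinity ratio, concentrated media
#'
#' Exact form for any composition: `ratio = 1 / (alpha_w + kp * alpha_lb)`
#' with `alpha_w = 1 - alpha_lb - alpha_p`.  Reduces to [bias_dilute()]
#' within 1% when `alpha_w >= 0.99`.  For ligands excluded from the bilayer
#' (`kp_lb_lw < 1`) the ratio can exceed 1: exclusion concentrates the
#' ligand in the aqueous phase and *increases* the apparent affinity.
#'
#' @inheritParams bias_dilute
#' @param alpha_p Protein volume fraction (default 0); `alpha_w` must stay
#'   > 0.
#' @inherit bias_dilute return
#' @examples
#' bias_general(0.1, alpha_lb = 0.10) # ~10% increase in apparent affinity
#' @export
bias_general <- function(kp_lb_lw, alpha_lb, alpha_p = 0) {
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  .check_scalar(alpha_lb, "alpha_lb", nonneg = TRUE)
  .check_scalar(alpha_p, "alpha_p", nonneg = TRUE)
  alpha_w <- 1 - alpha_lb - alpha_p
  if (alpha_w <= 0) {
    stop("`alpha_w = 1 - alpha_lb - alpha_p` must be > 0", call. = FALSE)
  }
  .bias_prediction(1 / (alpha_w + kp_lb_lw * alpha_lb), "general")
}

#' Intrinsic binding constant from an apparent one
#'
#' Inverts the sequestration bias: `keq_lw = keq_app / ratio`, using the
#' dilute relation by default and the concentrated-media relation when
#' `alpha_p` is supplied.  Applying the bias to the returned constant
#' recovers `keq_app` exactly (roundtrip identity).
#'
#' @param keq_app Apparent binding constant (1/M, > 0), obtained with the
#'   lipid-neglecting analysis.
#' @inheritParams bias_general
#' @param alpha_p Optional protein volume fraction; when given, the
#'   concentrated-media regime is used.
#' @return Intrinsic binding constant `keq_lw` in 1/M.
#' @examples
#' intrinsic_from_apparent(1e4, kp_lb_lw = 1e4, alpha_lb = 0.01) # ~1.01e6
#' @export
intrinsic_from_apparent <- function(keq_app, kp_lb_lw, alpha_lb,
                                    alpha_p = NULL) {
  .check_scalar(keq_app, "keq_app", positive = TRUE)
  pred <- if (is.null(alpha_p)) {
    bias_dilute(kp_lb_lw, alpha_lb)
  } else {
    bias_general(kp_lb_lw, alpha_lb, alpha_p)
  }
  keq_app / pred$ratio
}

#' Orders of magnitude lost to lipid sequestration
#'
#' `log10(1 + kp_lb_lw * alpha_lb)`: how many orders of magnitude the
#' apparent binding constant falls below the intrinsic one in the dilute
#' regime.  Useful to desk-check literature affinities measured in
#' lipid-rich systems (detergent micelles, nanodiscs) against those from
#' native membranes.
#'
#' @inheritParams bias_dilute
#' @return Dimensionless orders of magnitude (>= 0).
#' @examples
#' orders_of_decrease(10^6.8, 0.01) # ~4.8 orders (micelle-like lipid load)
#' orders_of_decrease(10^6.8, 1e-4) # ~2.8 orders (native-membrane load)
#' @export
orders_of_decrease <- function(kp_lb_lw, alpha_lb) {
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  .check_scalar(alpha_lb, "alpha_lb", nonneg = TRUE)
  if (alpha_lb >= 1) stop("`alpha_lb` must be < 1", call. = FALSE)
  log10(1 + kp_lb_lw * alpha_lb)
}

#' Intrinsic affinity by extrapolation to zero lipid
#'
#' Fits a series of apparent binding constants measured at different
#' bilayer volume fractions with `keq_app = keq_lw / (1 + kp * alpha_lb)`,
#' recovering both the intrinsic constant and the ligand's partition
#' coefficient.  The nonlinear fit (Levenberg-Marquardt) minimises
#' residuals on the log scale, the natural error model for equilibrium
#' constants (measurement error on affinities is multiplicative, and the
#' fitted values span orders of magnitude along a lipid titration).  The
#' equivalent linear regression of `1/keq_app` on `alpha_lb` (slope
#' `kp/keq`, intercept `1/keq`) provides starting values and a
#' cross-check, but is not used for inference because the reciprocal
#' transform distorts the noise.
#'
#' @param alpha_lb Bilayer volume fractions (>= 3 points, at least 3
#'   distinct values).
#' @param keq_app Apparent binding constants (1/M, > 0), same length.
#' @return An object of class `lipid_extrapolation`: list with `keq_lw`,
#'   `kp_lb_lw`, `stderr` (named, from the nonlinear fit), `linear`
#'   (reciprocal-route estimates), `fit` (the `nls` object), `residuals`
#'   (log scale) and `rss`.
#' @examples
#' a <- c(0.001, 0.005, 0.01, 0.05)
#' k <- 1e6 / (1 + 1e3 * a)
#' extrapolate_to_zero_lipid(a, k)
#' @export
extrapolate_to_zero_lipid <- function(alpha_lb, keq_app) {
  if (length(alpha_lb) != length(keq_app)) {
    stop("`alpha_lb` and `keq_app` must have the same length", call. = FALSE)
  }
  if (length(alpha_lb) < 3L) {
    stop("at least 3 (alpha_lb, keq_app) points are required", call. = FALSE)
  }
  if (length(unique(alpha_lb)) < 3L) {
    stop("at least 3 distinct `alpha_lb` values are required", call. = FALSE)
  }
  if (any(!is.finite(alpha_lb)) || any(alpha_lb < 0) || any(alpha_lb >= 1)) {
    stop("`alpha_lb` values must lie in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(keq_app)) || any(keq_app <= 0)) {
    stop("`keq_app` values must be > 0", call. = FALSE)
  }

  # reciprocal linear route: 1/keq_app = 1/keq + (kp/keq) * alpha_lb
  lin <- stats::lm(I(1 / keq_app) ~ alpha_lb)
  intercept <- stats::coef(lin)[[1]]
  slope <- stats::coef(lin)[[2]]
  if (intercept > 0) {
    keq0 <- 1 / intercept
    kp0 <- max(slope * keq0, 0)
  } else {
    # noisy series can push the reciprocal intercept through zero; start
    # from the largest observed constant instead
    keq0 <- max(keq_app)
    kp0 <- 1 / max(alpha_lb)
  }

  df <- data.frame(alpha_lb = alpha_lb, log_keq_app = log(keq_app))
  fit <- minpack.lm::nlsLM(
    log_keq_app ~ log(keq) - log(1 + kp * alpha_lb),
    data = df,
    start = list(keq = keq0, kp = max(kp0, 1e-8)),
    lower = c(1e-300, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15)
  )
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) c(keq = NA_real_, kp = NA_real_)
  )
  structure(
    list(
      keq_lw = est[["keq"]],
      kp_lb_lw = est[["kp"]],
      stderr = c(keq_lw = se[["keq"]], kp_lb_lw = se[["kp"]]),
      linear = c(keq_lw = keq0, kp_lb_lw = kp0),
      fit = fit,
      residuals = stats::residuals(fit),
      rss = sum(stats::residuals(fit)^2)
    ),
    class = "lipid_extrapolation"
  )
}

#' @export
print.lipid_extrapolation <- function(x, ...) {
  cat("<lipid_extrapolation> keq_app = keq_lw / (1 + kp * alpha_lb)\n")
  cat(sprintf(
    "  keq_lw  = %.6g 1/M (se %.3g)\n  kp_lb_lw = %.6g (se %.3g)\n",
    x$keq_lw, x$stderr[["keq_lw"]], x$kp_lb_lw, x$stderr[["kp_lb_lw"]]
  ))
  cat(sprintf("  rss = %.6g on %d points\n", x$rss, length(x$residuals)))
  invisible(x)
}
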