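# Titration datasets, the two commonly used approximate binding models, and
# least-squares fitting of titration curves (full model or approximations).
#
# Model ids:
#   "full"          exact distribution; estimates the intrinsic keq_lw
#                   (requires kp_lb_lw and alpha_lb as known quantities)
#   "lipid_neglect" depletion-corrected single-site model that ignores the
#                   lipid bilayer; estimates an apparent keq_app_lw
#   "excess_ligand" hyperbola assuming ligand in large excess over protein;
#                   estimates an apparent keq_app_lt

#' Titration dataset
#'
#' A grid of total ligand concentrations with the observed response
#' (protein saturation fraction or bound ligand concentration), plus the
#' assay metadata needed to fit it.
#'
#' @param lt_values Strictly positive total ligand concentrations (M, per
#'   total volume); length >= 3.
#' @param observed Observed responses, same length as `lt_values`.
#'   Saturation responses must lie in `[0, 1]`.
#' @param response_kind `"saturation"` (default) or `"bound_concentration"`.
#' @param metadata Named list of assay parameters.  Recognized keys:
#'   `pt_molar`, `alpha_lb`, `mw_gmol`, `specific_volume`, `kp_lb_lw`, and
#'   (for synthetic data) `truth`, `sigma`, `seed`.
#' @return A data.frame of class `titration_dataset` with columns
#'   `lt_molar` and `response`; metadata stored in attributes
#'   `response_kind` and `metadata`.
#' @export
titration_dataset <- function(lt_values, observed,
                              response_kind = c(
                                "saturation",
                                "bound_concentration"
                              ),
                              metadata = list()) {
  response_kind <- match.arg(response_kind)
  if (length(lt_values) != length(observed)) {
    stop("`lt_values` and `observed` must have the same length", call. = FALSE)
  }
  if (length(lt_values) < 3L) {
    stop("a titration dataset needs at least 3 points", call. = FALSE)
  }
  if (any(!is.finite(lt_values)) || any(lt_values <= 0)) {
    stop("`lt_values` must be strictly positive and finite", call. = FALSE)
  }
  if (any(!is.finite(observed))) {
    stop("`observed` must be finite", call. = FALSE)
  }
  if (response_kind == "saturation" &&
    (any(observed < 0) || any(observed > 1))) {
    stop("saturation observations must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(lt_molar = as.numeric(lt_values), response = as.numeric(observed)),
    response_kind = response_kind,
    metadata = metadata,
    class = c("titration_dataset", "data.frame")
  )
}

#' Bound ligand predicted by the lipid-neglecting single-site model
#'
#' The depletion-corrected single-site model that accounts for ligand bound
#' to the protein but ignores the lipid bilayer: the free ligand is the
#' larger root of `K*LW^2 + (1 - K*(LT - PT))*LW - LT = 0` and the bound
#' ligand is `LP = LT - LW`.  Fitting this model to data generated in the
#' presence of a lipid phase yields an apparent, lipid-dependent constant.
#'
#' @param keq_app Apparent binding constant, 1/M (>= 0).
#' @param pt Total protein concentration, M per total volume (>= 0).
#' @param lt Total ligand concentration(s), M per total volume (>= 0);
#'   vectorized.
#' @return Bound ligand concentration(s) `LP` in M, with
#'   `0 <= LP <= min(LT, PT)`.
#' @examples
#' bound_lipid_neglect(1e6, pt = 1e-5, lt = 1e-5)
#' @export
bound_lipid_neglect <- function(keq_app, pt, lt) {
  .check_scalar(keq_app, "keq_app", nonneg = TRUE)
  .check_scalar(pt, "pt", nonneg = TRUE)
  stopifnot(is.numeric(lt), all(lt >= 0))
  parts <- .dist_dilute(keq_app, 0, lt, pt, 0, 1)
  parts$l_p
}

#' Bound ligand predicted by the excess-ligand hyperbola
#'
#' Assumes the ligand is in large excess over the protein so that the free
#' concentration equals the total: `LP = PT * K * LT / (1 + K * LT)`.  This
#' is the most commonly used — and, under ligand depletion, most biased —
#' analysis model.
#'
#' @inheritParams bound_lipid_neglect
#' @return Bound ligand concentration(s) `LP` in M.
#' @examples
#' bound_excess_ligand(1e6, pt = 1e-5, lt = 1e-6) # half-saturation: 5e-6 M
#' @export
bound_excess_ligand <- function(keq_app, pt, lt) {
  .check_scalar(keq_app, "keq_app", nonneg = TRUE)
  .check_scalar(pt, "pt", nonneg = TRUE)
  stopifnot(is.numeric(lt), all(lt >= 0))
  pt * keq_app * lt / (1 + keq_app * lt)
}

# Predicted response (on the dataset's response scale) for one model at
# binding constant k.  meta must carry pt_molar and, for "full", alpha_lb,
# kp_lb_lw and the protein volume fractions.
.predict_response <- function(k, lt, model, meta, response_kind) {
  l_p <- switch(model,
    full = .dist_general(
      k, meta$kp_lb_lw, lt, meta$pt_molar,
      meta$alpha_lb, meta$alpha_w
    )$l_p,
    lipid_neglect = .dist_dilute(k, 0, lt, meta$pt_molar, 0, 1)$l_p,
    excess_ligand = meta$pt_molar * k * lt / (1 + k * lt)
  )
  if (response_kind == "saturation") l_p / meta$pt_molar else l_p
}

#' Fit a titration dataset
#'
#' Least-squares estimation of the binding constant from a saturation (or
#' bound-concentration) titration, with the model of choice:
#'
#' * `"full"` — exact water/bilayer/protein distribution
#'   ([solve_general()]); the estimate is the *intrinsic* `keq_lw`.  The
#'   lipid parameters (`kp_lb_lw`, `alpha_lb`) and `pt_molar` must be known
#'   (dataset metadata or `fixed`).
#' * `"lipid_neglect"` — depletion-corrected single-site model without the
#'   lipid term ([bound_lipid_neglect()]); estimates `keq_app_lw`.
#' * `"excess_ligand"` — hyperbola ([bound_excess_ligand()]); estimates
#'   `keq_app_lt`.
#'
#' The optimisation runs in `log10(K)` to enforce positivity, initialized
#' at the half-saturation point of the data (`K0 = 1/LT` at the response
#' closest to half its maximum), with a 5-point log-spaced multistart
#' fallback.  Residuals are unweighted, on the observed response scale.
#'
#' @param dataset A [titration_dataset()] (or data.frame with columns
#'   `lt_molar`, `response`).
#' @param model One of `"full"`, `"lipid_neglect"`, `"excess_ligand"`.
#' @param fixed Named list overriding/supplying metadata:
#'   `pt_molar`, `alpha_lb`, `kp_lb_lw`, `mw_gmol`, `specific_volume`.
#' @return An object of class `affinity_fit`: list with `model_id`,
#'   `estimates` (named, 1/M), `stderr`, `residuals`, `rss`, `converged`,
#'   `n_iter`, `fitted`.
#' @examples
#' ds <- generate_titration(
#'   keq_lw = 1e6, kp_lb_lw = 1e3, alpha_lb = 0.01,
#'   protein_total = 1e-5, sigma = 0, seed = 1
#' )
#' fit_titration(ds, "full")
#' @export
fit_titration <- function(dataset,
                          model = c("full", "lipid_neglect", "excess_ligand"),
                          fixed = list()) {
  model <- match.arg(model)
  if (!is.data.frame(dataset) ||
    !all(c("lt_molar", "response") %in% names(dataset))) {
    stop("`dataset` must have columns `lt_molar` and `response`", call. = FALSE)
  }
  response_kind <- attr(dataset, "response_kind")
  if (is.null(response_kind)) response_kind <- "saturation"
  meta <- attr(dataset, "metadata")
  if (is.null(meta)) meta <- list()
  meta[names(fixed)] <- fixed

  if (is.null(meta$pt_molar)) {
    stop("`pt_molar` must be supplied (dataset metadata or `fixed`)",
      call. = FALSE
    )
  }
  if (model == "full") {
    if (is.null(meta$kp_lb_lw) || is.null(meta$alpha_lb)) {
      stop("the full model needs known `kp_lb_lw` and `alpha_lb`",
        call. = FALSE
      )
    }
    mw <- if (is.null(meta$mw_gmol)) 50000 else meta$mw_gmol
    sv <- if (is.null(meta$specific_volume)) 0.84 else meta$specific_volume
    prot <- protein_spec(mw, sv)
    meta$alpha_w <- 1 - meta$alpha_lb - meta$pt_molar * prot$molar_volume
    if (meta$alpha_w <= 0) stop("non-positive aqueous volume fraction", call. = FALSE)
  }

  lt <- dataset$lt_molar
  obs <- dataset$response
  if (stats::sd(obs) == 0) {
    stop("degenerate dataset: constant response carries no affinity information",
      call. = FALSE
    )
  }

  rss_of <- function(logk) {
    pred <- .predict_response(10^logk, lt, model, meta, response_kind)
    sum((obs - pred)^2)
  }

  # init from the half-saturation point of the observed response
  half <- max(obs) / 2
  k0 <- 1 / lt[which.min(abs(obs - half))]
  starts <- log10(k0)
  run <- function(start) {
    stats::optim(start, rss_of,
      method = "BFGS",
      control = list(reltol = 1e-14, maxit = 500)
    )
  }
  best <- run(starts)
  n_iter <- best$counts[["function"]]
  if (best$convergence != 0 || !is.finite(best$value)) {
    # multistart fallback spanning the concentration range of the data
    more <- seq(log10(1 / max(lt)) - 1, log10(1 / min(lt)) + 1, length.out = 5)
    fits <- lapply(more, function(s) tryCatch(run(s), error = function(e) NULL))
    fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
    if (length(fits)) {
      vals <- vapply(fits, `[[`, numeric(1), "value")
      cand <- fits[[which.min(vals)]]
      n_iter <- n_iter + sum(vapply(fits, function(f) f$counts[["function"]], numeric(1)))
      if (cand$value < best$value || best$convergence != 0) best <- cand
    }
  }
  # local 1-D polish: BFGS stops on rss stagnation, Brent refines the
  # parameter itself to ~1e-12 relative
  polish <- stats::optimize(rss_of,
    lower = best$par - 0.5, upper = best$par + 0.5, tol = 1e-12
  )
  if (polish$objective <= best$value) {
    best$par <- polish$minimum
    best$value <- polish$objective
  }
  k_hat <- 10^best$par
  pred <- .predict_response(k_hat, lt, model, meta, response_kind)
  res <- obs - pred
  rss <- sum(res^2)

  # delta-method standard error on the natural K scale from a central-
  # difference jacobian of the predicted response
  h <- k_hat * 1e-5
  jac <- (.predict_response(k_hat + h, lt, model, meta, response_kind) -
    .predict_response(k_hat - h, lt, model, meta, response_kind)) / (2 * h)
  jtj <- sum(jac^2)
  dof <- max(length(lt) - 1L, 1L)
  se <- if (jtj > 0) sqrt(rss / dof / jtj) else NA_real_

  est_name <- switch(model,
    full = "keq_lw",
    lipid_neglect = "keq_app_lw",
    excess_ligand = "keq_app_lt"
  )
  structure(
    list(
      model_id = model,
      estimates = stats::setNames(k_hat, est_name),
      stderr = stats::setNames(se, est_name),
      residuals = res,
      fitted = pred,
      rss = rss,
      converged = best$convergence == 0,
      n_iter = as.integer(n_iter),
      response_kind = response_kind
    ),
    class = "affinity_fit"
  )
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat(sprintf("<affinity_fit> model = %s\n", x$model_id))
  cat(sprintf(
    "  %s = %.6g 1/M (se %.3g)\n",
    names(x$estimates)[1], x$estimates[1], x$stderr[1]
  ))
  cat(sprintf(
    "  rss = %.6g on %d points; converged: %s (%d evaluations)\n",
    x$rss, length(x$residuals), x$converged, x$n_iter
  ))
  invisible(x)
}
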