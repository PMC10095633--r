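# Exact equilibrium distribution of ligand among water, lipid bilayer and a
# single-site protein.  Two solvers:
#   - dilute:  quadratic in LW (per total volume), valid for alpha_w >= 0.99
#   - general: quadratic in the LOCAL aqueous concentration cW = nW/VW, exact
#              volume bookkeeping for any composition with alpha_w > 0

# Larger root of a*x^2 + b*x + c = 0 with a >= 0, c <= 0 (so the equation has
# exactly one non-negative root).  Cancellation-safe: when b > 0 the root is
# computed as -2c / (b + sqrt(disc)).  Vectorized.
.quad_pos_root <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  c <- rep_len(c, n)
  root <- numeric(n)
  lin <- a == 0
  root[lin] <- ifelse(c[lin] == 0, 0, -c[lin] / b[lin])
  q <- !lin
  if (any(q)) {
    disc <- b[q]^2 - 4 * a[q] * c[q]
    if (any(disc < 0)) {
      stop("internal error: negative discriminant in equilibrium quadratic",
        call. = FALSE
      )
    }
    sq <- sqrt(disc)
    root[q] <- ifelse(b[q] <= 0,
      (-b[q] + sq) / (2 * a[q]),
      -2 * c[q] / (b[q] + sq)
    )
  }
  root
}

# Vectorized (over lt) dilute-regime distribution.  Returns per-total-volume
# amounts.  LW solves Keq*(1+r)*LW^2 + (1+r - Keq*(LT-PT))*LW - LT = 0 with
# r = KP * V_Lb / V_W; the physical root is always the larger one.
.dist_dilute <- function(keq_lw, kp_lb_lw, lt, pt, alpha_lb, alpha_w) {
  r <- kp_lb_lw * alpha_lb / alpha_w
  if (keq_lw == 0 || pt == 0) {
    l_w <- lt / (1 + r)
  } else {
    a <- keq_lw * (1 + r)
    b <- (1 + r) - keq_lw * (lt - pt)
    l_w <- .quad_pos_root(a, b, -lt)
  }
  l_lb <- l_w * r
  l_p <- pmax(lt - l_w - l_lb, 0)
  list(l_w = l_w, l_lb = l_lb, l_p = l_p)
}

# Vectorized exact distribution for arbitrary composition.  The local aqueous
# concentration cW = nW/VW drives both the lipid partition
# (nLb = KP * cW * VLb) and the binding step (LP / (P * cW) = Keq), so with
# A = alpha_w + KP * alpha_lb the mass balance is
#   A*Keq*cW^2 + (A + Keq*(PT - LT))*cW - LT = 0.
.dist_general <- function(keq_lw, kp_lb_lw, lt, pt, alpha_lb, alpha_w) {
  a_eff <- alpha_w + kp_lb_lw * alpha_lb
  if (keq_lw == 0 || pt == 0) {
    c_w <- lt / a_eff
  } else {
    a <- a_eff * keq_lw
    b <- a_eff + keq_lw * (pt - lt)
    c_w <- .quad_pos_root(a, b, -lt)
  }
  l_w <- c_w * alpha_w
  l_lb <- kp_lb_lw * c_w * alpha_lb
  l_p <- pmax(lt - l_w - l_lb, 0)
  list(l_w = l_w, l_lb = l_lb, l_p = l_p)
}

.distribution_result <- function(parts, lt, pt, regime) {
  f <- function(x) ifelse(lt > 0, x / lt, 0)
  structure(
    list(
      l_w = parts$l_w,
      l_lb = parts$l_lb,
      l_p = parts$l_p,
      p_free = pt - parts$l_p,
      f_w = f(parts$l_w),
      f_lb = f(parts$l_lb),
      f_p = f(parts$l_p),
      saturation = if (pt > 0) parts$l_p / pt else 0 * parts$l_p,
      ligand_total = lt,
      protein_total = pt,
      regime = regime
    ),
    class = "ligand_distribution"
  )
}

#' @export
print.ligand_distribution <- function(x, ...) {
  cat(sprintf("<ligand_distribution> (%s regime)\n", x$regime))
  cat(sprintf(
    "  L_W = %.6g M (f = %.4g)  L_Lb = %.6g M (f = %.4g)  L_P = %.6g M (f = %.4g)\n",
    x$l_w[1], x$f_w[1], x$l_lb[1], x$f_lb[1], x$l_p[1], x$f_p[1]
  ))
  cat(sprintf(
    "  free protein = %.6g M, saturation = %.4g\n",
    x$p_free[1], x$saturation[1]
  ))
  invisible(x)
}

#' @export
as.data.frame.ligand_distribution <- function(x, ...) {
  data.frame(
    lt_molar = x$ligand_total,
    l_w_molar = x$l_w,
    l_lb_molar = x$l_lb,
    l_p_molar = x$l_p,
    p_free_molar = x$p_free,
    f_w = x$f_w,
    f_lb = x$f_lb,
    f_p = x$f_p,
    saturation = x$saturation
  )
}

#' Equilibrium ligand distribution, dilute-regime analytical solution
#'
#' Solves the mass balance for the free aqueous ligand concentration as the
#' physically meaningful (larger) root of a quadratic and distributes the
#' remaining ligand between the lipid bilayer (partition, non-saturable) and
#' the protein's single site (binding, saturable).  All concentrations are
#' per total volume.  Valid in dilute media; a warning is emitted when
#' `alpha_w < 0.99`, where [solve_general()] should be preferred.
#'
#' @param keq_lw Intrinsic binding constant from water, 1/M (>= 0).
#' @param kp_lb_lw Water -> bilayer partition coefficient (dimensionless
#'   local-concentration ratio, >= 0).
#' @param composition A [system_composition()].
#' @return An object of class `ligand_distribution` with per-total-volume
#'   amounts `l_w`, `l_lb`, `l_p`, `p_free` (M), the ligand fractions `f_w`,
#'   `f_lb`, `f_p`, and the protein `saturation` `= l_p / protein_total`.
#'   Mass and protein conservation hold to better than 1e-10 relative.
#' @examples
#' comp <- system_composition(
#'   ligand_total = 1e-5, protein_total = 1e-5,
#'   alpha_lb = 0.01
#' )
#' solve_dilute(keq_lw = 1e6, kp_lb_lw = 1e3, comp)
#' @seealso [solve_general()] for concentrated media, [saturation_curve()].
#' @export
solve_dilute <- function(keq_lw, kp_lb_lw, composition) {
  .check_scalar(keq_lw, "keq_lw", nonneg = TRUE)
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  stopifnot(inherits(composition, "system_composition"))
  if (composition$alpha_w < 0.99) {
    warning(sprintf(
      "dilute-regime solution requested with alpha_w = %.4g < 0.99; consider solve_general()",
      composition$alpha_w
    ), call. = FALSE)
  }
  parts <- .dist_dilute(
    keq_lw, kp_lb_lw,
    composition$ligand_total, composition$protein_total,
    composition$alpha_lb, composition$alpha_w
  )
  .distribution_result(
    parts, composition$ligand_total,
    composition$protein_total, "dilute"
  )
}

#' Equilibrium ligand distribution, exact for any composition
#'
#' Exact volume bookkeeping: the local aqueous concentration
#' `cW = nW / VW` enters both the lipid partition (`nLb = KP * cW * VLb`)
#' and the binding step (`LP / (P * cW) = KeqLW`).  Reduces to
#' [solve_dilute()] within 0.1% whenever `alpha_lb + alpha_p <= 0.01`.
#' Unlike the dilute approximation, it captures the exclusion effect: a
#' ligand with `kp_lb_lw < 1` is concentrated in the aqueous phase by the
#' presence of the bilayer, *increasing* protein saturation.
#'
#' @inheritParams solve_dilute
#' @inherit solve_dilute return
#' @examples
#' comp <- system_composition(
#'   ligand_total = 1e-6, protein_total = 1e-6,
#'   alpha_lb = 0.10
#' )
#' solve_general(keq_lw = 1e6, kp_lb_lw = 0.1, comp)
#' @export
solve_general <- function(keq_lw, kp_lb_lw, composition) {
  .check_scalar(keq_lw, "keq_lw", nonneg = TRUE)
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  stopifnot(inherits(composition, "system_composition"))
  parts <- .dist_general(
    keq_lw, kp_lb_lw,
    composition$ligand_total, composition$protein_total,
    composition$alpha_lb, composition$alpha_w
  )
  .distribution_result(
    parts, composition$ligand_total,
    composition$protein_total, "general"
  )
}

#' Protein saturation as a function of total ligand
#'
#' Solves the equilibrium distribution along a grid of total ligand
#' concentrations at fixed composition, returning the saturation binding
#' curve.  Saturation is non-decreasing in the total ligand concentration.
#'
#' @inheritParams solve_dilute
#' @param composition A [system_composition()]; its `ligand_total` is
#'   ignored and replaced by each grid value in turn.
#' @param lt_grid Strictly positive, sorted vector of total ligand
#'   concentrations (M, per total volume).
#' @param solver `"general"` (exact, default) or `"dilute"`.
#' @return A data.frame with columns `lt_molar`, `l_w_molar`, `l_lb_molar`,
#'   `l_p_molar`, `f_w`, `f_lb`, `saturation`.
#' @examples
#' comp <- system_composition(1e-6, protein_total = 1e-5, alpha_lb = 0.01)
#' saturation_curve(1e6, 1e3, comp, lt_grid = 10^seq(-8, -3, length.out = 9))
#' @export
saturation_curve <- function(keq_lw, kp_lb_lw, composition, lt_grid,
                             solver = c("general", "dilute")) {
  solver <- match.arg(solver)
  .check_scalar(keq_lw, "keq_lw", nonneg = TRUE)
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  stopifnot(inherits(composition, "system_composition"))
  if (length(lt_grid) < 1L) stop("`lt_grid` must be non-empty", call. = FALSE)
  if (any(!is.finite(lt_grid)) || any(lt_grid <= 0)) {
    stop("`lt_grid` must be strictly positive and finite", call. = FALSE)
  }
  if (is.unsorted(lt_grid, strictly = FALSE)) {
    stop("`lt_grid` must be sorted increasingly", call. = FALSE)
  }
  fun <- if (solver == "general") .dist_general else .dist_dilute
  parts <- fun(
    keq_lw, kp_lb_lw, lt_grid, composition$protein_total,
    composition$alpha_lb, composition$alpha_w
  )
  pt <- composition$protein_total
  data.frame(
    lt_molar = lt_grid,
    l_w_molar = parts$l_w,
    l_lb_molar = parts$l_lb,
    l_p_molar = parts$l_p,
    f_w = ifelse(lt_grid > 0, parts$l_w / lt_grid, 0),
    f_lb = ifelse(lt_grid > 0, parts$l_lb / lt_grid, 0),
    saturation = if (pt > 0) parts$l_p / pt else 0 * lt_grid
  )
}
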