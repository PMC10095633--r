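# Independent oracles: scalar mass-balance residuals solved by bisection
# (stats::uniroot), kept separate from the analytical quadratic route they
# validate.

# Free aqueous ligand (per total volume) under the dilute-regime model:
# LT = LW * (1 + KP*VLb/VW) + Keq*LW*PT / (1 + Keq*LW)
bisect_lw_dilute <- function(keq, kp, lt, pt, alpha_lb, alpha_w) {
  if (lt == 0) {
    return(0)
  }
  r <- kp * alpha_lb / alpha_w
  f <- function(lw) lw * (1 + r) + keq * lw * pt / (1 + keq * lw) - lt
  stats::uniroot(f, c(0, lt), tol = lt * 1e-13)$root
}

# Local aqueous concentration under exact volume bookkeeping:
# LT = cW * (alpha_w + KP*alpha_lb) + Keq*cW*PT / (1 + Keq*cW)
bisect_cw_general <- function(keq, kp, lt, pt, alpha_lb, alpha_w) {
  if (lt == 0) {
    return(0)
  }
  a_eff <- alpha_w + kp * alpha_lb
  f <- function(cw) cw * a_eff + keq * cw * pt / (1 + keq * cw) - lt
  upper <- lt / min(a_eff, 1)
  stats::uniroot(f, c(0, upper), tol = upper * 1e-13)$root
}

# noiseless saturation dataset from the exact solver, for fit tests
make_clean_dataset <- function(keq, kp, alpha_lb, pt, mw = 50000, n = 20,
                               lt_range = c(0.01, 100) / keq) {
  generate_titration(
    keq_lw = keq, kp_lb_lw = kp, alpha_lb = alpha_lb,
    protein_total = pt, protein = protein_spec(mw),
    n_points = n, lt_range = lt_range, sigma = 0, seed = 1
  )
}
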