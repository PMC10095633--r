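# Unit conventions and thermodynamic-cycle relations among binding
# constants and partition coefficients.
#
# Conventions (documented per argument throughout):
#   - concentrations: mol / L of TOTAL system volume
#   - partition coefficients: ratios of LOCAL (per-phase) concentrations
#   - binding constants: 1/M; molar volumes: L/mol

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' Molar volume of a protein
#'
#' Converts a molecular weight and a partial specific volume into the volume
#' occupied by one mole of protein.  The molar volume is what links a
#' dimensionless water/protein partition coefficient to a molar binding
#' constant (see [keq_from_partition()]).
#'
#' @param molecular_weight Molecular weight in g/mol. Must be > 0.
#' @param specific_volume Partial specific volume in mL/g.  The default,
#'   0.84 mL/g, reproduces the convention that 10 uM of a 50 kDa protein
#'   occupies a volume fraction of 4.2e-4.  Must be > 0.
#' @return Molar volume in L/mol.
#' @examples
#' molar_volume(50000)        # 42 L/mol
#' molar_volume(66000, 0.84)  # 55.44 L/mol
#' @export
molar_volume <- function(molecular_weight, specific_volume = 0.84) {
  .check_scalar(molecular_weight, "molecular_weight", positive = TRUE)
  .check_scalar(specific_volume, "specific_volume", positive = TRUE)
  molecular_weight * specific_volume / 1000
}

#' Protein specification
#'
#' A single-binding-site protein described by its molecular weight and
#' partial specific volume; the derived molar volume converts protein
#' partition coefficients to molar binding constants and protein molar
#' concentrations to volume fractions.
#'
#' @inheritParams molar_volume
#' @return An object of class `protein_spec` with fields `molecular_weight`
#'   (g/mol), `specific_volume` (mL/g), `molar_volume` (L/mol) and `n_sites`
#'   (fixed at 1).
#' @examples
#' protein_spec(50000)
#' @export
protein_spec <- function(molecular_weight, specific_volume = 0.84) {
  structure(
    list(
      molecular_weight = molecular_weight,
      specific_volume = specific_volume,
      molar_volume = molar_volume(molecular_weight, specific_volume),
      n_sites = 1L
    ),
    class = "protein_spec"
  )
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf(
    "<protein_spec> MW = %g g/mol, specific volume = %g mL/g, molar volume = %g L/mol, 1 site\n",
    x$molecular_weight, x$specific_volume, x$molar_volume
  ))
  invisible(x)
}

#' Convert between a protein partition coefficient and a binding constant
#'
#' A dimensionless ligand partition coefficient between a medium X and the
#' protein relates to the molar binding constant from X through the molar
#' volume of the protein: `Keq = KP * Vbar_P`.  `partition_from_keq()` is the
#' exact inverse.
#'
#' @param kp_p_lx Dimensionless partition coefficient of the ligand between
#'   medium X (water or lipid bilayer) and the protein; ratio of local
#'   concentrations. Must be >= 0.
#' @param molar_volume Molar volume of the protein in L/mol (> 0); see
#'   [molar_volume()].
#' @return `keq_from_partition()`: binding constant in 1/M;
#'   `partition_from_keq()`: dimensionless partition coefficient.
#' @examples
#' keq_from_partition(23809.52, 42)   # ~1e6 1/M
#' partition_from_keq(1e6, 42)
#' @export
keq_from_partition <- function(kp_p_lx, molar_volume) {
  .check_scalar(kp_p_lx, "kp_p_lx", nonneg = TRUE)
  .check_scalar(molar_volume, "molar_volume", positive = TRUE)
  kp_p_lx * molar_volume
}

#' @param keq_lx Binding constant in 1/M (>= 0).
#' @rdname keq_from_partition
#' @export
partition_from_keq <- function(keq_lx, molar_volume) {
  .check_scalar(keq_lx, "keq_lx", nonneg = TRUE)
  .check_scalar(molar_volume, "molar_volume", positive = TRUE)
  keq_lx / molar_volume
}

#' Complete the thermodynamic cycle of partition coefficients
#'
#' The three ligand equilibria (water/bilayer, water/protein,
#' bilayer/protein) form a closed cycle, so micro-reversibility fixes
#' `kp_p_lw = kp_lb_lw * kp_p_lb`.  Given any two of the three coefficients,
#' the third is determined even when it does not correspond to a physically
#' followed path.
#'
#' @param kp_lb_lw Water -> lipid-bilayer partition coefficient
#'   (dimensionless local-concentration ratio; the ligand's lipophilicity).
#' @param kp_p_lw Water -> protein partition coefficient (dimensionless).
#' @param kp_p_lb Lipid-bilayer -> protein partition coefficient
#'   (dimensionless).
#' @return A named list with all three coefficients filled in.
#' @examples
#' close_cycle(kp_lb_lw = 1e3, kp_p_lb = 23.81)  # kp_p_lw = 2.381e4
#' @export
close_cycle <- function(kp_lb_lw = NULL, kp_p_lw = NULL, kp_p_lb = NULL) {
  known <- !c(
    kp_lb_lw = is.null(kp_lb_lw),
    kp_p_lw = is.null(kp_p_lw),
    kp_p_lb = is.null(kp_p_lb)
  )
  if (sum(known) != 2L) {
    stop("exactly two of `kp_lb_lw`, `kp_p_lw`, `kp_p_lb` must be supplied",
      call. = FALSE
    )
  }
  for (nm in names(known)[known]) .check_scalar(get(nm), nm, nonneg = TRUE)
  div0 <- function(num, den, den_name) {
    if (den == 0) {
      stop(sprintf("cannot close the cycle: division by zero `%s`", den_name),
        call. = FALSE
      )
    }
    num / den
  }
  if (is.null(kp_p_lw)) {
    kp_p_lw <- kp_lb_lw * kp_p_lb
  } else if (is.null(kp_p_lb)) {
    kp_p_lb <- div0(kp_p_lw, kp_lb_lw, "kp_lb_lw")
  } else {
    kp_lb_lw <- div0(kp_p_lw, kp_p_lb, "kp_p_lb")
  }
  list(kp_lb_lw = kp_lb_lw, kp_p_lw = kp_p_lw, kp_p_lb = kp_p_lb)
}

#' Overall ligand partition coefficient towards a protein-containing membrane
#'
#' For a membrane protein the experimentally accessible quantities are the
#' partition towards the protein-free bilayer and the partition towards the
#' whole membrane (bilayer + protein).  The whole-membrane coefficient is the
#' volume-weighted average of the two component coefficients; the protein
#' term cannot be neglected even for dilute protein, because the volume is
#' multiplied by a (possibly very large) partition coefficient.
#'
#' @inheritParams close_cycle
#' @param v_lb Volume of the lipid bilayer (any volume unit, consistent with
#'   `v_p`); >= 0.
#' @param v_p Volume of the protein in the membrane (same unit as `v_lb`);
#'   >= 0.  `v_lb + v_p` must be > 0.
#' @return Dimensionless water -> membrane partition coefficient.
#' @examples
#' membrane_partition(kp_lb_lw = 1e3, kp_p_lw = 2.381e4, v_lb = 0.99, v_p = 0.01)
#' @export
membrane_partition <- function(kp_lb_lw, kp_p_lw, v_lb, v_p) {
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  .check_scalar(kp_p_lw, "kp_p_lw", nonneg = TRUE)
  .check_scalar(v_lb, "v_lb", nonneg = TRUE)
  .check_scalar(v_p, "v_p", nonneg = TRUE)
  v_m <- v_lb + v_p
  if (v_m <= 0) stop("`v_lb + v_p` must be > 0", call. = FALSE)
  kp_lb_lw * v_lb / v_m + kp_p_lw * v_p / v_m
}

#' @description `invert_membrane_partition()` solves the same relation for
#' the water -> protein coefficient given the whole-membrane and bilayer
#' coefficients, the workflow used to extract intrinsic affinities for
#' membrane proteins.
#' @param kp_m_lw Water -> whole-membrane partition coefficient
#'   (dimensionless); must be at least `kp_lb_lw * v_lb / (v_lb + v_p)`,
#'   otherwise the implied protein coefficient would be negative.
#' @rdname membrane_partition
#' @export
invert_membrane_partition <- function(kp_m_lw, kp_lb_lw, v_lb, v_p) {
  .check_scalar(kp_m_lw, "kp_m_lw", nonneg = TRUE)
  .check_scalar(kp_lb_lw, "kp_lb_lw", nonneg = TRUE)
  .check_scalar(v_lb, "v_lb", nonneg = TRUE)
  .check_scalar(v_p, "v_p", positive = TRUE)
  v_m <- v_lb + v_p
  kp_p_lw <- (kp_m_lw * v_m - kp_lb_lw * v_lb) / v_p
  if (kp_p_lw < 0) {
    stop(sprintf(
      paste0(
        "inconsistent inputs: kp_m_lw = %g is below the bilayer-only bound ",
        "kp_lb_lw * v_lb / (v_lb + v_p) = %g, implying a negative protein ",
        "partition coefficient"
      ),
      kp_m_lw, kp_lb_lw * v_lb / v_m
    ), call. = FALSE)
  }
  kp_p_lw
}

#' Affinity set joined by cycle closure
#'
#' Bundles the three partition coefficients, the intrinsic binding constant
#' and (optionally) the whole-membrane coefficient, validating
#' micro-reversibility (`kp_p_lw = kp_lb_lw * kp_p_lb`, relative tolerance
#' 1e-12) and, when a protein is attached, the constant/coefficient
#' correspondence `keq_lw = kp_p_lw * molar_volume`.
#'
#' @inheritParams close_cycle
#' @param keq_lw Intrinsic binding constant from water, 1/M.  Derived from
#'   `kp_p_lw` when a `protein` is given and `keq_lw` is missing.
#' @param kp_m_lw Optional water -> whole-membrane coefficient.
#' @param protein Optional [protein_spec()] used to interconvert `keq_lw`
#'   and `kp_p_lw`.
#' @return An object of class `affinity_set`.
#' @examples
#' affinity_set(kp_lb_lw = 1e3, kp_p_lb = 23.81, protein = protein_spec(50000))
#' @export
affinity_set <- function(kp_lb_lw = NULL, kp_p_lw = NULL, kp_p_lb = NULL,
                         keq_lw = NULL, kp_m_lw = NULL, protein = NULL) {
  if (!is.null(keq_lw) && is.null(kp_p_lw) && !is.null(protein)) {
    kp_p_lw <- partition_from_keq(keq_lw, protein$molar_volume)
  }
  n_known <- sum(!vapply(
    list(kp_lb_lw, kp_p_lw, kp_p_lb), is.null,
    logical(1)
  ))
  if (n_known == 2L) {
    cyc <- close_cycle(kp_lb_lw = kp_lb_lw, kp_p_lw = kp_p_lw, kp_p_lb = kp_p_lb)
  } else if (n_known == 3L) {
    cyc <- list(kp_lb_lw = kp_lb_lw, kp_p_lw = kp_p_lw, kp_p_lb = kp_p_lb)
    gap <- abs(cyc$kp_p_lw - cyc$kp_lb_lw * cyc$kp_p_lb)
    if (gap > 1e-12 * max(cyc$kp_p_lw, cyc$kp_lb_lw * cyc$kp_p_lb, 1e-300)) {
      stop("cycle closure violated: kp_p_lw != kp_lb_lw * kp_p_lb",
        call. = FALSE
      )
    }
  } else {
    stop("supply two or three of `kp_lb_lw`, `kp_p_lw`, `kp_p_lb`",
      call. = FALSE
    )
  }
  if (!is.null(protein)) {
    keq_cons <- keq_from_partition(cyc$kp_p_lw, protein$molar_volume)
    if (!is.null(keq_lw) &&
      abs(keq_lw - keq_cons) > 1e-12 * max(keq_lw, keq_cons, 1e-300)) {
      stop("`keq_lw` inconsistent with `kp_p_lw * molar_volume`",
        call. = FALSE
      )
    }
    keq_lw <- keq_cons
  }
  structure(
    c(cyc, list(keq_lw = keq_lw, kp_m_lw = kp_m_lw, protein = protein)),
    class = "affinity_set"
  )
}

#' @export
print.affinity_set <- function(x, ...) {
  cat("<affinity_set>\n")
  cat(sprintf("  kp_lb_lw (water->bilayer, dimensionless): %g\n", x$kp_lb_lw))
  cat(sprintf("  kp_p_lw  (water->protein, dimensionless): %g\n", x$kp_p_lw))
  cat(sprintf("  kp_p_lb  (bilayer->protein, dimensionless): %g\n", x$kp_p_lb))
  if (!is.null(x$keq_lw)) {
    cat(sprintf("  keq_lw   (intrinsic binding constant, 1/M): %g\n", x$keq_lw))
  }
  if (!is.null(x$kp_m_lw)) {
    cat(sprintf("  kp_m_lw  (water->membrane, dimensionless): %g\n", x$kp_m_lw))
  }
  invisible(x)
}

#' Serialize an affinity set to JSON with explicit unit tags
#'
#' @param x An [affinity_set()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return A JSON string (invisibly, when `path` is given).
#' @export
affinity_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "affinity_set"))
  tagged <- list(
    kp_lb_lw = list(value = x$kp_lb_lw, unit = "dimensionless"),
    kp_p_lw = list(value = x$kp_p_lw, unit = "dimensionless"),
    kp_p_lb = list(value = x$kp_p_lb, unit = "dimensionless")
  )
  if (!is.null(x$keq_lw)) {
    tagged$keq_lw <- list(value = x$keq_lw, unit = "per_molar")
  }
  if (!is.null(x$kp_m_lw)) {
    tagged$kp_m_lw <- list(value = x$kp_m_lw, unit = "dimensionless")
  }
  if (!is.null(x$protein)) {
    tagged$molar_volume <- list(
      value = x$protein$molar_volume,
      unit = "L_per_mol"
    )
  }
  json <- jsonlite::toJSON(tagged, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(json)
}

#' System composition for one assay condition
#'
#' Describes one equilibrium condition: total ligand and protein
#' concentrations (moles per litre of total volume) and the volume fractions
#' of the lipid bilayer, the protein and the aqueous medium.
#'
#' @param ligand_total Total ligand concentration LT, mol per L of total
#'   volume; >= 0.
#' @param protein_total Total protein concentration PT, mol per L of total
#'   volume; >= 0.
#' @param alpha_lb Volume fraction of the lipid bilayer, `V_Lb / V_T`;
#'   in `[0, 1)`.
#' @param protein A [protein_spec()]; its molar volume converts
#'   `protein_total` into the protein volume fraction.  Defaults to a
#'   medium-size 50 kDa protein.
#' @param total_volume Total system volume in L (bookkeeping only; all
#'   concentrations are already per total volume). Default 1.
#' @return An object of class `system_composition` with fields
#'   `ligand_total`, `protein_total`, `alpha_lb`, `alpha_p`
#'   (= `protein_total * molar_volume`), `alpha_w`
#'   (= `1 - alpha_lb - alpha_p`, must stay > 0), `protein`, `total_volume`.
#' @examples
#' system_composition(
#'   ligand_total = 1e-5, protein_total = 1e-5,
#'   alpha_lb = 0.01, protein = protein_spec(50000)
#' )
#' @export
system_composition <- function(ligand_total, protein_total = 0, alpha_lb = 0,
                               protein = protein_spec(50000),
                               total_volume = 1) {
  .check_scalar(ligand_total, "ligand_total", nonneg = TRUE)
  .check_scalar(protein_total, "protein_total", nonneg = TRUE)
  .check_scalar(alpha_lb, "alpha_lb", nonneg = TRUE)
  .check_scalar(total_volume, "total_volume", positive = TRUE)
  stopifnot(inherits(protein, "protein_spec"))
  if (alpha_lb >= 1) stop("`alpha_lb` must be < 1", call. = FALSE)
  alpha_p <- protein_total * protein$molar_volume
  if (alpha_p >= 1) stop("protein volume fraction must be < 1", call. = FALSE)
  alpha_w <- 1 - alpha_lb - alpha_p
  if (alpha_w <= 0) {
    stop("aqueous volume fraction `alpha_w = 1 - alpha_lb - alpha_p` must be > 0",
      call. = FALSE
    )
  }
  structure(
    list(
      ligand_total = ligand_total,
      protein_total = protein_total,
      alpha_lb = alpha_lb,
      alpha_p = alpha_p,
      alpha_w = alpha_w,
      protein = protein,
      total_volume = total_volume
    ),
    class = "system_composition"
  )
}

#' @export
print.system_composition <- function(x, ...) {
  cat("<system_composition>\n")
  cat(sprintf("  ligand_total  LT: %g M (per total volume)\n", x$ligand_total))
  cat(sprintf("  protein_total PT: %g M (per total volume)\n", x$protein_total))
  cat(sprintf(
    "  volume fractions: alpha_lb = %g, alpha_p = %g, alpha_w = %g\n",
    x$alpha_lb, x$alpha_p, x$alpha_w
  ))
  invisible(x)
}
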