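#' Titration series container for one-site ITC
#'
#' Describes the injection protocol of an isothermal titration calorimetry
#' experiment: macromolecule in the cell, ligand in the syringe, a list of
#' injection volumes, and (optionally) per-injection heats. Defaults match
#' the experiment modelled throughout the package: a 200 ul cell at 25 uM
#' titrated with 19 x 2 ul injections of 150 uM ligand.
#'
#' @param cell_volume_ul Cell volume V0 in microliters.
#' @param cell_conc_uM Initial macromolecule concentration in the cell (uM).
#' @param syringe_conc_uM Ligand concentration in the syringe (uM).
#' @param injection_volumes_ul Per-injection volumes in microliters.
#' @param heats_ucal Optional per-injection heats in microcalories (same
#'   length as `injection_volumes_ul`).
#' @return An object of class `nap_titration` with an `$injections` tibble.
#' @export
titration_series <- function(cell_volume_ul = 200, cell_conc_uM = 25,
                             syringe_conc_uM = 150,
                             injection_volumes_ul = rep(2, 19),
                             heats_ucal = NULL) {
  stopifnot(cell_volume_ul > 0, cell_conc_uM > 0, syringe_conc_uM > 0,
            all(injection_volumes_ul > 0))
  n_inj <- length(injection_volumes_ul)
  if (!is.null(heats_ucal) && length(heats_ucal) != n_inj) {
    abort("heats_ucal must match the number of injections")
  }
  structure(
    list(
      cell_volume_ul = cell_volume_ul,
      cell_conc_uM = cell_conc_uM,
      syringe_conc_uM = syringe_conc_uM,
      injections = tibble(
        injection = seq_len(n_inj),
        volume_ul = as.numeric(injection_volumes_ul),
        heat_ucal = if (is.null(heats_ucal)) NA_real_ else
          as.numeric(heats_ucal)
      )
    ),
    class = "nap_titration"
  )
}

#' @export
print.nap_titration <- function(x, ...) {
  cat("ITC titration: ", x$cell_volume_ul, " ul cell at ", x$cell_conc_uM,
      " uM, syringe ", x$syringe_conc_uM, " uM, ",
      nrow(x$injections), " injections\n", sep = "")
  invisible(x)
}

#' One-site binding parameters
#'
#' Stoichiometry `n` (sites per macromolecule), dissociation constant and
#' binding enthalpy, with free energy and entropy derived at the stated
#' temperature: `dG = RT ln(Kd)`, `dS = (dH - dG) / T`.
#'
#' @param n Sites per macromolecule.
#' @param kd_nM Dissociation constant in nM.
#' @param dH_kcal Binding enthalpy in kcal/mol.
#' @param temperature_C Temperature in degrees Celsius (default 25).
#' @return An object of class `nap_one_site_params`.
#' @export
one_site_params <- function(n, kd_nM, dH_kcal, temperature_C = 25) {
  stopifnot(n > 0, kd_nM > 0)
  T_K <- temperature_C + 273.15
  R <- 1.98720425864083e-3  # kcal / (mol K)
  dG <- R * T_K * log(kd_nM * 1e-9)
  structure(
    list(n = n, kd_nM = kd_nM, dH_kcal = dH_kcal,
         dG_kcal = dG, dS_cal = 1000 * (dH_kcal - dG) / T_K,
         temperature_C = temperature_C),
    class = "nap_one_site_params"
  )
}

#' @export
print.nap_one_site_params <- function(x, ...) {
  cat(sprintf(
    "One-site model: n = %.3f, Kd = %.1f nM, dH = %.2f kcal/mol (dG = %.2f, -TdS = %.2f)\n",
    x$n, x$kd_nM, x$dH_kcal, x$dG_kcal, x$dG_kcal - x$dH_kcal
  ))
  invisible(x)
}

# Bound-site fraction Theta from the one-site quadratic
#   Theta^2 - Theta (1 + X/(n M) + Kd/(n M)) + X/(n M) = 0
# taking the root in [0, 1]. All concentrations in uM.
one_site_theta <- function(Mt, Xt, n, kd_uM) {
  r <- Xt / (n * Mt)
  k <- kd_uM / (n * Mt)
  b <- 1 + r + k
  disc <- b^2 - 4 * r
  if (any(disc < 0)) abort("one-site quadratic has no real root")
  theta <- (b - sqrt(disc)) / 2
  if (any(theta < -1e-9 | theta > 1 + 1e-9)) {
    abort("one-site quadratic root outside [0, 1]")
  }
  pmin(pmax(theta, 0), 1)
}

# Cell concentrations after each injection under discrete displacement:
# injecting dv displaces cell content, M -> M (1 - dv/V0),
# X -> X (1 - dv/V0) + Xs dv/V0. Returns per-injection Mt, Xt (uM).
titration_concentrations <- function(series) {
  V0 <- series$cell_volume_ul
  dv <- series$injections$volume_ul
  Mt <- numeric(length(dv))
  Xt <- numeric(length(dv))
  m <- series$cell_conc_uM
  x <- 0
  for (i in seq_along(dv)) {
    f <- 1 - dv[i] / V0
    m <- m * f
    x <- x * f + series$syringe_conc_uM * dv[i] / V0
    Mt[i] <- m
    Xt[i] <- x
  }
  list(Mt = Mt, Xt = Xt)
}

# Forward model: per-injection heats (ucal) for a one-site isotherm.
# Cumulative heat after injection i is Q_i = n Theta_i Mt_i dH V0 and the
# observed injection heat carries the mid-point volume-displacement
# correction dq_i = Q_i - Q_{i-1} + (dv_i/V0) (Q_i + Q_{i-1}) / 2.
one_site_heats <- function(n, kd_nM, dH_kcal, series) {
  conc <- titration_concentrations(series)
  V0 <- series$cell_volume_ul
  dv <- series$injections$volume_ul
  theta <- one_site_theta(conc$Mt, conc$Xt, n, kd_nM / 1000)
  # uM * ul * kcal/mol = 1e-12 mol/1e-6... -> ucal factor 1e-3
  Q <- n * theta * conc$Mt * V0 * dH_kcal * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (dv / V0) * (Q + Qprev) / 2
}

#' Simulate a one-site ITC titration
#'
#' Forward simulation of per-injection heats under the single-site
#' (Wiseman) isotherm with cumulative dilution of both cell and syringe
#' species and a mid-point volume-displacement correction for each
#' injection heat. Gaussian noise is added when `noise_sd > 0`.
#'
#' @param n Stoichiometry (sites per macromolecule).
#' @param kd_nM Dissociation constant in nM.
#' @param dH_kcal Binding enthalpy in kcal/mol.
#' @param series A [titration_series()] giving the injection protocol.
#' @param noise_sd Gaussian noise standard deviation in ucal.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return The input `series` with `heat_ucal` filled in.
#' @examples
#' sim <- simulate_one_site_titration(n = 0.5, kd_nM = 83, dH_kcal = -10)
#' fit_one_site(sim)
#' @export
simulate_one_site_titration <- function(n, kd_nM, dH_kcal,
                                        series = titration_series(),
                                        noise_sd = 0, seed = 1) {
  stopifnot(inherits(series, "nap_titration"), n > 0, kd_nM > 0,
            noise_sd >= 0)
  dq <- one_site_heats(n, kd_nM, dH_kcal, series)
  if (noise_sd > 0) {
    dq <- dq + withr::with_seed(seed, stats::rnorm(length(dq), 0, noise_sd))
  }
  series$injections$heat_ucal <- dq
  series
}

#' Fit the one-site isotherm to integrated injection heats
#'
#' Least-squares estimation of stoichiometry `n`, dissociation constant and
#' enthalpy from per-injection heats, using the same forward model as
#' [simulate_one_site_titration()] (Levenberg-Marquardt on `(n, log Kd,
#' dH)`). Starting values are heuristic: `dH` from the first-injection
#' heat per mole of injectant, `n` from the molar ratio at which heats have
#' fallen to half their initial value, and `Kd` at `Mt / 20`.
#'
#' @param series A [titration_series()] with observed `heat_ucal`.
#' @param init Optional named list overriding starting values
#'   (`n`, `kd_nM`, `dH_kcal`).
#' @return An object of class `nap_itc_fit`: list with `params`
#'   ([one_site_params()]), `fitted` tibble (observed and fitted heats,
#'   molar ratio), `rss`, `converged` and `init`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
fit_one_site <- function(series, init = NULL) {
  stopifnot(inherits(series, "nap_titration"))
  dq <- series$injections$heat_ucal
  if (anyNA(dq)) abort("series has missing heats; nothing to fit")
  if (length(dq) < 5) abort("need at least 5 injections to fit")
  if (stats::sd(dq) < 1e-12) abort("unidentifiable: injection heats are flat")

  conc <- titration_concentrations(series)
  molar_ratio <- conc$Xt / conc$Mt

  if (is.null(init)) {
    mol_per_inj <- series$syringe_conc_uM * series$injections$volume_ul # pmol-scale
    dH0 <- dq[1] / (mol_per_inj[1] * 1e-3)  # ucal / (uM*ul*1e-3) = kcal/mol
    drop_idx <- which(abs(dq) <= abs(dq[1]) / 2)
    n0 <- if (length(drop_idx) > 0) max(molar_ratio[drop_idx[1]], 0.05) else
      molar_ratio[ceiling(length(dq) / 2)]
    init <- list(n = n0, kd_nM = 1000 * series$cell_conc_uM / 20,
                 dH_kcal = dH0)
  }

  resid_fun <- function(par) {
    one_site_heats(exp(par[1]), exp(par[2]), par[3], series) - dq
  }
  start <- c(log(init$n), log(init$kd_nM), init$dH_kcal)
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(paste0("one-site fit did not converge cleanly (info = ", fit$info,
                "): ", fit$message))
  }
  par <- fit$par
  params <- one_site_params(exp(par[1]), exp(par[2]), par[3])
  fitted_dq <- one_site_heats(params$n, params$kd_nM, params$dH_kcal, series)
  structure(
    list(
      params = params,
      fitted = tibble(
        injection = series$injections$injection,
        molar_ratio = molar_ratio,
        heat_ucal = dq,
        fitted_ucal = fitted_dq
      ),
      rss = sum((dq - fitted_dq)^2),
      converged = converged,
      init = init,
      series = series
    ),
    class = "nap_itc_fit"
  )
}

#' @export
print.nap_itc_fit <- function(x, ...) {
  cat("One-site ITC fit", if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$params)
  cat(sprintf("  RSS = %.4g ucal^2 over %d injections\n", x$rss,
              nrow(x$fitted)))
  invisible(x)
}

#' @export
tidy.nap_itc_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("n", "kd_nM", "dH_kcal", "dG_kcal", "dS_cal"),
    estimate = c(p$n, p$kd_nM, p$dH_kcal, p$dG_kcal, p$dS_cal)
  )
}

#' @export
glance.nap_itc_fit <- function(x, ...) {
  tibble(rss = x$rss, n_injections = nrow(x$fitted), converged = x$converged)
}

#' Simulate a fraction-bound binding curve
#'
#' Hyperbolic one-site curve `f = P / (Kd + P)` with protein in excess over
#' probe, the model used to quantify shift assays.
#'
#' @param kd_uM Dissociation constant in uM.
#' @param protein_uM Protein concentration series in uM.
#' @param noise_sd Gaussian noise on the fractions (clamped to `[0, 1]`).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Tibble with `protein_uM` and `fraction_bound`.
#' @export
simulate_fraction_bound <- function(kd_uM, protein_uM =
                                      c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4),
                                    noise_sd = 0, seed = 1) {
  stopifnot(kd_uM > 0, all(protein_uM >= 0))
  f <- protein_uM / (kd_uM + protein_uM)
  if (noise_sd > 0) {
    f <- withr::with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
    f <- pmin(pmax(f, 0), 1)
  }
  tibble(protein_uM = protein_uM, fraction_bound = f)
}

#' Fit a dissociation constant to a fraction-bound curve
#'
#' Least-squares fit of `f = P / (Kd + P)` (protein in excess, single
#' non-cooperative site) with `Kd > 0` enforced by fitting on the log
#' scale.
#'
#' @param curve Tibble with columns `protein_uM` and `fraction_bound`.
#' @return An object of class `nap_emsa_fit` with `kd_uM`, `fitted`,
#'   `rss`, `converged`. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
fit_fraction_bound_kd <- function(curve) {
  stopifnot(all(c("protein_uM", "fraction_bound") %in% names(curve)))
  P <- curve$protein_uM
  f <- curve$fraction_bound
  if (length(P) < 3) abort("need at least 3 concentrations")
  if (all(f <= 0) || all(f >= 1) || stats::sd(f) < 1e-12) {
    abort("unidentifiable: fractions do not span a binding transition")
  }
  # start at the concentration closest to half-saturation
  kd0 <- P[which.min(abs(f - 0.5))]
  if (kd0 <= 0) kd0 <- stats::median(P[P > 0])
  fit <- minpack.lm::nls.lm(
    par = log(kd0),
    fn = function(par) P / (exp(par) + P) - f,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  kd <- exp(fit$par[1])
  fitted <- P / (kd + P)
  structure(
    list(
      kd_uM = kd,
      fitted = tibble(protein_uM = P, fraction_bound = f,
                      fitted = fitted),
      rss = sum((f - fitted)^2),
      converged = fit$info %in% 1:4
    ),
    class = "nap_emsa_fit"
  )
}

#' @export
print.nap_emsa_fit <- function(x, ...) {
  cat(sprintf("Fraction-bound fit: Kd = %.3g uM (RSS %.3g, %d points)\n",
              x$kd_uM, x$rss, nrow(x$fitted)))
  invisible(x)
}

#' @export
tidy.nap_emsa_fit <- function(x, ...) {
  tibble(term = "kd_uM", estimate = x$kd_uM)
}

#' @export
glance.nap_emsa_fit <- function(x, ...) {
  tibble(rss = x$rss, n_points = nrow(x$fitted), converged = x$converged)
}

#' Mutually exclusive ligand competition
#'
#' Fraction of protein-DNA complex retained when a competing ligand binds
#' the same surface: with mutually exclusive binding the DNA-bound fraction
#' is `(P/Kd_dna) / (1 + P/Kd_dna + (C/Kd_lig)^m)`, reported relative to
#' its value at `C = 0`. The half-inhibition ligand concentration for
#' `m = 1` is `Kd_lig * (1 + P/Kd_dna)`. This is an exploratory simple
#' competition model; it deliberately ignores any conformational coupling
#' between the two binding modes.
#'
#' @param protein_uM Free protein concentration (uM).
#' @param ligand_uM Competing ligand concentration(s) (uM); vectorized.
#' @param kd_dna_uM Protein-DNA dissociation constant (uM).
#' @param kd_ligand_uM Protein-ligand dissociation constant (uM).
#' @param hill_m Ligand cooperativity exponent (default 1; use 2 for two
#'   ligands per binding unit).
#' @return Fraction of the `C = 0` protein-DNA complex retained, in
#'   `[0, 1]`.
#' @export
competition_occupancy <- function(protein_uM, ligand_uM, kd_dna_uM,
                                  kd_ligand_uM, hill_m = 1) {
  stopifnot(protein_uM > 0, kd_dna_uM > 0, kd_ligand_uM > 0, hill_m > 0,
            all(ligand_uM >= 0))
  p <- protein_uM / kd_dna_uM
  base <- p / (1 + p)
  occ <- p / (1 + p + (ligand_uM / kd_ligand_uM)^hill_m)
  occ / base
}

#' Convert per-cell copy numbers to cellular concentration
#'
#' `(copies / subunits) / (N_A * volume)`, reported in uM. With 7000
#' monomers per cell, 4 subunits per complex and a 1.32 fL cytoplasmic
#' volume this gives the 2.2 uM tetramer concentration of the worked
#' example.
#'
#' @param copies_per_cell Monomer copies per cell.
#' @param subunits_per_complex Monomers per complex (default 1).
#' @param cell_volume_fL Cytoplasmic volume in femtoliters.
#' @return Concentration in uM.
#' @examples
#' copies_to_concentration(7000, subunits_per_complex = 4,
#'                         cell_volume_fL = 1.32)
#' @export
copies_to_concentration <- function(copies_per_cell, subunits_per_complex = 1,
                                    cell_volume_fL) {
  stopifnot(copies_per_cell > 0, subunits_per_complex > 0)
  if (any(cell_volume_fL <= 0)) abort("cell volume must be positive")
  complexes <- copies_per_cell / subunits_per_complex
  molar <- complexes / (AVOGADRO * cell_volume_fL * 1e-15)
  molar * 1e6
}

#' Quantify copies per cell from an immunoblot standard curve
#'
#' Fits `intensity = a * mass + b` to standards of known loaded mass,
#' inverts the fit at the sample intensity, and converts the recovered mass
#' to molecule copies per cell.
#'
#' @param standard_amounts_ng Loaded standard masses (ng), >= 3 values.
#' @param standard_intensities Standard band intensities (arbitrary units).
#' @param sample_intensity Sample band intensity (same units).
#' @param molecular_weight_Da Protein molecular weight (Da).
#' @param cells_loaded Number of cells in the sample lane.
#' @return List with `mass_ng`, `copies_per_cell` and the fitted `slope` /
#'   `intercept`. Warns on extrapolation outside the standard range and on
#'   non-monotone standards.
#' @export
standard_curve_quantify <- function(standard_amounts_ng, standard_intensities,
                                    sample_intensity, molecular_weight_Da,
                                    cells_loaded) {
  if (length(standard_amounts_ng) < 3) abort("need at least 3 standards")
  stopifnot(length(standard_amounts_ng) == length(standard_intensities),
            molecular_weight_Da > 0, cells_loaded > 0)
  ord <- order(standard_amounts_ng)
  if (is.unsorted(standard_intensities[ord])) {
    warn("standard intensities are not monotone in loaded mass")
  }
  fit <- lm(standard_intensities ~ standard_amounts_ng)
  a <- coef(fit)[2]
  b <- coef(fit)[1]
  mass_ng <- unname((sample_intensity - b) / a)
  if (sample_intensity < min(standard_intensities) ||
      sample_intensity > max(standard_intensities)) {
    warn("sample intensity outside the standard range; extrapolating")
  }
  copies <- mass_ng * 1e-9 / molecular_weight_Da * AVOGADRO / cells_loaded
  list(mass_ng = mass_ng, copies_per_cell = copies,
       slope = unname(a), intercept = unname(b))
}

#' Apparent mass from size-exclusion elution volume
#'
#' Linear fit of `log10(mass)` versus elution volume over a standard
#' ladder, evaluated at the query volume.
#'
#' @param standards Tibble/data frame with columns `elution_ml` and
#'   `mass_kDa` (>= 3 standards).
#' @param query_volume_ml Elution volume to interpolate at.
#' @return Apparent mass in kDa. Warns when the query lies outside the
#'   standard volume range.
#' @export
sec_mass_from_elution <- function(standards, query_volume_ml) {
  stopifnot(all(c("elution_ml", "mass_kDa") %in% names(standards)))
  if (nrow(standards) < 3) abort("need at least 3 standards")
  fit <- lm(log10(mass_kDa) ~ elution_ml, data = standards)
  if (any(query_volume_ml < min(standards$elution_ml)) ||
      any(query_volume_ml > max(standards$elution_ml))) {
    warn("query volume outside the standard range; extrapolating")
  }
  10^unname(predict(fit, tibble(elution_ml = query_volume_ml)))
}

#' Masses of a typical size-exclusion standard mixture
#'
#' @return Named numeric vector of standard masses in kDa (thyroglobulin
#'   through RNase A).
#' @export
sec_standard_masses <- function() {
  c(
    thyroglobulin = 669, ferritin = 440, carboanhydrase = 158,
    aldolase = 75, ovalbumin = 44, conalbumin = 29, rnase_a = 13.7
  )
}

#' Comparative-Ct relative expression
#'
#' `fold = 2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control))`.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in
#'   the sample condition.
#' @param ct_target_control,ct_ref_control Same in the control condition.
#' @return Fold change (vectorized).
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_control, ct_ref_control) {
  stopifnot(all(is.finite(c(ct_target_sample, ct_ref_sample,
                            ct_target_control, ct_ref_control))))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
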