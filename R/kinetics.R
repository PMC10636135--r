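#' @include AllClasses.R
NULL

#' Fit Michaelis-Menten kinetics to initial-rate data
#'
#' Nonlinear least squares on `v0/[E] = kcat [S] / (Km + [S])`. The start
#' values come from a Lineweaver-Burk (double-reciprocal) linear fit, and
#' the nonlinear fit uses the bounded Gauss-Newton algorithm so `Km` stays
#' positive; standard errors are taken from the fit covariance. Replicate
#' measurements enter individually with equal weights.
#'
#' @param data `data.frame` with columns `substrate_mM` (> 0) and
#'   `v0_over_E` (per second).
#' @return List of class `MMParameters`: `kcat` (s-1), `Km` (mM),
#'   `kcat_over_Km` (mM-1 s-1), `se_kcat`, `se_Km`, and the `fit` object.
#'   Warns when `Km` is poorly identified (data far above saturation or
#'   relative SE > 50%).
#' @export
fitMichaelisMenten <- function(data) {
  stopifnot(all(c("substrate_mM", "v0_over_E") %in% names(data)))
  s <- data$substrate_mM
  v <- data$v0_over_E
  if (length(unique(s)) < 3L)
    stop("need at least 3 distinct substrate concentrations")
  if (any(s <= 0)) stop("substrate concentrations must be positive")
  ok <- v > 0
  lb <- stats::lm(I(1 / v[ok]) ~ I(1 / s[ok]))
  kcat0 <- 1 / stats::coef(lb)[[1L]]
  km0 <- stats::coef(lb)[[2L]] * kcat0
  if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s)
  fit <- tryCatch(
    stats::nls(v ~ kcat * s / (Km + s),
               start = list(kcat = kcat0, Km = km0),
               lower = c(kcat = 1e-12, Km = 1e-9),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e),
                             " (start kcat=", signif(kcat0, 3),
                             ", Km=", signif(km0, 3), ")", call. = FALSE))
  co <- summary(fit)$coefficients
  kcat <- co["kcat", "Estimate"]
  Km <- co["Km", "Estimate"]
  seK <- co["kcat", "Std. Error"]
  seM <- co["Km", "Std. Error"]
  if (Km < min(s) / 20 || seM / Km > 0.5)
    warning("Km is poorly identified by these substrate levels ",
            "(wide standard error)")
  structure(list(kcat = kcat, Km = Km, kcat_over_Km = kcat / Km,
                 se_kcat = seK, se_Km = seM, fit = fit),
            class = "MMParameters")
}

#' @export
print.MMParameters <- function(x, ...) {
  cat(sprintf("kcat = %.4g +/- %.2g s-1; Km = %.4g +/- %.2g mM; kcat/Km = %.4g mM-1 s-1\n",
              x$kcat, x$se_kcat, x$Km, x$se_Km, x$kcat_over_Km))
  invisible(x)
}

#' Fold change in catalytic efficiency
#'
#' Ratio `a / b` of two catalytic efficiencies (kcat/Km), taken as given
#' (no re-rounding). `MMParameters` objects are accepted directly.
#'
#' @param a,b Positive efficiencies, or `MMParameters`.
#' @return The fold ratio.
#' @export
efficiencyFold <- function(a, b) {
  val <- function(z) if (inherits(z, "MMParameters")) z$kcat_over_Km else
    as.numeric(z)
  a <- val(a); b <- val(b)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("efficiencies must be positive")
  a / b
}

#' PET depolymerization conversion, TPA yield and product composition
#'
#' Bookkeeping of the aromatic products released during enzymatic PET
#' depolymerization. The theoretical monomer amount is
#' `pet_mass / repeat-unit molar mass`; conversion at each time point is
#' the summed aromatic product (BHET + MHET + TPA, each counting one
#' aromatic unit) over the theoretical amount; TPA yield is TPA over the
#' theoretical amount; composition is each species over the summed
#' product. Composition is undefined (NA) where no product is present.
#'
#' @param tc `data.frame` with columns `time_h`, `BHET_mM`, `MHET_mM`,
#'   `TPA_mM` (cumulative released concentrations).
#' @param petMass_g PET mass in the reaction (> 0).
#' @param volume_L Reaction volume.
#' @param repeatUnit_gmol Molar mass of the ethylene terephthalate repeat
#'   unit (default 192.17 g/mol).
#' @return `data.frame` per time point: `conversion_pct`, `tpaYield_pct`,
#'   `comp_BHET_pct`, `comp_MHET_pct`, `comp_TPA_pct`.
#' @export
petConversion <- function(tc, petMass_g, volume_L,
                          repeatUnit_gmol = 192.17) {
  stopifnot(petMass_g > 0, volume_L > 0, repeatUnit_gmol > 0)
  need <- c("time_h", "BHET_mM", "MHET_mM", "TPA_mM")
  stopifnot(all(need %in% names(tc)))
  if (any(diff(tc$time_h) <= 0)) stop("times must be strictly increasing")
  if (any(tc$BHET_mM < 0 | tc$MHET_mM < 0 | tc$TPA_mM < 0))
    stop("concentrations must be non-negative")
  theo_mol <- petMass_g / repeatUnit_gmol
  molOf <- function(conc_mM) conc_mM / 1000 * volume_L
  bhet <- molOf(tc$BHET_mM); mhet <- molOf(tc$MHET_mM); tpa <- molOf(tc$TPA_mM)
  total <- bhet + mhet + tpa
  comp <- function(p) ifelse(total > 0, p / total * 100, NA_real_)
  data.frame(time_h = tc$time_h,
             conversion_pct = total / theo_mol * 100,
             tpaYield_pct = tpa / theo_mol * 100,
             comp_BHET_pct = comp(bhet),
             comp_MHET_pct = comp(mhet),
             comp_TPA_pct = comp(tpa))
}

#' Percent crystallinity of a PET sample from DSC enthalpies
#'
#' `crystallinity = (dHm - dHcc) / dHm100 * 100`, with `dHm100` the
#' melting enthalpy of a 100% crystalline PET reference (140.1 J/g).
#' A negative value (cold crystallization exceeding melting) is returned
#' with a warning rather than clipped.
#'
#' @param dHm Enthalpy of melting, J/g.
#' @param dHcc Enthalpy of cold crystallization, J/g.
#' @param dHm100 Reference enthalpy, J/g (> 0; default 140.1).
#' @return Percent crystallinity.
#' @export
crystallinity <- function(dHm, dHcc, dHm100 = 140.1) {
  if (!is.finite(dHm) || !is.finite(dHcc)) stop("enthalpies must be finite")
  if (!is.finite(dHm100) || dHm100 <= 0)
    stop("reference enthalpy must be positive")
  out <- (dHm - dHcc) / dHm100 * 100
  if (out < 0) warning("negative crystallinity (dHcc > dHm)")
  out
}
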