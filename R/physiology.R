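# Leaf-physiology calculators: pigment contents from 80%-acetone extract
# absorbances and saturation-pulse chlorophyll-fluorescence parameters.

#' Chlorophyll and carotenoid content from extract absorbances
#'
#' Lichtenthaler-style equations for an 80% acetone extract.  Concentrations
#' in mg/L:
#' \deqn{ca = 12.21 \cdot OD_{663} - 2.81 \cdot OD_{646}}
#' \deqn{cb = 20.13 \cdot OD_{646} - 5.03 \cdot OD_{663}}
#' \deqn{cxc = (1000 \cdot OD_{470} - 3.27 \cdot ca - 104 \cdot cb) / 229}
#' Contents per gram fresh weight scale each concentration by
#' `volume_ml / (1000 * mass_g)`.  Negative computed values are returned
#' as-is with a quality flag rather than clipped, so instrument noise near
#' zero stays visible.
#'
#' @param od663,od646,od470 absorbances at 663, 646 and 470 nm (vectorised).
#' @param volume_ml extract volume in mL (> 0).
#' @param mass_g sample fresh mass in g (> 0).
#' @return data.frame chl_a, chl_b, carotenoids (mg per g fresh weight) and
#'   logical `flag_negative`.
#' @examples
#' pigment_content(0.5, 0.2, 0.3, volume_ml = 25, mass_g = 0.15)
#' @export
pigment_content <- function(od663, od646, od470, volume_ml, mass_g) {
  n <- max(length(od663), length(od646), length(od470))
  assert_that(all(is.finite(c(od663, od646, od470))) &&
                all(c(od663, od646, od470) >= 0),
              "absorbances must be finite and >= 0")
  assert_that(all(volume_ml > 0) && all(mass_g > 0),
              "`volume_ml` and `mass_g` must be positive")
  ca <- 12.21 * od663 - 2.81 * od646
  cb <- 20.13 * od646 - 5.03 * od663
  cxc <- (1000 * od470 - 3.27 * ca - 104 * cb) / 229
  scale <- volume_ml / (1000 * mass_g)
  out <- data.frame(chl_a = ca * scale, chl_b = cb * scale,
                    carotenoids = cxc * scale)
  out$flag_negative <- out$chl_a < 0 | out$chl_b < 0 | out$carotenoids < 0
  out
}

#' Maximum quantum yield of photosystem II
#'
#' `Fv/Fm = (Fm - Fo) / Fm` from dark-adapted minimal (Fo) and maximal (Fm)
#' fluorescence; `Fv/Fo = (Fm - Fo) / Fo`, related by the identity
#' `Fv/Fo = (Fv/Fm) / (1 - Fv/Fm)`.
#'
#' @param fo,fm dark-adapted fluorescence with `fm > fo > 0` (vectorised).
#' @return the ratio.
#' @examples
#' fvfm(0.5, 2)   # 0.75
#' fvfo(0.5, 2)   # 3
#' @export
fvfm <- function(fo, fm) {
  assert_that(all(fo > 0) && all(fm > fo),
              "need fm > fo > 0 for dark-adapted yields")
  (fm - fo) / fm
}

#' @rdname fvfm
#' @export
fvfo <- function(fo, fm) {
  assert_that(all(fo > 0) && all(fm > fo),
              "need fm > fo > 0 for dark-adapted yields")
  (fm - fo) / fo
}

#' Saturation-pulse chlorophyll-fluorescence parameters
#'
#' Standard PAM quenching analysis from dark-adapted (Fo, Fm) and
#' light-adapted (Ft, Fm') levels:
#' Genty effective yield `Y(II) = (Fm' - Ft)/Fm'`;
#' Stern–Volmer `NPQ = (Fm - Fm')/Fm'`;
#' `qN = 1 - (Fm' - Fo')/(Fm - Fo)`;
#' puddle-model `qP = (Fm' - Ft)/(Fm' - Fo')` and lake-model
#' `qL = qP * Fo'/Ft`;
#' Kramer yields `Y(NPQ) = Ft/Fm' - Ft/Fm` and `Y(NO) = Ft/Fm`, so that
#' `Y(II) + Y(NPQ) + Y(NO) = 1` identically;
#' `ETR = 0.5 * 0.84 * PAR * Y(II)` (PSII fraction 0.5, leaf absorptance
#' 0.84).  When `fo_prime` is not measured it is estimated by the
#' Oxborough–Baker relation `Fo' = Fo / (Fv/Fm + Fo/Fm')`.
#'
#' @param fo,fm dark-adapted minimal and maximal fluorescence (`fm > fo > 0`).
#' @param ft,fm_prime light-adapted steady-state and pulse-maximum
#'   fluorescence (`fm_prime >= ft > 0`).
#' @param fo_prime light-adapted minimal fluorescence; estimated when `NULL`.
#' @param par actinic irradiance in umol m-2 s-1; `ETR` is `NA` when absent.
#' @param psii_fraction,absorptance ETR factors (defaults 0.5 and 0.84).
#' @return data.frame fvfm, fvfo, yii, npq, qn, qp, ql, ynpq, yno, etr and
#'   logical `flag_qp_undefined` (set where `fm_prime <= fo_prime`, which
#'   leaves qP and qL undefined).
#' @examples
#' saturation_pulse_params(fo = 0.2, fm = 1, ft = 0.4, fm_prime = 0.7,
#'                         fo_prime = 0.18)
#' @export
saturation_pulse_params <- function(fo, fm, ft, fm_prime, fo_prime = NULL,
                                    par = NULL, psii_fraction = 0.5,
                                    absorptance = 0.84) {
  assert_that(all(fo > 0) && all(fm > fo), "need fm > fo > 0")
  assert_that(all(ft > 0) && all(fm_prime >= ft),
              "need fm_prime >= ft > 0")
  fvfm_v <- fvfm(fo, fm)
  if (is.null(fo_prime)) {
    fo_prime <- fo / (fvfm_v + fo / fm_prime)   # Oxborough-Baker estimate
  }
  yii <- (fm_prime - ft) / fm_prime
  npq <- (fm - fm_prime) / fm_prime
  qn <- 1 - (fm_prime - fo_prime) / (fm - fo)
  qp_ok <- fm_prime > fo_prime
  qp <- ifelse(qp_ok, (fm_prime - ft) / (fm_prime - fo_prime), NA_real_)
  ql <- ifelse(qp_ok, qp * fo_prime / ft, NA_real_)
  ynpq <- ft / fm_prime - ft / fm
  yno <- ft / fm
  etr <- if (is.null(par)) NA_real_ else psii_fraction * absorptance * par * yii
  data.frame(fvfm = fvfm_v, fvfo = fvfo(fo, fm), yii = yii, npq = npq,
             qn = qn, qp = qp, ql = ql, ynpq = ynpq, yno = yno, etr = etr,
             flag_qp_undefined = !qp_ok)
}

#' Percent change between two treatment groups
#'
#' Mutant-vs-wild-type style comparison: percent change
#' `100 * (mean(a) - mean(b)) / mean(b)`, the ratio `100 * mean(a)/mean(b)`,
#' and a Welch two-sample t-test on the replicate vectors.
#'
#' @param values_a treatment replicate values (e.g. mutant).
#' @param values_b reference replicate values (e.g. wild type); mean must be
#'   positive.
#' @return list: percent_change, percent_of_reference, mean_a, mean_b,
#'   t_statistic, p_value (p and t are `NA` when either group has fewer
#'   than 2 replicates).
#' @export
treatment_comparison <- function(values_a, values_b) {
  assert_that(length(values_a) >= 1 && length(values_b) >= 1,
              "both groups need at least one value")
  mb <- mean(values_b)
  assert_that(mb > 0, "reference mean must be positive")
  ma <- mean(values_a)
  tt <- NA_real_
  pv <- NA_real_
  if (length(values_a) >= 2 && length(values_b) >= 2 &&
      (stats::sd(values_a) > 0 || stats::sd(values_b) > 0)) {
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
    tt <- unname(ht$statistic)
    pv <- ht$p.value
  }
  list(percent_change = 100 * (ma - mb) / mb,
       percent_of_reference = 100 * ma / mb,
       mean_a = ma, mean_b = mb, t_statistic = tt, p_value = pv)
}
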