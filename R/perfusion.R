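#' Mean arterial pressure from cuff pressures
#'
#' `MAP = DBP + (SBP - DBP) / 3`, the standard estimate from systolic and
#' diastolic brachial pressure.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @param dbp Diastolic blood pressure (mmHg); must satisfy
#'   `sbp >= dbp > 0`.
#' @return MAP in mmHg. Vectorized.
#' @export
#' @examples
#' mean_arterial_pressure(136, 80) # 98.67 mmHg
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    abort("Blood pressures must be finite.", class = "lsfg_bad_pressure")
  }
  if (any(dbp <= 0) || any(sbp < dbp)) {
    abort("Require sbp >= dbp > 0 mmHg.", class = "lsfg_bad_pressure")
  }
  dbp + (sbp - dbp) / 3
}

#' Ocular perfusion pressure (sitting)
#'
#' `OPP = 2/3 * MAP - IOP`, the driving pressure for ocular blood flow in
#' the sitting position. A non-positive OPP is physiologically extreme but
#' arithmetically legal; it is returned with a warning.
#'
#' @param map_mmHg Mean arterial pressure (mmHg), e.g. from
#'   [mean_arterial_pressure()].
#' @param iop Intraocular pressure (mmHg, >= 0).
#' @return OPP in mmHg. Vectorized.
#' @export
#' @examples
#' ocular_perfusion_pressure(mean_arterial_pressure(136, 80), 14.4) # 51.38
ocular_perfusion_pressure <- function(map_mmHg, iop) {
  if (any(!is.finite(map_mmHg)) || any(!is.finite(iop))) {
    abort("Inputs must be finite.", class = "lsfg_bad_pressure")
  }
  if (any(iop < 0)) {
    abort("IOP must be >= 0 mmHg.", class = "lsfg_bad_pressure")
  }
  opp <- 2 / 3 * map_mmHg - iop
  if (any(opp <= 0)) {
    warn("OPP <= 0 mmHg for at least one eye; check the input pressures.")
  }
  opp
}
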