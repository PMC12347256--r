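# Right-heart-catheterization derived quantities and the hemodynamic
# definition of pulmonary hypertension.

#' Pulmonary vascular resistance
#'
#' PVR = (mPAP - PCWP) / CO in Wood units; 1 WU = 80 dyn.s.cm^-5 exactly.
#' A negative transpulmonary gradient (PCWP > mPAP) is allowed but flagged.
#'
#' @param mpap mean pulmonary arterial pressure, mmHg (or a list/row with
#'   `mpap`, `pcwp`, `co` fields)
#' @param pcwp pulmonary capillary wedge pressure, mmHg
#' @param co cardiac output, L/min (> 0)
#' @return list: `pvr_wu`, `pvr_dyn`, `negative_gradient`
#' @export
compute_pvr <- function(mpap, pcwp = NULL, co = NULL) {
  if (is.list(mpap)) {
    rec <- mpap; mpap <- rec$mpap; pcwp <- rec$pcwp; co <- rec$co
  }
  if (any(co <= 0)) stop("cardiac output must be > 0")
  if (any(c(mpap, pcwp) < 0)) stop("pressures must be >= 0")
  wu <- (mpap - pcwp) / co
  if (any(wu < 0))
    warning("negative transpulmonary gradient (PCWP > mPAP)")
  list(pvr_wu = wu, pvr_dyn = 80 * wu, negative_gradient = wu < 0)
}

#' Hemodynamic pulmonary-hypertension classification
#'
#' PH is defined as mPAP >= 20 mmHg at rest together with PVR >= 3 Wood
#' units; both boundaries are inclusive. The 2022 guideline threshold
#' (PVR > 2 WU) can be selected via `pvr_cutoff = 2, pvr_inclusive = FALSE`.
#'
#' @param mpap mmHg (or a list/row with `mpap`, `pcwp`, `co`)
#' @param pcwp mmHg
#' @param co L/min
#' @param mpap_cutoff mmHg, inclusive (default 20)
#' @param pvr_cutoff Wood units (default 3)
#' @param pvr_inclusive whether the PVR bound is `>=` (default) or `>`
#' @return list: `pvr_wu`, `pvr_dyn`, `is_ph`
#' @export
classify_ph <- function(mpap, pcwp = NULL, co = NULL, mpap_cutoff = 20,
                        pvr_cutoff = 3, pvr_inclusive = TRUE) {
  if (is.list(mpap)) {
    rec <- mpap; mpap <- rec$mpap; pcwp <- rec$pcwp; co <- rec$co
  }
  pvr <- compute_pvr(mpap, pcwp, co)
  pvr_ok <- if (pvr_inclusive) pvr$pvr_wu >= pvr_cutoff
            else pvr$pvr_wu > pvr_cutoff
  list(pvr_wu = pvr$pvr_wu, pvr_dyn = pvr$pvr_dyn,
       is_ph = (mpap >= mpap_cutoff) & pvr_ok)
}

#' Apply the wedge-pressure eligibility rule
#'
#' Subjects with PCWP > 15 mmHg are excluded (post-capillary component);
#' PCWP exactly 15 is retained. The number removed is reported as an
#' attribute and a message.
#'
#' @param records data frame with a `pcwp` column
#' @param pcwp_max mmHg, exclusive upper bound retained (default 15)
#' @return the eligible rows, with attribute `n_excluded`
#' @export
filter_cohort <- function(records, pcwp_max = 15) {
  keep <- records$pcwp <= pcwp_max
  out <- records[keep, , drop = FALSE]
  n_exc <- sum(!keep)
  attr(out, "n_excluded") <- n_exc
  message(sprintf("[hemodynamics] excluded %d subject(s) with PCWP > %g mmHg",
                  n_exc, pcwp_max))
  out
}
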