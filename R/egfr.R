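#' Estimated glomerular filtration rate (CKD-EPI 2009 creatinine equation)
#'
#' Computes eGFR in ml/min/1.73 m^2 from serum creatinine using the 2009
#' CKD-EPI creatinine equation:
#' \deqn{eGFR = 141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{Age} \cdot 1.018[f] \cdot 1.159[b]}
#' with kappa = 0.7 (female) / 0.9 (male) and alpha = -0.329 (female) /
#' -0.411 (male). The 1.159 ancestry coefficient of the original equation is
#' kept behind `ancestry_flag` for completeness; the simulator default is
#' FALSE.
#'
#' @param scr serum creatinine in mg/dL (> 0).
#' @param age age in years (>= 18).
#' @param sex character vector, "female" or "male".
#' @param ancestry_flag logical, apply the 1.159 coefficient.
#' @return eGFR in ml/min/1.73 m^2.
#' @examples
#' ckdepi_egfr(0.7, 50, "female")  # about 101
#' @export
ckdepi_egfr <- function(scr, age, sex, ancestry_flag = FALSE) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive", call. = FALSE)
  }
  if (any(age < 18)) stop("CKD-EPI equation applies to adults (age >= 18)", call. = FALSE)
  sex <- match.arg_vec(sex, c("female", "male"))
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- scr / kappa
  egfr <- 141 *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^(-1.209) *
    0.993^age *
    ifelse(female, 1.018, 1)
  if (isTRUE(ancestry_flag)) egfr <- egfr * 1.159
  egfr
}

# vectorized match.arg for factor-like string inputs
match.arg_vec <- function(x, choices) {
  x <- as.character(x)
  if (!all(x %in% choices)) {
    stop("values must be one of: ", paste(choices, collapse = ", "), call. = FALSE)
  }
  x
}

#' Winsorize eGFR to [15, 200] and take the natural log
#'
#' eGFR values are clamped at 15 and 200 ml/min/1.73 m^2 before natural-log
#' transformation, so the analysed phenotype always lies in [ln 15, ln 200].
#'
#' @param egfr eGFR in ml/min/1.73 m^2 (> 0).
#' @return log-eGFR in [ln 15, ln 200].
#' @export
winsorize_log_egfr <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("eGFR must be positive", call. = FALSE)
  }
  log(pmin(pmax(egfr, 15), 200))
}

# Invert the CKD-EPI equation: creatinine that yields a target eGFR for the
# given covariates. The equation is strictly decreasing and piecewise
# log-linear in scr, so the inverse is closed-form: solve the constant part,
# then invert whichever branch (scr below/above kappa) the target falls in.
ckdepi_invert <- function(egfr_target, age, sex, ancestry_flag = FALSE) {
  sex <- match.arg_vec(sex, c("female", "male"))
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  const <- 141 * 0.993^age * ifelse(female, 1.018, 1) *
    (if (isTRUE(ancestry_flag)) 1.159 else 1)
  # value of the equation at scr == kappa (both ratio terms equal 1)
  ratio <- egfr_target / const
  # ratio > 1 -> scr below kappa (branch with exponent alpha, negative)
  scr <- ifelse(ratio >= 1,
    kappa * ratio^(1 / alpha),
    kappa * ratio^(-1 / 1.209)
  )
  scr
}
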