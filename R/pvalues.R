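#' Two-sided p-value from a z-statistic, kept finite on the log scale
#'
#' GWAS meta-analyses routinely produce p-values far below the smallest
#' representable double (e.g. 5.9e-188 and beyond); all p-value arithmetic in
#' this package is therefore carried out on the log scale and every p-value is
#' returned together with its -log10 companion.
#'
#' @param z numeric vector of z-statistics.
#' @return data.frame with columns `p` (two-sided, may underflow to 0) and
#'   `log10p` (-log10 p, always finite for finite z).
#' @export
p_two_sided <- function(z) {
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  data.frame(p = exp(lp), log10p = -lp / log(10))
}

#' One-sided p-value from a z-statistic in a given direction
#'
#' @param z numeric vector of z-statistics.
#' @param sign_ref reference direction (+1 or -1); the p-value is the
#'   probability of a deviation at least as extreme as `z` in that direction.
#' @return data.frame with columns `p` and `log10p`.
#' @export
p_one_sided <- function(z, sign_ref) {
  stopifnot(all(sign_ref %in% c(-1, 1)))
  lp <- stats::pnorm(sign_ref * z, lower.tail = FALSE, log.p = TRUE)
  data.frame(p = exp(lp), log10p = -lp / log(10))
}

#' Chi-square survival p-value on the log scale
#'
#' @param x chi-square statistic(s).
#' @param df degrees of freedom.
#' @return data.frame with columns `p` and `log10p`.
#' @export
p_chisq <- function(x, df) {
  lp <- stats::pchisq(x, df = df, lower.tail = FALSE, log.p = TRUE)
  data.frame(p = exp(lp), log10p = -lp / log(10))
}

# two-sided p from a t-statistic (study-level GWAS); log-scale like the rest
p_two_sided_t <- function(tval, df) {
  lp <- stats::pt(abs(tval), df = df, lower.tail = FALSE, log.p = TRUE) + log(2)
  data.frame(p = exp(lp), log10p = -lp / log(10))
}
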