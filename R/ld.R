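#' Construct an LD reference panel from dosages
#'
#' @param dosage individuals x variants matrix of allele dosages in [0, 2];
#'   columns named by variant id (or supply `ids`).
#' @param ids variant identifiers (defaults to column names).
#' @return an object of class `ld_reference` with the dosage matrix, ids,
#'   per-variant EAF and centered dosages cached for correlation queries.
#' @export
ld_reference <- function(dosage, ids = colnames(dosage)) {
  stopifnot(is.matrix(dosage), !is.null(ids), length(ids) == ncol(dosage))
  centered <- scale(dosage, center = TRUE, scale = FALSE)
  obj <- list(dosage = dosage, ids = as.character(ids),
              eaf = colMeans(dosage) / 2,
              centered = centered,
              ss = colSums(centered^2),
              n = nrow(dosage))
  class(obj) <- "ld_reference"
  obj
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("ld_reference:", x$n, "individuals,", length(x$ids), "variants\n")
  invisible(x)
}

#' Pairwise linkage disequilibrium between two variants
#'
#' Pearson correlation of the dosage vectors in the reference panel.
#'
#' @param ldref an [ld_reference()] object.
#' @param a,b variant ids.
#' @return list with `r` and `r2`.
#' @export
compute_ld <- function(ldref, a, b) {
  stopifnot(inherits(ldref, "ld_reference"))
  ia <- match(a, ldref$ids)
  ib <- match(b, ldref$ids)
  if (is.na(ia) || is.na(ib)) stop("variant not in LD reference", call. = FALSE)
  if (ldref$ss[ia] == 0 || ldref$ss[ib] == 0) {
    stop("LD undefined for a monomorphic variant", call. = FALSE)
  }
  r <- unname(sum(ldref$centered[, ia] * ldref$centered[, ib]) /
                sqrt(ldref$ss[ia] * ldref$ss[ib]))
  list(r = r, r2 = r^2)
}

# correlation submatrix for a set of variant indices
ld_submatrix <- function(ldref, idx) {
  s <- ldref$centered[, idx, drop = FALSE]
  cp <- crossprod(s)
  d <- sqrt(diag(cp))
  cp / outer(d, d)
}
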