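# Shared fixture builders for the suite. Everything is generated in code;
# sizes are kept small except where a stated property needs scale.

# one-variant-per-row toy summary statistics
toy_stats <- function(snp, beta, se, n = 1000, eaf = 0.3, ea = "A", oa = "C",
                      info = 0.95, chr = 1, pos = seq_along(snp) * 1e5) {
  pv <- stratgwas::p_two_sided(beta / se)
  data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
             BETA = beta, SE = se, P = pv$p, LOG10P = pv$log10p, N = n,
             INFO = info, stringsAsFactors = FALSE)
}

# independent brute-force interval merger: single-linkage clustering of
# significant positions at <= merge bp, padded by flank. Used as the
# clumping oracle; deliberately coded differently from define_loci().
oracle_clump <- function(chr, pos, flank = 250000, merge = 500000) {
  out <- list()
  for (c in sort(unique(chr))) {
    p <- sort(pos[chr == c])
    if (!length(p)) next
    start <- p[1]
    prev <- p[1]
    for (x in p[-1]) {
      if (x - prev <= merge) {
        prev <- x
      } else {
        out[[length(out) + 1]] <- c(c, start - flank, prev + flank)
        start <- x
        prev <- x
      }
    }
    out[[length(out) + 1]] <- c(c, start - flank, prev + flank)
  }
  m <- do.call(rbind, out)
  df <- data.frame(CHR = m[, 1], START = m[, 2], END = m[, 3])
  df <- df[order(df$CHR, df$START), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# GLS solve for a one-variant inverse-variance meta-analysis (oracle)
oracle_gls_meta <- function(beta, se) {
  V <- diag(se^2, nrow = length(se))
  one <- rep(1, length(se))
  vinv <- solve(V)
  var_hat <- 1 / drop(t(one) %*% vinv %*% one)
  list(beta = drop(var_hat * t(one) %*% vinv %*% beta), se = sqrt(var_hat))
}
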