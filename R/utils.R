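# Internal helpers shared across modules.

# Dirichlet draw via independent gammas; alpha entries of 0 give exact zeros,
# which is how structurally absent OTUs (e.g. system-specific OTUs outside
# their system) stay absent.
.rdirichlet <- function(alpha) {
  g <- rep(0, length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(g)
  if (s <= 0) {
    # pathological all-zero draw: fall back to the normalized alphas
    return(alpha / sum(alpha))
  }
  g / s
}

.assertCountMatrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (OTUs x samples)")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("'counts' contains missing or non-finite values")
  }
  if (any(counts < 0)) stop("'counts' contains negative values")
  invisible(TRUE)
}

# Pretty "OTU_0001 (sample S1)" style cell name for error messages.
.cellName <- function(mat, idx) {
  sprintf("OTU '%s', sample '%s'", rownames(mat)[idx[1L]], colnames(mat)[idx[2L]])
}

.isWholeNumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# Letter labels a, b, ..., z, aa, ab, ... for compact letter displays.
.letterLabels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(t(outer(letters, letters, paste0))))[seq_len(n)]
}
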