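#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a parent seed and a label; keeps independent,
# reproducible streams for the simulator's stages (R integers are 32-bit).
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

# Symmetrise and, if needed, jitter a matrix onto the SPD cone.
# Jitter scale follows trace/n; repairs are counted on the returned attribute.
ensure_spd <- function(m, jitter = 1e-8) {
  m <- (m + t(m)) / 2
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  repaired <- FALSE
  if (ev <= 0) {
    m <- m + diag(abs(ev) + jitter * mean(diag(m)), nrow(m))
    repaired <- TRUE
  }
  attr(m, "spd_repaired") <- repaired
  m
}

# Partial correlations from a precision matrix: unit diagonal, entries in [-1,1].
precision_to_partial <- function(prec) {
  d <- 1 / sqrt(diag(prec))
  pc <- -prec * outer(d, d)
  diag(pc) <- 1
  pc
}

# Column-wise Pearson correlation between two matrices with matching columns.
colwise_cor <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
}

logdet <- function(m) as.numeric(determinant(m, logarithm = TRUE)$modulus)

# Multivariate log-gamma and digamma sums used by Wishart expectations.
lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}
mvdigamma <- function(a, d) sum(digamma(a + (1 - seq_len(d)) / 2))

`%||%` <- function(x, y) if (is.null(x)) y else x
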