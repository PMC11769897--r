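# Internal helpers shared across modules.

# Condition labels: control crossed with valence, fixed order.
.conditions <- c("extrinsic-win", "extrinsic-loss", "intrinsic-win", "intrinsic-loss")

.condition_of <- function(control, valence) paste(control, valence, sep = "-")

.control_of <- function(condition) sub("-.*$", "", condition)

.valence_of <- function(condition) sub("^.*-", "", condition)

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable small integer derived from a string, for per-subject seed streams.
.hash_seed <- function(base_seed, ...) {
  s <- paste(..., collapse = "|")
  h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))
  as.integer((as.numeric(base_seed) * 1009 + h) %% .Machine$integer.max)
}

# Log density of a multivariate normal with mean m and covariance S.
.dmvnorm_log <- function(x, m, S) {
  d <- length(m)
  ch <- chol(S)
  z <- backsolve(ch, x - m, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Force a matrix to be symmetric positive-definite by eigenvalue flooring.
.make_spd <- function(S, floor = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  (S2 + t(S2)) / 2
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Truncated-normal draws by rejection; falls back to clamping for extreme bounds.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 50L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  pmin(pmax(out, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
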