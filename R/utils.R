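# Internal helpers shared across modules.

#' Standardize a numeric vector to mean 0, SD 1
#'
#' @param x numeric vector (NAs allowed; they stay NA).
#' @param what label used in the zero-variance error message.
#' @return standardized vector with attributes `center` and `scale`.
#' @keywords internal
standardize <- function(x, what = "variable") {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    stop("cannot standardize ", what, ": zero or undefined variance", call. = FALSE)
  }
  out <- (x - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

# Run an expression under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Counter-based replicate seed derivation: reproducible, no seed reuse across
# replicates, and independent of execution order. Keeps seeds < 2^31.
derive_seeds <- function(master_seed, n) {
  (as.double(master_seed) * 69069 + 10007 * seq_len(n)) %% 2147483587
}

assert_scalar_in <- function(x, lo, hi, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    stop(name, " must be a single value in ", if (open) "(" else "[",
         lo, ", ", hi, if (open) ")" else "]", call. = FALSE)
  }
  invisible(x)
}

# OLS fit on an explicit design matrix (intercept must be a column) returning
# the coefficient table used throughout. Thin wrapper over stats::lm.fit so the
# hot simulation paths avoid formula overhead.
ols_fit <- function(X, y) {
  keep <- stats::complete.cases(X) & !is.na(y)
  Xc <- X[keep, , drop = FALSE]
  yc <- y[keep]
  n <- nrow(Xc)
  p <- ncol(Xc)
  if (n <= p) stop("too few complete observations (n = ", n, ") for ", p, " terms", call. = FALSE)
  fit <- stats::lm.fit(Xc, yc)
  if (fit$rank < p) {
    bad <- colnames(Xc)[is.na(fit$coefficients)]
    stop("singular design; offending columns: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)
  se <- sqrt(diag(XtXinv) * sigma2)
  beta <- fit$coefficients
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((yc - mean(yc))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  list(
    coefficients = data.frame(
      term = colnames(Xc), beta = unname(beta), se = unname(se),
      t = unname(tval), p = unname(pval), stringsAsFactors = FALSE
    ),
    n = n, df = df, r2 = r2, adj_r2 = adj_r2, sigma2 = sigma2,
    residuals = fit$residuals, fitted = fit$fitted.values, kept = which(keep)
  )
}
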