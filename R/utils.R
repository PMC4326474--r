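# internal helpers shared across modules

# Truncated box-car average of `x * theta` over windows of radius r, in one
# cumsum pass.  x may carry NAs wherever theta == 0; positions whose whole
# window has theta == 0 come back NA.
boxcar_masked <- function(x, theta, r) {
  stopifnot(length(x) == length(theta))
  if (r < 0) abort("window radius `r` must be >= 0", class = "xgram_bad_radius")
  n <- length(x)
  xt <- ifelse(theta > 0, x, 0)
  xt[is.na(xt)] <- 0
  cs_x <- cumsum(c(0, xt))
  cs_t <- cumsum(c(0, as.numeric(theta > 0)))
  i <- seq_len(n)
  lo <- pmax(1L, i - r)
  hi <- pmin(n, i + r)
  num <- cs_x[hi + 1L] - cs_x[lo]
  den <- cs_t[hi + 1L] - cs_t[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Column variance of a matrix along rows (var across columns, n-1 denominator).
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) || x < 0)
    abort(sprintf("`%s` must be a single non-negative integer", name))
  invisible(as.integer(x))
}

# A parse error that names the offending line.
parse_abort <- function(path, line, msg) {
  abort(sprintf("%s:%d: %s", path, line, msg), class = "xgram_parse_error")
}
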