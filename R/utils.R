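# internal helpers shared across modules

# run a generator body under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# weighted quantiles by linear interpolation on the cumulative weight scale;
# probs 0 and 1 return the sample minimum and maximum exactly
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  # midpoint convention: F(x_i) = (cw_i - w_i/2) / sum(w)
  p <- (cw - w / 2) / sum(w)
  vapply(probs, function(q) {
    if (q <= p[1]) return(x[1])
    if (q >= p[length(p)]) return(x[length(x)])
    stats::approx(p, x, xout = q, ties = "ordered")$y
  }, numeric(1))
}

# cubic smoothstep: 0 for u <= 0, 1 for u >= 1, 3u^2 - 2u^3 between
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# smooth unit step centred on a transition from t0 lasting tau seconds
soft_step <- function(t, t0, tau) {
  if (tau <= 0) return(as.numeric(t >= t0))
  smoothstep((t - t0) / tau)
}

# contiguous runs where a logical vector is TRUE; returns start/end indices
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
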