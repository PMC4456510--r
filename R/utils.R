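# Internal helpers shared across modules.

# Log-normal draw parameterized by mode (same units as output) and log-sd.
# mode = exp(mu - sigma^2)  =>  mu = log(mode) + sigma^2.
rlnorm_mode <- function(n, mode, sigma) {
  rlnorm(n, meanlog = log(mode) + sigma^2, sdlog = sigma)
}

# Truncated normal by rejection; bounds in the same units as mean/sd.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x > lower & x < upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Centered moving average with edge padding; width in samples (>=1).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  pad <- width %/% 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], width - pad - 1))
  as.numeric(stats::filter(xp, k, sides = 1))[(width - 1) + seq_along(x)]
}

# Runs of TRUE in a logical vector: matrix with columns start, end (indices).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Evaluate code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Half-open interval membership: onset <= t < offset for any row of ivals.
in_any_interval <- function(t, onsets, offsets) {
  if (!length(onsets)) return(rep(FALSE, length(t)))
  idx <- findInterval(t, sort(onsets))
  out <- rep(FALSE, length(t))
  ord <- order(onsets)
  on <- onsets[ord]; off <- offsets[ord]
  hit <- idx > 0
  out[hit] <- t[hit] < off[idx[hit]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
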