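# Internal numerical and RNG helpers shared across modules.

# Deterministic integer seed mixing. Keeps every intermediate below 2^53 and
# every result in [1, 2147483586] so it is always a valid set.seed() input.
mix_seed <- function(...) {
  parts <- c(...)
  m <- 2147483587
  s <- 97
  for (p in parts) {
    p <- as.numeric(p) %% m
    s <- (s * 39989 + p * 30011 + 17) %% m
  }
  as.integer(s %% 2147483586L + 1)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user simulations.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# ---- truncated normal -------------------------------------------------------

# Draw from N(mu, sd) truncated to [a, b] by inverse-CDF; vectorised in n.
rtnorm <- function(n, mu, sd, a = -Inf, b = Inf) {
  if (sd <= 0) {
    return(rep(clamp(mu, a, b), n))
  }
  pa <- stats::pnorm(a, mu, sd)
  pb <- stats::pnorm(b, mu, sd)
  u <- stats::runif(n, pa, pb)
  clamp(stats::qnorm(u, mu, sd), a, b)
}

# Mean and sd of N(mu, sd) truncated to [a, b].
tnorm_moments <- function(mu, sd, a = -Inf, b = Inf) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z <= 0) {
    return(c(mean = clamp(mu, a, b), sd = 0))
  }
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  m <- mu + sd * (da - db) / Z
  t1 <- if (is.finite(al)) al * da else 0
  t2 <- if (is.finite(be)) be * db else 0
  v <- sd^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for underlying (mu, sd) so that N(mu, sd) truncated to [a, b] has the
# requested mean and sd.  Used wherever a printed summary pins the moments of
# a bounded quantity.  Returns list(mu, sd, a, b).
tnorm_solve <- function(mean, sd, a = -Inf, b = Inf) {
  if (sd <= 0) {
    return(list(mu = mean, sd = 0, a = a, b = b))
  }
  obj <- function(par) {
    mo <- tnorm_moments(par[1], exp(par[2]), a, b)
    (mo[1] - mean)^2 / max(sd, 1e-8)^2 + (mo[2] - sd)^2 / max(sd, 1e-8)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sd = exp(fit$par[2]), a = a, b = b)
}

rtnorm_target <- function(n, spec) rtnorm(n, spec$mu, spec$sd, spec$a, spec$b)

# Shifted-Gamma latent with the requested mean and sd on (floor, Inf);
# right-skewed, well-behaved for any sd (unlike a truncated normal, whose
# moment matching degenerates when sd approaches mean - floor).
gamma_solve <- function(mean, sd, floor = 0, cap = Inf) {
  m <- max(mean - floor, 1e-6)
  list(type = "gamma", shape = (m / sd)^2, scale = sd^2 / m,
       floor = floor, cap = cap)
}

# Draw from a latent spec produced by gamma_solve() or tnorm_solve().
draw_latent <- function(n, spec) {
  if (identical(spec$type, "gamma")) {
    pmin(spec$floor + stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         spec$cap)
  } else {
    rtnorm_target(n, spec)
  }
}

# ---- moment-matched Beta ----------------------------------------------------

# Beta(shape1, shape2) with given mean/sd; requires sd^2 < mean(1-mean).
beta_solve <- function(mean, sd) {
  mean <- clamp(mean, 1e-6, 1 - 1e-6)
  vmax <- mean * (1 - mean)
  v <- min(sd^2, vmax * 0.98)
  k <- vmax / v - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

rbeta_target <- function(n, spec) stats::rbeta(n, spec$shape1, spec$shape2)

# Reduce a target variance by the expected extraction noise so that the
# *observed* feature (latent + noise) matches the printed SD.
shrink_var <- function(target_sd, noise_var) {
  sqrt(max(target_sd^2 - noise_var, (0.15 * target_sd)^2))
}

# ---- geometry ---------------------------------------------------------------

# Even-odd (crossing number) point-in-polygon, vectorised over points.
# Points within `eps` of an edge are classified inside (deterministic
# tie-break for touch points exactly on an outline).
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  px <- poly[, 1]
  py <- poly[, 2]
  np <- length(px)
  nx <- c(px[-1], px[1])
  ny <- c(py[-1], py[1])
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (i in seq_len(np)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- nx[i]; y2 <- ny[i]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xint <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- rep(FALSE, length(x))
      flip[crosses] <- x[crosses] < xint
      inside <- xor(inside, flip)
    }
    # distance from each point to the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) clamp(((x - x1) * dx + (y - y1) * dy) / len2, 0, 1) else 0
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
  }
  inside | on_edge
}

# Linear interpolation that returns NA outside the support.
interp1 <- function(t, v, tout) {
  stats::approx(t, v, xout = tout, method = "linear", rule = 1, ties = "ordered")$y
}

# Periodic Hann window: a sinusoid at an exact bin frequency contributes
# nothing beyond +/-2 bins, which keeps sub-band signal out of the analysis
# band exactly.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}
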