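# Internal helpers: seeded evaluation, truncated-normal sampling, hashing.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness flows through this so that no function perturbs
# global random state as a side effect.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# Inverse-CDF draw from a normal truncated to [lo, hi], driven by a uniform
# u in (0,1). Equivalent to rejection sampling (no point mass at the bounds)
# but deterministic given u, which keeps copula correlations intact.
qnorm_trunc <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) {
    return(rep(mean, length(u)))
  }
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

# Inverse-CDF draw from a log-normal moment-matched to the target mean/SD
# (natural scale). Used for right-skewed, non-negative urine measures.
qlnorm_match <- function(u, mean, sd) {
  if (sd == 0) {
    return(rep(mean, length(u)))
  }
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  stats::qlnorm(u, meanlog = mu, sdlog = sqrt(sigma2))
}

# Solve for the (mu, sigma) of an untruncated normal such that, after
# truncation to [lo, hi], the distribution has the requested mean and SD.
# Without this, truncating (e.g. age to [18, 98]) would shift the realized
# mean away from its calibration target.
trunc_norm_params <- function(mean, sd, lo, hi) {
  if (sd == 0 || (is.infinite(lo) && is.infinite(hi))) {
    return(c(mu = mean, sigma = sd))
  }
  moments <- function(mu, sig) {
    a <- (lo - mu) / sig
    b <- (hi - mu) / sig
    Z <- stats::pnorm(b) - stats::pnorm(a)
    lam <- (stats::dnorm(a) - stats::dnorm(b)) / Z
    m <- mu + sig * lam
    v <- sig^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - lam^2)
    c(m, sqrt(pmax(v, 0)))
  }
  obj <- function(par) {
    if (par[2] <= 0) {
      return(1e10)
    }
    sum((moments(par[1], par[2]) - c(mean, sd))^2)
  }
  sol <- stats::optim(c(mean, sd), obj, control = list(reltol = 1e-14, maxit = 2000))
  c(mu = sol$par[1], sigma = sol$par[2])
}

# 32-bit FNV-1a over a character serialization; used only to stamp output
# files with a short configuration fingerprint.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); keeps h a double, avoiding the
    # 32-bit limits of bitwXor
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, split into
    # 16-bit halves so intermediates stay under 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
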