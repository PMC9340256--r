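# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Triangular(min, mode, max) sampler by inverse CDF.
rtriangular <- function(n, min, mode, max) {
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(fn, x, eps = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x), 1) * eps
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

sample_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- var(x)
  z <- x - m
  list(mean = m,
       variance = s2,
       skewness = mean(z^3) / s2^1.5,
       kurtosis = mean(z^4) / s2^2 - 3)
}
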