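# internal helpers: deterministic seed streams, truncated normals, rounding

# stable 31-based string hash in [0, 2^31-2]; exact in double arithmetic
# because intermediate values stay below 2^31 * 31 + 255 < 2^53
stableHash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  h
}

# per-scan RNG seed derived from the master seed and the scan id
scanSeed <- function(masterSeed, id) {
  as.integer((as.numeric(masterSeed) %% 2147483647 * 48271 + stableHash(id)) %%
               2147483647)
}

# inverse-CDF truncated normal; exact and vectorised, no rejection loop
rtruncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# largest-remainder rounding of n * w to integer counts summing to n
largestRemainderCounts <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }
  as.integer(cnt)
}

# ellipsoid mask on a voxel grid (0-based voxel index convention: the centre
# is given in 0-based coordinates, matching the stored mask orientation)
ellipsoidMask <- function(dim3, center, semi) {
  ix <- (seq_len(dim3[1]) - 1 - center[1]) / semi[1]
  iy <- (seq_len(dim3[2]) - 1 - center[2]) / semi[2]
  iz <- (seq_len(dim3[3]) - 1 - center[3]) / semi[3]
  r2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  array(r2 <= 1, dim = dim3)
}

emptyMask <- function(dim3) array(FALSE, dim = dim3)

`%||%` <- function(a, b) if (is.null(a)) b else a
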