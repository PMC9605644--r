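# Independent brute-force oracles, deliberately written as plain scalar
# loops so they share no code path with the implementation.

# even-odd point-in-polygon with boundary counted as inside
oracle_point_in_polygon <- function(qx, qy, px, py, eps = 1e-9) {
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- (xj - xi) * (qy - yi) - (yj - yi) * (qx - xi)
    if (abs(cross) <= eps * (abs(xj - xi) + abs(yj - yi) + 1) &&
        qx >= min(xi, xj) - eps && qx <= max(xi, xj) + eps &&
        qy >= min(yi, yj) - eps && qy <= max(yi, yj) + eps) {
      return(TRUE)
    }
    if ((yi > qy) != (yj > qy)) {
      xint <- xi + (qy - yi) * (xj - xi) / (yj - yi)
      if (qx < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(polys, height, width) {
  out <- matrix(0, height, width)
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      for (poly in polys) {
        if (oracle_point_in_polygon(j - 1, i - 1, poly$x, poly$y)) {
          out[i, j] <- 1
          break
        }
      }
    }
  }
  out
}

# sliding-window max/min filter over a k x k box clipped at the borders
# (equivalent to a reflective border for rank filters)
oracle_rank_filter <- function(x, k, fun) {
  h <- nrow(x); w <- ncol(x); r <- (k - 1) / 2
  out <- x
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- max(1, i - r):min(h, i + r)
      jj <- max(1, j - r):min(w, j + r)
      out[i, j] <- fun(x[ii, jj])
    }
  }
  out
}

oracle_gradient <- function(x, k) {
  oracle_rank_filter(x, k, max) - oracle_rank_filter(x, k, min)
}

oracle_binary_closing <- function(mask, k) {
  dil <- oracle_rank_filter(mask, k, max)
  oracle_rank_filter(dil, k, min)
}

# per-pixel Gaussian-weighted local mean threshold, direct nested loops
oracle_adaptive_binarize <- function(resp, block, c_offset) {
  h <- nrow(resp); w <- ncol(resp); r <- (block - 1) / 2
  sigma <- block / 6
  d <- seq(-r, r)
  g1 <- exp(-d^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  # reflective padding by direct index mirroring
  refl <- function(i, n) {
    i <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n) + 1
    ifelse(i > n, 2 * n - i + 1, i)
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (a in seq_len(block)) {
        for (b in seq_len(block)) {
          acc <- acc + kern[a, b] * resp[refl(i + a - r - 1, h), refl(j + b - r - 1, w)]
        }
      }
      out[i, j] <- as.numeric(resp[i, j] - acc > c_offset)
    }
  }
  out
}

# classical global histogram equalization on the 0-255 scale
oracle_hist_equalize <- function(img) {
  v <- floor(as.vector(img))
  counts <- rep(0, 256)
  for (p in v) counts[p + 1] <- counts[p + 1] + 1
  cdf <- cumsum(counts) / length(v)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min >= 1) return(img)
  lut <- pmin(pmax(floor(255 * (cdf - cdf_min) / (1 - cdf_min) + 0.5), 0), 255)
  matrix(lut[v + 1], nrow(img), ncol(img))
}

# coarse-to-fine grid search for least-squares (m, b)
oracle_grid_ols <- function(x, y) {
  sse <- function(m, b) sum((y - m * x - b)^2)
  m0 <- 0; b0 <- mean(y); span <- max(abs(y)) + max(abs(x)) + 1
  offsets <- seq(-3, 3, by = 0.25)
  grid_mb <- expand.grid(dm = offsets, db = offsets)
  for (step in span * 0.6^(0:60)) {
    ms <- m0 + grid_mb$dm * step
    bs <- b0 + grid_mb$db * step
    errs <- mapply(sse, ms, bs)
    best <- which.min(errs)
    m0 <- ms[best]; b0 <- bs[best]
  }
  c(m = m0, b = b0)
}

random_polygon <- function(n = NULL, lim = 31) {
  if (is.null(n)) n <- sample(3:8, 1)
  # star-shaped polygon around a random center: simple by construction
  cx <- runif(1, 0.35 * lim, 0.65 * lim)
  cy <- runif(1, 0.35 * lim, 0.65 * lim)
  ang <- sort(runif(n, 0, 2 * pi))
  max_rad <- max(1.5, min(cx, cy, lim - cx, lim - cy))
  rad <- runif(n, 1, max_rad)
  list(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}
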