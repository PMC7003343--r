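# Independent brute-force oracles for the matrix texture families and the
# wavelet transform. These enumerate voxel pairs / runs / zones explicitly
# in plain R and compute every feature from its defining sum, sharing no
# code with the package implementation.

oracleOffsets <- function() {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
         (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
}

# --- GLCM ------------------------------------------------------------------
oracleGLCMmatrix <- function(lev, nL, off) {
  d <- dim(lev)
  P <- matrix(0, nL, nL)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
      next
    b <- lev[x2, y2, z2]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracleGLCMfeatures <- function(P) {
  n <- nrow(P)
  P <- P / sum(P)
  f <- numeric(22)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:n) * px); muy <- sum((1:n) * py)
  sx <- sqrt(sum(((1:n) - mux)^2 * px)); sy <- sqrt(sum(((1:n) - muy)^2 * py))
  ent <- 0; hxy1 <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    f[1] <- f[1] + (i - j)^2 * p
    f[2] <- f[2] + abs(i - j) * p
    f[3] <- f[3] + p / (1 + abs(i - j))
    f[4] <- f[4] + p / (1 + (i - j)^2)
    f[5] <- f[5] + p^2
    if (p > 0) ent <- ent - p * log2(p)
    f[8] <- f[8] + i * j * p
    f[9] <- f[9] + (i + j - mux - muy)^3 * p
    f[10] <- f[10] + (i + j - mux - muy)^4 * p
    f[11] <- f[11] + (i + j - mux - muy)^2 * p
    if (p > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - p * log2(px[i] * py[j])
    f[21] <- f[21] + p / (1 + ((i - j) / n)^2)
    f[22] <- f[22] + p / (1 + abs(i - j) / n)
  }
  f[6] <- ent
  f[7] <- if (sx * sy > 0) (f[8] - mux * muy) / (sx * sy) else 1
  f[12] <- max(P)
  ps <- sapply(2:(2 * n), function(k) sum(P[row(P) + col(P) == k]))
  pd <- sapply(0:(n - 1), function(k) sum(P[abs(row(P) - col(P)) == k]))
  ks <- 2:(2 * n); kd <- 0:(n - 1)
  f[13] <- sum(ks * ps)
  f[14] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  f[15] <- sum((ks - f[13])^2 * ps)
  f[16] <- sum(kd * pd)
  f[17] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  f[18] <- sum((kd - f[16])^2 * pd)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy2 <- 0
  for (i in 1:n) for (j in 1:n)
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  f[19] <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  f[20] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  f
}

oracleGLCM <- function(lev, nL) {
  offs <- oracleOffsets()
  acc <- numeric(22); used <- 0
  for (k in seq_len(nrow(offs))) {
    P <- oracleGLCMmatrix(lev, nL, offs[k, ])
    if (sum(P) == 0) next
    acc <- acc + oracleGLCMfeatures(P)
    used <- used + 1
  }
  acc / used
}

# --- GLRLM -----------------------------------------------------------------
oracleRuns <- function(lev, off) {
  d <- dim(lev)
  runs <- list()
  inside <- function(x, y, z)
    x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    xp <- x - off[1]; yp <- y - off[2]; zp <- z - off[3]
    if (inside(xp, yp, zp) && !is.na(lev[xp, yp, zp]) &&
        lev[xp, yp, zp] == a) next
    len <- 1
    xc <- x + off[1]; yc <- y + off[2]; zc <- z + off[3]
    while (inside(xc, yc, zc) && !is.na(lev[xc, yc, zc]) &&
           lev[xc, yc, zc] == a) {
      len <- len + 1
      xc <- xc + off[1]; yc <- yc + off[2]; zc <- zc + off[3]
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  do.call(rbind, runs)
}

oracleGLRLMfeatures <- function(runs, Np) {
  i <- runs[, 1]; j <- runs[, 2]
  Nr <- nrow(runs)
  p <- rep(1 / Nr, Nr)
  cellp <- as.vector(table(paste(i, j))) / Nr
  c(sum(p / j^2), sum(p * j^2),
    sum(tapply(rep(1, Nr), i, sum)^2) / Nr,
    sum(tapply(rep(1, Nr), i, sum)^2) / Nr^2,
    sum(tapply(rep(1, Nr), j, sum)^2) / Nr,
    sum(tapply(rep(1, Nr), j, sum)^2) / Nr^2,
    Nr / Np,
    sum(p * (i - mean(i))^2), sum(p * (j - mean(j))^2),
    -sum(cellp * log2(cellp)),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
    sum(p * j^2 / i^2), sum(p * i^2 * j^2))
}

oracleGLRLM <- function(lev, Np) {
  offs <- oracleOffsets()
  acc <- numeric(16)
  for (k in seq_len(nrow(offs)))
    acc <- acc + oracleGLRLMfeatures(oracleRuns(lev, offs[k, ]), Np)
  acc / nrow(offs)
}

# --- GLZSM -----------------------------------------------------------------
oracleZones <- function(lev) {
  d <- dim(lev)
  lab <- array(0L, d)
  zones <- list()
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  nz <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(lev[x, y, z]) || lab[x, y, z] > 0) next
    nz <- nz + 1
    queue <- matrix(c(x, y, z), 1)
    lab[x, y, z] <- nz
    size <- 0
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1
      for (k in seq_len(nrow(nbhd))) {
        w <- v + nbhd[k, ]
        if (any(w < 1) || any(w > d)) next
        if (!is.na(lev[w[1], w[2], w[3]]) && lab[w[1], w[2], w[3]] == 0 &&
            lev[w[1], w[2], w[3]] == lev[v[1], v[2], v[3]]) {
          lab[w[1], w[2], w[3]] <- nz
          queue <- rbind(queue, w)
        }
      }
    }
    zones[[nz]] <- c(lev[x, y, z], size)
  }
  do.call(rbind, zones)
}

oracleGLZSM <- function(lev, Np) {
  zs <- oracleZones(lev)
  i <- zs[, 1]; s <- zs[, 2]
  Nz <- nrow(zs)
  p <- rep(1 / Nz, Nz)
  cellp <- as.vector(table(paste(i, s))) / Nz
  c(sum(p / s^2), sum(p * s^2),
    sum(tapply(rep(1, Nz), i, sum)^2) / Nz,
    sum(tapply(rep(1, Nz), s, sum)^2) / Nz,
    Nz / Np,
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * s^2)), sum(p * i^2 / s^2),
    sum(p * s^2 / i^2), sum(p * i^2 * s^2),
    sum(p * (i - mean(i))^2), sum(p * (s - mean(s))^2),
    -sum(cellp * log2(cellp)))
}

# --- wavelet ----------------------------------------------------------------
# Direct convolution with half-sample symmetric reflection, one tap at a
# time, against which the package's separable filtering is checked.
oracleWavelet <- function(v, lo, hi, label) {
  d <- dim(v)
  reflect <- function(i, n) ifelse(i > n, 2 * n + 1 - i, i)
  filt <- list(L = lo, H = hi)
  h1 <- filt[[substr(label, 1, 1)]]
  h2 <- filt[[substr(label, 2, 2)]]
  h3 <- filt[[substr(label, 3, 3)]]
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(h1)) for (b in seq_along(h2))
      for (cc in seq_along(h3)) {
        xi <- reflect(x + a - 1, d[1])
        yi <- reflect(y + b - 1, d[2])
        zi <- reflect(z + cc - 1, d[3])
        acc <- acc + h1[a] * h2[b] * h3[cc] * v[xi, yi, zi]
      }
    out[x, y, z] <- acc
  }
  out
}

# --- first-order -----------------------------------------------------------
oracleHistogram <- function(x, nBins) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  q <- quantile(x, c(.05, .10, .25, .50, .75, .90, .95), names = FALSE)
  xr <- x[x >= q[2] & x <= q[6]]
  if (max(x) == min(x)) {
    pr <- 1; modeBin <- 1
  } else {
    w <- (max(x) - min(x)) / nBins
    lv <- pmin(floor((x - min(x)) / w) + 1, nBins)
    cnt <- table(factor(lv, levels = 1:nBins))
    modeBin <- unname(which.max(cnt))
    pr <- as.numeric(cnt[cnt > 0]) / n
  }
  c(mu, median(x), min(x), max(x), max(x) - min(x), m2, sqrt(m2),
    if (m2 > 0) m3 / m2^1.5 else 0, if (m2 > 0) m4 / m2^2 else 0,
    sum(x^2), sqrt(sum(x^2) / n), -sum(pr * log2(pr)), sum(pr^2),
    q, q[5] - q[3], sum(abs(x - mu)) / n,
    if (length(xr)) sum(abs(xr - sum(xr) / length(xr))) / length(xr) else 0,
    if (mu != 0) sqrt(m2) / mu else 0, modeBin)
}
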