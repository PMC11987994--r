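# Brute-force oracles, independent of the package's code paths.

# gift-wrapping (Jarvis march) convex hull of a point set, CCW in (x, y)
oracleHull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (k in seq_len(n)) {
      if (k == cur || k == cand) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_cand <- sum((pts[cand, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < -1e-12 || (abs(cr) <= 1e-12 && d_k > d_cand)) cand <- k
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# polygon area and centroid by triangle-fan decomposition from vertex 1
oracleAreaCentroid <- function(poly) {
  n <- nrow(poly)
  A <- 0; cx <- 0; cy <- 0
  for (k in 2:(n - 1)) {
    x1 <- poly[1, 1]; y1 <- poly[1, 2]
    x2 <- poly[k, 1]; y2 <- poly[k, 2]
    x3 <- poly[k + 1, 1]; y3 <- poly[k + 1, 2]
    a <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
    A <- A + a
    cx <- cx + a * (x1 + x2 + x3) / 3
    cy <- cy + a * (y1 + y2 + y3) / 3
  }
  list(area = abs(A), centroid = c(cx / A, cy / A))
}

# blob measurement by explicit pixel enumeration: corner-point hull,
# fan area/centroid
oracleBlobMeasure <- function(us, vs) {
  pts <- unique(cbind(c(us, us + 1, us, us + 1),
                      c(vs, vs, vs + 1, vs + 1)))
  h <- oracleHull(pts)
  oracleAreaCentroid(h)
}

# largest 8-connected component by explicit BFS over an R matrix
oracleLargestComponent <- function(mask, min_area = 1) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  best <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || seen[i, j]) next
    comp <- matrix(c(i, j), 1)
    seen[i, j] <- TRUE
    q <- list(c(i, j))
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        if (mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          comp <- rbind(comp, c(ii, jj))
          q <- c(q, list(c(ii, jj)))
        }
      }
    }
    if (nrow(comp) >= min_area &&
        (is.null(best) || nrow(comp) > nrow(best))) best <- comp
  }
  best
}

# Kruskal-Wallis H with tie correction from first principles
oracleKW <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  ord <- order(x)
  r <- numeric(N)
  i <- 1
  while (i <= N) {                       # explicit mid-ranking of ties
    j <- i
    while (j < N && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  gi <- rep(seq_along(groups), vapply(groups, length, 1L))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, gi, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  tt <- table(x)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr > 0) H <- H / corr else H <- 0
  H
}

# Dunn pairwise z matrix from first principles (same mid-ranks as oracleKW)
oracleDunnZ <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  ord <- order(x)
  r <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  gi <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(r, gi, mean)
  n <- tapply(r, gi, length)
  tt <- table(x)
  varfac <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  k <- length(groups)
  z <- matrix(0, k, k)
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    se <- sqrt(varfac * (1 / n[a] + 1 / n[b]))
    z[a, b] <- (rbar[a] - rbar[b]) / se
    z[b, a] <- -z[a, b]
  }
  z
}

# mean of a normal truncated below at 0
oracleTruncNormMean <- function(mu, sigma) {
  a <- (0 - mu) / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}
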