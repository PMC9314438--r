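# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most naive formulation available.

# closed-form crossed-polarizer signal at the 18 acquisition angles
model18 <- function(A = 1, phi = 0, offset = 0, angles = seq(0, 85, by = 5)) {
  A * sin(2 * (angles - phi) * pi / 180)^2 + offset
}

# build a stack in which every pixel has the same angular profile `y`
uniform_stack <- function(y, h = 2, w = 2) {
  polar_stack(array(rep(y, each = h * w), dim = c(h, w, length(y))),
              angles = seq(0, by = 5, length.out = length(y)))
}

# O(n^2) windowed mean pairwise wrapped angular difference
oracle_mad <- function(orient, w) {
  h <- nrow(orient); wd <- ncol(orient)
  half <- (w - 1) %/% 2
  out <- matrix(NA_real_, h, wd)
  for (r in (half + 1):(h - half)) {
    for (c in (half + 1):(wd - half)) {
      v <- as.vector(orient[(r - half):(r + half), (c - half):(c + half)])
      s <- 0
      for (i in 1:(length(v) - 1)) for (j in (i + 1):length(v)) {
        d <- abs(v[i] - v[j])
        s <- s + min(d, 90 - d)
      }
      out[r, c] <- s / (length(v) * (length(v) - 1) / 2)
    }
  }
  out
}

# naive symmetric GLCM by explicit pair counting
oracle_glcm <- function(q, direction, distance = 1, levels = 8) {
  off <- switch(as.character(direction),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  G <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      G[q[r, c], q[r2, c2]] <- G[q[r, c], q[r2, c2]] + 1
      G[q[r2, c2], q[r, c]] <- G[q[r2, c2], q[r, c]] + 1
    }
  }
  G / sum(G)
}

# naive double-loop Haralick features
oracle_haralick <- function(p) {
  n <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mi <- sum((1:n) * px); mj <- sum((1:n) * py)
  si <- sqrt(sum((1:n - mi)^2 * px)); sj <- sqrt(sum((1:n - mj)^2 * py))
  contrast <- 0; corr_num <- 0; energy <- 0; homog <- 0; entropy <- 0
  for (i in 1:n) for (j in 1:n) {
    v <- p[i, j]
    contrast <- contrast + v * (i - j)^2
    corr_num <- corr_num + (i - mi) * (j - mj) * v
    energy <- energy + v^2
    homog <- homog + v / (1 + abs(i - j))
    if (v > 0) entropy <- entropy - v * log2(v)
  }
  c(contrast = contrast,
    correlation = if (si * sj > 0) corr_num / (si * sj) else 0,
    energy = energy, homogeneity = homog, entropy = entropy)
}

# exact two-tailed Fisher p by full enumeration over the feasible a-cell,
# using the standard "no more probable than observed" rule
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# reference FCM membership for one point given centroids (fuzzifier m)
oracle_fcm_membership <- function(xrow, centers, m = 2) {
  d2 <- apply(centers, 1, function(cc) sum((xrow - cc)^2))
  if (any(d2 == 0)) return(as.numeric(d2 == 0) / sum(d2 == 0))
  u <- sapply(seq_len(nrow(centers)), function(ci)
    1 / sum((d2[ci] / d2)^(1 / (m - 1))))
  u
}
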