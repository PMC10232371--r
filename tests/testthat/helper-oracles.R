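# Independent oracles used to freeze expected values. These deliberately
# use different algorithms from the package implementation.

# bisection on the 1:1 complexation mass balance; returns free metal
bisect_free_metal <- function(m_t, l_t, k, tol = 1e-14) {
  if (k == 0 || l_t == 0 || m_t == 0) return(m_t)
  f <- function(x) {
    ml <- m_t - x
    k * x * (l_t - ml) - ml  # K*[M]*[L] = [ML]
  }
  lo <- 0; hi <- m_t
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# bisection on 2 m^2 + K m - K p = 0
bisect_monomer <- function(p, k) {
  f <- function(m) 2 * m^2 + k * m - k * p
  lo <- 0; hi <- p
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# plain Needleman-Wunsch with affine gaps (gap open charged on first gap
# residue: open + ext), returning score and an optimal aligned pair
nw_align <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e9
  M <- X <- Y <- matrix(neg, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force coordination count: all atoms of elements O/N within cutoff
# of the metal position, excluding the metal's own residue
brute_cn <- function(model, site, cutoff = 3.0) {
  a <- model$atoms
  cnt <- 0
  for (i in seq_len(nrow(a))) {
    if (!(a$element[i] %in% c("O", "N"))) next
    if (a$chain[i] == site$chain && a$resno[i] == site$resno &&
        a$resid[i] == site$resid) next
    d <- sqrt((a$x[i] - site$x)^2 + (a$y[i] - site$y)^2 +
                (a$z[i] - site$z)^2)
    if (d <= cutoff) cnt <- cnt + 1
  }
  cnt
}

# trapezoid integration of a continuous two-peak elution model over a
# window, for purity/yield cross-checks against the fraction-based path
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# rigid rotation about z then y by given angles (radians)
rotate_model <- function(model, az = 0.7, ay = 0.3, shift = c(5, -3, 2)) {
  rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3,
               byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rz %*% ry)
  m2 <- model
  m2$atoms$x <- xyz[, 1] + shift[1]
  m2$atoms$y <- xyz[, 2] + shift[2]
  m2$atoms$z <- xyz[, 3] + shift[3]
  m2
}
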