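# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; no stored data.

# --- histogram fixtures -------------------------------------------------

# Random mixture of 1-3 discretized Gaussians over gray levels 0..255.
random_hist <- function(seed, k = NULL) {
  set.seed(seed)
  k <- if (is.null(k)) sample(1:3, 1) else k
  w <- stats::runif(k)
  w <- w / sum(w)
  mu <- stats::runif(k, 20, 235)
  sd <- stats::runif(k, 5, 30)
  g <- 0:255
  p <- numeric(256)
  for (i in seq_len(k)) p <- p + w[i] * stats::dnorm(g, mu[i], sd[i])
  p / sum(p)
}

# Two-delta histogram: all mass at the two given levels.
delta2_hist <- function(lev1 = 50, lev2 = 200, w1 = 0.5) {
  p <- numeric(256)
  p[lev1 + 1] <- w1
  p[lev2 + 1] <- 1 - w1
  p
}

# --- independent threshold-criterion oracles ----------------------------
# Direct-formula implementations, written as plain loops over the class
# partition [0..t] / [t+1..255]; independent of the package's shared
# optimizer machinery.

.osplit <- function(p, t) {
  lo <- 1:(t + 1)
  hi <- (t + 2):256
  list(lo = lo, hi = hi, w0 = sum(p[lo]), w1 = sum(p[hi]))
}

oracle_within_class_variance <- function(p, t) {
  g <- 0:255
  s <- .osplit(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  mu0 <- sum(p[s$lo] * g[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g[s$hi]) / s$w1
  sum(p[s$lo] * (g[s$lo] - mu0)^2) + sum(p[s$hi] * (g[s$hi] - mu1)^2)
}

oracle_neg_kapur_entropy <- function(p, t) {
  s <- .osplit(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  -(ent(p[s$lo] / s$w0) + ent(p[s$hi] / s$w1))
}

oracle_cross_entropy <- function(p, t) {
  g1 <- 1:256  # +1 intensity shift
  s <- .osplit(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  mu0 <- sum(p[s$lo] * g1[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g1[s$hi]) / s$w1
  sum(g1[s$lo] * p[s$lo] * log(g1[s$lo] / mu0)) +
    sum(g1[s$hi] * p[s$hi] * log(g1[s$hi] / mu1))
}

oracle_kittler_illingworth <- function(p, t) {
  g <- 0:255
  s <- .osplit(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  mu0 <- sum(p[s$lo] * g[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g[s$hi]) / s$w1
  v0 <- sum(p[s$lo] * (g[s$lo] - mu0)^2) / s$w0
  v1 <- sum(p[s$hi] * (g[s$hi] - mu1)^2) / s$w1
  if (v0 <= 0 || v1 <= 0) return(NA_real_)
  1 + 2 * (s$w0 * log(sqrt(v0)) + s$w1 * log(sqrt(v1))) -
    2 * (s$w0 * log(s$w0) + s$w1 * log(s$w1))
}

oracle_fuzzy_entropy <- function(p, t) {
  g <- 0:255
  s <- .osplit(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  occ <- which(p > 0)
  C <- max(occ) - min(occ)
  if (C == 0) return(NA_real_)
  mu0 <- sum(p[s$lo] * g[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g[s$hi]) / s$w1
  mu_class <- c(rep(mu0, t + 1), rep(mu1, 255 - t))
  m <- 1 / (1 + abs(g - mu_class) / C)
  S <- ifelse(m <= 0 | m >= 1, 0, -m * log(m) - (1 - m) * log(1 - m))
  sum(p * S)
}

# Exhaustive minimizer of a criterion over t in 0..254, smallest-t ties.
oracle_argmin <- function(p, criterion) {
  vals <- vapply(0:254, function(t) criterion(p, t), numeric(1))
  which.min(vals) - 1L
}

# Selector t matches the exhaustive oracle, allowing a floating-point
# pseudo-tie (criterion values equal to 1e-9 relative).
expect_matches_oracle <- function(t_impl, p, criterion) {
  t_orc <- oracle_argmin(p, criterion)
  if (t_impl == t_orc) {
    succeed()
    return(invisible(TRUE))
  }
  vi <- criterion(p, t_impl)
  vo <- criterion(p, t_orc)
  expect_true(!is.na(vi) && abs(vi - vo) <= 1e-9 * max(1, abs(vo)),
              label = sprintf("t=%d vs oracle %d (criterion %g vs %g)",
                              t_impl, t_orc, vi, vo))
}

# Independently coded isodata iteration (the paper's Alg. 2 recurrence).
oracle_isodata <- function(p) {
  g <- 0:255
  t <- sum(p * g)
  for (i in 1:100) {
    lo <- g <= t
    w0 <- sum(p[lo]); w1 <- sum(p[!lo])
    mu0 <- if (w0 > 0) sum(p[lo] * g[lo]) / w0 else t
    mu1 <- if (w1 > 0) sum(p[!lo] * g[!lo]) / w1 else t
    t_new <- (mu0 + mu1) / 2
    done <- abs(t_new - t) < 0.5
    t <- t_new
    if (done) break
  }
  as.integer(min(max(round(t), 0), 254))
}

# --- image fixtures -----------------------------------------------------

# The standard clean scene: 256x256, 8 nuclei (2 abnormal), noise sigma 8.
std_scene <- function(seed = 11) generate_scene(scene_config(seed = seed))

# The standard degraded fixture: clean scene plus Gaussian noise, blob
# artefacts, and fine impulse debris.
std_degraded <- function(scene) {
  degrade_image(scene$clean, noise_sigma = 10, n_artefacts = 40,
                seed = scene$config$seed, impulse_frac = 0.02)
}

# Dark disk (level fg) of given radius on a bright field (level bg).
disk_image <- function(n = 128, radius = 30, fg = 70, bg = 220,
                       center = c(n / 2, n / 2)) {
  r <- matrix(seq_len(n), n, n) - center[1]
  c <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  img <- matrix(bg, n, n)
  img[r^2 + c^2 <= radius^2] <- fg
  img
}

disk_mask <- function(n = 128, radius = 30, center = c(n / 2, n / 2)) {
  disk_image(n, radius, fg = 0, bg = 255, center = center) == 0
}

# Under-segmenting Chan-Vese init: 5x5 seed squares at alternate nuclei.
seed_init_mask <- function(scene) {
  d <- dim(scene$image)
  init <- matrix(FALSE, d[1], d[2])
  nz <- scene$nuclei[seq(1, nrow(scene$nuclei), by = 2), ]
  for (i in seq_len(nrow(nz))) {
    rr <- round(nz$center_r[i])
    cc <- round(nz$center_c[i])
    init[max(1, rr - 2):min(d[1], rr + 2),
         max(1, cc - 2):min(d[2], cc + 2)] <- TRUE
  }
  init
}
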