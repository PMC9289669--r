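# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# Kendall's W by direct evaluation of the rank-sum formula.
kendall_oracle <- function(series, tie_correction = FALSE) {
  K <- nrow(series); n <- ncol(series)
  R <- matrix(0, K, n)
  for (j in seq_len(K)) R[j, ] <- rank(series[j, ], ties.method = "average")
  Rt <- numeric(n)
  for (t in seq_len(n)) Rt[t] <- sum(R[, t])
  Rbar <- K * (n + 1) / 2
  S <- sum((Rt - Rbar)^2)
  den <- K^2 * (n^3 - n) / 12
  if (tie_correction) {
    Tj <- 0
    for (j in seq_len(K)) {
      tt <- as.numeric(table(series[j, ]))
      Tj <- Tj + sum(tt^3 - tt)
    }
    den <- den - K * Tj / 12
  }
  S / den
}

# Benjamini-Hochberg step-up by explicit scan of the ordered p-values.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  istar <- 0L
  for (i in seq_len(m)) if (ps[i] <= i / m * q) istar <- i
  rej <- logical(m)
  if (istar > 0) rej[o[seq_len(istar)]] <- TRUE
  rej
}

# Connected components by breadth-first flood fill over an explicit queue.
floodfill_oracle <- function(binary, connectivity = 26) {
  sh <- dim(binary)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1), ,
             drop = FALSE]
  lab <- array(0L, dim = sh)
  cur <- 0L
  todo <- which(binary, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    v <- todo[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (s in seq_len(nrow(off))) {
        w <- u + off[s, ]
        if (any(w < 1) || any(w > sh)) next
        if (!binary[w[1], w[2], w[3]]) next
        if (lab[w[1], w[2], w[3]] != 0L) next
        lab[w[1], w[2], w[3]] <- cur
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  lab
}

# ellipsoidal analysis mask inscribed in a grid (test fixture helper)
ellipsoid_grid_mask <- function(shape, margin = 1) {
  ctr <- (shape + 1) / 2
  semi <- shape / 2 - margin
  out <- array(FALSE, dim = shape)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3]))
      if (((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
          ((k - ctr[3]) / semi[3])^2 <= 1) out[i, j, k] <- TRUE
  out
}

# logical sphere on a grid (test fixture helper)
sphere_block <- function(shape, center, radius) {
  out <- array(FALSE, dim = shape)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3]))
      if (sum((c(i, j, k) - center)^2) <= radius^2) out[i, j, k] <- TRUE
  out
}

# white-noise BOLD series on a fully masked grid
white_bold <- function(shape, nt, seed = 1, tr = 2.4) {
  set.seed(seed)
  g <- image_grid(shape)
  bold_series(array(stats::rnorm(prod(shape) * nt), dim = c(shape, nt)),
              g, tr, "wn")
}

# small cohort configuration for fast tests (clusters placed for the
# 16 x 18 x 16 grid so they stay inside the ellipsoidal mask)
quick_cohort_config <- function(...) {
  cohort_config(grid_shape = c(16, 18, 16), n_timepoints = 24,
                n_per_group = c(pre_rt = 5, post_rt_re_neg = 5,
                                post_rt_re_pos = 5),
                n_missing_dose = c(post_rt_re_neg = 1L, post_rt_re_pos = 1L),
                effect_clusters = list(
                  list(name = "deep_gray", center = c(9, 10, 9),
                       radius_vox = 2,
                       effects = c(pre_rt = 0, post_rt_re_neg = 0.5,
                                   post_rt_re_pos = 1.2)),
                  list(name = "medial_temporal", center = c(6, 8, 6),
                       radius_vox = 1.5,
                       effects = c(pre_rt = 0, post_rt_re_neg = -0.5,
                                   post_rt_re_pos = -1.2))),
                ...)
}

# one shared full-size cohort (study-default configuration), built lazily
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- generate_cohort(cohort_config(), seed = 101L)
    .cohort_cache$coupling <- cohort_coupling_maps(.cohort_cache$cohort)
  }
  list(cohort = .cohort_cache$cohort, coupling = .cohort_cache$coupling)
}
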