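# Independent brute-force re-implementations used as oracles. These walk
# voxel pairs and runs explicitly and share no code with the package's
# vectorized engines.

.oracle_step <- function(angle) {
  switch(as.character(angle),
         `0` = c(0L, 1L), `45` = c(-1L, 1L),
         `90` = c(-1L, 0L), `135` = c(-1L, -1L))
}

# GLCM by explicit enumeration of every in-mask ordered voxel pair
brute_glcm <- function(levels, G, offset, angle) {
  st <- .oracle_step(angle) * offset
  d <- dim(levels)
  m <- matrix(0, G, G)
  for (z in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    i <- levels[r, c, z]
    if (is.na(i)) next
    r2 <- r + st[1]; c2 <- c + st[2]
    if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
    j <- levels[r2, c2, z]
    if (is.na(j)) next
    m[i, j] <- m[i, j] + 1
    m[j, i] <- m[j, i] + 1
  }
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

# RLM by explicit chain walking and manual run splitting
brute_rlm <- function(levels, G, offset, angle) {
  st <- .oracle_step(angle) * offset
  d <- dim(levels)
  runs_lev <- integer(0); runs_len <- integer(0)
  for (z in seq_len(d[3])) {
    sl <- matrix(levels[, , z], d[1], d[2])
    for (r0 in seq_len(d[1])) for (c0 in seq_len(d[2])) {
      # chain starts where the predecessor falls outside the grid
      rp <- r0 - st[1]; cp <- c0 - st[2]
      if (rp >= 1 && rp <= d[1] && cp >= 1 && cp <= d[2]) next
      r <- r0; c <- c0
      cur <- NA_integer_; len <- 0L
      while (r >= 1 && r <= d[1] && c >= 1 && c <= d[2]) {
        v <- sl[r, c]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1L
        } else {
          if (!is.na(cur)) { runs_lev <- c(runs_lev, cur); runs_len <- c(runs_len, len) }
          cur <- v; len <- if (is.na(v)) 0L else 1L
          if (is.na(v)) cur <- NA_integer_
        }
        r <- r + st[1]; c <- c + st[2]
      }
      if (!is.na(cur)) { runs_lev <- c(runs_lev, cur); runs_len <- c(runs_len, len) }
    }
  }
  if (length(runs_lev) == 0) return(NULL)
  R <- max(runs_len)
  m <- matrix(0, G, R)
  for (k in seq_along(runs_lev))
    m[runs_lev[k], runs_len[k]] <- m[runs_lev[k], runs_len[k]] + 1
  m
}

# literal-formula GLCM statistics, written independently
brute_glcm_stats <- function(p) {
  G <- nrow(p)
  e <- 0; h <- 0; inert <- 0; idm <- 0; cs <- 0; cp <- 0
  mx <- 0; my <- 0
  for (i in 1:G) for (j in 1:G) { mx <- mx + i * p[i, j]; my <- my + j * p[i, j] }
  vx <- 0; vy <- 0; cov <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- p[i, j]
    e <- e + q^2
    if (q > 0) h <- h - q * log2(q)
    inert <- inert + (i - j)^2 * q
    idm <- idm + q / (1 + (i - j)^2)
    cs <- cs + (i + j - mx - my)^3 * q
    cp <- cp + (i + j - mx - my)^4 * q
    vx <- vx + (i - mx)^2 * q; vy <- vy + (j - my)^2 * q
    cov <- cov + (i - mx) * (j - my) * q
  }
  corr <- if (vx > 0 && vy > 0) cov / sqrt(vx * vy) else 0
  c(Energy = e, GLCMEntropy = h, Inertia = inert, Correlation = corr,
    `Inverse Difference Moment` = idm, `Cluster Shade` = cs,
    `Cluster Prominence` = cp, `Haralick Correlation` = corr)
}

# literal-formula RLM statistics
brute_rlm_stats <- function(m, n_voxels) {
  Nr <- sum(m)
  sre <- lre <- lgl <- hgl <- srl <- lrl <- lrh <- 0
  for (i in seq_len(nrow(m))) for (l in seq_len(ncol(m))) {
    q <- m[i, l]
    sre <- sre + q / l^2; lre <- lre + q * l^2
    lgl <- lgl + q / i^2; hgl <- hgl + q * i^2
    srl <- srl + q / (i^2 * l^2); lrl <- lrl + q * l^2 / i^2
    lrh <- lrh + q * l^2 * i^2
  }
  c(`Short Run Emphasis` = sre / Nr, `Long Run Emphasis` = lre / Nr,
    `Gray Level Nonuniformity` = sum(rowSums(m)^2) / Nr,
    `Run Length Nonuniformity` = sum(colSums(m)^2) / Nr,
    `Run Percentage` = Nr / n_voxels,
    `Low Gray Level Run Emphasis` = lgl / Nr,
    `High Gray Level Run Emphasis` = hgl / Nr,
    `Short Run Low Gray Level Emphasis` = srl / Nr,
    `Long Run Low Gray Level Emphasis` = lrl / Nr,
    `Long Run High Gray Level Emphasis` = lrh / Nr)
}

# random quantized ROI on a small grid, with a random mask
random_qroi <- function(dims = c(8, 8, 4), G = 8, p_mask = 0.8) {
  lev <- array(sample.int(G, prod(dims), replace = TRUE), dim = dims)
  msk <- array(runif(prod(dims)) < p_mask, dim = dims)
  if (!any(msk)) msk[1] <- TRUE
  lev[!msk] <- NA_integer_
  structure(list(levels = lev, G = G, n_voxels = sum(msk),
                 spacing = c(1, 1, 1)), class = "hr_qroi")
}

# small constant-intensity volume/mask pair
constant_pair <- function(dims = c(5, 5, 3), value = 7) {
  list(volume = hr_volume(array(value, dims)),
       mask = hr_mask(array(1, dims)))
}

# tiny cohort spec for fast end-to-end tests
tiny_cohort_spec <- function(n = c(6L, 6L), seed = 1L, ...) {
  cohort_spec(n_per_group = n, grid = c(24L, 24L, 16L),
              semi_axes = list(case = c(4.2, 3.2, 2.6),
                               control = c(4.5, 3.5, 3)),
              seed = seed, ...)
}
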