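# Independent brute-force oracles used to verify the package's fast paths.
# These deliberately avoid the implementation's algorithms.

# Convex-hull area by exhaustive edge search: (i, j) is a hull edge when all
# other points lie on one side; hull vertices are ordered by angle around
# their centroid and the area comes from the shoelace formula.
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- pts[j, ] - pts[i, ]
    s <- sapply(seq_len(n)[-c(i, j)], function(k) {
      v <- pts[k, ] - pts[i, ]
      d[1] * v[2] - d[2] * v[1]
    })
    if (all(s <= 1e-12) || all(s >= -1e-12)) on_hull[c(i, j)] <- TRUE
  }
  hv <- pts[on_hull, , drop = FALSE]
  if (nrow(hv) < 3) return(0)
  ctr <- colMeans(hv)
  ord <- order(atan2(hv[, 2] - ctr[2], hv[, 1] - ctr[1]))
  x <- hv[ord, 1]; y <- hv[ord, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Point-in-convex-hull test (closed), for the rasterization occupancy oracle.
oracle_in_hull <- function(p, hull_pts) {
  hv <- unique(as.matrix(hull_pts))
  h <- grDevices::chull(hv)
  hv <- hv[h, , drop = FALSE]
  n <- nrow(hv)
  if (n < 3) return(FALSE)
  sgn <- sapply(seq_len(n), function(i) {
    j <- if (i == n) 1 else i + 1
    d <- hv[j, ] - hv[i, ]
    v <- p - hv[i, ]
    d[1] * v[2] - d[2] * v[1]
  })
  all(sgn >= -1e-9) || all(sgn <= 1e-9)
}

# Occupied cells by rasterizing each cell interior at a fixed step and
# testing sample points against the hull.
oracle_occupied_cells <- function(pts, grid, step = 1) {
  half <- attr(grid, "cell_size") / 2
  hit <- vapply(seq_len(nrow(grid)), function(i) {
    gx <- seq(grid$x[i] - half + step / 2, grid$x[i] + half - step / 2, by = step)
    gy <- seq(grid$y[i] - half + step / 2, grid$y[i] + half - step / 2, by = step)
    for (x in gx) for (y in gy)
      if (oracle_in_hull(c(x, y), pts)) return(TRUE)
    FALSE
  }, logical(1))
  grid$cell_id[hit]
}

# Two-sample KS D by scanning every pooled breakpoint.
oracle_ks_d <- function(a, b, alternative = "two_sided") {
  br <- sort(unique(c(a, b)))
  Fa <- sapply(br, function(t) mean(a <= t))
  Fb <- sapply(br, function(t) mean(b <= t))
  switch(alternative,
         two_sided = max(abs(Fa - Fb)),
         greater = max(Fa - Fb),
         less = max(Fb - Fa))
}

# Exact rank-sum p-value by full enumeration of label assignments.
oracle_ranksum_p <- function(a, b, alternative = "two.sided") {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_of)
  switch(alternative,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

# Clopper-Pearson limits by direct numerical inversion of binomial tails.
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else
    uniroot(function(p) sum(dbinom(k:n, n, p)) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) sum(dbinom(0:k, n, p)) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Plain logistic regression by hand-rolled IRLS (Newton-Raphson).
oracle_irls_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# Small equal-area test grid without SST noise.
toy_grid <- function(nx = 6, ny = 6, cell_size = 50) {
  make_grid(nx, ny, cell_size, sst_noise_sd = 0, seed = 1)
}
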