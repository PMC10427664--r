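## Phylogenetic signal of exploitation across families: the D statistic for
## a binary trait (1 ~ phylogenetically random, 0 ~ Brownian-threshold
## expectation), Pagel's lambda and Blomberg's K for continuous traits such
## as the proportion of exploited species per family.

.match_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait must have one value per tip")
    names(trait) <- tree$tip.label
  }
  off <- setdiff(tree$tip.label, names(trait))
  extra <- setdiff(names(trait), tree$tip.label)
  if (length(off) || length(extra))
    stop("tip/trait mismatch; missing: ", paste(off, collapse = ", "),
         "; extra: ", paste(extra, collapse = ", "))
  trait[tree$tip.label]
}

## Precomputed traversal structure for repeated downpasses on one tree.
.d_prep <- function(tree) {
  tree <- reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  nn <- n_tip + tree$Nnode
  bl0 <- numeric(nn)
  bl0[tree$edge[, 2]] <- tree$edge.length
  bl0[bl0 <= 0] <- 1e-8                # guard zero-length branches
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  parents <- unique(tree$edge[, 1])    # postorder: children before parents
  list(n_tip = n_tip, nn = nn, bl0 = bl0,
       kids = kids[as.character(parents)], parents = parents)
}

## Sum over internal nodes of absolute differences between daughter nodal
## values, with nodal values from a Felsenstein-style weighted-average
## downpass (branch lengths re-weighted as information is combined).
## Polytomies contribute the sum of |daughter - nodal mean|.
.d_sum_prep <- function(prep, x) {
  val <- c(as.numeric(x), rep(NA_real_, prep$nn - prep$n_tip))
  bl <- prep$bl0
  d <- 0
  for (k in seq_along(prep$parents)) {
    ch <- prep$kids[[k]]
    w <- 1 / bl[ch]
    v <- val[ch]
    sw <- sum(w)
    nodal <- sum(w * v) / sw
    val[prep$parents[k]] <- nodal
    d <- d + if (length(ch) == 2) abs(v[1] - v[2]) else sum(abs(v - nodal))
    bl[prep$parents[k]] <- bl[prep$parents[k]] + 1 / sw
  }
  d
}

.d_sum <- function(tree, x) .d_sum_prep(.d_prep(tree), x)

## Brownian motion down the tree: one draw per edge, accumulated preorder.
.bm_prep <- function(tree) {
  tree <- reorder(tree, "cladewise")
  list(edge = tree$edge, sd = sqrt(tree$edge.length),
       n_tip = length(tree$tip.label), nn = length(tree$tip.label) + tree$Nnode)
}

.sim_bm_prep <- function(bm) {
  val <- numeric(bm$nn)
  dev <- rnorm(nrow(bm$edge), 0, bm$sd)
  for (i in seq_len(nrow(bm$edge)))
    val[bm$edge[i, 2]] <- val[bm$edge[i, 1]] + dev[i]
  val[seq_len(bm$n_tip)]
}

.sim_bm <- function(tree) .sim_bm_prep(.bm_prep(tree))

#' Phylogenetic D statistic for a binary trait
#'
#' Measures how a presence/absence trait is dispersed across the tips of a
#' phylogeny. The observed sum of sister-clade differences in estimated
#' nodal values (`d_obs`) is standardized between two simulated null
#' expectations: tip values shuffled at random (D calibrated to 1) and a
#' continuous Brownian trait thresholded to the observed prevalence
#' (D calibrated to 0):
#' `D = (d_obs - mean_d_brownian) / (mean_d_random - mean_d_brownian)`.
#'
#' @param tree an ultrametric `phylo`; polytomies allowed.
#' @param trait 0/1 (or logical) vector named by tip label.
#' @param n_sim simulations per null (>= 100).
#' @param seed optional integer seed.
#' @return list of class `"phylo_d"`: `D`, `p_random` (fraction of random
#'   null `d <= d_obs`, small when the trait is more clumped than random),
#'   `p_brownian` (fraction of Brownian null `d >= d_obs`), `d_obs`,
#'   `mean_d_random`, `mean_d_brownian`, `n_sim`.
#' @export
phylo_d <- function(tree, trait, n_sim = 1000, seed = NULL) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  x <- .match_trait(tree, trait)
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  k <- sum(x)
  n <- length(x)
  if (k == 0 || k == n) stop("trait is monomorphic: both states required")

  prep <- .d_prep(tree)
  bm <- .bm_prep(tree)
  d_obs <- .d_sum_prep(prep, x)
  d_rand <- vapply(seq_len(n_sim), function(i)
    .d_sum_prep(prep, sample(x)), numeric(1))
  d_brown <- vapply(seq_len(n_sim), function(i) {
    z <- .sim_bm_prep(bm)
    b <- as.numeric(rank(-z, ties.method = "random") <= k)
    .d_sum_prep(prep, b)
  }, numeric(1))

  structure(list(
    D = (d_obs - mean(d_brown)) / (mean(d_rand) - mean(d_brown)),
    p_random = mean(d_rand <= d_obs),
    p_brownian = mean(d_brown >= d_obs),
    d_obs = d_obs, mean_d_random = mean(d_rand),
    mean_d_brownian = mean(d_brown), n_sim = n_sim), class = "phylo_d")
}

#' @export
print.phylo_d <- function(x, ...) {
  cat(sprintf("phylo-D = %.3f (d_obs = %.3f; random null %.3f, Brownian null %.3f)\n",
              x$D, x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("p(random) = %.3f, p(Brownian) = %.3f  [%d simulations]\n",
              x$p_random, x$p_brownian, x$n_sim))
  invisible(x)
}

.phylo_mvn <- function(tree, y) {
  C <- ape::vcv(tree)
  y <- y[rownames(C)]
  list(C = C, y = as.numeric(y))
}

.lambda_loglik <- function(lambda, C, y) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  ch <- tryCatch(chol(Cl), error = function(e)
    stop("singular phylogenetic covariance; jitter zero-length branches"))
  n <- length(y)
  Cinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Cinv_y) / sum(Cinv_1)
  r <- y - mu
  Cinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Cinv_r) / n
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Fits the multivariate-normal likelihood of a continuous tip trait under a
#' Brownian covariance whose off-diagonal entries are multiplied by lambda,
#' maximizing over lambda bounded on [0, 1].
#'
#' @param tree a `phylo` (>= 4 tips).
#' @param trait numeric vector named by tip label.
#' @return list of class `"pagel_lambda"`: `lambda`, `logL`, `logL0`
#'   (lambda = 0), `logL1` (lambda = 1).
#' @export
pagel_lambda <- function(tree, trait) {
  if (length(tree$tip.label) < 4) stop("need at least 4 tips")
  y <- .match_trait(tree, trait)
  if (!all(is.finite(y))) stop("non-finite trait values")
  if (sd(y) == 0) stop("trait has zero variance: lambda undefined")
  m <- .phylo_mvn(tree, y)
  opt <- optimize(function(l) .lambda_loglik(l, m$C, m$y),
                  interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  structure(list(lambda = opt$maximum, logL = opt$objective,
                 logL0 = .lambda_loglik(0, m$C, m$y),
                 logL1 = .lambda_loglik(1, m$C, m$y)),
            class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.3f (logL = %.2f; logL[0] = %.2f, logL[1] = %.2f)\n",
              x$lambda, x$logL, x$logL0, x$logL1))
  invisible(x)
}

.k_stat <- function(C, Cinv, y) {
  n <- length(y)
  one <- rep(1, n)
  mu <- as.numeric(one %*% Cinv %*% y) / as.numeric(one %*% Cinv %*% one)
  r <- y - mu
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(r %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / as.numeric(one %*% Cinv %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of among-tip to phylogenetically corrected
#' trait variance with its Brownian expectation on the same tree; K = 1
#' under Brownian motion, K < 1 when close relatives resemble each other
#' less than expected. The p-value is the fraction of tip-shuffled
#' permutations with K at least as large as observed.
#'
#' @param tree a `phylo` with internal structure (a star phylogeny has no
#'   phylogenetically corrected variance to compare and is rejected).
#' @param trait numeric vector named by tip label.
#' @param n_perm permutations for the p-value.
#' @param seed optional integer seed.
#' @return list of class `"blomberg_k"`: `K`, `p_K`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (length(tree$tip.label) < 4) stop("need at least 4 tips")
  if (tree$Nnode < 2) stop("star phylogeny: no internal structure, K degenerate")
  if (!is.null(seed)) set.seed(seed)
  y <- .match_trait(tree, trait)
  if (sd(y) == 0) stop("trait has zero variance: K undefined")
  m <- .phylo_mvn(tree, y)
  Cinv <- tryCatch(solve(m$C), error = function(e)
    stop("singular phylogenetic covariance; jitter zero-length branches"))
  k_obs <- .k_stat(m$C, Cinv, m$y)
  k_perm <- vapply(seq_len(n_perm), function(i)
    .k_stat(m$C, Cinv, sample(m$y)), numeric(1))
  structure(list(K = k_obs, p_K = mean(k_perm >= k_obs), n_perm = n_perm),
            class = "blomberg_k")
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f, p = %.3f (%d permutations)\n",
              x$K, x$p_K, x$n_perm))
  invisible(x)
}

#' Per-family exploitation summary
#'
#' @param records species data.frame with `family` and `exploited` columns.
#' @return data.frame `family, n_species, n_exploited, proportion,
#'   any_exploited`, one row per family.
#' @export
family_exploitation_summary <- function(records) {
  stopifnot(all(c("family", "exploited") %in% names(records)))
  agg <- aggregate(cbind(n_species = rep(1L, nrow(records)),
                         n_exploited = as.integer(records$exploited)),
                   by = list(family = records$family), FUN = sum)
  agg$proportion <- agg$n_exploited / agg$n_species
  agg$any_exploited <- agg$n_exploited > 0
  agg[order(agg$family), ]
}
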