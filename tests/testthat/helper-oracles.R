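# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the PCA oracle works from an explicit
# eigen-decomposition, and the birth-death oracle simulates lineages by
# per-lineage recursion instead of the package's global-clock Gillespie
# sweep.

# Eigen-decomposition PCA scores for a small standardized matrix.
# Returns scores for the first two axes with the same band-sign convention
# as the package (PC1 positive mean loading over 400-480 nm, PC2 over
# 320-380 nm).
oracle_pca_scores <- function(mat, wavelengths) {
  std <- scale(mat)
  cp <- crossprod(std) / (nrow(std) - 1)
  ev <- eigen(cp, symmetric = TRUE)
  rot <- ev$vectors[, 1:2, drop = FALSE]
  sw <- wavelengths >= 400 & wavelengths <= 480
  uv <- wavelengths >= 320 & wavelengths <= 380
  if (mean(rot[sw, 1]) < 0) rot[, 1] <- -rot[, 1]
  if (mean(rot[uv, 2]) < 0) rot[, 2] <- -rot[, 2]
  std %*% rot
}

# Naive recursive birth-death simulator. Each lineage draws its own
# exponential waiting time; the tree is built as nested lists, pruned to
# extant descendants, lag-collapsed bottom-up, and cherry ages collected.
naive_bd_cherries <- function(lambda, mu, phi, t_sim, n_trees) {
  spawn <- function(t0) {
    wait <- stats::rexp(1, lambda + mu)
    t1 <- t0 + wait
    if (t1 >= t_sim)
      return(list(tip = TRUE, extant = TRUE, t_end = t_sim))
    if (stats::runif(1) < lambda / (lambda + mu))
      list(tip = FALSE, t_end = t1, left = spawn(t1), right = spawn(t1))
    else
      list(tip = TRUE, extant = FALSE, t_end = t1)
  }
  has_extant <- function(nd) {
    if (nd$tip) return(nd$extant)
    has_extant(nd$left) || has_extant(nd$right)
  }
  ages <- c()
  # resolve() returns "leaf", "internal" or "dead"; appends cherry ages
  resolve <- function(nd) {
    while (!nd$tip) {
      sl <- has_extant(nd$left); sr <- has_extant(nd$right)
      if (sl && sr) break
      if (!sl && !sr) return("dead")
      nd <- if (sl) nd$left else nd$right
    }
    if (nd$tip) return(if (nd$extant) "leaf" else "dead")
    a <- resolve(nd$left); b <- resolve(nd$right)
    age <- t_sim - nd$t_end
    if (a == "leaf" && b == "leaf") {
      lag <- if (phi > 0) stats::rexp(1, 1 / phi) else 0
      if (age < lag) return("leaf")
      ages <<- c(ages, age)
    }
    "internal"
  }
  for (i in seq_len(n_trees)) {
    left <- spawn(0); right <- spawn(0)
    sl <- has_extant(left); sr <- has_extant(right)
    n_tips <- function(nd) if (nd$tip) as.integer(nd$extant)
      else n_tips(nd$left) + n_tips(nd$right)
    if (n_tips(left) + n_tips(right) < 2) next
    if (sl && sr) {
      a <- resolve(left); b <- resolve(right)
      if (a == "leaf" && b == "leaf") {
        lag <- if (phi > 0) stats::rexp(1, 1 / phi) else 0
        if (t_sim >= lag) ages <- c(ages, t_sim)
      }
    } else if (sl) resolve(left) else if (sr) resolve(right)
  }
  ages
}

# Synthetic half-normal divergence observations under a known BM/OU truth.
make_divergence_obs <- function(n, b_beta = 0, c_beta = 1, b_alpha = 0,
                                c_alpha = 0, family = "BM",
                                S_range = c(0, 2), T_range = c(0.5, 5)) {
  S <- stats::runif(n, S_range[1], S_range[2])
  T_ <- stats::runif(n, T_range[1], T_range[2])
  beta <- b_beta * S + c_beta
  alpha <- b_alpha * S + c_alpha
  V <- pair_variance(family, beta, alpha, T_)
  data.frame(D = abs(stats::rnorm(n, 0, sqrt(V))), T = T_, S = S)
}
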