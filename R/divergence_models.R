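#' Variance of the between-pair trait difference under BM or OU
#'
#' For a sister pair separated by total distance T (so each lineage evolved
#' independently for tau = T/2 after the split), the difference in trait
#' values X = x1 - x2 is Gaussian with mean zero and variance
#' \itemize{
#'   \item Brownian motion: V = 2 * beta * tau,
#'   \item Ornstein--Uhlenbeck toward a shared optimum:
#'     V = (beta / alpha) * (1 - exp(-2 * alpha * tau)).
#' }
#' As alpha approaches 0 the OU variance collapses to the BM form; small
#' alpha * tau is evaluated by the BM limit to avoid catastrophic
#' cancellation.
#'
#' @param family \code{"BM"} or \code{"OU"}.
#' @param beta positive divergence-rate parameter(s).
#' @param alpha non-negative constraint parameter(s) (OU only; ignored for
#'   BM).
#' @param T total separating distance (genetic distance or age); positive.
#' @return variance of the pair difference, vectorized over inputs.
#' @export
pair_variance <- function(family = c("BM", "OU"), beta, alpha = 0, T) {
  family <- match.arg(family)
  if (any(beta <= 0)) stop("beta must be positive")
  if (any(T <= 0)) stop("T must be positive")
  tau <- T / 2
  if (family == "BM") return(2 * beta * tau)
  if (any(alpha < 0)) stop("alpha must be non-negative")
  v <- 2 * beta * tau          # BM limit
  big <- alpha * tau > 1e-8
  if (any(big)) {
    a <- rep_len(alpha, length(v)); b <- rep_len(beta, length(v))
    tt <- rep_len(tau, length(v))
    v[big] <- (b[big] / a[big]) * (1 - exp(-2 * a[big] * tt[big]))
  }
  v
}

#' Half-normal log-density of an observed divergence
#'
#' The 1-D Euclidean divergence D = |x1 - x2| of a zero-mean Gaussian
#' difference with variance V follows a folded (half-) normal distribution
#' with density f(D) = 2 / sqrt(2 pi V) * exp(-D^2 / (2V)) on D >= 0.
#'
#' @param D non-negative divergence.
#' @param V positive variance of the underlying difference.
#' @param log return log-density (default TRUE).
#' @export
dhalfnorm <- function(D, V, log = TRUE) {
  if (any(D < 0)) stop("D must be non-negative")
  if (any(V <= 0)) stop("V must be positive")
  ld <- log(2) + stats::dnorm(D, mean = 0, sd = sqrt(V), log = TRUE)
  if (log) ld else exp(ld)
}

## parameter-vector layout per (family, covariate); slopes fixed at 0 in
## constant models so k matches the free-parameter count
.evo_par_names <- function(family, covariate) {
  switch(paste(family, covariate, sep = "."),
         BM.constant = "c_beta",
         BM.linear_in_S = c("b_beta", "c_beta"),
         OU.constant = c("c_beta", "c_alpha"),
         OU.linear_in_S = c("b_beta", "c_beta", "b_alpha", "c_alpha"),
         stop("unknown model"))
}

.evo_expand <- function(par, family, covariate) {
  full <- c(b_beta = 0, c_beta = NA_real_, b_alpha = 0, c_alpha = 0)
  full[.evo_par_names(family, covariate)] <- par
  full
}

#' Log-likelihood of pair divergences under a covariate-rate BM/OU model
#'
#' Computes the summed half-normal log-likelihood of observed per-pair
#' divergences D_i at separations T_i, where the rate beta and (for OU) the
#' constraint alpha are linear functions of the pair-level dichromatism
#' covariate S_i: beta(S) = b_beta * S + c_beta and
#' alpha(S) = b_alpha * S + c_alpha. Constant models fix the slopes at zero.
#' Parameter vectors implying beta(S_i) <= 0 or alpha(S_i) < 0 at any
#' observed S_i return \code{-Inf} so that optimizers treat the region as
#' infeasible; the linear-in-S parameterization itself is the model and is
#' not log-transformed.
#'
#' @param observations data.frame with columns \code{D}, \code{T}, \code{S}.
#' @param par named or positional numeric vector matching the model's free
#'   parameters (see Details in [fit_divergence_model()]).
#' @param family \code{"BM"} or \code{"OU"}.
#' @param covariate \code{"constant"} or \code{"linear_in_S"}.
#' @return scalar log-likelihood (possibly \code{-Inf}).
#' @export
loglik_divergence <- function(observations, par, family = c("BM", "OU"),
                              covariate = c("constant", "linear_in_S")) {
  family <- match.arg(family); covariate <- match.arg(covariate)
  if (any(observations$D < 0)) stop("D must be non-negative")
  if (any(observations$T <= 0)) stop("T must be positive")
  p <- .evo_expand(par, family, covariate)
  beta <- p["b_beta"] * observations$S + p["c_beta"]
  alpha <- p["b_alpha"] * observations$S + p["c_alpha"]
  if (any(!is.finite(beta)) || any(beta <= 0)) return(-Inf)
  if (family == "OU" && (any(!is.finite(alpha)) || any(alpha < 0)))
    return(-Inf)
  V <- if (family == "BM") beta * observations$T
       else pair_variance("OU", beta, alpha, observations$T)
  sum(dhalfnorm(observations$D, V, log = TRUE))
}

#' Fit a BM or OU divergence-rate model by maximum likelihood
#'
#' Maximizes [loglik_divergence()] with a derivative-free Nelder--Mead
#' simplex, restarted from jittered starting points. The BM-constant model
#' has the closed-form MLE beta-hat = mean(D^2 / T), used both as a starting
#' point and a cross-check; richer models start from the BM-constant
#' solution with small slopes.
#'
#' @param observations data.frame with columns \code{D}, \code{T}, \code{S}
#'   (single trait and sex).
#' @param family \code{"BM"} or \code{"OU"}.
#' @param covariate \code{"constant"} or \code{"linear_in_S"}.
#' @param n_restarts number of jittered restarts (default 20).
#' @param seed integer seed for the restart jitter.
#' @return object of class \code{evo_fit}: list with \code{params} (named
#'   full parameter vector), \code{free} (free-parameter estimates),
#'   \code{logL}, \code{k}, \code{n}, \code{AICc}, \code{family},
#'   \code{covariate}, \code{convergence} (TRUE if any restart converged).
#' @export
fit_divergence_model <- function(observations,
                                 family = c("BM", "OU"),
                                 covariate = c("constant", "linear_in_S"),
                                 n_restarts = 20, seed = 1L) {
  family <- match.arg(family); covariate <- match.arg(covariate)
  pn <- .evo_par_names(family, covariate)
  k <- length(pn)
  n <- nrow(observations)
  if (n < k + 2) stop("need at least k + 2 observations (k = ", k, ")")

  beta0 <- mean(observations$D^2 / observations$T)
  start <- c(b_beta = 0.01, c_beta = beta0, b_alpha = 0.01,
             c_alpha = 0.1)[pn]
  negll <- function(par) {
    ll <- loglik_divergence(observations, par, family, covariate)
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  for (r in if (k == 1L) integer(0) else seq_len(n_restarts)) {
    st <- if (r == 1L) start else start * stats::runif(k, 0.3, 1.7) +
      stats::rnorm(k, 0, 0.05)
    if (!is.finite(negll(st))) next
    opt <- tryCatch(
      stats::optim(st, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$converged <- opt$convergence == 0
    }
  }
  # the 1-parameter model has a closed-form MLE; a bracketed 1-D search
  # around it replaces the simplex and the closed form is kept if better
  if (k == 1L) {
    o1 <- stats::optimize(negll, c(beta0 / 10, beta0 * 10), tol = 1e-12)
    best <- list(par = o1$minimum, value = o1$objective, converged = TRUE)
    if (negll(beta0) < best$value) {
      best$par <- beta0; best$value <- negll(beta0)
    }
  }
  if (is.null(best) || best$value >= 1e10) stop("fit failed")

  free <- stats::setNames(as.numeric(best$par), pn)
  logL <- -best$value
  structure(list(
    params = .evo_expand(free, family, covariate),
    free = free, logL = logL, k = k, n = n,
    AICc = aicc(logL, k, n),
    family = family, covariate = covariate,
    convergence = isTRUE(best$converged)), class = "evo_fit")
}

#' @exportS3Method base::print
print.evo_fit <- function(x, ...) {
  cat(sprintf("%s model, covariate: %s\n", x$family, x$covariate))
  cat("  free parameters:\n")
  print(round(x$free, 5))
  cat(sprintf("  logL = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$logL, x$k, x$n, x$AICc))
  invisible(x)
}

#' Akaike information criterion with small-sample correction
#'
#' AICc = -2 logL + 2k + 2k(k + 1) / (n - k - 1).
#'
#' @param logL log-likelihood at the maximum.
#' @param k number of free parameters.
#' @param n number of observations.
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) stop("n must exceed k + 1 for the AICc correction")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted divergence models by AICc
#'
#' Builds the model-selection table: AICc, delta-AICc relative to the best
#' model, and Akaike weights. A model is flagged best-supported when its
#' weight exceeds 0.70 and the runner-up's delta-AICc exceeds 2. Ties
#' (delta-AICc < 0.01) are broken toward fewer parameters for determinism.
#'
#' @param fits named list of \code{evo_fit} objects fitted to the same
#'   observations.
#' @return data.frame with model, family, covariate, k, logL, AICc,
#'   delta_AICc, weight, best_supported.
#' @export
information_criteria <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f)
      paste(f$family, f$covariate, sep = "_"), character(1L))
  ns <- vapply(fits, `[[`, numeric(1L), "n")
  if (length(unique(ns)) != 1L)
    stop("fits were made on different observation sets (n differs)")
  aic <- vapply(fits, `[[`, numeric(1L), "AICc")
  k <- vapply(fits, `[[`, numeric(1L), "k")
  logL <- vapply(fits, `[[`, numeric(1L), "logL")
  # deterministic tie-break: among near-ties prefer fewer parameters
  ord_best <- order(aic + 1e-9 * k)
  delta <- aic - aic[ord_best[1L]]
  w <- exp(-delta / 2); w <- w / sum(w)
  best <- rep(FALSE, length(fits))
  if (length(fits) > 1L) {
    i1 <- ord_best[1L]; i2 <- ord_best[2L]
    best[i1] <- w[i1] > 0.70 && (aic[i2] - aic[i1]) > 2
  }
  out <- data.frame(
    model = names(fits),
    family = vapply(fits, `[[`, character(1L), "family"),
    covariate = vapply(fits, `[[`, character(1L), "covariate"),
    k = k, logL = logL, AICc = aic, delta_AICc = delta, weight = w,
    best_supported = best, row.names = NULL)
  out[order(out$AICc + 1e-9 * out$k), ]
}

#' Shared versus sex-specific divergence rates
#'
#' Fits (a) one parameter set to the pooled male + female data and (b)
#' separate parameter sets per sex, then compares the two structures by
#' AICc (pooled n, sex-specific k doubled). Both sexes must cover the same
#' pairs.
#'
#' @param male,female data.frames with columns \code{pair_id}, \code{D},
#'   \code{T}, \code{S}.
#' @param family,covariate model structure passed to
#'   [fit_divergence_model()].
#' @param ... further arguments to [fit_divergence_model()].
#' @return list with \code{shared}, \code{male}, \code{female} fits,
#'   \code{AICc_shared}, \code{AICc_sex_specific}, \code{preferred}
#'   (\code{"shared"} or \code{"sex_specific"}).
#' @export
compare_sex_rates <- function(male, female, family = c("BM", "OU"),
                              covariate = c("constant", "linear_in_S"),
                              ...) {
  family <- match.arg(family); covariate <- match.arg(covariate)
  if (!setequal(male$pair_id, female$pair_id))
    stop("male and female observation sets cover different pairs")
  pooled <- rbind(male[c("D", "T", "S")], female[c("D", "T", "S")])
  f_shared <- fit_divergence_model(pooled, family, covariate, ...)
  f_m <- fit_divergence_model(male, family, covariate, ...)
  f_f <- fit_divergence_model(female, family, covariate, ...)
  n <- nrow(pooled)
  k2 <- f_m$k + f_f$k
  logL2 <- f_m$logL + f_f$logL
  aicc_shared <- aicc(f_shared$logL, f_shared$k, n)
  aicc_sex <- aicc(logL2, k2, n)
  list(shared = f_shared, male = f_m, female = f_f,
       logL_shared = f_shared$logL, logL_sex_specific = logL2,
       AICc_shared = aicc_shared, AICc_sex_specific = aicc_sex,
       preferred = if (aicc_sex < aicc_shared - 1e-9) "sex_specific"
                   else "shared")
}
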