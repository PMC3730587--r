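#' Assemble the pair-level modelling table
#'
#' Joins divergence summaries, dichromatism scores and pair covariates into
#' one row per pair x sex, log-transforms the responses and the
#' dichromatism predictor (offset delta = half the smallest positive
#' observed value, recorded in the attributes, so zero divergences remain
#' finite), converts genetic distance to age with the molecular clock, and
#' optionally drops mutually ornamented pairs while retaining dull
#' monomorphic ones.
#'
#' @param divergence data.frame from
#'   \code{standardize_and_diverge()$divergence}.
#' @param dichromatism pair-level data.frame with \code{pair_id}, \code{S}
#'   (from [pair_dichromatism()]).
#' @param pairs pair covariate table: \code{pair_id}, \code{species_1},
#'   \code{species_2}, \code{pair_type}, \code{genetic_distance},
#'   \code{sympatry}, \code{body_mass_g}, \code{mutual_ornamentation}, and
#'   optionally \code{family}, \code{genus}.
#' @param exclude_mutual drop pairs with \code{mutual_ornamentation == 1}.
#' @return data.frame (one row per pair x sex) with
#'   \code{response_total}, \code{response_max}, \code{dichromatism}
#'   (log-transformed pair mean), \code{sex}, \code{age_myr},
#'   \code{sympatry}, \code{body_mass}, grouping labels, and a
#'   \code{sisterhood} factor; complete cases only. Attributes
#'   \code{offsets} (the deltas used) and \code{dropped} (pair ids lost to
#'   unresolved joins or missing covariates).
#' @export
build_model_table <- function(divergence, dichromatism, pairs,
                              exclude_mutual = FALSE) {
  tab <- merge(divergence, dichromatism, by = "pair_id")
  tab <- merge(tab, pairs, by = "pair_id")
  unresolved <- setdiff(divergence$pair_id,
                        intersect(dichromatism$pair_id, pairs$pair_id))
  if (length(unresolved) > 0L)
    warning("pairs dropped (unresolved joins): ",
            paste(unique(unresolved), collapse = ", "))
  if (exclude_mutual && "mutual_ornamentation" %in% names(tab))
    tab <- tab[tab$mutual_ornamentation != 1, , drop = FALSE]

  log_offset <- function(x) {
    pos <- x[is.finite(x) & x > 0]
    if (length(pos) == 0L) return(1e-6)
    min(pos) / 2
  }
  d_tot <- log_offset(tab$total)
  d_max <- log_offset(tab$maximum)
  d_S <- log_offset(tab$S)
  out <- data.frame(
    pair_id = tab$pair_id,
    sisterhood = factor(tab$pair_id),
    sex = factor(tab$sex),
    response_total = log(tab$total + d_tot),
    response_max = log(tab$maximum + d_max),
    dichromatism = log(tab$S + d_S),
    age_myr = clock_age(tab$genetic_distance),
    sympatry = tab$sympatry,
    body_mass = tab$body_mass_g,
    species_1 = factor(tab$species_1),
    species_2 = factor(tab$species_2))
  for (g in c("family", "genus"))
    out[[g]] <- if (g %in% names(tab)) factor(tab[[g]]) else factor(NA)

  model_cols <- c("response_total", "response_max", "dichromatism",
                  "age_myr", "sympatry", "body_mass")
  cc <- stats::complete.cases(out[model_cols])
  if (any(!cc))
    warning("incomplete rows dropped for pairs: ",
            paste(unique(out$pair_id[!cc]), collapse = ", "))
  res <- out[cc, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "offsets") <- c(total = d_tot, maximum = d_max,
                            dichromatism = d_S)
  attr(res, "dropped") <- unique(c(unresolved, out$pair_id[!cc]))
  res
}

#' Linear mixed model of phenotypic divergence
#'
#' Fits, through the standard REML mixed-model machinery of
#' \pkg{lme4}/\pkg{lmerTest}, a model with fixed effects dichromatism, sex,
#' their interaction, evolutionary age, sympatry and body mass, and random
#' intercepts for sisterhood (pair), each member species, and genus nested
#' in family. Satterthwaite degrees of freedom give the t tests.
#'
#' @param table modelling table from [build_model_table()].
#' @param response \code{"response_total"} or \code{"response_max"}.
#' @return list with \code{coefficients} (data.frame: term, estimate, se,
#'   df, t, p), \code{varcomp} (random-effect variances), \code{singular}
#'   flag, \code{n}, and the fitted \code{model} object.
#' @export
fit_lmm <- function(table, response = c("response_total", "response_max")) {
  response <- match.arg(response)
  for (g in c("sisterhood", "species_1", "species_2", "family", "genus"))
    if (nlevels(droplevels(table[[g]])) < 2L)
      stop("random grouping factor '", g, "' has fewer than 2 levels")
  fml <- stats::as.formula(paste(
    response,
    "~ dichromatism * sex + age_myr + sympatry + body_mass",
    "+ (1 | sisterhood) + (1 | species_1) + (1 | species_2)",
    "+ (1 | family / genus)"))
  fit <- lmerTest::lmer(fml, data = table, REML = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm),
                      estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      df = sm[, "df"],
                      t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(coefficients = coefs,
       varcomp = vc[, c("grp", "vcov")],
       singular = lme4::isSingular(fit),
       n = nrow(table),
       model = fit)
}

#' Phylogenetic correlation structure among independent pairs
#'
#' Builds the expected Brownian correlation among pair-level observations
#' from a dated tree: one representative tip per pair (its
#' \code{species_1}), correlation = shared root-to-tip path length divided
#' by the geometric mean of total depths, with off-diagonal entries
#' multiplied by Pagel's lambda. lambda = 0 gives the identity
#' (no phylogenetic signal); lambda = 1 the full Brownian expectation.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param taxa character vector of representative tip labels, one per row
#'   of the modelling data.
#' @param lambda_pagel scaling in [0, 1].
#' @return list with \code{corr} (the lambda-scaled correlation matrix),
#'   \code{vcv} (unscaled Brownian covariance), \code{lambda_pagel}.
#' @export
phylo_corr <- function(tree, taxa, lambda_pagel = 1) {
  stopifnot(inherits(tree, "phylo"), lambda_pagel >= 0, lambda_pagel <= 1)
  missing_taxa <- setdiff(taxa, tree$tip.label)
  if (length(missing_taxa) > 0L)
    stop("taxa missing from tree: ", paste(missing_taxa, collapse = ", "))
  sub <- ape::keep.tip(tree, unique(taxa))
  V <- ape::vcv(sub)[taxa, taxa, drop = FALSE]
  R <- stats::cov2cor(V)
  Rl <- R * lambda_pagel
  diag(Rl) <- 1
  list(corr = Rl, vcv = V, lambda_pagel = lambda_pagel)
}

## GLS profile log-likelihood at a given correlation matrix (ML sigma^2)
.gls_loglik <- function(y, X, C) {
  n <- length(y)
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) return(list(logL = -Inf))
  # whiten: solve L' w = v  (C = L'L with chol returning upper triangular)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  qr_ <- qr(wX)
  beta <- qr.coef(qr_, wy)
  e <- wy - wX %*% beta
  rss <- sum(e^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  logL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(logL = logL, beta = beta, rss = rss, sigma2 = sigma2,
       XtCinvX_inv = chol2inv(qr.R(qr_)))
}

## golden-section maximization on [lo, hi]
.golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(maximum = x, objective = f(x))
}

#' Phylogenetic generalized least squares with maximum-likelihood lambda
#'
#' Fits a GLS regression whose error correlation is the lambda-scaled
#' Brownian structure from [phylo_corr()], profiling Pagel's lambda over
#' [0, 1] by golden-section search (tolerance 1e-4) on the GLS
#' log-likelihood. At lambda = 0 the fit reduces exactly to ordinary least
#' squares.
#'
#' @param formula model formula evaluated in \code{data}.
#' @param data data.frame, one row per independent pair.
#' @param tree \code{ape::phylo} tree containing the representative taxa.
#' @param taxa character vector mapping rows of \code{data} to tip labels.
#' @param lambda_pagel if non-\code{NULL}, fix lambda instead of
#'   estimating it.
#' @return list with \code{coefficients} (term, estimate, se, t, p),
#'   \code{lambda_pagel} (the ML or fixed value), \code{logL},
#'   \code{logL_lambda0}, \code{logL_lambda1}, \code{n}.
#' @export
fit_pgls <- function(formula, data, tree, taxa, lambda_pagel = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  base <- phylo_corr(tree, taxa, lambda_pagel = 1)

  ll_at <- function(lam) {
    Cl <- base$corr * lam
    diag(Cl) <- 1
    .gls_loglik(y, X, Cl)$logL
  }
  if (is.null(lambda_pagel)) {
    # the profile can be multimodal: coarse global grid, then
    # golden-section refinement in the bracketing interval
    grid <- seq(0, 1, by = 0.05)
    vals <- vapply(grid, ll_at, numeric(1L))
    i <- which.max(vals)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    opt <- .golden_max(ll_at, lo, hi, tol = 1e-4)
    cand <- c(opt$maximum, grid[i], 0, 1)
    lam_hat <- cand[which.max(vapply(cand, ll_at, numeric(1L)))]
  } else {
    lam_hat <- lambda_pagel
  }
  Cl <- base$corr * lam_hat
  diag(Cl) <- 1
  g <- .gls_loglik(y, X, Cl)
  if (!is.finite(g$logL)) stop("phylogenetic covariance is not positive definite")
  p <- ncol(X)
  s2 <- g$rss / (n - p)
  se <- sqrt(diag(g$XtCinvX_inv) * s2)
  tval <- as.numeric(g$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  list(coefficients = data.frame(term = colnames(X),
                                 estimate = as.numeric(g$beta),
                                 se = se, t = tval, p = pval,
                                 row.names = NULL),
       lambda_pagel = lam_hat,
       logL = g$logL,
       logL_lambda0 = ll_at(0),
       logL_lambda1 = ll_at(1),
       n = n)
}
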