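#' Configuration of a synthetic sister-pair study
#'
#' Bundles the generating parameters for a complete synthetic study:
#' reflectance spectra with sex-specific colour offsets, morphometrics,
#' pair covariates, per-pair trait divergences under a covariate-rate BM/OU
#' truth, recognized sister ages under a birth--death truth, and a random
#' tree. Defaults emulate the scale of the empirical study this package
#' targets: 84 pairs (39 true sisters, 45 clade sisters), dichromatism
#' covariate S ~ U(0, 2), pair separations T ~ U(0.5, 5), a male
#' divergence rate rising in S (b_beta = 0.5, c_beta = 0.1) with a flat
#' female rate, and a birth--death truth of lambda = 0.3, mu = 0,
#' lag phi = 0.3 Myr.
#'
#' @param n_pairs total number of pairs.
#' @param n_sister number of true sister pairs (the rest are clade
#'   sisters).
#' @param S_range,T_range uniform supports for the dichromatism covariate
#'   and pair separation.
#' @param divergence_truth named list per sex; each element a list with
#'   \code{family}, \code{b_beta}, \code{c_beta}, \code{b_alpha},
#'   \code{c_alpha}.
#' @param bd_truth list with \code{b_lambda}, \code{c_lambda}, \code{b_mu},
#'   \code{c_mu}, \code{phi}.
#' @param n_specimens specimens per species x sex for reflectance and
#'   morphometrics.
#' @param specimen_noise_sd SD of i.i.d. Gaussian specimen noise on
#'   reflectance (percent units).
#' @param sex_offset_range uniform support of per-species male colour-bump
#'   magnitudes (sets the dichromatism gradient).
#' @param T_sim_gen horizon (Myr) for birth--death tree simulation when
#'   generating sister ages.
#' @param seed mandatory integer seed.
#' @return object of class \code{study_config} (a list).
#' @export
study_config <- function(n_pairs = 84, n_sister = 39,
                         S_range = c(0, 2), T_range = c(0.5, 5),
                         divergence_truth = list(
                           male = list(family = "BM", b_beta = 0.5,
                                       c_beta = 0.1, b_alpha = 0,
                                       c_alpha = 0),
                           female = list(family = "BM", b_beta = 0,
                                         c_beta = 0.1, b_alpha = 0,
                                         c_alpha = 0)),
                         bd_truth = list(b_lambda = 0, c_lambda = 0.3,
                                         b_mu = 0, c_mu = 0, phi = 0.3),
                         n_specimens = 3, specimen_noise_sd = 1,
                         sex_offset_range = c(0, 6),
                         T_sim_gen = 10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_sister <- min(n_sister, n_pairs)
  structure(list(n_pairs = n_pairs, n_sister = n_sister,
                 S_range = S_range, T_range = T_range,
                 divergence_truth = divergence_truth,
                 bd_truth = bd_truth,
                 n_specimens = n_specimens,
                 specimen_noise_sd = specimen_noise_sd,
                 sex_offset_range = sex_offset_range,
                 T_sim_gen = T_sim_gen,
                 seed = as.integer(seed)),
            class = "study_config")
}

.regions <- c("crown", "throat", "belly", "tail", "back", "wing_coverts")

.species_names <- function(config) {
  data.frame(pair_id = sprintf("P%03d", seq_len(config$n_pairs)),
             species_1 = sprintf("sp%03da", seq_len(config$n_pairs)),
             species_2 = sprintf("sp%03db", seq_len(config$n_pairs)))
}

#' Generate a synthetic reflectance table
#'
#' Base spectra (one per species x region) are a linear ramp plus two
#' Gaussian bumps with species-specific centres and heights -- smooth,
#' positive and band-controllable. Males additionally receive additive
#' bumps centred in the 400--480 nm (short-wave chroma) and 320--380 nm
#' (ultraviolet) bands whose per-species magnitude sets a known target
#' dichromatism ordering. Specimen noise is i.i.d. Gaussian; negative
#' values are clipped at zero with a warning.
#'
#' @param config a [study_config()].
#' @return list with \code{reflectance} (long data.frame: species, sex,
#'   specimen, region, wavelength_nm, reflectance_pct) and \code{truth}
#'   (per-species male offset magnitudes).
#' @export
gen_reflectance <- function(config) {
  set.seed(config$seed)
  wl <- seq(320, 700, by = 5)
  sp <- .species_names(config)
  species <- c(sp$species_1, sp$species_2)
  offsets <- stats::runif(length(species), config$sex_offset_range[1L],
                          config$sex_offset_range[2L])
  names(offsets) <- species
  bump <- function(center, sd, height) height * exp(-(wl - center)^2 / (2 * sd^2))

  rows <- vector("list", length(species) * length(.regions) *
                   2L * config$n_specimens)
  k <- 0L
  clipped <- FALSE
  for (s in species) {
    for (rg in .regions) {
      base <- 20 + 10 * (wl - 320) / 380 +
        bump(stats::runif(1, 350, 650), stats::runif(1, 20, 60),
             stats::runif(1, 0, 15)) +
        bump(stats::runif(1, 350, 650), stats::runif(1, 20, 60),
             stats::runif(1, 0, 15))
      male_extra <- bump(440, 25, offsets[s]) + bump(350, 20, offsets[s] / 2)
      for (sx in c("male", "female")) {
        mu <- if (sx == "male") base + male_extra else base
        for (i in seq_len(config$n_specimens)) {
          refl <- mu + stats::rnorm(length(wl), 0, config$specimen_noise_sd)
          if (any(refl < 0)) { clipped <- TRUE; refl <- pmax(refl, 0) }
          k <- k + 1L
          rows[[k]] <- data.frame(species = s, sex = sx,
                                  specimen = paste0(s, "_", sx, "_", i),
                                  region = rg, wavelength_nm = wl,
                                  reflectance_pct = refl)
        }
      }
    }
  }
  if (clipped) warning("negative reflectance clipped at 0")
  list(reflectance = do.call(rbind, rows[seq_len(k)]),
       truth = data.frame(species = species, male_offset = offsets,
                          row.names = NULL))
}

#' Generate synthetic morphometrics
#'
#' Beak, tarsus and wing lengths per specimen: species means drawn around
#' passerine-scale values, specimen noise Gaussian.
#'
#' @param config a [study_config()].
#' @return data.frame with species, sex, specimen, beak_mm, tarsus_mm,
#'   wing_mm.
#' @export
gen_morphology <- function(config) {
  set.seed(config$seed + 1L)
  sp <- .species_names(config)
  species <- c(sp$species_1, sp$species_2)
  base <- c(beak_mm = 12, tarsus_mm = 22, wing_mm = 70)
  rows <- list()
  for (s in species) {
    sp_mean <- base * exp(stats::rnorm(3, 0, 0.15))
    for (sx in c("male", "female")) {
      sex_mean <- sp_mean * exp(stats::rnorm(3, 0, 0.03))
      for (i in seq_len(config$n_specimens)) {
        v <- sex_mean * exp(stats::rnorm(3, 0, 0.02))
        rows[[length(rows) + 1L]] <- data.frame(
          species = s, sex = sx, specimen = paste0(s, "_", sx, "_", i),
          beak_mm = v[1L], tarsus_mm = v[2L], wing_mm = v[3L])
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate the pair covariate table
#'
#' @param config a [study_config()].
#' @param S optional known pair-level dichromatism values; drawn uniform on
#'   \code{config$S_range} if omitted.
#' @return data.frame matching the pairs.csv schema, plus \code{family}
#'   and \code{genus} grouping labels and the drawn \code{S}.
#' @export
gen_pairs <- function(config, S = NULL) {
  set.seed(config$seed + 2L)
  sp <- .species_names(config)
  n <- config$n_pairs
  if (is.null(S))
    S <- stats::runif(n, config$S_range[1L], config$S_range[2L])
  T_ <- stats::runif(n, config$T_range[1L], config$T_range[2L])
  n_fam <- max(2L, round(n / 4))
  fam <- sprintf("fam%02d", sample.int(n_fam, n, replace = TRUE))
  data.frame(sp,
             pair_type = c(rep("sister", config$n_sister),
                           rep("clade_sister", n - config$n_sister)),
             genetic_distance = T_ * 2 * 0.0105,  # so clock_age() returns T_
             sympatry = stats::rbinom(n, 1, 0.3),
             body_mass_g = exp(stats::rnorm(n, log(20), 0.4)),
             mutual_ornamentation = stats::rbinom(n, 1, 0.15),
             family = fam,
             genus = paste0(fam, "_g", sample.int(2L, n, replace = TRUE)),
             S = S)
}

#' Generate per-pair trait divergences under a known BM/OU truth
#'
#' For each pair, given its covariate S and separation T, draws
#' D = |X|, X ~ Normal(0, V(beta(S), alpha(S), T)) per sex, where the
#' variance follows [pair_variance()] under the configured truth.
#'
#' @param config a [study_config()].
#' @param pairs optional pair table from [gen_pairs()] (regenerated if
#'   omitted); must carry \code{S} and \code{genetic_distance}.
#' @return list with \code{observations} (pair_id, sex, D, T, S) and
#'   \code{truth} (the generating parameters).
#' @export
gen_pair_divergences <- function(config, pairs = NULL) {
  if (is.null(pairs)) pairs <- gen_pairs(config)
  set.seed(config$seed + 3L)
  T_ <- clock_age(pairs$genetic_distance)
  obs <- list()
  for (sx in names(config$divergence_truth)) {
    tr <- config$divergence_truth[[sx]]
    beta <- tr$b_beta * pairs$S + tr$c_beta
    alpha <- (tr$b_alpha %||% 0) * pairs$S + (tr$c_alpha %||% 0)
    if (any(beta <= 0) || any(alpha < 0))
      stop("invalid generating rates over the S support")
    V <- pair_variance(tr$family, beta, alpha, T_)
    obs[[sx]] <- data.frame(pair_id = pairs$pair_id, sex = sx,
                            D = abs(stats::rnorm(nrow(pairs), 0, sqrt(V))),
                            T = T_, S = pairs$S)
  }
  list(observations = do.call(rbind, obs),
       truth = config$divergence_truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate recognized sister-species ages under a birth--death truth
#'
#' For each pair, draws S, evaluates the configured rates
#' lambda(S), mu(S), and runs the birth--death simulator at those rates
#' until a replicate yields at least one recognized cherry, then samples
#' one cherry age uniformly. This is the round-trip counterpart of
#' [fit_bd()].
#'
#' @param config a [study_config()].
#' @param n number of ages (default: the number of true sister pairs).
#' @param max_attempts attempts per age before giving up.
#' @return list with \code{observations} (pair_id, age, S) and
#'   \code{truth}.
#' @export
gen_sister_ages <- function(config, n = config$n_sister,
                            max_attempts = 10000) {
  set.seed(config$seed + 4L)
  tr <- config$bd_truth
  S <- stats::runif(n, config$S_range[1L], config$S_range[2L])
  lam <- tr$b_lambda * S + tr$c_lambda
  mu <- tr$b_mu * S + tr$c_mu
  if (any(lam <= 0) || any(mu < 0) || tr$phi < 0)
    stop("invalid birth-death truth over the S support")
  ages <- numeric(n)
  for (i in seq_len(n)) {
    got <- FALSE
    for (a in seq_len(max_attempts)) {
      sim <- .bd_cherry_ages(lam[i], mu[i], tr$phi, config$T_sim_gen, 1L)
      if (length(sim$ages) > 0L) {
        ages[i] <- sim$ages[sample.int(length(sim$ages), 1L)]
        got <- TRUE
        break
      }
    }
    if (!got)
      stop("no surviving cherries in ", max_attempts,
           " attempts; birth-death truth is pathological")
  }
  list(observations = data.frame(pair_id = sprintf("P%03d", seq_len(n)),
                                 age = ages, S = S),
       truth = tr)
}

#' Generate a complete synthetic study bundle on disk
#'
#' Writes every input file the pipeline reads -- reflectance.csv,
#' morphology.csv, pairs.csv, divergence_obs.csv, sister_ages.csv, a
#' random coalescent-like Newick tree over the pair representatives --
#' plus truth.json recording the generating parameters.
#'
#' @param config a [study_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths plus the in-memory
#'   tables.
#' @export
gen_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refl <- gen_reflectance(config)
  morph <- gen_morphology(config)
  pairs <- gen_pairs(config)
  div <- gen_pair_divergences(config, pairs)
  ages <- gen_sister_ages(config)

  set.seed(config$seed + 5L)
  tree <- ape::rcoal(config$n_pairs, tip.label = pairs$species_1)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) *
    max(clock_age(pairs$genetic_distance))

  paths <- list(
    reflectance = file.path(dir, "reflectance.csv"),
    morphology = file.path(dir, "morphology.csv"),
    pairs = file.path(dir, "pairs.csv"),
    divergence_obs = file.path(dir, "divergence_obs.csv"),
    sister_ages = file.path(dir, "sister_ages.csv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(refl$reflectance, paths$reflectance, row.names = FALSE)
  utils::write.csv(morph, paths$morphology, row.names = FALSE)
  utils::write.csv(pairs, paths$pairs, row.names = FALSE)
  utils::write.csv(div$observations, paths$divergence_obs,
                   row.names = FALSE)
  utils::write.csv(ages$observations, paths$sister_ages, row.names = FALSE)
  ape::write.tree(tree, paths$tree)
  jsonlite::write_json(
    list(config = unclass(config),
         reflectance_truth = refl$truth,
         divergence_truth = div$truth,
         bd_truth = ages$truth),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(tables = list(
    reflectance = refl$reflectance, morphology = morph, pairs = pairs,
    divergence_obs = div$observations, sister_ages = ages$observations,
    tree = tree))))
}
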