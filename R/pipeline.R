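#' Select non-phylogenetically nested pairs
#'
#' Where the same species appears in two or more pairs, only the youngest
#' pair is retained, so that no species contributes to more than one
#' retained pair. Pairs that share no species with any other pair are kept
#' unconditionally.
#'
#' @param pairs data.frame with \code{pair_id}, \code{species_1},
#'   \code{species_2}.
#' @param ages data.frame with \code{pair_id}, \code{age}; every pair that
#'   conflicts with another must have an age.
#' @return the subset of \code{pairs} with no shared species.
#' @export
select_non_nested_pairs <- function(pairs, ages) {
  sp_all <- c(pairs$species_1, pairs$species_2)
  conflicted <- unique(sp_all[duplicated(sp_all)])
  in_conflict <- pairs$species_1 %in% conflicted |
    pairs$species_2 %in% conflicted
  age <- ages$age[match(pairs$pair_id, ages$pair_id)]
  if (any(in_conflict & is.na(age)))
    stop("missing age for conflicted pairs: ",
         paste(pairs$pair_id[in_conflict & is.na(age)], collapse = ", "))
  ord <- order(age, pairs$pair_id)   # youngest first, id breaks ties
  used <- character(0)
  keep <- logical(nrow(pairs))
  for (i in ord) {
    if (pairs$species_1[i] %in% used || pairs$species_2[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, pairs$species_1[i], pairs$species_2[i])
  }
  pairs[keep, , drop = FALSE]
}

#' Run the full sister-pair analysis pipeline
#'
#' Orchestrates the stages end to end on a set of input files:
#' \describe{
#'   \item{phenotype}{reflectance PCA, dichromatism scores, standardized
#'     trait divergences, clock ages;}
#'   \item{analysis1}{linear mixed model of divergence on dichromatism,
#'     sex and covariates, plus PGLS with maximum-likelihood Pagel's
#'     lambda;}
#'   \item{analysis2}{BM/OU divergence-rate model selection by AICc on
#'     non-nested pairs, per sex, with a shared-versus-sex-specific rate
#'     contrast;}
#'   \item{analysis3}{birth--death fits (constant and
#'     dichromatism-linear) to true-sister recognized ages.}
#' }
#' Result files, a run log with seeds and timings, and the returned list
#' are written under \code{outdir}.
#'
#' @param config list with elements \code{inputs} (named paths:
#'   reflectance, morphology, pairs, divergence_obs, sister_ages, tree),
#'   \code{outdir}, \code{seed}, optional \code{analyses} (character
#'   subset of \code{c("phenotype", "analysis1", "analysis2",
#'   "analysis3")}), and optional \code{sim_config} for the birth--death
#'   stage. May also be a path to a YAML or JSON file with those fields.
#' @return invisibly, a list of stage results; stage failures raise
#'   errors after the run log records the failing stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  analyses <- config$analyses %||%
    c("phenotype", "analysis1", "analysis2", "analysis3")
  outdir <- config$outdir %||% stop("config error: outdir is mandatory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("config error: missing input file ", p)

  logf <- file.path(outdir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", sep = "")
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
  }
  cat("", file = logf)
  log_line("pipeline start, seed = %d, stages: %s", config$seed,
           paste(analyses, collapse = ", "))

  res <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line("stage %s done (%.1f s)", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  pairs <- utils::read.csv(config$inputs$pairs)

  if ("phenotype" %in% analyses) {
    res$phenotype <- run_stage("phenotype", {
      refl <- utils::read.csv(config$inputs$reflectance)
      morph <- utils::read.csv(config$inputs$morphology)
      pc <- reflectance_pca(refl)
      dich <- dichromatism_score(pc$scores)
      pair_S <- pair_dichromatism(dich, pairs)

      wide <- stats::reshape(
        pc$scores[c("species", "sex", "region", "pc1_sw_chroma", "pc2_uv")],
        direction = "wide", idvar = c("species", "sex"),
        timevar = "region")
      morph_sp <- stats::aggregate(
        cbind(beak_mm, tarsus_mm, wing_mm) ~ species + sex, data = morph,
        FUN = mean)
      traits <- merge(morph_sp, wide, by = c("species", "sex"))
      div <- standardize_and_diverge(traits, pairs)

      utils::write.csv(pc$scores, file.path(outdir, "plumage_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(dich, file.path(outdir, "dichromatism.csv"),
                       row.names = FALSE)
      utils::write.csv(pair_S, file.path(outdir, "pair_dichromatism.csv"),
                       row.names = FALSE)
      utils::write.csv(div$divergence, file.path(outdir, "divergence.csv"),
                       row.names = FALSE)
      list(scores = pc$scores, dichromatism = dich, pair_S = pair_S,
           divergence = div)
    })
  }

  pair_S <- if (!is.null(res$phenotype)) res$phenotype$pair_S
            else data.frame(pair_id = pairs$pair_id, S = pairs$S)

  if ("analysis1" %in% analyses) {
    res$analysis1 <- run_stage("analysis1", {
      divtab <- if (!is.null(res$phenotype))
        res$phenotype$divergence$divergence
      else stop("analysis1 requires the phenotype stage")
      tab <- build_model_table(divtab, pair_S, pairs)
      lmm <- fit_lmm(tab, "response_total")
      utils::write.csv(lmm$coefficients,
                       file.path(outdir, "lmm_results.csv"),
                       row.names = FALSE)
      pgls <- NULL
      if (!is.null(config$inputs$tree)) {
        tree <- ape::read.tree(config$inputs$tree)
        sub <- tab[tab$sex == "male", , drop = FALSE]
        sub <- sub[as.character(sub$species_1) %in% tree$tip.label, ,
                   drop = FALSE]
        pgls <- fit_pgls(response_total ~ dichromatism + age_myr +
                           sympatry + body_mass,
                         sub, tree, as.character(sub$species_1))
        utils::write.csv(pgls$coefficients,
                         file.path(outdir, "pgls_results.csv"),
                         row.names = FALSE)
      }
      list(model_table = tab, lmm = lmm, pgls = pgls)
    })
  }

  if ("analysis2" %in% analyses) {
    res$analysis2 <- run_stage("analysis2", {
      obs <- utils::read.csv(config$inputs$divergence_obs)
      age_tab <- data.frame(pair_id = pairs$pair_id,
                            age = clock_age(pairs$genetic_distance))
      keep <- select_non_nested_pairs(pairs, age_tab)
      obs <- obs[obs$pair_id %in% keep$pair_id, , drop = FALSE]
      per_sex <- lapply(split(obs, obs$sex), function(o) {
        fits <- list(
          BM_constant = fit_divergence_model(o, "BM", "constant",
                                             seed = config$seed),
          BM_linear = fit_divergence_model(o, "BM", "linear_in_S",
                                           seed = config$seed),
          OU_constant = fit_divergence_model(o, "OU", "constant",
                                             seed = config$seed),
          OU_linear = fit_divergence_model(o, "OU", "linear_in_S",
                                           seed = config$seed))
        information_criteria(fits)
      })
      sexes <- names(per_sex)
      contrast <- if (all(c("male", "female") %in% sexes))
        compare_sex_rates(obs[obs$sex == "male", ],
                          obs[obs$sex == "female", ],
                          "BM", "linear_in_S", seed = config$seed)
      tab <- do.call(rbind, Map(function(s, d) cbind(sex = s, d),
                                sexes, per_sex))
      utils::write.csv(tab, file.path(outdir, "model_selection.csv"),
                       row.names = FALSE)
      list(model_selection = per_sex, sex_contrast = contrast,
           n_pairs_used = nrow(keep))
    })
  }

  if ("analysis3" %in% analyses) {
    res$analysis3 <- run_stage("analysis3", {
      ages <- utils::read.csv(config$inputs$sister_ages)
      sisters <- pairs$pair_id[pairs$pair_type == "sister"]
      n_before <- nrow(ages)
      ages <- ages[ages$pair_id %in% sisters | !ages$pair_id %in%
                     pairs$pair_id, , drop = FALSE]
      log_line("analysis3 using %d of %d ages (true sisters only)",
               nrow(ages), n_before)
      sim_cfg <- utils::modifyList(list(seed = config$seed),
                                   config$sim_config %||% list())
      f_const <- fit_bd(ages, "constant", sim_cfg)
      f_lin <- fit_bd(ages, "linear_in_S", sim_cfg)
      cmp <- compare_bd(f_const, f_lin,
                        S_grid = seq(min(ages$S), max(ages$S),
                                     length.out = 21))
      utils::write.csv(cmp$curves, file.path(outdir, "fig3_curves.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(constant = f_const[c("params", "logL", "k", "AIC")],
             linear = f_lin[c("params", "logL", "k", "AIC")],
             delta_AIC = cmp$delta_AIC, r_slope = cmp$r_slope),
        file.path(outdir, "bd_fits.json"), auto_unbox = TRUE, digits = NA)
      list(constant = f_const, linear = f_lin, comparison = cmp)
    })
  }

  log_line("pipeline complete")
  invisible(res)
}
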