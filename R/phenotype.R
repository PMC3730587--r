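#' Principal-component scores of plumage reflectance spectra
#'
#' Collapses spectrophotometric reflectance curves (320--700 nm) into two
#' principal-component axes summarising spectral shape independently of
#' overall brightness. Each wavelength column is centred and scaled to unit
#' variance before the decomposition, so a uniform brightness shift of a
#' spectrum does not move its scores. The first component is oriented so that
#' its mean loading over the 400--480 nm band (short-wavelength chroma) is
#' positive; the second so that its mean loading over the 320--380 nm band
#' (ultraviolet reflectance) is positive.
#'
#' Spectra measured on different wavelength grids are resampled onto a common
#' 5-nm grid by linear interpolation. Each specimen spectrum is scored
#' individually and scores are then averaged per species x sex x region.
#'
#' @param spectra data.frame in long format with columns \code{species},
#'   \code{sex} (\code{"male"}/\code{"female"}), \code{specimen},
#'   \code{region}, \code{wavelength_nm}, \code{reflectance_pct}.
#' @return A list with components \code{scores} (data.frame: species, sex,
#'   region, \code{pc1_sw_chroma}, \code{pc2_uv}, n_specimens),
#'   \code{specimen_scores} (per-specimen scores before averaging),
#'   \code{loadings} (wavelength x 2 matrix), \code{variance_explained}
#'   (length-2 numeric), and \code{wavelengths} (the common grid).
#' @examples
#' refl <- gen_reflectance(study_config(n_pairs = 3, seed = 1))$reflectance
#' pc <- reflectance_pca(refl)
#' head(pc$scores)
#' @export
reflectance_pca <- function(spectra) {
  req <- c("species", "sex", "specimen", "region", "wavelength_nm",
           "reflectance_pct")
  missing_cols <- setdiff(req, names(spectra))
  if (length(missing_cols) > 0L)
    stop("spectra is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(spectra$reflectance_pct)) ||
      any(spectra$reflectance_pct < 0))
    stop("reflectance values must be finite and non-negative")
  wl <- spectra$wavelength_nm
  if (any(wl < 320 | wl > 700))
    stop("wavelengths must lie within [320, 700] nm")

  spectra$rec_id <- interaction(spectra$species, spectra$sex,
                                spectra$region, spectra$specimen, drop = TRUE)
  grids <- split(spectra$wavelength_nm, spectra$rec_id)
  common <- sort(unique(grids[[1L]]))
  same_grid <- all(vapply(grids, function(g) identical(sort(unique(g)), common),
                          logical(1L)))
  if (!same_grid) {
    # spectrophotometers differ in step size; harmonize on a 5-nm grid
    lo <- max(vapply(grids, min, numeric(1L)))
    hi <- min(vapply(grids, max, numeric(1L)))
    if (hi <= lo) stop("inconsistent wavelength grid: no common support")
    common <- seq(ceiling(lo / 5) * 5, floor(hi / 5) * 5, by = 5)
  }
  if (length(common) < 2L) stop("need at least 2 distinct wavelengths")

  recs <- split(spectra, spectra$rec_id)
  if (length(recs) < 3L) stop("need at least 3 spectra")
  mat <- t(vapply(recs, function(d) {
    d <- d[order(d$wavelength_nm), , drop = FALSE]
    if (identical(d$wavelength_nm, common)) d$reflectance_pct
    else stats::approx(d$wavelength_nm, d$reflectance_pct, xout = common,
                       rule = 2)$y
  }, numeric(length(common))))
  colnames(mat) <- common

  sds <- apply(mat, 2L, stats::sd)
  if (sum(sds > 0) < 2L) stop("degenerate spectra: zero total variance")
  keep <- sds > 0
  std <- scale(mat[, keep, drop = FALSE])
  pc <- stats::prcomp(std, center = FALSE, scale. = FALSE)

  load_full <- matrix(0, length(common), 2L,
                      dimnames = list(common, c("PC1", "PC2")))
  load_full[keep, ] <- pc$rotation[, 1:2]
  wlk <- common
  sw_band <- wlk >= 400 & wlk <= 480
  uv_band <- wlk >= 320 & wlk <= 380
  sgn <- c(
    if (mean(load_full[sw_band, 1L]) < 0) -1 else 1,
    if (mean(load_full[uv_band, 2L]) < 0) -1 else 1
  )
  load_full <- sweep(load_full, 2L, sgn, `*`)
  sc <- sweep(pc$x[, 1:2, drop = FALSE], 2L, sgn, `*`)

  meta <- do.call(rbind, lapply(recs, function(d)
    d[1L, c("species", "sex", "region", "specimen")]))
  spec_scores <- data.frame(meta, pc1_sw_chroma = sc[, 1L], pc2_uv = sc[, 2L],
                            row.names = NULL)

  agg <- stats::aggregate(
    cbind(pc1_sw_chroma, pc2_uv) ~ species + sex + region,
    data = spec_scores, FUN = mean)
  n_spec <- stats::aggregate(specimen ~ species + sex + region,
                             data = spec_scores, FUN = length)
  names(n_spec)[4L] <- "n_specimens"
  scores <- merge(agg, n_spec, by = c("species", "sex", "region"))
  scores <- scores[order(scores$species, scores$sex, scores$region), ]
  rownames(scores) <- NULL

  ve <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  list(scores = scores, specimen_scores = spec_scores, loadings = load_full,
       variance_explained = ve, wavelengths = common)
}

#' Sexual dichromatism score of a species
#'
#' The dichromatism score is the sum, over body regions and the two plumage
#' principal components, of the absolute male--female difference in mean
#' component score. A score of zero means the sexes have identical mean
#' colour profiles (monochromatism); larger values mean stronger
#' dichromatism. Regions missing either sex are skipped (and recorded in the
#' \code{skipped_regions} attribute).
#'
#' @param scores data.frame of plumage scores as returned in
#'   \code{reflectance_pca()$scores}.
#' @param species species to score; if \code{NULL}, all species present.
#' @return data.frame with columns \code{species}, \code{score},
#'   \code{n_regions_used}; attribute \code{skipped_regions} lists
#'   species/region combinations dropped for lacking one sex.
#' @export
dichromatism_score <- function(scores, species = NULL) {
  if (is.null(species)) species <- unique(scores$species)
  skipped <- list()
  res <- lapply(species, function(sp) {
    d <- scores[scores$species == sp, , drop = FALSE]
    m <- d[d$sex == "male", , drop = FALSE]
    f <- d[d$sex == "female", , drop = FALSE]
    if (nrow(m) == 0L || nrow(f) == 0L)
      stop("monosex species: ", sp, " lacks scored ",
           if (nrow(m) == 0L) "males" else "females")
    shared <- intersect(m$region, f$region)
    miss <- setdiff(union(m$region, f$region), shared)
    if (length(miss) > 0L)
      skipped[[sp]] <<- miss
    if (length(shared) == 0L)
      stop("monosex species: ", sp, " has no region scored for both sexes")
    m <- m[match(shared, m$region), ]
    f <- f[match(shared, f$region), ]
    s <- sum(abs(m$pc1_sw_chroma - f$pc1_sw_chroma)) +
      sum(abs(m$pc2_uv - f$pc2_uv))
    data.frame(species = sp, score = s, n_regions_used = length(shared))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "skipped_regions") <- skipped
  out
}

#' Pair-level dichromatism covariate
#'
#' The pair-level index of sexual selection S is the arithmetic mean of the
#' two member species' dichromatism scores.
#'
#' @param dichromatism data.frame from [dichromatism_score()].
#' @param pairs data.frame with columns \code{pair_id}, \code{species_1},
#'   \code{species_2}.
#' @return data.frame with \code{pair_id} and \code{S}.
#' @export
pair_dichromatism <- function(dichromatism, pairs) {
  s1 <- dichromatism$score[match(pairs$species_1, dichromatism$species)]
  s2 <- dichromatism$score[match(pairs$species_2, dichromatism$species)]
  if (anyNA(s1) || anyNA(s2)) {
    bad_sp <- unique(c(pairs$species_1[is.na(s1)], pairs$species_2[is.na(s2)]))
    stop("species without dichromatism scores: ",
         paste(bad_sp, collapse = ", "))
  }
  data.frame(pair_id = pairs$pair_id, S = (s1 + s2) / 2)
}

#' Standardized trait divergence between pair members
#'
#' Each trait is standardized across species within sex
#' (z = (value - cross-species mean) / cross-species SD); per-pair, per-trait
#' divergence is |z1 - z2|. Two pair-level summaries are returned: the
#' \emph{total} divergence (sum of |dz| across traits) and the \emph{maximum}
#' (largest single-trait |dz|). Traits with zero cross-species variance are
#' dropped with a warning; traits missing in either pair member are excluded
#' from that pair's summaries and counted in the coverage fraction.
#'
#' @param traits data.frame with columns \code{species}, \code{sex}, and one
#'   numeric column per trait.
#' @param pairs data.frame with \code{pair_id}, \code{species_1},
#'   \code{species_2}.
#' @return list with \code{divergence} (pair_id, sex, total, maximum,
#'   n_traits_used, coverage), \code{per_trait} (long data.frame of |dz| per
#'   pair x sex x trait), and \code{z} (the standardized trait table).
#' @export
standardize_and_diverge <- function(traits, pairs) {
  trait_cols <- setdiff(names(traits), c("species", "sex"))
  if (length(trait_cols) == 0L) stop("no trait columns found")

  z <- traits
  dropped <- character(0)
  for (sx in unique(traits$sex)) {
    idx <- traits$sex == sx
    for (tc in trait_cols) {
      v <- traits[[tc]][idx]
      ok <- is.finite(v)
      if (sum(ok) < 2L) { dropped <- c(dropped, tc); next }
      s <- stats::sd(v[ok])
      if (s == 0) { dropped <- c(dropped, tc); next }
      z[[tc]][idx] <- (v - mean(v[ok])) / s
    }
  }
  dropped <- unique(dropped)
  if (length(dropped) > 0L) {
    warning("traits dropped (zero cross-species SD or <2 species): ",
            paste(dropped, collapse = ", "))
    trait_cols <- setdiff(trait_cols, dropped)
    if (length(trait_cols) == 0L) stop("all traits degenerate")
  }

  rows <- list(); per_trait <- list()
  for (i in seq_len(nrow(pairs))) {
    for (sx in unique(z$sex)) {
      z1 <- z[z$species == pairs$species_1[i] & z$sex == sx, trait_cols,
              drop = FALSE]
      z2 <- z[z$species == pairs$species_2[i] & z$sex == sx, trait_cols,
              drop = FALSE]
      if (nrow(z1) == 0L || nrow(z2) == 0L) next
      dz <- abs(as.numeric(z1[1L, ]) - as.numeric(z2[1L, ]))
      use <- is.finite(dz)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], sex = sx,
        total = sum(dz[use]),
        maximum = if (any(use)) max(dz[use]) else NA_real_,
        n_traits_used = sum(use),
        coverage = sum(use) / length(trait_cols))
      per_trait[[length(per_trait) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], sex = sx,
        trait = trait_cols[use], divergence = dz[use])
    }
  }
  list(divergence = do.call(rbind, rows),
       per_trait = do.call(rbind, per_trait),
       z = z)
}

#' Evolutionary age of a lineage pair from genetic distance
#'
#' Converts a pairwise cytochrome-b genetic distance (substitutions/site,
#' total along the path joining the two lineages) into an age in million
#' years using a molecular clock of 1.05% sequence divergence per lineage
#' per Myr, i.e. 2.1% between a pair per Myr.
#'
#' @param genetic_distance non-negative numeric vector of pairwise distances.
#' @param rate_per_lineage clock rate per lineage per Myr (default 0.0105).
#' @return ages in Myr.
#' @examples
#' clock_age(0.021)  # 1 Myr
#' @export
clock_age <- function(genetic_distance, rate_per_lineage = 0.0105) {
  if (any(genetic_distance < 0, na.rm = TRUE))
    stop("genetic distance must be non-negative")
  genetic_distance / (2 * rate_per_lineage)
}
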