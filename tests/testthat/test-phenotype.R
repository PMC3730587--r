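make_spectra <- function(mat, wavelengths, species, sex, region,
                         specimen = NULL) {
  if (is.null(specimen)) specimen <- paste0("spec", seq_len(nrow(mat)))
  species <- rep_len(species, nrow(mat))
  sex <- rep_len(sex, nrow(mat))
  region <- rep_len(region, nrow(mat))
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i)
    data.frame(species = species[i], sex = sex[i], specimen = specimen[i],
               region = region[i], wavelength_nm = wavelengths,
               reflectance_pct = mat[i, ])))
}

test_that("PCA separates groups that differ only in the 400-480 nm band", {
  wl <- seq(320, 700, by = 20)
  set.seed(11)
  base <- 30 + 5 * sin(wl / 50)
  lift <- ifelse(wl >= 400 & wl <= 480, 10, 0)
  mat <- rbind(
    t(replicate(5, base + rnorm(length(wl), 0, 0.5))),
    t(replicate(5, base + lift + rnorm(length(wl), 0, 0.5))))
  spectra <- make_spectra(mat, wl, species = rep(c("a", "b"), each = 5),
                          sex = "male", region = "crown")
  res <- reflectance_pca(spectra)
  sc <- res$specimen_scores
  expect_gt(min(sc$pc1_sw_chroma[sc$species == "b"]),
            max(sc$pc1_sw_chroma[sc$species == "a"]))
})

test_that("PC1 and PC2 specimen scores are uncorrelated", {
  set.seed(12)
  wl <- seq(320, 700, by = 10)
  mat <- matrix(runif(20 * length(wl), 10, 60), nrow = 20)
  spectra <- make_spectra(mat, wl, species = paste0("s", 1:20),
                          sex = "male", region = "crown")
  res <- reflectance_pca(spectra)
  expect_lt(abs(cor(res$specimen_scores$pc1_sw_chroma,
                    res$specimen_scores$pc2_uv)), 1e-8)
})

test_that("scores match an independent eigen-decomposition on 4 spectra", {
  wl <- c(340, 420, 460, 560, 660)
  mat <- rbind(c(10, 20, 25, 15, 30),
               c(12, 35, 40, 14, 28),
               c(30, 22, 21, 40, 35),
               c( 8, 18, 30, 22, 26))
  spectra <- make_spectra(mat, wl, species = paste0("s", 1:4),
                          sex = "male", region = "crown")
  res <- reflectance_pca(spectra)
  oracle <- oracle_pca_scores(mat, wl)
  got <- res$specimen_scores[match(paste0("s", 1:4),
                                   res$specimen_scores$species), ]
  expect_equal(got$pc1_sw_chroma, oracle[, 1], tolerance = 1e-8)
  expect_equal(got$pc2_uv, oracle[, 2], tolerance = 1e-8)
})

test_that("PCA scores are invariant to a constant shift at one wavelength", {
  set.seed(13)
  wl <- seq(320, 700, by = 20)
  mat <- matrix(runif(12 * length(wl), 10, 60), nrow = 12)
  spectra <- make_spectra(mat, wl, species = paste0("s", 1:12),
                          sex = "male", region = "crown")
  shifted <- spectra
  shifted$reflectance_pct[shifted$wavelength_nm == 500] <-
    shifted$reflectance_pct[shifted$wavelength_nm == 500] + 7.3
  a <- reflectance_pca(spectra)$specimen_scores
  b <- reflectance_pca(shifted)$specimen_scores
  expect_equal(a$pc1_sw_chroma, b$pc1_sw_chroma, tolerance = 1e-8)
  expect_equal(a$pc2_uv, b$pc2_uv, tolerance = 1e-8)
})

test_that("PCA rejects degenerate and inconsistent inputs", {
  wl <- seq(320, 700, by = 20)
  flat <- matrix(5, nrow = 4, ncol = length(wl))
  spectra <- make_spectra(flat, wl, species = paste0("s", 1:4),
                          sex = "male", region = "crown")
  expect_error(reflectance_pca(spectra), "degenerate")
  expect_error(reflectance_pca(data.frame()), "missing columns")
})

make_scores <- function(m_pc1, m_pc2, f_pc1, f_pc2,
                        regions = c("crown", "throat", "belly", "tail",
                                    "back", "wing_coverts"),
                        species = "sp1") {
  rbind(
    data.frame(species = species, sex = "male", region = regions,
               pc1_sw_chroma = m_pc1, pc2_uv = m_pc2),
    data.frame(species = species, sex = "female", region = regions,
               pc1_sw_chroma = f_pc1, pc2_uv = f_pc2))
}

test_that("identical male and female profiles give dichromatism zero", {
  sc <- make_scores(1:6, 6:1, 1:6, 6:1)
  expect_equal(dichromatism_score(sc)$score, 0)
})

test_that("a single PC1 difference of 1 at the crown scores exactly 1", {
  m <- c(2, 1, 1, 1, 1, 1)
  sc <- make_scores(m, rep(0, 6), rep(1, 6), rep(0, 6))
  expect_equal(dichromatism_score(sc)$score, 1.0)
})

test_that("dichromatism equals the exhaustive sum over all 12 cells", {
  set.seed(14)
  m1 <- rnorm(6); m2 <- rnorm(6); f1 <- rnorm(6); f2 <- rnorm(6)
  sc <- make_scores(m1, m2, f1, f2)
  expect_equal(dichromatism_score(sc)$score,
               sum(abs(m1 - f1)) + sum(abs(m2 - f2)))
})

test_that("dichromatism is region-permutation invariant and sex-symmetric", {
  set.seed(15)
  m1 <- rnorm(6); m2 <- rnorm(6); f1 <- rnorm(6); f2 <- rnorm(6)
  sc <- make_scores(m1, m2, f1, f2)
  perm <- sample(6)
  sc_perm <- make_scores(m1[perm], m2[perm], f1[perm], f2[perm])
  sc_swap <- make_scores(f1, f2, m1, m2)
  expect_equal(dichromatism_score(sc_perm)$score,
               dichromatism_score(sc)$score)
  expect_equal(dichromatism_score(sc_swap)$score,
               dichromatism_score(sc)$score)
})

test_that("a species without scored females is rejected", {
  sc <- make_scores(1:6, 1:6, 1:6, 1:6)
  expect_error(dichromatism_score(sc[sc$sex == "male", ]), "monosex")
})

test_that("pair dichromatism S is the mean of the two species' scores", {
  d <- data.frame(species = c("a", "b"), score = c(1, 3))
  pairs <- data.frame(pair_id = "P1", species_1 = "a", species_2 = "b")
  expect_equal(pair_dichromatism(d, pairs)$S, 2)
  bad <- data.frame(pair_id = "P2", species_1 = "a", species_2 = "zz")
  expect_error(pair_dichromatism(d, bad), "zz")
})

toy_traits <- data.frame(
  species = c("a", "b", "c", "d"), sex = "male",
  beak = c(10, 12, 14, 16), tarsus = c(20, 20, 24, 24),
  wing = c(60, 62, 64, 70))

test_that("identical species diverge by zero in every summary", {
  tr <- rbind(toy_traits,
              within(toy_traits[1, ], species <- "a2"))
  pairs <- data.frame(pair_id = "P1", species_1 = "a", species_2 = "a2")
  res <- standardize_and_diverge(tr, pairs)
  expect_equal(res$divergence$total, 0)
  expect_equal(res$divergence$maximum, 0)
})

test_that("z-scores have mean 0 and SD 1 across species", {
  pairs <- data.frame(pair_id = "P1", species_1 = "a", species_2 = "b")
  res <- standardize_and_diverge(toy_traits, pairs)
  for (tc in c("beak", "tarsus", "wing")) {
    expect_equal(mean(res$z[[tc]]), 0, tolerance = 1e-12)
    expect_equal(sd(res$z[[tc]]), 1, tolerance = 1e-12)
  }
})

test_that("toy totals match the hand-worked z formula", {
  pairs <- data.frame(pair_id = c("P1", "P2"),
                      species_1 = c("a", "c"), species_2 = c("b", "d"))
  res <- standardize_and_diverge(toy_traits, pairs)
  hand_z <- function(v) (v - mean(v)) / sd(v)
  zb <- hand_z(toy_traits$beak); zt <- hand_z(toy_traits$tarsus)
  zw <- hand_z(toy_traits$wing)
  tot1 <- abs(zb[1] - zb[2]) + abs(zt[1] - zt[2]) + abs(zw[1] - zw[2])
  tot2 <- abs(zb[3] - zb[4]) + abs(zt[3] - zt[4]) + abs(zw[3] - zw[4])
  expect_equal(res$divergence$total, c(tot1, tot2))
  expect_equal(res$divergence$maximum,
               c(max(abs(zb[1] - zb[2]), abs(zt[1] - zt[2]),
                     abs(zw[1] - zw[2])),
                 max(abs(zb[3] - zb[4]), abs(zt[3] - zt[4]),
                     abs(zw[3] - zw[4]))))
})

test_that("maximum never exceeds total, equality iff one nonzero trait", {
  set.seed(16)
  n_sp <- 10
  tr <- data.frame(species = paste0("s", 1:n_sp), sex = "male",
                   t1 = rnorm(n_sp), t2 = rnorm(n_sp), t3 = rnorm(n_sp))
  pairs <- data.frame(pair_id = paste0("P", 1:5),
                      species_1 = paste0("s", 1:5),
                      species_2 = paste0("s", 6:10))
  res <- standardize_and_diverge(tr, pairs)
  expect_true(all(res$divergence$maximum <= res$divergence$total + 1e-12))
  one_hot <- data.frame(species = c("x", "y", "z"), sex = "male",
                        t1 = c(0, 1, 2), t2 = c(3, 3, 4))
  res2 <- standardize_and_diverge(
    one_hot, data.frame(pair_id = "P1", species_1 = "x", species_2 = "y"))
  expect_equal(res2$divergence$maximum, res2$divergence$total)
})

test_that("a zero-variance trait is dropped with a warning", {
  tr <- toy_traits
  tr$flat <- 7
  pairs <- data.frame(pair_id = "P1", species_1 = "a", species_2 = "b")
  expect_warning(res <- standardize_and_diverge(tr, pairs), "flat")
  expect_false("flat" %in% res$per_trait$trait)
})

test_that("the molecular clock converts distances as 1.05%/lineage/Myr", {
  expect_equal(clock_age(0.021), 1.0)
  expect_equal(clock_age(0), 0)
  expect_equal(clock_age(0.0105), 0.5)
  a <- 0.004; b <- 0.013
  expect_equal(clock_age(a + b), clock_age(a) + clock_age(b))
  expect_error(clock_age(-0.01), "non-negative")
})
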