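test_that("pairwise distances are symmetric, zero for identical spectra, and
           order-invariant", {
  ds <- cleanSpectra(simulatePopulation(
    flowerArchetype("gaussian_peak", center = 470, width = 45,
                    amplitude = 0.6),
    jitter = numeric(0), n = 2, seed = 1))
  for (v in list(buildViewer("bee"), buildViewer("bird_VS"))) {
    d <- pairwiseDistances(ds, v)
    expect_equal(d@distances[1, 2], 0)
  }

  jds <- cleanSpectra(simulatePopulation(
    flowerArchetype("gaussian_peak", center = 470, width = 45,
                    amplitude = 0.6),
    jitter = c(center = 8, amplitude = 0.08), n = 7, seed = 2))
  bee <- buildViewer("bee")
  d1 <- pairwiseDistances(jds, bee)
  perm <- sample(ncol(jds))
  d2 <- pairwiseDistances(jds[, perm], bee)
  expect_equal(sort(d1@distances[upper.tri(d1@distances)]),
               sort(d2@distances[upper.tri(d2@distances)]),
               tolerance = 1e-12)
  expect_error(pairwiseDistances(jds[, 1], bee), "at least 2")
})

test_that("a 15-flower population yields 105 unique pairs", {
  ds <- cleanSpectra(simulatePopulation(
    flowerArchetype("longpass_sigmoid"), jitter = c(inflection = 8),
    n = 15, seed = 4))
  fr <- fractionDiscriminable(pairwiseDistances(ds, buildViewer("bird_VS")))
  expect_identical(fr$n_flowers, 15L)
  expect_identical(fr$n_pairs, as.integer(choose(15, 2)))
  expect_identical(fr$n_pairs, 105L)
})

test_that("fraction discriminable counts strictly-above-threshold pairs", {
  # constructed 4-flower distance set {0.05, 0.12, 0.12, 0.05, 0.20, 0.02}
  d <- matrix(0, 4, 4)
  d[1, 2] <- 0.05; d[1, 3] <- 0.12; d[1, 4] <- 0.12
  d[2, 3] <- 0.05; d[2, 4] <- 0.20; d[3, 4] <- 0.02
  d <- d + t(d)
  dm <- new("DistanceMatrix", population_id = "p", species_code = "s",
            pollination_system = "Bee", viewer_label = "bee",
            flower_ids = paste0("f", 1:4), distances = d, threshold = 0.11)
  expect_equal(fractionDiscriminable(dm)$fraction_discriminable, 0.5)
  # ties at the threshold are indiscriminable
  expect_equal(fractionDiscriminable(dm, threshold = 0.12)$n_discriminable, 1L)
  # bounds
  expect_equal(fractionDiscriminable(dm, threshold = 0.3)$fraction_discriminable, 0)
  expect_equal(fractionDiscriminable(dm, threshold = 1e-9)$fraction_discriminable, 1)
  expect_error(fractionDiscriminable(dm, threshold = -1), "positive")
})

test_that("fraction discriminable is monotone non-increasing in threshold and
           never increased by duplicating a flower", {
  ds <- cleanSpectra(simulatePopulation(
    flowerArchetype("longpass_sigmoid"), jitter = c(inflection = 10),
    n = 8, seed = 11))
  bird <- buildViewer("bird_VS")
  dm <- pairwiseDistances(ds, bird)
  fr <- vapply(c(0.2, 0.5, 1, 2, 4), function(th)
    fractionDiscriminable(dm, th)$fraction_discriminable, numeric(1))
  expect_true(all(diff(fr) <= 0))

  # duplicate the first flower: its new pairs are all indiscriminable copies
  refl <- cbind(reflectance(ds), dup = reflectance(ds)[, 1])
  meta <- data.frame(flower_id = colnames(refl),
                     population_id = "p", species_code = "s",
                     pollination_system = "Bird")
  ds2 <- SpectralDataset(refl, wavelengths(ds), meta, cleaned = TRUE)
  fr2 <- fractionDiscriminable(pairwiseDistances(ds2, bird))
  expect_lte(fr2$fraction_discriminable,
             fractionDiscriminable(dm)$fraction_discriminable)
})

test_that("study summary aggregates populations, species and study levels", {
  cfg <- defaultStudyConfig(nSpecies = c(Bee = 3, Bird = 2),
                            populationsPerSpecies = 2,
                            flowersPerPopulation = 6, seed = 8)
  ds <- cleanSpectra(simulateStudy(cfg))
  s <- summarizeStudy(ds)
  pops <- populationFractions(s)
  expect_identical(nrow(pops), 10L * 2L)  # 10 populations x 2 viewers
  expect_true(all(pops$n_pairs == choose(6, 2)))

  # independent group-by recomputation of the species means
  sp <- speciesFractions(s)
  for (i in seq_len(nrow(sp))) {
    g <- pops[pops$species_code == sp$species_code[i] &
              pops$viewer_label == sp$viewer_label[i], ]
    expect_equal(sp$mean_fraction[i], mean(g$fraction_discriminable))
    expect_equal(sp$se_fraction[i],
                 sd(g$fraction_discriminable) / sqrt(nrow(g)))
  }
  st <- studyMeans(s)
  for (i in seq_len(nrow(st))) {
    g <- pops[pops$viewer_label == st$viewer_label[i], ]
    expect_equal(st$mean_over_populations[i], mean(g$fraction_discriminable))
  }
})

test_that("single-population species have undefined (NA) species-level SE", {
  cfg <- defaultStudyConfig(nSpecies = c(Bee = 2, Bird = 1),
                            populationsPerSpecies = 1,
                            flowersPerPopulation = 5, seed = 2)
  s <- summarizeStudy(cleanSpectra(simulateStudy(cfg)))
  expect_true(all(is.na(speciesFractions(s)$se_fraction)))
})

test_that("a zero-jitter study is invisible to both viewers", {
  cfg <- defaultStudyConfig(nSpecies = c(Bee = 2, Bird = 2),
                            flowersPerPopulation = 4, seed = 3)
  cfg$flowerJitter <- list(gaussian_peak = numeric(0),
                           longpass_sigmoid = numeric(0))
  s <- summarizeStudy(cleanSpectra(simulateStudy(cfg)))
  expect_true(all(populationFractions(s)$fraction_discriminable == 0))
})
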