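test_that("archetype rendering matches the defining formulas", {
  grid <- 300:700
  a <- flowerArchetype("gaussian_peak", center = 450, width = 40,
                       amplitude = 0.6, baseline = 0.05)
  r <- renderArchetype(a, grid)
  spots <- c(320, 380, 420, 450, 480, 520, 560, 600, 650, 700)
  expect_equal(r[match(spots, grid)],
               0.05 + 0.6 * exp(-(spots - 450)^2 / (2 * 40^2)),
               tolerance = 1e-12)
  expect_lte(abs(grid[which.max(r)] - 450), 1)

  s <- flowerArchetype("longpass_sigmoid", inflection = 620, steepness = 15,
                       amplitude = 0.6, baseline = 0.02)
  rs <- renderArchetype(s, grid)
  expect_equal(rs[match(spots, grid)],
               0.02 + 0.6 / (1 + exp(-(spots - 620) / 15)),
               tolerance = 1e-12)
  # monotone long-pass shape
  expect_gt(rs[grid == 700], rs[grid == 550])
  expect_gt(rs[grid == 550], rs[grid == 350])
  # red bird-type signal reflects essentially nothing in the UV
  expect_true(all(rs[grid < 400] < 0.05))

  expect_error(flowerArchetype("gaussian_peak", amplitude = -1), "negative")
  uv <- flowerArchetype("gaussian_peak",
                        uvBump = c(center = 340, amplitude = 0.2, width = 25))
  expect_gt(renderArchetype(uv, grid)[grid == 340],
            renderArchetype(a, grid)[grid == 340])
})

test_that("population simulation is seed-reproducible and zero jitter gives
           clones", {
  a <- flowerArchetype("gaussian_peak", center = 470)
  d1 <- simulatePopulation(a, jitter = c(center = 5), n = 6, seed = 42)
  d2 <- simulatePopulation(a, jitter = c(center = 5), n = 6, seed = 42)
  expect_identical(reflectance(d1), reflectance(d2))

  clones <- simulatePopulation(a, jitter = numeric(0), n = 5, seed = 1)
  expect_true(all(apply(reflectance(clones), 1, function(x)
    all(x == x[1]))))
  for (v in list(buildViewer("bee"), buildViewer("bird_VS"))) {
    fr <- fractionDiscriminable(pairwiseDistances(cleanSpectra(clones), v))
    expect_equal(fr$fraction_discriminable, 0)
  }
  expect_error(simulatePopulation(a, n = 1), "at least 2")
})

test_that("long-wavelength jitter on red flowers is conspicuous to birds but
           hidden from bees", {
  red <- flowerArchetype("longpass_sigmoid", inflection = 620,
                         steepness = 15, amplitude = 0.6, baseline = 0.02)
  ds <- cleanSpectra(simulatePopulation(red, jitter = c(inflection = 8),
                                        n = 15, seed = 7,
                                        pollination_system = "Bird"))
  beeFr <- fractionDiscriminable(pairwiseDistances(ds, buildViewer("bee")))
  birdFr <- fractionDiscriminable(pairwiseDistances(ds, buildViewer("bird_VS")))
  expect_gt(birdFr$fraction_discriminable, beeFr$fraction_discriminable)
  expect_gt(birdFr$fraction_discriminable, 0.5)
  expect_lt(beeFr$fraction_discriminable, 0.1)
})

test_that("UV-free red archetypes are achromatic in bee visual space", {
  grid <- 300:700
  bee <- buildViewer("bee")
  for (infl in c(600, 620, 640)) {
    r <- renderArchetype(flowerArchetype("longpass_sigmoid",
                                         inflection = infl, steepness = 12,
                                         amplitude = 0.65, baseline = 0.02),
                         grid)
    q <- quantumCatches(matrix(r, ncol = 1, dimnames = list(NULL, "red")), bee)
    expect_lt(hexagonPoint(q)$saturation, 0.1)
  }
})

test_that("the default study design has the paper-scale shape", {
  cfg <- defaultStudyConfig()
  ds <- simulateStudy(cfg)
  expect_identical(length(populationIds(ds)), 62L)   # (24 + 7) x 2
  expect_identical(ncol(ds), 930L)                   # 62 x 15 flowers
  expect_identical(unique(table(SummarizedExperiment::colData(ds)$population_id)),
                   15L)
  # same seed -> bit-identical dataset
  expect_identical(reflectance(simulateStudy(cfg))[, 1:20],
                   reflectance(ds)[, 1:20])
  # survives the CSV round trip with all invariants
  sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  writeSpectra(ds[, 1:30], sp, mp)
  back <- readSpectra(sp, mp)
  expect_s4_class(back, "SpectralDataset")
  expect_equal(reflectance(back), reflectance(ds[, 1:30]), tolerance = 1e-6)
})

test_that("perceived variation increases with jitter on average over seeds", {
  red <- flowerArchetype("longpass_sigmoid", inflection = 620,
                         steepness = 15, amplitude = 0.6, baseline = 0.02)
  bird <- buildViewer("bird_VS")
  frac <- function(sd, seed) {
    ds <- cleanSpectra(simulatePopulation(red, jitter = c(inflection = sd),
                                          n = 10, seed = seed))
    fractionDiscriminable(pairwiseDistances(ds, bird))$fraction_discriminable
  }
  seeds <- 1:6
  lo <- mean(vapply(seeds, function(s) frac(2, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) frac(6, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) frac(14, s), numeric(1)))
  expect_lte(lo, mid)
  expect_lte(mid, hi)
})
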