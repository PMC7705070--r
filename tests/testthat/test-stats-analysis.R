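test_that("mixed-system regrouping reproduces the robustness species counts", {
  set.seed(1)
  t <- mixedSystemsTable()  # 24 Bee + 7 Bird + 2 Bee/Bird + 4 Bee/Fly + 1 Bee/Hawkmoth
  nSpecies <- function(x) length(unique(x$species_code))

  main <- regroupMixedSystems(t, "main")
  expect_identical(nSpecies(main), 31L)

  s1 <- regroupMixedSystems(t, "beebird_to_bee")
  expect_identical(nSpecies(s1), 33L)
  expect_identical(unique(s1$pollination_system[grepl("^BBD", s1$species_code)]),
                   "Bee")

  s2 <- regroupMixedSystems(t, "beebird_to_bird")
  expect_identical(nSpecies(s2), 33L)
  expect_identical(unique(s2$pollination_system[grepl("^BBD", s2$species_code)]),
                   "Bird")

  s3 <- regroupMixedSystems(t, "mixed_to_bee")
  expect_identical(nSpecies(s3), 36L)
  expect_false(any(grepl("^BBD", s3$species_code)))

  # no mixed species -> identity
  pure <- t[t$pollination_system %in% c("Bee", "Bird"), ]
  rownames(pure) <- NULL
  expect_identical(regroupMixedSystems(pure, "beebird_to_bee")$species_code,
                   pure$species_code)
  expect_error(regroupMixedSystems(t, "bogus"))
})

test_that("the variation model recovers an injected interaction and is
           invariant to population relabeling", {
  set.seed(21)
  # pure interaction: only the bird-viewer x Bird-plant cell shifted
  t <- simulateVariationTable(shift = c(0, 0, 0, 0.3))
  fit <- fitVariationModel(t)
  lrt <- lrtTable(fit)
  expect_true(all(lrt$chisq >= 0))
  expect_lt(lrt$p_value[lrt$term == "visual_system:pollination_system"], 0.05)
  # the injected cell shift is recovered within 2 SE by the cell contrast
  ct <- contrastTable(fit)
  birdRow <- ct[ct$within == "bird" & ct$contrast == "Bee - Bird", ]
  expect_lt(abs(birdRow$estimate - (-0.3)), 2 * birdRow$se)

  # relabeling populations within species leaves the fit unchanged
  t2 <- t
  t2$population_id <- paste0("X", t2$population_id)
  fit2 <- fitVariationModel(t2, contrasts = FALSE)
  expect_equal(lrtTable(fit2)$chisq, lrt$chisq, tolerance = 1e-6)
})

test_that("interaction power at study scale is high for a strong cell shift", {
  set.seed(33)
  rej <- replicate(40, {
    t <- simulateVariationTable(shift = c(0, 0, 0, 0.3))
    fit <- fitVariationModel(t, contrasts = FALSE)
    lrtTable(fit)$p_value[3] < 0.05
  })
  expect_gte(mean(rej), 0.95)
})

test_that("degenerate analysis tables are rejected informatively", {
  set.seed(2)
  t <- simulateVariationTable()
  expect_error(fitVariationModel(t[t$visual_system == "bee", ]),
               "both visual systems")
  expect_error(fitVariationModel(t[t$pollination_system == "Bee" |
                                     t$visual_system == "bee", ]))
  # removing all-but-one Bird species trips the species-count check
  few <- t[!t$species_code %in% sprintf("R%02d", 2:7), ]
  expect_error(fitVariationModel(few), "fewer than 2 species")
  mixed <- t
  mixed$pollination_system[1:4] <- "Bee/Fly"
  expect_error(fitVariationModel(mixed), "regroup")
})

test_that("cross-space regression handles exact, null and AICc cases", {
  set.seed(4)
  t <- simulateVariationTable()
  # make bird exactly twice bee, population by population
  bee <- t$visual_system == "bee"
  key <- t$population_id
  t$fraction_discriminable[!bee] <-
    2 * t$fraction_discriminable[bee][match(key[!bee], key[bee])]
  reg <- suppressWarnings(regressAcrossSpaces(t))  # exact fit by design
  expect_equal(reg$slope[reg$model == "bird ~ bee"], 2, tolerance = 1e-8)
  expect_gt(reg$adj_r_squared[1], 0.999)
  expect_identical(sum(reg$best), 1L)

  # AICc identity against hand computation for every candidate
  wide <- data.frame(
    bee = t$fraction_discriminable[bee],
    bird = t$fraction_discriminable[!bee][match(key[bee], key[!bee])],
    pollination_system = t$pollination_system[bee])
  for (f in reg$model) {
    m <- lm(as.formula(f), data = wide)
    k <- attr(logLik(m), "df"); n <- nobs(m)
    expect_equal(reg$AICc[reg$model == f],
                 -2 * as.numeric(logLik(m)) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 tolerance = 1e-10)
  }

  # independent noise: no slope signal at study size in most seeds
  set.seed(6)
  ps <- replicate(20, {
    tn <- simulateVariationTable()
    tn$fraction_discriminable <- runif(nrow(tn))
    regressAcrossSpaces(tn)$slope_p[1]
  })
  expect_gte(mean(ps > 0.05), 0.6)
  r2 <- regressAcrossSpaces(within(simulateVariationTable(), {
    fraction_discriminable <- runif(124)
  }))$adj_r_squared[1]
  expect_lt(abs(r2), 0.2)

  # unpaired populations are named
  bad <- t[-which(bee)[1], ]
  expect_error(regressAcrossSpaces(bad), "unpaired")
})

test_that("saturation model finds bee flowers more saturated in bee space and
           is equivariant under shared rescaling", {
  cfg <- defaultStudyConfig(nSpecies = c(Bee = 6, Bird = 6),
                            flowersPerPopulation = 8, seed = 5)
  ds <- cleanSpectra(simulateStudy(cfg))
  sat <- saturationTable(ds)
  expect_identical(nrow(sat), 24L * 2L)  # 24 populations x 2 viewers

  fit <- fitSaturationModel(regroupMixedSystems(sat, "main"))
  ct <- contrastTable(fit)
  beeRow <- ct[ct$within == "bee" & ct$contrast == "Bee - Bird", ]
  expect_gt(beeRow$estimate, 0)   # bee-pollinated more saturated to bees
  expect_lt(beeRow$p_value, 0.05)

  # doubling every saturation rescales estimates but not the LRT statistics
  sat2 <- sat
  sat2$saturation <- 2 * sat2$saturation
  fit2 <- fitSaturationModel(sat2)
  expect_equal(lrtTable(fit2)$chisq, lrtTable(fit)$chisq, tolerance = 1e-4)

  # a flat saturation table shows no significant terms
  set.seed(10)
  flat <- sat
  flat$saturation <- 0.5 + rnorm(nrow(flat), 0, 1e-3)
  expect_true(all(lrtTable(fitSaturationModel(flat))$p_value > 0.05))
})
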