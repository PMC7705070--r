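#' Build the variation table for mixed-model analysis
#'
#' Reshapes per-population fractions discriminable into the analysis table:
#' one row per population x viewer with the response
#' `fraction_discriminable`, the predictor `visual_system` (`bee`/`bird`,
#' collapsing VS and UVS bird phenotypes to `bird`), `pollination_system`,
#' and the grouping variables `species_code` and `population_id` (populations
#' nested within species).
#'
#' @param x a [StudySummary-class] or its per-population data.frame.
#' @return data.frame ready for [fitVariationModel()].
#' @export
variationTable <- function(x) {
  tab <- if (methods::is(x, "StudySummary")) populationFractions(x) else x
  data.frame(
    fraction_discriminable = tab$fraction_discriminable,
    visual_system = ifelse(tab$viewer_label == "bee", "bee", "bird"),
    pollination_system = as.character(tab$pollination_system),
    species_code = as.character(tab$species_code),
    population_id = as.character(tab$population_id),
    viewer_label = as.character(tab$viewer_label))
}

#' Reassign mixed pollination systems for robustness analyses
#'
#' The main analysis keeps only species with pure `Bee` or `Bird` pollination
#' systems. Three robustness regroupings fold the mixed-system species back
#' in: `"beebird_to_bee"` counts `Bee/Bird` species as `Bee`,
#' `"beebird_to_bird"` counts them as `Bird`, and `"mixed_to_bee"` counts
#' `Bee/Fly` and `Bee/Hawkmoth` species as `Bee`. Species with systems not
#' covered by the chosen scheme are dropped, so every returned table has
#' `pollination_system` in `{Bee, Bird}`.
#'
#' @param t a [variationTable()]-style data.frame.
#' @param scheme `"main"`, `"beebird_to_bee"`, `"beebird_to_bird"`, or
#'   `"mixed_to_bee"`.
#' @return The regrouped, filtered table with a `grouping_scheme` attribute.
#' @export
regroupMixedSystems <- function(t, scheme = c("main", "beebird_to_bee",
                                              "beebird_to_bird",
                                              "mixed_to_bee")) {
  scheme <- match.arg(scheme)
  ps <- t$pollination_system
  if (scheme == "beebird_to_bee") ps[ps == "Bee/Bird"] <- "Bee"
  if (scheme == "beebird_to_bird") ps[ps == "Bee/Bird"] <- "Bird"
  if (scheme == "mixed_to_bee") ps[ps %in% c("Bee/Fly", "Bee/Hawkmoth")] <- "Bee"
  t$pollination_system <- ps
  out <- t[ps %in% c("Bee", "Bird"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grouping_scheme") <- scheme
  out
}

.aicc <- function(fit) {
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.checkCells <- function(t, response) {
  if (!all(c("bee", "bird") %in% t$visual_system))
    stop("both visual systems (bee, bird) are required")
  for (ps in unique(t$pollination_system)) {
    nsp <- length(unique(t$species_code[t$pollination_system == ps]))
    if (nsp < 2L)
      stop("pollination system '", ps, "' has fewer than 2 species")
  }
  cells <- table(t$visual_system, t$pollination_system)
  bad <- which(cells < 2L, arr.ind = TRUE)
  if (nrow(bad))
    stop("unreplicated cell(s): ",
         paste(sprintf("%s x %s", rownames(cells)[bad[, 1L]],
                       colnames(cells)[bad[, 2L]]), collapse = ", "))
  if (!response %in% names(t)) stop("table lacks response column ", response)
}

.lmmControl <- function()
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore")

.fitLMM <- function(t, response, scheme, contrasts = TRUE) {
  .checkCells(t, response)
  t$visual_system <- factor(t$visual_system, levels = c("bee", "bird"))
  t$pollination_system <- factor(t$pollination_system,
                                 levels = c("Bee", "Bird"))
  t$species_code <- factor(t$species_code)
  t$population_id <- factor(t$population_id)
  form <- function(fixed) as.formula(paste(
    response, "~", fixed,
    "+ (1 | species_code) + (1 | species_code:population_id)"))
  fit <- function(fixed) suppressMessages(suppressWarnings(
    lme4::lmer(form(fixed), data = t, REML = FALSE,
               control = .lmmControl())))
  full <- fit("visual_system * pollination_system")
  additive <- fit("visual_system + pollination_system")
  noVis <- fit("pollination_system")
  noPol <- fit("visual_system")
  lrtRow <- function(term, big, small) {
    chisq <- as.numeric(2 * (logLik(big) - logLik(small)))
    df <- attr(logLik(big), "df") - attr(logLik(small), "df")
    data.frame(term = term, chisq = max(chisq, 0), df = df,
               p_value = pchisq(max(chisq, 0), df, lower.tail = FALSE))
  }
  lrt <- rbind(
    lrtRow("visual_system", additive, noVis),
    lrtRow("pollination_system", additive, noPol),
    lrtRow("visual_system:pollination_system", full, additive))
  fe <- as.data.frame(summary(full)$coefficients)
  fe <- data.frame(term = rownames(fe), estimate = fe[, "Estimate"],
                   std_error = fe[, "Std. Error"], t_value = fe[, "t value"],
                   row.names = NULL)
  if (!contrasts)
    return(methods::new("VariationModelResult",
      response = response, groupingScheme = scheme, fixedEffects = fe,
      lrt = lrt, contrasts = data.frame(), cellMeans = data.frame(),
      fit = full))
  emGrid <- tryCatch(
    emmeans::emmeans(full, ~ visual_system * pollination_system,
                     lmer.df = "satterthwaite"),
    error = function(e)
      emmeans::emmeans(full, ~ visual_system * pollination_system,
                       lmer.df = "asymptotic"))
  cells <- data.frame(as.data.frame(emGrid))
  byViewer <- data.frame(as.data.frame(emmeans::contrast(
    emGrid, "pairwise", by = "visual_system")))
  byPlant <- data.frame(as.data.frame(emmeans::contrast(
    emGrid, "pairwise", by = "pollination_system")))
  names(byViewer)[2L] <- names(byPlant)[2L] <- "within"
  contrasts <- rbind(byViewer, byPlant)
  contrasts <- data.frame(
    contrast = contrasts$contrast, within = contrasts$within,
    estimate = contrasts$estimate, se = contrasts$SE, df = contrasts$df,
    t_ratio = contrasts$t.ratio, p_value = contrasts$p.value)
  methods::new("VariationModelResult",
    response = response, groupingScheme = scheme,
    fixedEffects = fe, lrt = lrt, contrasts = contrasts,
    cellMeans = cells, fit = full)
}

#' Fit the mixed model of perceived colour variation
#'
#' Fits a linear mixed-effects model by maximum likelihood with fraction
#' discriminable as the response; fixed effects for visual system,
#' pollination system and their interaction; and random intercepts for plant
#' species and for population nested within species. Likelihood-ratio
#' chi-square tests (full vs. reduced ML fits, df = difference in
#' fixed-effect parameters) are reported for the interaction and, from the
#' additive model, for each main effect. Cell-mean contrasts (pollination
#' system within each visual system, and visual system within each
#' pollination system) use estimated marginal means with Satterthwaite
#' degrees of freedom, unadjusted p-values. Fractions are analysed
#' untransformed on `[0, 1]`; set `logit = TRUE` for an empirical-logit
#' transform of the response.
#'
#' @param t a [variationTable()] (after [regroupMixedSystems()] if mixed
#'   systems are present; the table must only contain `Bee`/`Bird` systems).
#' @param logit analyse `log((y + 0.5/n)/(1 - y + 0.5/n))` instead of `y`
#'   (default `FALSE`).
#' @param contrasts compute estimated marginal means and cell contrasts
#'   (default `TRUE`; disable for speed in simulation studies, which only
#'   need the likelihood-ratio tests).
#' @return A [VariationModelResult-class].
#' @export
fitVariationModel <- function(t, logit = FALSE, contrasts = TRUE) {
  scheme <- attr(t, "grouping_scheme") %||% "main"
  extra <- setdiff(unique(t$pollination_system), c("Bee", "Bird"))
  if (length(extra))
    stop("table contains unregrouped pollination system(s): ",
         paste(extra, collapse = ", "), "; apply regroupMixedSystems() first")
  if (logit) {
    n <- if ("n_pairs" %in% names(t)) t$n_pairs else 105
    y <- t$fraction_discriminable
    t$fraction_discriminable <- log((y + 0.5 / n) / (1 - y + 0.5 / n))
  }
  .fitLMM(t, "fraction_discriminable", scheme, contrasts = contrasts)
}

#' Fit the mixed model of colour saturation
#'
#' Applies the same mixed-model machinery as [fitVariationModel()] with
#' saturation (spectral purity) as the response: visual system, pollination
#' system and their interaction as fixed effects, species and population
#' within species as random intercepts, ML fits and LRT chi-squares.
#'
#' Hexagon saturation (origin distance, at most 1) and RNL saturation
#' (JND to the achromatic point, often 5-20) live on incommensurable scales;
#' a single residual variance would be dominated by the bird space and mask
#' any bee-space contrast. By default the response is therefore z-scored
#' within each visual system before fitting. Within-system contrasts and the
#' interaction remain meaningful and the statistics become invariant to
#' rescaling either space; the visual-system main effect is removed by
#' construction (it is scale-arbitrary across spaces) and its LRT should not
#' be interpreted. Set `scale = FALSE` to analyse raw model units.
#'
#' @param t a [saturationTable()]-style data.frame (column `saturation`).
#' @param scale standardise saturation within visual system (default `TRUE`).
#' @return A [VariationModelResult-class].
#' @export
fitSaturationModel <- function(t, scale = TRUE) {
  scheme <- attr(t, "grouping_scheme") %||% "main"
  extra <- setdiff(unique(t$pollination_system), c("Bee", "Bird"))
  if (length(extra))
    stop("table contains unregrouped pollination system(s): ",
         paste(extra, collapse = ", "))
  if (scale) {
    for (vs in unique(t$visual_system)) {
      idx <- t$visual_system == vs
      s <- sd(t$saturation[idx])
      t$saturation[idx] <- if (s > 0)
        (t$saturation[idx] - mean(t$saturation[idx])) / s
      else t$saturation[idx] - mean(t$saturation[idx])
    }
  }
  .fitLMM(t, "saturation", scheme)
}

#' Per-population (or per-flower) saturation table
#'
#' Computes each flower's saturation in every viewer's space -- hexagon
#' origin distance for bees, RNL distance to the adaptation background for
#' birds -- and aggregates to population means by default (the unit of
#' analysis for the saturation mixed model; use `level = "flower"` to keep
#' individual flowers).
#'
#' @param x a cleaned [SpectralDataset-class].
#' @param viewers list of [ViewerPhenotype-class] or labels for
#'   [buildViewer()].
#' @param illuminant irradiance on the working grid; default D65.
#' @param level `"population"` or `"flower"`.
#' @return data.frame with `saturation`, `visual_system`,
#'   `pollination_system`, `species_code`, `population_id` (and `flower_id`
#'   at flower level).
#' @export
saturationTable <- function(x, viewers = c("bee", "bird_VS"),
                            illuminant = NULL,
                            level = c("population", "flower")) {
  level <- match.arg(level)
  if (is.character(viewers))
    viewers <- lapply(viewers, buildViewer, grid = wavelengths(x))
  meta <- data.frame(flower_id = flowerIds(x), as.data.frame(colData(x)))
  out <- list()
  for (v in viewers) {
    pts <- colorPoints(x, v, illuminant)
    tab <- merge(meta, pts[, c("flower_id", "saturation")], by = "flower_id")
    tab$viewer_label <- v@label
    tab$visual_system <- if (v@model == "hexagon") "bee" else "bird"
    out[[length(out) + 1L]] <- tab
  }
  tab <- do.call(rbind, out)
  if (level == "flower") return(tab)
  key <- interaction(tab$population_id, tab$viewer_label, drop = TRUE)
  agg <- lapply(split(tab, key), function(g) data.frame(
    saturation = mean(g$saturation),
    visual_system = g$visual_system[1L],
    pollination_system = g$pollination_system[1L],
    species_code = g$species_code[1L],
    population_id = g$population_id[1L],
    viewer_label = g$viewer_label[1L]))
  do.call(rbind, c(agg, list(make.row.names = FALSE)))
}

#' Regress bird-perceived on bee-perceived variation
#'
#' Tests whether the amount of perceived colour variation is correlated
#' across visual spaces by regressing bird fraction discriminable on bee
#' fraction discriminable per population. Three nested candidates are
#' compared by small-sample-corrected AIC
#' (`AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`): slope only, plus pollination
#' system, plus the pollination system x bee-fraction interaction.
#'
#' @param t a [variationTable()]-style table containing paired bee and bird
#'   rows for every population.
#' @return data.frame, one row per candidate model: formula, `k`, `AICc`,
#'   `delta_AICc`, `adj_r_squared`, `slope`, `slope_p`, `best`.
#' @export
regressAcrossSpaces <- function(t) {
  bee <- t[t$visual_system == "bee", ]
  bird <- t[t$visual_system == "bird", ]
  if (anyDuplicated(bee$population_id) || anyDuplicated(bird$population_id))
    stop("multiple rows per population and visual system; one bird viewer ",
         "at a time")
  unpaired <- union(setdiff(bee$population_id, bird$population_id),
                    setdiff(bird$population_id, bee$population_id))
  if (length(unpaired))
    stop("unpaired population(s): ", paste(unpaired, collapse = ", "))
  wide <- data.frame(
    population_id = bee$population_id,
    pollination_system = factor(bee$pollination_system),
    bee = bee$fraction_discriminable,
    bird = bird$fraction_discriminable[
      match(bee$population_id, bird$population_id)])
  forms <- c("bird ~ bee",
             "bird ~ bee + pollination_system",
             "bird ~ bee * pollination_system")
  rows <- lapply(forms, function(f) {
    m <- stats::lm(as.formula(f), data = wide)
    sm <- summary(m)
    data.frame(model = f,
               k = attr(logLik(m), "df"),
               AICc = .aicc(m),
               adj_r_squared = sm$adj.r.squared,
               slope = coef(m)[["bee"]],
               slope_p = sm$coefficients["bee", "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  out$delta_AICc <- out$AICc - min(out$AICc)
  out$best <- out$delta_AICc == 0
  rownames(out) <- NULL
  out[, c("model", "k", "AICc", "delta_AICc", "adj_r_squared", "slope",
          "slope_p", "best")]
}

setMethod("show", "VariationModelResult", function(object) {
  cat(sprintf("VariationModelResult: %s ~ visual_system * pollination_system",
              object@response),
      sprintf("(scheme: %s)\n", object@groupingScheme))
  cat("Likelihood-ratio tests (ML):\n")
  print(object@lrt, row.names = FALSE, digits = 4)
  cat("Cell-mean contrasts:\n")
  print(object@contrasts, row.names = FALSE, digits = 4)
})

#' @rdname VariationModelResult-accessors
#' @param x a [VariationModelResult-class].
#' @export
lrtTable <- function(x) x@lrt

#' Accessors for VariationModelResult
#' @rdname VariationModelResult-accessors
#' @export
contrastTable <- function(x) x@contrasts

#' @rdname VariationModelResult-accessors
#' @export
cellMeans <- function(x) x@cellMeans
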