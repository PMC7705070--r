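#' Pairwise colour distances within one population
#'
#' Computes the full symmetric matrix of colour distances between the flowers
#' of a (single-population) dataset as perceived by one viewer: Euclidean
#' hexagon distances for a hexagon viewer, Delta S for an RNL viewer.
#'
#' @param x a cleaned [SpectralDataset-class], normally one population
#'   (see [populationSubset()]); must contain at least 2 flowers.
#' @param viewer a [ViewerPhenotype-class].
#' @param illuminant irradiance on the viewer's grid; default D65.
#' @return A [DistanceMatrix-class].
#' @examples
#' ds <- cleanSpectra(simulatePopulation(
#'   flowerArchetype("gaussian_peak", center = 450, width = 40,
#'                   amplitude = 0.6),
#'   jitter = c(center = 5), n = 4, seed = 1))
#' d <- pairwiseDistances(ds, buildViewer("bee"))
#' fractionDiscriminable(d)
#' @export
pairwiseDistances <- function(x, viewer, illuminant = NULL) {
  if (ncol(x) < 2L)
    stop("need at least 2 flowers to form pairs")
  pop <- unique(as.character(colData(x)$population_id))
  q <- quantumCatches(x, viewer, illuminant)
  n <- nrow(q)
  if (viewer@model == "hexagon") {
    pts <- hexagonPoint(q)
    d <- as.matrix(dist(cbind(pts$x, pts$y)))
  } else {
    e <- rnlNoise(viewer)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- rnlDistance(q[i, ], q[j, ], e)
  }
  dimnames(d) <- list(rownames(q), rownames(q))
  cd <- colData(x)
  methods::new("DistanceMatrix",
    population_id = paste(pop, collapse = "+"),
    species_code = paste(unique(as.character(cd$species_code)), collapse = "+"),
    pollination_system = paste(unique(as.character(cd$pollination_system)),
                               collapse = "+"),
    viewer_label = viewer@label,
    flower_ids = rownames(q),
    distances = d,
    threshold = viewer@threshold)
}

setMethod("show", "DistanceMatrix", function(object) {
  n <- length(object@flower_ids)
  off <- object@distances[upper.tri(object@distances)]
  cat(sprintf(
    "DistanceMatrix: population %s, viewer %s, %d flowers (%d pairs)\n",
    object@population_id, object@viewer_label, n, length(off)))
  cat(sprintf("  distances %.4g-%.4g, threshold %g, %d pair(s) above\n",
              min(off), max(off), object@threshold,
              sum(off > object@threshold)))
})

#' Fraction of flower pairs a viewer can discriminate
#'
#' Counts the within-population flower pairs whose colour distance strictly
#' exceeds the viewer's discrimination threshold: pairs at or below the
#' threshold (including ties at exactly 0.11 hexagon units or 1 JND) are
#' indiscriminable. For `n` flowers there are `n (n - 1) / 2` pairs.
#'
#' @param d a [DistanceMatrix-class].
#' @param threshold override of the threshold stored in `d` (model units).
#' @return One-row data.frame: `population_id`, `species_code`,
#'   `pollination_system`, `viewer_label`, `n_flowers`, `n_pairs`,
#'   `n_discriminable`, `fraction_discriminable`.
#' @rdname fractionDiscriminable
#' @export
setMethod("fractionDiscriminable", "DistanceMatrix",
  function(d, threshold = NULL) {
    if (is.null(threshold)) threshold <- d@threshold
    if (threshold <= 0) stop("threshold must be positive")
    n <- length(d@flower_ids)
    if (n < 2L) stop("distance matrix has no pairs")
    off <- d@distances[upper.tri(d@distances)]
    disc <- sum(off > threshold)
    data.frame(
      population_id = d@population_id,
      species_code = d@species_code,
      pollination_system = d@pollination_system,
      viewer_label = d@viewer_label,
      n_flowers = n,
      n_pairs = length(off),
      n_discriminable = disc,
      fraction_discriminable = disc / length(off))
  })

.se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_

#' Summarise perceived variation across a whole study
#'
#' Runs the distance/threshold machinery for every population and viewer and
#' aggregates: per-population fractions discriminable, species-level means
#' and standard errors across each species' 1-3 populations (SE undefined,
#' hence `NA`, for single-population species), and study-wide means per
#' viewer computed both across populations and across species means (the two
#' conventions can differ when species contribute unequal population counts,
#' so both are reported).
#'
#' @param x a cleaned [SpectralDataset-class] covering the whole study.
#' @param viewers list of [ViewerPhenotype-class] objects (or character
#'   labels passed to [buildViewer()]).
#' @param illuminant irradiance on the working grid; default D65.
#' @return A [StudySummary-class].
#' @export
summarizeStudy <- function(x, viewers = c("bee", "bird_VS"),
                           illuminant = NULL) {
  if (is.character(viewers))
    viewers <- lapply(viewers, buildViewer, grid = wavelengths(x))
  pops <- populationIds(x)
  rows <- list()
  for (v in viewers) {
    for (p in pops) {
      sub <- populationSubset(x, p)
      if (ncol(sub) < 2L)
        stop("population ", p, " has fewer than 2 flowers")
      d <- pairwiseDistances(sub, v, illuminant)
      rows[[length(rows) + 1L]] <- fractionDiscriminable(d)
    }
  }
  popTab <- do.call(rbind, rows)
  key <- interaction(popTab$species_code, popTab$viewer_label, drop = TRUE)
  spRows <- lapply(split(popTab, key), function(g) data.frame(
    species_code = g$species_code[1L],
    pollination_system = g$pollination_system[1L],
    viewer_label = g$viewer_label[1L],
    n_populations = nrow(g),
    mean_fraction = mean(g$fraction_discriminable),
    se_fraction = .se(g$fraction_discriminable)))
  spTab <- do.call(rbind, c(spRows, list(make.row.names = FALSE)))
  stRows <- lapply(split(popTab, popTab$viewer_label), function(g) {
    sp <- spTab[spTab$viewer_label == g$viewer_label[1L], ]
    data.frame(
      viewer_label = g$viewer_label[1L],
      n_populations = nrow(g),
      n_species = nrow(sp),
      mean_over_populations = mean(g$fraction_discriminable),
      mean_over_species = mean(sp$mean_fraction),
      min_fraction = min(g$fraction_discriminable),
      max_fraction = max(g$fraction_discriminable))
  })
  stTab <- do.call(rbind, c(stRows, list(make.row.names = FALSE)))
  methods::new("StudySummary", populations = popTab, species = spTab,
               study = stTab)
}

setMethod("show", "StudySummary", function(object) {
  cat(sprintf("StudySummary: %d populations x %d viewer(s)\n",
              length(unique(object@populations$population_id)),
              length(unique(object@populations$viewer_label))))
  print(object@study, row.names = FALSE, digits = 3)
})

#' @rdname StudySummary-accessors
#' @param x a [StudySummary-class].
#' @export
populationFractions <- function(x) x@populations

#' Accessors for StudySummary tables
#' @rdname StudySummary-accessors
#' @export
speciesFractions <- function(x) x@species

#' @rdname StudySummary-accessors
#' @export
studyMeans <- function(x) x@study
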