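#' SpectralDataset: reflectance spectra with flower metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one reflectance
#' spectrum per flower. Rows are wavelengths (nm), columns are flowers; the
#' single assay `"reflectance"` stores reflectance as a proportion. Per-flower
#' metadata (`population_id`, `species_code`, `pollination_system`) lives in
#' `colData`, the wavelength grid in `rowData(x)$wavelength`.
#'
#' Invariants enforced by the validity method: strictly increasing wavelength
#' grid; matching assay dimensions; unique flower ids; complete metadata
#' columns. Cleaned datasets (see [cleanSpectra()]) additionally span exactly
#' 300-700 nm on a uniform grid with no negative reflectance, recorded in
#' `metadata(x)$cleaned`.
#'
#' @slot See [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [readSpectra()], [cleanSpectra()], [simulateStudy()]
#' @export
setClass("SpectralDataset", contains = "SummarizedExperiment")

.requiredMetaCols <- c("population_id", "species_code", "pollination_system")

.pollinationSystems <- c("Bee", "Bird", "Bee/Fly", "Bee/Bird", "Bee/Hawkmoth")

setValidity("SpectralDataset", function(object) {
  msg <- character()
  wl <- rowData(object)$wavelength
  if (is.null(wl)) {
    msg <- c(msg, "rowData must contain a 'wavelength' column")
  } else {
    if (any(!is.finite(wl))) msg <- c(msg, "wavelengths must be finite")
    if (any(diff(wl) <= 0)) msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if (!"reflectance" %in% names(assays(object)))
    msg <- c(msg, "assay 'reflectance' is required")
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "flower ids (colnames) must be present and unique")
  missing <- setdiff(.requiredMetaCols, names(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks metadata column(s): ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ViewerPhenotype: a pollinator's visual system
#'
#' Bundles everything needed to model one viewer: receptor spectral
#' sensitivities on the working wavelength grid, relative receptor densities,
#' the Weber fraction of the most abundant receptor class, the colour-space
#' model (`"hexagon"` for trichromatic bees, `"rnl"` for birds), the
#' behavioural discrimination threshold in model units, and the adaptation
#' background reflectance used for von Kries normalisation.
#'
#' @slot label character, e.g. `"bee"`, `"bird_VS"`, `"bird_UVS"`.
#' @slot wavelengths numeric wavelength grid (nm), strictly increasing.
#' @slot sensitivities numeric matrix, one column per receptor (ordered short
#'   to long wavelength), unit peak, on `wavelengths`.
#' @slot lambdaMax numeric, nominal peak wavelength per receptor (nm).
#' @slot densities numeric, relative receptor densities (RNL noise scaling).
#' @slot weberFraction numeric scalar, Weber fraction of the densest class.
#' @slot model `"hexagon"` or `"rnl"`.
#' @slot threshold numeric scalar, discrimination threshold in model units.
#' @slot background numeric, background reflectance on `wavelengths`.
#' @seealso [buildViewer()], [quantumCatches()], [rnlNoise()]
#' @export
setClass("ViewerPhenotype",
  representation(
    label = "character",
    wavelengths = "numeric",
    sensitivities = "matrix",
    lambdaMax = "numeric",
    densities = "numeric",
    weberFraction = "numeric",
    model = "character",
    threshold = "numeric",
    background = "numeric"
  )
)

setValidity("ViewerPhenotype", function(object) {
  msg <- character()
  n <- ncol(object@sensitivities)
  if (nrow(object@sensitivities) != length(object@wavelengths))
    msg <- c(msg, "sensitivity rows must match wavelength grid")
  if (any(object@sensitivities < 0))
    msg <- c(msg, "sensitivities must be non-negative")
  if (length(object@densities) != n)
    msg <- c(msg, "one density per receptor required")
  if (any(object@densities <= 0))
    msg <- c(msg, "receptor densities must be positive")
  if (length(object@weberFraction) != 1L || object@weberFraction <= 0)
    msg <- c(msg, "weberFraction must be a positive scalar")
  if (!object@model %in% c("hexagon", "rnl"))
    msg <- c(msg, "model must be 'hexagon' or 'rnl'")
  if (object@model == "hexagon" && n != 3L)
    msg <- c(msg, "hexagon model requires exactly 3 receptors")
  if (object@threshold <= 0)
    msg <- c(msg, "threshold must be positive")
  if (length(object@background) != length(object@wavelengths))
    msg <- c(msg, "background must be on the viewer's wavelength grid")
  if (any(object@background < 0))
    msg <- c(msg, "background reflectance must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: pairwise colour distances within one population
#'
#' Symmetric matrix of colour distances (hexagon units or JND) between all
#' flowers of one population as seen by one viewer, with the population's
#' metadata carried along for downstream tabulation.
#'
#' @slot population_id,species_code,pollination_system character metadata.
#' @slot viewer_label character, the viewer the distances belong to.
#' @slot flower_ids character, flower ordering of the matrix.
#' @slot distances numeric symmetric matrix, zero diagonal, model units.
#' @slot threshold numeric, the viewer's discrimination threshold.
#' @seealso [pairwiseDistances()], [fractionDiscriminable()]
#' @export
setClass("DistanceMatrix",
  representation(
    population_id = "character",
    species_code = "character",
    pollination_system = "character",
    viewer_label = "character",
    flower_ids = "character",
    distances = "matrix",
    threshold = "numeric"
  )
)

setValidity("DistanceMatrix", function(object) {
  d <- object@distances
  msg <- character()
  if (nrow(d) != ncol(d)) msg <- c(msg, "distance matrix must be square")
  if (nrow(d) != length(object@flower_ids))
    msg <- c(msg, "flower_ids must match matrix dimension")
  if (any(abs(d - t(d)) > 1e-10)) msg <- c(msg, "distances must be symmetric")
  if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(d < 0)) msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StudySummary: fraction-discriminable tables at three aggregation levels
#'
#' @slot populations data.frame, one row per population x viewer with pair
#'   counts and fraction discriminable.
#' @slot species data.frame, species-level mean fraction and SE across that
#'   species' populations (SE is `NA` for single-population species).
#' @slot study data.frame, study-wide means per viewer computed two ways:
#'   across populations and across species means.
#' @seealso [summarizeStudy()]
#' @export
setClass("StudySummary",
  representation(
    populations = "data.frame",
    species = "data.frame",
    study = "data.frame"
  )
)

#' VariationModelResult: mixed-model fit of perceived variation
#'
#' Result container for the linear mixed-effects analysis of fraction
#' discriminable (or saturation): fixed-effect estimates, likelihood-ratio
#' chi-square tests for the interaction and main effects (models fit by ML),
#' cell-mean contrasts, and the grouping scheme the input table used.
#'
#' @slot response character, name of the modelled response.
#' @slot groupingScheme character, one of `"main"`, `"beebird_to_bee"`,
#'   `"beebird_to_bird"`, `"mixed_to_bee"`.
#' @slot fixedEffects data.frame of fixed-effect estimates.
#' @slot lrt data.frame with one row per tested term: chi-square, df, p.
#' @slot contrasts data.frame of cell-mean contrasts (estimate, t ratio, p).
#' @slot cellMeans data.frame of estimated marginal means per cell.
#' @slot fit the fitted `lmerMod` object (ML).
#' @seealso [fitVariationModel()], [fitSaturationModel()]
#' @export
setClass("VariationModelResult",
  representation(
    response = "character",
    groupingScheme = "character",
    fixedEffects = "data.frame",
    lrt = "data.frame",
    contrasts = "data.frame",
    cellMeans = "data.frame",
    fit = "ANY"
  )
)
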