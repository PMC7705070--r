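#' Construct a SpectralDataset
#'
#' @param reflectance numeric matrix, wavelengths in rows and flowers in
#'   columns (proportions; raw data may contain negatives until cleaned).
#' @param wavelengths numeric, strictly increasing wavelength grid in nm.
#' @param metadata data.frame with columns `flower_id`, `population_id`,
#'   `species_code`, `pollination_system`, one row per flower.
#' @param cleaned logical flag recorded in `metadata(x)$cleaned`.
#' @return A [SpectralDataset-class] object.
#' @examples
#' wl <- 300:700
#' refl <- matrix(runif(length(wl) * 2, 0, 1), ncol = 2,
#'                dimnames = list(NULL, c("f1", "f2")))
#' meta <- data.frame(flower_id = c("f1", "f2"), population_id = "p1",
#'                    species_code = "sp1", pollination_system = "Bee")
#' ds <- SpectralDataset(refl, wl, meta)
#' @export
SpectralDataset <- function(reflectance, wavelengths, metadata, cleaned = FALSE) {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelengths))
    stop("reflectance must have one row per wavelength")
  if (is.null(colnames(reflectance)))
    colnames(reflectance) <- metadata$flower_id
  metadata <- as.data.frame(metadata)
  if (!"flower_id" %in% names(metadata))
    stop("metadata must contain a 'flower_id' column")
  if (anyDuplicated(metadata$flower_id))
    stop("duplicate flower_id in metadata: ",
         paste(unique(metadata$flower_id[duplicated(metadata$flower_id)]),
               collapse = ", "))
  absent <- setdiff(colnames(reflectance), metadata$flower_id)
  if (length(absent))
    stop("flower(s) present in spectra but missing from metadata: ",
         paste(absent, collapse = ", "))
  metadata <- metadata[match(colnames(reflectance), metadata$flower_id), ,
                       drop = FALSE]
  cd <- DataFrame(metadata[setdiff(names(metadata), "flower_id")],
                  row.names = metadata$flower_id)
  se <- SummarizedExperiment(
    assays = list(reflectance = reflectance),
    rowData = DataFrame(wavelength = as.numeric(wavelengths)),
    colData = cd
  )
  out <- methods::new("SpectralDataset", se)
  metadata(out)$cleaned <- isTRUE(cleaned)
  methods::validObject(out)
  out
}

#' Accessors for SpectralDataset
#'
#' `wavelengths()` returns the wavelength grid (nm), `reflectance()` the
#' wavelength x flower reflectance matrix, `flowerIds()` the flower ids.
#'
#' @param x a [SpectralDataset-class].
#' @name SpectralDataset-accessors
#' @aliases wavelengths reflectance flowerIds
NULL

#' @rdname SpectralDataset-accessors
#' @export
setMethod("wavelengths", "SpectralDataset", function(x)
  as.numeric(rowData(x)$wavelength))

#' @rdname SpectralDataset-accessors
#' @export
setMethod("reflectance", "SpectralDataset", function(x)
  assay(x, "reflectance"))

#' @rdname SpectralDataset-accessors
#' @export
setMethod("flowerIds", "SpectralDataset", function(x) colnames(x))

setMethod("show", "SpectralDataset", function(object) {
  wl <- wavelengths(object)
  cat(sprintf(
    "SpectralDataset: %d flowers, %d wavelengths (%g-%g nm)%s\n",
    ncol(object), length(wl), min(wl), max(wl),
    if (isTRUE(metadata(object)$cleaned)) ", cleaned" else " (raw)"))
  cd <- colData(object)
  cat(sprintf("  %d population(s), %d species, systems: %s\n",
              length(unique(cd$population_id)),
              length(unique(cd$species_code)),
              paste(sort(unique(cd$pollination_system)), collapse = ", ")))
})

#' Read reflectance spectra and flower metadata
#'
#' Reads a wide-format spectra CSV (first column `wl` = wavelength in nm, one
#' column per flower) together with a metadata CSV (`flower_id`,
#' `population_id`, `species_code`, `pollination_system`). Reflectance given
#' in percent is rescaled to proportions automatically when any value exceeds
#' `percentThreshold` (field spectrometer exports are commonly in percent);
#' set `percent` to `TRUE`/`FALSE` to override the heuristic.
#'
#' Spectra are returned raw (untrimmed, possibly with spurious negative
#' values); pass the result through [cleanSpectra()] before visual modeling.
#'
#' @param path wide spectra CSV.
#' @param metadataPath metadata CSV.
#' @param percent `NA` (auto-detect), or logical forcing the interpretation.
#' @param percentThreshold auto-detection cut-off on the maximum value.
#' @return A raw [SpectralDataset-class].
#' @seealso [writeSpectra()], [cleanSpectra()]
#' @export
readSpectra <- function(path, metadataPath, percent = NA,
                        percentThreshold = 1.5) {
  spec <- read.csv(path, check.names = FALSE)
  if (ncol(spec) < 2L)
    stop("spectra file needs a wavelength column plus at least one flower")
  wl <- as.numeric(spec[[1L]])
  if (any(diff(wl) <= 0))
    stop("wavelength column must be strictly increasing (non-monotone grid)")
  ids <- names(spec)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate flower_id in spectra file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  refl <- as.matrix(spec[, -1L, drop = FALSE])
  storage.mode(refl) <- "double"
  if (is.na(percent)) percent <- max(refl, na.rm = TRUE) > percentThreshold
  if (percent) refl <- refl / 100
  meta <- read.csv(metadataPath, check.names = FALSE,
                   colClasses = "character")
  need <- c("flower_id", .requiredMetaCols)
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  SpectralDataset(refl, wl, meta)
}

#' Write a SpectralDataset to wide spectra + metadata CSVs
#'
#' Inverse of [readSpectra()]: reflectance is written as proportions, so a
#' write/read round trip reproduces the dataset.
#'
#' @param x a [SpectralDataset-class].
#' @param path output spectra CSV (wide, first column `wl`).
#' @param metadataPath output metadata CSV.
#' @return Invisibly, `x`.
#' @export
writeSpectra <- function(x, path, metadataPath) {
  out <- data.frame(wl = wavelengths(x), check.names = FALSE)
  out <- cbind(out, as.data.frame(reflectance(x), check.names = FALSE))
  write.csv(out, path, row.names = FALSE)
  cd <- as.data.frame(colData(x))
  meta <- cbind(flower_id = rownames(cd), cd)
  write.csv(meta, metadataPath, row.names = FALSE)
  invisible(x)
}

.cleanMatrix <- function(refl, wl, gridStep) {
  if (min(wl) > 300 || max(wl) < 700)
    stop(sprintf(
      "spectrum does not cover 300-700 nm (observed %g-%g nm; gap: %s)",
      min(wl), max(wl),
      paste(c(if (min(wl) > 300) sprintf("300-%g", min(wl)),
              if (max(wl) < 700) sprintf("%g-700", max(wl))),
            collapse = " and ")))
  grid <- seq(300, 700, by = gridStep)
  out <- apply(refl, 2L, function(r)
    approx(wl, r, xout = grid, method = "linear")$y)
  out <- matrix(out, nrow = length(grid), dimnames = list(NULL, colnames(refl)))
  out[out < 0] <- 0
  list(refl = out, wl = grid)
}

#' Clean reflectance spectra for visual modeling
#'
#' Trims spectra to 300-700 nm, interpolates linearly onto a uniform grid
#' (default 1 nm) and sets spurious negative reflectance values to zero.
#' Values above 1 (white-standard overshoot) are kept. The operation is
#' idempotent.
#'
#' @param x a [SpectralDataset-class] (raw or already cleaned).
#' @param gridStep target grid spacing in nm.
#' @return A cleaned [SpectralDataset-class] on `seq(300, 700, gridStep)`.
#' @examples
#' ds <- simulatePopulation(flowerArchetype("gaussian_peak", center = 450,
#'   width = 40, amplitude = 0.6), n = 3, seed = 1)
#' cleaned <- cleanSpectra(ds)
#' range(wavelengths(cleaned))
#' @rdname cleanSpectra
#' @export
setMethod("cleanSpectra", "SpectralDataset", function(x, gridStep = 1) {
  cl <- .cleanMatrix(reflectance(x), wavelengths(x), gridStep)
  meta <- cbind(flower_id = colnames(x),
                as.data.frame(colData(x)))
  SpectralDataset(cl$refl, cl$wl, meta, cleaned = TRUE)
})

#' Subset a SpectralDataset to one population
#'
#' @param x a [SpectralDataset-class].
#' @param population a `population_id` present in the metadata.
#' @return The [SpectralDataset-class] restricted to that population.
#' @export
populationSubset <- function(x, population) {
  keep <- colData(x)$population_id == population
  if (!any(keep)) stop("unknown population: ", population)
  x[, keep]
}

#' Population ids of a dataset
#' @param x a [SpectralDataset-class].
#' @return Character vector of unique population ids.
#' @export
populationIds <- function(x) unique(as.character(colData(x)$population_id))
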