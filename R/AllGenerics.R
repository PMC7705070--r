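#' @rdname SpectralDataset-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralDataset-accessors
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname SpectralDataset-accessors
#' @export
setGeneric("flowerIds", function(x) standardGeneric("flowerIds"))

#' @rdname cleanSpectra
#' @export
setGeneric("cleanSpectra", function(x, gridStep = 1) standardGeneric("cleanSpectra"))

#' @rdname quantumCatches
#' @export
setGeneric("quantumCatches",
  function(x, viewer, illuminant = NULL, adapt = TRUE)
    standardGeneric("quantumCatches"))

#' @rdname fractionDiscriminable
#' @export
setGeneric("fractionDiscriminable",
  function(d, threshold = NULL) standardGeneric("fractionDiscriminable"))
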