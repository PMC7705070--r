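#' Visual pigment sensitivity from the A1 nomogram
#'
#' Generates a receptor spectral-sensitivity curve from its peak wavelength
#' using the Govardovskii A1 visual-pigment template (alpha band plus the
#' short-wavelength beta band), normalised to unit peak. Deterministic: the
#' same `lambdaMax` on the same grid always yields bit-identical curves.
#'
#' @param lambdaMax peak wavelength in nm, within the grid.
#' @param grid wavelength grid in nm (default 300:700).
#' @param beta include the beta band; default (`NULL`) includes it for
#'   `lambdaMax >= 400` and omits it for short-wavelength pigments, whose
#'   beta band coincides with the alpha peak and would displace it.
#' @return Numeric vector of sensitivities on `grid`, max exactly 1.
#' @references Govardovskii et al. (2000) In search of the visual pigment
#'   template. Visual Neuroscience 17:509-528.
#' @examples
#' s <- pigmentTemplate(544)
#' which.max(s) # near 544 nm
#' @export
pigmentTemplate <- function(lambdaMax, grid = 300:700, beta = NULL) {
  if (length(lambdaMax) != 1L || !is.finite(lambdaMax))
    stop("lambdaMax must be a single finite wavelength")
  if (lambdaMax < min(grid) || lambdaMax > max(grid))
    stop("lambdaMax (", lambdaMax, " nm) outside the wavelength grid")
  if (is.null(beta)) beta <- lambdaMax >= 400
  x <- lambdaMax / grid
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta) {
    lmb <- 189 + 0.315 * lambdaMax
    b <- -40.5 + 0.195 * lambdaMax
    s <- s + 0.26 * exp(-((grid - lmb) / b)^2)
  }
  s / max(s)
}

#' D65 standard daylight illuminant
#'
#' The CIE D65 relative spectral power distribution (300-700 nm), converted
#' from relative energy to relative quanta (photon flux is proportional to
#' energy times wavelength) and linearly interpolated to the working grid.
#' Quantum-catch computation is invariant to the overall scale of the
#' illuminant under von Kries adaptation.
#'
#' @param grid wavelength grid in nm.
#' @param quanta convert to relative quanta (default `TRUE`).
#' @return Numeric irradiance vector on `grid`, normalised to max 1.
#' @export
illuminantD65 <- function(grid = 300:700, quanta = TRUE) {
  path <- system.file("extdata", "illuminant_d65.csv",
                      package = "floravision", mustWork = TRUE)
  tab <- read.csv(path)
  irr <- approx(tab$wl, tab$relative_energy, xout = grid, rule = 2)$y
  if (quanta) irr <- irr * grid
  irr / max(irr)
}

#' Flat (ideal achromatic) illuminant
#' @param grid wavelength grid in nm.
#' @return Unit irradiance on `grid`.
#' @export
illuminantFlat <- function(grid = 300:700) rep(1, length(grid))

.avianPhenotypes <- function() {
  path <- system.file("extdata", "avian_phenotypes.csv",
                      package = "floravision", mustWork = TRUE)
  read.csv(path)
}

.beeLambdaMax <- c(uv = 344, blue = 436, green = 544)

.readBackground <- function(background, grid) {
  if (is.null(background)) return(rep(0.5, length(grid)))
  if (is.character(background) && length(background) == 1L) {
    tab <- read.csv(background)
    return(approx(tab[[1L]], tab[[2L]], xout = grid, rule = 2)$y)
  }
  if (is.numeric(background)) {
    if (length(background) == 1L) return(rep(background, length(grid)))
    if (length(background) == length(grid)) return(as.numeric(background))
  }
  stop("background must be NULL, a scalar, a vector on the grid, or a CSV path")
}

#' Build a viewer phenotype
#'
#' Constructs the visual system of a named pollinator viewer. `"bee"` gives
#' the honeybee trichromat (receptor peaks 344/436/544 nm) evaluated with the
#' colour-hexagon model and a discrimination threshold of 0.11 hexagon units.
#' `"bird_VS"` and `"bird_UVS"` give the average violet-sensitive and
#' UV-sensitive avian tetrachromats (peak wavelengths from the packaged
#' phenotype table), evaluated with the receptor-noise limited model,
#' relative receptor densities 1:2:2:4 (shortest to longest), Weber fraction
#' 0.1 for the densest (long-wavelength) class, and a threshold of 1 JND.
#'
#' Every default is overridable: `lambdaMax`, `densities`, `weber`,
#' `threshold`, `background` (scalar reflectance, vector on the grid, or a
#' two-column CSV path), or a full `sensitivities` matrix replacing the
#' nomogram-generated curves (e.g. literature sensitivities including ocular
#' media or oil-droplet filtering).
#'
#' @param label `"bee"`, `"bird_VS"` or `"bird_UVS"`.
#' @param grid wavelength grid in nm (default 300:700, 1 nm).
#' @param lambdaMax optional receptor peak wavelengths (nm), short to long.
#' @param densities optional relative receptor densities.
#' @param weber optional Weber fraction of the densest receptor class.
#' @param threshold optional discrimination threshold in model units.
#' @param background adaptation background reflectance (default flat 0.5).
#' @param sensitivities optional matrix of sensitivity curves on `grid`
#'   (one column per receptor); overrides the nomogram.
#' @return A [ViewerPhenotype-class].
#' @examples
#' bee <- buildViewer("bee")
#' bird <- buildViewer("bird_VS")
#' rnlNoise(bird)
#' @export
buildViewer <- function(label = c("bee", "bird_VS", "bird_UVS"),
                        grid = 300:700, lambdaMax = NULL, densities = NULL,
                        weber = NULL, threshold = NULL, background = NULL,
                        sensitivities = NULL) {
  label <- match.arg(label)
  if (label == "bee") {
    lmax <- if (is.null(lambdaMax)) .beeLambdaMax else lambdaMax
    dens <- if (is.null(densities)) rep(1, length(lmax)) else densities
    model <- "hexagon"
    thr <- if (is.null(threshold)) 0.11 else threshold
    wf <- if (is.null(weber)) 0.1 else weber
  } else {
    tab <- .avianPhenotypes()
    tab <- tab[tab$phenotype == label, ]
    lmax <- if (is.null(lambdaMax)) setNames(tab$lambda_max, tab$receptor)
            else lambdaMax
    dens <- if (is.null(densities)) tab$relative_density else densities
    model <- "rnl"
    thr <- if (is.null(threshold)) 1.0 else threshold
    wf <- if (is.null(weber)) 0.1 else weber
  }
  if (any(dens <= 0)) stop("receptor densities must be positive")
  if (wf <= 0) stop("Weber fraction must be positive")
  if (is.null(sensitivities)) {
    sens <- vapply(lmax, pigmentTemplate, numeric(length(grid)), grid = grid)
  } else {
    sens <- as.matrix(sensitivities)
    sens <- sweep(sens, 2L, apply(sens, 2L, max), "/")
  }
  if (is.null(colnames(sens)))
    colnames(sens) <- names(lmax) %||% paste0("r", seq_along(lmax))
  methods::new("ViewerPhenotype",
    label = label, wavelengths = as.numeric(grid), sensitivities = sens,
    lambdaMax = unname(as.numeric(lmax)), densities = as.numeric(dens),
    weberFraction = wf, model = model, threshold = thr,
    background = .readBackground(background, grid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ViewerPhenotype", function(object) {
  cat(sprintf(
    "ViewerPhenotype '%s': %d receptors (peaks %s nm), model=%s, threshold=%g\n",
    object@label, ncol(object@sensitivities),
    paste(round(object@lambdaMax), collapse = "/"),
    object@model, object@threshold))
  cat(sprintf("  densities %s, Weber fraction %g, grid %g-%g nm\n",
              paste(object@densities, collapse = ":"),
              object@weberFraction,
              min(object@wavelengths), max(object@wavelengths)))
})

# trapezoid quadrature weights on an arbitrary (uniform or not) grid
.trapWeights <- function(wl) {
  n <- length(wl)
  w <- numeric(n)
  d <- diff(wl)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

.catchMatrix <- function(refl, viewer, illum) {
  # columns of refl are stimuli; returns stimuli x receptors matrix of
  # trapezoid-integrated catches Q_i = sum R * I * S_i * dl
  w <- .trapWeights(viewer@wavelengths)
  weighted <- viewer@sensitivities * (illum * w)   # grid x receptors
  t(refl) %*% weighted
}

#' Quantum catches of spectra for a viewer
#'
#' Integrates reflectance x illuminant x receptor sensitivity over the
#' wavelength grid (trapezoid rule) to obtain the photon catch of each
#' receptor class, and (by default) applies von Kries chromatic adaptation:
#' each catch is divided by the receptor's catch of the viewer's adaptation
#' background, so a stimulus identical to the background yields catches of
#' exactly 1 in every receptor, and scaling the illuminant leaves adapted
#' catches unchanged.
#'
#' @param x a cleaned [SpectralDataset-class], or a reflectance matrix with
#'   wavelengths in rows matching the viewer's grid.
#' @param viewer a [ViewerPhenotype-class].
#' @param illuminant irradiance on the viewer's grid; default
#'   [illuminantD65()].
#' @param adapt apply von Kries adaptation (default `TRUE`).
#' @return Matrix, one row per flower and one column per receptor.
#' @examples
#' bee <- buildViewer("bee")
#' bg <- matrix(bee@background, ncol = 1, dimnames = list(NULL, "bg"))
#' quantumCatches(bg, bee)  # all 1 (adaptation fixed point)
#' @rdname quantumCatches
#' @export
setMethod("quantumCatches", "SpectralDataset",
  function(x, viewer, illuminant = NULL, adapt = TRUE) {
    if (!isTRUE(all.equal(wavelengths(x), viewer@wavelengths)))
      stop("dataset and viewer wavelength grids differ; clean the spectra ",
           "onto the viewer's grid first")
    quantumCatches(reflectance(x), viewer, illuminant, adapt)
  })

#' @rdname quantumCatches
#' @export
setMethod("quantumCatches", "matrix",
  function(x, viewer, illuminant = NULL, adapt = TRUE) {
    if (nrow(x) != length(viewer@wavelengths))
      stop("reflectance rows must match the viewer's wavelength grid")
    if (is.null(illuminant)) illuminant <- illuminantD65(viewer@wavelengths)
    q <- .catchMatrix(x, viewer, illuminant)
    if (adapt) {
      qb <- drop(.catchMatrix(matrix(viewer@background, ncol = 1L),
                              viewer, illuminant))
      if (any(qb <= 0))
        stop("adaptation background yields zero catch in receptor(s): ",
             paste(colnames(viewer@sensitivities)[qb <= 0], collapse = ", "))
      q <- sweep(q, 2L, qb, "/")
    }
    q
  })
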