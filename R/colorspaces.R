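#' Map adapted catches into the bee colour hexagon
#'
#' Receptor excitations follow the half-maximal hyperbolic transform
#' `E = q / (q + 1)` of the background-adapted catches, so the adaptation
#' background sits at excitation 0.5 and maps to the hexagon centre. With
#' receptors ordered (UV, blue, green), hexagon coordinates are
#' `x = (sqrt(3)/2) * (E_g - E_uv)` and `y = E_b - (E_uv + E_g)/2`; hue is
#' the radial angle `atan2(y, x)` and saturation (spectral purity) the
#' distance from the origin, which is at most 1.
#'
#' @param q matrix of adapted quantum catches, one row per stimulus, three
#'   columns ordered short to long wavelength (UV, blue, green); a single
#'   stimulus may be given as a length-3 vector.
#' @return data.frame with columns `x`, `y`, `hue` (radians) and
#'   `saturation`, one row per stimulus.
#' @examples
#' hexagonPoint(c(1, 1, 1))  # background -> origin
#' @export
hexagonPoint <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (ncol(q) != 3L)
    stop("hexagon model requires exactly 3 receptor catches (uv, blue, green)")
  E <- q / (q + 1)
  x <- (sqrt(3) / 2) * (E[, 3L] - E[, 1L])
  y <- E[, 2L] - (E[, 1L] + E[, 3L]) / 2
  data.frame(x = x, y = y, hue = atan2(y, x), saturation = sqrt(x^2 + y^2),
             row.names = rownames(q))
}

#' Euclidean distance in the colour hexagon
#'
#' @param a,b hexagon points: single rows of [hexagonPoint()] output, or any
#'   objects with `x` and `y` components.
#' @return Distance in hexagon units.
#' @export
hexagonDistance <- function(a, b) {
  if (is.null(a$x) || is.null(b$x))
    stop("hexagonDistance expects hexagon points with x/y coordinates")
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Receptor noise vector of an RNL viewer
#'
#' Noise is proportional to the Weber fraction and independent of stimulus
#' magnitude: with relative receptor densities `eta`, the noise of receptor
#' `i` is `e_i = omega * sqrt(max(eta) / eta_i)`, so the densest receptor
#' class attains exactly the Weber fraction `omega`.
#'
#' @param v a [ViewerPhenotype-class] with `model = "rnl"`, or a numeric
#'   vector of relative densities.
#' @param weber Weber fraction (only used when `v` is a density vector).
#' @return Numeric noise vector, one value per receptor.
#' @examples
#' rnlNoise(c(1, 2, 2, 4), weber = 0.1)  # 0.2, 0.1*sqrt(2), 0.1*sqrt(2), 0.1
#' @export
rnlNoise <- function(v, weber = 0.1) {
  if (methods::is(v, "ViewerPhenotype")) {
    if (v@model != "rnl")
      stop("rnlNoise applies to receptor-noise limited viewers only")
    eta <- v@densities
    weber <- v@weberFraction
  } else {
    eta <- as.numeric(v)
  }
  if (any(eta <= 0)) stop("receptor densities must be positive")
  if (weber <= 0) stop("Weber fraction must be positive")
  weber * sqrt(max(eta) / eta)
}

#' Receptor-noise limited colour distance (Delta S)
#'
#' Weighted Euclidean distance between two stimuli in the receptor-noise
#' limited model, in just-noticeable-difference (JND) units. Receptor
#' contrasts are logarithmic, `df_i = log(qa_i / qb_i)`, and for `n`
#' receptors with noise `e`:
#' `dS^2 = sum_{i<j} (df_i - df_j)^2 prod_{k != i,j} e_k^2 /
#'         sum_i prod_{k != i} e_k^2`,
#' which reduces to `|df_1 - df_2| / sqrt(e_1^2 + e_2^2)` for a dichromat and
#' to the familiar tri- and tetrachromat expressions. The distance is
#' symmetric, zero iff the contrasts are equal, invariant to scaling both
#' stimuli's catches by a common factor, and unchanged by adding a common
#' offset to all contrasts.
#'
#' @param qa,qb positive adapted quantum-catch vectors of the two stimuli
#'   (same viewer, same receptor order).
#' @param v a [ViewerPhenotype-class] with `model = "rnl"`, or a numeric
#'   noise vector `e` used directly.
#' @return Delta S in JND units.
#' @examples
#' bird <- buildViewer("bird_VS")
#' rnlDistance(c(1, 1, 1, 1), c(1, 1, 1, 1.2), bird)
#' @export
rnlDistance <- function(qa, qb, v) {
  e <- if (methods::is(v, "ViewerPhenotype")) rnlNoise(v) else as.numeric(v)
  n <- length(e)
  if (length(qa) != n || length(qb) != n)
    stop("catch vectors must have one entry per receptor")
  if (any(qa <= 0) || any(qb <= 0))
    stop("RNL distance requires strictly positive quantum catches")
  df <- log(qa / qb)
  e2 <- e^2
  prodAll <- prod(e2)
  num <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    num <- num + (df[i] - df[j])^2 * prodAll / (e2[i] * e2[j])
  den <- sum(prodAll / e2)
  unname(sqrt(num / den))
}

#' Colour points of a dataset for one viewer
#'
#' Computes each flower's position in the viewer's colour space. For a
#' hexagon (bee) viewer this is the hexagon point with hue and saturation.
#' For an RNL (bird) viewer the coordinates are the log receptor contrasts
#' relative to the adaptation background, and "saturation" is the RNL
#' distance from the stimulus to the background (the achromatic point) --
#' the natural origin-distance analogue of spectral purity in a space that
#' has no canonical chromaticity diagram.
#'
#' @param x a cleaned [SpectralDataset-class].
#' @param viewer a [ViewerPhenotype-class].
#' @param illuminant irradiance on the viewer's grid; default D65.
#' @return data.frame with `flower_id`, `space`, coordinates (`x`,`y` and
#'   `hue` for hexagon; `f1..fn` log contrasts for rnl) and `saturation`.
#' @export
colorPoints <- function(x, viewer, illuminant = NULL) {
  q <- quantumCatches(x, viewer, illuminant)
  if (viewer@model == "hexagon") {
    pts <- hexagonPoint(q)
    data.frame(flower_id = rownames(q) %||% flowerIds(x), space = "hexagon",
               pts, row.names = NULL)
  } else {
    if (any(q <= 0))
      stop("RNL colour points require strictly positive catches")
    f <- log(q)   # contrast relative to background (background catch = 1)
    colnames(f) <- paste0("f", seq_len(ncol(f)))
    e <- rnlNoise(viewer)
    sat <- apply(q, 1L, function(qi) rnlDistance(qi, rep(1, length(qi)), e))
    data.frame(flower_id = rownames(q) %||% flowerIds(x), space = "rnl",
               f, saturation = sat, row.names = NULL)
  }
}
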