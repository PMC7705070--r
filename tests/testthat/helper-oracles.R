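# Independent oracle implementations and fixture builders. These deliberately
# avoid the package's own code paths for the quantities they check.

# RNL distance via the generic matrix form: with R = diag(1/e^2),
# dS^2 = df' (R - R 1 1' R / (1' R 1)) df
rnlMatrixOracle <- function(qa, qb, e) {
  df <- log(qa / qb)
  R <- diag(1 / e^2, length(e))
  one <- rep(1, length(e))
  M <- R - (R %*% one %*% t(one) %*% R) / drop(t(one) %*% R %*% one)
  sqrt(drop(t(df) %*% M %*% df))
}

# hexagon coordinates evaluated directly from the defining formulas
hexOracle <- function(q) {
  E <- q / (q + 1)
  c(x = (sqrt(3) / 2) * (E[3] - E[1]), y = E[2] - (E[1] + E[3]) / 2)
}

# exhaustive double-loop count of discriminable pairs from a distance
# function, the brute-force counterpart of fractionDiscriminable()
bruteFraction <- function(distFun, items, threshold) {
  n <- length(items)
  disc <- 0L; pairs <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pairs <- pairs + 1L
    if (distFun(items[[i]], items[[j]]) > threshold) disc <- disc + 1L
  }
  disc / pairs
}

# small raw dataset written by hand (values in percent, one negative dip)
makeRawFixture <- function(dir = tempfile("fix")) {
  dir.create(dir)
  wl <- seq(295, 705, by = 5)
  f1 <- 20 + 40 * exp(-(wl - 450)^2 / (2 * 45^2))
  f2 <- 10 + 70 / (1 + exp(-(wl - 620) / 15))
  f3 <- 5 + 30 * exp(-(wl - 520)^2 / (2 * 35^2))
  f1[wl == 305] <- -2  # spurious negative reading
  spec <- data.frame(wl = wl, fl1 = f1, fl2 = f2, fl3 = f3)
  meta <- data.frame(flower_id = c("fl1", "fl2", "fl3"),
                     population_id = c("p1", "p1", "p2"),
                     species_code = c("sp1", "sp1", "sp2"),
                     pollination_system = c("Bee", "Bee", "Bird"))
  sp <- file.path(dir, "spectra.csv"); mp <- file.path(dir, "meta.csv")
  write.csv(spec, sp, row.names = FALSE)
  write.csv(meta, mp, row.names = FALSE)
  list(spectra = sp, metadata = mp, dir = dir)
}

# variation table with configurable cell means, for inference simulations:
# 24 + 7 species x 2 populations x 2 viewers (the study's design size)
simulateVariationTable <- function(mu = 0.3, shift = c(0, 0, 0, 0),
                                   sdSpecies = 0.05, sdPop = 0.03,
                                   sdResid = 0.04, nBee = 24, nBird = 7) {
  nsp <- nBee + nBird
  sp <- c(sprintf("B%02d", seq_len(nBee)), sprintf("R%02d", seq_len(nBird)))
  ps <- rep(c("Bee", "Bird"), c(nBee, nBird))
  rows <- expand.grid(species = seq_len(nsp), pop = 1:2,
                      vs = c("bee", "bird"), stringsAsFactors = FALSE)
  spRE <- rnorm(nsp, 0, sdSpecies)
  popRE <- rnorm(nsp * 2, 0, sdPop)
  popIdx <- (rows$species - 1L) * 2L + rows$pop
  cell <- matrix(shift, 2, 2, dimnames = list(c("bee", "bird"),
                                              c("Bee", "Bird")))
  data.frame(
    fraction_discriminable = mu + cell[cbind(rows$vs, ps[rows$species])] +
      spRE[rows$species] + popRE[popIdx] + rnorm(nrow(rows), 0, sdResid),
    visual_system = rows$vs,
    pollination_system = ps[rows$species],
    species_code = sp[rows$species],
    population_id = sprintf("%s_P%d", sp[rows$species], rows$pop))
}

# variation table carrying mixed pollination systems, for regrouping tests
mixedSystemsTable <- function() {
  sp <- c(sprintf("BEE%02d", 1:24), sprintf("BRD%02d", 1:7),
          "BBD01", "BBD02", "BFL01", "BFL02", "BFL03", "BFL04", "BHM01")
  ps <- rep(c("Bee", "Bird", "Bee/Bird", "Bee/Fly", "Bee/Hawkmoth"),
            c(24, 7, 2, 4, 1))
  grid <- expand.grid(species = seq_along(sp), vs = c("bee", "bird"),
                      stringsAsFactors = FALSE)
  data.frame(
    fraction_discriminable = runif(nrow(grid)),
    visual_system = grid$vs,
    pollination_system = ps[grid$species],
    species_code = sp[grid$species],
    population_id = paste0(sp[grid$species], "_P1"))
}
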