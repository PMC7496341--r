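#' Load a bundled attenuation table
#'
#' The package ships plain-text linear attenuation tables (keV, 1/cm) for
#' the three phantom materials: liquid water, cortical bone and iron,
#' spanning 10-150 keV.
#'
#' @param material one of `"water"`, `"bone"`, `"iron"`.
#' @return an [AttenuationTable-class].
#' @examples
#' loadAttenuationTable("water")
#' @export
loadAttenuationTable <- function(material = c("water", "bone", "iron")) {
  material <- match.arg(material)
  path <- system.file("extdata", sprintf("mu_%s.txt", material),
                      package = "MARbench", mustWork = TRUE)
  tab <- read.table(path, comment.char = "#",
                    col.names = c("energy", "mu"))
  new("AttenuationTable", material = material,
      energies = tab$energy, mu = tab$mu)
}

#' All three phantom material tables
#'
#' @return named list of [AttenuationTable-class] objects
#'   (`water`, `bone`, `iron`).
#' @export
attenuationTables <- function() {
  mats <- c("water", "bone", "iron")
  stats::setNames(lapply(mats, loadAttenuationTable), mats)
}

#' Interpolate a linear attenuation coefficient
#'
#' Log-log linear interpolation of \eqn{\mu(E)} between tabulated energies;
#' exact at the grid points. Photon cross sections are near power laws in
#' energy away from absorption edges, which makes log-log interpolation the
#' standard choice.
#'
#' @param table an [AttenuationTable-class].
#' @param energy photon energies, keV; must lie within the table range.
#' @return linear attenuation coefficient(s), 1/cm.
#' @examples
#' interpolateMu(loadAttenuationTable("water"), 60)
#' @export
interpolateMu <- function(table, energy) {
  stopifnot(is(table, "AttenuationTable"))
  e <- energies(table)
  if (any(energy < min(e)) || any(energy > max(e)))
    stop(sprintf("energy outside table range [%g, %g] keV", min(e), max(e)))
  exp(approx(log(e), log(muValues(table)), xout = log(energy))$y)
}

#' Load a bundled x-ray spectrum
#'
#' @param fixture spectrum identifier; the package bundles `"120kvp"`, a
#'   filtered tungsten spectrum for a tube voltage of 120 kVp on a 1 keV
#'   grid.
#' @return a [Spectrum-class], weights normalized to sum to 1.
#' @examples
#' loadSpectrum("120kvp")
#' @export
loadSpectrum <- function(fixture = "120kvp") {
  path <- system.file("extdata", sprintf("spectrum_%s.txt", fixture),
                      package = "MARbench")
  if (!nzchar(path))
    stop(sprintf("unknown spectrum fixture '%s'", fixture))
  tab <- read.table(path, comment.char = "#",
                    col.names = c("energy", "weight"))
  kvp <- as.numeric(sub("kvp", "", fixture))
  new("Spectrum", energies = tab$energy,
      weights = tab$weight / sum(tab$weight), kvp = kvp)
}

#' Construct a monochromatic spectrum
#'
#' Single-energy degenerate spectrum, mainly useful for validating the
#' projection and reconstruction chain against Beer-Lambert closed forms.
#'
#' @param energy photon energy, keV.
#' @return a [Spectrum-class] with all weight in one bin.
#' @export
monochromaticSpectrum <- function(energy) {
  new("Spectrum", energies = energy, weights = 1, kvp = energy)
}

#' Rebin a spectrum onto a coarser energy grid
#'
#' Adjacent 1 keV bins are pooled; each pooled bin keeps the summed weight
#' at the fluence-weighted mean energy. Used to speed up the polychromatic
#' detection sum without altering the beam-hardening behaviour materially.
#'
#' @param spectrum a [Spectrum-class].
#' @param binWidth pooled bin width, keV.
#' @return a [Spectrum-class].
#' @export
rebinSpectrum <- function(spectrum, binWidth = 2) {
  if (binWidth <= 1) return(spectrum)
  e <- energies(spectrum); w <- fluenceWeights(spectrum)
  grp <- floor((e - min(e)) / binWidth)
  ws <- tapply(w, grp, sum)
  es <- tapply(w * e, grp, sum) / ws
  keep <- ws > 0
  new("Spectrum", energies = as.numeric(es[keep]),
      weights = as.numeric(ws[keep] / sum(ws[keep])), kvp = spectrum@kvp)
}

#' Effective water attenuation coefficient for a spectrum
#'
#' Fluence-weighted mean of \eqn{\mu_{water}(E)} over the spectrum; used as
#' the water reference for Hounsfield conversion.
#'
#' @param spectrum a [Spectrum-class].
#' @param table water [AttenuationTable-class]; loaded if missing.
#' @return effective \eqn{\mu_{water}}, 1/cm.
#' @export
muWaterEffective <- function(spectrum, table = loadAttenuationTable("water")) {
  sum(fluenceWeights(spectrum) * interpolateMu(table, energies(spectrum)))
}
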