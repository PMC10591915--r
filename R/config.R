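#' Generator configuration
#'
#' Settings shared by all synthetic-data generators: the random seed, the
#' fluorescence noise model (multiplicative Gaussian with a fixed
#' coefficient of variation), replicate count, the inhibitor concentration
#' grid, the exchange timepoints and the deuterium content of the exchange
#' buffer.
#'
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param noise_cv coefficient of variation of the multiplicative
#'   fluorescence noise (fraction, >= 0). Default 0.02 (2 percent), a
#'   typical plate-reader repeatability.
#' @param n_replicates number of independent replicates to generate.
#' @param concentration_grid molar inhibitor concentrations, strictly
#'   increasing and starting at 0. Default: 12 points spanning 0-10 uM,
#'   matching the titration range of the assay.
#' @param timepoints exchange incubation times in minutes. Default
#'   c(1, 2, 5, 10), the assay's schedule.
#' @param d2o_fraction deuterium fraction of the exchange buffer (0-1).
#'   Default 0.975 (99.9 percent D2O diluted 2 uL protein into 78 uL
#'   buffer).
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             noise_cv = 0.02,
                             n_replicates = 3L,
                             concentration_grid = titration_grid(10e-6),
                             timepoints = c(1, 2, 5, 10),
                             d2o_fraction = 0.975) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(concentration_grid) > 0) {
    if (concentration_grid[1] != 0)
      stop("concentration_grid must start at 0")
    if (any(diff(concentration_grid) <= 0))
      stop("concentration_grid must be strictly increasing")
  }
  if (d2o_fraction < 0 || d2o_fraction > 1)
    stop("d2o_fraction must be in [0, 1]")
  structure(
    list(seed = seed, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates),
         concentration_grid = as.numeric(concentration_grid),
         timepoints = as.numeric(timepoints),
         d2o_fraction = d2o_fraction),
    class = "generator_config")
}

#' Default titration concentration grid
#'
#' Twelve concentrations from 0 to `cmax` molar: zero plus eleven points
#' spaced evenly.
#'
#' @param cmax maximum inhibitor concentration (molar).
#' @param n number of points including zero.
#' @return numeric vector of molar concentrations.
#' @export
titration_grid <- function(cmax = 10e-6, n = 12L) {
  stopifnot(cmax > 0, n >= 2)
  seq(0, cmax, length.out = n)
}

# Deterministic per-stage seed expansion from one root seed. Offsets keep
# every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offsets <- c(plate = 101L, titration = 211L, ensemble = 307L,
               hdx = 401L, trajectory = 503L, pipeline = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max)
}

# Run a generator body under a local RNG state so callers' RNG streams are
# untouched and a fixed seed gives byte-identical output.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
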