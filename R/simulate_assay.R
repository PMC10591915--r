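#' Simulate a displacement titration
#'
#' Generates replicate emission-vs-concentration series for the
#' retinol-replacement fluorescence assay: as inhibitor is added, FRET from
#' the protein tryptophans to the bound retinoid is lost and emission at
#' 350 nm rises toward saturation, with a linear nonspecific component on
#' top. Noise is multiplicative Gaussian with the configured coefficient
#' of variation.
#'
#' Two signal models are available:
#' \describe{
#'   \item{`"apparent"` (default)}{The emission follows the one-site
#'     saturation curve `f0 + delta_f * c / (ki + c) + ns_slope * c`
#'     with half-saturation exactly at `ki`. This is the behaviour the
#'     assay empirically shows and the scale on which inhibition constants
#'     are reported: the fitted half-saturation constant *is* the Ki.}
#'   \item{`"equilibrium"`}{The emission tracks the equilibrium loss of the
#'     protein-retinol complex computed by [competitive_equilibrium()]
#'     under `spec`. At stoichiometric probe loading with a tight probe
#'     this curve's midpoint sits far above Ki (classical competition
#'     inflation by `1 + [L]free/Kd`), so it is provided for sensitivity
#'     analysis, not as the default truth model.}
#' }
#'
#' @param ki true inhibition constant (M) placed at the curve
#'   half-saturation in the apparent model, or used as the inhibitor's
#'   dissociation constant in the equilibrium model.
#' @param config a [generator_config()]; supplies the concentration grid,
#'   replicate count, noise CV and seed.
#' @param spec an [equilibrium_spec()] template giving protein/retinol
#'   totals and the probe Kd (its `inhibitor_total` and `ki_inhibitor`
#'   fields are ignored); used by the equilibrium model and recorded for
#'   provenance either way.
#' @param f0 baseline emission at zero inhibitor (a.u.).
#' @param delta_f saturable amplitude (a.u.); the default 250 gives the
#'   2.5-fold recovery of tryptophan emission over the FRET-quenched
#'   baseline that is typical when the retinoid leaves the pocket.
#' @param ns_slope nonspecific slope (a.u./M); default contributes 10% of
#'   `delta_f` at the top of the grid.
#' @param signal_model `"apparent"` or `"equilibrium"`.
#' @return A `titration_series` data frame with columns
#'   `concentration_M`, `emission350`, `replicate`, and attributes
#'   recording the truth parameters and signal model.
#' @export
simulate_titration <- function(ki, config = generator_config(),
                               spec = equilibrium_spec(1e-6, 1e-6, 0,
                                                       kd_retinol = 10e-9,
                                                       ki_inhibitor = ki),
                               f0 = 100, delta_f = 250,
                               ns_slope = NULL,
                               signal_model = c("apparent", "equilibrium")) {
  signal_model <- match.arg(signal_model)
  conc <- config$concentration_grid
  if (length(conc) == 0) stop("concentration grid is empty")
  if (is.null(ns_slope)) ns_slope <- 0.1 * delta_f / max(conc)

  mu <- titration_mean(conc, ki, spec, f0, delta_f, ns_slope, signal_model)
  with_seed(stage_seed(config$seed, "titration"), {
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      noise <- stats::rnorm(length(conc), mean = 1, sd = config$noise_cv)
      data.frame(concentration_M = conc,
                 emission350 = mu * noise,
                 replicate = r)
    })
    out <- do.call(rbind, reps)
    attr(out, "true_ki") <- ki
    attr(out, "signal_model") <- signal_model
    attr(out, "truth") <- list(f0 = f0, delta_f = delta_f,
                               ns_slope = ns_slope)
    class(out) <- c("titration_series", "data.frame")
    out
  })
}

# Noise-free mean emission for each signal model.
titration_mean <- function(conc, ki, spec, f0, delta_f, ns_slope,
                           signal_model) {
  if (signal_model == "apparent") {
    f0 + delta_f * conc / (ki + conc) + ns_slope * conc
  } else {
    pl0 <- two_component_bound(spec$protein_total, spec$retinol_total,
                               spec$kd_retinol)
    frac_displaced <- vapply(conc, function(ci) {
      s <- equilibrium_spec(spec$protein_total, spec$retinol_total, ci,
                            kd_retinol = spec$kd_retinol,
                            ki_inhibitor = ki)
      1 - competitive_equilibrium(s)$protein_retinol / pl0
    }, numeric(1))
    f0 + delta_f * frac_displaced + ns_slope * conc
  }
}

#' Simulate a screening plate
#'
#' Builds one dual-wavelength fluorescence plate with positive-control
#' wells (full retinol displacement: 350 nm up, 480 nm down), negative
#' control wells (holo protein plus vehicle), and compound wells labelled
#' by ground-truth class:
#' \describe{
#'   \item{binder}{duplicates the positive-control signature before noise;}
#'   \item{non_binder}{duplicates the negative control (no signal change);}
#'   \item{artifact}{carries a binder-like signal but an absorbance or
#'     autofluorescence flag, so exclusion, not the score, must remove it.}
#' }
#'
#' @param n_wells total wells on the plate, controls included.
#' @param class_mix named fractions for `binder`, `non_binder`, `artifact`
#'   among compound wells; must sum to 1.
#' @param config a [generator_config()] (noise CV and seed).
#' @param n_pos,n_neg numbers of positive/negative control wells.
#' @param nc350,nc480 negative-control mean signals (a.u.).
#' @param pc350,pc480 positive-control mean signals (a.u.).
#' @return A `plate_table` data frame with columns `well_id`, `role`,
#'   `f350`, `f480`, `absorbance_flag`, `autofluorescence_flag`,
#'   `true_class`.
#' @export
simulate_plate <- function(n_wells = 384,
                           class_mix = c(binder = 0.05, non_binder = 0.90,
                                         artifact = 0.05),
                           config = generator_config(),
                           n_pos = 8, n_neg = 8,
                           nc350 = 100, nc480 = 200,
                           pc350 = 200, pc480 = 100) {
  stopifnot(all(c("binder", "non_binder", "artifact") %in% names(class_mix)))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  n_cmp <- n_wells - n_pos - n_neg
  if (n_cmp < 0)
    stop("n_wells is smaller than the number of control wells requested")

  counts <- round(class_mix * n_cmp)
  # rounding drift goes to the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] + n_cmp - sum(counts)
  classes <- rep(names(counts), counts)

  with_seed(stage_seed(config$seed, "plate"), {
    classes <- sample(classes)
    role <- c(rep("pos_ctrl", n_pos), rep("neg_ctrl", n_neg),
              rep("compound", n_cmp))
    true_class <- c(rep(NA_character_, n_pos + n_neg), classes)
    mean350 <- c(rep(pc350, n_pos), rep(nc350, n_neg),
                 ifelse(classes == "non_binder", nc350, pc350))
    mean480 <- c(rep(pc480, n_pos), rep(nc480, n_neg),
                 ifelse(classes == "non_binder", nc480, pc480))
    abs_flag <- rep(FALSE, n_wells)
    auto_flag <- rep(FALSE, n_wells)
    art <- which(true_class == "artifact")
    if (length(art) > 0) {
      half <- art[seq_along(art) %% 2 == 1]
      abs_flag[half] <- TRUE
      auto_flag[setdiff(art, half)] <- TRUE
    }
    n <- n_wells
    noise350 <- stats::rnorm(n, 1, config$noise_cv)
    noise480 <- stats::rnorm(n, 1, config$noise_cv)
    out <- data.frame(
      well_id = sprintf("W%04d", seq_len(n)),
      role = role,
      f350 = mean350 * noise350,
      f480 = mean480 * noise480,
      absorbance_flag = abs_flag,
      autofluorescence_flag = auto_flag,
      true_class = true_class,
      stringsAsFactors = FALSE)
    class(out) <- c("plate_table", "data.frame")
    out
  })
}

#' Write / read plate tables as CSV
#'
#' Plain-CSV round trip for the plate format consumed by the screening
#' stage: `well_id,f350,f480,role,absorbance_flag,autofluorescence_flag`
#' (plus `true_class` when present).
#'
#' @param plate a `plate_table` data frame.
#' @param path file path.
#' @return `read_plate_csv` returns a `plate_table` data frame.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "f350", "f480", "role",
            "absorbance_flag", "autofluorescence_flag")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0)
    stop("plate CSV missing columns: ", paste(miss, collapse = ", "))
  out$absorbance_flag <- as.logical(out$absorbance_flag)
  out$autofluorescence_flag <- as.logical(out$autofluorescence_flag)
  class(out) <- c("plate_table", "data.frame")
  out
}

#' Write / read titration series as CSV
#'
#' Format: `concentration_M,emission350,replicate`.
#'
#' @param series a `titration_series` data frame.
#' @param path file path.
#' @return `read_titration_csv` returns a `titration_series` data frame.
#' @export
write_titration_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_M", "emission350", "replicate")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0)
    stop("titration CSV missing columns: ", paste(miss, collapse = ", "))
  class(out) <- c("titration_series", "data.frame")
  out
}
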