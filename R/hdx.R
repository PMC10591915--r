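# Monoisotopic residue masses (Da) and carbon counts for the 20 standard
# amino acids; water and proton masses; isotope mass steps.
AA_MONO_MASS <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
                  V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
                  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
                  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
                  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
AA_CARBON <- c(G = 2, A = 3, S = 3, P = 5, V = 5, T = 4, C = 3, L = 6,
               I = 6, N = 4, D = 4, Q = 5, K = 6, E = 5, M = 5, H = 6,
               F = 9, R = 6, Y = 9, W = 11)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.00727646688
MASS_C13_STEP <- 1.0033548378
MASS_D_STEP <- 1.0062767458
P_C13 <- 0.0107

#' Deterministic synthetic protein sequence
#'
#' A reproducible random 133-residue sequence (synthetic stand-in for the
#' real chain, which this package never claims to reproduce) with a
#' controlled number of prolines so the exchangeable-amide bookkeeping is
#' exercised.
#'
#' @param n_res chain length.
#' @param seed integer seed.
#' @return single character string.
#' @export
synthetic_sequence <- function(n_res = 133L, seed = 7L) {
  aas <- setdiff(names(AA_MONO_MASS), "P")
  with_seed(seed, {
    s <- sample(aas, n_res, replace = TRUE)
    pro_sites <- sample(2:n_res, max(2L, round(n_res * 0.04)))
    s[pro_sites] <- "P"
    paste(s, collapse = "")
  })
}

#' Tile a sequence into overlapping peptides
#'
#' Sliding-window peptide set emulating a pepsin digest with full
#' coverage and overlap.
#'
#' @param sequence protein sequence (string).
#' @param length peptide length (residues).
#' @param step window step.
#' @return data frame `peptide_id`, `start`, `end`, `sequence`.
#' @export
tile_peptides <- function(sequence, length = 12L, step = 6L) {
  n <- nchar(sequence)
  starts <- seq(1L, max(1L, n - length + 1L), by = step)
  if (starts[base::length(starts)] + length - 1L < n)
    starts <- c(starts, n - length + 1L)
  ends <- pmin(starts + length - 1L, n)
  data.frame(peptide_id = sprintf("pep%03d", seq_along(starts)),
             start = starts, end = ends,
             sequence = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}

#' Exchangeable-amide count of a peptide
#'
#' Number of backbone amides that can retain deuterium: peptide length
#' minus the first residue minus prolines after position 1 (prolines have
#' no amide hydrogen).
#'
#' @param sequence peptide sequence.
#' @return integer count.
#' @export
count_exchangeable <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  length(res) - 1L - sum(res[-1] == "P")
}

# Residue positions within a peptide that carry an exchangeable amide.
exchangeable_positions <- function(start, end, sequence_full) {
  pos <- seq(start, end)
  res <- strsplit(substring(sequence_full, start, end), "")[[1]]
  pos[-1][res[-1] != "P"]
}

# Natural carbon-isotope stick pattern (binomial over carbon count).
natural_isotope_pattern <- function(n_carbon, pmin = 1e-6) {
  k <- 0:n_carbon
  p <- stats::dbinom(k, n_carbon, P_C13)
  keep <- p > pmin
  list(shift = k[keep], prob = p[keep] / sum(p[keep]))
}

# Poisson-binomial deuteration distribution by sequential convolution of
# per-site Bernoulli(p) variables.
deuteration_distribution <- function(site_probs) {
  dist <- 1
  for (p in site_probs) dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  dist
}

#' Simulate hydrogen/deuterium-exchange envelope spectra
#'
#' Per-residue single-exponential exchange with intrinsic rate 1/min
#' slowed by a protection factor: the probability that residue r carries
#' deuterium after t minutes is
#' `d2o_fraction * (1 - exp(-t / P_r))`. Each peptide/timepoint envelope
#' is the convolution of the peptide's natural carbon-isotope stick
#' pattern with the Poisson-binomial deuteration distribution over its
#' exchangeable amides; peak intensities receive multiplicative Gaussian
#' noise. The undeuterated (t = 0) reference envelope is always included.
#'
#' @param sequence full protein sequence.
#' @param protection_factors per-residue protection factors (> 0, length
#'   = chain length; `Inf` = never exchanges).
#' @param config a [generator_config()] (timepoints, d2o fraction, noise,
#'   seed).
#' @param peptides peptide table (see [tile_peptides()]); default tiles
#'   the sequence.
#' @param charge charge state of all envelopes.
#' @return list with `spectra` (data frame `peptide_id`, `charge`,
#'   `timepoint_min`, `mz`, `intensity`) and `peptides`.
#' @export
simulate_hdx <- function(sequence, protection_factors,
                         config = generator_config(),
                         peptides = tile_peptides(sequence), charge = 2L) {
  n <- nchar(sequence)
  if (length(protection_factors) != n)
    stop("protection_factors must have one value per residue")
  if (any(protection_factors <= 0)) stop("protection factors must be > 0")
  timepoints <- c(0, config$timepoints)
  with_seed(stage_seed(config$seed, "hdx"), {
    rows <- lapply(seq_len(nrow(peptides)), function(i) {
      pep <- peptides[i, ]
      res <- strsplit(pep$sequence, "")[[1]]
      m0 <- sum(AA_MONO_MASS[res]) + MASS_WATER
      n_c <- sum(AA_CARBON[res])
      iso <- natural_isotope_pattern(n_c)
      ex_pos <- exchangeable_positions(pep$start, pep$end, sequence)
      lapply(timepoints, function(tp) {
        p_site <- if (tp == 0) numeric(0) else {
          config$d2o_fraction *
            (1 - exp(-tp / protection_factors[ex_pos]))
        }
        ddist <- deuteration_distribution(p_site)
        grid <- expand.grid(ci = seq_along(iso$shift),
                            di = seq_along(ddist))
        mass <- m0 + iso$shift[grid$ci] * MASS_C13_STEP +
          (grid$di - 1) * MASS_D_STEP
        inten <- iso$prob[grid$ci] * ddist[grid$di]
        keep <- inten > 1e-8
        mass <- mass[keep]; inten <- inten[keep]
        o <- order(mass)
        mass <- mass[o]; inten <- inten[o]
        inten <- inten * pmax(stats::rnorm(length(inten), 1,
                                           config$noise_cv), 0)
        data.frame(peptide_id = pep$peptide_id, charge = charge,
                   timepoint_min = tp,
                   mz = (mass + charge * MASS_PROTON) / charge,
                   intensity = inten, stringsAsFactors = FALSE)
      })
    })
    list(spectra = do.call(rbind, unlist(rows, recursive = FALSE)),
         peptides = peptides)
  })
}

#' Protection-factor profiles for the synthetic protein
#'
#' Scaffold residues exchange slowly (high protection); portal residues
#' exchange fast in the apo state and are protected in the holo state
#' (ligand-induced stabilization).
#'
#' @param n_res chain length.
#' @param scaffold,portal_apo,portal_holo protection factors.
#' @param regions a [portal_regions_from_strands()] definition.
#' @return numeric vector of protection factors.
#' @export
apo_protection_profile <- function(n_res = 133L, scaffold = 200,
                                   portal_apo = 3,
                                   regions = portal_regions_from_strands()) {
  prof <- rep(scaffold, n_res)
  prof[intersect(regions$portal, seq_len(n_res))] <- portal_apo
  prof
}

#' @rdname apo_protection_profile
#' @export
holo_protection_profile <- function(n_res = 133L, scaffold = 200,
                                    portal_holo = 60,
                                    regions = portal_regions_from_strands()) {
  prof <- rep(scaffold, n_res)
  prof[intersect(regions$portal, seq_len(n_res))] <- portal_holo
  prof
}

#' Intensity-weighted centroid of an isotopic envelope
#'
#' @param mz m/z values (strictly increasing).
#' @param intensity intensities (>= 0, at least one > 0).
#' @return centroid m/z (Th).
#' @export
centroid <- function(mz, intensity) {
  if (any(intensity < 0)) stop("negative intensities")
  if (sum(intensity) == 0) stop("all-zero intensities: centroid undefined")
  if (any(diff(mz) <= 0)) stop("m/z must be strictly increasing")
  sum(mz * intensity) / sum(intensity)
}

#' Deuterium uptake from two envelopes
#'
#' `(centroid_t - centroid_ref) * charge`, in Da. Small negative values
#' (noise) are reported, not clipped.
#'
#' @param env_t,env_ref data frames with `mz`, `intensity`, `charge` (the
#'   deuterated and undeuterated envelopes of one peptide).
#' @return uptake (Da).
#' @export
deuterium_uptake <- function(env_t, env_ref) {
  z_t <- unique(env_t$charge); z_r <- unique(env_ref$charge)
  if (length(z_t) != 1 || length(z_r) != 1 || z_t != z_r)
    stop("charge mismatch between envelopes")
  (centroid(env_t$mz, env_t$intensity) -
     centroid(env_ref$mz, env_ref$intensity)) * z_t
}

#' Percent of theoretical maximum uptake
#'
#' `100 * uptake / (N_ex * d2o_fraction)` with `N_ex` the peptide's
#' exchangeable-amide count. Values above 100 are clipped with a warning;
#' negative values (noise) are clipped to 0.
#'
#' @param uptake_da uptake (Da).
#' @param sequence peptide sequence.
#' @param d2o_fraction deuterium fraction of the exchange buffer.
#' @return percent in [0, 100].
#' @export
percent_uptake <- function(uptake_da, sequence, d2o_fraction = 0.975) {
  n_ex <- count_exchangeable(sequence)
  if (n_ex <= 0) stop("peptide has no exchangeable amides")
  pct <- 100 * uptake_da / (n_ex * d2o_fraction)
  if (any(pct > 100)) {
    warning(sprintf("%d percent-uptake value(s) above 100 clipped",
                    sum(pct > 100)))
    pct <- pmin(pct, 100)
  }
  pmax(pct, 0)
}

#' Per-peptide uptake table from envelope spectra
#'
#' Computes centroid uptake and percent of theoretical maximum for every
#' peptide/timepoint against that peptide's undeuterated (t = 0)
#' reference envelope.
#'
#' @param spectra envelope data frame (`peptide_id`, `charge`,
#'   `timepoint_min`, `mz`, `intensity`).
#' @param peptides peptide table (`peptide_id`, `start`, `end`,
#'   `sequence`).
#' @param d2o_fraction buffer deuterium fraction.
#' @return data frame `peptide_id`, `start`, `end`, `timepoint_min`,
#'   `uptake_da`, `percent`.
#' @export
peptide_uptake_table <- function(spectra, peptides, d2o_fraction = 0.975) {
  out <- list()
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides[i, ]
    sp <- spectra[spectra$peptide_id == pep$peptide_id, ]
    ref <- sp[sp$timepoint_min == 0, ]
    if (nrow(ref) == 0)
      stop("missing undeuterated reference for ", pep$peptide_id)
    tps <- sort(setdiff(unique(sp$timepoint_min), 0))
    for (tp in tps) {
      env <- sp[sp$timepoint_min == tp, ]
      up <- deuterium_uptake(env, ref)
      out[[length(out) + 1]] <- data.frame(
        peptide_id = pep$peptide_id, start = pep$start, end = pep$end,
        timepoint_min = tp, uptake_da = up,
        percent = suppressWarnings(
          percent_uptake(up, pep$sequence, d2o_fraction)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Project peptide-level percent deuteration onto residues
#'
#' Residue-level percent at one timepoint as the unweighted mean over all
#' peptides covering the residue (`length_weighted = TRUE` weights each
#' peptide by 1/length instead). Residues covered by no peptide are
#' reported as NA (absent, not zero).
#'
#' @param uptake a [peptide_uptake_table()] data frame.
#' @param timepoint timepoint (min) to project.
#' @param n_res chain length.
#' @param state state label stored on the result.
#' @param length_weighted weight covering peptides by inverse length.
#' @return A `deuteration_map` data frame: `residue`, `percent`; attribute
#'   `state`, `timepoint`.
#' @export
deuteration_map <- function(uptake, timepoint, n_res,
                            state = "apo", length_weighted = FALSE) {
  tab <- uptake[uptake$timepoint_min == timepoint, ]
  if (nrow(tab) == 0) stop("no peptides at timepoint ", timepoint)
  acc <- rep(0, n_res); w <- rep(0, n_res)
  for (i in seq_len(nrow(tab))) {
    idx <- seq(tab$start[i], tab$end[i])
    wt <- if (length_weighted) 1 / length(idx) else 1
    acc[idx] <- acc[idx] + wt * tab$percent[i]
    w[idx] <- w[idx] + wt
  }
  pct <- ifelse(w > 0, acc / w, NA_real_)
  out <- data.frame(residue = seq_len(n_res), percent = pct)
  attr(out, "state") <- state
  attr(out, "timepoint") <- timepoint
  class(out) <- c("deuteration_map", "data.frame")
  out
}

#' Apo/holo differential deuteration map
#'
#' Per-residue difference in percent deuteration between two states at
#' the same timepoint. Default convention `"stabilization_negative"`
#' reports `holo - apo`, so residues rigidified by the ligand (less
#' exchange in holo) come out negative; `"apo_minus_holo"` flips the
#' sign. The convention in force is recorded as an attribute.
#'
#' @param apo,holo `deuteration_map` objects at the same timepoint.
#' @param convention sign convention (see above).
#' @return data frame `residue`, `delta_percent` (NA where either state
#'   lacks coverage); attributes `convention`, `timepoint`.
#' @export
differential_map <- function(apo, holo,
                             convention = c("stabilization_negative",
                                            "apo_minus_holo")) {
  convention <- match.arg(convention)
  if (!isTRUE(all.equal(attr(apo, "timepoint"), attr(holo, "timepoint"))))
    stop("maps are at different timepoints")
  if (nrow(apo) != nrow(holo))
    stop("maps cover different chain lengths")
  delta <- holo$percent - apo$percent
  if (convention == "apo_minus_holo") delta <- -delta
  if (all(is.na(delta)))
    stop("no residues covered in both states")
  out <- data.frame(residue = apo$residue, delta_percent = delta)
  attr(out, "convention") <- convention
  attr(out, "timepoint") <- attr(apo, "timepoint")
  out
}

#' Write / read envelope spectra as CSV
#'
#' Format: `peptide_id,charge,timepoint_min,mz,intensity`.
#'
#' @param spectra envelope data frame.
#' @param path file path.
#' @return `read_hdx_spectra_csv` returns the data frame.
#' @export
write_hdx_spectra_csv <- function(spectra, path) {
  utils::write.csv(spectra, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hdx_spectra_csv
#' @export
read_hdx_spectra_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
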