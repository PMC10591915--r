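test_that("centroid does intensity-weighted arithmetic and validates input", {
  expect_equal(centroid(c(500.0, 500.5, 501.0), c(1, 2, 1)), 500.5)
  expect_equal(centroid(c(100.0, 101.0), c(1, 3)), 100.75)
  expect_equal(centroid(123.4, 7), 123.4)
  expect_error(centroid(c(100, 101), c(0, 0)), "all-zero")
  expect_error(centroid(c(101, 100), c(1, 1)), "increasing")
})

test_that("uptake is the charge-scaled centroid shift", {
  ref <- data.frame(mz = c(500.0, 500.5), intensity = c(2, 1), charge = 2)
  expect_equal(deuterium_uptake(ref, ref), 0)
  shifted <- ref; shifted$mz <- shifted$mz + 0.5
  expect_equal(deuterium_uptake(shifted, ref), 1.0)
  z1 <- data.frame(mz = c(800, 801), intensity = c(1, 1), charge = 1)
  expect_equal(deuterium_uptake(transform(z1, mz = mz + 1), z1), 1.0)
  expect_error(deuterium_uptake(transform(ref, charge = 3), ref),
               "charge mismatch")
})

test_that("percent uptake uses the exchangeable-amide convention", {
  # 10-mer, one internal proline: N_ex = 10 - 1 - 1 = 8
  pep <- "AGLPKTVEDS"
  expect_equal(count_exchangeable(pep), 8)
  expect_equal(percent_uptake(3.6, pep, d2o_fraction = 0.9), 50)
  expect_equal(percent_uptake(8 * 0.9, pep, d2o_fraction = 0.9), 100)
  expect_equal(percent_uptake(0, pep), 0)
  expect_warning(pct <- percent_uptake(10, pep, d2o_fraction = 0.9),
                 "clipped")
  expect_equal(pct, 100)
  expect_equal(percent_uptake(-0.05, pep), 0)  # noise floor
  expect_error(percent_uptake(1, "AP"), "no exchangeable")
})

test_that("fully protected residues take up nothing; protection 1 saturates", {
  cfg <- generator_config(seed = 3, noise_cv = 0, timepoints = c(1, 1000))
  seqc <- synthetic_sequence(24, seed = 5)
  sim_hi <- simulate_hdx(seqc, rep(1e9, 24), cfg)
  up_hi <- peptide_uptake_table(sim_hi$spectra, sim_hi$peptides,
                                cfg$d2o_fraction)
  expect_lt(max(abs(up_hi$uptake_da)), 1e-4)

  sim_1 <- simulate_hdx(seqc, rep(1, 24), cfg)
  up_1 <- peptide_uptake_table(sim_1$spectra, sim_1$peptides,
                               cfg$d2o_fraction)
  late <- up_1[up_1$timepoint_min == 1000, ]
  n_ex <- vapply(late$peptide_id, function(id)
    count_exchangeable(sim_1$peptides$sequence[
      sim_1$peptides$peptide_id == id]), numeric(1))
  # saturation: ~one deuteron mass per available amide, scaled by D2O
  expect_equal(late$uptake_da,
               unname(n_ex) * cfg$d2o_fraction * 1.0062767,
               tolerance = 1e-3)
})

test_that("uptake grows monotonically in time without noise", {
  cfg <- generator_config(seed = 4, noise_cv = 0)
  seqc <- synthetic_sequence(30, seed = 6)
  sim <- simulate_hdx(seqc, rep(5, 30), cfg)
  up <- peptide_uptake_table(sim$spectra, sim$peptides, cfg$d2o_fraction)
  for (id in unique(up$peptide_id)) {
    u <- up[up$peptide_id == id, ]
    expect_true(all(diff(u$uptake_da[order(u$timepoint_min)]) > 0))
  }
})

test_that("a missing undeuterated reference is an explicit error", {
  cfg <- generator_config(seed = 4)
  seqc <- synthetic_sequence(24, seed = 5)
  sim <- simulate_hdx(seqc, rep(5, 24), cfg)
  no_ref <- sim$spectra[sim$spectra$timepoint_min != 0, ]
  expect_error(peptide_uptake_table(no_ref, sim$peptides), "reference")
})

test_that("residue projection averages covering peptides and flags gaps", {
  up <- data.frame(peptide_id = c("a", "b"), start = c(1, 3),
                   end = c(4, 6), timepoint_min = 5,
                   uptake_da = c(1, 2), percent = c(40, 60))
  dm <- deuteration_map(up, 5, n_res = 8)
  expect_equal(dm$percent[1], 40)        # covered by a only
  expect_equal(dm$percent[3], 50)        # covered by both: mean(40, 60)
  expect_true(all(is.na(dm$percent[7:8])))
})

test_that("differential map sign convention makes stabilization negative", {
  mk <- function(pct, state) {
    out <- data.frame(residue = seq_along(pct), percent = pct)
    attr(out, "state") <- state; attr(out, "timepoint") <- 5
    class(out) <- c("deuteration_map", "data.frame")
    out
  }
  apo <- mk(c(60, 50, NA), "apo"); holo <- mk(c(40, 50, NA), "holo")
  d <- differential_map(apo, holo)
  expect_equal(d$delta_percent[1], -20)  # stabilized residue
  expect_equal(d$delta_percent[2], 0)
  expect_true(is.na(d$delta_percent[3]))
  d2 <- differential_map(apo, holo, convention = "apo_minus_holo")
  expect_equal(d2$delta_percent[1], 20)
  holo_late <- mk(c(40, 50, NA), "holo"); attr(holo_late, "timepoint") <- 10
  expect_error(differential_map(apo, holo_late), "timepoints")
  expect_error(differential_map(mk(c(NA, NA), "a"), mk(c(NA, NA), "h")),
               "no residues")
})

test_that("peptide-residue averaging reproduces the worked example", {
  up <- data.frame(peptide_id = c("a", "b"), start = c(10, 10),
                   end = c(12, 12), timepoint_min = 5,
                   uptake_da = c(1, 1), percent = c(30, 40))
  up_h <- transform(up, percent = c(20, 20))
  d <- differential_map(deuteration_map(up, 5, 15, "apo"),
                        deuteration_map(up_h, 5, 15, "holo"))
  # residue covered by peptides with deltas -10 and -20 averages to -15
  expect_equal(d$delta_percent[10], -15)
})
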