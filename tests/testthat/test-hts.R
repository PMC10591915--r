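ref <- screen_reference(pc350 = 200, pc480 = 100, nc350 = 100, nc480 = 200)

test_that("binding score is maximal for a control-duplicate and zero for no change", {
  expect_equal(binding_score(200, 100, ref), 2.0)
  expect_equal(binding_score(100, 200, ref), 0.0)
})

test_that("score reproduces the reconstructed-formula arithmetic", {
  # ratios 0.8 and 0.9 => 2 - 0.2 - 0.1 = 1.7
  f350 <- 100 + 0.8 * (200 - 100)
  f480 <- 200 + 0.9 * (100 - 200)
  expect_equal(binding_score(f350, f480, ref), 1.7)
})

test_that("score depends only on ratios: invariant under common rescaling", {
  k <- 3.7
  ref_k <- screen_reference(pc350 = 200 * k, pc480 = 100 * k,
                            nc350 = 100 * k, nc480 = 200 * k)
  for (fs in list(c(150, 150), c(210, 90), c(100, 200))) {
    expect_equal(binding_score(fs[1] * k, fs[2] * k, ref_k),
                 binding_score(fs[1], fs[2], ref))
  }
})

test_that("score decreases monotonically with deviation in either direction", {
  r350 <- c(1, 1.2, 1.5, 2, 0.8, 0.5, 0)
  f350 <- 100 + r350 * 100
  s <- binding_score(f350, rep(100, length(f350)), ref)  # r480 fixed at 1
  dev <- abs(1 - r350)
  o <- order(dev)
  expect_true(all(diff(s[o]) <= 0))
  expect_equal(s[1], 2)
  # a 2x overshoot at both wavelengths scores 0
  expect_equal(binding_score(100 + 2 * 100, 200 + 2 * (-100), ref), 0)
})

test_that("exclusion dominates the score and records a reason", {
  flt <- artifact_filter(c(TRUE, FALSE, FALSE, TRUE),
                         c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(flt$excluded, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(flt$exclusion_reason,
                   c("absorbance", "autofluorescence", NA, "absorbance"))

  plate <- data.frame(
    well_id = c("W1", "W2", "P1", "N1"),
    role = c("compound", "compound", "pos_ctrl", "neg_ctrl"),
    f350 = c(200, 200, 200, 100), f480 = c(100, 100, 100, 200),
    absorbance_flag = c(TRUE, FALSE, FALSE, FALSE),
    autofluorescence_flag = FALSE, stringsAsFactors = FALSE)
  res <- screen_plate(plate)
  w1 <- res[res$well_id == "W1", ]
  expect_equal(w1$score, 2)           # perfect signature...
  expect_true(w1$excluded)            # ...but flagged, so excluded
  expect_false(w1$is_hit)
  expect_identical(call_hits(res), "W2")
})

test_that("the 1.5 hit boundary is inclusive and ordering deterministic", {
  mk <- function(scores) {
    # wells engineered to given scores via r480 = 1, r350 = score - 1
    data.frame(
      well_id = sprintf("W%d", seq_along(scores)),
      role = "compound",
      f350 = 100 + (scores - 1) * 100, f480 = 100,
      absorbance_flag = FALSE, autofluorescence_flag = FALSE,
      stringsAsFactors = FALSE)
  }
  plate <- rbind(mk(c(1.49, 1.50, 1.51)),
                 data.frame(well_id = c("P1", "N1"),
                            role = c("pos_ctrl", "neg_ctrl"),
                            f350 = c(200, 100), f480 = c(100, 200),
                            absorbance_flag = FALSE,
                            autofluorescence_flag = FALSE,
                            stringsAsFactors = FALSE))
  res <- screen_plate(plate)
  expect_identical(call_hits(res), c("W3", "W2"))
  expect_true(res$is_hit[res$well_id == "W2"])   # exactly 1.5 is a hit
  # ties broken by well id
  expect_false(is.unsorted(rev(res$score)))
})

test_that("degenerate references and empty plates are handled", {
  expect_error(screen_reference(pc350 = 100, pc480 = 100,
                                nc350 = 100, nc480 = 200),
               "zero signal change")
  plate <- data.frame(well_id = c("P1", "N1"),
                      role = c("pos_ctrl", "neg_ctrl"),
                      f350 = c(200, 100), f480 = c(100, 200),
                      absorbance_flag = FALSE,
                      autofluorescence_flag = FALSE,
                      stringsAsFactors = FALSE)
  res <- screen_plate(plate)
  expect_identical(call_hits(res), character(0))
})

test_that("hits on a noisy synthetic plate equal the ground-truth binders", {
  plate <- simulate_plate(384, config = generator_config(seed = 42))
  res <- screen_plate(plate)
  truth <- plate$well_id[!is.na(plate$true_class) &
                           plate$true_class == "binder"]
  expect_setequal(call_hits(res), truth)
})

test_that("a custom scoring function can be plugged in", {
  alt <- function(r350, r480) 1 - 0.5 * (abs(1 - r350) + abs(1 - r480))
  expect_equal(binding_score(200, 100, ref, score_fn = alt), 1)
  expect_equal(binding_score(100, 200, ref, score_fn = alt), 0)
})
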