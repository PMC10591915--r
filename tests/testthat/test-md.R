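make_traj <- function(frames, resno = NULL, element = NULL,
                      is_ligand = NULL) {
  n <- nrow(frames[[1]])
  atoms <- data.frame(eleno = seq_len(n),
                      elety = rep("CA", n),
                      resno = resno %||% seq_len(n),
                      element = element %||% rep("C", n),
                      is_ligand = is_ligand %||% rep(FALSE, n),
                      stringsAsFactors = FALSE)
  xyz <- array(NA_real_, dim = c(n, 3, length(frames)))
  for (f in seq_along(frames)) xyz[, , f] <- frames[[f]]
  structure(list(atoms = atoms, xyz = xyz, system = "t", replicate = 1L),
            class = "trajectory_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the beta-strand selection is exactly the printed ranges", {
  sel <- strand_selection()
  expect_true(14 %in% sel); expect_false(15 %in% sel)
  expect_true(133 %in% sel); expect_false(134 %in% sel)
  expect_true(6 %in% sel); expect_false(5 %in% sel)
  expect_length(sel, 74)
  expect_false(any(duplicated(sel)))
})

test_that("portal regions are the inter-strand gaps", {
  reg <- portal_regions_from_strands()
  expect_equal(reg$alphaI_II, 15:38)
  expect_equal(reg$loop_b3_b4, 55:59)
  expect_equal(reg$loop_b5_b6, 74:80)
  expect_equal(reg$loop_b7_b8, 99:104)
  expect_setequal(reg$portal, c(15:38, 55:59, 74:80))
  # adjacent strands leave an empty, flagged gap
  reg2 <- portal_regions_from_strands(list(c(1, 5), c(6, 10), c(12, 15),
                                           c(16, 20), c(22, 25), c(26, 30),
                                           c(31, 33), c(34, 36), c(38, 40),
                                           c(41, 45)))
  expect_length(reg2$alphaI_II, 0)
  expect_true("alphaI_II" %in% attr(reg2, "empty_regions"))
  expect_error(portal_regions_from_strands(list(c(1, 10), c(5, 20))),
               "non-overlapping")
})

test_that("alignment removes rigid motion and preserves internal geometry", {
  set.seed(41)
  base <- matrix(rnorm(60, sd = 6), 20, 3)
  rand_rot <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  frames <- c(list(base), lapply(1:4, function(i)
    sweep(base %*% rand_rot(), 2, rnorm(3, sd = 5))))
  traj <- make_traj(frames)
  al <- align_frames(traj, residues = 1:20)
  for (f in 2:5) {
    expect_equal(al$xyz[, , f], base, tolerance = 1e-8)
    expect_equal(as.numeric(dist(al$xyz[, , f])),
                 as.numeric(dist(traj$xyz[, , f])), tolerance = 1e-8)
  }
  fr <- attr(al, "fit_rmsd")
  expect_true(all(fr$post <= fr$pre + 1e-12))
  # a static, already aligned trajectory is unchanged
  st <- make_traj(list(base, base))
  al2 <- align_frames(st, residues = 1:20)
  expect_equal(al2$xyz, st$xyz, tolerance = 1e-10)
})

test_that("RMSF matches the closed form for an alternating atom", {
  base <- matrix(rnorm(30), 10, 3)
  d <- 0.6
  up <- base; up[4, 1] <- up[4, 1] + d
  dn <- base; dn[4, 1] <- dn[4, 1] - d
  traj <- make_traj(list(up, dn, up, dn))
  prof <- rmsf(traj)
  expect_equal(prof$rmsf[prof$residue == 4], d, tolerance = 1e-10)
  expect_equal(max(prof$rmsf[prof$residue != 4]), 0, tolerance = 1e-10)
  # static trajectory: all zero
  expect_equal(max(rmsf(make_traj(list(base, base)))$rmsf), 0,
               tolerance = 1e-12)
  expect_error(rmsf(make_traj(list(base))), ">= 2")
})

test_that("hydrogens are excluded from RMSF by element, not name", {
  base <- matrix(rnorm(12), 4, 3)
  moved <- base; moved[2, ] <- moved[2, ] + 5
  traj <- make_traj(list(base, moved),
                    resno = c(1, 1, 2, 2),
                    element = c("C", "H", "C", "N"))
  prof <- rmsf(traj)
  expect_equal(prof$rmsf[prof$residue == 1], 0, tolerance = 1e-10)
})

test_that("RMSF-to-B conversion is 8 pi^2 / 3 times the square", {
  expect_equal(rmsf_to_bfactor(1), 8 * pi^2 / 3, tolerance = 1e-12)
  expect_equal(rmsf_to_bfactor(1), 26.319, tolerance = 1e-4)
  expect_equal(rmsf_to_bfactor(0), 0)
  expect_equal(rmsf_to_bfactor(1.9497), 100, tolerance = 1e-3)
  expect_error(rmsf_to_bfactor(-0.1), ">= 0")
})

test_that("no-fit region RMSD reads rigid displacement literally", {
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  d <- c(3, 0, 4)  # |d| = 5
  traj <- make_traj(list(base, sweep(base, 2, -d)))
  rr <- region_rmsd(traj, residues = 1:10)
  expect_equal(rr$series[1], 0)
  expect_equal(rr$series[2], 5, tolerance = 1e-10)
  expect_error(region_rmsd(traj, residues = 99), "empty")
  expect_error(region_rmsd(traj), "residues or ligand")
})

test_that("ligand RMSD ordering follows injected mobility", {
  prof <- rep(0.2, 40)
  stable <- simulate_trajectory(80, prof, ligand_mobility = 0.1,
                                config = generator_config(seed = 9))
  mobile <- simulate_trajectory(80, prof, ligand_mobility = 0.9,
                                config = generator_config(seed = 9))
  rs <- region_rmsd(align_frames(stable), ligand = TRUE)
  rm_ <- region_rmsd(align_frames(mobile), ligand = TRUE)
  expect_gt(rm_$mean, 2 * rs$mean)
})

test_that("a zero-amplitude trajectory is static after alignment", {
  traj <- simulate_trajectory(10, rep(0, 30), ligand_mobility = 0,
                              config = generator_config(seed = 2))
  al <- align_frames(traj)
  expect_equal(max(rmsf(al)$rmsf), 0, tolerance = 1e-7)
  expect_equal(region_rmsd(al, ligand = TRUE)$mean, 0, tolerance = 1e-7)
})

test_that("correlate reproduces hand OLS arithmetic and limits", {
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  r <- correlate(x, y)
  expect_equal(r$slope, 2); expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  r2 <- correlate(c(1, 2, 3), c(1, 2, 2))
  expect_equal(r2$r_squared, 0.75)
  expect_equal(r2$r_squared, oracle_r_squared(c(1, 2, 3), c(1, 2, 2)))
  set.seed(52)
  xr <- rnorm(500); yr <- rnorm(500)
  expect_lt(correlate(xr, yr)$r_squared, 0.05)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate(c(1, 2), c(1, 2)), ">= 3")
})

test_that("campaign bookkeeping validates totals", {
  d <- md_design_summary(9, 2, 500)
  expect_equal(d$total_ns, 9000)
  expect_equal(d$total_us, 9)
  expect_error(md_design_summary(0, 2, 500))
})

test_that("trajectories round-trip through the frame file format", {
  traj <- simulate_trajectory(6, rep(0.3, 15), ligand_mobility = 0.4,
                              config = generator_config(seed = 13))
  f <- withr::local_tempfile(fileext = ".trj")
  write_trajectory_frames(traj, f)
  back <- read_trajectory_frames(f)
  expect_equal(back$xyz, traj$xyz, tolerance = 1e-6)
  expect_identical(back$atoms$is_ligand, traj$atoms$is_ligand)
  expect_identical(back$system, traj$system)
})

test_that("B-factor profiles are invariant to a uniform rigid transform", {
  traj <- simulate_trajectory(30, rep(0.3, 20), ligand_mobility = 0.2,
                              config = generator_config(seed = 17),
                              rigid_wobble = FALSE)
  rot <- qr.Q(qr(matrix(c(0.2, 1, 0, -1, 0.3, 0.5, 0.1, 0, 1), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- traj
  for (f in seq_len(dim(traj$xyz)[3]))
    moved$xyz[, , f] <- sweep(traj$xyz[, , f] %*% rot, 2, c(-4, 2, 9))
  b1 <- rmsf_to_bfactor(rmsf(align_frames(traj))$rmsf)
  b2 <- rmsf_to_bfactor(rmsf(align_frames(moved))$rmsf)
  expect_equal(b2, b1, tolerance = 1e-6)
})
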