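# Small hand-built ensembles exercise the geometry operations with
# closed-form expectations.
tiny_ensemble <- function(xyz_models, elety = NULL, resno = NULL,
                          b = NULL) {
  n <- nrow(xyz_models[[1]])
  atoms <- data.frame(eleno = seq_len(n),
                      elety = elety %||% rep("CA", n),
                      resno = resno %||% seq_len(n),
                      element = "C", is_ligand = FALSE,
                      stringsAsFactors = FALSE)
  xyz <- array(NA_real_, dim = c(n, 3, length(xyz_models)))
  for (m in seq_along(xyz_models)) xyz[, , m] <- xyz_models[[m]]
  structure(list(atoms = atoms, xyz = xyz, b = b %||% rep(20, n),
                 n_res = length(unique(atoms$resno)),
                 structure_id = "tiny"),
            class = "structure_ensemble")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

test_that("Kabsch superposition recovers identity and pure rotations", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  tf <- kabsch_superpose(ref, ref)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)

  mob <- ref %*% rot_z(pi / 2)
  tf2 <- kabsch_superpose(mob, ref)
  expect_equal(tf2$rmsd, 0, tolerance = 1e-10)
  expect_equal(tf2$apply(mob), ref, tolerance = 1e-10)
  expect_equal(det(tf2$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch never returns a reflection and rejects degenerate input", {
  set.seed(12)
  ref <- matrix(rnorm(30), 10, 3)
  mirrored <- ref %*% diag(c(-1, 1, 1))
  tf <- kabsch_superpose(mirrored, ref)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-10)
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 0.1), "collinear")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), ">= 3")
})

test_that("main-chain B_eq averages isotropic B and converts ANISOU traces", {
  fold <- reference_fold(5)
  ens <- structure(list(atoms = fold$atoms,
                        xyz = array(fold$xyz, c(nrow(fold$xyz), 3, 1)),
                        b = rep(20, nrow(fold$atoms)), n_res = 5,
                        structure_id = "s"),
                   class = "structure_ensemble")
  tab <- extract_mainchain_beq(ens)
  expect_equal(tab$b_eq, rep(20, 5))

  ens$b[ens$atoms$resno == 3] <- c(10, 20, 30, 40)
  expect_equal(extract_mainchain_beq(ens)$b_eq[3], 25)

  # isotropic ANISOU with U11 = U22 = U33 = 0.01 A^2
  ens$u_trace <- rep(0.03, nrow(fold$atoms))
  tab2 <- extract_mainchain_beq(ens)
  expect_equal(tab2$b_eq, rep(8 * pi^2 * 0.01, 5), tolerance = 1e-10)
  expect_equal(tab2$b_eq[1], 0.7896, tolerance = 1e-4)
})

test_that("ANISOU written from isotropic B reads back as the same B_eq", {
  ens <- simulate_ensemble(2, rep(0.3, 10), generator_config(seed = 3),
                           rigid_jitter = FALSE)
  one <- ens; one$xyz <- ens$xyz[, , 1, drop = FALSE]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(one, f, anisou = TRUE)
  back <- read_ensemble_pdb(f)
  expect_true(all(!is.na(back$u_trace)))
  tab_iso <- extract_mainchain_beq(
    structure(list(atoms = back$atoms, b = back$b, n_res = 10,
                   structure_id = "x"), class = "structure_ensemble"))
  tab_aniso <- extract_mainchain_beq(back)
  expect_equal(tab_aniso$b_eq, tab_iso$b_eq, tolerance = 2e-3)
})

test_that("multi-model PDB files round-trip through bio3d", {
  ens <- simulate_ensemble(4, rep(0.4, 12), generator_config(seed = 6))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble_pdb(f)
  expect_equal(dim(back$xyz), dim(ens$xyz))
  expect_equal(back$xyz, ens$xyz, tolerance = 1e-3)
  expect_equal(back$b, ens$b, tolerance = 1e-2)
  expect_identical(back$atoms$resno, ens$atoms$resno)
})

test_that("z-score normalization has the stated arithmetic and invariances", {
  tab <- data.frame(structure_id = "s", residue = 1:3,
                    b_eq = c(10, 20, 30))
  z <- zscore_normalize(tab)
  expect_equal(z$z_b_eq, c(-1, 0, 1))

  set.seed(21)
  tab2 <- data.frame(structure_id = "s", residue = 1:50,
                     b_eq = rlnorm(50, 3, 0.4))
  z2 <- zscore_normalize(tab2)
  expect_equal(mean(z2$z_b_eq), 0, tolerance = 1e-9)
  expect_equal(sd(z2$z_b_eq), 1, tolerance = 1e-9)
  # affine invariance and idempotence
  tab3 <- tab2; tab3$b_eq <- 2 * tab3$b_eq + 5
  expect_equal(zscore_normalize(tab3)$z_b_eq, z2$z_b_eq, tolerance = 1e-9)
  z2b <- z2; z2b$b_eq <- z2$z_b_eq
  expect_equal(zscore_normalize(z2b)$z_b_eq, z2$z_b_eq, tolerance = 1e-9)

  expect_error(zscore_normalize(data.frame(residue = 1:2, b_eq = c(1, 2))),
               ">= 3")
  expect_error(zscore_normalize(data.frame(residue = 1:5,
                                           b_eq = rep(7, 5))),
               "constant")
})

test_that("B_eq differences are zero for identical states and additive", {
  tab <- zscore_normalize(data.frame(structure_id = "apo", residue = 1:10,
                                     b_eq = c(1:9, 20)))
  holo <- tab; holo$structure_id <- "h1"
  d <- beq_difference(tab, list(holo))
  expect_equal(d$diff_h1, rep(0, 10))
  holo2 <- holo; holo2$structure_id <- "h2"
  d2 <- beq_difference(tab, list(holo, holo2))
  expect_equal(d2$cumulative, 2 * d2$diff_h1)

  # a residue missing from one holo is absent, not zero
  holo3 <- zscore_normalize(holo[-4, ])
  d3 <- beq_difference(tab, list(holo3))
  expect_true(is.na(d3$diff_h1[d3$residue == 4]))
  disjoint <- zscore_normalize(data.frame(structure_id = "x",
                                          residue = 101:110,
                                          b_eq = c(1:9, 20)))
  expect_error(beq_difference(tab, list(disjoint)), "no residues")
  expect_error(beq_difference(tab[, c("structure_id", "residue", "b_eq")],
                              list(holo)), "normalized")
})

test_that("ensemble per-residue RMSD matches the closed-form displaced-atom case", {
  set.seed(31)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  d <- 0.8
  m2 <- base; m2[5, 1] <- m2[5, 1] + d
  ens <- tiny_ensemble(list(base, m2))
  out <- ensemble_residue_rmsd(ens, fit_residues = c(1:4, 6:10))
  expect_equal(out$rmsd[out$residue == 5], d / 2, tolerance = 1e-9)
  expect_equal(max(out$rmsd[out$residue != 5]), 0, tolerance = 1e-9)
  # pairwise convention: the displaced residue reads d
  outp <- ensemble_residue_rmsd(ens, fit_residues = c(1:4, 6:10),
                                method = "pairwise")
  expect_equal(outp$rmsd[outp$residue == 5], d, tolerance = 1e-9)
})

test_that("ensemble RMSD is invariant to rigid motion and model order", {
  set.seed(32)
  base <- matrix(rnorm(36, sd = 4), 12, 3)
  m2 <- base + matrix(rnorm(36, sd = 0.2), 12, 3)
  m3 <- sweep(m2 %*% rot_z(1.1), 2, c(-3, 8, 2))  # rigid copy of m2
  ens_a <- tiny_ensemble(list(base, m2))
  ens_b <- tiny_ensemble(list(base, m3))
  expect_equal(ensemble_residue_rmsd(ens_b)$rmsd,
               ensemble_residue_rmsd(ens_a)$rmsd, tolerance = 1e-9)
  # identical models give zeros; model order does not matter
  expect_equal(max(ensemble_residue_rmsd(
    tiny_ensemble(list(base, base)))$rmsd), 0, tolerance = 1e-10)
  ens_c <- tiny_ensemble(list(m2, base))
  expect_equal(sort(ensemble_residue_rmsd(ens_c)$rmsd),
               sort(ensemble_residue_rmsd(ens_a)$rmsd), tolerance = 1e-9)
})

test_that("injected flexibility shows up monotonically in ensemble RMSD", {
  prof <- apo_flexibility_profile()
  ens <- simulate_ensemble(10, prof, generator_config(seed = 15))
  out <- ensemble_residue_rmsd(ens)
  portal <- portal_regions_from_strands()$portal
  expect_gt(mean(out$rmsd[out$residue %in% portal]),
            2 * mean(out$rmsd[out$residue %in% strand_selection()]))
  expect_error(simulate_ensemble(1, prof), ">= 2")
})
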