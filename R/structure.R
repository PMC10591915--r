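# Main-chain atom set used for B_eq averaging and per-residue RMSD.
MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

eight_pi_sq <- 8 * pi^2

#' Kabsch least-squares superposition
#'
#' Optimal rigid transform (proper rotation + translation) mapping
#' `mobile` onto `reference` in the least-squares sense, computed from the
#' SVD of the covariance of the centred selections with the determinant
#' constrained to +1 (no reflection). Row-vector convention: a point `x`
#' maps to `x %*% rotation + translation`.
#'
#' @param mobile,reference n x 3 coordinate matrices with matching rows.
#' @param selection optional row indices used to compute the fit (default
#'   all rows); must contain >= 3 non-collinear points.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (fit RMSD over the selection after transformation), and `apply`, a
#'   function transforming any n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    stop("need >= 3 selection atoms for superposition")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  if (svd(P0)$d[2] < 1e-10 * max(svd(P0)$d[1], 1))
    stop("degenerate (collinear) selection")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- qc - pc %*% R
  apply_tf <- function(x) sweep(as.matrix(x) %*% R, 2, -as.numeric(tr))
  fitted <- apply_tf(P)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(tr), rmsd = rmsd,
       apply = apply_tf)
}

#' Synthetic reference fold
#'
#' Deterministic main-chain (N, CA, C, O) coordinates for a synthetic
#' single-chain protein laid out along a smooth non-degenerate 3D curve.
#' This is a stand-in scaffold for simulation: it reproduces the residue
#' numbering and atom bookkeeping of the real protein, not its geometry.
#'
#' @param n_res number of residues (default 133, the chain length used
#'   throughout the analyses).
#' @return list with `atoms` (data frame: `eleno`, `elety`, `resno`,
#'   `element`, `is_ligand`) and `xyz` (n_atoms x 3 matrix, angstrom).
#' @export
reference_fold <- function(n_res = 133L) {
  offsets <- rbind(N = c(-0.8, 0.4, 0.0), CA = c(0.0, 0.0, 0.0),
                   C = c(0.9, 0.5, 0.1), O = c(1.1, 1.5, 0.4))
  t <- seq_len(n_res)
  centre <- cbind(8 * cos(t / 3) + 0.05 * t,
                  8 * sin(t / 3),
                  1.5 * t + 2 * sin(t / 7))
  atoms <- do.call(rbind, lapply(t, function(i) {
    data.frame(elety = rownames(offsets), resno = i,
               element = c("N", "C", "C", "O"),
               is_ligand = FALSE, stringsAsFactors = FALSE)
  }))
  xyz <- do.call(rbind, lapply(t, function(i) {
    sweep(offsets, 2, -centre[i, ])
  }))
  atoms$eleno <- seq_len(nrow(atoms))
  atoms <- atoms[, c("eleno", "elety", "resno", "element", "is_ligand")]
  rownames(xyz) <- NULL
  list(atoms = atoms, xyz = unname(xyz))
}

#' Per-residue flexibility profiles for the synthetic protein
#'
#' Displacement standard deviations (angstrom, per coordinate) used by
#' [simulate_ensemble()] and [simulate_trajectory()], built the way real
#' per-residue mobility looks: a gently varying scaffold baseline, more
#' mobile chain termini, a beta7-beta8 hairpin loop that stays mobile in
#' both states, and the portal region (helices I/II plus the beta3-beta4
#' and beta5-beta6 loops) strongly elevated in apo. The holo profile
#' scales only the portal amplitude down (default 3-fold), emulating
#' ligand-induced rigidification; everything else is common to both
#' states, so state differences localize to the portal.
#'
#' @param n_res chain length.
#' @param scaffold baseline displacement SD (angstrom).
#' @param portal portal displacement SD in the apo state (angstrom).
#' @param portal_scale multiplier applied to the portal amplitude
#'   (`holo_flexibility_profile` default 1/3).
#' @param regions a [portal_regions_from_strands()] region definition.
#' @return numeric vector of length `n_res`.
#' @export
apo_flexibility_profile <- function(n_res = 133L, scaffold = 0.15,
                                    portal = 0.7,
                                    regions = portal_regions_from_strands()) {
  i <- seq_len(n_res)
  prof <- scaffold + 0.03 * (1 + sin(i / 6))      # smooth baseline texture
  term <- c(1:4, seq(max(1, n_res - 3), n_res))
  prof[term] <- prof[term] + 0.2                  # frayed termini
  b78 <- intersect(regions$loop_b7_b8, i)
  prof[b78] <- prof[b78] + 0.25                   # mobile in both states
  prof[intersect(regions$portal, i)] <- portal
  prof
}

#' @rdname apo_flexibility_profile
#' @export
holo_flexibility_profile <- function(n_res = 133L, scaffold = 0.15,
                                     portal = 0.7, portal_scale = 1 / 3,
                                     regions = portal_regions_from_strands()) {
  prof <- apo_flexibility_profile(n_res, scaffold, portal, regions)
  idx <- intersect(regions$portal, seq_len(n_res))
  prof[idx] <- prof[idx] * portal_scale
  prof
}

#' Simulate a multi-model structural ensemble
#'
#' Generates `n_models` copies of the synthetic reference fold, each
#' residue rigidly displaced by an isotropic Gaussian with the SD given by
#' `flexibility` (angstrom per coordinate), then each whole model given a
#' random rigid rotation/translation (which downstream superposition must
#' remove). Per-atom isotropic B-factors are set consistently with the
#' injected fluctuation: `B = b_base + 8 pi^2 sigma^2`.
#'
#' @param n_models number of models (>= 2).
#' @param flexibility per-residue displacement SD, length = residue count.
#' @param config a [generator_config()] (seed).
#' @param b_base baseline B-factor (angstrom^2).
#' @param rigid_jitter logical; apply a random rigid transform per model.
#' @param structure_id label carried into B-factor tables.
#' @return A `structure_ensemble`: list with `atoms`, `xyz` (array
#'   n_atoms x 3 x n_models), `b` (per-atom B, angstrom^2), `n_res`,
#'   `structure_id`.
#' @export
simulate_ensemble <- function(n_models, flexibility,
                              config = generator_config(),
                              b_base = 10, rigid_jitter = TRUE,
                              structure_id = "synthetic") {
  if (n_models < 2) stop("n_models must be >= 2")
  fold <- reference_fold(length(flexibility))
  atoms <- fold$atoms
  n_atoms <- nrow(atoms)
  sig_atom <- flexibility[atoms$resno]
  with_seed(stage_seed(config$seed, "ensemble"), {
    xyz <- array(NA_real_, dim = c(n_atoms, 3, n_models))
    for (m in seq_len(n_models)) {
      disp <- matrix(stats::rnorm(3 * length(flexibility), 0,
                                  pmax(flexibility, 0)),
                     ncol = 3)
      coords <- fold$xyz + disp[atoms$resno, , drop = FALSE]
      if (rigid_jitter) coords <- random_rigid_transform(coords)
      xyz[, , m] <- coords
    }
    structure(list(atoms = atoms, xyz = xyz,
                   b = b_base + eight_pi_sq * sig_atom^2,
                   n_res = length(flexibility),
                   structure_id = structure_id),
              class = "structure_ensemble")
  })
}

# Small random proper rotation + translation (uses the caller's RNG).
random_rigid_transform <- function(coords, max_shift = 5) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::runif(3, -max_shift, max_shift)
  sweep(coords %*% R, 2, -shift)
}

#' Write an ensemble (or single model) as a PDB file
#'
#' Emits standard fixed-column ATOM records, wrapped in MODEL/ENDMDL
#' blocks when more than one model is present. With `anisou = TRUE` each
#' ATOM is followed by an isotropic ANISOU record with
#' `U11 = U22 = U33 = B / (8 pi^2)`.
#'
#' @param ens a `structure_ensemble`.
#' @param path output path.
#' @param anisou write ANISOU records (single-model output only).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, anisou = FALSE) {
  atoms <- ens$atoms
  n_models <- dim(ens$xyz)[3]
  if (anisou && n_models > 1)
    stop("ANISOU output supported for single-model files only")
  con <- file(path, "w")
  on.exit(close(con))
  resid3 <- "ALA"
  for (m in seq_len(n_models)) {
    if (n_models > 1) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(atoms))) {
      name4 <- sprintf(" %-3s", atoms$elety[i])
      line <- sprintf(
        "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        atoms$eleno[i], name4, resid3, atoms$resno[i],
        ens$xyz[i, 1, m], ens$xyz[i, 2, m], ens$xyz[i, 3, m],
        1.00, ens$b[i], atoms$element[i])
      writeLines(line, con)
      if (anisou) {
        u <- round(ens$b[i] / eight_pi_sq * 1e4)
        aline <- sprintf(
          "ANISOU%5d %s %3s A%4d  %7d%7d%7d%7d%7d%7d      %2s",
          atoms$eleno[i], name4, resid3, atoms$resno[i],
          u, u, u, 0L, 0L, 0L, atoms$element[i])
        writeLines(aline, con)
      }
    }
    if (n_models > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file into an ensemble object
#'
#' Coordinate/B parsing is delegated to `bio3d::read.pdb` (multi-model
#' aware); ANISOU records, which bio3d does not retain, are recovered by
#' [read_anisou()] and attached as `u_trace` (U11+U22+U33, angstrom^2)
#' aligned to atom serial numbers.
#'
#' @param path PDB file path.
#' @return A `structure_ensemble` (single-model files give one model);
#'   element `u_trace` is NA for atoms without ANISOU records.
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_atoms <- nrow(at)
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
  n_models <- nrow(xyz_mat)
  xyz <- array(NA_real_, dim = c(n_atoms, 3, n_models))
  for (m in seq_len(n_models)) {
    xyz[, , m] <- matrix(xyz_mat[m, ], ncol = 3, byrow = TRUE)
  }
  element <- at$elesy
  if (is.null(element) || all(is.na(element)))
    element <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                      resno = at$resno, element = trimws(element),
                      is_ligand = !(at$type == "ATOM"),
                      stringsAsFactors = FALSE)
  u <- read_anisou(path)
  u_trace <- rep(NA_real_, n_atoms)
  if (nrow(u) > 0) {
    idx <- match(u$eleno, atoms$eleno)
    u_trace[idx[!is.na(idx)]] <- u$u_trace[!is.na(idx)]
  }
  structure(list(atoms = atoms, xyz = xyz,
                 b = at$b, u_trace = u_trace,
                 n_res = length(unique(atoms$resno[!atoms$is_ligand])),
                 structure_id = sub("\\.pdb$", "", basename(path))),
            class = "structure_ensemble")
}

#' Extract ANISOU records from a PDB file
#'
#' Fixed-column parse of ANISOU records (the anisotropic displacement
#' tensor in 1e-4 angstrom^2 units): returns the atom serial number and
#' the tensor trace U11+U22+U33 in angstrom^2.
#'
#' @param path PDB file path.
#' @return data frame with `eleno` and `u_trace`; zero rows if the file
#'   has no ANISOU records.
#' @export
read_anisou <- function(path) {
  lines <- readLines(path)
  an <- lines[startsWith(lines, "ANISOU")]
  if (length(an) == 0)
    return(data.frame(eleno = integer(0), u_trace = numeric(0)))
  eleno <- as.integer(substr(an, 7, 11))
  u11 <- as.numeric(substr(an, 29, 35))
  u22 <- as.numeric(substr(an, 36, 42))
  u33 <- as.numeric(substr(an, 43, 49))
  data.frame(eleno = eleno, u_trace = (u11 + u22 + u33) * 1e-4)
}

#' Per-residue main-chain equivalent isotropic B-factors
#'
#' For each residue, the unweighted mean over its main-chain atoms
#' (N, CA, C, O) of the equivalent isotropic B-factor: the recorded
#' isotropic B, or `8 pi^2 (U11+U22+U33) / 3` where an ANISOU tensor is
#' available. Residues with no main-chain atoms are excluded with a
#' warning.
#'
#' @param ens a `structure_ensemble` (first model's B column is used; B is
#'   constant across models in ensemble-refinement output conventions used
#'   here) or anything with `atoms`, `b`, optional `u_trace`.
#' @param structure_id optional label override.
#' @return A `residue_bfactor_table` data frame: `structure_id`,
#'   `residue`, `b_eq`.
#' @export
extract_mainchain_beq <- function(ens, structure_id = NULL) {
  atoms <- ens$atoms
  b_eq_atom <- ens$b
  if (!is.null(ens$u_trace)) {
    has_u <- !is.na(ens$u_trace)
    b_eq_atom[has_u] <- eight_pi_sq * ens$u_trace[has_u] / 3
  }
  keep <- !atoms$is_ligand & atoms$elety %in% MAINCHAIN_ATOMS
  all_res <- sort(unique(atoms$resno[!atoms$is_ligand]))
  if (!any(keep)) stop("no main-chain atoms found")
  tab <- stats::aggregate(b_eq_atom[keep],
                          by = list(residue = atoms$resno[keep]), FUN = mean)
  names(tab)[2] <- "b_eq"
  missing <- setdiff(all_res, tab$residue)
  if (length(missing) > 0)
    warning("residues with no main-chain atoms excluded: ",
            paste(missing, collapse = ", "))
  out <- data.frame(structure_id = structure_id %||% ens$structure_id,
                    residue = tab$residue, b_eq = tab$b_eq,
                    stringsAsFactors = FALSE)
  class(out) <- c("residue_bfactor_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score normalization of per-residue B_eq values
#'
#' Rescales one structure's per-residue B_eq values to mean 0 and unit
#' sample (n-1) standard deviation, so structures refined with different
#' overall B scales become comparable. Invariant under any affine map
#' `B -> a*B + b` with `a > 0`, and idempotent on an already-normalized
#' table.
#'
#' @param table a `residue_bfactor_table` (or data frame with `residue`,
#'   `b_eq`).
#' @return the table with a `z_b_eq` column added/recomputed.
#' @export
zscore_normalize <- function(table) {
  if (nrow(table) < 3) stop("need >= 3 residues to normalize")
  s <- stats::sd(table$b_eq)
  if (!is.finite(s) || s == 0)
    stop("constant B_eq across the structure: z-score undefined")
  table$z_b_eq <- (table$b_eq - mean(table$b_eq)) / s
  class(table) <- unique(c("residue_bfactor_table", class(table)))
  table
}

#' Apo-minus-holo differences of normalized B_eq
#'
#' For each holo structure, `diff = z_apo - z_holo` per residue (positive
#' where the holo structure is rigidified relative to apo), plus the
#' cumulative difference summed over holo structures. Residues absent
#' from any structure are reported as NA, not zero; residue alignment is
#' by residue number (isomorphous crystals).
#'
#' @param apo normalized `residue_bfactor_table` for the apo structure.
#' @param holos list of normalized tables for holo structures.
#' @return data frame with `residue`, one `diff_<structure_id>` column per
#'   holo, and `cumulative` (NA where any structure lacks the residue).
#' @export
beq_difference <- function(apo, holos) {
  if (!"z_b_eq" %in% names(apo) ||
      !all(vapply(holos, function(h) "z_b_eq" %in% names(h), logical(1))))
    stop("tables must be z-score normalized first (see zscore_normalize)")
  if (inherits(holos, "data.frame")) holos <- list(holos)
  residues <- sort(Reduce(union, c(list(apo$residue),
                                   lapply(holos, `[[`, "residue"))))
  if (length(Reduce(intersect, c(list(apo$residue),
                                 lapply(holos, `[[`, "residue")))) == 0)
    stop("apo and holo structures share no residues")
  out <- data.frame(residue = residues)
  z_apo <- apo$z_b_eq[match(residues, apo$residue)]
  for (h in holos) {
    id <- if ("structure_id" %in% names(h)) h$structure_id[1] else "holo"
    z_h <- h$z_b_eq[match(residues, h$residue)]
    out[[paste0("diff_", id)]] <- z_apo - z_h
  }
  diff_cols <- grep("^diff_", names(out), value = TRUE)
  out$cumulative <- rowSums(out[, diff_cols, drop = FALSE], na.rm = FALSE)
  out
}

#' Per-residue RMSD across a structural ensemble
#'
#' All models are superposed onto the first by [kabsch_superpose()] over
#' the fit selection (by default, main-chain atoms of the beta-strand
#' scaffold). Each residue's RMSD is then the root of the mean, over
#' models and that residue's main-chain atoms, of the squared deviation
#' from the across-model mean position (`method = "to_mean"`), or the
#' mean over model pairs of the per-residue inter-model RMSD
#' (`method = "pairwise"`).
#'
#' @param ens a `structure_ensemble` with >= 2 models.
#' @param fit_residues residues used for superposition (default: the
#'   beta-strand scaffold from [strand_selection()]).
#' @param method `"to_mean"` (default) or `"pairwise"`.
#' @return data frame with `residue` and `rmsd` (angstrom).
#' @export
ensemble_residue_rmsd <- function(ens, fit_residues = strand_selection(),
                                  method = c("to_mean", "pairwise")) {
  method <- match.arg(method)
  n_models <- dim(ens$xyz)[3]
  if (n_models < 2) stop("need >= 2 models")
  atoms <- ens$atoms
  sel <- which(!atoms$is_ligand & atoms$resno %in% fit_residues &
                 atoms$elety %in% MAINCHAIN_ATOMS)
  if (length(sel) == 0) stop("fit selection matches no atoms")
  ref <- ens$xyz[, , 1]
  aligned <- array(NA_real_, dim = dim(ens$xyz))
  aligned[, , 1] <- ref
  for (m in seq(2, n_models)) {
    tf <- kabsch_superpose(ens$xyz[, , m], ref, selection = sel)
    aligned[, , m] <- tf$apply(ens$xyz[, , m])
  }
  mc <- which(!atoms$is_ligand & atoms$elety %in% MAINCHAIN_ATOMS)
  res_ids <- sort(unique(atoms$resno[mc]))
  rmsd <- vapply(res_ids, function(r) {
    idx <- mc[atoms$resno[mc] == r]
    block <- aligned[idx, , , drop = FALSE]  # atoms x 3 x models
    model_mat <- function(m) matrix(block[, , m], ncol = 3)
    if (method == "to_mean") {
      mu <- apply(block, c(1, 2), mean)
      dev2 <- vapply(seq_len(n_models), function(m)
        mean(rowSums((model_mat(m) - mu)^2)), numeric(1))
      sqrt(mean(dev2))
    } else {
      pairs <- utils::combn(n_models, 2)
      mean(apply(pairs, 2, function(p) {
        sqrt(mean(rowSums((model_mat(p[1]) - model_mat(p[2]))^2)))
      }))
    }
  }, numeric(1))
  data.frame(residue = res_ids, rmsd = rmsd)
}
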