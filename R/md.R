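#' Beta-strand scaffold residues
#'
#' The ten beta-strand residue ranges used for trajectory and ensemble
#' superposition: 6-14, 39-45, 48-54, 60-65, 70-73, 81-89, 92-98,
#' 105-111, 114-121, 124-133 (74 residues).
#'
#' @return integer vector of residue numbers.
#' @export
strand_selection <- function() {
  unlist(lapply(strand_ranges(), function(r) seq(r[1], r[2])),
         use.names = FALSE)
}

strand_ranges <- function() {
  list(c(6, 14), c(39, 45), c(48, 54), c(60, 65), c(70, 73),
       c(81, 89), c(92, 98), c(105, 111), c(114, 121), c(124, 133))
}

#' Portal and loop regions derived from the strand list
#'
#' Names the inter-strand gaps of the beta-barrel: the helix I/II region
#' (between strands 1 and 2), the beta3-beta4, beta5-beta6 and
#' beta7-beta8 hairpin loops, and the portal region as the union of the
#' first three. With the printed strand list this gives
#' helices I/II = 15-38, beta3-beta4 = 55-59, beta5-beta6 = 74-80,
#' beta7-beta8 = 99-104. Zero-length gaps (adjacent strands) are kept as
#' empty, flagged regions.
#'
#' @param strands list of `c(start, end)` strand ranges, ordered and
#'   non-overlapping.
#' @return A `region_definition`: list of integer residue vectors
#'   `alphaI_II`, `loop_b3_b4`, `loop_b5_b6`, `loop_b7_b8`, `portal`,
#'   plus `beta_strands`; attribute `empty_regions` names any empty gap.
#' @export
portal_regions_from_strands <- function(strands = strand_ranges()) {
  starts <- vapply(strands, `[`, numeric(1), 1)
  ends <- vapply(strands, `[`, numeric(1), 2)
  if (is.unsorted(starts) || any(starts[-1] <= ends[-length(ends)]))
    stop("strand ranges must be ordered and non-overlapping")
  gap <- function(i) {
    lo <- ends[i] + 1; hi <- starts[i + 1] - 1
    if (lo > hi) integer(0) else seq(lo, hi)
  }
  regions <- list(
    beta_strands = unlist(Map(seq, starts, ends), use.names = FALSE),
    alphaI_II = gap(1),
    loop_b3_b4 = gap(3),
    loop_b5_b6 = gap(5),
    loop_b7_b8 = gap(7))
  regions$portal <- c(regions$alphaI_II, regions$loop_b3_b4,
                      regions$loop_b5_b6)
  empty <- names(regions)[vapply(regions, length, integer(1)) == 0]
  structure(regions, class = "region_definition", empty_regions = empty)
}

#' Simulate a trajectory
#'
#' Coordinate frames for the synthetic protein (plus a 10-heavy-atom
#' ligand placed in the pocket) generated as AR(1)
#' (Ornstein-Uhlenbeck-like) jitter around the reference fold: per
#' residue (and per ligand atom), each frame's displacement relaxes
#' toward zero with memory `rho` and stationary per-coordinate SD from
#' `rmsf_profile` (`ligand_mobility` for the ligand). Frame 1 carries no
#' thermal displacement — it is the minimized starting structure, the
#' reference that no-fit RMSD is measured against. Each frame optionally
#' receives a small random rigid wobble, which downstream alignment must
#' remove.
#'
#' @param n_frames number of frames (>= 2).
#' @param rmsf_profile per-residue displacement SD (angstrom, per
#'   coordinate).
#' @param ligand_mobility displacement SD of the ligand (angstrom); 0
#'   gives a pocket-locked ligand.
#' @param config a [generator_config()] (seed).
#' @param system,replicate labels.
#' @param rho AR(1) memory in (0, 1).
#' @param rigid_wobble apply small per-frame rigid transforms.
#' @return A `trajectory_set`: list with `atoms` (incl. `is_ligand`,
#'   `element`), `xyz` (n_atoms x 3 x n_frames), `system`, `replicate`.
#' @export
simulate_trajectory <- function(n_frames, rmsf_profile, ligand_mobility = 0.3,
                                config = generator_config(),
                                system = "system", replicate = 1L,
                                rho = 0.5, rigid_wobble = TRUE) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  fold <- reference_fold(length(rmsf_profile))
  lig_xyz <- ligand_coords(fold)
  lig_atoms <- data.frame(
    eleno = max(fold$atoms$eleno) + seq_len(nrow(lig_xyz)),
    elety = sprintf("C%d", seq_len(nrow(lig_xyz))),
    resno = max(fold$atoms$resno) + 1L,
    element = "C", is_ligand = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(fold$atoms, lig_atoms)
  ref <- rbind(fold$xyz, lig_xyz)
  # each residue moves as one unit; each ligand atom jitters independently
  n_units <- length(rmsf_profile) + nrow(lig_xyz)
  unit_of_atom <- c(fold$atoms$resno,
                    length(rmsf_profile) + seq_len(nrow(lig_xyz)))
  sig_unit <- c(rmsf_profile, rep(ligand_mobility, nrow(lig_xyz)))

  with_seed(stage_seed(config$seed, "trajectory") + as.integer(replicate), {
    xyz <- array(NA_real_, dim = c(nrow(ref), 3, n_frames))
    # frame 1 is the minimized starting structure: zero displacement
    disp <- matrix(0, n_units, 3)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        innov <- matrix(stats::rnorm(n_units * 3, 0,
                                     pmax(sig_unit, 0) * sqrt(1 - rho^2)),
                        ncol = 3)
        disp <- rho * disp + innov
      }
      coords <- ref + disp[unit_of_atom, , drop = FALSE]
      if (rigid_wobble) coords <- random_rigid_transform(coords, max_shift = 1)
      xyz[, , f] <- coords
    }
    structure(list(atoms = atoms, xyz = xyz, system = system,
                   replicate = as.integer(replicate)),
              class = "trajectory_set")
  })
}

# Rigid ligand template near the fold interior.
ligand_coords <- function(fold) {
  centre <- colMeans(fold$xyz)
  ang <- seq(0, 2 * pi, length.out = 11)[1:10]
  sweep(cbind(1.5 * cos(ang), 1.5 * sin(ang), seq(-1, 1, length.out = 10)),
        2, -centre)
}

#' Align trajectory frames on a residue selection
#'
#' Superposes every frame onto frame 1 by [kabsch_superpose()] over the
#' main-chain atoms of the selected residues (default: the beta-strand
#' scaffold). Per-frame fit RMSD before and after alignment is recorded
#' in attribute `fit_rmsd`.
#'
#' @param traj a `trajectory_set`.
#' @param residues fit residues (default [strand_selection()]).
#' @return the aligned `trajectory_set`.
#' @export
align_frames <- function(traj, residues = strand_selection()) {
  atoms <- traj$atoms
  sel <- which(!atoms$is_ligand & atoms$resno %in% residues &
                 atoms$elety %in% MAINCHAIN_ATOMS)
  if (length(sel) < 3) stop("degenerate fit selection")
  n_frames <- dim(traj$xyz)[3]
  ref <- traj$xyz[, , 1]
  pre <- post <- numeric(n_frames)
  out <- traj$xyz
  for (f in seq_len(n_frames)) {
    pre[f] <- sqrt(mean(rowSums((traj$xyz[sel, , f] - ref[sel, ])^2)))
    tf <- kabsch_superpose(traj$xyz[, , f], ref, selection = sel)
    out[, , f] <- tf$apply(traj$xyz[, , f])
    post[f] <- tf$rmsd
  }
  traj$xyz <- out
  attr(traj, "fit_rmsd") <- data.frame(frame = seq_len(n_frames),
                                       pre = pre, post = post)
  traj$aligned <- TRUE
  traj
}

#' Per-residue RMSF of an aligned trajectory
#'
#' Each atom's fluctuation is the root-mean-square deviation from its
#' time-average position; a residue's RMSF is the root of the mean squared
#' fluctuation over its heavy atoms (element not hydrogen).
#'
#' @param traj an aligned `trajectory_set` (see [align_frames()]).
#' @return data frame with `residue` and `rmsf` (angstrom); ligand atoms
#'   excluded.
#' @export
rmsf <- function(traj) {
  if (dim(traj$xyz)[3] < 2) stop("need >= 2 frames")
  atoms <- traj$atoms
  heavy <- !atoms$is_ligand & toupper(atoms$element) != "H"
  mu <- apply(traj$xyz, c(1, 2), mean)
  dev2 <- apply(traj$xyz, 3, function(fr) rowSums((fr - mu)^2))
  fluct2 <- rowMeans(dev2)  # per-atom mean squared fluctuation
  res_ids <- sort(unique(atoms$resno[heavy]))
  out <- vapply(res_ids, function(r) {
    sqrt(mean(fluct2[heavy & atoms$resno == r]))
  }, numeric(1))
  data.frame(residue = res_ids, rmsf = out)
}

#' Simulated B-factors from RMSF
#'
#' `B = (8 pi^2 / 3) * rmsf^2` (angstrom^2), the standard conversion from
#' mean squared positional fluctuation to an isotropic displacement
#' parameter.
#'
#' @param rmsf_values RMSF values (angstrom, >= 0).
#' @return B-factors (angstrom^2).
#' @export
rmsf_to_bfactor <- function(rmsf_values) {
  if (any(rmsf_values < 0)) stop("rmsf must be >= 0")
  (8 * pi^2 / 3) * rmsf_values^2
}

#' No-fit RMSD of a region (or the ligand) along a trajectory
#'
#' Heavy-atom RMSD of the selected atoms in each frame against frame 1,
#' with no additional fitting (the single global alignment is assumed to
#' have been applied already), plus mean and SD over frames.
#'
#' @param traj an aligned `trajectory_set`.
#' @param residues residues defining the region; ignored when
#'   `ligand = TRUE`.
#' @param ligand measure the ligand instead of a protein region.
#' @return list with `series` (per-frame RMSD, angstrom), `mean`, `sd`.
#' @export
region_rmsd <- function(traj, residues = NULL, ligand = FALSE) {
  atoms <- traj$atoms
  heavy <- toupper(atoms$element) != "H"
  idx <- if (ligand) {
    which(atoms$is_ligand & heavy)
  } else {
    if (is.null(residues)) stop("give residues or ligand = TRUE")
    which(!atoms$is_ligand & heavy & atoms$resno %in% residues)
  }
  if (length(idx) == 0) stop("empty region selection")
  ref <- traj$xyz[idx, , 1, drop = TRUE]
  n_frames <- dim(traj$xyz)[3]
  series <- vapply(seq_len(n_frames), function(f) {
    sqrt(mean(rowSums((traj$xyz[idx, , f, drop = TRUE] - ref)^2)))
  }, numeric(1))
  list(series = series, mean = mean(series), sd = stats::sd(series))
}

#' Ordinary least-squares correlation of two per-system statistics
#'
#' @param x,y numeric vectors (>= 3 finite paired values).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Simulation-campaign design summary
#'
#' Validates the bookkeeping of a simulation campaign: total simulated
#' time must equal systems x replicates x length.
#'
#' @param n_systems number of simulated systems.
#' @param n_replicates replicates per system.
#' @param length_ns production length per replicate (ns).
#' @return list with the inputs plus `total_ns` and `total_us`.
#' @export
md_design_summary <- function(n_systems = 9L, n_replicates = 2L,
                              length_ns = 500) {
  stopifnot(n_systems >= 1, n_replicates >= 1, length_ns > 0)
  total_ns <- n_systems * n_replicates * length_ns
  list(n_systems = n_systems, n_replicates = n_replicates,
       length_ns = length_ns, total_ns = total_ns,
       total_us = total_ns / 1000)
}

#' Simulate a multi-system trajectory study with coupled mobilities
#'
#' Generates `n_systems` ligand-bound systems (each in `n_replicates`
#' replicates) whose portal-region amplitude increases across systems and
#' whose ligand amplitude is a linear function of the portal amplitude
#' plus Gaussian scatter sized so that the expected R-squared between
#' per-system mean ligand RMSD and mean portal RMSD equals
#' `coupling_r2`. Each system also carries a nominal inhibition constant
#' increasing with portal amplitude (weaker binders let the portal move
#' more), so the portal-vs-Ki correlation has positive slope by
#' construction.
#'
#' @param n_systems number of systems (default 9).
#' @param coupling_r2 target R-squared in [0, 1].
#' @param config a [generator_config()] (seed).
#' @param n_replicates replicates per system (default 2).
#' @param n_frames frames per replicate.
#' @param n_res chain length.
#' @return A `trajectory_study`: list with `trajectories` (list of
#'   replicate lists), `systems` data frame (`system`, `portal_amp`,
#'   `ligand_amp`, `ki_uM`), and the generation settings.
#' @export
simulate_md_study <- function(n_systems = 9L, coupling_r2 = 0.9,
                              config = generator_config(),
                              n_replicates = 2L, n_frames = 150L,
                              n_res = 133L) {
  if (coupling_r2 < 0 || coupling_r2 > 1)
    stop("coupling_r2 must be in [0, 1]")
  regions <- portal_regions_from_strands()
  portal_amp <- seq(0.3, 1.0, length.out = n_systems)
  slope <- 0.8
  sd_sig <- stats::sd(slope * portal_amp)
  sd_noise <- if (coupling_r2 == 0) {
    10 * sd_sig
  } else {
    sd_sig * sqrt((1 - coupling_r2) / coupling_r2)
  }
  with_seed(stage_seed(config$seed, "trajectory"), {
    ligand_amp <- pmax(0.05,
                       0.2 + slope * portal_amp +
                         stats::rnorm(n_systems, 0, sd_noise))
    # nominal affinities: weaker binders free the portal; 15% assay scatter
    ki_uM <- 15 * portal_amp * exp(stats::rnorm(n_systems, 0, 0.15))
  })
  trajectories <- lapply(seq_len(n_systems), function(i) {
    prof <- apo_flexibility_profile(n_res, scaffold = 0.2,
                                    portal = portal_amp[i],
                                    regions = regions)
    lapply(seq_len(n_replicates), function(r) {
      cfg <- generator_config(
        seed = stage_seed(config$seed, "trajectory") + i * 37L,
        noise_cv = config$noise_cv)
      simulate_trajectory(n_frames, prof, ligand_mobility = ligand_amp[i],
                          config = cfg, system = sprintf("sys%02d", i),
                          replicate = r)
    })
  })
  structure(list(
    trajectories = trajectories,
    systems = data.frame(system = sprintf("sys%02d", seq_len(n_systems)),
                         portal_amp = portal_amp, ligand_amp = ligand_amp,
                         ki_uM = ki_uM),
    coupling_r2 = coupling_r2, n_replicates = n_replicates,
    n_frames = n_frames), class = "trajectory_study")
}

#' Dynamics summary and cross-system correlations of a trajectory study
#'
#' For every replicate: align on the beta-strand scaffold, then compute
#' ligand and portal no-fit RMSD. Per system, replicate means are
#' averaged (SD across replicates reported). Correlations are computed on
#' per-system means (default) and also on per-replicate points.
#'
#' @param study a `trajectory_study` from [simulate_md_study()].
#' @return list with `per_system` (data frame of mean/SD ligand and
#'   portal RMSD plus `ki_uM`), `ligand_vs_portal` and `portal_vs_ki`
#'   correlation results (per-system means), and
#'   `ligand_vs_portal_replicates` (per-replicate points).
#' @export
study_dynamics_summary <- function(study) {
  regions <- portal_regions_from_strands()
  per_rep <- do.call(rbind, lapply(seq_along(study$trajectories), function(i) {
    do.call(rbind, lapply(study$trajectories[[i]], function(tr) {
      al <- align_frames(tr)
      data.frame(system = tr$system, replicate = tr$replicate,
                 ligand_rmsd = region_rmsd(al, ligand = TRUE)$mean,
                 portal_rmsd = region_rmsd(al, residues = regions$portal)$mean,
                 stringsAsFactors = FALSE)
    }))
  }))
  agg <- function(v) {
    m <- tapply(per_rep[[v]], per_rep$system, mean)
    s <- tapply(per_rep[[v]], per_rep$system, stats::sd)
    list(mean = as.numeric(m), sd = as.numeric(s), system = names(m))
  }
  lig <- agg("ligand_rmsd"); por <- agg("portal_rmsd")
  per_system <- data.frame(system = lig$system,
                           ligand_rmsd_mean = lig$mean,
                           ligand_rmsd_sd = lig$sd,
                           portal_rmsd_mean = por$mean,
                           portal_rmsd_sd = por$sd,
                           stringsAsFactors = FALSE)
  per_system$ki_uM <- study$systems$ki_uM[
    match(per_system$system, study$systems$system)]
  list(per_system = per_system,
       per_replicate = per_rep,
       ligand_vs_portal = correlate(per_system$portal_rmsd_mean,
                                    per_system$ligand_rmsd_mean),
       ligand_vs_portal_replicates = correlate(per_rep$portal_rmsd,
                                               per_rep$ligand_rmsd),
       portal_vs_ki = correlate(per_system$ki_uM,
                                per_system$portal_rmsd_mean))
}

#' Write / read trajectories in the plain frame format
#'
#' Format: two header lines (`# n_atoms <n> units angstrom`,
#' `# system <label> replicate <r>`) then one whitespace-delimited row
#' per atom per frame: `frame atom_index residue_number atom_name element
#' is_ligand x y z`.
#'
#' @param traj a `trajectory_set`.
#' @param path file path.
#' @return `read_trajectory_frames` returns a `trajectory_set`.
#' @export
write_trajectory_frames <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_frames <- dim(traj$xyz)[3]
  writeLines(c(sprintf("# n_atoms %d units angstrom", nrow(traj$atoms)),
               sprintf("# system %s replicate %d", traj$system,
                       traj$replicate)), con)
  for (f in seq_len(n_frames)) {
    df <- data.frame(frame = f, atom = traj$atoms$eleno,
                     resno = traj$atoms$resno, name = traj$atoms$elety,
                     element = traj$atoms$element,
                     is_ligand = as.integer(traj$atoms$is_ligand),
                     x = traj$xyz[, 1, f], y = traj$xyz[, 2, f],
                     z = traj$xyz[, 3, f])
    utils::write.table(format(df, digits = 8, scientific = FALSE,
                              trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectory_frames
#' @export
read_trajectory_frames <- function(path) {
  hdr <- readLines(path, n = 2)
  n_atoms <- as.integer(sub("^# n_atoms (\\d+).*", "\\1", hdr[1]))
  sys <- sub("^# system (\\S+) replicate (\\d+)$", "\\1", hdr[2])
  rep_idx <- as.integer(sub("^# system (\\S+) replicate (\\d+)$", "\\2",
                            hdr[2]))
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("frame", "atom", "resno", "name",
                                        "element", "is_ligand",
                                        "x", "y", "z"),
                          stringsAsFactors = FALSE)
  frames <- sort(unique(df$frame))
  first <- df[df$frame == frames[1], ]
  if (nrow(first) != n_atoms)
    stop("frame atom count disagrees with header")
  atoms <- data.frame(eleno = first$atom, elety = first$name,
                      resno = first$resno, element = first$element,
                      is_ligand = as.logical(first$is_ligand),
                      stringsAsFactors = FALSE)
  xyz <- array(NA_real_, dim = c(n_atoms, 3, length(frames)))
  for (i in seq_along(frames)) {
    blk <- df[df$frame == frames[i], ]
    blk <- blk[match(atoms$eleno, blk$atom), ]
    xyz[, , i] <- as.matrix(blk[, c("x", "y", "z")])
  }
  structure(list(atoms = atoms, xyz = xyz, system = sys,
                 replicate = rep_idx), class = "trajectory_set")
}
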