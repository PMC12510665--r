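# Trajectory-derived interaction statistics: per-frame binding energy,
# interface hydrogen bonds and atomic contacts, RMSD / radius of gyration,
# and the 2D free-energy landscape over them.

HBOND_DA_CUTOFF <- 4.5    # donor heavy atom to acceptor heavy atom, Angstrom
HBOND_ANGLE_CUTOFF <- 150 # D-H...A angle at the hydrogen, degrees
HBOND_COVALENT_DH <- 1.2  # H belongs to a donor within this distance
CONTACT_CUTOFF <- 4.5     # 0.45 nm, converted to Angstrom at the boundary

#' Per-frame binding energy (interaction energy)
#'
#' `dE = E_complex - (E_protein + E_RNA)` per frame; more negative means a
#' more favorable protein-RNA interaction.
#'
#' @param energies data.frame with columns `e_complex`, `e_protein`,
#'   `e_rna` (kJ/mol), e.g. from [read_energy_table()].
#' @return List with `series` (kJ/mol per frame), `mean`, `sd`.
#' @export
binding_energy_series <- function(energies) {
  need <- c("e_complex", "e_protein", "e_rna")
  stopifnot(all(need %in% names(energies)))
  d <- energies$e_complex - (energies$e_protein + energies$e_rna)
  list(series = d, mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0)
}

selection_indices <- function(traj, selection) {
  if (is.character(selection)) {
    selection <- match.arg(selection, c("protein", "rna", "all"))
    idx <- switch(selection,
                  all = seq_len(nrow(traj$atoms)),
                  which(traj$atoms$chain_tag == selection))
  } else if (is.logical(selection)) {
    idx <- which(selection)
  } else idx <- as.integer(selection)
  if (length(idx) == 0L) stop("empty atom selection")
  idx
}

frame_hbonds <- function(xyz, atoms) {
  heavy_no <- which(atoms$element %in% c("N", "O"))
  hydro <- which(atoms$element == "H")
  if (length(hydro) == 0L)
    stop("no hydrogens in the topology; hydrogen-bond detection needs a ",
         "pre-protonated structure")
  count <- 0L
  for (d in heavy_no) {
    # covalently bonded hydrogens: same chain, within 1.2 Angstrom
    hd <- hydro[atoms$chain_tag[hydro] == atoms$chain_tag[d]]
    if (!length(hd)) next
    dh <- sqrt(colSums((t(xyz[hd, , drop = FALSE]) - xyz[d, ])^2))
    hd <- hd[dh <= HBOND_COVALENT_DH]
    if (!length(hd)) next
    acc <- heavy_no[atoms$chain_tag[heavy_no] != atoms$chain_tag[d]]
    if (!length(acc)) next
    da <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
    acc <- acc[da <= HBOND_DA_CUTOFF]
    for (a in acc) {
      ok <- FALSE
      for (h in hd) {
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= HBOND_ANGLE_CUTOFF) { ok <- TRUE; break }
      }
      if (ok) count <- count + 1L
    }
  }
  count
}

#' Interface hydrogen-bond counts per frame
#'
#' Donors are protein/RNA N or O heavy atoms carrying at least one hydrogen
#' within 1.2 Angstrom (covalent bond inferred from distance); acceptors are
#' N or O heavy atoms on the other chain. A donor-acceptor pair is counted
#' when the heavy-atom distance is at most 4.5 Angstrom AND some bonded
#' hydrogen gives a D-H...A angle (vertex at the hydrogen) of at least 150
#' degrees.
#'
#' @param traj An `rna_trajectory`.
#' @return Integer vector, one count per frame.
#' @export
detect_hbonds <- function(traj) {
  stopifnot(inherits(traj, "rna_trajectory"))
  vapply(traj$frames, frame_hbonds, 0L, atoms = traj$atoms)
}

#' Interface atomic contacts per frame
#'
#' Counts (protein atom, RNA atom) pairs within `cutoff` (default 4.5
#' Angstrom, i.e. 0.45 nm).
#'
#' @param traj An `rna_trajectory`.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Integer vector, one count per frame.
#' @export
count_contacts <- function(traj, cutoff = CONTACT_CUTOFF) {
  stopifnot(inherits(traj, "rna_trajectory"))
  pi_ <- which(traj$atoms$chain_tag == "protein")
  ri <- which(traj$atoms$chain_tag == "rna")
  vapply(traj$frames, function(xyz) {
    if (!length(pi_) || !length(ri)) return(0L)
    P <- xyz[pi_, , drop = FALSE]
    R <- xyz[ri, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(R^2), `+`) - 2 * P %*% t(R)
    sum(d2 <= cutoff^2 + 1e-9)
  }, 0L)
}

#' RMSD series against the first frame
#'
#' Root-mean-square deviation of the selected atoms from their positions in
#' frame 1. With `superpose = TRUE` (default) each frame is first optimally
#' superposed on the reference (rigid rotation + translation minimizing the
#' RMSD), so rigid-body motion contributes nothing.
#'
#' @param traj An `rna_trajectory`.
#' @param selection `"protein"` (default), `"rna"`, `"all"`, or an
#'   index/logical vector of atoms.
#' @param superpose Remove rigid-body motion before measuring.
#' @return Numeric vector of RMSD values (Angstrom), one per frame; the
#'   first is 0.
#' @export
rmsd_series <- function(traj, selection = "protein", superpose = TRUE) {
  stopifnot(inherits(traj, "rna_trajectory"))
  idx <- selection_indices(traj, selection)
  ref <- as.vector(t(traj$frames[[1L]][idx, , drop = FALSE]))
  vapply(traj$frames, function(xyz) {
    cur <- as.vector(t(xyz[idx, , drop = FALSE]))
    if (superpose) bio3d::rmsd(ref, cur, fit = TRUE)
    else bio3d::rmsd(ref, cur, fit = FALSE)
  }, 0)
}

#' Radius-of-gyration series
#'
#' Mass-weighted (default) spread of the selected atoms about their center
#' of mass: sqrt(sum m_i |x_i - xbar|^2 / sum m_i).
#'
#' @param traj An `rna_trajectory`.
#' @param selection As in [rmsd_series()]; default `"protein"`.
#' @param mass_weighted Use atomic masses (default) or unit weights.
#' @return Numeric vector (Angstrom), one value per frame.
#' @export
rg_series <- function(traj, selection = "protein", mass_weighted = TRUE) {
  stopifnot(inherits(traj, "rna_trajectory"))
  idx <- selection_indices(traj, selection)
  w <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  vapply(traj$frames, function(xyz) {
    x <- xyz[idx, , drop = FALSE]
    ctr <- colSums(x * w) / sum(w)
    sqrt(sum(w * rowSums((x - matrix(ctr, nrow(x), 3L, byrow = TRUE))^2)) /
           sum(w))
  }, 0)
}

gauss_smooth_1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
    out[i] <- sum(v[lo:hi] * kk) / sum(kk)
  }
  out
}

gauss_smooth_2d <- function(M, sigma) {
  if (sigma <= 0) return(M)
  for (j in seq_len(ncol(M))) M[, j] <- gauss_smooth_1d(M[, j], sigma)
  for (i in seq_len(nrow(M))) M[i, ] <- gauss_smooth_1d(M[i, ], sigma)
  M
}

axis_edges <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-12) return(c(lo - 0.5, hi + 0.5))  # single-bin axis
  seq(lo, hi, length.out = bins + 1L)
}

#' Free-energy landscape over RMSD x radius of gyration
#'
#' Builds a 2D histogram of the two order-parameter series over their
#' observed ranges, normalizes it to a probability `P`, optionally smooths
#' with a Gaussian filter (`sigma_bins` in bin units; 0 disables smoothing),
#' converts occupied bins with `F = -kT ln P` and shifts the minimum to
#' zero. Unoccupied bins stay masked (`NA`) rather than infinite, so the
#' basin depth — the largest finite `F`, i.e. the barrier between the most
#' and least stable sampled states — is well defined.
#'
#' @param rmsd,rg Equal-length numeric series (Angstrom).
#' @param bins Bins per axis (default 50).
#' @param sigma_bins Gaussian smoothing width in bin units (default 1).
#' @param temperature Temperature in Kelvin (default 310); kT uses
#'   k = 0.0019872 kcal/(mol K).
#' @return List of class `fel_grid`: `rmsd_edges`, `rg_edges`, `P`
#'   (sums to 1), `F` (kcal/mol, min 0, NA where unoccupied), `kT`,
#'   `depth`, `argmin` (bin indices of the free-energy minimum).
#' @export
free_energy_landscape <- function(rmsd, rg, bins = 50L, sigma_bins = 1.0,
                                  temperature = 310) {
  stopifnot(length(rmsd) == length(rg), length(rmsd) >= 1L)
  kT <- BOLTZMANN_KCAL * temperature
  re <- axis_edges(rmsd, bins)
  ge <- axis_edges(rg, bins)
  ri <- pmin(pmax(findInterval(rmsd, re, rightmost.closed = TRUE), 1L),
             length(re) - 1L)
  gi <- pmin(pmax(findInterval(rg, ge, rightmost.closed = TRUE), 1L),
             length(ge) - 1L)
  counts <- matrix(0, length(re) - 1L, length(ge) - 1L)
  for (k in seq_along(ri))
    counts[ri[k], gi[k]] <- counts[ri[k], gi[k]] + 1
  P <- counts / sum(counts)
  if (sigma_bins > 0 && length(P) > 1L) {
    P <- gauss_smooth_2d(P, sigma_bins)
    P <- P / sum(P)
  }
  F <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- P > 0
  F[occ] <- -kT * log(P[occ])
  F <- F - min(F, na.rm = TRUE)
  depth <- max(F, na.rm = TRUE)
  amin <- which(F == 0, arr.ind = TRUE)[1L, ]
  structure(list(rmsd_edges = re, rg_edges = ge, P = P, F = F, kT = kT,
                 depth = depth, argmin = unname(amin)),
            class = "fel_grid")
}

#' Write per-frame trajectory metrics as TSV
#'
#' Convenience wrapper combining [detect_hbonds()], [count_contacts()],
#' [rmsd_series()], [rg_series()] and (optionally) the binding-energy
#' series into one table.
#'
#' @param traj An `rna_trajectory`.
#' @param energies Optional energy table with one row per frame.
#' @param selection Atom selection for RMSD/RG.
#' @param path Optional output TSV path.
#' @return data.frame of per-frame metrics (invisibly writes `path` if set).
#' @export
trajectory_metrics <- function(traj, energies = NULL, selection = "protein",
                               path = NULL) {
  df <- data.frame(
    frame = seq_len(traj$frame_count),
    hbonds = detect_hbonds(traj),
    contacts = count_contacts(traj),
    rmsd = rmsd_series(traj, selection),
    rg = rg_series(traj, selection))
  if (!is.null(energies)) {
    if (nrow(energies) != traj$frame_count)
      stop("energy table rows (", nrow(energies),
           ") do not match frame count (", traj$frame_count, ")")
    df$delta_e <- binding_energy_series(energies)$series
  }
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
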