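#' Select the k lowest-energy poses
#'
#' Ties are broken lexicographically on (position, orientation) for
#' determinism. If fewer than k poses are available all are returned with a
#' warning.
#'
#' @param poses data.frame of pose records (`x`, `y`, `z`, `qw`..`qz`,
#'   `energy`).
#' @param k number to keep (default 1000).
#' @return data.frame of the k lowest-energy rows.
#' @export
select_lowest <- function(poses, k = 1000) {
  if (nrow(poses) < k) {
    warning("only ", nrow(poses), " poses available (requested ", k, ")")
    k <- nrow(poses)
  }
  ord <- order(poses$energy, poses$x, poses$y, poses$z,
               poses$qw, poses$qx, poses$qy, poses$qz)
  out <- poses[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

pose_list <- function(row) {
  list(position = c(row$x, row$y, row$z),
       quat = c(row$qw, row$qx, row$qy, row$qz))
}

#' Ligand RMSD between two poses of the test molecule
#'
#' RMSD over all test-molecule atoms between the two placements, in the
#' frame of the (already superposed) central copy.
#'
#' @param a,b single-row pose records.
#' @param mol test `rigid_molecule`.
#' @return RMSD, Angstrom.
#' @export
ligand_rmsd <- function(a, b, mol) {
  pa <- pose_list(a); pb <- pose_list(b)
  xa <- pose_coords(mol, pa$position, pa$quat)
  xb <- pose_coords(mol, pb$position, pb$quat)
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Greedy energy-ordered clustering of poses by ligand RMSD
#'
#' The lowest-energy unassigned pose seeds a cluster and absorbs every
#' unassigned pose within the RMSD cutoff of it; repeat until all poses are
#' assigned. Each cluster's representative is its seed (lowest-energy
#' member); clusters of `large_size` or more members are flagged large.
#'
#' @param poses data.frame of pose records.
#' @param mol test `rigid_molecule`.
#' @param cutoff ligand-RMSD cutoff, Angstrom (default 10).
#' @param large_size size threshold for the `large` flag (default 20).
#' @return list of class `pose_clusters`: `clusters` (list of row-index
#'   vectors, representative first), `summary` (data.frame with size,
#'   representative energy, large flag), `assignment`.
#' @export
cluster_poses <- function(poses, mol, cutoff = 10, large_size = 20) {
  n <- nrow(poses)
  ord <- order(poses$energy, poses$x, poses$y, poses$z,
               poses$qw, poses$qx, poses$qy, poses$qz)
  assigned <- rep(NA_integer_, n)
  clusters <- list()
  # precompute transformed coordinate sets once
  coords <- lapply(seq_len(n), function(i) {
    p <- pose_list(poses[i, ])
    pose_coords(mol, p$position, p$quat)
  })
  natom <- nrow(mol$atoms)
  for (i in ord) {
    if (!is.na(assigned[i])) next
    cid <- length(clusters) + 1L
    members <- i
    assigned[i] <- cid
    for (j in ord) {
      if (!is.na(assigned[j])) next
      rmsd <- sqrt(sum((coords[[i]] - coords[[j]])^2) / natom)
      if (rmsd <= cutoff) {
        assigned[j] <- cid
        members <- c(members, j)
      }
    }
    clusters[[cid]] <- members
  }
  sizes <- lengths(clusters)
  summary <- data.frame(
    cluster = seq_along(clusters), size = sizes,
    representative = vapply(clusters, `[`, numeric(1), 1),
    rep_energy = vapply(clusters, function(m) poses$energy[m[1]], numeric(1)),
    large = sizes >= large_size
  )
  structure(list(clusters = clusters, summary = summary,
                 assignment = assigned, cutoff = cutoff),
            class = "pose_clusters")
}

#' Mean per-residue energy profile over low-energy poses
#'
#' Two-way residue decomposition of each pose's pair energy (test split by
#' residue vs whole central, and central split by residue vs whole test),
#' averaged first over poses and then over the two decomposition
#' directions.
#'
#' @param poses data.frame of clash-free pose records (test-molecule pose
#'   relative to a central copy at the origin, identity orientation).
#' @param central,test `rigid_molecule`s with equal residue counts.
#' @param params an [energy_params()].
#' @return numeric vector of mean per-residue contributions (kcal/mol),
#'   named by the central copy's residues.
#' @export
residue_profile <- function(poses, central, test = central,
                            params = energy_params()) {
  nres <- nrow(central$residues)
  if (nrow(test$residues) != nres) {
    stop("central and test must have the same residue count")
  }
  pose0 <- list(position = c(0, 0, 0), quat = identity_quat())
  acc_t <- numeric(nres); acc_c <- numeric(nres)
  for (i in seq_len(nrow(poses))) {
    p <- pose_list(poses[i, ])
    acc_t <- acc_t + residue_decompose(central, pose0, test, p, params,
                                       decompose = "B")
    acc_c <- acc_c + residue_decompose(central, pose0, test, p, params,
                                       decompose = "A")
  }
  prof <- (acc_t + acc_c) / (2 * nrow(poses))
  names(prof) <- paste0(central$residues$residue_name,
                        central$residues$residue_index)
  prof
}

#' Difference between two residue profiles with 3-SD flagging
#'
#' Positions where `|delta|` exceeds mean(delta) +/- 3*SD(delta) are
#' flagged. Positions aligned to a gap in either profile (NA) contribute a
#' delta computed against 0.
#'
#' @param profile_a,profile_b numeric vectors on common positions (NA for a
#'   gap; its contribution is taken as 0).
#' @return data.frame with `position`, `delta`, `flag_low`, `flag_high`.
#' @export
profile_difference <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) {
    stop("profiles have different lengths; align them first")
  }
  a <- ifelse(is.na(profile_a), 0, profile_a)
  b <- ifelse(is.na(profile_b), 0, profile_b)
  delta <- a - b
  m <- mean(delta); s <- stats::sd(delta)
  data.frame(position = seq_along(delta), delta = delta,
             flag_low = delta < m - 3 * s, flag_high = delta > m + 3 * s)
}

sidechain_centroid <- function(mol, residue_index, coords) {
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")
  in_res <- mol$atoms$residue_index == residue_index
  if (!any(in_res)) stop("residue index ", residue_index, " not in molecule")
  side <- in_res & !(toupper(mol$atoms$name) %in% backbone)
  if (!any(side)) side <- in_res
  colMeans(coords[side, , drop = FALSE])
}

#' Distribution of site-site distances between the two pose partners
#'
#' Distance between the named residue's sidechain centroid in the central
#' copy (origin, identity orientation) and in the test molecule at each
#' pose, optionally weighted by the (normalised) Mayer factor
#' `exp(-beta U) - 1`.
#'
#' @param poses data.frame of pose records.
#' @param central,test `rigid_molecule`s.
#' @param residue_index residue to track (must exist in both molecules).
#' @param weighting `"none"` or `"mayer"`.
#' @param temperature K (for the Mayer weight).
#' @param params an [energy_params()] (for kB).
#' @param breaks histogram breaks (Angstrom), or a bin width via `dr`.
#' @param dr bin width when `breaks` is NULL.
#' @return data.frame with `r` (bin centres) and `density` (weights
#'   normalised to sum 1).
#' @export
site_distance_distribution <- function(poses, central, test = central,
                                       residue_index = 1,
                                       weighting = c("none", "mayer"),
                                       temperature = 298,
                                       params = energy_params(),
                                       breaks = NULL, dr = 1) {
  weighting <- match.arg(weighting)
  c0 <- sidechain_centroid(central, residue_index, molecule_coords(central))
  d <- vapply(seq_len(nrow(poses)), function(i) {
    p <- pose_list(poses[i, ])
    ct <- sidechain_centroid(test, residue_index,
                             pose_coords(test, p$position, p$quat))
    sqrt(sum((ct - c0)^2))
  }, numeric(1))
  w <- if (weighting == "mayer") {
    beta <- 1 / (params$kB * temperature)
    abs(exp(-beta * poses$energy) - 1)
  } else rep(1, length(d))
  w <- w / sum(w)
  if (is.null(breaks)) breaks <- seq(0, max(d) + dr, by = dr)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  dens <- vapply(seq_len(length(breaks) - 1), function(b) sum(w[bin == b]),
                 numeric(1))
  data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2, density = dens)
}
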