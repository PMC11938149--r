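# Trajectory analysis: contact-frequency maps, hydrogen bonds,
# receptor-aligned ligand RMSD, hierarchical clustering and
# representative-frame selection.

#' Read a trajectory
#'
#' Frames come from the MODEL blocks of a multi-model PDB, or from a
#' directory of single-model PDB files taken in lexicographic name
#' order.  All frames must share the topology of the first.
#'
#' @param source Path to a multi-model PDB file or to a directory of
#'   PDB files.
#' @param dt Optional frame spacing metadata (e.g. ps per frame).
#' @return A `trajectory`: list with `topology` (atom table), `frames`
#'   (list of n x 3 matrices), `dt`.
#' @export
read_trajectory <- function(source, dt = NA_real_) {
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) nd_stop("no .pdb files in directory ", source)
    s0 <- read_structure(files[1])
    frames <- list(s0$xyz[[1]])
    for (k in seq_along(files)[-1]) {
      sk <- read_structure(files[k])
      if (nrow(sk$atoms) != nrow(s0$atoms))
        nd_stop(sprintf("atom count mismatch at frame %d (%s): %d vs %d",
                        k, basename(files[k]), nrow(sk$atoms), nrow(s0$atoms)))
      frames[[k]] <- sk$xyz[[1]]
    }
    topo <- s0$atoms
  } else {
    s <- read_structure(source)
    topo <- s$atoms
    frames <- s$xyz
  }
  structure(list(topology = topo, frames = frames, dt = dt),
            class = "trajectory")
}

#' Build a trajectory from a structure's conformers
#' @param s A `structure3d`.
#' @param dt Optional frame spacing metadata.
#' @return A `trajectory`.
#' @export
as_trajectory <- function(s, dt = NA_real_) {
  stopifnot(inherits(s, "structure3d"))
  structure(list(topology = s$atoms, frames = s$xyz, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology)))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

resolve_window <- function(traj, window) {
  nf <- n_frames(traj)
  if (is.null(window)) return(seq_len(nf))
  window <- as.integer(window)
  if (!length(window)) nd_stop("empty frame window")
  if (length(window) == 2L && window[2] >= window[1])
    window <- seq.int(window[1], window[2])
  if (any(window < 1L | window > nf))
    nd_stop("window frames out of range 1..", nf)
  window
}

# trajectory frame as a structure3d sharing the topology
frame_structure <- function(traj, k) {
  new_structure3d(traj$topology, list(traj$frames[[k]]))
}

#' Inter-chain residue contact frequencies over a frame window
#'
#' For each residue pair across the two partners, the percentage of
#' window frames in which any interatomic distance (hydrogens included
#' when present) is within `cutoff`.  A frequency of 100 means the
#' contact is present in every analyzed frame.
#'
#' @param traj A `trajectory`.
#' @param chainsA,chainsB Partner chain ids.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @param window Frame window: `NULL` for all frames, a length-2
#'   `c(first, last)` range, or an explicit index vector.
#' @param include_h Include hydrogens (default `TRUE`).
#' @return A `contact_map`: data frame `resA`, `resB`, `frequency`
#'   (percent, only pairs ever in contact), with attributes `window`
#'   and `cutoff`.
#' @export
contact_frequency <- function(traj, chainsA, chainsB, cutoff = 5.0,
                              window = NULL, include_h = TRUE) {
  win <- resolve_window(traj, window)
  s0 <- frame_structure(traj, win[1])
  check_chain_groups(s0, chainsA, chainsB)
  if (include_h && !any(traj$topology$hydrogen)) include_h <- FALSE
  ia <- group_atoms(s0, chainsA, include_h = include_h)
  ib <- group_atoms(s0, chainsB, include_h = include_h)
  counts <- list()
  for (k in win) {
    sk <- frame_structure(traj, k)
    pairs <- residue_pair_mindist(sk, ia, ib, max_dist = cutoff)
    if (nrow(pairs)) {
      key <- paste(pairs$resA, pairs$resB)
      for (ky in key) counts[[ky]] <- (counts[[ky]] %||% 0L) + 1L
    }
  }
  if (!length(counts)) {
    out <- data.frame(resA = integer(0), resB = integer(0), frequency = numeric(0))
  } else {
    ks <- strsplit(names(counts), " ")
    out <- data.frame(resA = as.integer(vapply(ks, `[[`, "", 1)),
                      resB = as.integer(vapply(ks, `[[`, "", 2)),
                      frequency = 100 * unlist(counts) / length(win))
    out <- out[order(out$resA, out$resB), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "window") <- win
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_map", "data.frame")
  out
}

# Donor-hydrogen pairs: H within `bond_max` of an N/O of the same chain.
donor_h_pairs <- function(atoms, xyz, bond_max = 1.2) {
  h <- which(atoms$hydrogen)
  d <- which(atoms$element %in% c("N", "O") & !atoms$het)
  if (!length(h) || !length(d))
    return(data.frame(donor = integer(0), hydrogen = integer(0)))
  d2 <- cross_dist2(xyz[h, , drop = FALSE], xyz[d, , drop = FALSE])
  nearest <- max.col(-d2)
  dist <- sqrt(d2[cbind(seq_along(h), nearest)])
  ok <- dist <= bond_max & atoms$chain[d[nearest]] == atoms$chain[h]
  data.frame(donor = d[nearest[ok]], hydrogen = h[ok])
}

#' Inter-chain hydrogen bonds over a frame window
#'
#' A hydrogen bond is detected in a frame when the donor-acceptor
#' distance is within `d_cut` and the deviation of the D-H...A angle
#' from linearity is within `ang_cut`.  Donors are N/O atoms with a
#' covalently bonded hydrogen (H within 1.2 A when connectivity records
#' are absent); acceptors are N/O atoms of the partner chain group.
#'
#' @param traj A `trajectory`; must contain hydrogens.
#' @param chainsA,chainsB Partner chain ids (both directions are
#'   scanned).
#' @param d_cut Donor-acceptor distance cutoff in Angstrom (default 3).
#' @param ang_cut Deviation-from-linearity cutoff in degrees
#'   (default 20).
#' @param window Frame window (see [contact_frequency()]).
#' @return Data frame with one row per (donor, hydrogen, acceptor)
#'   triple ever detected: atom descriptors, `frequency` (percent of
#'   window frames), `mean_dist` (A) and `mean_dev` (degrees) over the
#'   frames where the bond is present.
#' @export
hbonds <- function(traj, chainsA, chainsB, d_cut = 3.0, ang_cut = 20,
                   window = NULL) {
  if (!any(traj$topology$hydrogen))
    nd_stop("trajectory has no hydrogens; protonate the structures first")
  win <- resolve_window(traj, window)
  s0 <- frame_structure(traj, win[1])
  grp <- check_chain_groups(s0, chainsA, chainsB)
  atoms <- traj$topology
  dh <- donor_h_pairs(atoms, traj$frames[[win[1]]])
  acc <- which(atoms$element %in% c("N", "O") & !atoms$het)
  # candidate triples: donor on one side, acceptor on the other
  side <- function(i) ifelse(atoms$chain[i] %in% grp$A, "A",
                             ifelse(atoms$chain[i] %in% grp$B, "B", NA))
  cand <- list()
  for (r in seq_len(nrow(dh))) {
    sd_ <- side(dh$donor[r])
    if (is.na(sd_)) next
    opp <- acc[side(acc) == (if (sd_ == "A") "B" else "A")]
    opp <- opp[!is.na(opp)]
    if (length(opp))
      cand[[length(cand) + 1L]] <- data.frame(donor = dh$donor[r],
                                              hydrogen = dh$hydrogen[r],
                                              acceptor = opp)
  }
  if (!length(cand)) return(empty_hbond_table())
  cand <- do.call(rbind, cand)
  stats_ <- vector("list", nrow(cand))
  nhit <- integer(nrow(cand)); sdist <- sdev <- numeric(nrow(cand))
  for (k in win) {
    m <- traj$frames[[k]]
    D <- m[cand$donor, , drop = FALSE]
    H <- m[cand$hydrogen, , drop = FALSE]
    A <- m[cand$acceptor, , drop = FALSE]
    da <- sqrt(rowSums((D - A)^2))
    v1 <- D - H; v2 <- A - H
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    dev <- 180 - acos(cosang) * 180 / pi
    hit <- da <= d_cut & dev <= ang_cut
    nhit <- nhit + hit
    sdist <- sdist + ifelse(hit, da, 0)
    sdev <- sdev + ifelse(hit, dev, 0)
  }
  keep <- nhit > 0L
  if (!any(keep)) return(empty_hbond_table())
  cand <- cand[keep, , drop = FALSE]
  lab <- function(i) sprintf("%s:%d:%s", atoms$chain[i], atoms$resno[i], atoms$name[i])
  out <- data.frame(donor = lab(cand$donor), hydrogen = lab(cand$hydrogen),
                    acceptor = lab(cand$acceptor),
                    donor_res = atoms$resno[cand$donor],
                    acceptor_res = atoms$resno[cand$acceptor],
                    frequency = 100 * nhit[keep] / length(win),
                    mean_dist = sdist[keep] / nhit[keep],
                    mean_dev = sdev[keep] / nhit[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_hbond_table <- function() {
  data.frame(donor = character(0), hydrogen = character(0),
             acceptor = character(0), donor_res = integer(0),
             acceptor_res = integer(0), frequency = numeric(0),
             mean_dist = numeric(0), mean_dev = numeric(0))
}

sel_idx <- function(traj, expr) {
  select_atoms(new_structure3d(traj$topology, traj$frames[1]), expr)$idx
}

#' Receptor-aligned ligand RMSD series
#'
#' Each frame is superposed onto the reference frame using the receptor
#' selection; the RMSD is then computed over the ligand selection
#' (minus excluded residue ranges, e.g. disordered tails) without
#' further fitting.
#'
#' @param traj A `trajectory`.
#' @param receptor_sel,ligand_sel Selection expressions (see
#'   [select_atoms()]), e.g. `"chain A and backbone"`.
#' @param exclude Residue numbers (vector or range string like
#'   `"1-10,94-105"`) removed from the ligand selection.
#' @param reference Reference frame index (default 1).
#' @param window Frame window over which the mean is reported.
#' @return List with `series` (per-frame RMSD, Angstrom), `mean`
#'   (over the window), `reference`, `window`.
#' @export
ligand_rmsd_series <- function(traj, receptor_sel, ligand_sel,
                               exclude = NULL, reference = 1L,
                               window = NULL) {
  ri <- sel_idx(traj, receptor_sel)
  li <- sel_idx(traj, ligand_sel)
  if (!length(ri)) nd_stop("empty receptor selection")
  if (!is.null(exclude)) {
    ex <- parse_ranges(exclude)
    li <- li[!(traj$topology$resno[li] %in% ex)]
  }
  if (!length(li)) nd_stop("ligand selection empty after exclusions")
  win <- resolve_window(traj, window)
  refR <- traj$frames[[reference]][ri, , drop = FALSE]
  refL <- traj$frames[[reference]][li, , drop = FALSE]
  series <- vapply(seq_len(n_frames(traj)), function(k) {
    sp <- superpose(traj$frames[[k]][ri, , drop = FALSE], refR)
    L <- apply_superposition(traj$frames[[k]][li, , drop = FALSE], sp)
    sqrt(mean(rowSums((L - refL)^2)))
  }, numeric(1))
  list(series = series, mean = mean(series[win]),
       reference = reference, window = win)
}

#' Hierarchical clustering of trajectory frames
#'
#' Frames are optionally aligned to the reference frame on `align_sel`,
#' a pairwise RMSD matrix is computed on `selection` (no per-pair
#' fitting), and agglomerative clustering (default average linkage) is
#' cut at `threshold`.  The representative is the frame with minimum
#' RMSD to the coordinate-wise mean structure of the most populated
#' cluster; ties (in cluster population and in RMSD) resolve to the
#' lowest frame index.
#'
#' @param traj A `trajectory`.
#' @param selection Selection expression for the RMSD coordinates.
#' @param linkage `hclust` method (default `"average"`).
#' @param threshold Cut height in Angstrom (> 0).
#' @param align_sel Optional selection used to superpose every frame
#'   onto the reference frame before the RMSD matrix is built.
#' @param reference Reference frame for alignment (default 1).
#' @return A `cluster_result`: list with `labels` (per frame),
#'   `sizes`, `representative` (frame index), `linkage`, `threshold`,
#'   `rmsd_matrix`.
#' @export
cluster_frames <- function(traj, selection = "all", linkage = "average",
                           threshold, align_sel = NULL, reference = 1L) {
  if (missing(threshold) || !is.numeric(threshold) || threshold <= 0)
    nd_stop("threshold must be > 0")
  nf <- n_frames(traj)
  if (nf < 2L) nd_stop("need >= 2 frames to cluster")
  si <- sel_idx(traj, selection)
  if (!length(si)) nd_stop("empty selection")
  coords <- lapply(seq_len(nf), function(k) traj$frames[[k]][si, , drop = FALSE])
  if (!is.null(align_sel)) {
    ai <- sel_idx(traj, align_sel)
    refA <- traj$frames[[reference]][ai, , drop = FALSE]
    coords <- lapply(seq_len(nf), function(k) {
      sp <- superpose(traj$frames[[k]][ai, , drop = FALSE], refA)
      apply_superposition(coords[[k]], sp)
    })
  }
  flat <- do.call(rbind, lapply(coords, as.vector))
  dm <- as.matrix(stats::dist(flat)) / sqrt(length(si))
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  labels <- stats::cutree(hc, h = threshold)
  sizes <- table(labels)
  top <- as.integer(names(sizes)[which.max(sizes)])  # which.max: first max => lowest label;
  members <- which(labels == top)
  avg <- Reduce(`+`, coords[members]) / length(members)
  dev <- vapply(members, function(k)
    sqrt(mean(rowSums((coords[[k]] - avg)^2))), numeric(1))
  rep_frame <- unname(members[which.min(dev)])
  structure(list(labels = labels, sizes = as.integer(sizes),
                 representative = rep_frame, linkage = linkage,
                 threshold = threshold, rmsd_matrix = dm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), sizes %s; representative frame %d\n",
              length(x$sizes), paste(x$sizes, collapse = "/"), x$representative))
  invisible(x)
}
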