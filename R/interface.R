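# Interface extraction, contact classification, solvent accessible and
# buried surface areas.

# Bondi-style van der Waals radii (Angstrom); unknown elements fall
# back to `default_radius`.
VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52,
               S = 1.80, P = 1.80, F = 1.47, CL = 1.75, BR = 1.85,
               SE = 1.90, FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.74,
               "NA" = 2.27, K = 2.75)

vdw_radius <- function(element, default_radius = 1.8) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- default_radius
  unname(r)
}

POLAR_ELEMENTS <- c("N", "O", "S")

# For each structure atom, the element class used by the polarity rule;
# hydrogens inherit the class of the nearest heavy atom (their bonded
# partner).
polarity_class <- function(atoms, xyz) {
  elem <- atoms$element
  hyd <- atoms$hydrogen
  cls <- elem %in% POLAR_ELEMENTS
  if (any(hyd)) {
    heavy_idx <- which(!hyd)
    if (length(heavy_idx)) {
      d2 <- cross_dist2(xyz[hyd, , drop = FALSE], xyz[heavy_idx, , drop = FALSE])
      nearest <- heavy_idx[max.col(-d2)]
      cls[hyd] <- elem[nearest] %in% POLAR_ELEMENTS
    }
  }
  cls
}

chain_split <- function(chains) trimws(strsplit(paste(chains, collapse = ","), ",")[[1]])

# Indices of the atoms belonging to a chain group, optionally without
# hydrogens / hetero atoms.
group_atoms <- function(s, chains, include_h = TRUE, include_het = FALSE) {
  a <- s$atoms
  sel <- a$chain %in% chain_split(chains)
  if (!include_h) sel <- sel & !a$hydrogen
  if (!include_het) sel <- sel & !a$het
  which(sel)
}

residue_key <- function(atoms, idx) paste0(atoms$chain[idx], ":", atoms$resno[idx])

check_chain_groups <- function(s, chainsA, chainsB) {
  ca <- chain_split(chainsA); cb <- chain_split(chainsB)
  if (length(intersect(ca, cb)))
    nd_stop("chain groups overlap: ", paste(intersect(ca, cb), collapse = ","))
  present <- unique(s$atoms$chain)
  miss <- setdiff(c(ca, cb), present)
  if (length(miss)) nd_stop("chain(s) not in structure: ", paste(miss, collapse = ","))
  list(A = ca, B = cb)
}

# Any-atom minimum distances per residue pair across two atom groups.
# Returns data frame resA, resB, mindist.
residue_pair_mindist <- function(s, ia, ib, conformer = 1L, max_dist = Inf) {
  xyz <- s$xyz[[conformer]]
  if (!length(ia) || !length(ib))
    return(data.frame(resA = integer(0), resB = integer(0), mindist = numeric(0)))
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  ra <- s$atoms$resno[ia]; rb <- s$atoms$resno[ib]
  fa <- factor(ra); fb <- factor(rb)
  # residue-pair minimum via per-block min
  dmin <- tapply(sqrt(as.vector(d2)),
                 list(rep(fa, times = length(ib)), rep(fb, each = length(ia))),
                 min)
  idx <- which(dmin <= max_dist, arr.ind = TRUE)
  data.frame(resA = as.integer(rownames(dmin)[idx[, 1]]),
             resB = as.integer(colnames(dmin)[idx[, 2]]),
             mindist = dmin[idx])
}

#' Interface residues of a two-partner complex
#'
#' A residue of partner A belongs to the predicted interface iff any of
#' its atoms lies within `cutoff` of any atom of partner B (and
#' symmetrically for B).  Hydrogens are included by default; if the
#' structure carries no hydrogens the computation falls back to heavy
#' atoms with a prominent warning (the cutoff is not rescaled).
#'
#' @param s A `structure3d`.
#' @param chainsA,chainsB Chain id(s) of the two partners (vector or
#'   comma-separated string); must be disjoint.
#' @param cutoff Any-atom distance cutoff in Angstrom (default 5).
#' @param include_h Include hydrogens (default `TRUE`).
#' @param conformer Conformer index (default 1).
#' @param include_het Include HETATM records (default `FALSE`).
#' @return An `interface_set`: list with `A`, `B` (sorted residue-number
#'   vectors), `chainsA`, `chainsB`, `cutoff`, `hydrogens_used`.
#' @export
interface_residues <- function(s, chainsA, chainsB, cutoff = 5.0,
                               include_h = TRUE, conformer = 1L,
                               include_het = FALSE) {
  check_chain_groups(s, chainsA, chainsB)
  hydrogens_used <- include_h
  if (include_h && !any(s$atoms$hydrogen)) {
    nd_warn("structure has no hydrogens; interface computed on heavy atoms ",
            "with the same ", cutoff, " A cutoff")
    hydrogens_used <- FALSE
  }
  ia <- group_atoms(s, chainsA, include_h = hydrogens_used, include_het = include_het)
  ib <- group_atoms(s, chainsB, include_h = hydrogens_used, include_het = include_het)
  pairs <- residue_pair_mindist(s, ia, ib, conformer, max_dist = cutoff)
  structure(list(A = sort(unique(pairs$resA)), B = sort(unique(pairs$resB)),
                 chainsA = chain_split(chainsA), chainsB = chain_split(chainsB),
                 cutoff = cutoff, hydrogens_used = hydrogens_used),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf("<interface_set> %s | %s : %d + %d residues (cutoff %.1f A%s)\n",
              paste(x$chainsA, collapse = ","), paste(x$chainsB, collapse = ","),
              length(x$A), length(x$B), x$cutoff,
              if (x$hydrogens_used) ", with H" else ", heavy atoms"))
  invisible(x)
}

#' Residue-residue contact pairs with polarity
#'
#' One record per residue pair whose minimum interatomic distance is
#' within `cutoff`.  A pair is polar when at least one contacting atom
#' pair within the cutoff has polar atoms (N/O/S, hydrogens inheriting
#' their bonded heavy atom's class) on both sides; otherwise nonpolar.
#'
#' @inheritParams interface_residues
#' @return Data frame `resA`, `resB`, `mindist`, `polarity`.
#' @export
contact_pairs <- function(s, chainsA, chainsB, cutoff = 5.0,
                          include_h = TRUE, conformer = 1L,
                          include_het = FALSE) {
  check_chain_groups(s, chainsA, chainsB)
  if (include_h && !any(s$atoms$hydrogen)) include_h <- FALSE
  ia <- group_atoms(s, chainsA, include_h = include_h, include_het = include_het)
  ib <- group_atoms(s, chainsB, include_h = include_h, include_het = include_het)
  xyz <- s$xyz[[conformer]]
  out <- residue_pair_mindist(s, ia, ib, conformer, max_dist = cutoff)
  if (!nrow(out)) return(cbind(out, polarity = character(0)))
  polA <- polarity_class(s$atoms[ia, , drop = FALSE], xyz[ia, , drop = FALSE])
  polB <- polarity_class(s$atoms[ib, , drop = FALSE], xyz[ib, , drop = FALSE])
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  within <- d2 <= cutoff^2
  polmat <- outer(polA, polB, "&") & within
  ra <- s$atoms$resno[ia]; rb <- s$atoms$resno[ib]
  out$polarity <- vapply(seq_len(nrow(out)), function(k) {
    sel <- polmat[ra == out$resA[k], rb == out$resB[k], drop = FALSE]
    if (any(sel)) "polar" else "nonpolar"
  }, character(1))
  out
}

# Deterministic quasi-uniform unit-sphere points (golden-section
# spiral); fixed given n, no RNG involved.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface using a
#' deterministic quasi-uniform point set on each expanded atom sphere.
#' Hydrogens and hetero atoms are excluded by default, matching common
#' practice for heavy-atom SASA.
#'
#' @param s A `structure3d` or an `atom_set`.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere quadrature points per atom (default 960).
#' @param include_h Include hydrogens (default `FALSE`).
#' @param include_het Include hetero atoms (default `FALSE`).
#' @param conformer Conformer index.
#' @param default_radius Radius for unknown elements (default 1.8).
#' @return A `sasa_result`: list with `atom_area` (per selected atom,
#'   Angstrom^2), `residue_area` (named by `chain:resno`), `total`,
#'   `probe`, `n_points`, and `atoms` (the atom table rows used).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, include_h = FALSE,
                 include_het = FALSE, conformer = 1L, default_radius = 1.8) {
  if (inherits(s, "atom_set")) {
    idx <- s$idx; conformer <- s$conformer; s <- s$structure
  } else {
    stopifnot(inherits(s, "structure3d"))
    a <- s$atoms
    sel <- rep(TRUE, nrow(a))
    if (!include_h) sel <- sel & !a$hydrogen
    if (!include_het) sel <- sel & !a$het
    idx <- which(sel)
  }
  if (!length(idx)) nd_stop("no atoms selected for SASA")
  atoms <- s$atoms[idx, , drop = FALSE]
  xyz <- s$xyz[[conformer]][idx, , drop = FALSE]
  radii <- vdw_radius(atoms$element, default_radius)
  ext <- radii + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  # neighbor lists from squared distances
  d2 <- cross_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (ext[i] + ext)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    p <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > ext[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * ext[i]^2 * sum(acc) / n_points
  }
  rk <- residue_key(s$atoms, idx)
  res_area <- tapply(area, rk, sum)
  structure(list(atom_area = area, residue_area = res_area,
                 total = sum(area), probe = probe, n_points = n_points,
                 atoms = atoms),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (probe %.2f, %d pts)\n",
              x$total, length(x$atom_area), x$probe, x$n_points))
  invisible(x)
}

# Structure restricted to a chain group, coordinates unchanged.
subset_chains <- function(s, chains) {
  keep <- s$atoms$chain %in% chain_split(chains)
  new_structure3d(s$atoms[keep, , drop = FALSE],
                  lapply(s$xyz, function(m) m[keep, , drop = FALSE]),
                  offsets = s$offsets)
}

#' Buried surface area of a complex
#'
#' SASA(A alone) + SASA(B alone) - SASA(complex), with the partners
#' extracted in place (no coordinate change).
#'
#' @inheritParams interface_residues
#' @param ... Passed to [sasa()] (probe, n_points, ...).
#' @return Buried area in Angstrom^2 (>= 0 up to quadrature error).
#' @export
buried_area <- function(s, chainsA, chainsB, conformer = 1L, ...) {
  check_chain_groups(s, chainsA, chainsB)
  sa <- sasa(subset_chains(s, chainsA), conformer = conformer, ...)$total
  sb <- sasa(subset_chains(s, chainsB), conformer = conformer, ...)$total
  sab <- sasa(subset_chains(s, c(chain_split(chainsA), chain_split(chainsB))),
              conformer = conformer, ...)$total
  sa + sb - sab
}
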