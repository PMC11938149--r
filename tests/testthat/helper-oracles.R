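# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (exhaustive grids, dense
# quadrature, closed forms) and do not call the code paths they check.

# Minimal hand-built structure for geometric edge cases.
toy_structure <- function(names, elements, chains, resnos, xyz,
                          resname = "ALA", het = FALSE) {
  n <- length(names)
  atoms <- data.frame(serial = seq_len(n), name = names, element = elements,
                      chain = chains, resno = as.integer(resnos), ins = "",
                      resname = resname,
                      hydrogen = elements %in% c("H", "D"),
                      het = het, occ = 1, stringsAsFactors = FALSE)
  nmrdock:::new_structure3d(atoms, list(matrix(xyz, ncol = 3, byrow = TRUE)))
}

# Brute-force rigid-fit RMSD: scan a grid of Euler rotations, solve the
# translation in closed form (centroid matching), keep the minimum.
grid_rmsd_oracle <- function(P, Q, step_deg = 4) {
  ang <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  ang_b <- seq(0, pi, by = step_deg * pi / 180)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (a in ang) for (b in ang_b) for (g in ang) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
    R <- Rz1 %*% Ry %*% Rz2
    v <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
    if (v < best) best <- v
  }
  best
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% R, 2, t, "+")

# Dense-quadrature SASA oracle, written independently of the package
# implementation (plain loops, latitude-band point sphere).
dense_sasa_oracle <- function(xyz, radii, probe = 1.4, n_points = 20000) {
  # latitude-band sphere points (different construction from the
  # package's golden spiral)
  n_lat <- floor(sqrt(n_points / 2))
  pts <- NULL
  for (i in seq_len(n_lat)) {
    th <- pi * (i - 0.5) / n_lat
    n_lon <- max(1, round(2 * n_lat * sin(th)))
    ph <- 2 * pi * (seq_len(n_lon) - 0.5) / n_lon
    pts <- rbind(pts, cbind(sin(th) * cos(ph), sin(th) * sin(ph),
                            rep(cos(th), n_lon)))
  }
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    Ri <- radii[i] + probe
    p <- sweep(pts * Ri, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      Rj <- radii[j] + probe
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > Rj^2
    }
    total <- total + 4 * pi * Ri^2 * mean(acc)
  }
  total
}

# Closed-form SASA buried area for two spheres of expanded radii R1, R2
# at center distance d (each loses a spherical cap).
two_sphere_buried_oracle <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  2 * pi * R1 * h1 + 2 * pi * R2 * h2
}

# All-pairs brute-force interface residues (plain loops).
brute_interface <- function(s, chainsA, chainsB, cutoff = 5, include_h = TRUE) {
  a <- s$atoms; m <- s$xyz[[1]]
  ia <- which(a$chain %in% chainsA & (include_h | !a$hydrogen) & !a$het)
  ib <- which(a$chain %in% chainsB & (include_h | !a$hydrogen) & !a$het)
  resA <- resB <- integer(0)
  for (i in ia) for (j in ib) {
    if (sqrt(sum((m[i, ] - m[j, ])^2)) <= cutoff) {
      resA <- c(resA, a$resno[i]); resB <- c(resB, a$resno[j])
    }
  }
  list(A = sort(unique(resA)), B = sort(unique(resB)))
}

# Single-frame "trajectory" with one candidate hydrogen bond at exact
# geometry: donor N-H on chain B, acceptor O on chain A; H at the
# origin, N = (0,1,0).  The H->A direction is set at (180 - dev)
# degrees from H->N and |HA| is solved so the D-A distance is exact:
# ha^2 + 2 ha cos(dev) + 1 = da^2.
hb_toy_traj <- function(da_dist, dev_deg) {
  th <- dev_deg * pi / 180
  ha <- -cos(th) + sqrt(cos(th)^2 + da_dist^2 - 1)
  xyz <- rbind(
    O = ha * c(sin(th), -cos(th), 0),
    N = c(0, 1.0, 0),
    H = c(0, 0, 0))
  s <- toy_structure(c("O", "N", "H"), c("O", "N", "H"),
                     c("A", "B", "B"), c(1, 1, 1), t(xyz))
  structure(list(topology = s$atoms, frames = s$xyz, dt = NA_real_),
            class = "trajectory")
}
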