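# Seed-deterministic synthetic fixtures with known ground truth: a
# two-chain complex with a designed interface, titration shift tables
# with planted CSPs and broadened peaks, jittered trajectories, and
# mono-exponential decay curves.

# Evaluate expr with a private RNG stream; the caller's RNG state is
# left untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Alanine-like residue template with ideal internal geometry; the
# amide H points -y, the carbonyl O +y, so a partner chain stacked
# above donates a linear N-H...O hydrogen bond to the O.
RES_TEMPLATE <- list(
  names = c("N", "H", "CA", "C", "O", "CB"),
  elements = c("N", "H", "C", "C", "O", "C"),
  xyz = rbind(
    N  = c(0.000,  0.000, 0.000),
    H  = c(0.000, -1.000, 0.000),
    CA = c(1.458,  0.000, 0.000),
    C  = c(2.000,  1.320, 0.000),
    O  = c(1.400,  2.400, 0.000),
    CB = c(2.000, -0.770, 1.200)
  )
)

RES_SPACING <- 12.0   # in-row residue spacing (A); exaggerated so only
                      # designed residue pairs come near each other
Z_ROW       <- 14.0   # z offset of the second residue row (keeps the
                      # chains 3D so rigid-body fits are well conditioned)
CONTACT_Y   <- 5.3    # chain-B origin height giving N-O = 2.9 A
FAR_Y       <- 12.0   # height of non-contact chain-B residues

place_residue <- function(origin) sweep(RES_TEMPLATE$xyz, 2, origin, "+")

#' Generate a synthetic two-chain complex with a designed interface
#'
#' Builds two alanine-like chains (amide hydrogens included) on a
#' coarse grid such that exactly `n_contacts` residue pairs have an
#' any-atom distance within 4.5 Angstrom and every other inter-chain
#' residue pair is beyond 6 Angstrom.  Each designed contact is a
#' linear N-H...O hydrogen bond (donor on chain B, N-O 2.9 A), so the
#' planted contacts are simultaneously planted hydrogen bonds.  Which
#' residues form the interface is drawn from the seed; geometry is
#' deterministic given the seed.
#'
#' @param n_res_a,n_res_b Residues per chain (chains "A" and "B").
#' @param n_contacts Number of designed contact pairs
#'   (`<= min(n_res_a, n_res_b)`).
#' @param seed Integer seed.
#' @return List with `structure` (a `structure3d`) and `truth`: list
#'   with `interface_a`, `interface_b` (residue numbers), `contacts`
#'   (data frame `resA`, `resB`), `hbonds` (data frame `donor_res` on
#'   B, `acceptor_res` on A), `seed`.
#' @export
make_complex <- function(n_res_a, n_res_b, n_contacts, seed = 1) {
  stopifnot(is_count(n_res_a), is_count(n_res_b), is_count(n_contacts),
            n_res_a >= 1, n_res_b >= 1, n_contacts >= 0)
  if (n_contacts > min(n_res_a, n_res_b))
    nd_stop("infeasible geometry: n_contacts exceeds min(n_res_a, n_res_b)")
  contact_res <- with_seed(seed, {
    sort(sample.int(min(n_res_a, n_res_b), n_contacts))
  })
  build_chain <- function(chain, n_res, y_of) {
    rows <- lapply(seq_len(n_res), function(i) {
      # chain B is shifted +1.4 A in x so its amide N-H (which points -y
      # in the template) sits directly above the carbonyl O of the
      # matching chain-A residue: a linear N-H...O hydrogen bond.
      xyz <- place_residue(c(RES_SPACING * ((i - 1) %/% 2) +
                               if (chain == "B") 1.4 else 0,
                             y_of(i),
                             Z_ROW * ((i - 1) %% 2)))
      list(atoms = data.frame(name = RES_TEMPLATE$names,
                              element = RES_TEMPLATE$elements,
                              chain = chain, resno = i, ins = "",
                              resname = "ALA",
                              hydrogen = RES_TEMPLATE$elements == "H",
                              het = FALSE, occ = 1,
                              stringsAsFactors = FALSE),
           xyz = xyz)
    })
    list(atoms = do.call(rbind, lapply(rows, `[[`, "atoms")),
         xyz = do.call(rbind, lapply(rows, `[[`, "xyz")))
  }
  A <- build_chain("A", n_res_a, function(i) 0)
  B <- build_chain("B", n_res_b,
                   function(i) if (i %in% contact_res) CONTACT_Y else FAR_Y)
  atoms <- rbind(A$atoms, B$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, c("serial", "name", "element", "chain", "resno", "ins",
                     "resname", "hydrogen", "het", "occ")]
  s <- new_structure3d(atoms, list(unname(rbind(A$xyz, B$xyz))))
  # verify the constructed margins
  ia <- which(atoms$chain == "A"); ib <- which(atoms$chain == "B")
  pd <- residue_pair_mindist(s, ia, ib)
  stopifnot(sum(pd$mindist <= 4.5) == n_contacts,
            all(pd$mindist[pd$mindist > 4.5] > 6))
  truth <- list(
    interface_a = contact_res, interface_b = contact_res,
    contacts = data.frame(resA = contact_res, resB = contact_res),
    hbonds = data.frame(donor_res = contact_res, acceptor_res = contact_res),
    n_res_a = n_res_a, n_res_b = n_res_b, seed = seed
  )
  list(structure = s, truth = truth)
}

#' Generate synthetic apo/bound titration shift tables
#'
#' Baseline amide shifts are drawn per residue (1H around 8.3 ppm, 15N
#' around 119 ppm).  In the bound state, interface residues (from the
#' complex ground truth) receive a planted perturbation of combined
#' magnitude `effect` ppm, split at a random phase between the 1H and
#' (x10) 15N axes so the weighted CSP equals `effect` exactly before
#' noise.  Every residue receives Gaussian measurement noise of scale
#' `noise` ppm on 1H and `10 * noise` on 15N.  A fraction of the
#' interface residues is deleted from the bound table, emulating peaks
#' broadened beyond detectability.
#'
#' @param truth Ground truth from [make_complex()] (or a list with
#'   `interface_a`/`interface_b` and `n_res_a`/`n_res_b`).
#' @param effect Planted CSP magnitude in ppm (> 0).
#' @param noise Per-axis 1H noise scale in ppm (15N noise is 10x).
#' @param broadened_fraction Fraction of interface residues removed
#'   from the bound table, in \[0, 1\].
#' @param seed Integer seed.
#' @param partner `"A"` or `"B"`: which chain's residues the tables
#'   describe.
#' @return List with `apo`, `holo` (`shift_table`s) and `truth`
#'   (augmented with `planted_csp` and `planted_broadened` residue
#'   vectors).
#' @export
make_titration <- function(truth, effect, noise = 0, broadened_fraction = 0,
                           seed = 1, partner = c("A", "B")) {
  partner <- match.arg(partner)
  if (!is.numeric(effect) || effect <= 0) nd_stop("effect must be > 0")
  if (broadened_fraction < 0 || broadened_fraction > 1)
    nd_stop("broadened_fraction outside [0, 1]")
  n_res <- if (partner == "A") truth$n_res_a else truth$n_res_b
  iface <- if (partner == "A") truth$interface_a else truth$interface_b
  with_seed(seed, {
    res <- seq_len(n_res)
    dH <- stats::rnorm(n_res, 8.3, 0.4)
    dN <- stats::rnorm(n_res, 119, 3.5)
    apo <- as_shift_table(data.frame(resno = res, restype = "ALA",
                                     dH = dH, dN = dN), state = "apo")
    phase <- stats::runif(n_res, 0, 2 * pi)
    on_iface <- res %in% iface
    dH2 <- dH + ifelse(on_iface, effect * cos(phase), 0) +
      stats::rnorm(n_res, 0, noise)
    dN2 <- dN + ifelse(on_iface, 10 * effect * sin(phase), 0) +
      stats::rnorm(n_res, 0, 10 * noise)
    n_brd <- round(broadened_fraction * length(iface))
    broadened <- if (n_brd > 0) sort(sample(iface, n_brd)) else integer(0)
    keep <- !(res %in% broadened)
    holo <- as_shift_table(data.frame(resno = res[keep], restype = "ALA",
                                      dH = dH2[keep], dN = dN2[keep]),
                           state = "bound")
    truth$planted_csp <- setdiff(iface, broadened)
    truth$planted_broadened <- broadened
    list(apo = apo, holo = holo, truth = truth)
  })
}

#' Generate a synthetic trajectory around a complex
#'
#' Frame 1 is the input complex unchanged (the initial configuration
#' used as RMSD reference); later frames add i.i.d. Gaussian jitter of
#' scale `jitter_sigma` to every coordinate.  Optionally, from frame
#' `escape_at` onward chain B is rigidly displaced by `escape_vector`
#' before jitter, destroying the designed contacts and hydrogen bonds
#' from that frame on.
#'
#' @param cplx Result of [make_complex()] (or a `structure3d` plus a
#'   `truth` attribute-free list; then ground-truth frequencies are not
#'   annotated).
#' @param n_frames Number of frames (>= 2).
#' @param jitter_sigma Per-coordinate jitter in Angstrom.
#' @param escape_at Optional first displaced frame (2..n_frames).
#' @param seed Integer seed.
#' @param escape_vector Rigid displacement applied to chain B from
#'   `escape_at` on (default 25 A along +y).
#' @return List with `trajectory` and `truth` (adds
#'   `expected_contact_frames`, the number of frames in which planted
#'   contacts persist).
#' @export
make_trajectory <- function(cplx, n_frames, jitter_sigma = 0,
                            escape_at = NULL, seed = 1,
                            escape_vector = c(0, 25, 0)) {
  stopifnot(is_count(n_frames), n_frames >= 2)
  s <- if (inherits(cplx, "structure3d")) cplx else cplx$structure
  truth <- if (inherits(cplx, "structure3d")) list() else cplx$truth
  if (!is.null(escape_at) &&
      (!is_count(escape_at) || escape_at < 2 || escape_at > n_frames))
    nd_stop("escape_at must lie in 2..n_frames")
  base <- s$xyz[[1]]
  bmask <- s$atoms$chain == "B"
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      m <- base
      if (!is.null(escape_at) && k >= escape_at)
        m[bmask, ] <- sweep(m[bmask, , drop = FALSE], 2, escape_vector, "+")
      if (k > 1L && jitter_sigma > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, jitter_sigma), ncol = 3)
      m
    })
  })
  truth$jitter_sigma <- jitter_sigma
  truth$escape_at <- escape_at
  truth$expected_contact_frames <- if (is.null(escape_at)) n_frames else escape_at - 1L
  truth$seed <- seed
  list(trajectory = structure(list(topology = s$atoms, frames = frames,
                                   dt = NA_real_), class = "trajectory"),
       truth = truth)
}

#' Generate a synthetic mono-exponential decay table
#'
#' \eqn{I(t) = I_0 e^{-R t} (1 + \epsilon)}, \eqn{\epsilon \sim N(0,
#' noise\_frac)}.
#'
#' @param rate Decay rate (> 0), reciprocal units of `delays`.
#' @param i0 Amplitude.
#' @param delays Non-negative delay values.
#' @param noise_frac Multiplicative noise fraction.
#' @param seed Integer seed.
#' @return Data frame `delay`, `intensity`.
#' @export
make_decay <- function(rate, i0 = 1, delays, noise_frac = 0, seed = 1) {
  if (!is.numeric(rate) || rate <= 0) nd_stop("rate must be > 0")
  if (any(delays < 0)) nd_stop("delays must be >= 0")
  with_seed(seed, {
    eps <- stats::rnorm(length(delays), 0, noise_frac)
    data.frame(delay = delays,
               intensity = i0 * exp(-rate * delays) * (1 + eps))
  })
}
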