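# Shift tables, CSP arithmetic, thresholds, restraints, relaxation.

shift_df <- function(resno, dH, dN, restype = "ALA", intensity = NA) {
  data.frame(resno = resno, restype = restype, dH = dH, dN = dN,
             intensity = intensity)
}

test_that("TSV and NMR-STAR readers agree on the same shifts", {
  df <- shift_df(1:3, c(8.1, 8.2, 7.9), c(118.5, 120.1, 122.3),
                 restype = c("ALA", "GLY", "LEU"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  t1 <- read_shift_table(tsv)
  expect_s3_class(t1, "shift_table")
  expect_equal(nrow(t1), 3)
  expect_true(all(t1$assigned))

  star <- c("data_synth", "save_assigned_chemical_shifts", "loop_",
            paste0("_Atom_chem_shift.",
                   c("ID", "Seq_ID", "Comp_ID", "Atom_ID", "Val")),
            sprintf("%d %d %s H %.3f", 1:3, df$resno, df$restype, df$dH),
            sprintf("%d %d %s N %.3f", 4:6, df$resno, df$restype, df$dN),
            sprintf("%d %d %s CA %.3f", 7:9, df$resno, df$restype, 55 + 1:3),
            "stop_", "save_")
  sf <- withr::local_tempfile(fileext = ".str")
  writeLines(star, sf)
  t2 <- read_shift_table(sf)
  expect_equal(t2$resno, t1$resno)
  expect_equal(t2$dH, t1$dH, tolerance = 1e-9)
  expect_equal(t2$dN, t1$dN, tolerance = 1e-9)
})

test_that("shift-table validation catches schema problems", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(resno = 1:2, restype = "A", dH = c(8, 8.1)),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_shift_table(tsv), "dN")
  expect_error(as_shift_table(shift_df(c(1, 1, 2), 8, 120)), "duplicate")
  expect_error(as_shift_table(shift_df(1:2, c("a", "b"), 120)), "non-numeric")
})

test_that("CSP follows the weighted-distance formula", {
  apo <- as_shift_table(shift_df(1:4, rep(8, 4), rep(120, 4)))
  holo <- as_shift_table(shift_df(1:4,
                                  8 + c(0.03, 0.03, 0, -0.04),
                                  120 + c(0, 0.40, 0, -0.30)))
  csp <- compute_csp(apo, holo)
  expect_equal(csp$delta, c(0.03, 0.05, 0, 0.05), tolerance = 1e-12)
  # alpha enters as the 15N divisor
  csp20 <- compute_csp(apo, holo, alpha = 20)
  expect_equal(csp20$delta[2], sqrt(0.03^2 + (0.4 / 20)^2), tolerance = 1e-12)
  expect_error(compute_csp(apo, holo, alpha = 0), "alpha")
})

test_that("status flags: broadened, unassigned, prolines, intensity floor", {
  apo <- as_shift_table(shift_df(1:5, rep(8, 5), rep(120, 5),
                                 restype = c("ALA", "PRO", "ALA", "ALA", "ALA"),
                                 intensity = c(10, 10, 10, 10, 10)))
  holo <- as_shift_table(shift_df(c(1, 2, 3, 5), rep(8.02, 4), rep(120.1, 4),
                                  restype = c("ALA", "PRO", "ALA", "ALA"),
                                  intensity = c(10, 10, 1, 10)))
  csp <- compute_csp(apo, holo)
  expect_equal(csp$status[csp$resno == 4], "broadened")   # vanished peak
  expect_true(is.na(csp$delta[csp$resno == 4]))
  expect_equal(csp$status[csp$resno == 2], "no_amide")    # proline
  expect_equal(csp$status[csp$resno == 3], "broadened")   # intensity ratio 0.1
  expect_equal(csp$status[csp$resno == 1], "shifted")
  # intensity criterion off
  csp2 <- compute_csp(apo, holo, intensity_floor = NA)
  expect_equal(csp2$status[csp2$resno == 3], "shifted")
})

test_that("CSP invariants: non-negativity, sign symmetry, monotonicity", {
  set.seed(5)
  for (i in 1:20) {
    dh <- rnorm(1, 0, 0.05); dn <- rnorm(1, 0, 0.5)
    apo <- as_shift_table(shift_df(1, 8, 120))
    d <- function(h, n) compute_csp(apo, as_shift_table(
      shift_df(1, 8 + h, 120 + n)))$delta
    expect_gte(d(dh, dn), 0)
    expect_equal(d(dh, dn), d(-dh, -dn), tolerance = 1e-12)
    expect_gte(d(2 * dh, dn), d(dh, dn))
    expect_gte(d(dh, 2 * dn), d(dh, dn))
    expect_identical(d(0, 0) == 0, TRUE)
  }
})

test_that("trimmed-SD threshold matches direct recomputation", {
  set.seed(9)
  base <- rnorm(95, 0.010, 0.0015)
  vals <- c(base, rep(0.200, 5))
  apo <- as_shift_table(shift_df(seq_along(vals), rep(8, 100), rep(120, 100)))
  holo <- as_shift_table(shift_df(seq_along(vals), 8 + vals, rep(120, 100)))
  csp <- compute_csp(apo, holo)
  got <- significance_threshold(csp)
  # independent oracle: literal re-implementation of the trimming loop
  # (with the same collapse guard: stop when < 2 values would survive)
  x <- vals
  repeat {
    s <- sd(x)
    keep <- x <= 3 * s
    if (all(keep) || sum(keep) < 2) break
    x <- x[keep]
  }
  expect_equal(got, s, tolerance = 1e-12)
  # here the loop drops the 5 planted outliers and then stops: the
  # threshold is the SD of the 95 baseline values
  expect_equal(got, sd(base), tolerance = 1e-12)
  # permutation invariance
  perm <- sample(nrow(csp))
  csp_p <- csp[perm, ]
  class(csp_p) <- class(csp)
  expect_equal(significance_threshold(csp_p), got, tolerance = 1e-15)
  # degenerate and fixed variants
  holo0 <- as_shift_table(shift_df(1:6, rep(8.02, 6), rep(120, 6)))
  apo0 <- as_shift_table(shift_df(1:6, rep(8, 6), rep(120, 6)))
  expect_equal(significance_threshold(compute_csp(apo0, holo0)), 0)
  expect_equal(significance_threshold(csp, method = "fixed", value = 0.012), 0.012)
  expect_error(significance_threshold(csp, method = "fixed"), "value")
  few <- compute_csp(apo0[1:3, ], holo0[1:3, ])
  class(few) <- c("csp_result", "data.frame")
  expect_error(significance_threshold(few), ">= 5")
})

test_that("perturbed_set honours threshold and broadening flags", {
  apo <- as_shift_table(shift_df(1:6, rep(8, 6), rep(120, 6)))
  holo <- as_shift_table(shift_df(1:5, 8 + c(0, 0.005, 0.03, 0.08, 0.002),
                                  rep(120, 5)))
  csp <- compute_csp(apo, holo)
  expect_equal(perturbed_set(csp, 0.02)$residues, c(3, 4, 6))
  expect_equal(perturbed_set(csp, 0.02, include_broadened = FALSE)$residues,
               c(3, 4))
  expect_equal(perturbed_set(csp, 0)$residues, c(2, 3, 4, 5, 6))  # >0 plus broadened
  expect_equal(perturbed_set(csp, 1)$residues, 6)                 # only broadened
  expect_equal(perturbed_set(csp, 1, include_broadened = FALSE)$residues,
               integer(0))
  expect_error(perturbed_set(csp, -1), "sigma")
  ev <- perturbed_set(csp, 0.02)$provenance
  expect_setequal(ev$evidence[ev$resno == 6], "broadened")
})

test_that("restraint categories are |i-j| bins and counts sum", {
  got <- classify_restraints(rbind(c(5, 5), c(5, 6), c(5, 8), c(5, 12)))
  expect_equal(got[c("intraresidue", "sequential", "medium", "long")],
               list(intraresidue = 1L, sequential = 1L, medium = 1L, long = 1L))
  expect_equal(got$total, 4L)
  empty <- classify_restraints(list())
  expect_equal(empty$total, 0L)
  set.seed(1)
  pairs <- cbind(sample(100, 500, TRUE), sample(100, 500, TRUE))
  cc <- classify_restraints(pairs)
  expect_equal(cc$intraresidue + cc$sequential + cc$medium + cc$long, 500L)
  # boundary separations
  expect_equal(classify_restraints(rbind(c(1, 5)))$medium, 1L)   # |i-j| = 4
  expect_equal(classify_restraints(rbind(c(1, 6)))$long, 1L)     # |i-j| = 5
})

test_that("assignment completeness prints the conventional percentage", {
  out <- assignment_completeness(96, 102)
  expect_equal(out$percent, 94)
  expect_equal(assignment_completeness(50, 100)$percent, 50)
})

test_that("decay fitting: exact, noisy-recovery, uncertainty, flags", {
  delays <- seq(0.15, 2.225, length.out = 10)
  exact <- make_decay(1, 2, delays, noise_frac = 0)
  fit <- fit_decay(exact$delay, exact$intensity)
  expect_equal(fit$R, 1, tolerance = 1e-8)
  expect_equal(fit$I0, 2, tolerance = 1e-8)
  expect_true(fit$valid)

  # duplicate delay with differing intensities -> nonzero uncertainty
  d2 <- rbind(exact, data.frame(delay = 0.6, intensity = 2 * exp(-0.6) * 1.05))
  f2 <- fit_decay(d2$delay, d2$intensity)
  expect_gt(f2$R_se, 0)

  expect_message(fneg <- fit_decay(delays, exp(+0.5 * delays)), "non-decaying")
  expect_false(fneg$valid)

  expect_error(fit_decay(c(1, 1, 1), c(1, 1, 1)), "distinct")
  expect_error(fit_decay(delays, -exp(-delays)), "positive")
})

test_that("hetNOE ratios", {
  sat <- data.frame(resno = 1:3, intensity = c(0.7, 1.4, 0.5))
  ref <- data.frame(resno = c(1, 2, 4), intensity = c(1, 2, 1))
  out <- hetnoe(sat, ref)
  expect_equal(out$resno, 1:2)
  expect_equal(out$ratio, c(0.7, 0.7))
  expect_equal(hetnoe(ref, ref)$ratio, rep(1, 3))
  expect_error(hetnoe(sat, data.frame(resno = 1, intensity = 0)), "zero")
})
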