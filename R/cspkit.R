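# Chemical-shift tables, CSP computation and thresholding, NOE
# restraint bookkeeping, relaxation fits and hetNOE.

#' Read an amide chemical-shift table
#'
#' Two formats are supported: a TSV/CSV with columns `resno`, `restype`,
#' `dH`, `dN` and optionally `intensity`; or a minimal NMR-STAR
#' chemical-shift loop (`_Atom_chem_shift` tags) from which amide H/N
#' rows are extracted.  Rows lacking either the 1H or the 15N shift are
#' marked unassigned.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"nmrstar"` or `"auto"` (guessed from the
#'   extension: `.str` means NMR-STAR).
#' @param state Label for the titration state (e.g. `"apo"`, `"1:0.5"`).
#' @return A `shift_table`: data frame with columns `resno`, `restype`,
#'   `dH` (ppm), `dN` (ppm), `intensity`, `assigned`, plus a `state`
#'   attribute.
#' @export
read_shift_table <- function(path, format = c("auto", "tsv", "nmrstar"),
                             state = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) nd_stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.str$", path, ignore.case = TRUE)) "nmrstar" else "tsv"
  tab <- switch(format,
                tsv = read_shift_tsv(path),
                nmrstar = read_shift_star(path))
  as_shift_table(tab, state = state)
}

#' Construct a shift table from a data frame
#'
#' @param df Data frame with columns `resno`, `restype`, `dH`, `dN` and
#'   optional `intensity`.
#' @param state State label.
#' @return A `shift_table`.
#' @export
as_shift_table <- function(df, state = NA_character_) {
  need <- c("resno", "restype", "dH", "dN")
  miss <- setdiff(need, names(df))
  if (length(miss))
    nd_stop("shift table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$resno))
    nd_stop("duplicate residue rows in shift table: ",
            paste(unique(df$resno[duplicated(df$resno)]), collapse = ","))
  if (!is.numeric(df$dH) || !is.numeric(df$dN))
    nd_stop("non-numeric chemical shifts")
  out <- data.frame(resno = as.integer(df$resno),
                    restype = toupper(as.character(df$restype)),
                    dH = as.numeric(df$dH), dN = as.numeric(df$dN),
                    intensity = if ("intensity" %in% names(df))
                      as.numeric(df$intensity) else NA_real_,
                    stringsAsFactors = FALSE)
  out$assigned <- is.finite(out$dH) & is.finite(out$dN)
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "state") <- state
  class(out) <- c("shift_table", "data.frame")
  out
}

read_shift_tsv <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  df
}

# Minimal NMR-STAR chemical-shift loop reader: collects Atom_chem_shift
# rows, keeps amide H and N, and pivots to one row per residue.
read_shift_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagline <- grep("^[[:space:]]*_Atom_chem_shift\\.", lines)
  if (!length(tagline)) nd_stop("no _Atom_chem_shift loop in ", path)
  tags <- sub("^_Atom_chem_shift\\.", "", trimws(lines[tagline]))
  body <- character(0)
  for (i in (max(tagline) + 1L):length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || ln == "stop_" || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "#")) break
    body <- c(body, ln)
  }
  toks <- strsplit(body, "[[:space:]]+")
  if (any(lengths(toks) != length(tags)))
    nd_stop("malformed NMR-STAR loop row in ", path)
  tab <- do.call(rbind, toks)
  colnames(tab) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(tab[, nm])
    nd_stop("NMR-STAR loop lacks tag ", c(...)[1])
  }
  resno <- as.integer(pick("Seq_ID", "Comp_index_ID"))
  restype <- pick("Comp_ID")
  atom <- pick("Atom_ID")
  val <- as.numeric(pick("Val"))
  keep <- atom %in% c("H", "HN", "N")
  resno <- resno[keep]; restype <- restype[keep]
  atom <- ifelse(atom[keep] == "HN", "H", atom[keep]); val <- val[keep]
  res <- sort(unique(resno))
  dH <- dN <- rep(NA_real_, length(res))
  rt <- rep(NA_character_, length(res))
  for (k in seq_along(res)) {
    sel <- resno == res[k]
    rt[k] <- restype[sel][1]
    h <- val[sel & atom == "H"]; n <- val[sel & atom == "N"]
    if (length(h)) dH[k] <- h[1]
    if (length(n)) dN[k] <- n[1]
  }
  data.frame(resno = res, restype = rt, dH = dH, dN = dN,
             stringsAsFactors = FALSE)
}

#' Write a shift table as TSV
#' @param tab A `shift_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[, c("resno", "restype", "dH", "dN", "intensity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute chemical shift perturbations between two states
#'
#' Per-residue weighted Euclidean distance in amide shift space,
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N/\alpha)^2}}
#' with the 15N change down-weighted by `alpha` (default 10).  A residue
#' assigned in the apo state but missing in the bound state is flagged
#' `broadened` (beyond-detectability line broadening); when intensities
#' are present in both states, a bound/apo intensity ratio below
#' `intensity_floor` also flags broadening.  Prolines (no amide proton)
#' get status `no_amide`; residues assigned in neither state are
#' `unassigned`.
#'
#' @param apo,holo `shift_table`s for the reference and titrated states.
#' @param alpha Positive 15N scaling divisor (default 10).
#' @param intensity_floor Bound/apo intensity ratio below which a peak
#'   counts as broadened (used only when both intensities are present).
#'   `NA` disables the criterion.
#' @return A `csp_result`: data frame with `resno`, `restype`, `dH_apo`,
#'   `dN_apo`, `dH_holo`, `dN_holo`, `delta` (ppm; `NA` where undefined)
#'   and `status` in `{shifted, broadened, unassigned, no_amide}`.
#' @export
compute_csp <- function(apo, holo, alpha = 10, intensity_floor = 0.15) {
  if (!is.numeric(alpha) || alpha <= 0) nd_stop("alpha must be > 0")
  A <- as.data.frame(apo); H <- as.data.frame(holo)
  res <- sort(union(A$resno, H$resno))
  ia <- match(res, A$resno); ih <- match(res, H$resno)
  a_ok <- !is.na(ia) & A$assigned[pmax(ia, 1L)] & !is.na(ia)
  a_ok[is.na(ia)] <- FALSE
  h_ok <- !is.na(ih)
  h_ok[h_ok] <- H$assigned[ih[h_ok]]
  restype <- ifelse(!is.na(ia), A$restype[ia],
                    ifelse(!is.na(ih), H$restype[ih], NA))
  out <- data.frame(resno = res, restype = restype,
                    dH_apo = ifelse(a_ok, A$dH[ia], NA_real_),
                    dN_apo = ifelse(a_ok, A$dN[ia], NA_real_),
                    dH_holo = ifelse(h_ok, H$dH[ih], NA_real_),
                    dN_holo = ifelse(h_ok, H$dN[ih], NA_real_),
                    stringsAsFactors = FALSE)
  delta <- sqrt((out$dH_holo - out$dH_apo)^2 +
                ((out$dN_holo - out$dN_apo) / alpha)^2)
  status <- rep("unassigned", length(res))
  status[a_ok & h_ok] <- "shifted"
  status[a_ok & !h_ok] <- "broadened"
  if (is.finite(intensity_floor)) {
    ra <- ifelse(!is.na(ia), A$intensity[pmax(ia, 1L)], NA_real_)
    rh <- ifelse(!is.na(ih), H$intensity[pmax(ih, 1L)], NA_real_)
    dim_peak <- a_ok & h_ok & is.finite(ra) & is.finite(rh) & ra > 0 &
      (rh / ra) < intensity_floor
    status[dim_peak] <- "broadened"
  }
  status[!is.na(restype) & restype %in% c("PRO", "P")] <- "no_amide"
  delta[status != "shifted"] <- NA_real_
  out$delta <- delta
  out$status <- status
  attr(out, "alpha") <- alpha
  class(out) <- c("csp_result", "data.frame")
  out
}

#' Significance threshold for CSPs
#'
#' Default method is the iteratively trimmed sample standard deviation:
#' compute the SD of all defined \eqn{\Delta\delta} values, drop values
#' exceeding `k_trim` times the SD, and repeat to convergence.
#' Broadened/unassigned residues carry no \eqn{\Delta\delta} and never
#' enter the statistic.
#'
#' @param csp A `csp_result`.
#' @param method `"trimmed_sd"` or `"fixed"`.
#' @param k_trim Trimming multiplier (default 3).
#' @param value Threshold in ppm when `method = "fixed"`.
#' @return Threshold sigma in ppm.
#' @export
significance_threshold <- function(csp, method = c("trimmed_sd", "fixed"),
                                   k_trim = 3, value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || !is.finite(value)) nd_stop("fixed method needs a value")
    return(as.numeric(value))
  }
  x <- csp$delta[is.finite(csp$delta)]
  if (length(x) < 5L)
    nd_stop("need >= 5 defined CSP values for trimmed_sd (got ", length(x), ")")
  repeat {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(0)
    keep <- x <= k_trim * s
    if (all(keep)) return(s)
    # collapse guard: when the surviving values cluster tightly around a
    # nonzero mean, the uncentered k*SD rule would discard everything;
    # the last SD computed on >= 2 values is the converged statistic
    if (sum(keep) < 2L) return(s)
    x <- x[keep]
  }
}

#' Build the NMR-perturbed residue set
#'
#' I_NMR = residues with defined \eqn{\Delta\delta \ge \sigma}, plus (by
#' default) residues broadened beyond detectability, which indicate
#' binding in the intermediate-exchange regime.
#'
#' @param csp A `csp_result`.
#' @param sigma Threshold in ppm (>= 0).
#' @param include_broadened Include broadened residues (default `TRUE`).
#' @param label Protein/partner label carried in the result.
#' @return A `perturbed_set`: list with `label`, `residues` (sorted
#'   integer vector), `sigma`, and `provenance` (data frame residue ->
#'   `csp`/`broadened` flag).
#' @export
perturbed_set <- function(csp, sigma, include_broadened = TRUE,
                          label = NA_character_) {
  if (!is.numeric(sigma) || sigma < 0) nd_stop("sigma must be >= 0")
  by_csp <- csp$resno[is.finite(csp$delta) & csp$delta >= sigma &
                        (sigma > 0 | csp$delta > 0)]
  by_brd <- if (include_broadened) csp$resno[csp$status == "broadened"] else integer(0)
  prov <- rbind(
    if (length(by_csp)) data.frame(resno = by_csp, evidence = "csp"),
    if (length(by_brd)) data.frame(resno = by_brd, evidence = "broadened")
  )
  if (is.null(prov)) prov <- data.frame(resno = integer(0), evidence = character(0))
  structure(list(label = label, residues = sort(unique(prov$resno)),
                 sigma = sigma, provenance = prov),
            class = "perturbed_set")
}

#' @export
print.perturbed_set <- function(x, ...) {
  cat(sprintf("<perturbed_set> %s: %d residues (sigma = %g ppm)\n",
              x$label, length(x$residues), x$sigma))
  invisible(x)
}

#' Categorize NOE distance restraints by sequence separation
#'
#' |i - j| = 0 intraresidue, 1 sequential, 2-4 medium range, >= 5 long
#' range.
#'
#' @param pairs Two-column matrix/data frame of residue numbers (i, j),
#'   or a list of length-2 vectors.
#' @return Named list of counts: `intraresidue`, `sequential`, `medium`,
#'   `long`, `total`.
#' @export
classify_restraints <- function(pairs) {
  if (length(pairs) == 0L || (is.data.frame(pairs) && nrow(pairs) == 0L))
    return(list(intraresidue = 0L, sequential = 0L, medium = 0L,
                long = 0L, total = 0L))
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, as.integer))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) nd_stop("pairs must have two columns")
  sep <- abs(pairs[, 1] - pairs[, 2])
  list(intraresidue = sum(sep == 0L),
       sequential = sum(sep == 1L),
       medium = sum(sep >= 2L & sep <= 4L),
       long = sum(sep >= 5L),
       total = nrow(pairs))
}

#' Assignment-completeness summary
#'
#' Bookkeeping for "n of N residues assigned": returns the assigned
#' count, the total, and the percentage rounded to the nearest integer
#' as conventionally printed.
#'
#' @param n_assigned,n_total Counts.
#' @return List `n_assigned`, `n_total`, `percent`.
#' @export
assignment_completeness <- function(n_assigned, n_total) {
  stopifnot(is_count(n_assigned), is_count(n_total), n_total > 0)
  list(n_assigned = as.integer(n_assigned), n_total = as.integer(n_total),
       percent = round(100 * n_assigned / n_total))
}

#' Fit a mono-exponential relaxation decay
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-R t}} to peak intensities at
#' a series of relaxation delays.  Start values come from a log-linear
#' regression and are refined by Gauss-Newton (`nls`).  The uncertainty
#' on R is the standard error from the fit covariance; when replicate
#' delays are present their scatter enters the residual variance, so
#' duplicated delays with differing intensities always yield a nonzero
#' uncertainty.
#'
#' @param delays Relaxation delays (seconds; any consistent unit - R is
#'   returned in its reciprocal).
#' @param intensities Positive peak intensities, same length.
#' @return A `relaxation_fit`: list with `R`, `I0`, `R_se`, `valid`
#'   (FALSE when the decay rate is not positive), `n`, `residual_sd`.
#' @export
fit_decay <- function(delays, intensities) {
  delays <- as.numeric(delays); intensities <- as.numeric(intensities)
  if (length(delays) != length(intensities)) nd_stop("length mismatch")
  if (length(unique(delays)) < 3L) nd_stop("need >= 3 distinct delays")
  if (any(!is.finite(delays)) || any(delays < 0)) nd_stop("delays must be finite and >= 0")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    nd_stop("intensities must be positive")
  lf <- stats::lm(log(intensities) ~ delays)
  R0 <- -unname(stats::coef(lf)[2]); I00 <- exp(unname(stats::coef(lf)[1]))
  df <- data.frame(t = delays, y = intensities)
  exact <- stats::sigma(lf) < 1e-10   # noiseless data: log-linear fit is final
  fit <- if (exact) NULL else tryCatch(
    suppressWarnings(
      stats::nls(y ~ I0 * exp(-R * t), data = df,
                 start = list(I0 = I00, R = if (is.finite(R0) && R0 > 0) R0 else 0.1),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (exact) {
    out <- list(R = R0, I0 = I00, R_se = 0, valid = is.finite(R0) && R0 > 0,
                n = length(delays), residual_sd = 0)
    if (!out$valid) nd_warn("non-decaying data: fitted R <= 0")
    class(out) <- "relaxation_fit"
    return(out)
  }
  if (is.null(fit)) {
    out <- list(R = R0, I0 = I00, R_se = NA_real_, valid = is.finite(R0) && R0 > 0,
                n = length(delays), residual_sd = NA_real_)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients["R", "Std. Error"],
                   error = function(e) NA_real_)
    out <- list(R = unname(cf["R"]), I0 = unname(cf["I0"]), R_se = unname(se),
                valid = unname(cf["R"]) > 0, n = length(delays),
                residual_sd = stats::sigma(fit))
  }
  if (!out$valid) nd_warn("non-decaying data: fitted R <= 0")
  class(out) <- "relaxation_fit"
  out
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation_fit> R = %.4g +/- %.2g, I0 = %.4g%s\n",
              x$R, x$R_se, x$I0, if (x$valid) "" else "  [INVALID: R <= 0]"))
  invisible(x)
}

#' Steady-state heteronuclear NOE ratios
#'
#' Per-residue intensity ratio of the saturated to the reference
#' spectrum of an interleaved pair.
#'
#' @param sat,ref Data frames with columns `resno` and `intensity`.
#' @return Data frame `resno`, `ratio` for residues present in both
#'   inputs; residues missing from either side are dropped with a log
#'   message.
#' @export
hetnoe <- function(sat, ref) {
  common <- intersect(sat$resno, ref$resno)
  dropped <- length(union(sat$resno, ref$resno)) - length(common)
  if (dropped > 0) nd_log("hetnoe: dropped ", dropped, " unmatched residue(s)")
  is_ <- match(common, sat$resno); ir <- match(common, ref$resno)
  if (any(ref$intensity[ir] == 0)) nd_stop("reference intensity is zero")
  data.frame(resno = common, ratio = sat$intensity[is_] / ref$intensity[ir])
}
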