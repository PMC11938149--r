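# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
nd_log <- function(..., level = "INFO") {
  opt <- getOption("nmrdock.verbosity", "info")
  if (identical(opt, "quiet")) return(invisible(NULL))
  if (identical(level, "DEBUG") && !identical(opt, "verbose")) return(invisible(NULL))
  message(sprintf("[nmrdock %s] %s", level, paste0(..., collapse = "")))
  invisible(NULL)
}

nd_warn <- function(...) nd_log(..., level = "WARN")

## stop() wrapper carrying a condition class so the CLI can map
## data errors to exit code 2 without string matching.
nd_stop <- function(..., class = "nmrdock_data_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(..., collapse = ""), call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

## Squared-distance matrix between row sets (n x 3, m x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Parse "11-90,95,100-102" into an integer vector.
parse_ranges <- function(txt) {
  if (is.numeric(txt)) return(as.integer(txt))
  parts <- strsplit(gsub("[[:space:]]", "", txt), ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    if (p == "") next
    m <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (length(m) == 3L) {
      out <- c(out, seq.int(as.integer(m[2]), as.integer(m[3])))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      nd_stop("cannot parse residue range token '", p, "'")
    }
  }
  unique(out)
}
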