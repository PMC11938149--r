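# Scoring candidate complex models against NMR perturbed-residue sets:
# interface coverage (C%), interface error (E%), C/E ranking, and
# mutation concordance.

#' Interface coverage
#'
#' Percentage of a model's predicted interface residues that are
#' NMR-perturbed:
#' \deqn{C\% = 100\,|I_{pred} \cap I_{NMR}| / |I_{pred}|}
#'
#' @param i_pred Residue numbers of the predicted interface (nonempty).
#' @param i_nmr Residue numbers of the NMR-perturbed set.
#' @return Coverage percentage in \[0, 100\].
#' @export
coverage <- function(i_pred, i_nmr) {
  i_pred <- unique(i_pred)
  if (!length(i_pred)) nd_stop("empty predicted interface: coverage undefined")
  100 * length(intersect(i_pred, i_nmr)) / length(i_pred)
}

#' Interface error
#'
#' Percentage of predicted interface residues that are not
#' NMR-perturbed:
#' \deqn{E\% = 100\,|I_{pred} \setminus I_{NMR}| / |I_{pred}|}
#' Computed as `100 - coverage()` so that C + E is exactly 100 (same
#' denominator, complementary numerators).
#'
#' @inheritParams coverage
#' @return Error percentage in \[0, 100\].
#' @export
error_pct <- function(i_pred, i_nmr) {
  100 - coverage(i_pred, i_nmr)
}

score_partner <- function(i_pred, i_nmr, restrict_to = NULL) {
  i_pred <- unique(i_pred)
  if (!is.null(restrict_to)) i_pred <- intersect(i_pred, restrict_to)
  if (!length(i_pred)) nd_stop("predicted interface empty after restriction")
  nc <- length(intersect(i_pred, i_nmr))
  list(n_pred = length(i_pred), n_common = nc, n_error = length(i_pred) - nc,
       C = 100 * nc / length(i_pred), E = 100 - 100 * nc / length(i_pred))
}

#' Score one complex model against NMR perturbed sets
#'
#' Extracts the model's predicted interface at the any-atom cutoff,
#' optionally restricts it to a common-residue set (for comparing
#' models with different constructs), and reports coverage/error per
#' partner plus a combined (union of partners) score and the C/E
#' ranking ratio.
#'
#' @param model A `structure3d` of the complex.
#' @param chainsA,chainsB Chains of the two partners.
#' @param perturbed_a,perturbed_b `perturbed_set`s (or plain residue
#'   vectors) for partners A and B.
#' @param restrict_a,restrict_b Optional residue vectors; I_pred is
#'   intersected with these before scoring (both numerator and
#'   denominator).
#' @param cutoff,include_h Passed to [interface_residues()].
#' @param id Model identifier used for ranking tie-breaks.
#' @return A `score_card`: list with per-partner and combined `C`, `E`,
#'   counts, `ratio` (C/E; `Inf` when E = 0), `id`, `restricted`.
#' @export
score_model <- function(model, chainsA, chainsB, perturbed_a, perturbed_b,
                        restrict_a = NULL, restrict_b = NULL,
                        cutoff = 5.0, include_h = TRUE, id = "model") {
  ia <- if (inherits(perturbed_a, "perturbed_set")) perturbed_a$residues else perturbed_a
  ib <- if (inherits(perturbed_b, "perturbed_set")) perturbed_b$residues else perturbed_b
  iface <- interface_residues(model, chainsA, chainsB,
                              cutoff = cutoff, include_h = include_h)
  pa <- score_partner(iface$A, ia, restrict_a)
  pb <- score_partner(iface$B, ib, restrict_b)
  n_pred <- pa$n_pred + pb$n_pred
  n_common <- pa$n_common + pb$n_common
  C <- 100 * n_common / n_pred
  E <- 100 - C
  structure(list(id = id, A = pa, B = pb,
                 C = C, E = E,
                 n_pred = n_pred, n_common = n_common,
                 n_error = n_pred - n_common,
                 ratio = if (E > 0) C / E else Inf,
                 restricted = !is.null(restrict_a) || !is.null(restrict_b),
                 interface = iface),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s: C = %.1f%%, E = %.1f%% (ratio %s); A: %.1f/%.1f, B: %.1f/%.1f\n",
              x$id, x$C, x$E,
              if (is.finite(x$ratio)) sprintf("%.2f", x$ratio) else "Inf",
              x$A$C, x$A$E, x$B$C, x$B$E))
  invisible(x)
}

#' Rank score cards by coverage/error ratio
#'
#' Descending C/E ratio; cards with E = 0 are best-possible and rank
#' above every finite ratio, ordered among themselves by C descending.
#' Remaining ties break lexicographically on model id, so the order is
#' total and deterministic.
#'
#' @param cards List of `score_card`s.
#' @return The list reordered best-first.
#' @export
rank_models <- function(cards) {
  if (!length(cards)) nd_stop("no score cards to rank")
  if (inherits(cards, "score_card")) cards <- list(cards)
  ratio <- vapply(cards, `[[`, numeric(1), "ratio")
  C <- vapply(cards, `[[`, numeric(1), "C")
  id <- vapply(cards, `[[`, character(1), "id")
  zeroE <- !is.finite(ratio)
  ord <- order(!zeroE,                      # E = 0 group first
               ifelse(zeroE, -C, -ratio),   # within group: C or ratio desc
               id)
  cards[ord]
}

#' Mutation concordance of a predicted interface
#'
#' Fraction of loss-of-interaction mutation sites that fall inside the
#' predicted interface of one partner, with a per-residue listing.
#'
#' @param iface An `interface_set`.
#' @param panel Integer vector of mutated residue numbers (nonempty),
#'   or a list with fields `residues` and optional `label`, `partner`.
#' @param partner `"A"` or `"B"`: which side of the interface the panel
#'   refers to (default `"A"`, overridden by `panel$partner`).
#' @return List with `fraction`, `n_in`, `n_panel` and `table` (data
#'   frame `resno`, `at_interface`).
#' @export
mutation_concordance <- function(iface, panel, partner = c("A", "B")) {
  if (is.list(panel)) {
    partner <- panel$partner %||% match.arg(partner)
    panel <- panel$residues
  } else partner <- match.arg(partner)
  panel <- unique(as.integer(panel))
  if (!length(panel)) nd_stop("empty mutation panel")
  iset <- iface[[partner]]
  hit <- panel %in% iset
  list(fraction = mean(hit), n_in = sum(hit), n_panel = length(panel),
       table = data.frame(resno = panel, at_interface = hit))
}
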