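# SmPC frequency categories: the European Commission guideline classifies
# the AE risk as very rare / rare / uncommon / common / very common at
# <0.01%, <0.1%, <1%, <10% and >= 10% respectively. The lower four
# cut-points are exclusive upper bounds; exactly 10% is "very common".

frequency_levels <- c("very_rare", "rare", "uncommon", "common",
                      "very_common")

#' SmPC frequency category of an AE probability
#'
#' @param p Numeric vector of probabilities in `[0, 1]` (unrounded
#'   estimates, not display values).
#' @return Ordered factor with levels
#'   `very_rare < rare < uncommon < common < very_common`.
#' @examples
#' categorize(c(0, 0.00005, 0.011, 0.1))
#' @export
categorize <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.1, Inf),
      labels = frequency_levels, right = FALSE, ordered_result = TRUE)
}

#' Cross-tabulate frequency categories against the gold standard
#'
#' Counts (trial, AE-type) units by the category the gold-standard
#' Aalen-Johansen estimate assigns (rows) against the category a
#' comparator estimator assigns (columns). Off-diagonal entries are
#' category deviations induced by the choice of estimator.
#'
#' @param gold Numeric vector of gold-standard AE probabilities.
#' @param other Numeric vector of comparator probabilities, paired with
#'   `gold` by unit.
#' @param name Comparator estimator name (stored as an attribute).
#' @return 5 x 5 contingency `table` (rows = gold, columns = comparator)
#'   with attribute `comparator`.
#' @export
category_crosstab <- function(gold, other, name = "comparator") {
  if (length(gold) != length(other))
    stop("gold and comparator vectors must be paired (equal length)",
         call. = FALSE)
  tab <- table(gold = categorize(gold), comparator = categorize(other))
  attr(tab, "comparator") <- name
  tab
}
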