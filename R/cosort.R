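#' Expected free-virus co-sorts per sorted drop
#'
#' The mean number of free viral particles accidentally deposited with a
#' sorted cell, lambda = concentration x drop sample volume, assuming no
#' discrimination against viral particles during sorting. Concentrations may
#' be given per mL (converted at 1e9 pL per mL). Typical surface sea water
#' carries 1e7-1e8 viruses per mL, i.e. 0.01-0.1 per pL; at a 21 pL drop
#' sample volume this brackets roughly one co-sorted virus per five cells up
#' to two viruses per cell.
#'
#' @param volume_pl drop sample volume in pL (positive).
#' @param concentration free-virus concentration (per pL unless `per_ml`).
#' @param per_ml if TRUE, `concentration` is viruses per mL.
#' @return expected co-sorts per sorted drop (lambda).
#' @examples
#' expected_cosorts(21, 0.1)          # 2.1
#' expected_cosorts(21, 1e7, per_ml = TRUE)  # 0.21
#' @export
expected_cosorts <- function(volume_pl, concentration, per_ml = FALSE) {
  if (any(volume_pl <= 0)) stop("volume must be positive")
  if (any(concentration < 0)) stop("concentration must be non-negative")
  conc_pl <- if (per_ml) concentration / 1e9 else concentration
  conc_pl * volume_pl
}

#' Probability of at least one co-sorted virus
#'
#' Poisson co-sort counts with mean lambda: P(N >= 1) = 1 - exp(-lambda).
#'
#' @param lambda expected co-sorts per drop (non-negative).
#' @return probability in \[0, 1).
#' @export
prob_at_least_one <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  1 - exp(-lambda)
}

#' Co-sorting expectation bounds
#'
#' Tabulates lambda and P(>=1 co-sort) at every combination of drop volume
#' and the two concentration corners, and optionally flags observed per-SAG
#' virus prevalences that exceed the upper Poisson bound (such prevalences
#' cannot be explained by co-sorting alone).
#'
#' @param volumes_pl drop sample volumes in pL.
#' @param conc_range length-2 (low, high) concentrations per pL.
#' @param observed_prevalence optional named numeric vector of observed
#'   fractions of SAGs containing viral sequence.
#' @return object of class `cosort_report`: list with `table` (volume_pl,
#'   concentration, lambda, p_at_least_one) and `flags` (data.frame of
#'   prevalences exceeding the upper bound; empty if none supplied).
#' @export
cosort_bounds <- function(volumes_pl, conc_range,
                          observed_prevalence = NULL) {
  if (length(volumes_pl) == 0L) {
    tab <- data.frame(volume_pl = numeric(), concentration = numeric(),
                      lambda = numeric(), p_at_least_one = numeric())
  } else {
    if (length(conc_range) != 2L || conc_range[1] > conc_range[2])
      stop("conc_range must be (low, high) with low <= high")
    grid <- expand.grid(volume_pl = volumes_pl,
                        concentration = conc_range,
                        KEEP.OUT.ATTRS = FALSE)
    lam <- expected_cosorts(grid$volume_pl, grid$concentration)
    tab <- data.frame(grid, lambda = lam,
                      p_at_least_one = prob_at_least_one(lam))
  }
  flags <- data.frame(group = character(), prevalence = numeric(),
                      upper_bound = numeric(), stringsAsFactors = FALSE)
  if (!is.null(observed_prevalence) && nrow(tab) > 0) {
    upper <- max(tab$p_at_least_one)
    over <- observed_prevalence[observed_prevalence > upper]
    if (length(over) > 0)
      flags <- data.frame(group = names(over), prevalence = unname(over),
                          upper_bound = upper, stringsAsFactors = FALSE)
  }
  structure(list(table = tab, flags = flags), class = "cosort_report")
}

#' @export
print.cosort_report <- function(x, ...) {
  cat("Co-sorting expectation bounds (Poisson):\n")
  print(x$table, row.names = FALSE)
  if (nrow(x$flags) > 0) {
    cat("Prevalences exceeding the upper co-sort bound:\n")
    print(x$flags, row.names = FALSE)
  }
  invisible(x)
}
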