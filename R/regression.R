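# Per-functional-class ordinary least squares of gene count on genome size.
# The regression is count-on-size (size is the predictor, matching how the
# trend is read off: genes gained or lost per Mbp of genome).

#' Construct a regression fit
#'
#' A container for one class's count-versus-size line. Useful for applying
#' a published formula (for example the class G line
#' y = 95.452 x - 52.387) without refitting.
#'
#' @param class_code Single-letter class code.
#' @param slope Genes per Mbp.
#' @param intercept Genes.
#' @param r2 Coefficient of determination (optional).
#' @param n Number of strains fitted (optional).
#' @return An object of class `regression_fit`.
#' @export
#' @examples
#' fit <- regression_fit("G", 95.452, -52.387)
#' deduce_count(fit, 1.46)
regression_fit <- function(class_code, slope, intercept, r2 = NA_real_, n = NA_integer_) {
  if (!is.finite(slope) || !is.finite(intercept)) {
    abort_format("slope and intercept must be finite")
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) abort_format("r2 must be in [0, 1]")
  structure(list(class_code = class_code, slope = slope,
                 intercept = intercept, r2 = r2, n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> class %s: y = %.4g x %+.4g (r2 = %.3g, n = %s)\n",
              x$class_code, x$slope, x$intercept, x$r2,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' @export
tidy.regression_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "genome_size_mbp"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.regression_fit <- function(x, ...) {
  tibble::tibble(class = x$class_code, slope = x$slope,
                 intercept = x$intercept, r.squared = x$r2, nobs = x$n)
}

#' Fit the count-versus-size regression for one class
#'
#' Ordinary least squares of the class gene count on genome size (Mbp)
#' across strains. A class with zero genes in every strain yields slope 0,
#' intercept 0 and r2 0 (flagged via the `all_zero` attribute) rather than
#' an error; identical genome sizes for all strains are a degenerate
#' design and raise an error.
#'
#' @param metadata Metadata tibble (see [read_genome_metadata()]).
#' @param class_counts Class count tibble (see [read_class_counts()]).
#' @param class_code Single-letter class to fit.
#' @return A `regression_fit`.
#' @export
#' @examples
#' md <- tibble::tibble(strain_id = c("A", "B"), genome_size_mbp = c(1, 2),
#'                      group = "x", is_focal = FALSE)
#' cc <- tibble::tibble(strain_id = c("A", "B"), G = c(50L, 150L))
#' fit_class_regression(md, cc, "G")
fit_class_regression <- function(metadata, class_counts, class_code) {
  if (!class_code %in% names(class_counts)) {
    abort_format(sprintf("class '%s' not present in the count table", class_code))
  }
  check_strains(metadata$strain_id, class_counts$strain_id, "class counts")
  dat <- dplyr::inner_join(
    metadata[, c("strain_id", "genome_size_mbp")],
    class_counts[, c("strain_id", class_code)],
    by = "strain_id")
  n <- nrow(dat)
  if (n < 2) abort_format("at least 2 strains are required")
  x <- dat$genome_size_mbp
  y <- dat[[class_code]]
  if (diff(range(x)) == 0) abort_format("degenerate design: all genome sizes identical")
  if (all(y == 0)) {
    fit <- regression_fit(class_code, 0, 0, 0, n)
    attr(fit, "all_zero") <- TRUE
    return(fit)
  }
  mod <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(residuals(mod)^2) / ss_tot
  regression_fit(class_code, unname(coef(mod)[2]), unname(coef(mod)[1]),
                 max(0, min(1, r2)), n)
}

#' Fit regressions for every class
#'
#' @inheritParams fit_class_regression
#' @param classes Classes to fit (default: every count column).
#' @return A tibble with one row per class: `class`, `slope`, `intercept`,
#'   `r2`, `n`, `all_zero`.
#' @export
fit_class_regressions <- function(metadata, class_counts, classes = NULL) {
  classes <- classes %||% setdiff(names(class_counts), "strain_id")
  purrr::map_dfr(classes, function(cl) {
    fit <- fit_class_regression(metadata, class_counts, cl)
    tibble::tibble(class = cl, slope = fit$slope, intercept = fit$intercept,
                   r2 = fit$r2, n = fit$n,
                   all_zero = isTRUE(attr(fit, "all_zero")))
  })
}

#' Rank classes by regression slope
#'
#' Descending by slope; ties broken alphabetically by class code. The
#' steepest class is the one whose gene complement responds most strongly
#' to genome reduction.
#'
#' @param fits Tibble from [fit_class_regressions()] (needs `class` and
#'   `slope` columns).
#' @return The fits tibble reordered, with a `rank` column prepended.
#' @export
#' @examples
#' fits <- tibble::tibble(class = c("E", "G", "K"),
#'                        slope = c(61.3, 95.5, 91.4))
#' rank_classes(fits)
rank_classes <- function(fits) {
  if (nrow(fits) < 1) abort_format("at least one fit is required")
  out <- dplyr::arrange(fits, dplyr::desc(.data$slope), .data$class)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Deduced gene count for a genome size
#'
#' Evaluates the fitted line `slope * size + intercept`. Returned
#' unrounded; display rounding is the caller's choice.
#'
#' @param fit A `regression_fit` (or any list/one-row data frame with
#'   `slope` and `intercept`).
#' @param genome_size_mbp Genome size(s) in Mbp, positive.
#' @return Numeric vector of deduced counts.
#' @export
#' @examples
#' deduce_count(regression_fit("G", 95.452, -52.387), c(1.46, 1.58, 1.54))
deduce_count <- function(fit, genome_size_mbp) {
  if (any(genome_size_mbp <= 0)) abort_format("genome size must be positive")
  fit$slope * genome_size_mbp + fit$intercept
}

#' Observed-over-deduced shortfall
#'
#' Percentage of the deduced gene count actually observed, computed from
#' the unrounded deduced value and then rounded half away from zero. A
#' value below 100 means the strain carries fewer genes of the class than
#' its genome size predicts.
#'
#' @param observed Observed integer count(s).
#' @param deduced Deduced count(s) from [deduce_count()]; must be positive.
#' @return A tibble with columns `observed`, `deduced` and `percent`
#'   (integer).
#' @export
#' @examples
#' shortfall(54, deduce_count(regression_fit("G", 95.452, -52.387), 1.46))
shortfall <- function(observed, deduced) {
  if (any(deduced <= 0)) abort_format("deduced count must be positive")
  tibble::tibble(
    observed = as.integer(observed),
    deduced = deduced,
    percent = as.integer(round_half_away(100 * observed / deduced))
  )
}

#' Shortfall report for designated strains
#'
#' Fits (or reuses) the class regression and reports observed counts,
#' deduced counts and shortfall percentages for the requested strains.
#'
#' @inheritParams fit_class_regression
#' @param strains Strain ids to report on.
#' @param fit Optional `regression_fit` to use instead of refitting (for
#'   example a published formula).
#' @return A tibble with `strain_id`, `class_code`, `observed`, `deduced`,
#'   `percent`.
#' @export
class_shortfall <- function(metadata, class_counts, class_code, strains,
                            fit = NULL) {
  fit <- fit %||% fit_class_regression(metadata, class_counts, class_code)
  missing_strains <- setdiff(strains, metadata$strain_id)
  if (length(missing_strains)) {
    abort_format(sprintf("unknown strain(s): %s",
                         paste(missing_strains, collapse = ", ")))
  }
  md <- metadata[match(strains, metadata$strain_id), ]
  obs <- class_counts[[class_code]][match(strains, class_counts$strain_id)]
  ded <- deduce_count(fit, md$genome_size_mbp)
  dplyr::bind_cols(
    tibble::tibble(strain_id = strains, class_code = class_code),
    shortfall(obs, ded)
  )
}

#' Per-strain residuals from a class regression
#'
#' @inheritParams fit_class_regression
#' @param fit Optional precomputed `regression_fit`.
#' @return Tibble with `strain_id`, `observed`, `expected`, `residual`.
#' @export
class_residuals <- function(metadata, class_counts, class_code, fit = NULL) {
  fit <- fit %||% fit_class_regression(metadata, class_counts, class_code)
  dat <- dplyr::inner_join(metadata[, c("strain_id", "genome_size_mbp")],
                           class_counts[, c("strain_id", class_code)],
                           by = "strain_id")
  expected <- deduce_count(fit, dat$genome_size_mbp)
  tibble::tibble(strain_id = dat$strain_id,
                 observed = dat[[class_code]],
                 expected = expected,
                 residual = dat[[class_code]] - expected)
}
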