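# 'Specific'/'missing' marker-gene screen and the binomial chance model.
#
# A family is 'specific' to the focal group when it is conserved in more
# than q_high of focal strains and less than q_low of the others, and
# 'missing' when conserved in less than q_low of focal strains and more
# than q_high of the others. The strict-inequality fractions convert to
# integer cutoffs floor(q_high*n)+1 and ceiling(q_low*n)-1; at the study's
# group sizes (10 focal, 164 others, 80%/20%) these are exactly the
# printed cutoffs 9, 1, 132 and 32.

#' Integer thresholds for the marker screen
#'
#' @param n_focal Number of focal strains.
#' @param n_other Number of non-focal strains.
#' @param q_high Upper conservation fraction (strict), default 0.8.
#' @param q_low Lower conservation fraction (strict), default 0.2.
#' @return An object of class `screen_thresholds` with integer cutoffs
#'   `k_focal_high` (minimum focal count for "conserved in > q_high of
#'   focal"), `k_focal_low` (maximum focal count for "< q_low"), and
#'   likewise `k_other_high`, `k_other_low`.
#' @export
#' @examples
#' screen_thresholds(10, 164)
screen_thresholds <- function(n_focal, n_other, q_high = 0.8, q_low = 0.2) {
  if (n_focal < 1 || n_other < 1) abort_format("group sizes must be at least 1")
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    abort_format("need 0 < q_low < q_high < 1")
  }
  k_high <- function(n) as.integer(floor(q_high * n) + 1)
  k_low <- function(n) as.integer(ceiling(q_low * n) - 1)
  th <- structure(list(
    n_focal = as.integer(n_focal), n_other = as.integer(n_other),
    q_high = q_high, q_low = q_low,
    k_focal_high = k_high(n_focal), k_focal_low = k_low(n_focal),
    k_other_high = k_high(n_other), k_other_low = k_low(n_other)
  ), class = "screen_thresholds")
  with(th, {
    if (!(0 <= k_focal_low && k_focal_low < k_focal_high && k_focal_high <= n_focal) ||
        !(0 <= k_other_low && k_other_low < k_other_high && k_other_high <= n_other)) {
      abort_format("thresholds collapse at these group sizes; widen q_low/q_high")
    }
  })
  th
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat(sprintf(
    "<screen_thresholds> focal n=%d: specific needs >=%d, missing needs <=%d\n",
    x$n_focal, x$k_focal_high, x$k_focal_low))
  cat(sprintf(
    "                    other n=%d: specific needs <=%d, missing needs >=%d\n",
    x$n_other, x$k_other_low, x$k_other_high))
  invisible(x)
}

#' @export
tidy.screen_thresholds <- function(x, ...) {
  tibble::tibble(
    group = c("focal", "focal", "other", "other"),
    bound = c("high", "low", "high", "low"),
    k = c(x$k_focal_high, x$k_focal_low, x$k_other_high, x$k_other_low))
}

#' Screen for focal-specific and focal-missing gene families
#'
#' Classifies every family by its presence counts in the focal and
#' non-focal strain groups: `specific` when focal count >= `k_focal_high`
#' and other count <= `k_other_low`; `missing` when focal count <=
#' `k_focal_low` and other count >= `k_other_high`; otherwise `neither`.
#'
#' @param presence Presence table (tibble with `family_id`) or 0/1 matrix,
#'   families x strains.
#' @param focal Character vector of focal strain ids; must be a non-empty
#'   strict subset of the matrix strains.
#' @param thresholds Optional [screen_thresholds()]; defaults to 80%/20%
#'   at the matrix's group sizes.
#' @return A tibble with `family_id`, `focal_count`, `other_count`,
#'   `category` (factor specific/missing/neither).
#' @export
#' @examples
#' m <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 2,
#'             dimnames = list(c("fam1", "fam2"), c("A", "B", "C", "D")))
#' screen_markers(m, focal = "A")
screen_markers <- function(presence, focal, thresholds = NULL) {
  m <- as_presence_matrix(presence)
  strains <- colnames(m)
  if (length(focal) == 0) abort_format("focal set must be non-empty")
  if (!all(focal %in% strains)) {
    abort_format(sprintf("focal strains absent from matrix: %s",
                         paste(setdiff(focal, strains), collapse = ", ")))
  }
  others <- setdiff(strains, focal)
  if (!length(others)) abort_format("focal set must be a strict subset of strains")
  th <- thresholds %||% screen_thresholds(length(focal), length(others))
  if (th$n_focal != length(focal) || th$n_other != length(others)) {
    abort_format("thresholds were built for different group sizes")
  }
  fc <- as.integer(rowSums(m[, focal, drop = FALSE]))
  oc <- as.integer(rowSums(m[, others, drop = FALSE]))
  category <- rep("neither", nrow(m))
  category[fc >= th$k_focal_high & oc <= th$k_other_low] <- "specific"
  category[fc <= th$k_focal_low & oc >= th$k_other_high] <- "missing"
  tibble::tibble(
    family_id = rownames(m),
    focal_count = fc,
    other_count = oc,
    category = factor(category, levels = c("specific", "missing", "neither"))
  )
}

#' Binomial chance model for the marker screen
#'
#' Null model for how often independent random loss produces a marker
#' family: suppose a gene is lost with probability `x` independently in
#' every species, starting from a common ancestor that carried all genes.
#' The probability that such a gene ends up retained by at most `k_focal`
#' of the `n_focal` focal species, times the probability that it is lost
#' by at most `k_other` of the `n_other` remaining species (i.e. retained
#' by at least `n_other - k_other` of them), is
#' \deqn{f(x) = \sum_{k=0}^{k_f} \binom{n_f}{k} (1-x)^k x^{n_f-k}
#'       \cdot \sum_{k=0}^{k_o} \binom{n_o}{k} x^k (1-x)^{n_o-k}.}
#' The first factor is non-decreasing and the second non-increasing in
#' `x`, so their product has a single sharp interior peak.
#'
#' @param n_focal Focal group size (default 10).
#' @param n_other Other group size (default 164).
#' @param k_focal Retained-count cap in the focal group (default 1).
#' @param k_other Lost-count cap in the other group (default 32).
#' @return An object of class `chance_model`.
#' @export
#' @examples
#' mod <- chance_model()
#' chance_probability(0.2, mod)
chance_model <- function(n_focal = 10L, n_other = 164L,
                         k_focal = 1L, k_other = 32L) {
  if (k_focal < 0 || k_focal > n_focal || k_other < 0 || k_other > n_other) {
    abort_format("k caps must lie within the group sizes")
  }
  structure(list(n_focal = as.integer(n_focal), n_other = as.integer(n_other),
                 k_focal = as.integer(k_focal), k_other = as.integer(k_other)),
            class = "chance_model")
}

#' @export
print.chance_model <- function(x, ...) {
  cat(sprintf(
    "<chance_model> retained by <= %d of %d focal, lost by <= %d of %d others\n",
    x$k_focal, x$n_focal, x$k_other, x$n_other))
  invisible(x)
}

# One binomial tail sum in log space with compensated (Kahan) summation:
# sum_{k=0}^{kmax} C(n,k) p^k (1-p)^(n-k), exact at p in {0, 1}.
binom_lower_sum <- function(kmax, n, p) {
  if (p <= 0) return(1)                 # k = 0 term is 1, all others 0
  if (p >= 1) return(if (kmax >= n) 1 else 0)
  ks <- 0:kmax
  logterms <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  terms <- exp(logterms)
  s <- 0; comp <- 0
  for (t in terms) {                     # Kahan compensated summation
    yv <- t - comp
    tv <- s + yv
    comp <- (tv - s) - yv
    s <- tv
  }
  min(s, 1)
}

#' Chance probability f(x)
#'
#' Evaluates the product of the two binomial sums of the chance model at
#' per-species loss probability `x` (vectorised).
#'
#' @param x Loss probability in \[0, 1\].
#' @param model A [chance_model()].
#' @return Numeric vector of probabilities.
#' @export
chance_probability <- function(x, model = chance_model()) {
  if (any(x < 0 | x > 1)) abort_format("x must lie in [0, 1]")
  vapply(x, function(xi) {
    # retained by <= k_focal of the focal group: success prob (1 - x)
    f1 <- binom_lower_sum(model$k_focal, model$n_focal, 1 - xi)
    # lost by <= k_other of the other group: success prob x
    f2 <- binom_lower_sum(model$k_other, model$n_other, xi)
    f1 * f2
  }, numeric(1))
}

#' The two factors of the chance model
#'
#' @inheritParams chance_probability
#' @return Tibble with `x`, `focal_factor` (non-decreasing in x),
#'   `other_factor` (non-increasing in x) and `f` (their product).
#' @export
chance_factors <- function(x, model = chance_model()) {
  if (any(x < 0 | x > 1)) abort_format("x must lie in [0, 1]")
  f1 <- vapply(x, function(xi) binom_lower_sum(model$k_focal, model$n_focal, 1 - xi), numeric(1))
  f2 <- vapply(x, function(xi) binom_lower_sum(model$k_other, model$n_other, xi), numeric(1))
  tibble::tibble(x = x, focal_factor = f1, other_factor = f2, f = f1 * f2)
}

#' Locate the peak of the chance model
#'
#' Grid scan over \[0, 1\] followed by golden-section/parabolic refinement
#' of the bracketing interval.
#'
#' @param model A [chance_model()].
#' @param grid_step Grid resolution (default 1e-4).
#' @return A list with `x_peak` and `f_peak`.
#' @export
#' @examples
#' find_chance_peak(chance_model())
find_chance_peak <- function(model = chance_model(), grid_step = 1e-4) {
  xs <- seq(0, 1, by = grid_step)
  fs <- chance_probability(xs, model)
  i <- which.max(fs)
  lo <- xs[max(1L, i - 1L)]
  hi <- xs[min(length(xs), i + 1L)]
  if (lo == hi) return(list(x_peak = xs[i], f_peak = fs[i]))
  opt <- optimize(function(x) chance_probability(x, model),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  list(x_peak = opt$maximum, f_peak = opt$objective)
}

#' Expected number of chance hits
#'
#' Upper-envelope expectation of the number of families meeting the
#' marker criterion (lost across the focal group, retained by the rest)
#' under independent random loss: the peak probability (the least
#' favourable per-species loss rate) times the pan-genome size.
#'
#' @param f_peak Peak probability from [find_chance_peak()].
#' @param n_families Number of gene families considered.
#' @return Expected hit count.
#' @export
#' @examples
#' pk <- find_chance_peak(chance_model())
#' expected_chance_hits(pk$f_peak, 2340)
expected_chance_hits <- function(f_peak, n_families) {
  if (n_families < 1) abort_format("n_families must be at least 1")
  f_peak * n_families
}

#' @export
tidy.chance_model <- function(x, ...) {
  chance_factors(seq(0, 1, by = 0.001), x)
}

#' @export
glance.chance_model <- function(x, ...) {
  pk <- find_chance_peak(x)
  tibble::tibble(n_focal = x$n_focal, n_other = x$n_other,
                 k_focal = x$k_focal, k_other = x$k_other,
                 x_peak = pk$x_peak, f_peak = pk$f_peak)
}
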