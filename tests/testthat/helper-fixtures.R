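# shared fixtures and independent oracles, all built in code at test time

# random 0/1 matrix with family rownames and strain colnames
rand_presence <- function(nfam, nstrain, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(nfam * nstrain, 1, p), nfam, nstrain,
              dimnames = list(sprintf("K%05d", seq_len(nfam)),
                              sprintf("S%d", seq_len(nstrain))))
  m
}

# literal per-family application of the screen rules (brute-force oracle)
brute_screen <- function(m, focal, th) {
  others <- setdiff(colnames(m), focal)
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    fc <- 0L
    for (s in focal) fc <- fc + m[i, s]
    oc <- 0L
    for (s in others) oc <- oc + m[i, s]
    cat_i <- "neither"
    if (fc >= th$k_focal_high && oc <= th$k_other_low) cat_i <- "specific"
    if (fc <= th$k_focal_low && oc >= th$k_other_high) cat_i <- "missing"
    out[i] <- cat_i
  }
  out
}

# O(n^3) agglomeration oracle: cluster-pair distances recomputed from the
# ORIGINAL pairwise distances at every step (no Lance-Williams updates),
# same lexicographic tie rule as the implementation
oracle_cophenetic <- function(dmat, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  labels <- rownames(dmat)
  n <- nrow(dmat)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      cross <- dmat[clusters[[a]], clusters[[b]], drop = FALSE]
      dd <- if (linkage == "average") mean(cross) else max(cross)
      key <- paste(sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]]))),
                   collapse = "\r")
      if (dd < best_d || (dd == best_d && key < best_key)) {
        best <- c(a, b); best_d <- dd; best_key <- key
      }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- best_d; coph[ib, ia] <- best_d
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# closed-form normal-equations OLS oracle
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# f(x) for the study-default chance model, computed once with exact
# rational arithmetic (arbitrary precision) and frozen; column x holds the
# rational grid points p/q as doubles
chance_oracle <- data.frame(
  x = c(1/20, 1/10, 3/20, 1/5, 11/50, 1/4, 3/10, 7/20, 2/5, 9/20, 1/2,
        11/20, 3/5, 13/20, 7/10, 3/4, 4/5, 17/20, 9/10, 19/20),
  f = c(1.86523437498533909e-11, 9.09929216619200815e-09,
        3.17230457059342022e-07, 2.03394077276559391e-06,
        2.44979904533160880e-06, 1.76891575615912541e-06,
        2.30208158868743206e-07, 5.52856501668352378e-09,
        2.78106538632252187e-11, 3.02486579453060701e-14,
        6.73294883406130030e-18, 2.65803904840131787e-22,
        1.45320501708960783e-27, 7.45572674943625774e-34,
        1.96060587365631145e-41, 1.00409689729409448e-50,
        1.92663293140092522e-62, 6.14070744645888523e-78,
        2.90115271585231532e-100, 3.67897461567112961e-139)
)

# small full-pipeline configuration used across tests (fast but non-trivial)
small_config <- function(seed = 1, ...) {
  simulation_config(n_strains = 30L, n_focal = 6L, n_families = 200L,
                    n_planted_missing = 6L, n_planted_specific = 1L,
                    padding_genes = 80L, kb_per_gene = 10, seed = seed, ...)
}
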