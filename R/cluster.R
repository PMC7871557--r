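# Hierarchical clustering of strains on binary gene-content profiles.
#
# The agglomeration is implemented in the package (Lance-Williams updates)
# rather than delegated, because reproducible Newick export requires a
# deterministic tie-break: when several cluster pairs sit at the same
# distance, the pair whose lexicographically smallest member strain_id is
# smallest wins. stats::hclust breaks such ties by input order instead.

#' Pairwise binary distances between strains
#'
#' Jaccard: `1 - |a AND b| / |a OR b|` on presence profiles (0 when both
#' profiles are empty). Hamming: mismatch count divided by the number of
#' families.
#'
#' @param presence Presence table (tibble with `family_id` column) or 0/1
#'   matrix, families x strains.
#' @param metric `"jaccard"` (default) or `"hamming"`.
#' @return A `stats::dist` object over strains.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'             dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
#' binary_distance(m, "jaccard")
binary_distance <- function(presence, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  m <- as_presence_matrix(presence)
  if (ncol(m) < 2) abort_format("at least 2 strains are required")
  x <- t(m)                                  # strains x families
  storage.mode(x) <- "double"
  both <- tcrossprod(x)
  ones <- rowSums(x)
  if (metric == "jaccard") {
    union <- outer(ones, ones, "+") - both
    d <- 1 - both / union
    d[union == 0] <- 0
  } else {
    d <- (outer(ones, ones, "+") - 2 * both) / ncol(x)
  }
  diag(d) <- 0
  out <- as.dist(d)
  attr(out, "method") <- metric
  out
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering with Lance-Williams distance updates
#' (`average` = UPGMA, `complete`, or `ward` using the squared-distance
#' ward.D2 form). Equal-distance merge candidates are resolved
#' deterministically: the pair whose lexicographically smallest member
#' label sorts first is merged. Merge heights are checked to be
#' non-decreasing for the monotone linkages (average, complete).
#'
#' @param distances A `stats::dist` object (or symmetric matrix with zero
#'   diagonal) with labels.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return An object of class `c("flab_dendrogram", "hclust")`, usable
#'   with [stats::cutree()], [stats::cophenetic()], [write_newick()] and
#'   plotting.
#' @export
#' @examples
#' d <- as.dist(matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
#'                     dimnames = list(LETTERS[1:3], LETTERS[1:3])))
#' hierarchical_cluster(d, "average")$height
hierarchical_cluster <- function(distances, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (is.matrix(distances)) {
    if (!isSymmetric(unname(distances)) || any(diag(distances) != 0)) {
      abort_format("distance matrix must be symmetric with zero diagonal")
    }
    labels <- rownames(distances) %||% as.character(seq_len(nrow(distances)))
    d <- unname(distances)
  } else if (inherits(distances, "dist")) {
    labels <- attr(distances, "Labels") %||% as.character(seq_len(attr(distances, "Size")))
    d <- unname(as.matrix(distances))
  } else {
    abort_format("distances must be a dist object or a symmetric matrix")
  }
  n <- nrow(d)
  if (n < 2) abort_format("at least 2 observations are required")

  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)                    # hclust ids: -obs or +merge row
  rep_label <- labels                    # lexicographically smallest member
  work <- d
  diag(work) <- Inf
  work[!upper.tri(work) & !lower.tri(work)] <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    work[!active, ] <- Inf
    work[, !active] <- Inf
    dmin <- min(work)
    cand <- which(work == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted representative-label pairs
    keys <- apply(cand, 1L, function(p) {
      lab <- sort(c(rep_label[p[1]], rep_label[p[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    ni <- size[i]; nj <- size[j]
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    new_d <- switch(linkage,
      average  = (ni * work[i, others] + nj * work[j, others]) / (ni + nj),
      complete = pmax(work[i, others], work[j, others]),
      ward     = {
        nk <- size[others]
        sqrt(((ni + nk) * work[i, others]^2 + (nj + nk) * work[j, others]^2 -
                nk * dmin^2) / (ni + nj + nk))
      })
    a <- sort(c(node[i], node[j]))
    merge[step, ] <- a
    height[step] <- dmin
    # cluster j folds into slot i
    work[i, others] <- new_d
    work[others, i] <- new_d
    work[i, j] <- Inf; work[j, i] <- Inf
    active[j] <- FALSE
    size[i] <- ni + nj
    node[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
  }

  if (linkage %in% c("average", "complete") &&
      any(diff(height) < -1e-12 * max(height, 1))) {
    abort_format("internal error: non-monotone merge heights under a monotone linkage")
  }

  ord_leaves <- function(id) {
    if (id < 0) return(-id)
    c(ord_leaves(merge[id, 1]), ord_leaves(merge[id, 2]))
  }
  structure(list(
    merge = merge, height = height, order = ord_leaves(n - 1L),
    labels = labels, method = linkage,
    call = match.call(), dist.method = attr(distances, "method") %||% "unknown"
  ), class = c("flab_dendrogram", "hclust"))
}

#' Cophenetic distances of a dendrogram
#'
#' The height at which two strains first join. Thin wrapper over
#' [stats::cophenetic()] returning a labelled matrix.
#'
#' @param dendrogram An `hclust`-compatible object.
#' @return Symmetric matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(dendrogram) {
  as.matrix(cophenetic(dendrogram))
}

#' Evaluate focal-group co-clustering
#'
#' Cuts the dendrogram into `k` clusters (or at height `h`) and reports
#' whether the focal strains fall in a single cluster, plus the focal
#' purity (fraction of focal strains in the focal-majority cluster).
#'
#' @param dendrogram An `hclust`-compatible object over strains.
#' @param focal Character vector of focal strain ids (subset of the
#'   dendrogram labels).
#' @param k Number of clusters (1..n).
#' @param h Cut height (alternative to `k`).
#' @return A list of class `focal_cluster_report`: `k`, `assignments`
#'   (tibble strain_id/cluster/is_focal), `focal_purity`,
#'   `focal_single_cluster`.
#' @export
evaluate_focal_cluster <- function(dendrogram, focal, k = NULL, h = NULL) {
  labels <- dendrogram$labels
  n <- length(labels)
  if (is.null(k) && is.null(h)) abort_format("supply k or h")
  if (!is.null(k) && (k < 1 || k > n)) abort_format("k must be between 1 and n")
  if (!all(focal %in% labels)) {
    abort_format(sprintf("focal strains not in dendrogram: %s",
                         paste(setdiff(focal, labels), collapse = ", ")))
  }
  cl <- if (!is.null(k)) cutree(dendrogram, k = k) else cutree(dendrogram, h = h)
  focal_cl <- cl[focal]
  tab <- table(focal_cl)
  purity <- max(tab) / length(focal)
  structure(list(
    k = if (!is.null(k)) k else length(unique(cl)),
    assignments = tibble::tibble(strain_id = labels,
                                 cluster = unname(cl[labels]),
                                 is_focal = labels %in% focal),
    focal_purity = unname(purity),
    focal_single_cluster = length(tab) == 1L
  ), class = "focal_cluster_report")
}

#' @export
print.focal_cluster_report <- function(x, ...) {
  cat(sprintf("<focal_cluster_report> k = %d: focal %s (purity %.2f)\n",
              x$k,
              if (x$focal_single_cluster) "in a single cluster" else "split",
              x$focal_purity))
  invisible(x)
}

#' @export
glance.focal_cluster_report <- function(x, ...) {
  tibble::tibble(k = x$k, focal_purity = x$focal_purity,
                 focal_single_cluster = x$focal_single_cluster)
}

#' Sensitivity of focal co-clustering across cut levels
#'
#' The cut level is a reading choice, so the report is a sweep: one row
#' per `k` with the focal purity and single-cluster flag.
#'
#' @inheritParams evaluate_focal_cluster
#' @param ks Integer vector of cluster counts to evaluate.
#' @return A tibble with columns `k`, `focal_purity`,
#'   `focal_single_cluster`.
#' @export
focal_cluster_sweep <- function(dendrogram, focal, ks = 2:12) {
  purrr::map_dfr(ks, function(k) {
    rep <- evaluate_focal_cluster(dendrogram, focal, k = k)
    tibble::tibble(k = k, focal_purity = rep$focal_purity,
                   focal_single_cluster = rep$focal_single_cluster)
  })
}
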