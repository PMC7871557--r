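# On-disk exchange formats. Everything is TSV, UTF-8, with '#'-prefixed
# comment lines ignored, matching common bioinformatics matrix conventions.
# Dendrograms are exchanged as Newick.

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read strain metadata
#'
#' Reads a tab-separated metadata table with one row per strain and columns
#' `strain_id`, `genome_size_mbp`, `group` and `is_focal`. The focal flag
#' marks membership of the group under study (for FLAB, the fructophilic
#' species) and is encoded as 0/1 on disk.
#'
#' @param path Path to a TSV file. Lines starting with `#` are ignored.
#' @return A tibble with columns `strain_id` (character),
#'   `genome_size_mbp` (double, megabase pairs), `group` (character) and
#'   `is_focal` (logical).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("strain_id\tgenome_size_mbp\tgroup\tis_focal",
#'              "S1\t1.46\tApilactobacillus\t1"), tf)
#' read_genome_metadata(tf)
read_genome_metadata <- function(path) {
  md <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("strain_id", "genome_size_mbp", "group", "is_focal")
  for (col in required) {
    if (!col %in% names(md)) {
      abort_format(sprintf("metadata is missing required column '%s'", col))
    }
  }
  size <- suppressWarnings(as.numeric(md$genome_size_mbp))
  if (anyNA(size) && nrow(md) > 0) {
    abort_format("metadata column 'genome_size_mbp' contains non-numeric values")
  }
  focal_raw <- md$is_focal
  if (nrow(md) > 0 && !all(focal_raw %in% c("0", "1"))) {
    abort_format("metadata column 'is_focal' must contain only 0 or 1")
  }
  out <- tibble::tibble(
    strain_id = md$strain_id,
    genome_size_mbp = size,
    group = md$group,
    is_focal = focal_raw == "1"
  )
  validate_metadata(out)
  out
}

validate_metadata <- function(metadata) {
  if (anyDuplicated(metadata$strain_id)) {
    dup <- unique(metadata$strain_id[duplicated(metadata$strain_id)])
    abort_format(sprintf("duplicate strain_id in metadata: %s",
                         paste(dup, collapse = ", ")))
  }
  if (nrow(metadata) > 0 && any(grepl("\\s", metadata$strain_id))) {
    abort_format("strain_id must not contain whitespace")
  }
  if (nrow(metadata) > 0 && any(!is.finite(metadata$genome_size_mbp) |
                                metadata$genome_size_mbp <= 0)) {
    abort_format("genome_size_mbp must be positive")
  }
  invisible(metadata)
}

#' Write strain metadata
#'
#' Inverse of [read_genome_metadata()]; `is_focal` is written as 0/1.
#'
#' @param metadata Tibble as returned by [read_genome_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  out <- dplyr::mutate(metadata, is_focal = as.integer(.data$is_focal))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a per-strain functional-class gene-count table
#'
#' The table has one row per strain (`strain_id` first column) and one
#' column per single-letter functional class holding non-negative integer
#' gene counts.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `strain_id` plus one integer column per class.
#' @export
read_class_counts <- function(path) {
  cc <- read_tsv_quiet(path)
  if (!"strain_id" %in% names(cc)) {
    abort_format("class count table is missing required column 'strain_id'")
  }
  classes <- setdiff(names(cc), "strain_id")
  if (anyDuplicated(classes)) {
    abort_format("duplicate class codes in class count table")
  }
  if (anyDuplicated(cc$strain_id)) {
    abort_format("duplicate strain_id in class count table")
  }
  for (cl in classes) {
    v <- cc[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      abort_format(sprintf("class '%s' contains values that are not non-negative integers", cl))
    }
    cc[[cl]] <- as.integer(v)
  }
  cc
}

#' Write a per-strain functional-class gene-count table
#'
#' @param class_counts Tibble as returned by [read_class_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_class_counts <- function(class_counts, path) {
  readr::write_tsv(class_counts, path, progress = FALSE)
  invisible(path)
}

#' Read a binary gene-family presence/absence matrix
#'
#' The on-disk layout is one row per gene family: the first column holds
#' the family id (KO-style strings), remaining columns one strain each,
#' and cells 0/1. Cells holding counts greater than 1 are coerced to 1
#' with a warning, so per-family copy-number tables are accepted
#' (presence means at least one copy). Families observed in fewer than
#' `min_prevalence` strains are dropped and the number dropped is
#' reported via a message.
#'
#' @param path Path to a TSV file.
#' @param min_prevalence Minimum number of strains a family must be
#'   present in to be retained (default 1, which drops all-absent rows).
#' @return A tibble with `family_id` plus one 0/1 integer column per
#'   strain, column order as on disk.
#' @export
read_presence_matrix <- function(path, min_prevalence = 1L) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) abort_format("presence matrix needs a family id column plus strain columns")
  fam_col <- names(raw)[1]
  fams <- raw[[1]]
  if (anyDuplicated(fams)) abort_format("duplicate family ids in presence matrix")
  strains <- names(raw)[-1]
  mat <- matrix(0L, nrow(raw), length(strains),
                dimnames = list(fams, strains))
  coerced <- 0L
  for (j in seq_along(strains)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort_format(sprintf(
        "non-numeric presence value '%s' at row %d (family %s), column '%s'",
        raw[[j + 1]][bad[1]], bad[1], fams[bad[1]], strains[j]))
    }
    if (any(v < 0)) abort_format(sprintf("negative value in column '%s'", strains[j]))
    coerced <- coerced + sum(v > 1)
    mat[, j] <- as.integer(v >= 1)
  }
  if (coerced > 0) {
    warning(sprintf("%d cells held counts > 1 and were coerced to presence = 1", coerced),
            call. = FALSE)
  }
  keep <- rowSums(mat) >= min_prevalence
  if (any(!keep)) {
    message(sprintf("dropped %d families below min_prevalence = %d",
                    sum(!keep), min_prevalence))
  }
  out <- tibble::as_tibble(mat[keep, , drop = FALSE], rownames = "family_id")
  names(out)[1] <- "family_id"
  out
}

#' Write a binary gene-family presence/absence matrix
#'
#' @param presence Tibble (with `family_id` column) or 0/1 matrix with
#'   family rownames and strain colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(presence, path) {
  m <- as_presence_matrix(presence)
  out <- tibble::as_tibble(m, rownames = "family_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Convert a dendrogram to an ape phylogeny
#'
#' Branch lengths equal merge-height differences, so the depth of every
#' leaf below the root equals the final merge height (a two-leaf
#' dendrogram with merge height h becomes `(A:h,B:h);`).
#'
#' @param dendrogram An object from [hierarchical_cluster()] (or any
#'   `hclust`).
#' @return An object of class `phylo`.
#' @export
dendrogram_to_phylo <- function(dendrogram) {
  if (!inherits(dendrogram, "hclust")) {
    abort_format("dendrogram must be an hclust-compatible object")
  }
  if (length(dendrogram$height) < 1) abort_format("dendrogram is empty")
  phy <- ape::as.phylo(dendrogram)
  # ape halves the heights when converting (leaf depth = height/2);
  # restore leaf depth = merge height
  phy$edge.length <- phy$edge.length * 2
  phy
}

#' Write a dendrogram as Newick
#'
#' @inheritParams dendrogram_to_phylo
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- if (inherits(dendrogram, "phylo")) dendrogram else dendrogram_to_phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}
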