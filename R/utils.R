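# internal helpers shared across modules

# Derive a reproducible sub-seed for a named random substream, so that
# changing the number of draws in one stage never perturbs another.
# Must stay below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, label, k = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  as.integer((as.numeric(seed) * 48271 + h * 16807 + k * 69621) %% 2147483647)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_format <- function(msg) stop(msg, call. = FALSE)

# Coerce the accepted presence-matrix representations to an integer matrix
# with family ids as rownames and strain ids as colnames.
as_presence_matrix <- function(presence) {
  if (is.matrix(presence)) {
    m <- presence
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort_format("presence matrix must have family rownames and strain colnames")
    }
  } else if (is.data.frame(presence)) {
    idcol <- intersect(c("family_id", "family"), names(presence))
    if (!length(idcol)) {
      abort_format("presence table must have a 'family_id' column")
    }
    m <- as.matrix(presence[setdiff(names(presence), idcol[1])])
    rownames(m) <- as.character(presence[[idcol[1]]])
  } else {
    abort_format("presence must be a matrix or a data frame")
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0L | m > 1L)) {
    abort_format("presence values must all be 0 or 1")
  }
  if (anyDuplicated(rownames(m))) {
    abort_format("duplicate family ids in presence matrix")
  }
  m
}

# strain sets must agree exactly; mismatches are an error, never a reindex
check_strains <- function(metadata_ids, other_ids, what = "table") {
  if (!setequal(metadata_ids, other_ids)) {
    missing_ids <- setdiff(metadata_ids, other_ids)
    extra_ids <- setdiff(other_ids, metadata_ids)
    abort_format(sprintf(
      "strain sets disagree between metadata and %s (%d missing, %d unexpected)",
      what, length(missing_ids), length(extra_ids)
    ))
  }
  invisible(TRUE)
}
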