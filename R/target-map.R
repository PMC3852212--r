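#' Construct a miRNA-to-target-gene map
#'
#' A target map records which genes each miRNA is predicted to repress.
#' Each (miRNA, gene) pair carries an integer vote count: the number of
#' target-prediction programs (out of the 11 aggregated by miRecords-style
#' resources) that support the pair.  Vote counts support threshold
#' filtering via [filter_by_votes()].
#'
#' @param mirna_id,gene_id Character vectors naming the paired features.
#' @param votes Integer votes in 1..11, one per pair.
#' @return A data frame of class `target_map` with columns `mirna_id`,
#'   `gene_id`, `votes`.
#' @export
target_map <- function(mirna_id, gene_id, votes = rep(11L, length(mirna_id))) {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  votes <- as.integer(votes)
  if (length(gene_id) != length(mirna_id) || length(votes) != length(mirna_id)) {
    stop_arg("mirna_id, gene_id and votes must have equal length")
  }
  if (length(votes) && (anyNA(votes) || any(votes < 1))) {
    stop_arg("votes must be integers >= 1")
  }
  key <- paste(mirna_id, gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_arg("duplicated miRNA-gene pair: %s",
             gsub("\r", " -> ", d, fixed = TRUE))
  }
  structure(
    data.frame(mirna_id = mirna_id, gene_id = gene_id, votes = votes,
               stringsAsFactors = FALSE),
    class = c("target_map", "data.frame")
  )
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d miRNA-gene pairs (%d miRNAs, %d genes)\n",
              nrow(x), length(unique(x$mirna_id)), length(unique(x$gene_id))))
  invisible(x)
}

#' Read a target-pair table
#'
#' Expects a TSV with columns `mirna_id`, `gene_id` and (optionally)
#' `votes`; a two-column file is treated as fully supported pairs
#' (votes = 11).  Pairs referencing features absent from the supplied
#' feature lists are dropped with a warning, mirroring the usual mismatch
#' between a target database and the features measured on a platform.
#'
#' @param path Path to the TSV file.
#' @param mirna_features,gene_features Character vectors of measured
#'   feature identifiers used to validate (and optionally drop) pairs.
#'   `NULL` skips the corresponding check.
#' @return A [target_map].
#' @export
read_target_map <- function(path, mirna_features = NULL, gene_features = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(df))) {
    stop_arg("target file %s must have columns mirna_id, gene_id", path)
  }
  if (!"votes" %in% names(df)) {
    df$votes <- 11L
  }
  bad <- which(is.na(df$votes) | is.na(df$mirna_id) | is.na(df$gene_id))
  if (length(bad)) {
    stop_arg("malformed target row at line %d of %s", bad[1] + 1L, path)
  }
  keep <- rep(TRUE, nrow(df))
  if (!is.null(mirna_features)) keep <- keep & df$mirna_id %in% mirna_features
  if (!is.null(gene_features)) keep <- keep & df$gene_id %in% gene_features
  if (any(!keep)) {
    warning(sprintf("dropped %d target pair(s) referencing unmeasured features",
                    sum(!keep)), call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    stop_arg("no usable target pairs in %s after matching features", path)
  }
  target_map(df$mirna_id, df$gene_id, df$votes)
}

#' @rdname read_target_map
#' @param map A [target_map].
#' @export
write_target_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter target pairs by vote count
#'
#' Retains the pairs supported by at least `min_votes` prediction programs.
#' Filtering is monotone: raising the threshold can only shrink the map.
#'
#' @param map A [target_map].
#' @param min_votes Integer threshold in 1..11.
#' @return A new [target_map]; the input is unmodified.  An empty result is
#'   allowed here and only rejected where a non-empty map is required.
#' @export
filter_by_votes <- function(map, min_votes) {
  if (!inherits(map, "target_map")) stop_arg("map must be a target_map")
  if (length(min_votes) != 1 || is.na(min_votes) ||
      min_votes < 1 || min_votes > 11) {
    stop_arg("min_votes must be a single integer in 1..11")
  }
  keep <- map$votes >= min_votes
  structure(as.data.frame(map)[keep, , drop = FALSE],
            class = c("target_map", "data.frame"))
}

# Restrict a map to pairs whose features appear in the given lists; used
# when graphs are built from feature-selected matrices.
restrict_map <- function(map, mirna_features, gene_features) {
  keep <- map$mirna_id %in% mirna_features & map$gene_id %in% gene_features
  structure(as.data.frame(map)[keep, , drop = FALSE],
            class = c("target_map", "data.frame"))
}

check_nonempty_map <- function(map) {
  if (!inherits(map, "target_map")) stop_arg("map must be a target_map")
  if (nrow(map) == 0) {
    stop_arg(paste("target map is empty: the inter-relation score would be",
                   "identically zero"))
  }
  invisible(TRUE)
}
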