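#' OTU count table with taxonomy
#'
#' Container for a samples-by-OTUs matrix of non-negative integer counts plus
#' a ranked taxonomy (phylum ... genus) per OTU. Samples are rows everywhere
#' in this package. Genus-level labels may be of the form
#' `"unclassified <family>"` for OTUs classified only to family rank.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; dimnames
#'   give sample and OTU identifiers (generated when missing).
#' @param taxonomy `data.frame` with column `otu_id` and any of `phylum`,
#'   `class`, `order`, `family`, `genus`. OTUs absent from `taxonomy` get an
#'   `"unclassified"` lineage with a warning.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (data.frame keyed by `otu_id`).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' tab <- otu_table(m)
#' sample_ids(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) stop_invalid("'counts' must be a matrix")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_invalid("counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) stop_invalid("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("sample_%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("otu_%04d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop_invalid("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop_invalid("duplicate OTU ids")

  ranks <- c("phylum", "class", "order", "family", "genus")
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(otu_id = colnames(counts), stringsAsFactors = FALSE)
    for (r in ranks) taxonomy[[r]] <- "unclassified"
  } else {
    if (!is.data.frame(taxonomy) || !"otu_id" %in% names(taxonomy)) {
      stop_invalid("'taxonomy' must be a data.frame with an 'otu_id' column")
    }
    taxonomy <- taxonomy[!duplicated(taxonomy$otu_id), , drop = FALSE]
    extra <- setdiff(taxonomy$otu_id, colnames(counts))
    if (length(extra)) {
      stop_invalid("taxonomy contains OTU ids absent from the count table: ",
                   paste(utils::head(extra, 3), collapse = ", "))
    }
    missing <- setdiff(colnames(counts), taxonomy$otu_id)
    if (length(missing)) {
      warning(length(missing), " OTU(s) missing from taxonomy; ",
              "lineage set to 'unclassified'", call. = FALSE)
      fill <- data.frame(otu_id = missing, stringsAsFactors = FALSE)
      for (r in intersect(ranks, names(taxonomy))) fill[[r]] <- "unclassified"
      taxonomy <- rbind(taxonomy[names(fill)], fill)
    }
    for (r in ranks) {
      if (!r %in% names(taxonomy)) taxonomy[[r]] <- "unclassified"
      taxonomy[[r]] <- as.character(taxonomy[[r]])
      taxonomy[[r]][is.na(taxonomy[[r]]) | taxonomy[[r]] == ""] <- "unclassified"
    }
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id),
                         c("otu_id", ranks)]
    rownames(taxonomy) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%d genera)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$genus))))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x$counts)

#' Per-sample sequencing depths
#' @param x an `otu_table`.
#' @return named integer vector of library sizes.
#' @export
sample_depths <- function(x) rowSums(x$counts)

#' Aggregate an OTU table to genus level
#'
#' Sums counts over OTUs sharing a genus label. OTUs classified only to
#' family rank keep their `"unclassified <family>"` genus-level label, so
#' they aggregate within the family as in standard practice.
#'
#' @param x an `otu_table`.
#' @param relative if `TRUE`, return per-sample relative abundances
#'   (rows sum to 1) instead of counts.
#' @return numeric matrix samples x genera, with a `"phylum"` attribute
#'   mapping each genus column to its (majority) phylum.
#' @export
genus_table <- function(x, relative = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  genus <- x$taxonomy$genus
  agg <- t(rowsum(t(x$counts), group = genus))
  mode(agg) <- "numeric"
  phyl <- vapply(split(x$taxonomy$phylum, genus), function(p) {
    names(sort(table(p), decreasing = TRUE))[1]
  }, character(1))
  if (relative) {
    depth <- rowSums(agg)
    keep <- depth > 0
    if (!all(keep)) {
      warning(sum(!keep), " zero-depth sample(s) excluded", call. = FALSE)
      agg <- agg[keep, , drop = FALSE]
      depth <- depth[keep]
    }
    agg <- agg / depth
  }
  attr(agg, "phylum") <- phyl[colnames(agg)]
  agg
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its library size. Zero-depth samples are
#' excluded with a warning.
#'
#' @param x an `otu_table` or a non-negative numeric matrix (samples in rows).
#' @return numeric matrix whose rows sum to 1.
#' @examples
#' to_relative_abundance(matrix(c(2, 0, 2, 5), 2, 2))
#' @export
to_relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else x
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  if (any(m < 0)) stop_invalid("abundances must be non-negative")
  depth <- rowSums(m)
  keep <- depth > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-depth sample(s) excluded: ",
            paste(rownames(m)[!keep], collapse = ", "), call. = FALSE)
    m <- m[keep, , drop = FALSE]
    depth <- depth[keep]
  }
  m / depth
}

#' Read / write an OTU table as TSV
#'
#' The canonical on-disk dialect is TSV with sample ids in the first column
#' and OTU ids as the header; the taxonomy is a second TSV keyed by `otu_id`.
#'
#' @param path count-table TSV path.
#' @param taxonomy_path optional taxonomy TSV path.
#' @return `read_otu_table`: an [otu_table]. `write_otu_table`: `path`,
#'   invisibly.
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  if (!file.exists(path)) stop_invalid("count table file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop_invalid("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m)) stop_invalid("non-numeric counts in ", path)
  if (any(m < 0)) stop_invalid("negative counts in ", path)
  if (any(m != round(m))) stop_invalid("non-integer counts in ", path)
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    if (!file.exists(taxonomy_path)) {
      stop_invalid("taxonomy file not found: ", taxonomy_path)
    }
    tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  }
  otu_table(m, tax)
}

#' @rdname read_otu_table
#' @param x an `otu_table`.
#' @export
write_otu_table <- function(x, path, taxonomy_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path)) {
    utils::write.table(x$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a square distance matrix as TSV
#' @param d a `dist` object (for writing) or TSV path (for reading).
#' @param path output path.
#' @return `write_distance_matrix`: `path` invisibly;
#'   `read_distance_matrix`: a `dist`.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_dist_checked(m, tol = 1e-8)
}
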