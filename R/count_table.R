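#' Construct a sample-by-taxon count table
#'
#' The central container for OTU/feature counts. Counts are stored as a
#' samples x taxa integer matrix; an optional semicolon-delimited taxonomy
#' lineage (kingdom -> genus/species, at most 7 ranks) can be attached per
#' taxon.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns. Dimnames
#'   are required and must be unique. All entries must be nonnegative
#'   integers.
#' @param taxonomy optional character vector of lineage strings, one per
#'   taxon (named or in column order), e.g.
#'   `"k__Bacteria;p__Firmicutes;...;g__Lactobacillus"`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample (row) and taxon (column) names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate sample id: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop("duplicate taxon id: ", dup)
  }
  if (!is.numeric(counts) || anyNA(counts)) stop("counts must be numeric and complete")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) taxonomy <- taxonomy[colnames(counts)]
    if (length(taxonomy) != ncol(counts)) {
      stop("taxonomy must have one lineage per taxon")
    }
    names(taxonomy) <- colnames(counts)
    nrank <- vapply(strsplit(taxonomy, ";", fixed = TRUE), length, 1L)
    if (any(nrank > 7L)) stop("taxonomy lineages must have at most 7 ranks")
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: %d samples x %d taxa (total reads %s)%s\n",
    nrow(x$counts), ncol(x$counts),
    format(sum(x$counts), big.mark = ","),
    if (is.null(x$taxonomy)) "" else ", taxonomy attached"
  ))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
library_sizes <- function(x) rowSums(x$counts)

#' Read a feature table from TSV
#'
#' Accepts both the taxa-rows dialect common to amplicon workflows (first
#' column `#OTU ID`, samples in columns, optional trailing `taxonomy` column
#' with a semicolon-delimited lineage) and the transposed samples-rows
#' layout. Internally tables are always samples x taxa.
#'
#' @param path TSV file path.
#' @param orientation `"taxa-rows"` (default) or `"samples-rows"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("feature table needs an id column plus data columns")
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  taxonomy <- NULL
  if (tolower(names(body)[ncol(body)]) == "taxonomy") {
    taxonomy <- as.character(body[[ncol(body)]])
    body <- body[, -ncol(body), drop = FALSE]
  }
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad], names(body)[j]))
    }
    body[[j]] <- v
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (orientation == "taxa-rows") {
    if (!is.null(taxonomy)) names(taxonomy) <- ids
    mat <- t(mat)
  } else if (!is.null(taxonomy)) {
    stop("a taxonomy column is only meaningful in the taxa-rows dialect")
  }
  count_table(mat, taxonomy = taxonomy)
}

#' Write a feature table to TSV
#'
#' Writes the taxa-rows dialect by default (`#OTU ID` first column, samples
#' in columns, `taxonomy` appended when present) so that
#' `read_count_table(write_count_table(x))` round-trips bit-exactly.
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @param orientation `"taxa-rows"` (default) or `"samples-rows"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path,
                              orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  if (orientation == "taxa-rows") {
    df <- data.frame(`#OTU ID` = taxon_ids(table), t(table$counts),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  } else {
    df <- data.frame(`#Sample ID` = sample_ids(table), table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Expects a TSV with header and columns `sample_id`, `subject_id`,
#' `litter_id`, `age_days`, `diet_group`, `oral_group`, `health_label`.
#' Group labels are checked against the closed study vocabularies
#' (diet: I5007/control; oral: Oral/Nonoral; health:
#' healthy/diarrhea/unknown) and ages against the study window 0-42 days.
#'
#' @param path TSV file path.
#' @return a `data.frame` of validated metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta a data.frame to validate in place of a file.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "subject_id", "litter_id", "age_days",
            "diet_group", "oral_group", "health_label")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("metadata lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  meta$age_days <- as.integer(meta$age_days)
  if (any(is.na(meta$age_days)) || any(meta$age_days < 0L) || any(meta$age_days > 42L)) {
    stop("age_days must be integers within the study window [0, 42]")
  }
  check_vocab <- function(x, vocab, what) {
    bad <- setdiff(unique(x), vocab)
    if (length(bad)) stop(sprintf("invalid %s label(s): %s", what,
                                  paste(bad, collapse = ", ")))
  }
  check_vocab(meta$diet_group, c("I5007", "control"), "diet_group")
  check_vocab(meta$oral_group, c("Oral", "Nonoral"), "oral_group")
  check_vocab(meta$health_label, c("healthy", "diarrhea", "unknown"), "health_label")
  meta
}

#' Convert counts to per-sample relative abundances
#'
#' @param table a [count_table()].
#' @return a `relative_abundance` object: the same axes with per-sample
#'   proportions summing to one.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "count_table"))
  ls <- library_sizes(table)
  if (any(ls == 0)) {
    stop("zero-sum sample(s): ", paste(names(ls)[ls == 0], collapse = ", "))
  }
  rel <- table$counts / ls
  structure(list(values = rel, taxonomy = table$taxonomy),
            class = "relative_abundance")
}

#' @export
print.relative_abundance <- function(x, ...) {
  cat(sprintf("relative_abundance: %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

rank_vocab <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[kpcofgs]__", "", p)
    p[p == ""] <- NA_character_
    p
  })
}

#' Collapse a count table at a taxonomic rank
#'
#' Counts are summed within identical lineage prefixes up to the requested
#' rank. Taxa whose lineage is unresolved at that rank are pooled under
#' `"unclassified_<deepest resolved name>"`. Total counts are conserved per
#' sample.
#'
#' @param table a [count_table()] with taxonomy attached.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return a collapsed [count_table()] whose taxon ids are lineage prefixes.
#' @export
collapse_rank <- function(table, rank) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$taxonomy)) stop("taxonomy is required to collapse ranks")
  if (!rank %in% rank_vocab[2:6]) {
    stop("rank must be one of: ", paste(rank_vocab[2:6], collapse = ", "))
  }
  depth <- match(rank, rank_vocab)
  lin <- parse_lineage(table$taxonomy)
  keys <- vapply(lin, function(p) {
    p <- p[!is.na(p)]
    if (length(p) >= depth) {
      paste(p[seq_len(depth)], collapse = ";")
    } else {
      parent <- if (length(p)) p[length(p)] else "root"
      paste0("unclassified_", parent)
    }
  }, character(1))
  groups <- split(seq_along(keys), keys)
  out <- vapply(groups, function(idx) {
    rowSums(table$counts[, idx, drop = FALSE])
  }, numeric(nrow(table$counts)))
  if (nrow(table$counts) == 1L) out <- matrix(out, nrow = 1L,
                                              dimnames = list(sample_ids(table), names(groups)))
  count_table(out)
}
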