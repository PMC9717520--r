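#' Rarefy a count table to a fixed sequencing depth
#'
#' Subsamples every sample's reads without replacement to a common depth
#' (hypergeometric rarefaction), mirroring the standard practice of
#' downsizing libraries to equalize sequencing effort. Samples with fewer
#' reads than `depth` are dropped and listed in the drop report.
#'
#' @param table a [count_table()].
#' @param depth target depth (positive integer).
#' @param seed integer seed; identical seeds give identical output.
#' @return a [count_table()] where every retained sample sums exactly to
#'   `depth`, with attribute `"dropped"` naming removed samples.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "count_table"))
  if (length(depth) != 1L || is.na(depth) || depth < 1) {
    stop("depth must be a positive integer")
  }
  depth <- as.integer(depth)
  ls <- library_sizes(table)
  keep <- ls >= depth
  if (!any(keep)) stop("no samples retained: all library sizes below depth")
  counts <- table$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(counts, 1L, function(x) {
      # draw `depth` reads without replacement from the read multiset
      reads <- rep.int(seq_along(x), x)
      drawn <- sample(reads, depth, replace = FALSE)
      tabulate(drawn, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(counts)
  res <- count_table(out, taxonomy = table$taxonomy)
  attr(res, "dropped") <- data.frame(
    sample_id = names(ls)[!keep],
    library_size = unname(ls[!keep]),
    stringsAsFactors = FALSE
  )
  res
}

#' Remove rare taxa by abundance and prevalence
#'
#' A taxon is removed iff its mean relative abundance is below
#' `abundance_cut` AND it is present (nonzero) in fewer than
#' `prevalence_cut` of the samples. The conjunctive reading follows the
#' filtering rule "relative abundance <0.01% and present in <20% across all
#' samples"; a disjunctive variant is available via `rule = "or"`.
#'
#' @param table a `relative_abundance` table.
#' @param abundance_cut mean relative-abundance threshold (default 1e-4,
#'   i.e. 0.01%).
#' @param prevalence_cut prevalence threshold as a fraction of samples
#'   (default 0.20).
#' @param rule `"and"` (default) or `"or"` combination of the two criteria.
#' @return the filtered `relative_abundance` table with attribute
#'   `"removed"`: a data.frame logging each removed taxon with its mean
#'   abundance and prevalence.
#' @export
filter_rare_taxa <- function(table, abundance_cut = 1e-4, prevalence_cut = 0.20,
                             rule = c("and", "or")) {
  stopifnot(inherits(table, "relative_abundance"))
  rule <- match.arg(rule)
  if (abundance_cut < 0 || abundance_cut > 1 || prevalence_cut < 0 || prevalence_cut > 1) {
    stop("cuts must lie in [0, 1]")
  }
  v <- table$values
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty table")
  mean_ab <- colMeans(v)
  prev <- colMeans(v > 0)
  low_ab <- mean_ab < abundance_cut
  low_prev <- prev < prevalence_cut
  drop <- if (rule == "and") low_ab & low_prev else low_ab | low_prev
  out <- structure(list(values = v[, !drop, drop = FALSE],
                        taxonomy = table$taxonomy[colnames(v)[!drop]]),
                   class = "relative_abundance")
  attr(out, "removed") <- data.frame(
    taxon_id = colnames(v)[drop],
    mean_abundance = unname(mean_ab[drop]),
    prevalence = unname(prev[drop]),
    stringsAsFactors = FALSE
  )
  out
}
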