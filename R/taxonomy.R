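#' Read a taxonomy assignment table
#'
#' Expects a TSV with columns `taxon_id`, `lineage`, `percent_identity`,
#' `percent_coverage` — the tabulated output of a reference-database
#' annotation run.
#'
#' @param path TSV file path.
#' @return A data frame with the four columns, percents validated to
#'   lie in \[0, 100\].
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("taxon_id", "lineage", "percent_identity", "percent_coverage")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("taxonomy table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_taxonomy(df)
}

validate_taxonomy <- function(records) {
  for (col in c("percent_identity", "percent_coverage")) {
    v <- records[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop(col, " must lie in [0, 100]", call. = FALSE)
  }
  records
}

#' Apply the annotation confidence filter
#'
#' Assignments are kept only when BOTH percent identity and percent
#' coverage strictly exceed their thresholds (defaults 90/90); all other
#' records have their lineage replaced by `"unclassified"`.  The record
#' count never changes.
#'
#' @param records data frame as returned by [read_taxonomy()].
#' @param min_identity,min_coverage thresholds in percent; comparisons
#'   are strict (`>`).
#' @return The same data frame with lineages of failing records set to
#'   `"unclassified"` and a logical `classified` column added.
#' @export
filter_taxonomy <- function(records, min_identity = 90, min_coverage = 90) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100)
  records <- validate_taxonomy(records)
  keep <- records$percent_identity > min_identity &
    records$percent_coverage > min_coverage
  keep[is.na(keep)] <- FALSE
  records$lineage[!keep] <- "unclassified"
  records$classified <- keep
  records
}

#' Dominant taxa at a grouping level
#'
#' Aggregates relative abundance to a higher level (typically phylum)
#' over a pooled set of samples.  Groups whose pooled fraction strictly
#' exceeds `threshold` (default 1%) are reported individually; the
#' remainder is summed into `"Others"`.  Taxa absent from `level_map`
#' fall into an `"unclassified"` group (reported via a message).
#'
#' @param table a relative `otu_table`.
#' @param level_map named character vector, taxon id -> group label.
#' @param threshold dominance threshold as a fraction (strict `>`).
#' @param samples sample ids to pool; default all samples.
#' @return Named numeric vector of fractions summing to 1, dominant
#'   groups first (descending), then `"Others"` if non-zero.
#' @export
dominant_taxa <- function(table, level_map, threshold = 0.01, samples = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (!is_relative(table)) stop("dominant_taxa needs a relative table", call. = FALSE)
  samples <- samples %||% colnames(table)
  missing_s <- setdiff(samples, colnames(table))
  if (length(missing_s))
    stop("unknown samples: ", paste(missing_s, collapse = ", "), call. = FALSE)
  x <- unclass(table)[, samples, drop = FALSE]
  groups <- unname(level_map[rownames(x)])
  unmapped <- is.na(groups)
  if (any(unmapped)) {
    message(sum(unmapped), " taxa missing from level_map assigned to 'unclassified'")
    groups[unmapped] <- "unclassified"
  }
  pooled <- rowSums(x) / length(samples)          # mean relative abundance
  frac <- tapply(pooled, groups, sum)
  frac <- frac / sum(frac)
  dominant <- frac[frac > threshold]
  others <- sum(frac[frac <= threshold])
  out <- sort(dominant, decreasing = TRUE)
  if (others > 0) out <- c(out, Others = unname(others))
  out
}
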