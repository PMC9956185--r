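#' OTU abundance table
#'
#' Constructs a validated OTU-by-sample abundance table.  Rows are taxa
#' (OTUs), columns are samples.  Counts must be non-negative and finite;
#' taxon and sample identifiers must be unique.  A relative table has
#' every sample column summing to 1.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   dimnames giving taxon and sample identifiers.
#' @param is_relative logical; `TRUE` when columns are relative
#'   proportions.
#' @return An object of class `otu_table` (a classed matrix).
#' @export
otu_table <- function(counts, is_relative = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(counts))) stop("counts must be finite", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is_relative) {
    cs <- colSums(counts)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad))
      stop("relative table columns must sum to 1: ",
           paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  }
  structure(counts, class = c("otu_table", "matrix"), is_relative = is_relative)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d taxa x %d samples (%s)\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_relative"))) "relative" else "counts"))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Test or query OTU table properties
#' @param x an `otu_table`.
#' @return `is_relative()` returns a logical flag; `taxon_ids()` and
#'   `sample_ids()` return character vectors.
#' @export
is_relative <- function(x) isTRUE(attr(x, "is_relative"))

#' @rdname is_relative
#' @export
taxon_ids <- function(x) rownames(x)

#' @rdname is_relative
#' @export
sample_ids <- function(x) colnames(x)

#' Read an OTU table from a tab-separated file
#'
#' The file has an identifier first column and a header row.  Orientation
#' `"taxa_rows"` means rows are taxa and columns are samples (the usual
#' layout for metabarcoding OTU tables); `"samples_rows"` the transpose.
#' With `"auto"` the table is assumed to be taxa-in-rows whenever it has
#' at least as many rows as samples columns, since OTUs almost always
#' outnumber samples; pass the orientation explicitly for small tables.
#'
#' @param path file path to a TSV file.
#' @param orientation `"auto"`, `"taxa_rows"`, or `"samples_rows"`.
#' @return An `otu_table` (counts as given in the file).
#' @export
read_otu_table <- function(path, orientation = c("auto", "taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("OTU table needs an id column and at least one data column",
                          call. = FALSE)
  ids <- raw[[1]]
  chr <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(num) & !(is.na(chr) | chr == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("malformed numeric cell '%s' at row '%s', column '%s'",
                 chr[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(raw)[-1][bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num)) stop("OTU table contains missing values", call. = FALSE)
  dimnames(num) <- list(ids, colnames(raw)[-1])
  if (orientation == "auto")
    orientation <- if (nrow(num) >= ncol(num)) "taxa_rows" else "samples_rows"
  if (orientation == "samples_rows") num <- t(num)
  otu_table(num)
}

#' Write an OTU table to a tab-separated file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip is lossless at double precision.
#'
#' @param table an `otu_table`.
#' @param path output file path.
#' @param id_column header for the taxon-id column.
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(table, path, id_column = "taxon_id") {
  stopifnot(inherits(table, "otu_table"))
  vals <- apply(unclass(table), 2, format_full)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(table))
  out <- cbind(rownames(table), vals)
  colnames(out) <- c(id_column, colnames(table))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average PCR replicates into one column per biological sample
#'
#' When the metadata carries a `replicate` column, the table's replicate
#' columns are averaged (mean abundance per taxon) into a single column
#' per `sample_id`-without-replicate group.  Tables without replicates
#' are returned unchanged.  Downstream analyses may instead keep
#' replicates as distinct samples, as ordinations often plot them.
#'
#' @param table an `otu_table` whose columns are replicate sample ids.
#' @param meta a `sample_metadata` with a `replicate` column; replicates
#'   of one biological sample share `site_id` and `layer`.  The
#'   collapsed column keeps the first replicate's sample id.
#' @return An `otu_table` with one column per (site, layer) group.
#' @export
average_replicates <- function(table, meta) {
  stopifnot(inherits(table, "otu_table"))
  if (!"replicate" %in% names(meta)) return(table)
  i <- match(colnames(table), meta$sample_id)
  if (anyNA(i)) stop("table samples missing from metadata", call. = FALSE)
  grp <- paste(meta$site_id[i], meta$layer[i], sep = "\x1f")
  keep <- !duplicated(grp)
  out <- vapply(grp[keep], function(g)
    rowMeans(unclass(table)[, grp == g, drop = FALSE]),
    numeric(nrow(table)))
  colnames(out) <- colnames(table)[keep]
  otu_table(out, is_relative = is_relative(table))
}

#' Convert counts to relative proportions
#'
#' Divides every sample column by its sum.  Idempotent on an
#' already-relative table.
#'
#' @param table an `otu_table`.
#' @return A relative `otu_table` whose columns sum to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  cs <- colSums(table)
  zero <- which(cs <= 0)
  if (length(zero))
    stop("sample column sums to zero: ",
         paste(colnames(table)[zero], collapse = ", "), call. = FALSE)
  otu_table(sweep(unclass(table), 2, cs, "/"), is_relative = TRUE)
}
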