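#' Read and validate sample metadata
#'
#' Metadata is a CSV with mandatory columns `sample_id`, `site_id`,
#' `layer`, `latitude`, `longitude`; any further numeric columns are
#' treated as environmental variables (e.g. `salinity`, `DO`,
#' `turbidity`, `TALK`, `depth`, `offshore_distance`).  An optional
#' `replicate` column tags PCR replicates.  Missing environmental values
#' are kept as `NA` and excluded pairwise downstream, never imputed.
#'
#' @param path CSV file path.
#' @return A data frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df a data frame with the columns described above.
#' @export
sample_metadata <- function(df) {
  needed <- c("sample_id", "site_id", "layer", "latitude", "longitude")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("metadata lacks mandatory columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (!all(df$layer %in% c("surface", "bottom")))
    stop("layer must be 'surface' or 'bottom'", call. = FALSE)
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE) || anyNA(df$latitude))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE) || anyNA(df$longitude))
    stop("longitude out of [-180, 180]", call. = FALSE)
  env <- setdiff(names(df), c(needed, "replicate"))
  env <- env[vapply(df[env], is.numeric, logical(1))]
  bad <- env[vapply(df[env], function(x) any(!is.finite(x) & !is.na(x)), logical(1))]
  if (length(bad))
    stop("non-finite environmental values in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(df, class = c("sample_metadata", "data.frame"), env_vars = env)
}

#' Environmental variable names in a metadata table
#' @param meta a `sample_metadata`.
#' @return Character vector of environmental column names.
#' @export
env_variables <- function(meta) attr(meta, "env_vars")

#' Write sample metadata to CSV
#' @param meta a `sample_metadata`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag hypoxic samples
#'
#' A sample is hypoxic when its dissolved oxygen is strictly below the
#' threshold (default 2 mg/L, the conventional hypoxia standard).
#'
#' @param meta a `sample_metadata` with a `DO` column (mg/L).
#' @param threshold hypoxia threshold in mg/L.
#' @return Named logical vector over samples with non-missing DO;
#'   samples with missing DO are omitted with a warning.
#' @export
flag_hypoxia <- function(meta, threshold = 2.0) {
  if (!"DO" %in% names(meta)) stop("metadata has no DO column", call. = FALSE)
  do <- meta$DO
  names(do) <- meta$sample_id
  if (anyNA(do)) {
    warning("samples with missing DO omitted: ",
            paste(names(do)[is.na(do)], collapse = ", "))
    do <- do[!is.na(do)]
  }
  do < threshold
}
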