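#' Symmetric sample-by-sample matrix
#'
#' Light container for the pairwise quantities the pipeline moves around:
#' Bray-Curtis dissimilarity, great-circle distance in km, beta nearest
#' taxon index, Raup-Crick values, and patristic distances between taxa.
#' Dissimilarity-like kinds must have a zero diagonal and non-negative
#' entries; Bray-Curtis is additionally bounded by 1.
#'
#' @param values square numeric matrix with matching dimnames.
#' @param kind one of `"braycurtis"`, `"geographic_km"`, `"bnti"`,
#'   `"rcbray"`, `"phylo_patristic"`.
#' @return A matrix of class `pairwise_matrix` with a `kind` attribute.
#' @export
pairwise_matrix <- function(values,
                            kind = c("braycurtis", "geographic_km", "bnti",
                                     "rcbray", "phylo_patristic")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("pairwise matrix must be square", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("pairwise matrix needs row and column labels", call. = FALSE)
  if (!identical(rownames(values), colnames(values)))
    stop("row and column labels differ", call. = FALSE)
  finite <- values[is.finite(values)]
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("matrix is not symmetric within 1e-12", call. = FALSE)
  if (kind %in% c("braycurtis", "geographic_km", "phylo_patristic")) {
    if (any(abs(diag(values)) > 1e-12))
      stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
    if (any(finite < -1e-12))
      stop("dissimilarity values must be non-negative", call. = FALSE)
  }
  if (kind == "braycurtis" && any(finite > 1 + 1e-12))
    stop("Bray-Curtis values must lie in [0, 1]", call. = FALSE)
  structure(values, class = c("pairwise_matrix", "matrix"), kind = kind)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix (%s): %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

# labels of a pairwise matrix
pm_labels <- function(x) rownames(x)

# upper-triangle index pairs (i < j) as a two-column integer matrix
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
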