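#' Great-circle distance matrix between samples
#'
#' Haversine distances on a sphere of radius `radius_km` between the
#' coordinates of all samples in a metadata table.
#'
#' @param meta a `sample_metadata` (or data frame with `sample_id`,
#'   `latitude`, `longitude`).
#' @param radius_km sphere radius; default the IUGG mean Earth radius
#'   6371.0088 km.
#' @return A `pairwise_matrix` of kind `"geographic_km"`.
#' @export
haversine_matrix <- function(meta, radius_km = 6371.0088) {
  lat <- meta$latitude
  lon <- meta$longitude
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates out of range", call. = FALSE)
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(phi)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  dk <- 2 * radius_km * asin(sqrt(a))
  dk <- (dk + t(dk)) / 2
  diag(dk) <- 0
  dimnames(dk) <- list(meta$sample_id, meta$sample_id)
  pairwise_matrix(dk, "geographic_km")
}

#' Distance-decay of community similarity
#'
#' Relates Bray-Curtis similarity (`1 - BC`) to geographic distance over
#' all sample pairs: Spearman rank correlation with a Mantel-style
#' permutation test (sample labels of the similarity matrix are permuted,
#' which respects the non-independence of pairwise entries), plus an
#' ordinary least-squares line for plotting.
#'
#' @param bc Bray-Curtis `pairwise_matrix`.
#' @param geo geographic `pairwise_matrix` with identical labels.
#' @param permutations number of label permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return An object of class `decay_fit`: list with `rho`, `p_value`
#'   (two-sided permutation p), `slope`, `intercept`, `n_pairs`,
#'   `permutations`, `seed`.
#' @export
distance_decay <- function(bc, geo, permutations = 999, seed = 42) {
  bc <- as.matrix(bc)
  geo <- as.matrix(geo)
  if (!identical(rownames(bc), rownames(geo)))
    stop("sample labels of the two matrices differ", call. = FALSE)
  stopifnot(permutations >= 99)
  m <- nrow(bc)
  ut <- upper.tri(bc)
  sim <- 1 - bc
  sim_v <- sim[ut]
  dist_v <- geo[ut]
  rd <- rank(dist_v)
  rho_obs <- cor(rank(sim_v), rd)
  exceed <- local_seed(seed, {
    count <- 0L
    for (p in seq_len(permutations)) {
      pm <- sample.int(m)
      sv <- sim[pm, pm][ut]
      if (abs(cor(rank(sv), rd)) >= abs(rho_obs) - 1e-12) count <- count + 1L
    }
    count
  })
  p_value <- (exceed + 1) / (permutations + 1)
  fit <- lm(sim_v ~ dist_v)
  structure(list(rho = rho_obs, p_value = p_value,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n_pairs = length(sim_v), permutations = permutations,
                 seed = seed),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("distance-decay: rho = %.3f, p = %.4g (%d perms), slope = %.3g /km, n = %d pairs\n",
              x$rho, x$p_value, x$permutations, x$slope, x$n_pairs))
  invisible(x)
}

#' @importFrom stats coef
NULL
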