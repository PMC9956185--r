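#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` in nats, with `p_i` the relative abundance of
#' taxa with positive abundance.  Scale-invariant, so counts and
#' relative proportions give the same value.
#'
#' @param x non-negative abundance vector with at least one positive
#'   entry.
#' @return Shannon index in nats, `0 <= H <= log(richness)`.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  x <- x[x > 0]
  if (!length(x)) stop("all-zero abundance vector", call. = FALSE)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of an OTU table
#' @param table an `otu_table`.
#' @return Named numeric vector of Shannon indices, one per sample.
#' @export
shannon_index <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  apply(unclass(table), 2, shannon)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(A, B) = sum |a_i - b_i| / sum (a_i + b_i)`, computed on the table
#' as given (counts or relative).  Identical samples give 0, samples
#' with disjoint taxon support give 1.
#'
#' @param table an `otu_table` with no zero-sum sample.
#' @return A `pairwise_matrix` of kind `"braycurtis"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  x <- unclass(table)
  cs <- colSums(x)
  zero <- which(cs <= 0)
  if (length(zero))
    stop("zero-sum sample: ", paste(colnames(x)[zero], collapse = ", "),
         call. = FALSE)
  num <- as.matrix(dist(t(x), method = "manhattan"))
  bc <- num / outer(cs, cs, "+")
  diag(bc) <- 0
  pairwise_matrix(bc, "braycurtis")
}

#' Spearman correlations between alpha diversity and environment
#'
#' Rank correlation (mid-ranks for ties) of a per-sample statistic,
#' typically the Shannon index, against each environmental variable.
#' Two-sided p values use the t approximation.  Pairs with missing
#' values are dropped per variable; no multiple-testing correction is
#' applied by default (Benjamini-Hochberg available via `adjust`).
#'
#' @param alpha named numeric vector, sample id -> value.
#' @param meta a `sample_metadata`.
#' @param variables environmental columns to test; default all.
#' @param adjust logical; add Benjamini-Hochberg adjusted p values.
#' @return Data frame with columns `variable`, `n`, `rho`, `p`
#'   (and `p_adj` when `adjust = TRUE`).
#' @export
spearman_env <- function(alpha, meta, variables = NULL, adjust = FALSE) {
  variables <- variables %||% env_variables(meta)
  h <- alpha[match(meta$sample_id, names(alpha))]
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    ok <- !is.na(x) & !is.na(h)
    n <- sum(ok)
    if (n < 4)
      return(data.frame(variable = v, n = n, rho = NA_real_, p = NA_real_))
    if (sd(x[ok]) == 0 || sd(h[ok]) == 0) {
      warning("constant values for ", v, "; rho undefined")
      return(data.frame(variable = v, n = n, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(h[ok], x[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(variable = v, n = n, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Welch two-sample t test of an environmental variable between layers
#'
#' @param meta a `sample_metadata`.
#' @param variable environmental column name.
#' @param group grouping column, default `"layer"`.
#' @return List with `t`, `p`, `df`, and the two group means.
#' @export
group_ttest <- function(meta, variable, group = "layer") {
  x <- meta[[variable]]
  g <- meta[[group]]
  if (is.null(x)) stop("unknown variable: ", variable, call. = FALSE)
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  counts <- table(g)
  if (length(counts) != 2 || any(counts < 2))
    stop("need two groups with at least 2 observations each", call. = FALSE)
  gs <- split(x, g)
  if (all(vapply(gs, var, numeric(1)) == 0)) {
    # degenerate Welch case: no within-group variance
    dm <- mean(gs[[1]]) - mean(gs[[2]])
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf,
                p = if (dm == 0) 1 else 0,
                df = NA_real_,
                means = vapply(gs, mean, numeric(1))))
  }
  tt <- t.test(x ~ g)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       means = tt$estimate)
}

#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test), used to
#' compare Shannon diversity between sample groups.
#'
#' @param groups named list of numeric vectors, one per group; at least
#'   two groups with at least two values each.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- sum(n) - length(groups)
  if (ssw <= 0)
    stop("degenerate groups: zero within-group variance, F undefined",
         call. = FALSE)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}
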