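# Two-stage null-model quantification of community assembly:
# phylogenetic stage (betaMNTD -> betaNTI by taxa-label randomisation)
# followed by a taxonomic stage (Raup-Crick on Bray-Curtis), with
# per-pair classification into selection / dispersal / undominated
# processes and per-stratum fraction summaries.

#' Patristic distances between tree tips
#'
#' Sum of branch lengths on the path between each pair of requested
#' tips, after pruning the tree to those tips.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param taxa tip labels to keep; default all tips.
#' @return A `pairwise_matrix` of kind `"phylo_patristic"` with rows and
#'   columns ordered as `taxa`.
#' @export
patristic_distances <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- taxa %||% tree$tip.label
  absent <- setdiff(taxa, tree$tip.label)
  if (length(absent))
    stop("taxa missing from tree: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  pruned <- if (length(taxa) < length(tree$tip.label))
    ape::keep.tip(tree, taxa) else tree
  d <- ape::cophenetic.phylo(pruned)[taxa, taxa]
  d <- (d + t(d)) / 2
  pairwise_matrix(d, "phylo_patristic")
}

# validate + index a community vector against the distance labels
community_index <- function(x, labels, what) {
  if (is.null(names(x))) stop(what, " must be a named abundance vector", call. = FALSE)
  x <- x[labels]
  if (anyNA(x)) stop(what, " is not aligned to the distance labels", call. = FALSE)
  idx <- which(x > 0)
  if (!length(idx)) stop(what, " is an empty community", call. = FALSE)
  list(idx = idx, w = unname(x[idx] / sum(x[idx])))
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted mean, over the taxa of each community, of the
#' phylogenetic distance to the nearest taxon present in the other
#' community, averaged across the two directions:
#' `0.5 * (sum_i f_iA min_j d_ij + sum_j f_jB min_i d_ij)`.
#' A taxon shared by both communities has nearest-taxon distance 0, so
#' identical communities give 0.
#'
#' @param rel_a,rel_b named relative-abundance vectors over (a superset
#'   of) the taxa of `d`.
#' @param d `pairwise_matrix` of patristic distances.
#' @param weighted abundance-weighted (default) or presence/absence.
#' @return betaMNTD value (same units as the branch lengths).
#' @export
bmntd <- function(rel_a, rel_b, d, weighted = TRUE) {
  labels <- pm_labels(d)
  a <- community_index(rel_a, labels, "rel_a")
  b <- community_index(rel_b, labels, "rel_b")
  if (!weighted) {
    a$w <- rep(1 / length(a$idx), length(a$idx))
    b$w <- rep(1 / length(b$idx), length(b$idx))
  }
  cpp_bmntd(unclass(d), a$idx - 1L, b$idx - 1L, a$w, b$w)
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against a null distribution obtained
#' by shuffling taxa labels across the tips of the phylogeny: abundances
#' stay fixed while phylogenetic positions are permuted uniformly, and
#' betaMNTD is recomputed each rep.  `|betaNTI| > 2` is the conventional
#' signature of selection.
#'
#' @inheritParams bmntd
#' @param reps number of label permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return List with `bmntd_obs`, `bnti`, `null_mean`, `null_sd`,
#'   `reps`, `seed`.
#' @export
bnti <- function(rel_a, rel_b, d, reps = 999, seed = 42, weighted = TRUE) {
  stopifnot(reps >= 99)
  labels <- pm_labels(d)
  n <- length(labels)
  a <- community_index(rel_a, labels, "rel_a")
  b <- community_index(rel_b, labels, "rel_b")
  if (!weighted) {
    a$w <- rep(1 / length(a$idx), length(a$idx))
    b$w <- rep(1 / length(b$idx), length(b$idx))
  }
  obs <- cpp_bmntd(unclass(d), a$idx - 1L, b$idx - 1L, a$w, b$w)
  perms <- local_seed(seed,
    vapply(seq_len(reps), function(i) sample.int(n), integer(n))) - 1L
  null <- cpp_bmntd_null(unclass(d), a$idx - 1L, b$idx - 1L, a$w, b$w, perms)
  null_sd <- sd(null)
  if (!is.finite(null_sd) || null_sd < 1e-12)
    stop("degenerate null: betaMNTD is invariant under taxa shuffles ",
         "(e.g. star phylogeny); betaNTI is uninformative", call. = FALSE)
  list(bmntd_obs = obs, bnti = (obs - mean(null)) / null_sd,
       null_mean = mean(null), null_sd = null_sd, reps = reps, seed = seed)
}

bc_pair <- function(xa, xb) sum(abs(xa - xb)) / (sum(xa) + sum(xb))

#' Raup-Crick metric on Bray-Curtis (RCbray)
#'
#' Position of the observed Bray-Curtis dissimilarity of two samples
#' within a null distribution of probabilistically reassembled
#' communities.  Each rep assembles both null communities independently:
#' the observed richness of the sample is drawn from the regional pool
#' without replacement with probability proportional to occurrence
#' frequency (number of samples in which the taxon occurs), then the
#' observed total count is allocated across the drawn taxa by sampling
#' with replacement with probability proportional to regional relative
#' abundance.  `RC = 2 * ((#\{BC_null < BC_obs\} + 0.5 #\{BC_null =
#' BC_obs\}) / reps - 0.5)`, bounded in \[-1, 1\]; ties count half.
#'
#' @param table an `otu_table` of integer counts (the regional pool is
#'   derived from the whole table).
#' @param a,b sample ids of the pair.
#' @param reps null reps (>= 99; default 999).
#' @param seed RNG seed.
#' @return List with `bc_obs`, `rc`, `reps`, `seed`.
#' @export
raup_crick_bc <- function(table, a, b, reps = 999, seed = 42) {
  stopifnot(inherits(table, "otu_table"), reps >= 99)
  if (is_relative(table))
    stop("raup_crick_bc needs integer counts; reconstitute with ",
         "reconstitute_counts()", call. = FALSE)
  x <- unclass(table)
  if (max(abs(x - round(x))) > 1e-9)
    stop("raup_crick_bc needs integer counts", call. = FALSE)
  for (s in c(a, b)) if (!s %in% colnames(x)) stop("unknown sample: ", s, call. = FALSE)
  occ <- rowSums(x > 0)
  pool <- rowSums(x) / sum(x)
  xa <- x[, a]; xb <- x[, b]
  if (sum(xa) <= 0 || sum(xb) <= 0) stop("zero-count sample", call. = FALSE)
  rich_a <- sum(xa > 0); rich_b <- sum(xb > 0)
  pool_size <- sum(occ > 0)
  if (rich_a > pool_size || rich_b > pool_size)
    stop("sample richness exceeds regional pool size", call. = FALSE)
  bc_obs <- bc_pair(xa, xb)
  null <- local_seed(seed,
    cpp_rc_null(occ, pool, rich_a, as.integer(sum(xa)),
                rich_b, as.integer(sum(xb)), as.integer(reps)))
  list(bc_obs = bc_obs, rc = rc_score(null, bc_obs), reps = reps, seed = seed)
}

# Raup-Crick rescaling of an observed value against its null distribution:
# 2 * ((#{null < obs} + 0.5 #{null = obs}) / reps - 0.5), in [-1, 1];
# ties count half, so the statistic is bounded and symmetric.
rc_score <- function(null, obs) {
  2 * ((sum(null < obs) + 0.5 * sum(null == obs)) / length(null) - 0.5)
}

#' Reconstitute integer counts from a relative table
#'
#' Multiplies each sample column by `depth` and rounds by largest
#' remainder so that every column sums exactly to `depth`.  Used before
#' the Raup-Crick stage when only relative proportions are available;
#' the chosen depth changes the null variance and is therefore recorded
#' in run manifests.
#'
#' @param table a relative `otu_table`.
#' @param depth individuals per sample (default 10000).
#' @return An integer-count `otu_table`.
#' @export
reconstitute_counts <- function(table, depth = 10000) {
  stopifnot(inherits(table, "otu_table"))
  x <- apply(unclass(table), 2, largest_remainder, total = depth)
  rownames(x) <- rownames(table)
  otu_table(x)
}

process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Classify a sample pair into an assembly process
#'
#' Two-stage decision rule: `betaNTI > +thresh` means heterogeneous
#' selection, `betaNTI < -thresh` homogeneous selection; otherwise
#' `RC > +rc_thresh` means dispersal limitation, `RC < -rc_thresh`
#' homogenizing dispersal, and anything else is undominated (drift plus
#' weak selection/dispersal).  Defaults 2 and 0.95.  Vectorised.
#'
#' @param bnti betaNTI value(s).
#' @param rc RCbray value(s).
#' @param bnti_thresh,rc_thresh positive decision thresholds.
#' @return Factor with levels heterogeneous_selection,
#'   homogeneous_selection, dispersal_limitation,
#'   homogenizing_dispersal, undominated.
#' @export
classify_pair <- function(bnti, rc, bnti_thresh = 2, rc_thresh = 0.95) {
  stopifnot(bnti_thresh > 0, rc_thresh > 0)
  if (any(!is.finite(bnti)) || any(!is.finite(rc)))
    stop("non-finite betaNTI or RC", call. = FALSE)
  out <- ifelse(bnti > bnti_thresh, "heterogeneous_selection",
         ifelse(bnti < -bnti_thresh, "homogeneous_selection",
         ifelse(rc > rc_thresh, "dispersal_limitation",
         ifelse(rc < -rc_thresh, "homogenizing_dispersal", "undominated"))))
  factor(out, levels = process_levels)
}

#' Per-pair assembly analysis of a community table
#'
#' Runs the two-stage null model over sample pairs: betaNTI from
#' taxa-label shuffles on the phylogeny, then RCbray for pairs not
#' dominated by selection, and classifies each pair.  Pairs are
#' processed with independent derived seeds
#' (`derive_seed(seed, sample_a, sample_b)`), so results do not depend
#' on processing order and pairs may be computed concurrently.
#'
#' @param table an `otu_table` (counts preferred; a relative table is
#'   reconstituted to counts at `depth`).
#' @param tree rooted `phylo` tree whose tips cover the table's taxa.
#' @param meta optional `sample_metadata`; when given, the default pair
#'   universe is within-layer pairs only.
#' @param reps null reps for both stages.
#' @param seed global seed; every pair derives its own stream from it.
#' @param bnti_thresh,rc_thresh classification thresholds.
#' @param depth reconstitution depth for relative tables.
#' @param pairs optional two-column character matrix of sample pairs.
#' @param weighted abundance-weighted betaMNTD (default).
#' @return Data frame of class `pair_assembly` with columns `sample_a`,
#'   `sample_b`, `bmntd_obs`, `bnti`, `bc_obs`, `rc`, `process`.
#' @export
assembly_analysis <- function(table, tree, meta = NULL, reps = 999, seed = 42,
                              bnti_thresh = 2, rc_thresh = 0.95,
                              depth = 10000, pairs = NULL, weighted = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  counts <- if (is_relative(table)) reconstitute_counts(table, depth) else table
  rel <- to_relative(counts)
  d <- patristic_distances(tree, taxon_ids(counts))
  samples <- sample_ids(counts)
  if (is.null(pairs)) {
    if (!is.null(meta)) {
      layer <- meta$layer[match(samples, meta$sample_id)]
      keep <- !is.na(layer)
      pr <- upper_pairs(length(samples))
      pr <- pr[keep[pr[, 1]] & keep[pr[, 2]] &
                 layer[pr[, 1]] == layer[pr[, 2]], , drop = FALSE]
    } else {
      pr <- upper_pairs(length(samples))
    }
    pairs <- cbind(samples[pr[, 1]], samples[pr[, 2]])
  }
  if (nrow(pairs) == 0) stop("no sample pairs to analyse", call. = FALSE)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    nt <- bnti(rel[, a], rel[, b], d, reps = reps,
               seed = derive_seed(seed, "bnti", a, b), weighted = weighted)
    rcres <- raup_crick_bc(counts, a, b, reps = reps,
                           seed = derive_seed(seed, "rc", a, b))
    res[[i]] <- data.frame(sample_a = a, sample_b = b,
                           bmntd_obs = nt$bmntd_obs, bnti = nt$bnti,
                           bc_obs = rcres$bc_obs, rc = rcres$rc)
  }
  out <- do.call(rbind, res)
  out$process <- classify_pair(out$bnti, out$rc, bnti_thresh, rc_thresh)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "thresholds") <- c(bnti = bnti_thresh, rc = rc_thresh)
  class(out) <- c("pair_assembly", "data.frame")
  out
}

#' Per-site distribution of assembly processes
#'
#' Pairwise classifications have no canonical single-site mapping; as an
#' interpretation, each site is summarised by the distribution of
#' process labels over all pairs involving any of its samples.
#'
#' @param pairs a `pair_assembly` data frame.
#' @param meta a `sample_metadata` mapping samples to sites.
#' @return Data frame with columns `site_id`, `process`, `fraction`,
#'   `n_pairs`.
#' @export
site_process_fractions <- function(pairs, meta) {
  site_of <- function(s) meta$site_id[match(s, meta$sample_id)]
  sa <- site_of(pairs$sample_a)
  sb <- site_of(pairs$sample_b)
  rows <- lapply(sort(unique(c(sa, sb))), function(site) {
    sub <- pairs[sa == site | sb == site, , drop = FALSE]
    tab <- table(factor(sub$process, levels = process_levels))
    data.frame(site_id = site, process = names(tab),
               fraction = as.numeric(tab) / max(nrow(sub), 1L),
               n_pairs = nrow(sub), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Regional fractions of assembly processes
#'
#' Fraction of sample pairs assigned to each process, per stratum.  A
#' layer stratum keeps only pairs whose two samples are both in that
#' layer; `"all"` keeps every pair.  Fractions within a stratum sum
#' to 1.
#'
#' @param pairs a `pair_assembly` data frame.
#' @param meta a `sample_metadata` (needed for layer strata).
#' @param strata subset of `c("surface", "bottom", "all")`.
#' @return Data frame with columns `stratum`, `process`, `fraction`,
#'   `n_pairs`.
#' @export
summarize_processes <- function(pairs, meta = NULL,
                                strata = c("surface", "bottom", "all")) {
  strata <- match.arg(strata, several.ok = TRUE)
  layer_of <- function(s) meta$layer[match(s, meta$sample_id)]
  rows <- list()
  for (st in strata) {
    sub <- if (st == "all") pairs else {
      if (is.null(meta)) stop("layer strata need metadata", call. = FALSE)
      pairs[layer_of(pairs$sample_a) == st & layer_of(pairs$sample_b) == st, ,
            drop = FALSE]
    }
    if (nrow(sub) == 0) {
      warning("empty stratum omitted: ", st)
      next
    }
    tab <- table(factor(sub$process, levels = process_levels))
    rows[[st]] <- data.frame(stratum = st, process = names(tab),
                             fraction = as.numeric(tab) / nrow(sub),
                             n_pairs = nrow(sub), row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
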