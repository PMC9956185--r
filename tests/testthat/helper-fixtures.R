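# Fixtures and independent oracles shared across the test files.
# Oracles are deliberately written as naive brute-force code, never
# calling the implementation paths they check.

as_matrix <- function(tb) {
  m <- unclass(tb)
  attr(m, "is_relative") <- NULL
  m
}

# iid-multinomial world: m samples drawn from one log-normal pool
make_neutral_table <- function(S = 100, m = 40, depth = 1000, sdlog = 1.5,
                               seed = 1) {
  withr::with_seed(seed, {
    pool <- rlnorm(S, 0, sdlog)
    pool <- pool / sum(pool)
    counts <- vapply(seq_len(m), function(i) rmultinom(1, depth, pool)[, 1],
                     integer(S))
    dimnames(counts) <- list(paste0("OTU_", seq_len(S)),
                             paste0("S", seq_len(m)))
    otu_table(counts)
  })
}

random_counts_table <- function(S = 20, m = 6, seed = 1, max_count = 50) {
  withr::with_seed(seed, {
    x <- matrix(rpois(S * m, lambda = 5), S, m)
    x[sample(length(x), length(x) %/% 3)] <- 0
    x[, colSums(x) == 0] <- 1   # keep all samples non-empty
    dimnames(x) <- list(paste0("OTU_", seq_len(S)), paste0("S", seq_len(m)))
    otu_table(x)
  })
}

random_tree <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n, 1, 0.25)
    tr$tip.label <- paste0("OTU_", seq_len(n))
    tr
  })
}

tiny_meta <- function(n = 6, seed = 1) {
  withr::with_seed(seed, sample_metadata(data.frame(
    sample_id = paste0("S", seq_len(n)),
    site_id = paste0("site", rep(seq_len(ceiling(n / 2)), each = 2))[seq_len(n)],
    layer = rep(c("surface", "bottom"), length.out = n),
    latitude = runif(n, 21, 23), longitude = runif(n, 112, 115),
    DO = runif(n, 0.5, 9), salinity = runif(n, 2, 32),
    turbidity = runif(n, 1, 20), TALK = runif(n, 1.5, 2.5),
    depth = runif(n, 1, 20), offshore_distance = runif(n, 2, 90))))
}

# --- independent oracles ------------------------------------------------

# betaMNTD by naive double loop over taxa
bmntd_oracle <- function(rel_a, rel_b, dmat) {
  ia <- names(rel_a)[rel_a > 0]
  ib <- names(rel_b)[rel_b > 0]
  wa <- rel_a[ia] / sum(rel_a[ia])
  wb <- rel_b[ib] / sum(rel_b[ib])
  s <- 0
  for (i in ia) s <- s + wa[i] * min(sapply(ib, function(j) dmat[i, j]))
  for (j in ib) s <- s + wb[j] * min(sapply(ia, function(i) dmat[i, j]))
  s / 2
}

# patristic distances by Floyd-Warshall on the tree's edge graph
patristic_oracle <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  d <- matrix(Inf, nn, nn)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    d[a, b] <- d[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(nn)) for (i in seq_len(nn)) for (j in seq_len(nn))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  ntip <- length(tree$tip.label)
  out <- d[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# pure-R re-implementation of the Raup-Crick null community sampler,
# using a different RNG consumption pattern than the C++ path
rc_null_oracle <- function(counts, a, b, reps, seed) {
  occ <- rowSums(counts > 0)
  pool <- rowSums(counts) / sum(counts)
  S <- nrow(counts)
  draw <- function(rich, tot) {
    taxa <- sample.int(S, rich, replace = FALSE, prob = occ)
    x <- numeric(S)
    x[taxa] <- 1
    extra <- tot - rich
    if (extra > 0) {
      p <- pool[taxa] / sum(pool[taxa])
      picked <- sample(taxa, extra, replace = TRUE, prob = p)
      tab <- table(factor(picked, levels = taxa))
      x[taxa] <- x[taxa] + as.numeric(tab)
    }
    x
  }
  xa <- counts[, a]; xb <- counts[, b]
  withr::with_seed(seed, {
    null <- replicate(reps, {
      na <- draw(sum(xa > 0), sum(xa))
      nb <- draw(sum(xb > 0), sum(xb))
      sum(abs(na - nb)) / (sum(na) + sum(nb))
    })
  })
  obs <- sum(abs(xa - xb)) / (sum(xa) + sum(xb))
  2 * ((sum(null < obs) + 0.5 * sum(null == obs)) / reps - 0.5)
}
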