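test_that("patristic distances match trivial trees and the Floyd-Warshall oracle", {
  tr <- ape::read.tree(text = "(A:1,B:2);")
  d <- patristic_distances(tr)
  expect_equal(d[["A", "B"]], 3)

  # ultrametric 4-tip tree: all root-spanning pairs equal
  tr2 <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
  d2 <- patristic_distances(tr2)
  expect_equal(d2[["A", "C"]], 6)
  expect_equal(d2[["A", "D"]], 6)
  expect_equal(d2[["B", "C"]], 6)
  expect_equal(d2[["B", "D"]], 6)

  tr3 <- random_tree(20, seed = 31)
  expect_equal(unclass(patristic_distances(tr3)),
               patristic_oracle(tr3)[tr3$tip.label, tr3$tip.label],
               tolerance = 1e-10, ignore_attr = "kind")

  expect_error(patristic_distances(tr, c("A", "Z")), "Z")
})

rel_vec <- function(x, labels) {
  v <- setNames(numeric(length(labels)), labels)
  v[names(x)] <- x
  v / sum(v)
}

test_that("betaMNTD matches closed forms and the double-loop oracle", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")
  d <- patristic_distances(tr)
  lab <- rownames(d)

  # identical communities share every taxon -> 0
  a <- rel_vec(c(A = 0.5, C = 0.5), lab)
  expect_equal(bmntd(a, a, d), 0)

  # two single-taxon communities -> their patristic distance
  expect_equal(bmntd(rel_vec(c(A = 1), lab), rel_vec(c(D = 1), lab), d),
               d[["A", "D"]])

  # random 6-taxon pairs on a random tree vs oracle, plus symmetry
  tr6 <- random_tree(6, seed = 17)
  d6 <- patristic_distances(tr6)
  for (s in 1:10) {
    ab <- withr::with_seed(s, {
      a <- runif(6) * rbinom(6, 1, 0.7)
      b <- runif(6) * rbinom(6, 1, 0.7)
      a[1] <- a[1] + 0.1; b[6] <- b[6] + 0.1  # keep non-empty
      list(a = setNames(a / sum(a), rownames(d6)),
           b = setNames(b / sum(b), rownames(d6)))
    })
    got <- bmntd(ab$a, ab$b, d6)
    expect_equal(got, unname(bmntd_oracle(ab$a, ab$b, unclass(d6))))
    expect_equal(got, bmntd(ab$b, ab$a, d6))
  }
})

test_that("betaNTI matches exact permutation enumeration and is deterministic", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")
  d <- patristic_distances(tr)
  lab <- rownames(d)
  a <- rel_vec(c(A = 0.6, B = 0.4), lab)
  b <- rel_vec(c(C = 0.7, D = 0.3), lab)

  # exhaustive 4! tip-label permutations via the R oracle
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  vals <- apply(perms, 1, function(p) {
    dp <- unclass(d)[p, p]
    dimnames(dp) <- list(lab, lab)
    bmntd_oracle(a, b, dp)
  })
  obs <- bmntd_oracle(a, b, unclass(d))
  z_exact <- (obs - mean(vals)) / sd(vals)

  mc <- bnti(a, b, d, reps = 10000, seed = 8)
  expect_equal(mc$bmntd_obs, unname(obs))
  expect_lt(abs(mc$bnti - z_exact), 0.1)
  expect_identical(bnti(a, b, d, reps = 499, seed = 3),
                   bnti(a, b, d, reps = 499, seed = 3))
})

test_that("betaNTI reports a degenerate null on a star phylogeny", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  d <- patristic_distances(star)
  a <- rel_vec(c(A = 0.5, B = 0.5), rownames(d))
  b <- rel_vec(c(C = 0.5, D = 0.5), rownames(d))
  expect_error(bnti(a, b, d, reps = 99), "degenerate null")
})

test_that("Raup-Crick scoring hits its definition boundaries and is monotone", {
  rc <- ecoassembly:::rc_score
  null <- c(0.2, 0.3, 0.4)
  expect_equal(rc(null, 0.5), 1)       # obs above every null
  expect_equal(rc(null, 0.1), -1)      # obs below every null
  expect_equal(rc(null, 0.3), 2 * ((1 + 0.5) / 3 - 0.5))  # tie counts half
  # monotone non-decreasing in the observed value, fixed null
  obs_grid <- seq(0, 1, by = 0.01)
  vals <- sapply(obs_grid, rc, null = withr::with_seed(2, runif(200)))
  expect_true(all(diff(vals) >= 0))
})

test_that("RCbray end-to-end: identical pair gives -1; oracle agreement", {
  tb <- make_neutral_table(S = 20, m = 8, depth = 100, sdlog = 1, seed = 4)
  x <- unclass(tb)
  x[, "S2"] <- x[, "S1"]                   # identical pair
  tb2 <- otu_table(x)
  out <- raup_crick_bc(tb2, "S1", "S2", reps = 199, seed = 1)
  expect_equal(out$bc_obs, 0)
  expect_equal(out$rc, -1)

  # cross-implementation oracle with a different RNG consumption pattern
  tb5 <- make_neutral_table(S = 5, m = 10, depth = 60, sdlog = 0.5, seed = 6)
  ours <- raup_crick_bc(tb5, "S1", "S4", reps = 4000, seed = 2)$rc
  ref <- rc_null_oracle(unclass(tb5), "S1", "S4", reps = 4000, seed = 77)
  expect_lt(abs(ours - ref), 0.05)

  expect_error(raup_crick_bc(to_relative(tb5), "S1", "S2", reps = 99),
               "integer counts")
})

test_that("classification partitions the (bNTI, RC) plane exactly", {
  expect_equal(as.character(classify_pair(2.5, 0)), "heterogeneous_selection")
  expect_equal(as.character(classify_pair(-2.5, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_pair(0.3, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(0.3, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_pair(0.3, 0.5)), "undominated")

  grid <- expand.grid(bnti = seq(-4, 4, by = 0.25), rc = seq(-1, 1, by = 0.05))
  cls <- classify_pair(grid$bnti, grid$rc)
  expect_false(anyNA(cls))                      # collectively exhaustive
  manual <- with(grid, ifelse(bnti > 2, "heterogeneous_selection",
                  ifelse(bnti < -2, "homogeneous_selection",
                  ifelse(rc > 0.95, "dispersal_limitation",
                  ifelse(rc < -0.95, "homogenizing_dispersal", "undominated")))))
  expect_equal(as.character(cls), manual)       # mutually exclusive regions
  expect_error(classify_pair(NaN, 0), "non-finite")
})

test_that("process summaries tally fractions per stratum", {
  meta <- tiny_meta(8)
  pairs <- data.frame(
    sample_a = c("S1", "S1", "S3", "S2"),
    sample_b = c("S3", "S5", "S5", "S4"),
    bmntd_obs = 1, bnti = 0, bc_obs = 0.5, rc = 0,
    process = factor(c("dispersal_limitation", "dispersal_limitation",
                       "undominated", "heterogeneous_selection"),
                     levels = ecoassembly:::process_levels))
  class(pairs) <- c("pair_assembly", "data.frame")
  out <- summarize_processes(pairs, meta)
  all_frac <- out[out$stratum == "all", ]
  expect_equal(sum(all_frac$fraction), 1)
  expect_equal(all_frac$fraction[all_frac$process == "dispersal_limitation"], 0.5)
  expect_equal(all_frac$fraction[all_frac$process == "undominated"], 0.25)
  # surface stratum only keeps surface-surface pairs (S1/S3/S5/S7)
  surf <- out[out$stratum == "surface", ]
  expect_equal(unique(surf$n_pairs), 3)
  # random-label tally oracle
  pr <- withr::with_seed(12, data.frame(
    sample_a = "S1", sample_b = "S3",
    bmntd_obs = 1, bnti = 0, bc_obs = 0.5, rc = 0,
    process = factor(sample(ecoassembly:::process_levels, 40, TRUE),
                     levels = ecoassembly:::process_levels)))
  class(pr) <- c("pair_assembly", "data.frame")
  got <- summarize_processes(pr, meta, strata = "all")
  for (lv in ecoassembly:::process_levels)
    expect_equal(got$fraction[got$process == lv],
                 sum(pr$process == lv) / 40)
})

test_that("per-site fractions tally pairs involving each site", {
  meta <- tiny_meta(4)          # sites: site1 = S1,S2; site2 = S3,S4
  pairs <- data.frame(
    sample_a = c("S1", "S1", "S3"),
    sample_b = c("S2", "S3", "S4"),
    bmntd_obs = 1, bnti = 0, bc_obs = 0.5, rc = 0,
    process = factor(c("dispersal_limitation", "undominated", "undominated"),
                     levels = ecoassembly:::process_levels))
  out <- site_process_fractions(pairs, meta)
  s1 <- out[out$site_id == "site1", ]
  expect_equal(unique(s1$n_pairs), 2)   # S1-S2 and S1-S3 involve site1
  expect_equal(s1$fraction[s1$process == "dispersal_limitation"], 0.5)
  expect_equal(s1$fraction[s1$process == "undominated"], 0.5)
  s2 <- out[out$site_id == "site2", ]
  expect_equal(unique(s2$n_pairs), 2)
  expect_equal(s2$fraction[s2$process == "undominated"], 1)
})

test_that("assembly_analysis is order-independent via per-pair seeds", {
  sc <- simulate_scenario("dispersal_limitation",
                          scenario_config(n_sites = 4, n_taxa = 40,
                                          depth = 400, seed = 5))
  samples <- sample_ids(sc$table)
  pairs <- t(combn(samples[1:4], 2))
  a <- assembly_analysis(sc$table, sc$tree, reps = 99, seed = 9, pairs = pairs)
  b <- assembly_analysis(sc$table, sc$tree, reps = 99, seed = 9,
                         pairs = pairs[c(4, 2, 6, 1, 3, 5), ])
  b <- b[match(paste(a$sample_a, a$sample_b), paste(b$sample_a, b$sample_b)), ]
  expect_equal(a$bnti, b$bnti)
  expect_equal(a$rc, b$rc)
  expect_equal(as.character(a$process), as.character(b$process))
})
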