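# Synthetic metacommunity generator: birth-death phylogeny, Brownian
# niche evolution, an estuarine coastal landscape with a strong salinity
# gradient, and OTU tables assembled under controlled regimes (selection,
# dispersal limitation, homogenizing dispersal, drift) so that every
# pipeline stage can be verified without sequencing data.

#' Scenario configuration for the synthetic generator
#'
#' Defaults emulate a coastal estuarine survey: 17 sites sampled at
#' surface and bottom, a salinity gradient running 1.82 to 32.17 permil
#' along the estuary axis, a ~270 x 180 km coastal box, and sequencing
#' depth of 10,000 individuals per sample (500 under the drift regime,
#' where amplified sampling noise is the point).
#'
#' @param n_sites number of sites (each yields a surface and a bottom
#'   sample).
#' @param n_taxa number of OTUs.
#' @param birth,death birth-death tree rates (death < birth).
#' @param niche_signal Brownian-motion rate for niche evolution on the
#'   tree, in squared gradient units per unit branch length; `NULL`
#'   scales it so tip optima roughly span the gradient.
#' @param env_gradient two-element range of the driving variable
#'   (salinity, permil).
#' @param selection_strength Gaussian niche breadth sigma, in gradient
#'   units.
#' @param dispersal_scale_km exponential dispersal kernel length.
#' @param migration mixing weight in \[0, 1\] of the shared regional pool
#'   into every sample's expected abundances (0 = none).
#' @param depth individuals per sample.
#' @param drift_depth individuals per sample under the drift regime.
#' @param seed scenario seed; all substreams (tree, niches, landscape,
#'   assembly) are derived from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 17, n_taxa = 300, birth = 1, death = 0.25,
                            niche_signal = NULL,
                            env_gradient = c(1.82, 32.17),
                            selection_strength = 3, dispersal_scale_km = 30,
                            migration = 0, depth = 10000, drift_depth = 500,
                            seed = 1) {
  stopifnot(n_sites >= 2, n_taxa >= 2, birth > 0, death >= 0,
            depth >= 1, drift_depth >= 1, migration >= 0, migration <= 1,
            selection_strength > 0, dispersal_scale_km > 0,
            length(env_gradient) == 2, all(is.finite(env_gradient)))
  structure(list(n_sites = n_sites, n_taxa = n_taxa, birth = birth,
                 death = death, niche_signal = niche_signal,
                 env_gradient = sort(env_gradient),
                 selection_strength = selection_strength,
                 dispersal_scale_km = dispersal_scale_km,
                 migration = migration, depth = depth,
                 drift_depth = drift_depth, seed = seed),
            class = "scenario_config")
}

#' Simulate a birth-death phylogeny
#'
#' Birth-death tree conditioned on the configured number of tips, with
#' tip labels `OTU_1..OTU_n`.  Deterministic given the scenario seed.
#'
#' @param config a `scenario_config`.
#' @return A rooted `phylo` tree with positive branch lengths.
#' @export
simulate_tree <- function(config) {
  if (config$death >= config$birth)
    stop("death rate must be below birth rate for a surviving lineage",
         call. = FALSE)
  tree <- local_seed(derive_seed(config$seed, "tree"),
                     ape::rphylo(config$n_taxa, birth = config$birth,
                                 death = config$death))
  tree$tip.label <- paste0("OTU_", seq_len(config$n_taxa))
  tree
}

#' Evolve niche optima along a tree by Brownian motion
#'
#' Starting from `root` at the root node, each branch adds a
#' `N(0, rate * branch_length)` increment; tip values are the niche
#' optima.  Closely related taxa therefore have similar optima
#' (phylogenetic niche conservatism), which is what betaNTI detects.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param rate Brownian-motion rate (variance per unit branch length).
#' @param seed RNG seed.
#' @param root ancestral value at the root.
#' @return Named numeric vector of tip optima.
#' @export
evolve_niches <- function(tree, rate, seed = 1, root = 0) {
  stopifnot(rate >= 0)
  n <- length(tree$tip.label)
  val <- numeric(n + tree$Nnode)
  val[n + 1L] <- root
  tr <- stats::reorder(tree, "cladewise")
  local_seed(seed, {
    for (e in seq_len(nrow(tr$edge))) {
      val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] +
        rnorm(1, 0, sqrt(rate * tr$edge.length[e]))
    }
  })
  stats::setNames(val[seq_len(n)], tree$tip.label)
}

# BM rate that makes tip optima roughly span the gradient: tip sd about
# a quarter of the range at the mean root-to-tip depth.
auto_niche_rate <- function(tree, env_gradient) {
  depth <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  ((diff(env_gradient) / 4)^2) / max(depth, .Machine$double.eps)
}

#' Simulate a coastal estuarine landscape
#'
#' Places sites along a coastline-like arc inside a ~270 x 90 km box,
#' with a surface and a bottom sample per site.  The driving variable
#' (salinity) increases monotonically along the estuary axis and spans
#' exactly the configured gradient; dissolved oxygen, turbidity, depth,
#' total alkalinity, and offshore distance are drawn with layer-specific
#' means, including a hypoxic pocket in mid-estuary bottom waters.
#'
#' @param config a `scenario_config`.
#' @return A `sample_metadata` with `2 * n_sites` rows.
#' @export
simulate_landscape <- function(config) {
  n <- config$n_sites
  lo <- config$env_gradient[1]; hi <- config$env_gradient[2]
  local_seed(derive_seed(config$seed, "landscape"), {
    t <- seq(0, 1, length.out = n)
    lon <- 112.6 + 2.6 * t + rnorm(n, 0, 0.02)
    lat <- 22.5 - 0.8 * sin(pi * t) + rnorm(n, 0, 0.02)
    sal <- lo + (hi - lo) * t
    jitter <- rnorm(n, 0, 0.02 * (hi - lo))
    jitter[c(1, n)] <- 0
    sal <- pmin(pmax(sal + jitter, lo), hi)
    sal[1] <- lo; sal[n] <- hi
    offshore <- pmax(1, (22.9 - lat) * 111.32 + rnorm(n, 0, 2))
    site_depth <- pmax(5, 5 + 20 * offshore / max(offshore) + rnorm(n, 0, 2))
    surf_do <- pmax(4, rnorm(n, 7, 0.8))
    bot_do <- pmax(0.15, 5.5 - 4.8 * exp(-(t - 0.4)^2 / 0.02) + rnorm(n, 0, 0.4))
    surf_turb <- pmax(0.5, rnorm(n, 5, 2))
    bot_turb <- pmax(0.5, rnorm(n, 15, 5))
    talk <- 1.8 + 0.4 * t + rnorm(n, 0, 0.05)
    site <- paste0("GB-", seq_len(n))
    df <- rbind(
      data.frame(sample_id = paste0(site, "S"), site_id = site,
                 layer = "surface", latitude = lat, longitude = lon,
                 salinity = sal, DO = surf_do,
                 turbidity = surf_turb, TALK = talk,
                 depth = pmax(0.5, rnorm(n, 1, 0.2)),
                 offshore_distance = offshore),
      data.frame(sample_id = paste0(site, "B"), site_id = site,
                 layer = "bottom", latitude = lat, longitude = lon,
                 salinity = sal, DO = bot_do,
                 turbidity = bot_turb, TALK = talk,
                 depth = site_depth,
                 offshore_distance = offshore))
    sample_metadata(df)
  })
}

#' Assemble communities under a controlled regime
#'
#' Builds per-sample expected abundances and draws multinomial counts at
#' the configured depth:
#' * `selection` — Gaussian environmental filtering of Brownian niche
#'   optima, `lambda ~ exp(-(E_site - mu_t)^2 / (2 sigma^2))`, no
#'   spatial term;
#' * `dispersal_limitation` — each taxon has a random spatial centre and
#'   a regional log-normal abundance decaying exponentially with
#'   distance from the centre, no environmental term;
#' * `homogenizing_dispersal` — every sample drawn from one shared
#'   regional pool at full depth;
#' * `drift` — independent draws from the shared pool at low depth.
#'
#' @param regime one of `"selection"`, `"dispersal_limitation"`,
#'   `"homogenizing_dispersal"`, `"drift"`.
#' @param tree the scenario phylogeny (labels give the taxa).
#' @param niches named niche optima (used by the selection regime).
#' @param landscape a `sample_metadata` from [simulate_landscape()].
#' @param config a `scenario_config`.
#' @return An `otu_table` of integer counts.
#' @export
assemble_communities <- function(regime, tree, niches, landscape, config) {
  regime <- match.arg(regime, c("selection", "dispersal_limitation",
                                "homogenizing_dispersal", "drift"))
  taxa <- tree$tip.label
  S <- length(taxa)
  samples <- landscape$sample_id
  # moderately long-tailed regional abundances (log-normal, sdlog 2): rare
  # OTUs keep sample supports distinct (informative betaNTI nulls) while the
  # dominance structure stays mild enough that each regime's designed signal
  # (not dominant-taxon occupancy noise) drives the classifier
  pool_w <- local_seed(derive_seed(config$seed, "pool"), rlnorm(S, 0, 2))
  pool_p <- pool_w / sum(pool_w)
  lam <- switch(regime,
    selection = {
      mu <- niches[taxa]
      if (anyNA(mu)) stop("niches do not cover the tree tips", call. = FALSE)
      E <- landscape$salinity
      exp(-outer(mu, E, "-")^2 / (2 * config$selection_strength^2))
    },
    dispersal_limitation = {
      centers <- local_seed(derive_seed(config$seed, "centers"), {
        i <- sample.int(nrow(landscape), S, replace = TRUE)
        cbind(lat = landscape$latitude[i] + rnorm(S, 0, 0.05),
              lon = landscape$longitude[i] + rnorm(S, 0, 0.05))
      })
      km <- haversine_km(centers[, "lat"], centers[, "lon"],
                         landscape$latitude, landscape$longitude)
      pool_w * exp(-km / config$dispersal_scale_km)
    },
    homogenizing_dispersal = matrix(pool_w, S, length(samples)),
    drift = matrix(pool_w, S, length(samples)))
  lam <- lam + 1e-10
  lam <- sweep(lam, 2, colSums(lam), "/")
  if (config$migration > 0)
    lam <- (1 - config$migration) * lam + config$migration * pool_p
  depth <- if (regime == "drift") config$drift_depth else config$depth
  counts <- matrix(0L, S, length(samples), dimnames = list(taxa, samples))
  for (j in seq_along(samples)) {
    counts[, j] <- local_seed(derive_seed(config$seed, "sample", samples[j]),
                              rmultinom(1, depth, lam[, j])[, 1])
  }
  otu_table(counts)
}

# cross distances (km) between a set of centres and a set of sites;
# returns an S x n_sites matrix
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  p1 <- lat1 * pi / 180; l1 <- lon1 * pi / 180
  p2 <- lat2 * pi / 180; l2 <- lon2 * pi / 180
  a <- sin(outer(p1, p2, "-") / 2)^2 +
    outer(cos(p1), cos(p2)) * sin(outer(l1, l2, "-") / 2)^2
  2 * radius_km * asin(sqrt(pmin(pmax(a, 0), 1)))
}

#' Simulate a full scenario
#'
#' Orchestrates tree, niches, landscape, and community assembly under
#' one regime, with all randomness derived from the scenario seed
#' through named substreams.
#'
#' @inheritParams assemble_communities
#' @param config a `scenario_config`.
#' @return List of class `scenario`: `table`, `tree`, `niches`, `meta`,
#'   `regime`, `config`.
#' @export
simulate_scenario <- function(regime, config = scenario_config()) {
  tree <- simulate_tree(config)
  rate <- config$niche_signal %||% auto_niche_rate(tree, config$env_gradient)
  niches <- evolve_niches(tree, rate, seed = derive_seed(config$seed, "niches"),
                          root = mean(config$env_gradient))
  meta <- simulate_landscape(config)
  table <- assemble_communities(regime, tree, niches, meta, config)
  structure(list(table = table, tree = tree, niches = niches, meta = meta,
                 regime = regime, config = config),
            class = "scenario")
}

#' Write a scenario to disk in pipeline formats
#'
#' Emits `table.tsv`, `tree.nwk`, `meta.csv`, and `truth.json` (regime
#' plus generating parameters) into a directory; the pipeline runs
#' end-to-end on these files.
#'
#' @param scenario a `scenario`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("table.tsv", "tree.nwk", "meta.csv", "truth.json"))
  write_otu_table(scenario$table, paths[1])
  ape::write.tree(scenario$tree, paths[2])
  write_sample_metadata(scenario$meta, paths[3])
  cfg <- unclass(scenario$config)
  cfg$niche_signal <- cfg$niche_signal %||% "auto"
  jsonlite::write_json(list(regime = scenario$regime, config = cfg),
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
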