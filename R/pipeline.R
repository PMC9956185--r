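# End-to-end orchestration: validate -> diversity -> ordination ->
# distance-decay -> assembly -> report, with a reproducibility manifest.

#' Cross-validate pipeline inputs
#'
#' Checks label consistency between the OTU table, the tree, and the
#' metadata: tree tips not in the table are reported as prunable
#' (non-fatal); table taxa missing from the tree, and sample mismatches,
#' are fatal when the intersection is empty.
#'
#' @param table an `otu_table`.
#' @param tree a `phylo` tree.
#' @param meta a `sample_metadata`.
#' @return List with `issues` (character), `fatal` (logical),
#'   `taxa` and `samples` (the usable intersections).
#' @export
validate_inputs <- function(table, tree, meta) {
  issues <- character(0)
  fatal <- FALSE
  taxa <- intersect(taxon_ids(table), tree$tip.label)
  extra_tips <- setdiff(tree$tip.label, taxon_ids(table))
  missing_taxa <- setdiff(taxon_ids(table), tree$tip.label)
  if (length(extra_tips))
    issues <- c(issues, sprintf("%d tree tips absent from table (pruned)",
                                length(extra_tips)))
  if (length(missing_taxa))
    issues <- c(issues, sprintf("%d table taxa absent from tree (dropped)",
                                length(missing_taxa)))
  if (!length(taxa)) {
    issues <- c(issues, "no taxa shared between table and tree")
    fatal <- TRUE
  }
  samples <- intersect(sample_ids(table), meta$sample_id)
  if (!length(samples)) {
    issues <- c(issues, "no samples shared between table and metadata")
    fatal <- TRUE
  } else if (length(samples) < length(sample_ids(table))) {
    issues <- c(issues, sprintf("%d table samples missing from metadata (dropped)",
                                length(sample_ids(table)) - length(samples)))
  }
  list(issues = issues, fatal = fatal, taxa = taxa, samples = samples,
       pruned_tips = extra_tips, dropped_taxa = missing_taxa)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_full)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Validates inputs, computes per-sample Shannon diversity with a
#' between-layer one-way ANOVA, Bray-Curtis dissimilarity, an NMDS
#' ordination, per-layer distance-decay fits, and the two-stage null
#' model with per-pair classification and per-stratum process
#' fractions.  Writes per-stage TSVs, a JSON manifest (parameters,
#' seed, input checksums), and a plain-text summary.  Outputs are
#' deterministic: identical config and inputs give byte-identical
#' files.
#'
#' @param otu path to an OTU table TSV, or an `otu_table`.
#' @param tree path to a Newick file, or a `phylo` tree.
#' @param meta path to a metadata CSV, or a `sample_metadata`.
#' @param out_dir output directory; created if needed.
#' @param reps null-model reps for both assembly stages.
#' @param seed global seed.
#' @param bnti_thresh,rc_thresh assembly classification thresholds.
#' @param permutations distance-decay permutations.
#' @param nmds_restarts NMDS restarts.
#' @param depth count-reconstitution depth for relative tables.
#' @return Invisibly, a list with every stage result plus the manifest.
#' @export
run_pipeline <- function(otu, tree, meta, out_dir, reps = 999, seed = 42,
                         bnti_thresh = 2, rc_thresh = 0.95,
                         permutations = 999, nmds_restarts = 20,
                         depth = 10000) {
  inputs <- list()
  if (is.character(otu)) {
    if (!file.exists(otu)) stop("OTU table not found: ", otu, call. = FALSE)
    inputs$otu <- otu
    otu <- read_otu_table(otu)
  }
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("tree file not found: ", tree, call. = FALSE)
    inputs$tree <- tree
    tree <- ape::read.tree(tree)
  }
  if (is.character(meta)) {
    if (!file.exists(meta)) stop("metadata not found: ", meta, call. = FALSE)
    inputs$meta <- meta
    meta <- read_sample_metadata(meta)
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  val <- stage("validate", {
    v <- validate_inputs(otu, tree, meta)
    if (v$fatal) stop(paste(v$issues, collapse = "; "))
    v
  })
  otu <- otu_table(unclass(otu)[val$taxa, val$samples, drop = FALSE],
                   is_relative = is_relative(otu))
  meta <- meta[meta$sample_id %in% val$samples, , drop = FALSE]

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  alpha <- stage("alpha", shannon_index(otu))
  layers <- meta$layer[match(names(alpha), meta$sample_id)]
  groups <- split(alpha, layers)
  alpha_anova <- if (length(groups) >= 2 && all(lengths(groups) >= 2))
    tryCatch(anova_oneway(groups), error = function(e) NULL) else NULL
  write_tsv(data.frame(sample_id = names(alpha), layer = layers,
                       shannon = unname(alpha)),
            file.path(out_dir, "alpha.tsv"))

  rel <- stage("beta", to_relative(otu))
  bc <- bray_curtis(rel)
  write_tsv(data.frame(sample_id = rownames(bc),
                       as.data.frame(unclass(bc), check.names = FALSE)),
            file.path(out_dir, "bray_curtis.tsv"))

  ord <- stage("nmds", nmds(bc, k = 2, restarts = nmds_restarts,
                            seed = derive_seed(seed, "nmds")))
  write_tsv(data.frame(sample_id = rownames(ord$points),
                       as.data.frame(ord$points)),
            file.path(out_dir, "nmds.tsv"))

  geo <- stage("geo", haversine_matrix(meta))
  decay <- stage("decay", {
    out <- list()
    for (ly in c("surface", "bottom", "all")) {
      ids <- if (ly == "all") meta$sample_id else
        meta$sample_id[meta$layer == ly]
      ids <- intersect(rownames(bc), ids)
      if (length(ids) < 4) next
      out[[ly]] <- distance_decay(
        pairwise_matrix(unclass(bc)[ids, ids], "braycurtis"),
        pairwise_matrix(unclass(geo)[ids, ids], "geographic_km"),
        permutations = permutations, seed = derive_seed(seed, "decay", ly))
    }
    out
  })
  write_tsv(do.call(rbind, lapply(names(decay), function(ly) {
    f <- decay[[ly]]
    data.frame(stratum = ly, rho = f$rho, p_value = f$p_value,
               slope = f$slope, intercept = f$intercept, n_pairs = f$n_pairs)
  })), file.path(out_dir, "distance_decay.tsv"))

  pairs <- stage("assembly",
                 assembly_analysis(otu, tree, meta, reps = reps, seed = seed,
                                   bnti_thresh = bnti_thresh,
                                   rc_thresh = rc_thresh, depth = depth))
  write_tsv(as.data.frame(pairs), file.path(out_dir, "assembly_pairs.tsv"))
  summary_df <- summarize_processes(pairs, meta)
  write_tsv(summary_df, file.path(out_dir, "process_summary.tsv"))

  manifest <- list(
    package = "ecoassembly",
    version = as.character(utils::packageVersion("ecoassembly")),
    parameters = list(reps = reps, seed = seed, bnti_thresh = bnti_thresh,
                      rc_thresh = rc_thresh, permutations = permutations,
                      nmds_restarts = nmds_restarts, depth = depth),
    inputs = if (length(inputs))
      lapply(inputs, function(p) unname(tools::md5sum(p))) else NULL,
    nmds_stress = ord$stress,
    alpha_anova = if (!is.null(alpha_anova))
      list(F = alpha_anova$F, p = alpha_anova$p) else NULL,
    validation = val$issues)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  modal <- summary_df[summary_df$stratum == "all", ]
  modal <- modal$process[which.max(modal$fraction)]
  summary_lines <- c(
    sprintf("samples: %d   taxa: %d", ncol(otu), nrow(otu)),
    sprintf("Shannon range: %.3f - %.3f", min(alpha), max(alpha)),
    if (!is.null(alpha_anova))
      sprintf("layer ANOVA: F = %.3f, p = %.4g", alpha_anova$F, alpha_anova$p),
    sprintf("NMDS stress: %.4f", ord$stress),
    vapply(names(decay), function(ly)
      sprintf("distance-decay [%s]: rho = %.3f, p = %.4g", ly,
              decay[[ly]]$rho, decay[[ly]]$p_value), character(1)),
    sprintf("modal assembly process (all pairs): %s", modal))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(alpha = alpha, alpha_anova = alpha_anova, bray_curtis = bc,
                 ordination = ord, decay = decay, pairs = pairs,
                 process_summary = summary_df, manifest = manifest,
                 validation = val))
}
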