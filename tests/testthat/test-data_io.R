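test_that("OTU table round trip is lossless and validates identifiers", {
  # literal 2x2 identity round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tA\tB", "OTU_1\t5\t0", "OTU_2\t3\t2"), f)
  tb <- read_otu_table(f, orientation = "taxa_rows")
  expect_equal(as_matrix(tb), matrix(c(5, 3, 0, 2), 2, 2,
               dimnames = list(c("OTU_1", "OTU_2"), c("A", "B"))))

  # random 50x10 full-precision round trip
  x <- withr::with_seed(7, matrix(runif(500) * 1000, 50, 10,
       dimnames = list(paste0("OTU_", 1:50), paste0("S", 1:10))))
  tb <- otu_table(x)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tb, f2)
  expect_equal(as_matrix(read_otu_table(f2)), x, tolerance = 0)

  # duplicate taxon id rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tA", "OTU_1\t5", "OTU_1\t3"), f3)
  expect_error(read_otu_table(f3, orientation = "taxa_rows"), "duplicate taxon")

  # malformed cell names row and column
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tA\tB", "OTU_1\t5\tx2", "OTU_2\t3\t2"), f4)
  expect_error(read_otu_table(f4, orientation = "taxa_rows"), "OTU_1.*B")
})

test_that("orientation handling transposes sample-major tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tOTU_1\tOTU_2\tOTU_3",
               "A\t1\t2\t3", "B\t4\t5\t6"), f)
  tb <- read_otu_table(f, orientation = "samples_rows")
  expect_equal(taxon_ids(tb), c("OTU_1", "OTU_2", "OTU_3"))
  expect_equal(unname(unclass(tb)[, "A"]), c(1, 2, 3))
  # auto picks the transposed reading here too: 2 rows < 3 data columns
  expect_equal(as_matrix(read_otu_table(f)), as_matrix(tb))
})

test_that("to_relative normalises columns, errors on zero samples, idempotent", {
  x <- matrix(c(2, 2, 0, 4), 2, 2,
              dimnames = list(c("OTU_1", "OTU_2"), c("A", "B")))
  rel <- to_relative(otu_table(x))
  expect_equal(unname(unclass(rel)[, "A"]), c(0.5, 0.5))
  expect_true(is_relative(rel))
  expect_equal(unclass(to_relative(rel)), unclass(rel))  # idempotent

  bad <- otu_table(matrix(c(1, 1, 0, 0), 2, 2,
                   dimnames = list(c("OTU_1", "OTU_2"), c("A", "Bzero"))))
  expect_error(to_relative(bad), "Bzero")

  # property: sums to 1, rank order preserved
  for (s in 1:5) {
    tb <- random_counts_table(seed = s)
    rel <- to_relative(tb)
    expect_equal(unname(colSums(rel)), rep(1, ncol(rel)), tolerance = 1e-12)
    for (j in seq_len(ncol(tb)))
      expect_equal(order(unclass(rel)[, j]), order(unclass(tb)[, j]))
  }
})

test_that("taxonomy filter applies strict 90/90 thresholds without dropping records", {
  rec <- data.frame(taxon_id = paste0("OTU_", 1:4),
                    lineage = paste0("lin", 1:4),
                    percent_identity = c(95, 90, 99, 89.9),
                    percent_coverage = c(92, 95, 90, 95))
  out <- filter_taxonomy(rec)
  expect_equal(out$lineage, c("lin1", "unclassified", "unclassified", "unclassified"))
  expect_equal(nrow(out), nrow(rec))

  # brute-force conjunction oracle on random records, plus monotonicity
  rnd <- withr::with_seed(3, data.frame(
    taxon_id = paste0("OTU_", 1:200), lineage = paste0("lin", 1:200),
    percent_identity = runif(200, 80, 100),
    percent_coverage = runif(200, 80, 100)))
  kept_at <- function(mi, mc) sum(filter_taxonomy(rnd, mi, mc)$classified)
  expect_equal(kept_at(90, 90),
               sum(rnd$percent_identity > 90 & rnd$percent_coverage > 90))
  expect_true(kept_at(95, 90) <= kept_at(90, 90))
  expect_true(kept_at(90, 95) <= kept_at(90, 90))
})

test_that("dominant_taxa pools by group with a strict 1% rule", {
  x <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("OTU_1", "OTU_2"), c("A", "B")))
  rel <- otu_table(x, is_relative = TRUE)
  one <- dominant_taxa(rel, c(OTU_1 = "PhyX", OTU_2 = "PhyX"))
  expect_equal(one, c(PhyX = 1.0))

  # a group at exactly the threshold goes to Others (strict >)
  x2 <- matrix(c(0.01, 0.99), 2, 1,
               dimnames = list(c("OTU_1", "OTU_2"), "A"))
  out <- dominant_taxa(otu_table(x2, is_relative = TRUE),
                       c(OTU_1 = "Rare", OTU_2 = "Common"))
  expect_false("Rare" %in% names(out))
  expect_equal(unname(out["Others"]), 0.01)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  # random table against a brute-force group-by oracle
  tb <- to_relative(random_counts_table(S = 30, m = 5, seed = 9))
  map <- withr::with_seed(2, setNames(sample(paste0("P", 1:6), 30, TRUE),
                                      taxon_ids(tb)))
  got <- dominant_taxa(tb, map, threshold = 0.05)
  pooled <- rowSums(unclass(tb)) / ncol(tb)
  oracle <- tapply(pooled, map[names(pooled)], sum)
  oracle <- oracle / sum(oracle)
  for (g in setdiff(names(got), "Others"))
    expect_equal(unname(got[g]), unname(oracle[g]))
  expect_equal(sum(got), 1, tolerance = 1e-9)

  # unmapped taxa land in an unclassified bucket
  expect_message(dominant_taxa(tb, map[-1], threshold = 0.05), "unclassified")
})

test_that("hypoxia flag uses strict DO < 2 mg/L", {
  meta <- tiny_meta(6)
  meta$DO <- c(0.23, 2.0, 1.99, 7.5, NA, 0.5)
  expect_warning(fl <- flag_hypoxia(meta), "missing DO")
  expect_true(fl[["S1"]])            # severe hypoxia
  expect_false(fl[["S2"]])           # boundary: 2.0 is not hypoxic
  expect_true(fl[["S3"]])
  expect_false("S5" %in% names(fl))  # NA omitted
  # element-wise oracle on random DO
  do <- withr::with_seed(4, runif(20, 0, 4))
  m2 <- tiny_meta(20); m2$DO <- do
  expect_equal(unname(flag_hypoxia(m2)), do < 2)
})

test_that("replicate averaging collapses to one column per site and layer", {
  meta <- as.data.frame(tiny_meta(6))
  meta$site_id <- rep(c("GB-1", "GB-2"), each = 3)
  meta$layer <- rep("surface", 6)
  meta$replicate <- rep(1:3, 2)
  meta <- sample_metadata(meta)
  x <- matrix(c(3, 0,  6, 3,  0, 6,   2, 2,  4, 4,  0, 6), 2, 6,
              dimnames = list(c("OTU_1", "OTU_2"), paste0("S", 1:6)))
  avg <- average_replicates(otu_table(x), meta)
  expect_equal(ncol(avg), 2)
  expect_equal(unname(unclass(avg)[, 1]), c(3, 3))      # mean of S1..S3
  expect_equal(unname(unclass(avg)[, 2]), c(2, 4))      # mean of S4..S6
  # no replicate column: unchanged
  expect_identical(average_replicates(otu_table(x), tiny_meta(6)), otu_table(x))
})

test_that("metadata validation enforces ranges and layers", {
  df <- as.data.frame(tiny_meta(6))
  bad <- df; bad$latitude[1] <- 95
  expect_error(sample_metadata(bad), "latitude")
  bad <- df; bad$layer[2] <- "middle"
  expect_error(sample_metadata(bad), "layer")
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample_metadata(tiny_meta(6), f)
  back <- read_sample_metadata(f)
  expect_equal(back$sample_id, df$sample_id[seq_len(6)])
  expect_true(all(c("DO", "salinity", "TALK") %in% env_variables(back)))
})
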