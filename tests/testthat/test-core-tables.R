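test_that("count tables validate identifiers and counts", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ct <- count_table(m)
  expect_identical(sample_ids(ct), c("s1", "s2"))
  expect_identical(unname(library_sizes(ct)), c(9, 12))

  bad <- m; rownames(bad) <- c("s1", "s1")
  expect_error(count_table(bad), "s1")
  expect_error(count_table(-m), "negative")
  expect_error(count_table(m + 0.5), "integer")
})

test_that("TSV round-trip is bit-exact in both orientations", {
  set.seed(11)
  m <- matrix(rpois(60, 30), 5, 12,
              dimnames = list(paste0("s", 1:5), paste0("OTU", 1:12)))
  tax <- setNames(paste0("k__Bacteria;p__P", 1:12, ";g__G", 1:12),
                  colnames(m))
  ct <- count_table(m, taxonomy = tax)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  back <- read_count_table(f)
  expect_identical(back$counts, ct$counts)
  expect_identical(back$taxonomy, ct$taxonomy)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(count_table(m), f2, orientation = "samples-rows")
  back2 <- read_count_table(f2, orientation = "samples-rows")
  expect_identical(back2$counts, ct$counts)
})

test_that("reader reports parse errors and duplicate ids by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "t1\t3\tx", "t2\t1\t2"), f)
  expect_error(read_count_table(f), "t1")
  writeLines(c("#OTU ID\ts1\ts2", "t1\t3\t4", "t1\t1\t2"), f)
  expect_error(read_count_table(f), "t1")
})

test_that("relative abundance sums to one and rejects empty samples", {
  ct <- tiny_counts()
  rel <- to_relative_abundance(ct)
  expect_equal(unname(rel$values["s1", ]), c(0.25, 0.25, 0.5))
  expect_true(all(abs(rowSums(rel$values) - 1) < 1e-12))

  zero <- count_table(matrix(c(1, 0, 2, 0), 2, 2,
                             dimnames = list(c("ok", "empty"), c("a", "b"))))
  expect_error(to_relative_abundance(zero), "empty")

  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(50, 5) + 1, 5, 10,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:10)))
    expect_true(all(abs(rowSums(to_relative_abundance(count_table(m))$values) - 1) < 1e-12))
  }
})

test_that("rarefaction hits exact depth, drops shallow samples, is seeded", {
  set.seed(5)
  m <- rbind(s1 = rpois(20, 60), s2 = rpois(20, 60), shallow = rpois(20, 2))
  colnames(m) <- paste0("t", 1:20)
  ct <- count_table(m)
  rar <- rarefy(ct, 500, seed = 42)
  expect_true(all(library_sizes(rar) == 500))
  expect_identical(attr(rar, "dropped")$sample_id, "shallow")
  # no taxa introduced
  expect_true(all(rar$counts[, m["s1", ] == 0][1, ] == 0))
  # determinism
  expect_identical(rarefy(ct, 500, seed = 42)$counts, rar$counts)
  expect_error(rarefy(ct, 0, seed = 1), "positive")
  expect_error(rarefy(ct, 1e9, seed = 1), "no samples retained")
})

test_that("rarefied proportions match hypergeometric expectation", {
  counts <- c(300, 120, 60, 20)
  ct <- count_table(matrix(counts, 1, dimnames = list("s", paste0("t", 1:4))))
  props <- vapply(1:500, function(s) {
    as.vector(rarefy(ct, 100, seed = s)$counts) / 100
  }, numeric(4))
  expect_lt(max(abs(rowMeans(props) - counts / sum(counts))), 0.02)
})

test_that("rare-taxon filter applies the AND rule and is idempotent", {
  v <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("rare", "sparse_but_abundant", "common")))
  v[1, "rare"] <- 5e-4                    # mean 5e-5 (<1e-4), prevalence 0.1
  v[1:5, "sparse_but_abundant"] <- 1e-4   # mean 5e-5 (<1e-4), prevalence 0.5
  v[, "common"] <- 0.01
  rel <- as_rel(v)
  out <- filter_rare_taxa(rel)
  expect_identical(colnames(out$values), c("sparse_but_abundant", "common"))
  expect_identical(attr(out, "removed")$taxon_id, "rare")
  # OR rule removes the sparse one too
  out_or <- filter_rare_taxa(rel, rule = "or")
  expect_identical(colnames(out_or$values), "common")
  # idempotent
  twice <- filter_rare_taxa(filter_rare_taxa(rel))
  expect_identical(twice$values, out$values)
})

test_that("rank collapsing pools lineages and conserves totals", {
  m <- matrix(c(3, 7, 2, 5), 1, 4,
              dimnames = list("s1", paste0("OTU", 1:4)))
  tax <- c(OTU1 = "k__B;p__F;c__C;o__O;f__L;g__Lacto",
           OTU2 = "k__B;p__F;c__C;o__O;f__L;g__Lacto",
           OTU3 = "k__B;p__F;c__C;o__O;f__L",
           OTU4 = "k__B;p__P;c__G;o__E;f__E;g__Esch")
  ct <- count_table(m, taxonomy = tax)
  g <- collapse_rank(ct, "genus")
  expect_equal(sum(g$counts), sum(m))
  expect_equal(unname(g$counts[1, "B;F;C;O;L;Lacto"]), 10)
  expect_equal(unname(g$counts[1, "unclassified_L"]), 2)
  p <- collapse_rank(ct, "phylum")
  expect_equal(unname(p$counts[1, "B;F"]), 12)
  expect_error(collapse_rank(ct, "strain"), "rank")
  expect_error(collapse_rank(count_table(m), "genus"), "taxonomy")
})

test_that("metadata validation enforces vocabularies and the age window", {
  meta <- data.frame(sample_id = c("a", "b"), subject_id = "p1",
                     litter_id = "L1", age_days = c(0L, 42L),
                     diet_group = c("I5007", "control"),
                     oral_group = c("Oral", "Nonoral"),
                     health_label = c("healthy", "unknown"))
  expect_silent(validate_sample_metadata(meta))
  bad <- meta; bad$diet_group[1] <- "placebo"
  expect_error(validate_sample_metadata(bad), "placebo")
  bad2 <- meta; bad2$age_days[1] <- 60L
  expect_error(validate_sample_metadata(bad2), "0, 42")
})
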