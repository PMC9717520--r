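test_that("alpha diversity matches closed forms", {
  u <- count_table(matrix(c(5, 5, 5, 5), 1,
                          dimnames = list("s", paste0("t", 1:4))))
  a <- suppressWarnings(alpha_diversity(u))
  expect_equal(a$shannon, log(4))
  expect_equal(a$simpson, 0.75)
  expect_identical(a$richness, 4L)

  single <- count_table(matrix(c(9, 0), 1, dimnames = list("s", c("a", "b"))))
  s <- alpha_diversity(single)
  expect_equal(s$shannon, 0)
  expect_equal(s$simpson, 0)
  expect_identical(s$richness, 1L)

  m123 <- count_table(matrix(c(1, 2, 3), 1, dimnames = list("s", paste0("t", 1:3))))
  p <- c(1, 2, 3) / 6
  expect_equal(alpha_diversity(m123)$shannon, -sum(p * log(p)))
  # inverse-Simpson variant
  expect_equal(alpha_diversity(m123, simpson_variant = "inverse")$simpson,
               1 / sum(p^2))
  expect_warning(alpha_diversity(tiny_counts()), "unequal")
})

test_that("Bray-Curtis satisfies metric axioms and hand arithmetic", {
  m <- count_table(matrix(c(5, 5, 0,
                            0, 5, 5,
                            5, 5, 0,
                            1, 0, 0), 4, byrow = TRUE,
                          dimnames = list(paste0("s", 1:4), c("a", "b", "c"))))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s2"], 0.5)     # 10/20
  expect_equal(d["s1", "s3"], 0)       # identical
  expect_equal(d["s2", "s4"], 1)       # disjoint support
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(8)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  d <- dist(pts)
  ord <- pcoa(d, n_axes = 2)
  expect_lt(max(abs(dist(ord$coordinates) - d)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  expect_true(all(ord$proportion_explained >= 0))
  # two samples: single axis reproduces the distance
  d2 <- dist(matrix(c(0, 3), 2, dimnames = list(c("a", "b"), NULL)))
  expect_warning(o2 <- pcoa(d2, n_axes = 2), "truncating")
  expect_equal(as.numeric(dist(o2$coordinates)), 3)
})

test_that("PERMANOVA separates planted groups and hits its p floor", {
  # two tight clusters -> maximal separation -> p at (or within ties of)
  # the add-one floor; only permutations reproducing the true partition can
  # match the observed F
  set.seed(99)
  a <- c(10, 0, 0, 5); b <- c(0, 10, 5, 0)
  m <- rbind(t(replicate(8, a * 10 + rpois(4, 2))),
             t(replicate(8, b * 10 + rpois(4, 2))))
  dimnames(m) <- list(paste0("s", 1:16), paste0("t", 1:4))
  res <- permanova(bray_curtis(count_table(m)), rep(c("A", "B"), each = 8),
                   n_permutations = 199, seed = 1)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 2 / 200)
  expect_gt(res$R2, 0.8)
  expect_true(res$R2 <= 1)
  expect_error(permanova(bray_curtis(count_table(m[1:6, ])),
                         c("A", "A", "A", "A", "A", "B")),
               "size 1")
})

test_that("PERMANOVA is seeded and p-values never reach zero", {
  set.seed(12)
  x <- matrix(rpois(80, 15), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  d <- bray_curtis(count_table(x))
  g <- rep(c("u", "v"), each = 4)
  r1 <- permanova(d, g, n_permutations = 199, seed = 31)
  r2 <- permanova(d, g, n_permutations = 199, seed = 31)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
})

test_that("within-group distances are complete and contrast clones vs scatter", {
  set.seed(14)
  clones <- matrix(rep(c(5, 5, 5, 5, 0), each = 10), 10, 5)
  scatter <- matrix(rpois(50, 5), 10, 5)
  m <- rbind(clones, scatter) + 1
  rownames(m) <- paste0("s", 1:20); colnames(m) <- paste0("t", 1:5)
  d <- bray_curtis(count_table(m))
  g <- rep(c("clone", "scatter"), each = 10)
  res <- within_group_distances(d, g)
  expect_length(res$distances$clone, choose(10, 2))
  expect_length(res$distances$scatter, choose(10, 2))
  expect_true(all(res$distances$clone == 0))
  expect_lt(res$wilcoxon_p, 0.05)
  expect_warning(
    within_group_distances(d, c(rep("a", 19), "lonely")), "lonely")
})

test_that("Scheirer-Ray-Hare reduces to Kruskal-Wallis with one factor", {
  set.seed(15)
  for (i in 1:5) {
    v <- rnorm(24)
    fa <- gl(3, 8)
    srh <- scheirer_ray_hare(v, fa, gl(1, 24))
    kw <- kruskal.test(v, fa)
    expect_equal(srh$H[1], unname(kw$statistic), tolerance = 1e-9)
    expect_equal(srh$p_value[1], kw$p.value, tolerance = 1e-9)
  }
})

test_that("Scheirer-Ray-Hare finds a planted main effect and handles ties", {
  set.seed(16)
  fa <- gl(2, 16); fb <- gl(2, 8, 32)
  v <- rnorm(32) + 5 * (fa == "2")   # 5-SD shift on A only
  res <- scheirer_ray_hare(v, fa, fb)
  expect_lt(res$p_value[res$effect == "A"], 0.01)
  expect_gt(res$p_value[res$effect == "B"], 0.1)
  # all-identical values: H = 0, p = 1 throughout
  res0 <- scheirer_ray_hare(rep(3, 32), fa, fb)
  expect_true(all(res0$H == 0))
  expect_true(all(res0$p_value == 1))
  expect_error(scheirer_ray_hare(v[1:16], gl(2, 8), gl(2, 8)[c(1:8, 1:8)]),
               NA)
  expect_error(scheirer_ray_hare(1:4, factor(c("a", "a", "b", "b")),
                                 factor(c("x", "x", "x", "x"))[c(1, 2, 3, 4)]),
               NA)
  expect_error(scheirer_ray_hare(1:4, factor(c("a", "a", "a", "b")),
                                 factor(c("x", "y", "x", "x"))),
               "cell")
})
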