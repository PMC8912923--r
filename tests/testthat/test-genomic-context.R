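test_that("cluster chaining follows the inclusive 5 kb rule", {
  co <- data.frame(cpg_id = c("a", "b", "c"), chrom = "chr1",
                   pos = c(100, 4000, 9500))
  cl <- build_clusters(co)
  expect_equal(cl$cluster_id[cl$cpg_id == "a"],
               cl$cluster_id[cl$cpg_id == "b"])
  expect_true(cl$is_singleton[cl$cpg_id == "c"])
  expect_equal(attr(cl, "n_clusters"), 1L)
  expect_equal(attr(cl, "n_singletons"), 1L)

  # gaps of exactly 5000 chain into one cluster (inclusive rule)
  co2 <- data.frame(cpg_id = c("x", "y", "z"), chrom = "chr1",
                    pos = c(1, 5001, 10001))
  cl2 <- build_clusters(co2)
  expect_equal(length(unique(cl2$cluster_id)), 1L)
  expect_equal(cl2$cluster_size, rep(3L, 3))

  # single CpG: one singleton
  cl3 <- build_clusters(data.frame(cpg_id = "solo", chrom = "chr2",
                                   pos = 500))
  expect_true(cl3$is_singleton)

  expect_error(build_clusters(data.frame(cpg_id = c("p", "q"),
                                         chrom = "chr1",
                                         pos = c(10, 10))),
               "duplicate")
})

test_that("clustering is order-invariant and monotone in the gap", {
  set.seed(23)
  co <- data.frame(cpg_id = sprintf("c%02d", 1:40),
                   chrom = sample(c("chr1", "chr2"), 40, TRUE),
                   pos = sample.int(2e5, 40))
  cl_a <- build_clusters(co)
  perm <- sample(40)
  cl_b <- build_clusters(co[perm, ])
  m <- match(cl_a$cpg_id, cl_b$cpg_id)
  expect_equal(cl_a$cluster_size, cl_b$cluster_size[m])
  # same partition: co-membership preserved
  part_a <- split(cl_a$cpg_id, cl_a$cluster_id)
  part_b <- split(cl_b$cpg_id, cl_b$cluster_id)
  expect_setequal(
    unname(vapply(part_a, function(g) paste(sort(g), collapse = ","),
                  character(1))),
    unname(vapply(part_b, function(g) paste(sort(g), collapse = ","),
                  character(1))))
  # number of clusters is non-increasing in max_gap
  n_cl <- vapply(c(1000, 5000, 20000, 1e5), function(g)
    length(unique(build_clusters(co, g)$cluster_id)), numeric(1))
  expect_true(all(diff(n_cl) <= 0))
  # union of clusters = input set
  expect_setequal(cl_a$cpg_id, co$cpg_id)
})

test_that("de-clustering keeps one member per cluster and all singletons", {
  co <- data.frame(
    cpg_id = sprintf("c%02d", 1:9), chrom = "chr1",
    pos = c(100, 2000,            # cluster of 2
            5e5, 5e5 + 1000, 5e5 + 2000,  # cluster of 3
            2e6, 3e6, 4e6, 5e6))  # 4 singletons
  cl <- build_clusters(co)
  ds <- decluster(co$cpg_id, cl, seed = 5)
  expect_equal(length(ds), 6L)  # 2 clusters + 4 singletons
  expect_true(all(sprintf("c%02d", 6:9) %in% ds$cpg_ids))
  expect_identical(decluster(co$cpg_id, cl, seed = 5)$cpg_ids, ds$cpg_ids)

  # singleton-only set is the identity
  solo <- sprintf("c%02d", 6:9)
  expect_setequal(decluster(solo, cl)$cpg_ids, solo)

  expect_error(decluster(c("c01", "nope"), cl), "absent")
})

test_that("enrichment fold and Fisher p match the hypergeometric oracle", {
  # set 5/10 overlapping, background 50/1000 -> fold 10
  ids <- sprintf("cpg%06d", 1:1000)
  coords <- data.frame(cpg_id = ids, chrom = "chr1",
                       pos = seq(1e5, by = 5e4, length.out = 1000))
  in_track <- c(rep(TRUE, 5), rep(FALSE, 5),          # 5/10 in set
                rep(TRUE, 45), rep(FALSE, 945))       # 45 more outside
  track <- annotation_track("ME", intervals = GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = coords$pos[in_track] - 10,
                              end = coords$pos[in_track] + 10)))
  enr <- overlap_enrichment(cpg_set("soc_cpg", ids[1:10]), track, ids,
                            coordinates = coords)
  expect_equal(enr$fold, (5 / 10) / (50 / 1000))
  expect_equal(unname(enr$counts),
               c(5, 10, 50, 1000))
  # Fisher two-sided equals brute-force enumeration on the 2x2 table
  expect_equal(enr$p_value, hypergeom_p(5, 5, 45, 945), tolerance = 1e-9)
})

test_that("null and degenerate enrichment behave as documented", {
  ids <- sprintf("cpg%06d", 1:200)
  coords <- data.frame(cpg_id = ids, chrom = "chr1",
                       pos = seq(1e5, by = 5e4, length.out = 200))
  # set proportion equals background proportion -> fold 1, p ~1
  ovl <- c(rep(TRUE, 5), rep(FALSE, 45), rep(TRUE, 15), rep(FALSE, 135))
  track <- annotation_track("t", intervals = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(coords$pos[ovl] - 1, coords$pos[ovl] + 1)))
  enr <- overlap_enrichment(cpg_set("s", ids[1:50]), track, ids,
                            coordinates = coords)
  expect_equal(enr$fold, 1)
  expect_gt(enr$p_value, 0.9)

  # empty track: undefined fold, p still reported
  empty <- annotation_track("empty", intervals = GenomicRanges::GRanges())
  enr0 <- overlap_enrichment(cpg_set("s", ids[1:50]), empty, ids,
                             coordinates = coords)
  expect_true(is.na(enr0$fold))
  expect_equal(enr0$p_value, 1)

  expect_error(overlap_enrichment(cpg_set("s", "not_in_bg"), track, ids,
                                  coordinates = coords), "subset")
})

test_that("synthetic enrichment fold is recovered downstream", {
  pl <- place_cpgs_and_tracks(10000, hit_ids = sprintf("cpg%06d", 1:500),
                              enrichment_fold = 10, cluster_frac = 0,
                              seed = 29)
  enr <- overlap_enrichment(cpg_set("hits", sprintf("cpg%06d", 1:500)),
                            pl$tracks[[1]], pl$coords$cpg_id,
                            coordinates = pl$coords)
  expect_gt(enr$fold, 7)
  expect_lt(enr$fold, 13)
  expect_lt(enr$p_value, 1e-10)
})

test_that("cluster-adjusted enrichment de-clusters both sides", {
  pl <- place_cpgs_and_tracks(800, hit_ids = sprintf("cpg%06d", 1:100),
                              enrichment_fold = 8, cluster_frac = 0.8,
                              seed = 31)
  adj <- overlap_enrichment(cpg_set("hits", sprintf("cpg%06d", 1:100)),
                            pl$tracks[[1]], pl$coords$cpg_id,
                            coordinates = pl$coords,
                            cluster_adjust = TRUE, cluster_seeds = 1:20)
  expect_true(adj$cluster_adjusted)
  expect_gt(adj$fold, 1)
  expect_true(adj$p_value >= 0 && adj$p_value <= 1)
})

test_that("proximity curves are monotone with valid bootstrap CIs", {
  set.seed(37)
  ids <- sprintf("cpg%06d", 1:120)
  coords <- data.frame(cpg_id = ids, chrom = "chr1",
                       pos = seq(1e5, by = 6e4, length.out = 120))
  near <- sample(120, 30)
  track <- annotation_track("erv1", intervals = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(coords$pos[near] + 500,
                             coords$pos[near] + 600)))
  pc <- proximity_curve(ids, track, distances = c(100, 1000, 5000, 2e4),
                        coordinates = coords, n_boot = 200, seed = 7)
  expect_true(all(diff(pc$proportion) >= 0))
  expect_true(all(pc$ci_lo <= pc$proportion + 1e-12))
  expect_true(all(pc$ci_hi >= pc$proportion - 1e-12))
  # rough binomial width check at the middle distance
  p2 <- pc$proportion[2]
  expect_lt(pc$ci_hi[2] - pc$ci_lo[2],
            6 * sqrt(p2 * (1 - p2) / pc$n_cpgs[2]) + 1e-9)

  # a track covering everything: proportion 1 with degenerate CI
  whole <- annotation_track("all", intervals = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 1e9)))
  pcw <- proximity_curve(ids, whole, distances = c(10, 100),
                         coordinates = coords, n_boot = 100)
  expect_true(all(pcw$proportion == 1))
  expect_true(all(pcw$ci_lo == 1 & pcw$ci_hi == 1))

  expect_error(proximity_curve(character(0), track, 10, coords), "empty")
  expect_error(proximity_curve(ids, track, c(100, 50), coords),
               "ascending")
})

test_that("gamete status thresholds classify the canonical cases", {
  expect_equal(classify_gamete_status(10, 90), "oo_gDMR")
  expect_equal(classify_gamete_status(90, 10), "sperm_gDMR")
  expect_equal(classify_gamete_status(20, 50), "sperm_hypo_only")
  expect_equal(classify_gamete_status(30, 40), "none")
  # boundary: sperm exactly 25 is hypomethylated but not an oo-gDMR
  expect_equal(classify_gamete_status(25, 90), "sperm_hypo_only")
  # vectorised
  expect_equal(classify_gamete_status(c(10, 90), c(90, 10)),
               c("oo_gDMR", "sperm_gDMR"))
  expect_error(classify_gamete_status(120, 50), "\\[0, 100\\]")
})
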