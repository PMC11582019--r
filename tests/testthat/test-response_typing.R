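test_that("trajectories are replicate means with shared day-0 baselines", {
  x <- tinyExperiment()
  traj <- buildTrajectories(x, c("asvA", "asvB"))
  expect_identical(dim(trajectoryValues(traj)), c(8L, 5L))
  expect_identical(traj@days, c(0L, 4L, 8L, 16L, 32L))
  v <- trajectoryValues(traj)
  ## replicate mean: counts are base + slope*day + replicate (1..3)
  expect_equal(unname(v[traj@asv == "asvA" & traj@treatment == "+A/+M", ]),
               100 + 2 * c(0, 4, 8, 16, 32) + 2)
  ## shared day-0 value identical across the two nematode arms
  for (a in c("asvA", "asvB")) {
    expect_identical(v[traj@asv == a & traj@treatment == "-A/+M", 1],
                     v[traj@asv == a & traj@treatment == "+A/+M", 1])
    expect_identical(v[traj@asv == a & traj@treatment == "-A/-M", 1],
                     v[traj@asv == a & traj@treatment == "+A/-M", 1])
  }
  expect_error(buildTrajectories(x, character(0)), class = "ConfigError")
})

test_that("the stability screen applies the relative-range rule", {
  expect_true(screenStability(rep(100, 5)))
  expect_true(screenStability(c(100, 101, 99, 100, 100)))    # range 2 < 25
  expect_false(screenStability(c(100, 300, 100, 100, 100)))  # range 200
  m <- rbind(a = rep(1, 5), b = c(1, 5, 1, 1, 1))
  expect_identical(unname(screenStability(m)), c(TRUE, FALSE))
})

test_that("trajectory scaling obeys the z-score contract", {
  z <- scaleTrajectory(1:5)
  expect_equal(z, c(-1.26491, -0.63246, 0, 0.63246, 1.26491),
               tolerance = 1e-5)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(scaleTrajectory(z), z)                    # idempotent
  expect_error(scaleTrajectory(rep(2, 5)),
               class = "ConstantTrajectoryError")
  sim <- simulateDataset(simConfig(sAsvs = 10, depth = 1000), seed = 3)
  traj <- buildTrajectories(sim$experiment, rownames(sim$experiment)[1:4])
  sc <- scaleTrajectories(traj)
  v <- trajectoryValues(sc)
  expect_equal(unname(rowMeans(v)), rep(0, nrow(v)), tolerance = 1e-9)
  expect_equal(unname(apply(v, 1, sd)), rep(1, nrow(v)), tolerance = 1e-9)
})

test_that("cluster-number diagnostics recover planted structure", {
  set.seed(10)
  centres <- matrix(rnorm(15, sd = 6), 3, 5)
  X <- centres[rep(1:3, each = 30), ] + matrix(rnorm(90 * 5, sd = 0.5), 90)
  ks <- suggestK(X, kmax = 8, nboot = 20, seed = 1)
  expect_identical(ks$silhouette$k, 3L)
  expect_true(all(diff(ks$wss$curve$wss) <= 1e-8))   # non-increasing in k
  ## a single tight blob: the gap statistic picks k = 1
  X1 <- matrix(rnorm(60 * 4, sd = 0.2), 60)
  k1 <- suggestK(X1, kmax = 5, nboot = 20, seed = 1)
  expect_identical(k1$gap$k, 1L)
  expect_error(suggestK(X[1:5, ], kmax = 8), class = "TooFewItemsError")
})

test_that("k-means trajectory clustering is seeded and exact on archetypes", {
  days <- c(0, 4, 8, 16, 32)
  tmpl <- t(apply(archetypeTemplates(days), 1, scaleTrajectory))
  set.seed(99)
  X <- tmpl[rep(1:5, each = 20), ] + matrix(rnorm(100 * 5, sd = 0.1), 100)
  km1 <- clusterTrajectories(X, k = 5, seed = 7)
  km2 <- clusterTrajectories(X, k = 5, seed = 7)
  expect_identical(km1$cluster, km2$cluster)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(km1$cluster, rep(1:5, each = 20)),
               1.0)
  expect_error(clusterTrajectories(tmpl, k = 9), class = "KTooLargeError")
  ## best-of-n restarts never worsen the objective
  kmA <- clusterTrajectories(X, k = 4, nstart = 1, seed = 3)
  kmB <- clusterTrajectories(X, k = 4, nstart = 25, seed = 3)
  expect_lte(kmB$tot.withinss, kmA$tot.withinss + 1e-9)
})

test_that("centroid merging labels templates correctly", {
  days <- c(0, 4, 8, 16, 32)
  tmpl <- t(apply(archetypeTemplates(days), 1, scaleTrajectory))
  ## identity labelling when centroids equal the templates
  for (m in c("template", "agglomerate")) {
    lab <- mergeAndLabel(unname(tmpl), days, nFinal = 5, method = m)
    expect_identical(lab, c("A", "B", "C", "D", "E"))
  }
  ## 9 centroids: 5 templates plus 4 near-duplicates collapse to 5 labels
  set.seed(4)
  nine <- rbind(tmpl, tmpl[c(1, 2, 4, 5), ] +
                        matrix(rnorm(20, sd = 0.05), 4))
  for (m in c("template", "agglomerate")) {
    lab9 <- mergeAndLabel(unname(nine), days, nFinal = 5, method = m)
    expect_identical(lab9[1:5], c("A", "B", "C", "D", "E"))
    expect_identical(lab9[6:9], c("A", "B", "D", "E"))
    expect_identical(sort(unique(lab9)), c("A", "B", "C", "D", "E"))
  }
  ## manual map wins verbatim
  mm <- setNames(c("E", "D", "C", "B", "A"), 1:5)
  expect_identical(mergeAndLabel(unname(tmpl), days, manualMap = mm),
                   c("E", "D", "C", "B", "A"))
  ## a noise centroid triggers the conflict warning but is still labelled
  noisy <- rbind(tmpl, runif(5) - 0.5)
  expect_warning(mergeAndLabel(unname(noisy), days, nFinal = 5),
                 class = "LabelConflictWarning")
})

test_that("assignResponseTypes yields one row per (ASV, treatment)", {
  sim <- simulateDataset(simConfig(sAsvs = 40, depth = 5000), seed = 8)
  x <- sim$experiment
  asvs <- rownames(x)[1:10]
  a <- suppressWarnings(assignResponseTypes(x, asvs, seed = 1))
  expect_identical(nrow(a), 40L)
  expect_setequal(unique(a$treatment), canonicalTreatments())
  expect_true(all(a$response_type %in% c("A", "B", "C", "D", "E", "STABLE")))
  expect_true(all(is.na(a$cluster_id[a$response_type == "STABLE"])))
  expect_true(all(!is.na(a$cluster_id[a$response_type != "STABLE"])))
})

test_that("an all-stable community bypasses clustering", {
  meta <- makeDesignMeta()
  counts <- countsFromRule(c("s1", "s2"), meta,
    function(a, mz, nem, d, r) if (a == "s1") 100L else 50L)
  x <- makeIdentityExperiment(counts, meta)
  a <- assignResponseTypes(x, c("s1", "s2"))
  expect_true(all(a$response_type == "STABLE"))
  expect_true(all(is.na(a$cluster_id)))
})

test_that("labelled trajectories carry the template's peak semantics", {
  ## type D peaks at day 4, type E at day 8, type B dips at day 8
  hits <- c(D = 0, E = 0, B = 0); tot <- c(D = 0, E = 0, B = 0)
  for (s in 1:5) {
    sim <- simulateDataset(simConfig(preset = "recovery"), seed = s)
    x <- sim$experiment
    sel <- selectResponsiveAsvs(x)
    a <- suppressWarnings(assignResponseTypes(x, sel, seed = 42))
    traj <- buildTrajectories(x, responsiveAsvs(sel))
    v <- trajectoryValues(traj)
    key <- paste(traj@asv, traj@treatment)
    lab <- setNames(a$response_type, paste(a$asv_id, a$treatment))[key]
    days <- traj@days
    am <- days[apply(v, 1, which.max)]
    amin <- days[apply(v, 1, which.min)]
    hits["D"] <- hits["D"] + sum(lab == "D" & am == 4)
    hits["E"] <- hits["E"] + sum(lab == "E" & am == 8)
    hits["B"] <- hits["B"] + sum(lab == "B" & amin == 8)
    tot <- tot + c(sum(lab == "D"), sum(lab == "E"), sum(lab == "B"))
  }
  frac <- hits / pmax(tot, 1)
  expect_gte(frac[["D"]], 0.95)
  ## E and B admit adjacent-day argmax flips under replicate + qPCR noise
  ## (their day-4 and day-8 template values differ by ~0.33 log units),
  ## so their peak/dip semantics hold at a looser majority level
  expect_gte(frac[["E"]], 0.85)
  expect_gte(frac[["B"]], 0.70)
  expect_true(all(tot > 0))
})
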