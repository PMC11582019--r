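test_that("toAbsolute splits qPCR totals by read proportion", {
  counts <- matrix(c(50L, 50L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  meta <- data.frame(sample_id = "s1", maize = 0, nematode = 0, day = 0,
                     replicate = 1, shared_baseline = 1)
  x <- AsvExperiment(counts, meta, c(s1 = 2e8))
  expect_equal(unname(absoluteAbundance(x)[, 1]), c(1e8, 1e8))

  sim <- simulateDataset(simConfig(sAsvs = 30, depth = 2000), seed = 11)
  ab <- absoluteAbundance(sim$experiment)
  expect_equal(colSums(ab), qpcrTotals(sim$experiment), tolerance = 1e-9)
  expect_true(all((assay(sim$experiment, "counts") == 0) == (ab == 0)))

  counts0 <- matrix(c(1L, 0L), 1, 2, dimnames = list("a", c("s1", "s2")))
  meta0 <- data.frame(sample_id = c("s1", "s2"), maize = 0, nematode = 0,
                      day = 0, replicate = 1:2, shared_baseline = 1)
  x0 <- AsvExperiment(counts0, meta0, c(s1 = 1e8, s2 = 1e8))
  expect_error(toAbsolute(x0), class = "ZeroDepthError")
})

test_that("Hill numbers match closed forms and respect their ordering", {
  expect_equal(unname(hillNumbers(rep(0.1, 10))), c(10, 10, 10))
  h <- hillNumbers(c(0.8, 0.2))
  expect_equal(unname(h["d0"]), 2)
  expect_equal(unname(h["d1"]), exp(-(0.8 * log(0.8) + 0.2 * log(0.2))))
  expect_equal(unname(h["d1"]), 1.64938, tolerance = 1e-5)
  expect_equal(unname(h["d2"]), 1 / 0.68, tolerance = 1e-9)
  expect_equal(hillNumber(c(0.4, 0.3, 0.2, 0.1), 2), 1 / 0.30,
               tolerance = 1e-9)
  expect_error(hillNumber(c(0.5, 0.4), 1), class = "NormalizationError")
  expect_error(hillNumber(c(-0.5, 1.5), 1), class = "NormalizationError")

  set.seed(1)
  for (i in 1:1000) {
    p <- rgamma(sample(2:20, 1), shape = runif(1, 0.2, 2))
    p <- p / sum(p)
    h <- hillNumbers(p)
    expect_true(h["d0"] >= h["d1"] - 1e-9 && h["d1"] >= h["d2"] - 1e-9)
  }
})

test_that("dominance selection matches the brute-force rank oracle", {
  mkx <- function(counts) {
    meta <- data.frame(sample_id = colnames(counts), maize = 0, nematode = 0,
                       day = 0, replicate = seq_len(ncol(counts)),
                       shared_baseline = 1)
    makeIdentityExperiment(counts, meta)
  }
  ## single-sample closed-form cases
  c1 <- matrix(c(80L, 20L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_identical(selectDominantAsvs(mkx(c1)), "a")     # 2D = 1.47 -> n 1
  c2 <- matrix(c(40L, 30L, 20L, 10L), 4, 1,
               dimnames = list(letters[1:4], "s1"))
  expect_setequal(selectDominantAsvs(mkx(c2)), c("a", "b", "c"))  # n 3
  c3 <- matrix(rep(10L, 4), 4, 1, dimnames = list(letters[1:4], "s1"))
  expect_setequal(selectDominantAsvs(mkx(c3)), letters[1:4])

  set.seed(42)
  for (i in 1:30) {
    nA <- sample(2:12, 1); nS <- sample(1:5, 1)
    counts <- matrix(rpois(nA * nS, lambda = 20) + 1L, nA, nS,
                     dimnames = list(sprintf("t%02d", seq_len(nA)),
                                     sprintf("s%d", seq_len(nS))))
    x <- mkx(counts)
    expect_setequal(selectDominantAsvs(x),
                    oracleDominant(absoluteAbundance(x)))
  }
})

test_that("prevalence filter matches an exhaustive pattern oracle", {
  ## toy 2-treatment x 2-day design, 3 replicates, every possible
  ## presence/absence pattern over the 12 samples as one ASV each
  meta <- makeDesignMeta(days = c(0, 4), reps = 3, shared = FALSE,
                         nematodeLevels = FALSE)
  expect_identical(nrow(meta), 12L)
  pat <- as.matrix(expand.grid(rep(list(0:1), 12)))
  rownames(pat) <- sprintf("p%04d", seq_len(nrow(pat)))
  colnames(pat) <- meta$sample_id
  ## keep depth positive in every sample
  pat <- rbind(pat, allon = rep(1L, 12))
  x <- makeIdentityExperiment(pat, meta)
  expect_setequal(prevalenceFilter(x, minDetected = 2),
                  oraclePrevalence(pat, meta, 2))
  ## the strict rule: one weak cell kills the ASV
  weak <- pat[rowSums(pat[, meta$sample_id[meta$day == 0 &
                                             meta$maize == 0]]) == 1 &
                rowSums(pat) >= 10, , drop = FALSE]
  expect_false(any(rownames(weak) %in% prevalenceFilter(x)))
  ## "any" mode is a superset of "all" mode
  expect_true(all(prevalenceFilter(x, mode = "all") %in%
                    prevalenceFilter(x, mode = "any")))
})

test_that("shared day-0 samples count for both nematode arms", {
  meta <- makeDesignMeta(days = c(0, 4), reps = 3, shared = TRUE)
  ## ASV detected in 2/3 shared day-0 reps per maize level and all day-4
  ## samples: must pass for all four treatments
  counts <- countsFromRule(c("ok", "miss"), meta,
    function(a, mz, nem, d, r) {
      if (a == "ok") as.integer(d > 0 || r <= 2)
      else as.integer(d > 0)       # never detected at day 0
    })
  counts <- rbind(counts, depth = 5L)
  x <- makeIdentityExperiment(counts, meta)
  kept <- prevalenceFilter(x, minDetected = 2)
  expect_true("ok" %in% kept)
  expect_false("miss" %in% kept)
})

test_that("Pareto selection matches the prefix oracle", {
  ## engineered scores: ranges 50/30/15/5 via one treatment's day-4 jump
  meta <- makeDesignMeta(days = c(0, 4), reps = 2, shared = FALSE)
  jump <- c(a = 50L, b = 30L, c = 15L, d = 5L)
  counts <- countsFromRule(names(jump), meta,
    function(a, mz, nem, d, r)
      100L + if (d == 4 && mz && nem) jump[[a]] else 0L)
  x <- makeIdentityExperiment(counts, meta)
  rep80 <- paretoResponsive(x, names(jump), fraction = 0.8)
  expect_setequal(responsiveAsvs(rep80), c("a", "b"))
  expect_equal(rep80@coverage, 0.8)
  ## ties resolved by ASV id
  countsT <- countsFromRule(paste0("t", 1:5), meta,
    function(a, mz, nem, d, r) 100L + if (d == 4 && mz && nem) 10L else 0L)
  xT <- makeIdentityExperiment(countsT, meta)
  expect_identical(responsiveAsvs(paretoResponsive(xT, paste0("t", 1:5),
                                                   fraction = 0.8)),
                   paste0("t", 1:4))
  ## single candidate
  one <- paretoResponsive(x, "a")
  expect_identical(responsiveAsvs(one), "a")
  expect_equal(one@coverage, 1.0)

  ## randomised instances vs the oracle (<= 12 ASVs)
  set.seed(7)
  for (i in 1:20) {
    nA <- sample(3:12, 1)
    ids <- sprintf("r%02d", seq_len(nA))
    counts <- countsFromRule(ids, meta,
      function(a, mz, nem, d, r) {
        set.seed(sum(utf8ToInt(a)) + d + 10 * mz + 100 * nem)
        50L + sample(0:40, 1) * as.integer(d == 4)
      })
    x <- makeIdentityExperiment(counts, meta)
    f <- runif(1, 0.3, 1)
    got <- sort(responsiveAsvs(paretoResponsive(x, ids, fraction = f)))
    expect_identical(got, oraclePareto(oracleScores(x)[ids], f))
  }
})

test_that("raising the Pareto fraction never shrinks the selection", {
  sim <- simulateDataset(simConfig(sAsvs = 40, depth = 3000), seed = 5)
  x <- sim$experiment
  ids <- rownames(x)
  sizes <- vapply(seq(0.1, 1, by = 0.1), function(f)
    length(responsiveAsvs(paretoResponsive(x, ids, fraction = f))),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_identical(sizes[10], 40)
})

test_that("the selection cascade nests its three sets", {
  sim <- simulateDataset(simConfig(preset = "recovery"), seed = 2)
  sel <- selectResponsiveAsvs(sim$experiment)
  expect_true(all(responsiveAsvs(sel) %in%
                    intersect(sel@dominant, sel@prevalent)))
  expect_gte(sel@coverage, 0.8)
  df <- selectionAsDataFrame(sel)
  expect_true(all(df$responsive == (df$asv_id %in% responsiveAsvs(sel))))
})
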