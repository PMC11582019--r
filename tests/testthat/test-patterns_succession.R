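test_that("patterns assemble in canonical treatment order", {
  x <- tinyExperiment()
  a <- makeAssignments(c("asvA", "asvB"),
                       list(c("D", "D", "B", "E"),
                            rep("STABLE", 4)))
  p <- assemblePatterns(a, x)
  expect_identical(p$pattern[p$asv_id == "asvA"], "D,D,B,E")
  expect_identical(p[p$asv_id == "asvA", "+A/-M"], "B")
  expect_identical(p$pattern[p$asv_id == "asvB"],
                   "STABLE,STABLE,STABLE,STABLE")
  ## medians over every sample of the dataset
  expect_equal(p$median_abundance[p$asv_id == "asvA"],
               median(absoluteAbundance(x)["asvA", ]))
  ## a missing treatment is an error
  aBad <- a[a$treatment != "+A/+M" | a$asv_id != "asvB", ]
  expect_error(assemblePatterns(aBad, x),
               class = "IncompleteAssignmentError")
})

test_that("pattern ranking selects a descending prefix at coverage", {
  x <- tinyExperiment()
  p <- data.frame(asv_id = c("a1", "a2", "a3"),
                  pattern = c("P1", "P2", "P3"),
                  median_abundance = c(60, 25, 15))
  r <- rankPatterns(p, coverage = 0.8)
  expect_identical(r$table$pattern[r$table$selected], c("P1", "P2"))
  expect_equal(r$coverage, 0.85)
  ## single pattern
  r1 <- rankPatterns(p[1, ], coverage = 0.8)
  expect_equal(r1$coverage, 1.0)
  ## equal scores: lexicographic tuple order decides
  pEq <- data.frame(asv_id = paste0("a", 1:3),
                    pattern = c("Z", "M", "B"),
                    median_abundance = c(10, 10, 10))
  rEq <- rankPatterns(pEq, coverage = 0.5)
  expect_identical(rEq$table$pattern, c("B", "M", "Z"))
  expect_identical(rEq$table$pattern[rEq$table$selected], c("B", "M"))
  ## grouping: identical tuples pool their members
  pG <- data.frame(asv_id = paste0("a", 1:4),
                   pattern = c("P1", "P1", "P2", "P2"),
                   median_abundance = c(5, 5, 3, 3))
  rG <- rankPatterns(pG, coverage = 0.6)
  expect_identical(rG$table$n_asvs, c(2L, 2L))
  expect_equal(rG$table$score, c(10, 6))
  ## coverage monotonicity
  sizes <- vapply(seq(0.1, 1, 0.1), function(cv)
    sum(rankPatterns(pG, coverage = cv)$table$selected), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("succession groups match the rule oracle on all 1296 tuples", {
  types <- c("A", "B", "C", "D", "E", "STABLE")
  grid <- expand.grid(t1 = types, t2 = types, t3 = types, t4 = types,
                      stringsAsFactors = FALSE)
  pat <- data.frame(asv_id = sprintf("a%04d", seq_len(nrow(grid))),
                    check.names = FALSE)
  pat[["-A/-M"]] <- grid$t1; pat[["-A/+M"]] <- grid$t2
  pat[["+A/-M"]] <- grid$t3; pat[["+A/+M"]] <- grid$t4
  got <- successionGroups(pat)
  want <- apply(grid, 1, oracleSuccession)
  expect_identical(got$group, unname(want))
  ## the documented examples
  pick <- function(tp) got$group[grid$t1 == tp[1] & grid$t2 == tp[2] &
                                   grid$t3 == tp[3] & grid$t4 == tp[4]]
  expect_identical(pick(c("D", "D", "B", "E")), "III")
  expect_identical(pick(c("C", "C", "A", "A")), "I")
  expect_identical(pick(c("D", "B", "B", "E")), "NONE")
  ## eligibility semantics: NONE can still be eligible
  expect_true(any(got$eligible & got$group == "NONE"))
  expect_true(all(got$eligible[got$group != "NONE"]))
})

test_that("family roll-up conserves the ASV-level total", {
  sim <- simulateDataset(simConfig(sAsvs = 25, depth = 2000), seed = 6)
  x <- sim$experiment
  asvs <- rownames(x)[1:12]
  a <- suppressWarnings(assignResponseTypes(x, asvs, seed = 1))
  ru <- rollupByTaxon(a, x)
  med <- apply(absoluteAbundance(x)[asvs, ], 1, median)
  expect_equal(sum(ru$summed_median_abundance), 4 * sum(med),
               tolerance = 1e-9)
  ## additivity: two ASVs forced into one (family, type, treatment) cell
  meta <- makeDesignMeta(days = c(0, 4), reps = 2, shared = FALSE)
  counts <- countsFromRule(c("u1", "u2"), meta,
                           function(a, mz, nem, d, r)
                             if (a == "u1") 5L else 7L)
  tax <- data.frame(asv_id = c("u1", "u2"), domain = "Bacteria",
                    phylum = "Bacteroidota", class = "", order = "",
                    family = "Chitinophagaceae", genus = "")
  xs <- makeIdentityExperiment(counts, meta, tax)
  as2 <- makeAssignments(c("u1", "u2"),
                         list(rep("STABLE", 4), rep("STABLE", 4)))
  ru2 <- rollupByTaxon(as2, xs)
  cell <- ru2[ru2$treatment == "+A/+M", ]
  expect_identical(cell$display_family, "Chitinophagaceae")
  expect_equal(cell$summed_median_abundance, 12)
  expect_identical(cell$n_asvs, 2L)
})

test_that("type contributions partition the selected community", {
  ## hand-computed 3-ASV fixture over a 2-day design
  meta <- makeDesignMeta(days = c(0, 4), reps = 2, shared = FALSE)
  counts <- countsFromRule(c("h1", "h2", "h3"), meta,
    function(a, mz, nem, d, r)
      switch(a, h1 = 10L + 2L * as.integer(d == 4),
                h2 = 20L, h3 = 30L + 10L * as.integer(d == 4 && mz)))
  x <- makeIdentityExperiment(counts, meta)
  a <- makeAssignments(c("h1", "h2", "h3"),
                       list(rep("C", 4), rep("STABLE", 4), rep("D", 4)))
  tc <- typeContribution(a, x)
  ## day-4 +A/+M: h1 = 12 (type C), h2 = 20 (STABLE), h3 = 40 (type D)
  at <- function(tr, d, tp)
    tc$abundance[tc$treatment == tr & tc$day == d & tc$response_type == tp]
  expect_equal(at("+A/+M", 4, "C"), 12)
  expect_equal(at("+A/+M", 4, "STABLE"), 20)
  expect_equal(at("+A/+M", 4, "D"), 40)
  expect_equal(at("-A/-M", 4, "D"), 30)
  ## partition: strata sum to the summed mean abundance of all ASVs
  traj <- buildTrajectories(x, c("h1", "h2", "h3"))
  v <- trajectoryValues(traj)
  for (tr in canonicalTreatments())
    for (di in 1:2) {
      tot <- sum(tc$abundance[tc$treatment == tr &
                                tc$day == traj@days[di]])
      expect_equal(tot, sum(v[traj@treatment == tr, di]))
    }
  ## single-type input: that type carries everything
  a1 <- makeAssignments("h2", list(rep("E", 4)))
  tc1 <- typeContribution(a1, x)
  expect_true(all(tc1$response_type == "E"))
})
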