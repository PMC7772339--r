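test_that("contingency tables pool endophyte replicates and conserve margins", {
  cnt <- rbind(otu = c(3L, 2L, 1L), rest = c(97L, 98L, 99L))
  colnames(cnt) <- c("p1_endo1", "p1_endo2", "p1_epi")
  tab <- makeTable(cnt)
  md <- data.frame(sample_id = colnames(cnt), system = "sph", area = "A",
                   subsite = "A_s1", plant_label = "Sphagnum_fallax",
                   sample_class = "moss",
                   fraction = c("endophyte", "endophyte", "epiphyte"),
                   plant_unit = "p1", hydrology = "submerged",
                   pH = 4, temperature = 10, ch4 = 50, stringsAsFactors = FALSE)
  ct <- buildContingency(tab, md, "p1", "otu")
  expect_equal(unclass(ct)[1:4], c(5L, 1L, 195L, 99L))  # [[5,195],[1,99]]
  expect_equal(unname(rowSums(ct)), c(200L, 100L))
  # absent OTU is flagged untestable
  cnt2 <- rbind(otu = c(0L, 0L, 0L), rest = c(100L, 100L, 100L))
  colnames(cnt2) <- colnames(cnt)
  ct0 <- buildContingency(makeTable(cnt2), md, "p1", "otu")
  expect_true(attr(ct0, "untestable"))
  expect_error(buildContingency(tab, md, "p2", "otu"), "p2")
  # random fixtures: marginals always equal the library totals
  st <- generateStudy(smallStudyConfig(seed = 13))
  u <- st$metadata$plant_unit[!is.na(st$metadata$plant_unit)][1]
  libs <- st$metadata$sample_id[!is.na(st$metadata$plant_unit) &
                                  st$metadata$plant_unit == u]
  ctr <- buildContingency(st$table, st$metadata, u, otuIds(st$table)[1])
  tots <- librarySizes(st$table)[libs]
  fr <- st$metadata$fraction[match(libs, st$metadata$sample_id)]
  expect_equal(unname(rowSums(ctr)),
               unname(c(sum(tots[fr == "endophyte"]), sum(tots[fr == "epiphyte"]))))
})

test_that("Monte-Carlo chi-square matches trivial and enumerated cases", {
  eq <- monteCarloChisq(matrix(c(10, 10, 90, 90), 2, 2), seed = 1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # full hypergeometric enumeration of [[3,0],[0,3]] gives p = 2/20
  tab <- matrix(c(3, 0, 0, 3), 2, 2)
  expect_equal(exactChisqP(tab), 0.1)
  mc <- monteCarloChisq(tab, n_rep = 5000, seed = 2)
  se <- sqrt(0.1 * 0.9 / 5000)
  expect_lt(abs(mc$p_value - 0.1), 3 * se + 1 / 5001)
  # p never below the estimator floor
  big <- matrix(c(500, 5, 5, 500), 2, 2)
  expect_gte(monteCarloChisq(big, n_rep = 999, seed = 3)$p_value, 1 / 1000)
  # zero margin: untestable by convention
  z <- monteCarloChisq(matrix(c(0, 0, 5, 5), 2, 2), seed = 4)
  expect_true(z$untestable)
  expect_equal(z$p_value, 1)
  expect_error(monteCarloChisq(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
})

test_that("general RxC sampling agrees with the base simulate-p contingency test", {
  t3 <- withr::with_seed(4, matrix(rpois(9, 8) + 1, 3, 3))
  mc <- monteCarloChisq(t3, n_rep = 10000, seed = 8)
  ct <- stats::chisq.test(t3, simulate.p.value = TRUE, B = 10000)
  expect_equal(mc$statistic, unname(ct$statistic), tolerance = 1e-12)
  se <- sqrt(ct$p.value * (1 - ct$p.value) / 10000)
  expect_lt(abs(mc$p_value - ct$p.value), 3 * se + 2 / 10001)
})

test_that("the screen applies the abundance and significance gates", {
  # planted: OTU 'endo' strongly enriched in endophyte libraries of 5 units;
  # OTU 'few' abundant in only 3 units; OTU 'flat' equal everywhere
  nU <- 5
  ids <- unlist(lapply(seq_len(nU), function(i)
    paste0("u", i, c("_e1", "_e2", "_ep"))))
  md <- data.frame(sample_id = ids, system = "sph", area = "A",
                   subsite = "A_s1", plant_label = "Sphagnum_fallax",
                   sample_class = "moss",
                   fraction = rep(c("endophyte", "endophyte", "epiphyte"), nU),
                   plant_unit = rep(paste0("u", seq_len(nU)), each = 3),
                   hydrology = "submerged", pH = 4, temperature = 10, ch4 = 1,
                   stringsAsFactors = FALSE)
  base <- 10000L
  cnt <- matrix(0L, 3, 3 * nU, dimnames = list(c("endo", "few", "flat"), ids))
  for (i in seq_len(nU)) {
    e <- (i - 1) * 3 + 1:2; ep <- (i - 1) * 3 + 3
    cnt["endo", e] <- 400L; cnt["endo", ep] <- 20L
    cnt["few", e] <- if (i <= 3) 300L else 2L
    cnt["few", ep] <- 2L
    cnt["flat", c(e, ep)] <- 100L
  }
  filler <- base - colSums(cnt)
  cnt <- rbind(cnt, matrix(0L, 37, 3 * nU))
  rownames(cnt)[4:40] <- sprintf("bg%02d", 1:37)
  cnt[4, ] <- as.integer(filler)
  tab <- makeTable(cnt)
  # n_rep chosen so the Monte-Carlo p floor 1/(n_rep+1) lies below alpha
  scr <- classifyEndophytes(tab, md, min_samples = 4L, n_rep = 1999, seed = 3)
  calls <- scr$calls
  expect_true(calls$qualifies[calls$otu_id == "endo"])
  # abundant in only 3 units: filtered out regardless of significance
  expect_false("few" %in% calls$otu_id[calls$qualifies])
  if ("flat" %in% calls$otu_id) {
    expect_false(calls$qualifies[calls$otu_id == "flat"])
  }
  # determinism under seed
  scr2 <- classifyEndophytes(tab, md, min_samples = 4L, n_rep = 1999, seed = 3)
  expect_identical(scr$tests$p_value, scr2$tests$p_value)
})

test_that("replicate-consistent units are always called endophyte-higher", {
  # whenever both endophyte technical replicates individually exceed the
  # epiphyte relative abundance, pooling them must not flip the direction
  st <- generateStudy(smallStudyConfig(seed = 17))
  scr <- classifyEndophytes(st$table, st$metadata, n_rep = 199, seed = 17)
  rel <- relativeAbundance(st$table)
  md <- st$metadata
  checked <- 0L
  for (i in seq_len(nrow(scr$tests))) {
    tt <- scr$tests[i, ]
    eIds <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == tt$plant_unit &
                           md$fraction == "endophyte"]
    pIds <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == tt$plant_unit &
                           md$fraction == "epiphyte"]
    if (all(rel[tt$otu_id, eIds] > rel[tt$otu_id, pIds])) {
      expect_equal(tt$direction, "endo_higher")
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("heatmap matrix applies the log2 scale and clusters both axes", {
  st <- generateStudy(studyConfig(seed = 5))
  scr <- classifyEndophytes(st$table, st$metadata, n_rep = 1000, seed = 5)
  nQ <- sum(scr$calls$qualifies)
  expect_gt(nQ, 0)
  hm <- heatmapMatrix(scr)
  expect_equal(nrow(hm$matrix), nQ)
  expect_equal(ncol(hm$matrix), scr$params$n_units)
  # closed-form entries: relabund 0.001 -> log2(100); 1e-5 -> 0
  expect_equal(unname(log2(0.001 * 1e5)), 6.643856, tolerance = 1e-6)
  tt <- scr$tests[scr$tests$otu_id %in% rownames(hm$matrix) &
                    scr$tests$endo_mean_relabund > 0, ]
  i <- which.max(tt$endo_mean_relabund)
  expect_equal(hm$matrix[tt$otu_id[i], tt$plant_unit[i]],
               log2(tt$endo_mean_relabund[i] * 1e5), tolerance = 1e-9)
  expect_s4_class(hm$row_dendrogram, "DendrogramResult")
  expect_error(heatmapMatrix(list(calls = data.frame(otu_id = "x",
                                                     qualifies = FALSE),
                                  tests = NULL)), "no qualifying")
})
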