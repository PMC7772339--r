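test_that("TSV round trip preserves the table", {
  tab <- makeTable(matrix(c(5L, 0L, 2L, 3L, 1L, 9L), 3, 2),
                   taxonomy = c("k__Bacteria; p__A", "k__Bacteria; p__B",
                                "k__Bacteria; p__C"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeOtuTable(tab, path)
  back <- readOtuTable(path)
  expect_equal(counts(back), counts(tab))
  expect_equal(taxonomy(back), taxonomy(tab))
  expect_equal(otuIds(back), otuIds(tab))
  expect_equal(sampleIds(back), sampleIds(tab))
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeOtuTable(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reader rejects malformed tables and tolerates missing taxonomy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2\ttaxonomy",
               "A\t1\t2\tk__Bacteria",
               "A\t3\t4\tk__Bacteria"), path)
  expect_error(readOtuTable(path), "duplicate OTU identifier.*A")
  writeLines(c("otu_id\ts1\ts2\ttaxonomy",
               "A\t1\t2\tk__Bacteria",
               "B\t-3\t4\tk__Bacteria"), path)
  expect_error(readOtuTable(path), "negative count.*'B'.*'s1'")
  writeLines(c("otu_id\ts1\ts2\ttaxonomy",
               "A\t1\t2\tk__Bacteria",
               "B\t3.5\t4\tk__Bacteria"), path)
  expect_error(readOtuTable(path), "non-integer count")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t2", "B\t3\t4"), path)
  expect_warning(tab <- readOtuTable(path), "taxonomy")
  expect_equal(unname(taxonomy(tab)), c("Unassigned", "Unassigned"))
})

test_that("BIOM files are converted on read", {
  m <- matrix(c(5L, 0L, 2L, 3L, 1L, 9L), 3, 2,
              dimnames = list(paste0("o", 1:3), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), path)
  expect_warning(back <- readOtuTable(path, format = "biom"), "taxonomy")
  expect_equal(counts(back)[rownames(m), colnames(m)], m)
})

test_that("taxonomy filter drops excluded lineages and wrong-domain OTUs", {
  tax <- c("k__Bacteria; p__Cyanobacteria; c__Chloroplast; o__Streptophyta",
           "k__Bacteria; p__Acidobacteria",
           "k__Archaea; p__Euryarchaeota",
           "k__Bacteria; p__Proteobacteria",
           "k__Bacteria; p__Verrucomicrobia")
  tab <- makeTable(matrix(1L, 5, 3), taxonomy = tax)
  out <- filterTaxa(tab)
  expect_equal(nrow(out), 3L)  # chloroplast + archaeal OTU removed
  expect_false(any(grepl("Chloroplast|Archaea", taxonomy(out))))
  # archaeal table with a bacterial contaminant
  atab <- makeTable(matrix(1L, 2, 2),
                    taxonomy = c("k__Archaea; p__Euryarchaeota",
                                 "k__Bacteria; p__Firmicutes"),
                    domain = "archaea")
  expect_equal(nrow(filterTaxa(atab)), 1L)
  # no matches: identity
  clean <- makeTable(matrix(1L, 2, 2),
                     taxonomy = rep("k__Bacteria; p__Acidobacteria", 2))
  expect_equal(counts(filterTaxa(clean)), counts(clean))
  # removing everything is an error
  allchl <- makeTable(matrix(1L, 1, 2), taxonomy = "k__Bacteria; c__Chloroplast")
  expect_error(filterTaxa(allchl), "every OTU")
})

test_that("rare filter zeroes strictly below threshold and keeps the boundary", {
  cnt <- matrix(c(1L, 9999L,      # s1 total 10000: entry 1 is exactly 0.01%
                  9L, 99991L),    # s2 total 100000: entry 9 is 0.009%
                2, 2, dimnames = list(c("lo", "hi"), c("s1", "s2")))
  tab <- makeTable(cnt)
  out <- filterRare(tab, min_fraction = 1e-4)
  # boundary entry kept (strict "<"), sub-threshold entry zeroed
  expect_equal(counts(out)["lo", "s1"], 1L)
  expect_equal(counts(out)["lo", "s2"], 0L)
  expect_equal(S4Vectors::metadata(out)$rareFilter$entries_zeroed, 1L)
  # nothing below threshold: identity
  big <- makeTable(matrix(c(100L, 200L, 300L, 400L), 2, 2))
  expect_equal(counts(filterRare(big)), counts(big))
  # all-zero rows are dropped
  tiny <- makeTable(matrix(c(1L, 50000L, 2L, 60000L), 2, 2))
  out2 <- filterRare(tiny)
  expect_equal(nrow(out2), 1L)
  expect_equal(S4Vectors::metadata(out2)$rareFilter$otus_dropped, "OTU_001")
  expect_error(filterRare(tab, min_fraction = 0), "min_fraction")
  expect_error(filterRare(tab, min_fraction = 1), "min_fraction")
})

test_that("rare filter is idempotent and never increases counts or dimensions", {
  tab <- randomTable(40, 8, lambda = 2, seed = 3)
  f1 <- filterRare(tab, min_fraction = 0.01)
  f2 <- filterRare(f1, min_fraction = 0.01)
  # second pass recomputes against the already-filtered totals; entries that
  # survived round one stay (totals only shrank at most slightly)
  expect_true(all(counts(f1)[otuIds(f2), ] >= counts(f2)))
  expect_lte(nrow(f1), nrow(tab))
  expect_true(all(counts(f1) <= counts(tab)[otuIds(f1), ]))
  ft <- filterTaxa(tab, exclude_patterns = "nomatch")
  expect_equal(dim(ft), dim(tab))
})

test_that("relative abundance puts every sample on the simplex", {
  expect_equal(relativeAbundance(matrix(c(2, 2, 6), 3, 1,
               dimnames = list(letters[1:3], "s")))[, 1],
               c(a = 0.2, b = 0.2, c = 0.6))
  one <- makeTable(matrix(c(5L, 7L), 1, 2))
  expect_true(all(relativeAbundance(one) == 1))
  for (seed in 1:5) {
    tab <- randomTable(30, 6, seed = seed)
    expect_equal(unname(colSums(relativeAbundance(tab))), rep(1, 6))
  }
  bad <- cbind(ok = c(1, 2), empty = c(0, 0))
  expect_error(relativeAbundance(bad), "empty")
})

test_that("hellinger columns have unit squared norm", {
  h <- hellinger(matrix(c(1, 1, 1, 1), 4, 1, dimnames = list(1:4, "s")))
  expect_equal(unname(h[, 1]), rep(0.5, 4))
  h2 <- hellinger(matrix(c(4, 0), 2, 1, dimnames = list(1:2, "s")))
  expect_equal(unname(h2[, 1]), c(1, 0))
  for (seed in 1:5) {
    tab <- randomTable(25, 7, seed = seed + 10)
    expect_equal(unname(colSums(hellinger(tab)^2)), rep(1, 7))
  }
})

test_that("metadata validation enforces the paired-design invariants", {
  st <- generateStudy(smallStudyConfig(seed = 2))
  expect_silent(validateSampleMetadata(st$metadata, table = st$table))
  bad <- st$metadata
  bad$plant_unit[bad$fraction == "endophyte"][1] <- NA
  expect_error(validateSampleMetadata(bad), "plant_unit")
  bad2 <- st$metadata
  bad2$pH[1] <- 15
  expect_error(validateSampleMetadata(bad2), "pH")
  # metadata TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSampleMetadata(st$metadata, path)
  back <- readSampleMetadata(path)
  expect_equal(back$sample_id, st$metadata$sample_id)
  expect_equal(back$pH, st$metadata$pH, tolerance = 1e-9)
  tab <- attachSampleData(st$table, back)
  expect_equal(sampleData(tab)$system,
               st$metadata$system[match(sampleIds(tab), st$metadata$sample_id)])
})
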