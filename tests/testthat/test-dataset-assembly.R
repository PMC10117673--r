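test_that("positive set is the reviewed union of DTI targets and biomarkers", {
  # printed dataset arithmetic: 24 unique approved targets + 91 disjoint
  # biomarkers, all reviewed -> 115 positives
  targets <- randomGeneSymbols(24, "TGT")
  biomarkers <- randomGeneSymbols(91, "BIO")
  flags <- setNames(rep(TRUE, 115), c(targets, biomarkers))
  pos <- buildPositiveSet(data.frame(drug_id = "D", gene_symbol = targets),
                          biomarkers, flags)
  expect_equal(nrow(pos), 115)
  expect_true(all(pos$label == 1L))

  # union with an empty biomarker list
  pos2 <- buildPositiveSet(data.frame(gene_symbol = c("A", "B", "C")),
                           character(), c(A = TRUE, B = TRUE, C = TRUE))
  expect_equal(nrow(pos2), 3)

  # overlapping sources collapse by set union
  pos3 <- buildPositiveSet(data.frame(gene_symbol = c("A", "B")),
                           c("B", "C"), c(A = TRUE, B = TRUE, C = TRUE))
  expect_setequal(pos3$symbol, c("A", "B", "C"))

  # unreviewed genes are removed; an empty result is an error
  pos4 <- buildPositiveSet(data.frame(gene_symbol = c("A", "B")), character(),
                           c(A = TRUE, B = FALSE))
  expect_equal(pos4$symbol, "A")
  expect_error(buildPositiveSet(data.frame(gene_symbol = "A"), character(),
                                c(A = FALSE)),
               "no positive genes")
})

test_that("positive-set size matches a brute-force set-union oracle", {
  withr::with_seed(42, {
    for (i in 1:25) {
      universe <- randomGeneSymbols(60)
      dti <- sample(universe, sample(5:30, 1), replace = TRUE)
      bio <- sample(universe, sample(0:30, 1))
      flags <- setNames(sample(c(TRUE, FALSE), 60, replace = TRUE), universe)
      oracle <- sum(flags[unique(c(dti, bio))])
      if (oracle == 0) {
        expect_error(suppressMessages(
          buildPositiveSet(data.frame(gene_symbol = dti), bio, flags)))
      } else {
        pos <- suppressMessages(
          buildPositiveSet(data.frame(gene_symbol = dti), bio, flags))
        expect_equal(nrow(pos), oracle)
      }
    }
  })
})

test_that("negative pool removes all positives and guards its size", {
  pool_tab <- data.frame(gene_symbol = randomGeneSymbols(10))
  pos <- pool_tab$gene_symbol[1:3]
  expect_length(buildNegativePool(pool_tab, pos), 7)
  expect_length(buildNegativePool(pool_tab, c("ZZZ1", "ZZZ2")), 10)
  expect_error(buildNegativePool(pool_tab, pool_tab$gene_symbol),
               "insufficient negative pool")
  expect_error(buildNegativePool(pool_tab, pos, min_size = 8),
               "insufficient negative pool")
})

test_that("negative sampling is balanced, deterministic and non-overlapping", {
  pool <- randomGeneSymbols(500)
  # k = 215 mirrors the largest per-cancer positive count in the curated data
  neg <- sampleNegatives(pool, 215, seed = 3)
  expect_equal(nrow(neg), 215)
  expect_true(all(neg$label == 0L))

  expect_identical(sampleNegatives(pool, 50, seed = 7),
                   sampleNegatives(pool, 50, seed = 7))

  # threading already_used gives disjoint draws
  withr::with_seed(99, {
    for (i in 1:100) {
      s1 <- sampleNegatives(pool, 40, seed = sample.int(1e6, 1))
      s2 <- sampleNegatives(pool, 40, seed = sample.int(1e6, 1),
                            already_used = s1$symbol)
      expect_length(intersect(s1$symbol, s2$symbol), 0)
    }
  })

  expect_error(sampleNegatives(pool[1:30], 40, seed = 1), "short by 10")
})

test_that("assembled datasets are balanced with disjoint classes", {
  pos <- geneRecords(randomGeneSymbols(215, "P"), 1L)
  neg <- geneRecords(randomGeneSymbols(215, "N"), 0L)
  ds <- assembleDataset("leukemia", pos, neg)
  expect_equal(length(geneSymbols(ds)), 430)
  expect_equal(nrow(positives(ds)), nrow(negatives(ds)))

  tiny <- assembleDataset("toy", geneRecords("A", 1L), geneRecords("B", 0L))
  expect_equal(length(geneSymbols(tiny)), 2)

  expect_error(assembleDataset("bad", geneRecords(c("A", "B"), 1L),
                               geneRecords(c("B", "C"), 0L)),
               "unique")
  expect_error(assembleDataset("bad", geneRecords(c("A", "B"), 1L),
                               geneRecords("C", 0L)),
               "imbalanced")
})

test_that("multi-cancer assembly keeps negatives pairwise disjoint and reruns identically", {
  universe <- randomGeneSymbols(400)
  dti <- list(alpha = data.frame(gene_symbol = universe[1:20]),
              beta = data.frame(gene_symbol = universe[21:35]),
              gamma = data.frame(gene_symbol = universe[36:40]))
  bio <- list(alpha = universe[41:50], beta = universe[51:55],
              gamma = character())
  pool <- data.frame(gene_symbol = universe, reviewed = TRUE)

  asm <- assembleCancerDatasets(dti, bio, pool, master_seed = 17)
  negs <- lapply(asm$datasets, function(d) negatives(d)$symbol)
  expect_equal(length(unlist(negs)), length(unique(unlist(negs))))
  for (d in asm$datasets) {
    expect_equal(nrow(positives(d)), nrow(negatives(d)))
  }
  # negatives never come from any cancer's positive set
  all_pos <- unique(unlist(lapply(asm$datasets, function(d) positives(d)$symbol)))
  expect_length(intersect(unlist(negs), all_pos), 0)

  # byte-identical rerun
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  writeDatasets(asm, out1)
  writeDatasets(assembleCancerDatasets(dti, bio, pool, master_seed = 17), out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # manifest reports both per-cancer and global-unique counts
  expect_true(asm$manifest$total_unique_genes <= asm$manifest$total_records)

  # datasets round-trip through the file format
  ds_back <- readDatasetFile(file.path(out1, "alpha_dataset.tsv"))
  expect_equal(geneData(ds_back)$symbol, geneData(asm$datasets$alpha)$symbol)
  expect_equal(geneData(ds_back)$label, geneData(asm$datasets$alpha)$label)
})

test_that("genes without sequences are dropped from records with a warning", {
  recs <- geneRecords(c("A", "B", "C"), 1L)
  seqs <- c(A = "MKV", C = "ACDE")
  expect_warning(kept <- attachSequences(recs, seqs), "no sequence")
  expect_setequal(kept$symbol, c("A", "C"))
  expect_equal(kept$sequence[kept$symbol == "A"], "MKV")
})
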