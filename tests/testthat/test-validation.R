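toyGDI <- function() {
  nds <- sprintf("g%d", 1:12)
  targets <- c("g2", "g3", "g4", "g5")
  ed <- data.frame(source = "g1", target = targets, weight = 0.25,
                   numerator = 1, denominator = 4, stringsAsFactors = FALSE)
  new("GDINetwork", nodes = nds, edges = ed, provenance = list())
}

test_that("mean-threshold binarization handles plain and constant genes", {
  se <- expressionExperiment(
    matrix(c(1, 2, 3, 4,
             5, 5, 5, 5), nrow = 2, byrow = TRUE,
           dimnames = list(c("gA", "gB"), sprintf("s%d", 1:4))),
    c("wt", "wt", "ko:gA", "ko:gA"))
  expect_warning(bin <- binarizeExpression(se), "constant gene")
  b <- SummarizedExperiment::assay(bin, "binary")
  expect_identical(unname(b["gA", ]), c(0L, 0L, 1L, 1L))  # mean 2.5
  expect_identical(unname(b["gB", ]), rep(0L, 4))
})

test_that("k-means binarization agrees with the mean threshold on separated data", {
  set.seed(120)
  values <- rbind(lo = c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1)))
  values <- values[rep(1, 6), ]
  rownames(values) <- sprintf("g%d", 1:6)
  values <- values + rnorm(length(values), sd = 0.05)
  se <- expressionExperiment(values, c(rep("wt", 4), rep("ko:g1", 4)))
  b1 <- SummarizedExperiment::assay(binarizeExpression(se, "gene_mean"), "binary")
  b2 <- SummarizedExperiment::assay(binarizeExpression(se, "two_means"), "binary")
  expect_identical(b1, b2)
})

test_that("binarization is idempotent on binary matrices with both values present", {
  set.seed(121)
  values <- matrix(sample(0:1, 40, replace = TRUE), nrow = 5,
                   dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  values[, 1] <- 0; values[, 2] <- 1  # every gene has both values
  se <- expressionExperiment(values, c(rep("wt", 4), rep("ko:g1", 4)))
  b <- SummarizedExperiment::assay(binarizeExpression(se), "binary")
  expect_identical(b, matrix(as.integer(values), nrow = 5,
                             dimnames = dimnames(values)))
})

test_that("affected sets compare majority consensus between conditions", {
  # identical profiles -> empty set
  values <- matrix(rep(c(1, 5, 1, 5), each = 4), nrow = 4, byrow = TRUE,
                   dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:4)))
  se <- expressionExperiment(values, c("wt", "wt", "ko:g9", "ko:g9"))
  expect_warning(bin <- binarizeExpression(se), "constant gene")
  expect_identical(affectedGeneSet(bin, "g9"), character(0))

  # single wt / single ko, one gene flipped
  values <- matrix(c(0, 10,
                     3, 3.1,
                     7, 7.1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gX", "gY", "gZ"), c("s1", "s2")))
  se <- expressionExperiment(values, c("wt", "ko:gQ"))
  # gX flips; gY/gZ cross their means too with 2 samples, so restrict check
  bin <- binarizeExpression(se)
  expect_true("gX" %in% affectedGeneSet(bin, "gQ"))

  expect_error(affectedGeneSet(bin, "gMissing"), "at least one")
  expect_error(affectedGeneSet(se, "gQ"), "binarize")
})

test_that("a noiseless planted knockout is recovered exactly", {
  gdi <- toyGDI()
  se <- synthesizeKnockoutDataset(gdi, "g1", nWt = 5, nKo = 5,
                                  noiseSd = 0, effectSize = 4, seed = 31)
  bin <- suppressWarnings(binarizeExpression(se))
  expSet <- affectedGeneSet(bin, "g1")
  expect_setequal(expSet, gdiOutSet(gdi, "g1"))
  expect_equal(precisionRatio(expSet, gdiOutSet(gdi, "g1")), 1)
  # determinism
  se2 <- synthesizeKnockoutDataset(gdi, "g1", nWt = 5, nKo = 5,
                                   noiseSd = 0, effectSize = 4, seed = 31)
  expect_identical(SummarizedExperiment::assay(se, "expr"),
                   SummarizedExperiment::assay(se2, "expr"))
})

test_that("with no effect the recovered ratio matches the random-overlap expectation", {
  gdi <- toyGDI()
  ratios <- sapply(1:120, function(s) {
    res <- validateKnockout(gdi,
      synthesizeKnockoutDataset(gdi, "g1", nWt = 5, nKo = 5,
                                noiseSd = 0.5, effectSize = 0, seed = s),
      "g1")
    res$ratio
  })
  ratios <- ratios[!is.na(ratios)]
  # affected genes are exchangeable, so E[ratio] ~ |GDI_O| / (|V| - 1)
  expected <- length(gdiOutSet(gdi, "g1")) / (length(nodes(gdi)) - 1)
  expect_lt(abs(mean(ratios) - expected), 0.1)
})

test_that("precision ratios are set arithmetic with an explicit undefined case", {
  expect_equal(precisionRatio(c("a", "b"), c("b", "c")), 0.5)
  expect_equal(precisionRatio(c("a", "b"), c("x")), 0)
  expect_equal(precisionRatio(c("a", "b"), c("a", "b", "c")), 1)
  expect_error(precisionRatio(character(0), "a"),
               class = "gdinet_undefined_ratio")
})

test_that("GDI out-sets equal an independent adjacency scan", {
  gdi <- toyGDI()
  expect_setequal(gdiOutSet(gdi, "g1"), c("g2", "g3", "g4", "g5"))
  expect_identical(gdiOutSet(gdi, "g7"), character(0))
  expect_error(gdiOutSet(gdi, "nope"), "unknown gene")
  ed <- edges(gdi)
  expect_setequal(gdiOutSet(gdi, "g1"),
                  unique(ed$target[ed$source == "g1"]))
})

test_that("expression matrices round-trip through the TSV format", {
  gdi <- toyGDI()
  se <- synthesizeKnockoutDataset(gdi, "g1", seed = 77)
  tf <- tempfile(fileext = ".tsv")
  writeExpression(se, tf)
  back <- readExpression(tf)
  expect_equal(SummarizedExperiment::assay(back, "expr"),
               SummarizedExperiment::assay(se, "expr"))
  expect_identical(as.character(SummarizedExperiment::colData(back)$condition),
                   as.character(SummarizedExperiment::colData(se)$condition))
})
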