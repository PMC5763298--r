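test_that("initial-state sets enumerate or sample distinct states reproducibly", {
  S <- sampleInitialStates(10, exhaustive = TRUE)
  expect_equal(nrow(initialStates(S)), 1024)
  expect_equal(anyDuplicated(apply(initialStates(S), 1, paste, collapse = "")), 0)

  # distinctness forces exhaustion of the space
  S3 <- sampleInitialStates(3, count = 8, exhaustive = FALSE, seed = 5)
  expect_equal(sort(apply(initialStates(S3), 1, paste, collapse = "")),
               sort(apply(initialStates(sampleInitialStates(3, exhaustive = TRUE)),
                          1, paste, collapse = "")))

  A <- sampleInitialStates(44, count = 2000, exhaustive = FALSE, seed = 9)
  B <- sampleInitialStates(44, count = 2000, exhaustive = FALSE, seed = 9)
  C <- sampleInitialStates(44, count = 2000, exhaustive = FALSE, seed = 10)
  expect_identical(initialStates(A), initialStates(B))
  expect_false(identical(initialStates(A), initialStates(C)))
  expect_equal(nrow(initialStates(A)), 2000)

  expect_error(sampleInitialStates(3, count = 9, exhaustive = FALSE), "distinct")
})

test_that("alignment distance matches its literal formula on all short sequence pairs", {
  expect_equal(as.numeric(sequenceDistance(c(0, 1), c(0, 0, 0, 1))), 1 / 4)
  expect_equal(as.numeric(sequenceDistance(c(1, 0, 1), c(1, 0, 1))), 0)
  expect_equal(as.numeric(sequenceDistance(1, 0)), 1)

  allSeqs <- function(p) {
    m <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
    lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  }
  seqs <- unlist(lapply(1:4, allSeqs), recursive = FALSE)
  for (a in seqs) {
    for (b in seqs) {
      d <- sequenceDistance(a, b)
      o <- oracleDistance(a, b)
      expect_equal(numerator(d), o[["numerator"]])
      expect_equal(denominator(d), o[["denominator"]])
      # symmetry and unrolling invariance
      d2 <- sequenceDistance(b, a)
      expect_equal(as.numeric(d), as.numeric(d2))
      expect_equal(as.numeric(sequenceDistance(rep(a, 3), b)), as.numeric(d))
    }
  }
})

test_that("influence is the exact mean of per-state distances and caching is transparent", {
  set.seed(414)
  for (rep in 1:6) {
    net <- randomTestNetwork(5, p = 0.4)
    rs <- randomRuleSet(net)
    S <- sampleInitialStates(5, exhaustive = TRUE)
    for (T in c(1, 5)) {
      im <- influenceMatrix(net, rs, S, duration = T)
      pairs <- expand.grid(i = nodes(net), j = nodes(net),
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$i != pairs$j, ]
      pick <- pairs[sample.int(nrow(pairs), 6), ]
      for (r in seq_len(nrow(pick))) {
        # per-pair re-simulation path (no shared attractor caching)
        d <- dynamicsInfluence(net, rs, pick$i[r], pick$j[r], S, duration = T)
        expect_equal(numerator(im)[pick$i[r], pick$j[r]], numerator(d))
        expect_equal(denominator(im)[pick$i[r], pick$j[r]], denominator(d))
      }
    }
  }
})

test_that("influence cannot flow against graph reachability", {
  chain <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "c"),
                                 sign = "+"))
  rs <- randomRuleSet(chain, seed = 2)
  S <- sampleInitialStates(3, exhaustive = TRUE)
  # c has no path to a
  expect_equal(as.numeric(dynamicsInfluence(chain, rs, "c", "a", S,
                                            duration = 5)), 0)
})

test_that("the GDI edge rule is strict positivity on exact fractions", {
  nds <- c("a", "b", "c")
  num <- den <- matrix(NA_real_, 3, 3, dimnames = list(nds, nds))
  off <- row(num) != col(num)
  num[off] <- 0; den[off] <- 1
  m0 <- new("InfluenceMatrix", numerator = num, denominator = den,
            nodes = nds, provenance = list())
  expect_equal(nrow(edges(buildGDINetwork(m0))), 0)

  num["a", "b"] <- 1; den["a", "b"] <- 1024
  m1 <- new("InfluenceMatrix", numerator = num, denominator = den,
            nodes = nds, provenance = list())
  gdi <- buildGDINetwork(m1)
  expect_equal(nrow(edges(gdi)), 1)
  expect_equal(edges(gdi)$weight, 1 / 1024)

  # edge count equals an independent recount of positive entries
  set.seed(21)
  num[off] <- sample(0:3, 6, replace = TRUE); den[off] <- 4
  m2 <- new("InfluenceMatrix", numerator = num, denominator = den,
            nodes = nds, provenance = list())
  expect_equal(nrow(edges(buildGDINetwork(m2))), sum(num[off] > 0))
})

test_that("pair classification partitions edges with the counting identities", {
  gmi <- gmiNetwork(data.frame(source = "a", target = "b", sign = "+"),
                    nodes = c("a", "b", "c"))
  ed <- data.frame(source = c("a", "a"), target = c("b", "c"),
                   weight = c(0.5, 0.25), numerator = c(1, 1),
                   denominator = c(2, 4))
  gdi <- new("GDINetwork", nodes = c("a", "b", "c"), edges = ed,
             provenance = list())
  cls <- classifyPairs(gmi, gdi)
  ct <- pairCounts(cls)
  expect_equal(unname(ct[c("MIDI", "MNDI", "MIDN")]), c(1L, 1L, 0L))

  # identities on random graph pairs
  set.seed(31)
  for (rep in 1:20) {
    g1 <- randomTestNetwork(6, p = 0.3)
    ed2 <- randomTestNetwork(6, p = 0.3)@edges
    gdi2 <- new("GDINetwork", nodes = nodes(g1),
                edges = data.frame(source = ed2$source, target = ed2$target,
                                   weight = 0.5, numerator = 1,
                                   denominator = 2),
                provenance = list())
    ct <- pairCounts(classifyPairs(g1, gdi2))
    expect_equal(ct[["gmiEdges"]], ct[["MIDI"]] + ct[["MIDN"]])
    expect_equal(ct[["gdiEdges"]], ct[["MIDI"]] + ct[["MNDI"]])
  }
  expect_error(classifyPairs(randomTestNetwork(4), gdi),
               class = "gdinet_validation_error")
})

test_that("influence matrices fill all ordered pairs and round-trip through TSV", {
  fx <- generateFixture("demo4")
  S <- sampleInitialStates(4, exhaustive = TRUE)
  im <- influenceMatrix(fx$network, fx$rules, S, duration = 2)
  off <- row(numerator(im)) != col(numerator(im))
  expect_equal(sum(off), 4 * 3)
  expect_false(anyNA(numerator(im)[off]))
  expect_true(all(influenceValues(im)[off] >= 0 & influenceValues(im)[off] <= 1))

  tf <- tempfile(fileext = ".tsv")
  writeInfluenceMatrix(im, tf)
  back <- readInfluenceMatrix(tf)
  expect_identical(back@numerator, numerator(im))
  expect_identical(back@denominator, denominator(im))
})
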