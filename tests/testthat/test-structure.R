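# Exhaustive path/cycle enumeration oracle: grow all walks without node
# repeats, count those ending at the target.
oraclePaths <- function(net, from, to, maxLen) {
  adj <- gdinet:::adjacencyList(net)
  count <- 0L
  grow <- function(path) {
    if (length(path) - 1L > maxLen) return()
    last <- path[length(path)]
    if (last == to && length(path) > 1L) { count <<- count + 1L; return() }
    for (nxt in adj[[last]])
      if (!(nxt %in% path) || nxt == to) grow(c(path, nxt))
  }
  grow(from)
  count
}

# All simple cycles (canonical rotation = lexicographically smallest start),
# filtered for membership of both nodes.
oracleCycles <- function(net, vi, vj, maxLen) {
  adj <- gdinet:::adjacencyList(net)
  cycles <- character(0)
  grow <- function(path) {
    if (length(path) - 1L > maxLen) return()
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt == path[1L] && length(path) > 1L) {
        cyc <- path
        rot <- which(cyc == min(cyc))[1L]
        canon <- paste(c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)]),
                       collapse = ">")
        cycles <<- union(cycles, canon)
      } else if (!(nxt %in% path)) {
        grow(c(path, nxt))
      }
    }
  }
  for (v in nodes(net)) grow(v)
  sum(vapply(strsplit(cycles, ">", fixed = TRUE),
             function(cyc) (vi %in% cyc) && (vj %in% cyc) &&
                           length(cyc) <= maxLen, logical(1)))
}

test_that("shortest paths count edges and flag unreachable pairs", {
  net <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "c"),
                               sign = "+"))
  expect_equal(shortestPathLength(net, "a", "b"), 1)
  expect_equal(shortestPathLength(net, "a", "c"), 2)
  expect_equal(shortestPathLength(net, "c", "a"), Inf)
  expect_error(shortestPathLength(net, "a", "a"), "must differ")
})

test_that("path counts match exhaustive enumeration", {
  chain <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "c"),
                                 sign = "+"))
  expect_equal(countPaths(chain, "a", "c"), 1)
  diamond <- gmiNetwork(data.frame(source = c("a", "a", "b", "c"),
                                   target = c("b", "c", "d", "d"),
                                   sign = "+"))
  expect_equal(countPaths(diamond, "a", "d"), 2)

  set.seed(91)
  for (rep in 1:15) {
    net <- randomTestNetwork(8, p = 0.25)
    pr <- sample(nodes(net), 2)
    expect_equal(countPaths(net, pr[1], pr[2], maxLen = 8),
                 oraclePaths(net, pr[1], pr[2], 8))
  }
})

test_that("feedback-loop counts match cycle enumeration and imply mutual reachability", {
  two <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "a"),
                               sign = "+"))
  expect_equal(countFeedbackLoops(two, "a", "b"), 1)
  dag <- gmiNetwork(data.frame(source = c("a", "a", "b"),
                               target = c("b", "c", "c"), sign = "+"))
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_equal(countFeedbackLoops(dag, pr[1], pr[2]), 0)

  set.seed(92)
  for (rep in 1:15) {
    net <- randomTestNetwork(8, p = 0.25)
    pr <- sample(nodes(net), 2)
    f <- countFeedbackLoops(net, pr[1], pr[2], maxLen = 8)
    expect_equal(f, oracleCycles(net, pr[1], pr[2], 8))
    if (f > 0) {
      expect_lt(shortestPathLength(net, pr[1], pr[2]), Inf)
      expect_lt(shortestPathLength(net, pr[2], pr[1]), Inf)
    }
  }
})

test_that("path and cycle counts are monotone in the length cap", {
  set.seed(93)
  for (rep in 1:10) {
    net <- randomTestNetwork(7, p = 0.3)
    pr <- sample(nodes(net), 2)
    np <- vapply(1:7, function(L) countPaths(net, pr[1], pr[2], maxLen = L),
                 integer(1))
    nf <- vapply(2:7, function(L)
      countFeedbackLoops(net, pr[1], pr[2], maxLen = L), integer(1))
    expect_true(all(diff(np) >= 0))
    expect_true(all(diff(nf) >= 0))
  }
})

test_that("degree histograms conserve the node count", {
  none <- gmiNetwork(nodes = letters[1:5])
  h <- degreeDistribution(none)
  expect_equal(h$frequency, 5)
  expect_equal(h$binStart, 0)

  star <- gmiNetwork(data.frame(source = "hub", target = paste0("l", 1:5),
                                sign = "+"))
  hOut <- degreeDistribution(star, mode = "out")
  expect_equal(sum(hOut$frequency), 6)
  expect_equal(hOut$frequency[hOut$binStart == 5], 1)  # the hub
  expect_equal(hOut$frequency[hOut$binStart == 0], 5)  # the leaves

  set.seed(94)
  net <- randomTestNetwork(12, p = 0.3)
  for (mode in c("total", "in", "out"))
    expect_equal(sum(degreeDistribution(net, mode, binWidth = 2)$frequency), 12)
})

test_that("correlations match the closed form and refuse degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x)$estimate, 1)
  expect_equal(correlate(x, -x)$estimate, -1)

  set.seed(95)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate(a, b)$estimate, direct)
  expect_equal(correlate(a, b, "spearman")$estimate,
               correlate(rank(a), rank(b))$estimate)

  expect_error(correlate(rep(1, 5), x), class = "gdinet_undefined_correlation")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("the feature table is consistent with the per-pair operations", {
  single <- gmiNetwork(data.frame(source = "a", target = "b", sign = "+"))
  nds <- c("a", "b")
  num <- den <- matrix(NA_real_, 2, 2, dimnames = list(nds, nds))
  num[1, 2] <- 1; den[1, 2] <- 2; num[2, 1] <- 0; den[2, 1] <- 1
  im <- new("InfluenceMatrix", numerator = num, denominator = den,
            nodes = nds, provenance = list())
  ft <- pairwiseFeatureTable(single, im)
  expect_equal(nrow(ft), 1)  # only the reachable ordered pair

  fx <- generateFixture("amrn_like", seed = 41)
  S <- sampleInitialStates(10, exhaustive = TRUE)
  im <- influenceMatrix(fx$network, fx$rules, S, duration = 5)
  ft <- pairwiseFeatureTable(fx$network, im, maxLen = 6)
  expect_lte(nrow(ft), 10 * 9)
  mu <- influenceValues(im)
  for (r in sample.int(nrow(ft), min(10, nrow(ft)))) {
    vi <- ft$source[r]; vj <- ft$target[r]
    expect_equal(ft$mu[r], mu[vi, vj])
    expect_equal(ft$shortestPath[r], shortestPathLength(fx$network, vi, vj))
    expect_equal(ft$nPaths[r], countPaths(fx$network, vi, vj, maxLen = 6))
    expect_equal(ft$nFeedbackLoops[r],
                 countFeedbackLoops(fx$network, vi, vj, maxLen = 6))
  }
})

test_that("group degree comparisons report means and rank-test p-values", {
  net <- gmiNetwork(data.frame(source = rep(c("a", "b", "c"), each = 2),
                               target = c("d", "e", "d", "e", "d", "e"),
                               sign = "+"))
  groups <- setNames(c("hub", "hub", "hub", "leaf", "leaf"),
                     c("a", "b", "c", "d", "e"))
  res <- groupDegreeComparison(net, groups)
  m <- res$means
  expect_equal(m$meanOutDegree[m$group == "hub"], 2)
  expect_equal(m$meanOutDegree[m$group == "leaf"], 0)
  expect_equal(m$meanInDegree[m$group == "leaf"], 3)
  expect_true(all(res$tests$p.value >= 0 & res$tests$p.value <= 1))

  # identical degree multisets give equal means
  sym <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "a"),
                               sign = "+"))
  res2 <- groupDegreeComparison(sym, setNames(c("g1", "g2"), c("a", "b")))
  expect_equal(res2$means$meanInDegree[1], res2$means$meanInDegree[2])

  # rank-test p-values roughly uniform under a random null labeling
  set.seed(96)
  net <- randomTestNetwork(20, p = 0.2)
  pv <- replicate(300, {
    gp <- setNames(sample(c("A", "B"), 20, replace = TRUE,
                          prob = c(0.5, 0.5)), nodes(net))
    if (length(unique(gp)) < 2) return(NA_real_)
    groupDegreeComparison(net, gp)$tests$p.value[2]
  })
  pv <- pv[!is.na(pv)]
  expect_lt(mean(pv < 0.05), 0.12)  # near-nominal type-I error
  expect_gt(mean(pv), 0.3)          # roughly uniform, not degenerate
})
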