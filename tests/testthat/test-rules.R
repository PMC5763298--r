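test_that("randomized NCF draws satisfy the default-output identity and are uniform", {
  set.seed(101)
  for (i in 1:1000) {
    k <- sample(1:4, 1)
    r <- randomNCF("x", sprintf("r%d", seq_len(k)))
    expect_identical(defaultOutput(r),
                     1L - canalyzedValues(r)[length(canalyzedValues(r))])
  }
  # k = 2, 10000 draws: empirical frequency of I_1 = 1 close to 1/2
  set.seed(202)
  i1 <- replicate(10000, canalyzingValues(randomNCF("x", c("a", "b")))[1L])
  expect_lt(abs(mean(i1) - 0.5), 0.02)
})

test_that("sign-respecting draws couple canalyzed to canalyzing values", {
  set.seed(7)
  for (i in 1:50) {
    r <- randomNCF("x", "a", signs = "-", mode = "sign_respecting")
    expect_identical(canalyzedValues(r), 1L - canalyzingValues(r))
    r <- randomNCF("x", "a", signs = "+", mode = "sign_respecting")
    expect_identical(canalyzedValues(r), canalyzingValues(r))
  }
  expect_error(randomNCF("x", character(0)), "at least one regulator")
})

test_that("cascade evaluation matches exhaustive truth-table oracle for k <= 4", {
  r <- ncfRule("z", c("a", "b"), c(1, 0), c(1, 0))
  expect_equal(evaluateNCF(r, c(1, 0)), 1)  # first clause fires
  expect_equal(evaluateNCF(r, c(1, 1)), 1)
  expect_equal(evaluateNCF(r, c(0, 0)), 0)  # second clause fires
  expect_equal(evaluateNCF(r, c(0, 1)), 1)  # default clause
  expect_error(evaluateNCF(r, c(1, 0, 1)), "input")

  set.seed(33)
  for (rep in 1:40) {
    k <- sample(1:4, 1)
    r <- randomNCF("z", sprintf("r%d", seq_len(k)))
    inputs <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
    got <- apply(inputs, 1L, function(x) evaluateNCF(r, x))
    expect_identical(got, oracleTruthTable(r))
  }
})

test_that("synchronous updates use only the old state and hold source nodes", {
  isolated <- gmiNetwork(nodes = c("a", "b", "c"))
  rs <- randomRuleSet(isolated, seed = 1)
  expect_identical(unname(synchronousStep(isolated, rs, c(1, 0, 1))),
                   c(1L, 0L, 1L))

  swap <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "a"),
                                sign = "+"))
  copy <- new("RuleSet",
              rules = setNames(list(ncfRule("a", "b", 1, 1),
                                    ncfRule("b", "a", 1, 1)), c("a", "b")),
              nodes = c("a", "b"))
  expect_identical(unname(synchronousStep(swap, copy, c(1, 0))), c(0L, 1L))

  set.seed(55)
  net <- randomTestNetwork(5, p = 0.4)
  rs <- randomRuleSet(net)
  stepf <- oracleStepper(net, rs)
  state <- sample(0:1, 5, replace = TRUE)
  for (t in 1:100) {
    nxt <- synchronousStep(net, rs, state)
    expect_identical(unname(nxt), stepf(state))
    expect_identical(nxt, synchronousStep(net, rs, state))  # deterministic
    state <- unname(nxt)
  }
})

test_that("rule sets serialize to JSON and reload losslessly", {
  set.seed(9)
  net <- randomTestNetwork(6, p = 0.35)
  rs <- randomRuleSet(net)
  tf <- tempfile(fileext = ".json")
  writeRules(rs, tf)
  rs2 <- readRules(tf, net)
  for (v in nodes(net)) {
    a <- rs@rules[[v]]; b <- rs2@rules[[v]]
    expect_identical(class(a), class(b))
    if (is(a, "NCFRule")) {
      expect_identical(regulators(a), regulators(b))
      expect_identical(canalyzingValues(a), canalyzingValues(b))
      expect_identical(canalyzedValues(a), canalyzedValues(b))
      expect_identical(defaultOutput(a), defaultOutput(b))
    }
  }
})

test_that("rule sets are reproducible from a seed and validated against the network", {
  net <- generateFixture("amrn_like", seed = 3)$network
  expect_identical(gdinet:::ruleHash(randomRuleSet(net, seed = 4)),
                   gdinet:::ruleHash(randomRuleSet(net, seed = 4)))
  expect_false(identical(gdinet:::ruleHash(randomRuleSet(net, seed = 4)),
                         gdinet:::ruleHash(randomRuleSet(net, seed = 5))))
  other <- generateFixture("amrn_like", seed = 8)$network
  expect_error(synchronousStep(other, randomRuleSet(net, seed = 4),
                               rep(0, 10)))
})
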