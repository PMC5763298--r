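# Independent brute-force oracles: coded from the definitions (truth-table
# enumeration, full stored trajectories, literal distance formula), not
# from the package's optimized paths.

# Literal nested-canalyzing cascade: O_m for the smallest m whose input
# equals I_m AND all earlier inputs differ from their I_j; default
# otherwise.  (The explicit prior-mismatch conjunction distinguishes this
# from the package's first-match loop.)
oracleNCFOutput <- function(rule, inputs) {
  I <- canalyzingValues(rule)
  O <- canalyzedValues(rule)
  k <- length(I)
  for (m in seq_len(k)) {
    priorAllMiss <- m == 1L || all(inputs[seq_len(m - 1L)] != I[seq_len(m - 1L)])
    if (priorAllMiss && inputs[m] == I[m]) return(O[m])
  }
  defaultOutput(rule)
}

# Full 2^k truth table of a rule (row r <-> input bits of r - 1, first
# regulator least significant).
oracleTruthTable <- function(rule) {
  k <- length(regulators(rule))
  inputs <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  apply(inputs, 1L, function(x) oracleNCFOutput(rule, x))
}

# Synchronous step via precomputed truth-table lookup.
oracleStepper <- function(network, rules) {
  nds <- nodes(network)
  N <- length(nds)
  regIdx <- vector("list", N)
  tabs <- vector("list", N)
  for (i in seq_len(N)) {
    r <- rules@rules[[nds[i]]]
    if (is(r, "SourceRule")) next
    regIdx[[i]] <- match(regulators(r), nds)
    tabs[[i]] <- oracleTruthTable(r)
  }
  function(state) {
    out <- integer(N)
    for (i in seq_len(N)) {
      if (is.null(regIdx[[i]])) { out[i] <- state[i]; next }
      x <- state[regIdx[[i]]]
      out[i] <- tabs[[i]][1L + sum(x * 2^(seq_along(x) - 1L))]
    }
    out
  }
}

# Brute-force attractor: store the whole trajectory, scan for the first
# repeated state.  Knockout semantics mirror the contract: states at steps
# 1..T carry a forced 0 on the target, repeat-scanning starts at step T
# (permanent knockout: forced at every step, scanning from 0).
oracleAttractor <- function(network, rules, v0, ko = NULL, maxSteps = 2000L) {
  stepf <- oracleStepper(network, rules)
  nds <- nodes(network)
  pow <- 2^(seq_along(nds) - 1L)  # exact state codes for N well below 53
  koIdx <- if (is.null(ko)) NA_integer_ else match(ko@target, nds)
  T <- if (is.null(ko)) 0 else ko@duration
  detectStart <- if (!is.null(ko) && is.finite(T)) T else 0
  traj <- matrix(NA_integer_, nrow = maxSteps + 1L, ncol = length(nds))
  codes <- numeric(maxSteps + 1L)
  cur <- as.integer(v0)
  for (t in 0:maxSteps) {
    traj[t + 1L, ] <- cur
    codes[t + 1L] <- sum(cur * pow)
    if (t >= detectStart) {
      window <- codes[(detectStart + 1L):(t + 1L)]
      first <- match(codes[t + 1L], window) + detectStart - 1L
      if (first < t) {
        st <- traj[(first + 1L):t, , drop = FALSE]
        colnames(st) <- nds
        return(list(tau = first, period = t - first, states = st))
      }
    }
    nxt <- stepf(cur)
    if (!is.null(ko) && (!is.finite(T) || (t + 1) <= T)) nxt[koIdx] <- 0L
    cur <- nxt
  }
  stop("oracle found no attractor within ", maxSteps, " steps")
}

# Literal alignment-distance formula: unroll to the lcm window, offsets
# over [0, gcd - 1], minimum mismatch ratio as a reduced fraction.
oracleGcd <- function(a, b) if (b == 0) a else oracleGcd(b, a %% b)
oracleDistance <- function(wt, mut) {
  p <- length(wt); q <- length(mut)
  g <- oracleGcd(p, q)
  cc <- p * q / g
  best <- Inf
  for (m in 0:(g - 1L)) {
    mis <- 0L
    for (l in 0:(cc - 1L))
      if (wt[(l + m) %% p + 1L] != mut[l %% q + 1L]) mis <- mis + 1L
    best <- min(best, mis)
  }
  r <- oracleGcd(best, cc)
  c(numerator = best / r, denominator = cc / r)
}

# Monolithic end-to-end influence oracle: re-simulates both trajectories
# for every initial state of this single pair, no shared caching.  Exact
# mean via a common-denominator accumulation.
oracleMu <- function(network, rules, source, target, S, T, maxSteps = 2000L) {
  nums <- dens <- numeric(nrow(S))
  ko <- knockout(source, T)
  for (r in seq_len(nrow(S))) {
    wt <- oracleAttractor(network, rules, S[r, ], maxSteps = maxSteps)
    mu <- oracleAttractor(network, rules, S[r, ], ko = ko, maxSteps = maxSteps)
    d <- oracleDistance(wt$states[, target], mu$states[, target])
    nums[r] <- d[["numerator"]]; dens[r] <- d[["denominator"]]
  }
  den <- Reduce(function(a, b) a * b / oracleGcd(a, b), dens)
  num <- sum(nums * (den / dens))
  den <- den * nrow(S)
  g <- oracleGcd(num, den)
  c(numerator = num / g, denominator = den / g)
}

# Random signed directed test network: each ordered non-self pair carries
# an edge with probability p (uses the current RNG stream).
randomTestNetwork <- function(N, p = 0.3) {
  labels <- sprintf("n%d", seq_len(N))
  pairs <- expand.grid(source = labels, target = labels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  pick$sign <- sample(c("+", "-"), nrow(pick), replace = TRUE)
  gmiNetwork(pick, nodes = labels)
}

expectSameAttractor <- function(a, o) {
  expect_identical(transientLength(a), as.integer(o$tau))
  expect_identical(period(a), as.integer(o$period))
  expect_identical(unname(attractorStates(a)), unname(o$states))
}
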