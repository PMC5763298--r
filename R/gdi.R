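#' Enumerate or sample the set of initial network states
#'
#' Exhaustive mode enumerates all 2^N states (guarded to N <= 20); sampled
#' mode draws the requested number of distinct states uniformly.  By
#' default exhaustive enumeration is used for networks of at most 14
#' nodes, and 2000 (N <= 100) or 4000 (N > 100) sampled states above,
#' matched to typical small/medium/large regulatory-network scales.
#'
#' @param N number of nodes.
#' @param count number of sampled states (ignored when exhaustive).
#' @param exhaustive enumerate all 2^N states.
#' @param seed optional integer seed for sampled mode.
#' @return An [InitialStateSet-class].
#' @examples
#' nrow(initialStates(sampleInitialStates(10, exhaustive = TRUE)))  # 1024
#' @export
sampleInitialStates <- function(N,
                                count = if (N <= 100) 2000L else 4000L,
                                exhaustive = N <= 14L, seed = NULL) {
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (exhaustive) {
    if (N > 20L)
      stop("exhaustive enumeration is limited to N <= 20", call. = FALSE)
    grid <- as.matrix(expand.grid(rep(list(0:1), N), KEEP.OUT.ATTRS = FALSE))
    dimnames(grid) <- NULL
    return(new("InitialStateSet", mode = "exhaustive",
               states = grid[, rev(seq_len(N)), drop = FALSE],
               seed = NA_integer_))
  }
  count <- as.integer(count)
  if (N <= 52 && count > 2^N)
    stop("cannot draw ", count, " distinct states from a space of 2^", N,
         call. = FALSE)
  withSeed(seed, {
    seenKeys <- character(0)
    states <- matrix(0L, nrow = 0L, ncol = N)
    while (nrow(states) < count) {
      draw <- matrix(sample(0:1, (count - nrow(states)) * N, replace = TRUE),
                     ncol = N)
      keys <- apply(draw, 1L, paste, collapse = "")
      fresh <- !duplicated(keys) & !(keys %in% seenKeys)
      states <- rbind(states, draw[fresh, , drop = FALSE])
      seenKeys <- c(seenKeys, keys[fresh])
    }
    new("InitialStateSet", mode = "sampled", states = states,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' @rdname gdinet-accessors
#' @export
setMethod("initialStates", "InitialStateSet", function(x) x@states)

setMethod("show", "InitialStateSet", function(object) {
  cat("InitialStateSet (", object@mode, "): ", nrow(object@states),
      " states over ", ncol(object@states), " nodes\n", sep = "")
})

#' Alignment distance between two periodic node sequences
#'
#' Both sequences are unrolled to their least common multiple length c;
#' for each cyclic offset m in `[0, g - 1]` (g = gcd of the two periods)
#' the number of mismatching positions is counted, and the distance is the
#' minimum mismatch count divided by c, as an exact fraction.
#' `alignmentMismatches()` exposes the per-offset mismatch counts;
#' `sequenceDistance()` returns the minimized distance.
#'
#' @param wt,mut 0/1 node sequences (one attractor period each).
#' @param fullAlignment also scan offsets `[g, c - 1]` (diagnostic mode;
#'   the definition restricts offsets to `[0, g - 1]`).
#' @return `sequenceDistance()`: a [Rational-class] in \[0, 1\].
#'   `alignmentMismatches()`: integer vector of mismatch counts per
#'   offset, with attribute `lcm`.
#' @examples
#' alignmentMismatches(c(0, 1), c(0, 0, 0, 1))  # 1 and 3 mismatches
#' sequenceDistance(c(0, 1), c(0, 0, 0, 1))     # 1/4
#' @export
sequenceDistance <- function(wt, mut, fullAlignment = FALSE) {
  counts <- alignmentMismatches(wt, mut, fullAlignment = fullAlignment)
  rational(min(counts), attr(counts, "lcm"))
}

#' @rdname sequenceDistance
#' @export
alignmentMismatches <- function(wt, mut, fullAlignment = FALSE) {
  wt <- assertBits(wt, "wild-type sequence")
  mut <- assertBits(mut, "mutant sequence")
  p <- length(wt); q <- length(mut)
  g <- gcdInt(p, q); cc <- (p / g) * q
  offsets <- 0:(if (fullAlignment) cc - 1L else g - 1L)
  l <- 0:(cc - 1L)
  mutUnrolled <- mut[(l %% q) + 1L]
  counts <- vapply(offsets, function(m)
    sum(wt[((l + m) %% p) + 1L] != mutUnrolled), integer(1))
  structure(counts, lcm = cc, offsets = offsets)
}

#' Dynamics influence of one gene on another
#'
#' For each initial state, the wild-type and source-knockout attractors
#' are computed, the target's state sequences are extracted, and their
#' alignment distance taken; the influence mu(source, target) is the exact
#' mean of these distances over the initial-state set.  This routine
#' re-simulates per pair; [influenceMatrix()] computes all ordered pairs
#' with shared wild-type/mutant attractors and is the fast path.
#'
#' @param network a [GMINetwork-class].
#' @param rules a matching [RuleSet-class].
#' @param source gene to knock out.
#' @param target gene whose sequence change is measured.
#' @param states an [InitialStateSet-class].
#' @param duration knockout duration T (positive integer or `Inf`).
#' @param fullAlignment see [sequenceDistance()].
#' @param maxSteps see [findAttractor()].
#' @return A [Rational-class] in \[0, 1\].
#' @export
dynamicsInfluence <- function(network, rules, source, target, states,
                              duration = 20,
                              fullAlignment = FALSE,
                              maxSteps = defaultMaxSteps(length(nodes(network)))) {
  if (identical(source, target))
    stop("source and target must differ", call. = FALSE)
  nodeIndex(network, c(source, target))
  ko <- knockout(source, duration)
  S <- states@states
  acc <- rational(0, 1)
  for (r in seq_len(nrow(S))) {
    v0 <- S[r, ]
    wt <- tryCatch(findAttractor(network, rules, v0, maxSteps = maxSteps),
                   gdinet_attractor_not_found = function(e)
                     stop("attractor not found for initial state ",
                          paste(v0, collapse = ""), ": ", conditionMessage(e),
                          call. = FALSE))
    mu <- tryCatch(findAttractor(network, rules, v0, ko = ko,
                                 maxSteps = maxSteps),
                   gdinet_attractor_not_found = function(e)
                     stop("attractor not found for initial state ",
                          paste(v0, collapse = ""), " under knockout of ",
                          source, ": ", conditionMessage(e), call. = FALSE))
    d <- sequenceDistance(nodeSequence(wt, target), nodeSequence(mu, target),
                          fullAlignment = fullAlignment)
    acc <- ratAdd(acc, d@numerator, d@denominator)
  }
  ratDivInt(acc, nrow(S))
}

#' Dynamics-influence values for every ordered gene pair
#'
#' Computes mu(v_i, v_j) for all N(N-1) ordered pairs.  Wild-type
#' attractors are computed once per initial state and reused across
#' knockout sources; each mutant attractor is computed once per (initial
#' state, source) and reused across targets.  Influence values are exact
#' reduced fractions.
#'
#' @inheritParams dynamicsInfluence
#' @param verbose print per-initial-state-batch progress.
#' @return An [InfluenceMatrix-class].
#' @examples
#' fx <- generateFixture("demo4")
#' S <- sampleInitialStates(4, exhaustive = TRUE)
#' im <- influenceMatrix(fx$network, fx$rules, S, duration = 2)
#' influenceValues(im)
#' @export
influenceMatrix <- function(network, rules, states,
                            duration = 20, fullAlignment = FALSE,
                            maxSteps = defaultMaxSteps(length(nodes(network))),
                            verbose = FALSE) {
  validObject(states)
  if (ncol(states@states) != length(network@nodes))
    stop("initial states do not match the network size", call. = FALSE)
  if (!is.infinite(duration) && (duration < 1 || duration != floor(duration)))
    stop("duration must be a positive integer or Inf", call. = FALSE)
  packed <- packRules(network, rules)
  if (verbose)
    message("computing influence for ", length(network@nodes),
            " sources x ", nrow(states@states), " initial states")
  res <- cpp_influence_matrix(packed, states@states, duration, maxSteps,
                              fullAlignment)
  num <- res$numerator; den <- res$denominator
  dimnames(num) <- dimnames(den) <- list(network@nodes, network@nodes)
  new("InfluenceMatrix", numerator = num, denominator = den,
      nodes = network@nodes,
      provenance = list(duration = duration,
                        nStates = nrow(states@states),
                        stateMode = states@mode,
                        stateSeed = states@seed,
                        fullAlignment = fullAlignment,
                        ruleHash = ruleHash(rules)))
}

# Content hash of a rule set (md5 of its canonical JSON serialization).
ruleHash <- function(rules) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeRules(rules, tf)
  unname(tools::md5sum(tf))
}

#' @rdname gdinet-accessors
#' @export
setMethod("nodes", "InfluenceMatrix", function(x) x@nodes)

#' @rdname gdinet-accessors
#' @export
setMethod("numerator", "InfluenceMatrix", function(x) x@numerator)

#' @rdname gdinet-accessors
#' @export
setMethod("denominator", "InfluenceMatrix", function(x) x@denominator)

#' @rdname gdinet-accessors
#' @export
setMethod("influenceValues", "InfluenceMatrix",
          function(x) x@numerator / x@denominator)

#' @rdname gdinet-accessors
#' @export
setMethod("provenance", "InfluenceMatrix", function(x) x@provenance)

setMethod("show", "InfluenceMatrix", function(object) {
  off <- row(object@numerator) != col(object@numerator)
  pos <- sum(object@numerator[off] > 0)
  cat("InfluenceMatrix over", length(object@nodes), "nodes:",
      sum(off), "ordered pairs,", pos, "with positive influence\n")
  cat("  T =", object@provenance$duration,
      ", |S| =", object@provenance$nStates,
      paste0("(", object@provenance$stateMode, ")"), "\n")
})

#' Threshold an influence matrix into the GDI network
#'
#' A directed edge (v_i, v_j) is present if and only if mu(v_i, v_j) > 0,
#' decided on the exact fractions (no epsilon).
#'
#' @param matrix an [InfluenceMatrix-class].
#' @return A [GDINetwork-class].
#' @export
buildGDINetwork <- function(matrix) {
  num <- matrix@numerator; den <- matrix@denominator
  pos <- which(!is.na(num) & num > 0, arr.ind = TRUE)
  ord <- order(pos[, 1L], pos[, 2L])
  pos <- pos[ord, , drop = FALSE]
  ed <- data.frame(source = matrix@nodes[pos[, 1L]],
                   target = matrix@nodes[pos[, 2L]],
                   weight = num[pos] / den[pos],
                   numerator = num[pos], denominator = den[pos],
                   stringsAsFactors = FALSE)
  new("GDINetwork", nodes = matrix@nodes, edges = ed,
      provenance = matrix@provenance)
}

#' Classify ordered gene pairs by molecular interaction vs. dynamical influence
#'
#' Partitions ordered pairs into MIDI (edge in both the GMI and the GDI
#' network), MNDI (GDI only) and MIDN (GMI only).  By construction
#' MIDI + MIDN equals the GMI edge count and MIDI + MNDI the GDI edge
#' count.
#'
#' @param gmi a [GMINetwork-class].
#' @param gdi a [GDINetwork-class] over the same node set.
#' @return A [PairClassification-class].
#' @export
classifyPairs <- function(gmi, gdi) {
  if (!setequal(gmi@nodes, gdi@nodes))
    stopWithClass("gdinet_validation_error",
                  "GMI and GDI networks must share the same node set")
  keyA <- paste(gmi@edges$source, gmi@edges$target, sep = "\r")
  keyB <- paste(gdi@edges$source, gdi@edges$target, sep = "\r")
  toDf <- function(keys) {
    if (length(keys) == 0L)
      return(data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, "", 1L),
               target = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  }
  midi <- sort(intersect(keyA, keyB))
  midn <- sort(setdiff(keyA, keyB))
  mndi <- sort(setdiff(keyB, keyA))
  new("PairClassification",
      midi = toDf(midi), mndi = toDf(mndi), midn = toDf(midn),
      counts = c(MIDI = length(midi), MNDI = length(mndi),
                 MIDN = length(midn),
                 gmiEdges = length(keyA), gdiEdges = length(keyB)))
}

#' Pair lists and counts of a classification
#'
#' @param x a [PairClassification-class].
#' @param group one of `"MIDI"`, `"MNDI"`, `"MIDN"`.
#' @return `pairGroup()`: data.frame of ordered pairs;
#'   `pairCounts()`: the named count vector.
#' @export
pairGroup <- function(x, group = c("MIDI", "MNDI", "MIDN")) {
  switch(match.arg(group), MIDI = x@midi, MNDI = x@mndi, MIDN = x@midn)
}

#' @rdname pairGroup
#' @export
pairCounts <- function(x) x@counts

setMethod("show", "PairClassification", function(object) {
  ct <- object@counts
  cat("Ordered gene-pair classification:\n")
  cat("  MIDI (interacting & influential):    ", ct[["MIDI"]], "\n")
  cat("  MNDI (non-interacting, influential): ", ct[["MNDI"]], "\n")
  cat("  MIDN (interacting, non-influential): ", ct[["MIDN"]], "\n")
  cat("  GMI edges:", ct[["gmiEdges"]], " GDI edges:", ct[["gdiEdges"]], "\n")
})

#' Write influence values / a GDI network as TSV
#'
#' The influence matrix is written one ordered pair per row with the exact
#' numerator and denominator plus the double value; the GDI network as a
#' weighted edge list with a JSON provenance sidecar (`<path>.prov.json`).
#'
#' @param matrix an [InfluenceMatrix-class].
#' @param gdi a [GDINetwork-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeInfluenceMatrix <- function(matrix, path) {
  N <- length(matrix@nodes)
  ij <- which(row(matrix@numerator) != col(matrix@numerator), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  df <- data.frame(source = matrix@nodes[ij[, 1L]],
                   target = matrix@nodes[ij[, 2L]],
                   mu_numerator = format(matrix@numerator[ij], scientific = FALSE, trim = TRUE),
                   mu_denominator = format(matrix@denominator[ij], scientific = FALSE, trim = TRUE),
                   mu_float = format(matrix@numerator[ij] / matrix@denominator[ij],
                                     digits = 15))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInfluenceMatrix
#' @export
writeGDINetwork <- function(gdi, path) {
  ed <- gdi@edges
  write.table(data.frame(source = ed$source, target = ed$target,
                         weight = format(ed$weight, digits = 15)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(gdi@provenance, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
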