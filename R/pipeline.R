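#' Generate a self-contained network + rule-set fixture
#'
#' `"demo4"` loads the bundled 4-node demonstration: a fixed network and
#' deterministic rules for which the wild-type and the v3-knockout
#' trajectories from state 0000 settle into attractors of periods 2 and 4
#' (least common multiple 4), the configuration used throughout the
#' documentation.  `"random"` draws a directed network where each ordered
#' non-self pair carries an edge with probability `density`.
#' `"amrn_like"` draws a 10-node, 20-edge network with both signs present,
#' the shape of a small plant-morphogenesis regulatory network.
#'
#' @param kind `"demo4"`, `"random"` or `"amrn_like"`.
#' @param n node count for `"random"`.
#' @param density edge probability for `"random"`.
#' @param seed integer seed (ignored for the deterministic `"demo4"`).
#' @return list with elements `network` ([GMINetwork-class]) and `rules`
#'   ([RuleSet-class]); `"demo4"` adds `knockoutTarget` and `duration`.
#' @export
generateFixture <- function(kind = c("demo4", "random", "amrn_like"),
                            n = 10L, density = 0.2, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "demo4") {
    netPath <- system.file("extdata", "demo4_network.tsv", package = "gdinet",
                           mustWork = TRUE)
    rulePath <- system.file("extdata", "demo4_rules.json", package = "gdinet",
                            mustWork = TRUE)
    network <- readNetwork(netPath)
    rules <- readRules(rulePath, network)
    return(list(network = network, rules = rules,
                knockoutTarget = "v3", duration = 2))
  }
  if (kind == "amrn_like") { n <- 10L; nEdges <- 20L }
  seeds <- expandSeed(seed, c("net", "rules"))
  network <- withSeed(seeds$net, {
    labels <- sprintf("g%d", seq_len(n))
    pairs <- expand.grid(source = labels, target = labels,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    if (kind == "random") {
      pick <- pairs[runif(nrow(pairs)) < density, , drop = FALSE]
    } else {
      repeat {  # every node must take part in at least one interaction
        pick <- pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
        if (all(labels %in% c(pick$source, pick$target))) break
      }
    }
    sgn <- sample(c("+", "-"), nrow(pick), replace = TRUE)
    if (kind == "amrn_like" && length(unique(sgn)) < 2L)
      sgn[1L] <- setdiff(c("+", "-"), sgn[1L])  # guarantee mixed signs
    pick$sign <- sgn
    gmiNetwork(pick, nodes = labels)
  })
  list(network = network, rules = randomRuleSet(network, seed = seeds$rules))
}

.pipelineKeys <- c("network", "generator", "rules", "seed", "duration",
                   "nStates", "exhaustive", "mode", "outputDir", "maxLen",
                   "features", "fullAlignment", "maxSteps")

#' Run the full influence pipeline from a configuration
#'
#' One reproducible run: load or generate the network, draw (or load) the
#' rule set, build the initial-state set, compute the influence matrix,
#' threshold it into the GDI network, classify ordered pairs, and compute
#' the structural feature table.  All outputs are written to
#' `config$outputDir`: `rules.json`, `influence.tsv`, `gdi.tsv` (+
#' provenance sidecar), `classification.json`, `features.tsv` and
#' `provenance.json`.  Re-running the same configuration reproduces
#' byte-identical numeric outputs.
#'
#' @param config named list, or path to a JSON file containing one.  Keys:
#'   `network` (edge-list TSV path) or `generator` (list with `kind` and
#'   [generateFixture()] arguments) — exactly one required; `rules`
#'   (optional rules JSON path); `seed` (required integer); `duration`
#'   (knockout duration T, default 20); `nStates` / `exhaustive`
#'   (initial-state specification, defaults as in
#'   [sampleInitialStates()]); `mode` (NCF randomization mode);
#'   `outputDir` (required); `maxLen`, `features`, `fullAlignment`,
#'   `maxSteps` (optional).  Unknown keys raise a schema error.
#' @return Invisibly, a list with the computed objects (`network`,
#'   `rules`, `states`, `matrix`, `gdi`, `classification`, `features`)
#'   and the output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopWithClass("gdinet_config_error",
                                      "config must be a list or a JSON path")
  unknown <- setdiff(names(config), .pipelineKeys)
  if (length(unknown) > 0L)
    stopWithClass("gdinet_config_error",
      paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  if (is.null(config$network) && is.null(config$generator))
    stopWithClass("gdinet_config_error",
                  "config must name a 'network' file or a 'generator' spec")
  if (!is.null(config$network) && !is.null(config$generator))
    stopWithClass("gdinet_config_error",
                  "give either 'network' or 'generator', not both")
  if (is.null(config$seed))
    stopWithClass("gdinet_config_error", "config must set 'seed'")
  if (is.null(config$outputDir))
    stopWithClass("gdinet_config_error", "config must set 'outputDir'")

  seeds <- expandSeed(config$seed, c("generator", "rules", "states"))
  outDir <- config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$network)) {
    network <- readNetwork(config$network)
    networkHash <- unname(tools::md5sum(config$network))
  } else {
    gen <- config$generator
    args <- gen[setdiff(names(gen), "kind")]
    fx <- do.call(generateFixture,
                  c(list(kind = gen$kind, seed = seeds$generator), args))
    network <- fx$network
    networkHash <- NA_character_
  }
  N <- length(nodes(network))

  if (!is.null(config$rules)) {
    rules <- readRules(config$rules, network)
  } else {
    rules <- randomRuleSet(network,
                           mode = if (is.null(config$mode)) "unconstrained"
                                  else config$mode,
                           seed = seeds$rules)
  }

  exhaustive <- if (is.null(config$exhaustive)) N <= 14L
                else isTRUE(config$exhaustive)
  states <- if (exhaustive) sampleInitialStates(N, exhaustive = TRUE)
            else sampleInitialStates(N,
                   count = if (is.null(config$nStates))
                             (if (N <= 100) 2000L else 4000L)
                           else config$nStates,
                   exhaustive = FALSE, seed = seeds$states)

  duration <- if (is.null(config$duration)) 20 else config$duration
  maxSteps <- if (is.null(config$maxSteps)) defaultMaxSteps(N)
              else config$maxSteps
  fullAlignment <- isTRUE(config$fullAlignment)

  mat <- influenceMatrix(network, rules, states, duration = duration,
                         fullAlignment = fullAlignment, maxSteps = maxSteps)
  gdi <- buildGDINetwork(mat)
  cls <- classifyPairs(network, gdi)

  paths <- list(rules = file.path(outDir, "rules.json"),
                influence = file.path(outDir, "influence.tsv"),
                gdi = file.path(outDir, "gdi.tsv"),
                classification = file.path(outDir, "classification.json"),
                provenance = file.path(outDir, "provenance.json"))
  writeRules(rules, paths$rules)
  writeInfluenceMatrix(mat, paths$influence)
  writeGDINetwork(gdi, paths$gdi)
  jsonlite::write_json(
    list(counts = as.list(pairCounts(cls)),
         MIDI = pairGroup(cls, "MIDI"), MNDI = pairGroup(cls, "MNDI"),
         MIDN = pairGroup(cls, "MIDN")),
    paths$classification, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  features <- NULL
  if (!identical(config$features, FALSE)) {
    maxLen <- if (is.null(config$maxLen)) defaultMaxLen(N) else config$maxLen
    features <- pairwiseFeatureTable(network, mat, maxLen = maxLen)
    paths$features <- file.path(outDir, "features.tsv")
    write.table(cbind(features[, c("source", "target")],
                      mu = format(features$mu, digits = 15),
                      features[, c("shortestPath", "nPaths", "nFeedbackLoops")]),
                paths$features, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(
    list(seed = config$seed, subSeeds = seeds,
         duration = duration, nStates = nrow(initialStates(states)),
         stateMode = states@mode, fullAlignment = fullAlignment,
         maxSteps = maxSteps, networkHash = networkHash,
         ruleHash = ruleHash(rules), nodes = N,
         gmiEdges = nrow(edges(network)), gdiEdges = nrow(edges(gdi))),
    paths$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(network = network, rules = rules, states = states,
                 matrix = mat, gdi = gdi, classification = cls,
                 features = features, paths = paths))
}
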