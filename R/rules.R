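#' Construct a nested canalyzing update rule
#'
#' @param target gene the rule updates.
#' @param regulators ordered regulator identifiers (canalyzation order).
#' @param canalyzingValues 0/1 vector I, one value per regulator.
#' @param canalyzedValues 0/1 vector O, one value per regulator.  The
#'   default output is always `1 - O[k]` and is derived, not supplied.
#' @return An [NCFRule-class].
#' @examples
#' r <- ncfRule("c", c("a", "b"), c(1, 0), c(1, 0))
#' evaluateNCF(r, c(0, 1))   # no regulator canalyzes -> default output 1
#' @export
ncfRule <- function(target, regulators, canalyzingValues, canalyzedValues) {
  O <- assertBits(canalyzedValues, "canalyzed values")
  new("NCFRule", target = as.character(target),
      regulators = as.character(regulators),
      canalyzingValues = assertBits(canalyzingValues, "canalyzing values"),
      canalyzedValues = O,
      defaultOutput = 1L - O[length(O)])
}

#' Construct a hold rule for an in-degree-0 node
#'
#' Source nodes (no regulators) keep their current state at every step,
#' which preserves the diversity of initial conditions.
#'
#' @param target node identifier.
#' @return A [SourceRule-class].
#' @export
sourceRule <- function(target) new("SourceRule", target = as.character(target))

#' Draw a randomized nested canalyzing rule
#'
#' In `"unconstrained"` mode every canalyzing value I_m and canalyzed value
#' O_m is an independent fair coin flip (edge signs are ignored).  In
#' `"sign_respecting"` mode I_m is free but O_m = I_m for activating and
#' O_m = 1 - I_m for inhibiting regulators, so an active activator pushes
#' its target on and an active inhibitor pushes it off.  In both modes the
#' canalyzation order is a random permutation of the regulators (drawn with
#' `permute = TRUE`) and the default output is the complement of the last
#' canalyzed value.  Uses the current RNG stream; seed at the caller
#' ([randomRuleSet()] takes a `seed` argument).
#'
#' @param target gene the rule updates.
#' @param regulators regulator identifiers.
#' @param signs edge signs (`"+"`/`"-"`), parallel to `regulators`;
#'   required for `"sign_respecting"`.
#' @param mode `"unconstrained"` (default) or `"sign_respecting"`.
#' @param permute randomly permute the canalyzation order (default TRUE).
#' @return An [NCFRule-class].
#' @export
randomNCF <- function(target, regulators, signs = NULL,
                      mode = c("unconstrained", "sign_respecting"),
                      permute = TRUE) {
  mode <- match.arg(mode)
  k <- length(regulators)
  if (k < 1L) stop("an NCF needs at least one regulator", call. = FALSE)
  ord <- if (permute && k > 1L) sample.int(k) else seq_len(k)
  regulators <- regulators[ord]
  I <- sample(0:1, k, replace = TRUE)
  if (mode == "unconstrained") {
    O <- sample(0:1, k, replace = TRUE)
  } else {
    if (is.null(signs) || length(signs) != k)
      stop("sign_respecting mode needs one sign per regulator", call. = FALSE)
    signs <- normalizeSign(signs)[ord]
    O <- ifelse(signs == "+", I, 1L - I)
  }
  ncfRule(target, regulators, I, O)
}

#' Generate a full randomized rule set for a network
#'
#' One rule per node: a randomized NCF over the node's in-neighbours, or a
#' hold rule ([sourceRule()]) for in-degree-0 nodes.
#'
#' @param network a [GMINetwork-class].
#' @param mode passed to [randomNCF()].
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A [RuleSet-class].
#' @examples
#' net <- generateFixture("amrn_like", seed = 1)$network
#' rs <- randomRuleSet(net, seed = 7)
#' rs
#' @export
randomRuleSet <- function(network, mode = c("unconstrained", "sign_respecting"),
                          seed = NULL) {
  mode <- match.arg(mode)
  nb <- inNeighborList(network)
  withSeed(seed, {
    rules <- lapply(network@nodes, function(v) {
      regs <- nb$regulators[[v]]
      if (length(regs) == 0L) sourceRule(v)
      else randomNCF(v, regs, nb$signs[[v]], mode = mode)
    })
    names(rules) <- network@nodes
    new("RuleSet", rules = rules, nodes = network@nodes)
  })
}

#' Evaluate a nested canalyzing rule on one input vector
#'
#' Returns O_m for the smallest m whose input equals its canalyzing value
#' I_m; if no regulator canalyzes, returns the default output.
#'
#' @param rule an [NCFRule-class].
#' @param inputs 0/1 vector, ordered as `regulators(rule)`.
#' @return 0 or 1.
#' @export
evaluateNCF <- function(rule, inputs) {
  k <- length(rule@regulators)
  if (length(inputs) != k)
    stop("expected ", k, " input value(s), got ", length(inputs), call. = FALSE)
  inputs <- assertBits(inputs, "inputs")
  m <- which(inputs == rule@canalyzingValues)
  if (length(m) == 0L) rule@defaultOutput else rule@canalyzedValues[m[1L]]
}

#' One synchronous update of all node states
#'
#' Every node's new value is computed from the old state only; in-degree-0
#' nodes hold their value.
#'
#' @param network a [GMINetwork-class].
#' @param rules a matching [RuleSet-class].
#' @param state 0/1 vector aligned with `nodes(network)`.
#' @return The next state (integer 0/1 vector, named by node).
#' @examples
#' net <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "a"),
#'                              sign = "+"))
#' rs <- new("RuleSet",
#'           rules = setNames(list(ncfRule("a", "b", 1, 1),
#'                                 ncfRule("b", "a", 1, 1)), c("a", "b")),
#'           nodes = c("a", "b"))
#' synchronousStep(net, rs, c(1, 0))
#' @export
synchronousStep <- function(network, rules, state) {
  checkRules(network, rules)
  if (length(state) != length(network@nodes))
    stop("state length must equal the node count", call. = FALSE)
  state <- setNames(assertBits0ok(state), network@nodes)
  out <- vapply(network@nodes, function(v) {
    r <- rules@rules[[v]]
    if (is(r, "SourceRule")) state[[v]]
    else evaluateNCF(r, unname(state[r@regulators]))
  }, integer(1))
  out
}

# states may legitimately be all-zero; assertBits requires non-empty only.
assertBits0ok <- function(x) {
  if (length(x) == 0L || anyNA(x) || !all(x == 0L | x == 1L))
    stop("state must be a 0/1 vector", call. = FALSE)
  as.integer(x)
}

# Rule set / network consistency: one rule per node, regulator sets equal
# to in-neighbour sets.
checkRules <- function(network, rules) {
  if (!identical(rules@nodes, network@nodes))
    stop("rule set nodes do not match the network", call. = FALSE)
  nb <- inNeighborList(network)
  for (v in network@nodes) {
    r <- rules@rules[[v]]
    regs <- nb$regulators[[v]]
    if (is(r, "SourceRule")) {
      if (length(regs) > 0L)
        stop("node ", v, " has regulators but a hold rule", call. = FALSE)
    } else if (!setequal(r@regulators, regs)) {
      stop("rule for node ", v,
           " does not use exactly its in-neighbours", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Serialize / reload a rule set as JSON
#'
#' The JSON records, per node, the regulator order, canalyzing and
#' canalyzed values and the default output; `readRules()` round-trips
#' losslessly and revalidates against a network when one is supplied.
#'
#' @param rules a [RuleSet-class].
#' @param path JSON file path.
#' @param network optional [GMINetwork-class] to validate against.
#' @return `writeRules()` returns `path` invisibly; `readRules()` a
#'   [RuleSet-class].
#' @export
writeRules <- function(rules, path) {
  doc <- lapply(rules@rules, function(r) {
    if (is(r, "SourceRule")) list(type = "source")
    else list(type = "ncf", regulators = as.list(r@regulators),
              canalyzing = r@canalyzingValues, canalyzed = r@canalyzedValues,
              default = r@defaultOutput)
  })
  jsonlite::write_json(list(nodes = rules@nodes, rules = doc), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRules
#' @export
readRules <- function(path, network = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nds <- vapply(doc$nodes, as.character, "")
  rules <- lapply(nds, function(v) {
    r <- doc$rules[[v]]
    if (identical(r$type, "source")) sourceRule(v)
    else ncfRule(v, vapply(r$regulators, as.character, ""),
                 vapply(r$canalyzing, as.integer, 0L),
                 vapply(r$canalyzed, as.integer, 0L))
  })
  names(rules) <- nds
  rs <- new("RuleSet", rules = rules, nodes = nds)
  if (!is.null(network)) checkRules(network, rs)
  rs
}

#' @rdname gdinet-accessors
#' @export
setMethod("nodes", "RuleSet", function(x) x@nodes)

#' @rdname gdinet-accessors
#' @export
setMethod("regulators", "NCFRule", function(x) x@regulators)

#' @rdname gdinet-accessors
#' @export
setMethod("canalyzingValues", "NCFRule", function(x) x@canalyzingValues)

#' @rdname gdinet-accessors
#' @export
setMethod("canalyzedValues", "NCFRule", function(x) x@canalyzedValues)

#' @rdname gdinet-accessors
#' @export
setMethod("defaultOutput", "NCFRule", function(x) x@defaultOutput)

setMethod("show", "NCFRule", function(object) {
  cat("NCFRule for", object@target, ":",
      paste0("[", paste(object@regulators, collapse = ","), "]"),
      "I =", paste(object@canalyzingValues, collapse = ""),
      "O =", paste(object@canalyzedValues, collapse = ""),
      "default =", object@defaultOutput, "\n")
})

setMethod("show", "SourceRule", function(object) {
  cat("SourceRule for", object@target, "(holds its state)\n")
})

setMethod("show", "RuleSet", function(object) {
  nSrc <- sum(vapply(object@rules, is, logical(1), class2 = "SourceRule"))
  cat("RuleSet over", length(object@nodes), "nodes (",
      length(object@nodes) - nSrc, "NCFs,", nSrc, "hold rules )\n")
})

# Flatten a rule set into the integer form the C++ core consumes:
# 0-based regulator indices, I/O bit vectors, default outputs.
packRules <- function(network, rules) {
  checkRules(network, rules)
  idx <- setNames(seq_along(network@nodes), network@nodes)
  regs <- vector("list", length(network@nodes))
  I <- vector("list", length(network@nodes))
  O <- vector("list", length(network@nodes))
  odef <- integer(length(network@nodes))
  for (i in seq_along(network@nodes)) {
    r <- rules@rules[[i]]
    if (is(r, "SourceRule")) {
      regs[[i]] <- integer(0); I[[i]] <- integer(0); O[[i]] <- integer(0)
      odef[i] <- 0L  # unused for hold rules
    } else {
      regs[[i]] <- unname(idx[r@regulators]) - 1L
      I[[i]] <- r@canalyzingValues
      O[[i]] <- r@canalyzedValues
      odef[i] <- r@defaultOutput
    }
  }
  list(regs = regs, I = I, O = O, odef = odef)
}
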