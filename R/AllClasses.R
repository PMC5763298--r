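.validBits <- function(x) length(x) == 0L || all(x %in% c(0L, 1L))

#' GMINetwork: a signed directed gene-gene molecular interaction network
#'
#' A directed graph G = (V, A).  Nodes are gene identifiers; each directed
#' edge carries a sign, `"+"` (activating) or `"-"` (inhibiting).
#' Self-loops are disallowed and at most one edge may connect an ordered
#' pair of nodes.
#'
#' @slot nodes character vector of unique gene identifiers (defines the
#'   state-vector index order).
#' @slot edges data.frame with columns `source`, `target`, `sign`.
#' @seealso [gmiNetwork()], [readNetwork()]
#' @exportClass GMINetwork
setClass("GMINetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("GMINetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (anyDuplicated(nd)) return("duplicated node identifiers")
  if (!all(c("source", "target", "sign") %in% names(ed)))
    return("edges must have columns source, target, sign")
  if (nrow(ed) == 0L) return(TRUE)
  if (!all(ed$sign %in% c("+", "-"))) return("edge signs must be '+' or '-'")
  if (any(ed$source == ed$target)) return("self-loops are not allowed")
  if (anyDuplicated(paste(ed$source, ed$target, sep = "\r")))
    return("duplicate ordered (source, target) pairs")
  if (!all(c(ed$source, ed$target) %in% nd))
    return("edge endpoints missing from node list")
  TRUE
})

#' Boolean update rules
#'
#' `NCFRule` is a nested canalyzing function: regulators are tested in a
#' fixed cascade order; the first regulator whose state equals its
#' canalyzing value I_m determines the output O_m, and if no regulator
#' canalyzes, the default output (the complement of the last canalyzed
#' value) is returned.  `SourceRule` is the rule of an in-degree-0 node:
#' the node holds its current state.
#'
#' @slot target gene the rule updates.
#' @slot regulators ordered regulator identifiers (canalyzation order).
#' @slot canalyzingValues integer 0/1 vector I, one per regulator.
#' @slot canalyzedValues integer 0/1 vector O, one per regulator.
#' @slot defaultOutput integer 0/1, always `1 - O[k]`.
#' @aliases NCFRule-class SourceRule-class BooleanRule-class
#' @seealso [ncfRule()], [randomNCF()], [evaluateNCF()]
#' @exportClass BooleanRule
#' @exportClass NCFRule
#' @exportClass SourceRule
setClass("BooleanRule", representation("VIRTUAL", target = "character"))

setClass("NCFRule", contains = "BooleanRule",
  representation(regulators = "character",
                 canalyzingValues = "integer",
                 canalyzedValues = "integer",
                 defaultOutput = "integer"))

setValidity("NCFRule", function(object) {
  k <- length(object@regulators)
  if (k < 1L) return("an NCF needs at least one regulator")
  if (anyDuplicated(object@regulators)) return("duplicated regulators")
  if (length(object@canalyzingValues) != k ||
      length(object@canalyzedValues) != k)
    return("canalyzing/canalyzed value vectors must have one entry per regulator")
  if (!.validBits(object@canalyzingValues) ||
      !.validBits(object@canalyzedValues) ||
      !.validBits(object@defaultOutput))
    return("rule values must be 0 or 1")
  if (object@defaultOutput != 1L - object@canalyzedValues[k])
    return("default output must be the complement of the last canalyzed value")
  TRUE
})

setClass("SourceRule", contains = "BooleanRule")

#' RuleSet: one Boolean update rule per network node
#'
#' @slot rules named list of [BooleanRule-class] objects, one per node,
#'   in node order.
#' @slot nodes node order the rules are aligned with.
#' @seealso [randomRuleSet()], [readRules()]
#' @exportClass RuleSet
setClass("RuleSet", representation(rules = "list", nodes = "character"))

setValidity("RuleSet", function(object) {
  if (length(object@rules) != length(object@nodes))
    return("exactly one rule per node required")
  if (!identical(names(object@rules), object@nodes))
    return("rule names must equal the node vector")
  ok <- vapply(object@rules, is, logical(1), class2 = "BooleanRule")
  if (!all(ok)) return("all rules must be BooleanRule objects")
  TRUE
})

#' Knockout: an in-silico knockout specification
#'
#' The target gene's update rule is replaced by the constant 0 for the
#' first `duration` update steps (states at steps 1..T), after which its
#' native rule is restored.  `duration = Inf` freezes the gene permanently.
#'
#' @slot target gene to freeze to 0.
#' @slot duration positive integer number of steps, or `Inf`.
#' @seealso [knockout()], [findAttractor()]
#' @exportClass Knockout
setClass("Knockout", representation(target = "character", duration = "numeric"))

setValidity("Knockout", function(object) {
  d <- object@duration
  if (length(object@target) != 1L) return("exactly one target gene")
  if (length(d) != 1L || is.na(d)) return("duration must be a single number")
  if (!is.infinite(d) && (d < 1 || d != floor(d)))
    return("duration must be a positive integer or Inf")
  TRUE
})

#' Attractor: the eventually repeating cycle of a Boolean trajectory
#'
#' Synchronous deterministic updating on a finite state space must revisit
#' a state; the attractor is the ordered cycle of `period` distinct network
#' states entered after `transient` steps.
#'
#' @slot transient number of steps before the cycle is entered (tau).
#' @slot period cycle length p.
#' @slot states integer 0/1 matrix, `period` rows, one column per node
#'   (column names are the node identifiers); row r is the network state at
#'   time `transient + r - 1`.
#' @slot nodes node order.
#' @seealso [findAttractor()], [nodeSequence()]
#' @exportClass Attractor
setClass("Attractor",
  representation(transient = "integer", period = "integer",
                 states = "matrix", nodes = "character"))

setValidity("Attractor", function(object) {
  p <- object@period
  if (p < 1L) return("period must be >= 1")
  if (object@transient < 0L) return("transient must be >= 0")
  st <- object@states
  if (nrow(st) != p) return("state matrix must have one row per cycle step")
  if (ncol(st) != length(object@nodes))
    return("state matrix must have one column per node")
  if (!.validBits(as.integer(st))) return("states must be 0/1")
  if (anyDuplicated(apply(st, 1L, paste, collapse = "")))
    return("cycle states must be pairwise distinct")
  TRUE
})

#' InitialStateSet: the set S of initial network states
#'
#' Either every one of the 2^N states (exhaustive mode) or a seeded uniform
#' sample of distinct states.
#'
#' @slot mode `"exhaustive"` or `"sampled"`.
#' @slot states integer 0/1 matrix, one row per initial state.
#' @slot seed integer seed used in sampled mode (NA otherwise).
#' @seealso [sampleInitialStates()]
#' @exportClass InitialStateSet
setClass("InitialStateSet",
  representation(mode = "character", states = "matrix", seed = "integer"))

setValidity("InitialStateSet", function(object) {
  if (!object@mode %in% c("exhaustive", "sampled"))
    return("mode must be 'exhaustive' or 'sampled'")
  st <- object@states
  if (!.validBits(as.integer(st))) return("states must be 0/1")
  key <- apply(st, 1L, paste, collapse = "")
  if (anyDuplicated(key)) return("initial states must be distinct")
  if (object@mode == "exhaustive" && nrow(st) != 2^ncol(st))
    return("exhaustive mode must enumerate all 2^N states")
  TRUE
})

#' Rational: an exact reduced fraction
#'
#' Influence values are averages of bit-mismatch ratios, i.e. rationals;
#' keeping them exact makes the strict-positivity edge rule of the GDI
#' network unambiguous.  Numerator and denominator are stored as whole
#' doubles (exactness guarded below 2^53).
#'
#' @slot numerator,denominator whole-valued doubles, `denominator >= 1`,
#'   `gcd(numerator, denominator) == 1`.
#' @seealso [rational()]
#' @exportClass Rational
setClass("Rational", representation(numerator = "numeric", denominator = "numeric"))

setValidity("Rational", function(object) {
  n <- object@numerator; d <- object@denominator
  if (length(n) != 1L || length(d) != 1L) return("scalar fraction expected")
  if (d < 1 || n != floor(n) || d != floor(d)) return("whole numerator and positive whole denominator required")
  if (abs(n) >= 2^53 || d >= 2^53) return("fraction exceeds exact double range")
  TRUE
})

#' InfluenceMatrix: exact dynamics-influence values for all ordered pairs
#'
#' Entry (i, j) is mu(v_i, v_j): the mean over initial states of the
#' minimum-alignment bit difference between v_j's wild-type and
#' v_i-knockout attractor sequences.  Stored as exact reduced fractions in
#' parallel numerator/denominator matrices; the diagonal is NA (self-pairs
#' are excluded).
#'
#' @slot numerator,denominator numeric N x N matrices.
#' @slot nodes node order (row = knockout source, column = target).
#' @slot provenance list recording duration T, the initial-state
#'   specification and seed, and the rule-set hash.
#' @seealso [influenceMatrix()], [buildGDINetwork()]
#' @exportClass InfluenceMatrix
setClass("InfluenceMatrix",
  representation(numerator = "matrix", denominator = "matrix",
                 nodes = "character", provenance = "list"))

setValidity("InfluenceMatrix", function(object) {
  N <- length(object@nodes)
  if (!all(dim(object@numerator) == c(N, N)) ||
      !all(dim(object@denominator) == c(N, N)))
    return("numerator/denominator must be N x N")
  off <- row(object@numerator) != col(object@numerator)
  n <- object@numerator[off]; d <- object@denominator[off]
  if (anyNA(n) || anyNA(d)) return("off-diagonal entries must be filled")
  if (any(n < 0) || any(d < 1)) return("negative fraction")
  if (any(n > d)) return("influence values must lie in [0, 1]")
  TRUE
})

#' GDINetwork: the thresholded dynamics-influence network
#'
#' Directed graph G' = (V, A') on the same nodes as the source GMI network;
#' (v_i, v_j) is an edge if and only if mu(v_i, v_j) > 0 (decided on exact
#' rationals).  Edge weight is the influence value.
#'
#' @slot nodes node identifiers.
#' @slot edges data.frame with columns `source`, `target`, `weight`,
#'   `numerator`, `denominator`.
#' @slot provenance inherited from the influence matrix.
#' @seealso [buildGDINetwork()], [gdiOutSet()]
#' @exportClass GDINetwork
setClass("GDINetwork",
  representation(nodes = "character", edges = "data.frame",
                 provenance = "list"))

setValidity("GDINetwork", function(object) {
  ed <- object@edges
  need <- c("source", "target", "weight", "numerator", "denominator")
  if (!all(need %in% names(ed))) return("missing edge columns")
  if (nrow(ed) == 0L) return(TRUE)
  if (any(ed$source == ed$target)) return("self-loops are not allowed")
  if (any(ed$numerator <= 0)) return("GDI edges require strictly positive influence")
  if (!all(c(ed$source, ed$target) %in% object@nodes))
    return("edge endpoints missing from node list")
  TRUE
})

#' PairClassification: MIDI / MNDI / MIDN partition of ordered gene pairs
#'
#' MIDI: molecularly interacting and dynamically influential (edge in both
#' networks).  MNDI: molecularly non-interacting but dynamically
#' influential (GDI only).  MIDN: molecularly interacting but dynamically
#' non-influential (GMI only).
#'
#' @slot midi,mndi,midn data.frames of ordered pairs (`source`, `target`).
#' @slot counts named integer vector: MIDI, MNDI, MIDN, gmiEdges, gdiEdges.
#' @seealso [classifyPairs()]
#' @exportClass PairClassification
setClass("PairClassification",
  representation(midi = "data.frame", mndi = "data.frame",
                 midn = "data.frame", counts = "integer"))

setValidity("PairClassification", function(object) {
  ct <- object@counts
  need <- c("MIDI", "MNDI", "MIDN", "gmiEdges", "gdiEdges")
  if (!all(need %in% names(ct))) return("missing counts")
  if (ct[["gmiEdges"]] != ct[["MIDI"]] + ct[["MIDN"]])
    return("MIDI + MIDN must equal the GMI edge count")
  if (ct[["gdiEdges"]] != ct[["MIDI"]] + ct[["MNDI"]])
    return("MIDI + MNDI must equal the GDI edge count")
  TRUE
})
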