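#' Specify an in-silico knockout
#'
#' @param target gene to freeze to the 0 (off) state.
#' @param duration number of update steps the knockout lasts (states at
#'   steps 1..T are produced with the target forced to 0), or `Inf` for a
#'   permanent knockout.
#' @return A [Knockout-class].
#' @examples
#' knockout("v3", duration = 10)
#' @export
knockout <- function(target, duration = Inf) {
  new("Knockout", target = as.character(target), duration = as.numeric(duration))
}

defaultMaxSteps <- function(N) if (N <= 64L) 1e4 else 1e5

#' Simulate to the attractor of a Boolean trajectory
#'
#' Iterates the synchronous dynamics from `v0` until a network state
#' repeats, and returns the attractor: the transient length tau, the
#' period p, and the ordered cycle states.  Under a finite-duration
#' knockout the target's rule is replaced by the constant 0 for steps
#' 1..T; cycle detection starts only after the rule is restored (the
#' mutation window is transient by construction), so the returned cycle is
#' an attractor of the unmutated rules.  Under a permanent knockout the
#' frozen rule applies throughout and the cycle is an attractor of the
#' mutant rules.  The supplied initial state itself is never modified.
#'
#' @param network a [GMINetwork-class].
#' @param rules a matching [RuleSet-class].
#' @param v0 0/1 initial state aligned with `nodes(network)`.
#' @param ko optional [Knockout-class].
#' @param maxSteps step cap before an "attractor not found" error (default
#'   10000 for networks of at most 64 nodes, 100000 above); deterministic
#'   finite dynamics guarantee a revisit, the cap only bounds time/memory.
#' @return An [Attractor-class].
#' @examples
#' fx <- generateFixture("demo4")
#' a <- findAttractor(fx$network, fx$rules, c(0, 0, 0, 0))
#' period(a)
#' @export
findAttractor <- function(network, rules, v0, ko = NULL,
                          maxSteps = defaultMaxSteps(length(nodes(network)))) {
  if (maxSteps < 1) stop("maxSteps must be >= 1", call. = FALSE)
  packed <- packRules(network, rules)
  if (length(v0) != length(network@nodes))
    stop("initial state length must equal the node count", call. = FALSE)
  v0 <- assertBits0ok(v0)
  koTarget <- -1L
  koDuration <- 0
  if (!is.null(ko)) {
    validObject(ko)
    koTarget <- nodeIndex(network, ko@target) - 1L
    koDuration <- ko@duration
  }
  res <- cpp_find_attractor(packed, v0, koTarget, koDuration, maxSteps)
  if (!isTRUE(res$found))
    stopWithClass("gdinet_attractor_not_found",
      sprintf("no attractor found within max_steps = %d", as.integer(maxSteps)))
  st <- res$states
  colnames(st) <- network@nodes
  new("Attractor", transient = as.integer(res$tau),
      period = as.integer(res$period), states = st, nodes = network@nodes)
}

#' Extract one node's state sequence across an attractor cycle
#'
#' @param attractor an [Attractor-class].
#' @param node node identifier.
#' @return Integer 0/1 vector of length `period(attractor)`.
#' @export
nodeSequence <- function(attractor, node) {
  i <- match(node, attractor@nodes)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  unname(attractor@states[, i])
}

#' Dump an attractor as JSON
#'
#' Records tau, p and the cycle states as bit strings; useful for
#' debugging and text fixtures.
#'
#' @param attractor an [Attractor-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAttractor <- function(attractor, path) {
  jsonlite::write_json(
    list(transient = attractor@transient, period = attractor@period,
         nodes = attractor@nodes,
         states = apply(attractor@states, 1L, paste, collapse = "")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname gdinet-accessors
#' @export
setMethod("period", "Attractor", function(x) x@period)

#' @rdname gdinet-accessors
#' @export
setMethod("transientLength", "Attractor", function(x) x@transient)

#' @rdname gdinet-accessors
#' @export
setMethod("attractorStates", "Attractor", function(x) x@states)

#' @rdname gdinet-accessors
#' @export
setMethod("nodes", "Attractor", function(x) x@nodes)

setMethod("show", "Attractor", function(object) {
  kind <- if (object@period == 1L) "fixed-point" else "limit-cycle"
  cat(kind, " attractor: transient ", object@transient,
      ", period ", object@period, "\n", sep = "")
  n <- min(object@period, 6L)
  for (r in seq_len(n))
    cat("  ", paste(object@states[r, ], collapse = ""), "\n", sep = "")
  if (object@period > n) cat("  ...\n")
})
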