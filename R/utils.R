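# Internal helpers: local seeding, integer gcd/lcm on doubles, bit checks.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Expand one user seed into named per-component sub-seeds (kept < 2^31).
expandSeed <- function(seed, components) {
  if (is.null(seed)) return(setNames(rep(list(NULL), length(components)), components))
  s <- (as.numeric(seed) + 7919 * seq_along(components)) %% 2147483647
  setNames(as.list(as.integer(s)), components)
}

gcdInt <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

lcmInt <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  (a / gcdInt(a, b)) * b
}

assertBits <- function(x, what = "state") {
  if (length(x) == 0L || anyNA(x) || !all(x == 0L | x == 1L))
    stop(what, " must be a non-empty 0/1 vector", call. = FALSE)
  invisible(as.integer(x))
}

# Node label -> index lookup with a clear error.
nodeIndex <- function(network, node) {
  i <- match(node, network@nodes)
  if (anyNA(i))
    stop("unknown node(s): ", paste(node[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

stopWithClass <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
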