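#' Random network by directed preferential attachment
#'
#' Growth model: start from `m` isolated seed nodes, then attach each
#' subsequent node with `m` edges to distinct existing nodes chosen with
#' probability proportional to their current total degree (uniformly when
#' all candidates still have degree 0).  Each generated edge is oriented
#' uniformly at random and assigned an activating sign with probability
#' `signProb`.  The result has exactly `m * (N - m)` edges, no self-loops
#' and no duplicate ordered pairs.
#'
#' @param N number of nodes (`N > m`).
#' @param m edges added per new node (`m >= 1`).
#' @param signProb probability of an activating (`+`) sign.
#' @param seed optional integer seed.
#' @return A [GMINetwork-class] with nodes `g1 ... gN`.
#' @examples
#' net <- baRandomNetwork(20, 2, seed = 1)
#' nrow(edges(net))  # 2 * 18
#' @export
baRandomNetwork <- function(N, m, signProb = 0.5, seed = NULL) {
  N <- as.integer(N); m <- as.integer(m)
  if (m < 1L || N <= m)
    stop("need N > m >= 1", call. = FALSE)
  labels <- sprintf("g%d", seq_len(N))
  withSeed(seed, {
    degree <- integer(N)
    src <- character(0); dst <- character(0)
    for (v in (m + 1L):N) {
      existing <- seq_len(v - 1L)
      w <- degree[existing]
      prob <- if (sum(w) == 0) rep(1, length(existing)) else w
      # distinct degree-proportional targets (weights without replacement)
      targets <- sample(existing, m, replace = FALSE, prob = prob)
      for (u in targets) {
        flip <- runif(1) < 0.5
        a <- if (flip) v else u
        b <- if (flip) u else v
        src <- c(src, labels[a]); dst <- c(dst, labels[b])
        degree[u] <- degree[u] + 1L
        degree[v] <- degree[v] + 1L
      }
    }
    sgn <- ifelse(runif(length(src)) < signProb, "+", "-")
    gmiNetwork(data.frame(source = src, target = dst, sign = sgn,
                          stringsAsFactors = FALSE), nodes = labels)
  })
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly picks two edges (a, b) and (c, d) and rewires them to
#' (a, d) and (c, b); swaps that would create a self-loop or a duplicate
#' ordered pair are rejected.  Signs travel with the source endpoint.
#' Every node's in-degree and out-degree are exactly preserved.  If the
#' graph is too small or dense to complete the requested swaps, the
#' partially shuffled network is returned with a warning after a bounded
#' number of rejections.
#'
#' @param network a [GMINetwork-class].
#' @param nSwaps number of successful swaps to perform (default
#'   `10 * |A|`, a standard mixing heuristic).
#' @param seed optional integer seed.
#' @return A [GMINetwork-class] with the same nodes and degree sequence.
#' @export
shuffleNetwork <- function(network, nSwaps = 10L * nrow(edges(network)),
                           seed = NULL) {
  nSwaps <- as.integer(nSwaps)
  if (nSwaps < 0L) stop("nSwaps must be >= 0", call. = FALSE)
  ed <- network@edges
  nE <- nrow(ed)
  if (nSwaps == 0L || nE < 2L) return(network)
  withSeed(seed, {
    key <- new.env(hash = TRUE, parent = emptyenv())
    for (r in seq_len(nE))
      assign(paste(ed$source[r], ed$target[r], sep = "\r"), TRUE, envir = key)
    done <- 0L
    tries <- 0L
    maxTries <- max(1000L, 100L * nSwaps)
    while (done < nSwaps && tries < maxTries) {
      tries <- tries + 1L
      idx <- sample.int(nE, 2L)
      a <- ed$source[idx[1L]]; b <- ed$target[idx[1L]]
      cc <- ed$source[idx[2L]]; d <- ed$target[idx[2L]]
      if (a == d || cc == b) next
      k1 <- paste(a, d, sep = "\r"); k2 <- paste(cc, b, sep = "\r")
      if (exists(k1, envir = key, inherits = FALSE) ||
          exists(k2, envir = key, inherits = FALSE)) next
      rm(list = c(paste(a, b, sep = "\r"), paste(cc, d, sep = "\r")),
         envir = key)
      assign(k1, TRUE, envir = key); assign(k2, TRUE, envir = key)
      ed$target[idx[1L]] <- d
      ed$target[idx[2L]] <- b
      done <- done + 1L
    }
    if (done < nSwaps)
      warning("completed only ", done, " of ", nSwaps,
              " swaps after ", tries, " attempts")
    gmiNetwork(ed, nodes = network@nodes)
  })
}
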