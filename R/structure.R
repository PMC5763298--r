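#' Structural pair metrics: shortest path, path count, feedback-loop count
#'
#' `shortestPathLength()` returns the number of edges on a shortest
#' directed path (`Inf` when the target is unreachable; unreachable pairs
#' are excluded from correlations downstream).  `countPaths()` counts
#' simple directed paths (no repeated node) of at most `maxLen` edges.
#' `countFeedbackLoops()` counts simple directed cycles of at most
#' `maxLen` edges containing both nodes; each cycle is counted once
#' regardless of rotation.  Path/cycle enumeration is exponential in
#' general, so the length cap is mandatory and is recorded in the feature
#' table output.
#'
#' @param network a [GMINetwork-class] or [GDINetwork-class].
#' @param from,to distinct node identifiers.
#' @param maxLen maximum path/cycle length in edges (default: N for
#'   networks of at most 15 nodes, 8 otherwise).
#' @return An integer count, or `Inf` for unreachable shortest paths.
#' @examples
#' net <- gmiNetwork(data.frame(source = c("a", "b"), target = c("b", "a"),
#'                              sign = "+"))
#' shortestPathLength(net, "a", "b")
#' countFeedbackLoops(net, "a", "b")
#' @export
shortestPathLength <- function(network, from, to) {
  if (identical(from, to)) stop("from and to must differ", call. = FALSE)
  nodeIndex(network, c(from, to))
  g <- asIgraph(network)
  d <- igraph::distances(g, v = from, to = to, mode = "out")[1L, 1L]
  if (is.infinite(d)) Inf else as.integer(d)
}

defaultMaxLen <- function(N) if (N <= 15L) as.integer(N) else 8L

#' @rdname shortestPathLength
#' @export
countPaths <- function(network, from, to,
                       maxLen = defaultMaxLen(length(nodes(network)))) {
  if (identical(from, to)) stop("from and to must differ", call. = FALSE)
  if (maxLen < 1) stop("maxLen must be >= 1", call. = FALSE)
  nodeIndex(network, c(from, to))
  g <- asIgraph(network)
  length(igraph::all_simple_paths(g, from = from, to = to, mode = "out",
                                  cutoff = maxLen))
}

#' @rdname shortestPathLength
#' @export
countFeedbackLoops <- function(network, from, to,
                               maxLen = defaultMaxLen(length(nodes(network)))) {
  if (identical(from, to)) stop("from and to must differ", call. = FALSE)
  nodeIndex(network, c(from, to))
  adj <- adjacencyList(network)
  # A simple cycle through both nodes decomposes uniquely into a simple
  # path from -> to and a node-disjoint simple path to -> from; enumerate
  # the first legs by DFS and count the return legs.
  total <- 0L
  forward <- simplePathsBetween(adj, from, to, maxLen - 1L)
  for (leg in forward) {
    inner <- setdiff(leg, c(from, to))
    budget <- maxLen - (length(leg) - 1L)
    total <- total + countReturnPaths(adj, to, from, budget, inner)
  }
  total
}

adjacencyList <- function(network) {
  ed <- if (is(network, "GDINetwork")) network@edges else network@edges
  split(ed$target, factor(ed$source, levels = network@nodes))
}

# All simple paths from -> to with at most maxLen edges, as node vectors.
simplePathsBetween <- function(adj, from, to, maxLen) {
  out <- list()
  recurse <- function(path, budget) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt == to) {
        out[[length(out) + 1L]] <<- c(path, to)
      } else if (budget > 1L && !(nxt %in% path)) {
        recurse(c(path, nxt), budget - 1L)
      }
    }
  }
  if (maxLen >= 1L) recurse(from, maxLen)
  out
}

countReturnPaths <- function(adj, from, to, maxLen, forbidden) {
  count <- 0L
  recurse <- function(path, budget) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt == to) {
        count <<- count + 1L
      } else if (budget > 1L && !(nxt %in% path) && !(nxt %in% forbidden)) {
        recurse(c(path, nxt), budget - 1L)
      }
    }
  }
  if (maxLen >= 1L) recurse(from, maxLen)
  count
}

#' Degree histogram of a directed network
#'
#' @param network a [GMINetwork-class] or [GDINetwork-class].
#' @param mode `"total"`, `"in"` or `"out"`.
#' @param binWidth histogram bin width (degrees \[b, b + binWidth)).
#' @return data.frame with columns `binStart`, `binEnd`, `frequency`;
#'   frequencies sum to the node count.
#' @export
degreeDistribution <- function(network, mode = c("total", "in", "out"),
                               binWidth = 1L) {
  mode <- match.arg(mode)
  if (binWidth < 1) stop("binWidth must be >= 1", call. = FALSE)
  deg <- nodeDegrees(network)
  d <- switch(mode, total = deg$inDegree + deg$outDegree,
              "in" = deg$inDegree, out = deg$outDegree)
  bin <- floor(d / binWidth)
  tab <- table(factor(bin, levels = 0:max(bin)))
  data.frame(binStart = as.integer(names(tab)) * binWidth,
             binEnd = (as.integer(names(tab)) + 1L) * binWidth - 1L,
             frequency = as.integer(tab))
}

# Per-node in/out degree table, aligned with the node order.
nodeDegrees <- function(network) {
  ed <- network@edges
  data.frame(node = network@nodes,
             inDegree = as.integer(table(factor(ed$target, levels = network@nodes))),
             outDegree = as.integer(table(factor(ed$source, levels = network@nodes))),
             stringsAsFactors = FALSE)
}

#' Correlation between two numeric vectors
#'
#' Thin wrapper over [stats::cor.test()] that refuses degenerate input: a
#' zero-variance vector raises a classed `gdinet_undefined_correlation`
#' error instead of returning a number.
#'
#' @param xs,ys numeric vectors of equal length (at least 3 finite pairs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `estimate`, `p.value`, `method`, `n`.
#' @export
correlate <- function(xs, ys, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(xs) != length(ys)) stop("length mismatch", call. = FALSE)
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  if (var(xs) == 0 || var(ys) == 0)
    stopWithClass("gdinet_undefined_correlation",
                  "correlation undefined: zero variance in an input vector")
  ct <- suppressWarnings(cor.test(xs, ys, method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method, n = length(xs))
}

#' Per-pair feature table: influence vs. structural properties
#'
#' One row per ordered gene pair with a finite shortest path in the GMI
#' network: the influence value mu, the shortest-path length l, the simple
#' path count n (up to `maxLen` edges) and the feedback-loop count f (up
#' to `maxLen` edges).  Ready for [correlate()].
#'
#' @param gmi a [GMINetwork-class].
#' @param matrix a matching [InfluenceMatrix-class].
#' @param maxLen path/cycle length cap in edges.
#' @return data.frame with columns `source`, `target`, `mu`,
#'   `shortestPath`, `nPaths`, `nFeedbackLoops`, plus attribute `maxLen`.
#' @export
pairwiseFeatureTable <- function(gmi, matrix,
                                 maxLen = defaultMaxLen(length(nodes(gmi)))) {
  if (!identical(gmi@nodes, matrix@nodes))
    stop("network and influence matrix node sets differ", call. = FALSE)
  g <- asIgraph(gmi)
  dist <- igraph::distances(g, mode = "out")
  adj <- adjacencyList(gmi)
  mu <- matrix@numerator / matrix@denominator
  rows <- list()
  for (i in seq_along(gmi@nodes)) {
    for (j in seq_along(gmi@nodes)) {
      if (i == j || is.infinite(dist[i, j])) next
      vi <- gmi@nodes[i]; vj <- gmi@nodes[j]
      rows[[length(rows) + 1L]] <- data.frame(
        source = vi, target = vj, mu = mu[i, j],
        shortestPath = as.integer(dist[i, j]),
        nPaths = countPaths(gmi, vi, vj, maxLen = maxLen),
        nFeedbackLoops = countFeedbackLoops(gmi, vi, vj, maxLen = maxLen),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L)
    data.frame(source = character(), target = character(), mu = numeric(),
               shortestPath = integer(), nPaths = integer(),
               nFeedbackLoops = integer(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "maxLen") <- maxLen
  out
}

#' Read a gene-group annotation table
#'
#' TSV with two columns, `gene<TAB>group` (e.g. drug-target classes).
#'
#' @param path file path.
#' @return Named character vector mapping gene to group label.
#' @export
readGroupMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Compare node degrees between gene groups
#'
#' Computes per-group mean in- and out-degree on the given network
#' (typically a GDI network) and two-sided Wilcoxon rank-sum p-values for
#' every group pair.  Labeled genes missing from the network raise an
#' error; empty groups are dropped with a warning.
#'
#' @param network a [GMINetwork-class] or [GDINetwork-class].
#' @param groups named character vector (names = genes, values = group
#'   labels), e.g. from [readGroupMap()].
#' @return list with `means` (data.frame: group, n, meanInDegree,
#'   meanOutDegree) and `tests` (data.frame: groupA, groupB, degree mode,
#'   p.value).
#' @export
groupDegreeComparison <- function(network, groups) {
  if (is.null(names(groups))) stop("groups must be a named vector", call. = FALSE)
  missing <- setdiff(names(groups), network@nodes)
  if (length(missing) > 0L)
    stop("labeled gene(s) not in network: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  deg <- nodeDegrees(network)
  rownames(deg) <- deg$node
  lab <- groups[names(groups)]
  split_ <- split(names(lab), lab)
  empty <- names(split_)[lengths(split_) == 0L]
  if (length(empty) > 0L) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    split_ <- split_[lengths(split_) > 0L]
  }
  if (length(split_) < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  means <- do.call(rbind, lapply(names(split_), function(gp) {
    d <- deg[split_[[gp]], ]
    data.frame(group = gp, n = nrow(d),
               meanInDegree = mean(d$inDegree),
               meanOutDegree = mean(d$outDegree), stringsAsFactors = FALSE)
  }))
  combs <- utils::combn(names(split_), 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(combs, function(pr) {
    dA <- deg[split_[[pr[1L]]], ]; dB <- deg[split_[[pr[2L]]], ]
    do.call(rbind, lapply(c("inDegree", "outDegree"), function(mode) {
      pv <- suppressWarnings(
        wilcox.test(dA[[mode]], dB[[mode]], alternative = "two.sided")$p.value)
      data.frame(groupA = pr[1L], groupB = pr[2L], degree = mode,
                 p.value = pv, stringsAsFactors = FALSE)
    }))
  }))
  rownames(means) <- rownames(tests) <- NULL
  list(means = means, tests = tests)
}
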