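#' Construct a signed directed gene-gene interaction network
#'
#' @param edges data.frame (or coercible) with columns `source`, `target`,
#'   `sign`; signs may be given as `+`/`-` or `activates`/`inhibits`.
#' @param nodes optional character vector fixing the node order; defaults
#'   to the sorted unique labels appearing in `edges`.  Nodes without any
#'   edge may be supplied here.
#' @return A [GMINetwork-class].
#' @examples
#' net <- gmiNetwork(data.frame(source = c("a", "b"),
#'                              target = c("b", "c"),
#'                              sign   = c("+", "-")))
#' nodes(net)
#' @export
gmiNetwork <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- normalizeSign(as.character(edges$sign))
  }
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$source, edges$target)))
  rownames(edges) <- NULL
  new("GMINetwork", nodes = as.character(nodes),
      edges = edges[, c("source", "target", "sign"), drop = FALSE])
}

normalizeSign <- function(sign) {
  out <- rep(NA_character_, length(sign))
  out[sign %in% c("+", "activates", "activating", "1")] <- "+"
  out[sign %in% c("-", "inhibits", "inhibiting", "-1")] <- "-"
  if (anyNA(out))
    stop("unrecognized edge sign(s): ",
         paste(unique(sign[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Read a signed edge list from a TSV file
#'
#' Expects three tab-separated fields per line: source, target, sign
#' (`+`/`-` or `activates`/`inhibits`); lines starting with `#` are
#' ignored.  Self-loops are dropped (with a message), duplicate identical
#' lines are collapsed to one edge, and duplicate ordered pairs with
#' conflicting signs raise an error.  Node order is the sorted unique
#' label order.
#'
#' @param path file path.
#' @return A [GMINetwork-class].
#' @seealso [writeNetwork()]
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- which(keep)
  if (length(lines) == 0L) return(gmiNetwork())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stopWithClass("gdinet_parse_error",
      sprintf("malformed network line %d: expected 'source<TAB>target<TAB>sign', got %s",
              lineNo[bad[1L]], sQuote(lines[bad[1L]])))
  ed <- data.frame(source = trimws(vapply(parts, `[`, "", 1L)),
                   target = trimws(vapply(parts, `[`, "", 2L)),
                   sign   = trimws(vapply(parts, `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  ed$sign <- normalizeSign(ed$sign)
  self <- ed$source == ed$target
  if (any(self)) {
    message("dropped ", sum(self), " self-loop edge(s)")
    ed <- ed[!self, , drop = FALSE]
  }
  key <- paste(ed$source, ed$target, sep = "\r")
  if (anyDuplicated(key)) {
    signsPerPair <- tapply(ed$sign, key, function(s) length(unique(s)))
    if (any(signsPerPair > 1L)) {
      clash <- names(signsPerPair)[signsPerPair > 1L][1L]
      stopWithClass("gdinet_validation_error",
        sprintf("conflicting signs for duplicated edge %s",
                gsub("\r", " -> ", clash, fixed = TRUE)))
    }
    ed <- ed[!duplicated(key), , drop = FALSE]
  }
  gmiNetwork(ed)
}

#' Write a network edge list as TSV
#'
#' @param network a [GMINetwork-class] or [GDINetwork-class].
#' @param path output file.  GDI networks are written as
#'   `source target weight` (weight = exact influence as a double).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  if (is(network, "GDINetwork")) {
    ed <- network@edges
    out <- data.frame(source = ed$source, target = ed$target,
                      weight = format(ed$weight, digits = 15))
  } else {
    out <- network@edges
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname gdinet-accessors
#' @export
setMethod("nodes", "GMINetwork", function(x) x@nodes)

#' @rdname gdinet-accessors
#' @export
setMethod("edges", "GMINetwork", function(x) x@edges)

#' @rdname gdinet-accessors
#' @export
setMethod("nodes", "GDINetwork", function(x) x@nodes)

#' @rdname gdinet-accessors
#' @export
setMethod("edges", "GDINetwork", function(x) x@edges)

#' @rdname gdinet-accessors
#' @export
setMethod("provenance", "GDINetwork", function(x) x@provenance)

setMethod("show", "GMINetwork", function(object) {
  cat("GMINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "signed directed edges\n")
  if (length(object@nodes) > 0L)
    cat("  nodes:", paste(head(object@nodes, 8L), collapse = ", "),
        if (length(object@nodes) > 8L) "..." else "", "\n")
})

setMethod("show", "GDINetwork", function(object) {
  cat("GDINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "positive-influence edges\n")
  pv <- object@provenance
  if (length(pv) > 0L)
    cat("  duration T =", pv$duration, ", |S| =", pv$nStates, "\n")
})

# In-neighbours (regulators) of each node, as a named list, with the edge
# signs in matching order.
inNeighborList <- function(network) {
  ed <- network@edges
  regs <- split(ed$source, factor(ed$target, levels = network@nodes))
  sgns <- split(ed$sign, factor(ed$target, levels = network@nodes))
  list(regulators = regs, signs = sgns)
}

# igraph view of the interaction structure (used by the structural metrics).
asIgraph <- function(network) {
  igraph::graph_from_data_frame(network@edges[, c("source", "target")],
                                directed = TRUE,
                                vertices = data.frame(name = network@nodes))
}
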