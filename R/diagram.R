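## Wright path-diagram engine: trace compound paths through multi-layer
## diagrams (breed -> composite -> cross), multiply segment coefficients,
## and accumulate determinations. Supports the two-layer diagram class
## used for composite cattle: at most one correlation arc per traced path,
## always as its first step.

#' Construct a path diagram
#'
#' @param nodes character vector of node labels.
#' @param edges data.frame with columns `from`, `to`, `coef`: directed
#'   causal edges carrying path coefficients; must form a DAG.
#' @param arcs optional data.frame with columns `from`, `to`, `r`:
#'   two-headed correlation arcs, allowed only between exogenous nodes
#'   (nodes with no incoming causal edge).
#' @return A [PathDiagram-class].
#' @examples
#' # a two-generation composite: breeds A and B form composite C, and the
#' # cross D receives half its variance from C and half directly from A
#' d <- pathDiagram(
#'   nodes = c("A", "B", "C", "D"),
#'   edges = data.frame(from = c("A", "B", "A", "C"),
#'                      to   = c("C", "C", "D", "D"),
#'                      coef = c(sqrt(0.625), sqrt(0.375),
#'                               sqrt(0.5), sqrt(0.5))))
#' determinationFromDiagram(d, "A", "D")  # 0.8125
#' @export
pathDiagram <- function(nodes, edges, arcs = NULL) {
  if (is.null(arcs))
    arcs <- data.frame(from = character(0), to = character(0),
                       r = numeric(0))
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  arcs$from <- as.character(arcs$from); arcs$to <- as.character(arcs$to)
  new("PathDiagram", nodes = as.character(nodes), edges = edges,
      arcs = arcs)
}

#' Exogenous nodes of a diagram
#'
#' Nodes with no incoming causal edge (the putative ancestral breeds).
#'
#' @param d a [PathDiagram-class].
#' @return character vector of node labels.
#' @export
exogenousNodes <- function(d) {
  setdiff(d@nodes, unique(d@edges$to))
}

## depth-first enumeration of directed chains from -> ... -> to;
## each chain is a data.frame(type, from, to, coef)
.directedChains <- function(edges, from, to, visited = character(0)) {
  if (from == to) return(list(NULL))
  out <- list()
  nxt <- edges[edges$from == from & !(edges$to %in% visited), ,
               drop = FALSE]
  for (i in seq_len(nrow(nxt))) {
    tails <- .directedChains(edges, nxt$to[i], to, c(visited, from))
    seg <- data.frame(type = "edge", from = nxt$from[i], to = nxt$to[i],
                      coef = nxt$coef[i])
    for (tl in tails) out[[length(out) + 1]] <- rbind(seg, tl)
  }
  out
}

#' Enumerate Wright paths between two nodes
#'
#' All distinct directed chains from `source` to `sink`, plus chains that
#' begin with exactly one correlation arc out of `source` followed by a
#' directed chain -- Wright's tracing rule for the supported diagram
#' class. No node is revisited within a chain.
#'
#' @param d a [PathDiagram-class].
#' @param source,sink node labels.
#' @return list of paths; each path is a data.frame with columns `type`
#'   (`"edge"` or `"arc"`), `from`, `to`, `coef`.
#' @export
traceWrightPaths <- function(d, source, sink) {
  if (!source %in% d@nodes) stop("unknown node: ", source)
  if (!sink %in% d@nodes) stop("unknown node: ", sink)
  paths <- Filter(Negate(is.null),
                  .directedChains(d@edges, source, sink))
  ## one leading correlation arc, then a directed chain from the far end
  a <- d@arcs
  touching <- which(a$from == source | a$to == source)
  for (i in touching) {
    other <- if (a$from[i] == source) a$to[i] else a$from[i]
    seg <- data.frame(type = "arc", from = source, to = other,
                      coef = a$r[i])
    for (tl in Filter(Negate(is.null),
                      .directedChains(d@edges, other, sink)))
      paths[[length(paths) + 1]] <- rbind(seg, tl)
  }
  paths
}

#' Coefficient of a compound path
#'
#' The product of all component segment coefficients (a correlation arc
#' contributes its correlation).
#'
#' @param path one element of the list returned by [traceWrightPaths()].
#' @return numeric scalar.
#' @export
compoundPathCoefficient <- function(path) {
  if (is.null(path) || nrow(path) == 0) stop("empty path")
  prod(path$coef)
}

#' Determination of a sink node by an exogenous source
#'
#' Sums the squared compound coefficients of all directed paths from
#' `source` to `sink`, plus cross terms for every pair of a directed path
#' from `source` and a directed path from an arc-connected exogenous node:
#' each pair contributes (source-path coefficient) x (arc correlation) x
#' (other-path coefficient). On a single-layer diagram this reproduces the
#' coefficient of combined determination of the equivalent flat system.
#'
#' @param d a [PathDiagram-class].
#' @param source an exogenous node label.
#' @param sink a downstream node label.
#' @return numeric determination coefficient.
#' @export
determinationFromDiagram <- function(d, source, sink) {
  direct <- Filter(function(p) p$type[1] == "edge",
                   traceWrightPaths(d, source, sink))
  det <- sum(vapply(direct, compoundPathCoefficient, numeric(1))^2)
  a <- d@arcs
  touching <- which(a$from == source | a$to == source)
  for (i in touching) {
    other <- if (a$from[i] == source) a$to[i] else a$from[i]
    otherPaths <- Filter(Negate(is.null),
                         .directedChains(d@edges, other, sink))
    for (p in direct) for (q in otherPaths)
      det <- det + compoundPathCoefficient(p) * a$r[i] *
        compoundPathCoefficient(q)
  }
  det
}

#' Breed composition implied by a path diagram
#'
#' Evaluates [determinationFromDiagram()] for every exogenous node and
#' normalises the determinations to a simplex.
#'
#' @param d a [PathDiagram-class].
#' @param sink the target node.
#' @return A [GBCEstimate-class] with method `"diagram"`; the raw
#'   determinations are attached as attribute `"determinations"`.
#' @export
diagramGBC <- function(d, sink) {
  ex <- exogenousNodes(d)
  det <- vapply(ex, function(s) determinationFromDiagram(d, s, sink),
                numeric(1))
  tot <- sum(det)
  if (tot <= 0) stop("total determination is not positive")
  comp <- det / tot
  clamped <- any(comp < 0)
  if (clamped) { comp <- pmax(comp, 0); comp <- comp / sum(comp) }
  est <- .asGBC(comp, sink, "diagram", clamped = clamped)
  attr(est, "determinations") <- det
  est
}

#' Read / write path diagrams as JSON
#'
#' The on-disk schema is a JSON object with fields `nodes` (array of
#' labels), `edges` (array of `{from, to, coef}`) and `arcs` (array of
#' `{from, to, r}`, possibly empty).
#'
#' @param path file to read or write.
#' @return [readPathDiagram()] returns a [PathDiagram-class];
#'   `writePathDiagram` returns `path` invisibly.
#' @export
readPathDiagram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(j$edges)
  arcs <- if (is.null(j$arcs) || length(j$arcs) == 0) NULL
          else as.data.frame(j$arcs)
  pathDiagram(unlist(j$nodes), edges, arcs)
}

#' @rdname readPathDiagram
#' @param d a [PathDiagram-class] to write.
#' @export
writePathDiagram <- function(d, path) {
  jsonlite::write_json(list(nodes = d@nodes, edges = d@edges,
                            arcs = d@arcs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
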