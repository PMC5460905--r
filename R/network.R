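# Compound-target-mechanism network construction and degree analysis.

#' Build a compound-target-mechanism network from consensus calls
#'
#' Creates a bipartite compound-target graph with one edge per positive
#' consensus call (duplicate calls for the same pair collapse to one edge),
#' plus annotation edges from each target to its mechanism-class node(s).
#' Compounds whose calls are all negative are retained as isolated nodes.
#'
#' @param calls data.frame from [predictProfile()] (needs `compound_id`,
#'   `target_id`, `interaction`).
#' @param targetTable data.frame of target metadata with `gene_symbol` and
#'   `subfamily` (semicolon-separated [mechanismClasses]); every called
#'   target must appear here.
#' @return a [CPINetwork-class].
#' @export
buildNetwork <- function(calls, targetTable) {
  validateTargetTable(targetTable)
  unknown <- setdiff(unique(calls$target_id), targetTable$gene_symbol)
  if (length(unknown))
    stop("calls reference unknown target(s): ", paste(unknown, collapse = ", "))
  compounds <- sort(unique(calls$compound_id))
  targets <- sort(unique(calls$target_id))
  pos <- unique(calls[calls$interaction, c("compound_id", "target_id")])
  subsOf <- function(tg) {
    s <- targetTable$subfamily[targetTable$gene_symbol == tg]
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  mechs <- sort(unique(unlist(lapply(targets, subsOf))))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(compounds), name = compounds,
                            type = "compound")
  g <- igraph::add_vertices(g, length(targets), name = targets,
                            type = "target")
  g <- igraph::add_vertices(g, length(mechs), name = mechs,
                            type = "mechanism")
  if (nrow(pos)) {
    ord <- order(pos$compound_id, pos$target_id)
    pos <- pos[ord, ]
    g <- igraph::add_edges(g, as.vector(rbind(pos$compound_id, pos$target_id)),
                           relation = "interacts")
  }
  memb <- do.call(rbind, lapply(targets, function(tg)
    data.frame(target = tg, mech = subsOf(tg))))
  if (!is.null(memb) && nrow(memb))
    g <- igraph::add_edges(g, as.vector(rbind(memb$target, memb$mech)),
                           relation = "member_of")
  new("CPINetwork", graph = g, compounds = compounds, targets = targets,
      mechanisms = mechs)
}

interactionDegrees <- function(net) {
  g <- net@graph
  keep <- igraph::E(g)[igraph::E(g)$relation == "interacts"]
  gi <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
  deg <- igraph::degree(gi)
  list(compound = deg[net@compounds], target = deg[net@targets])
}

#' Degree statistics of a compound-target network
#'
#' Node degrees over compound-target interaction edges only (mechanism
#' annotation edges never enter the statistics), the mean number of targets
#' per compound and compounds per target, and degree-ranked hub lists (ties
#' broken by node id). The handshake identity
#' `meanTargetsPerCompound * nCompounds = nEdges =
#' meanCompoundsPerTarget * nTargets` holds exactly.
#'
#' @param net a [CPINetwork-class].
#' @return list with `degree` (per-side named vectors), `nEdges`,
#'   `meanTargetsPerCompound`, `meanCompoundsPerTarget` and `hubs`.
#' @export
networkStats <- function(net) {
  if (!length(net@compounds) || !length(net@targets))
    stop("network needs at least one compound and one target node")
  deg <- interactionDegrees(net)
  nEdges <- sum(deg$compound)
  rankSide <- function(d) {
    ord <- order(-d, names(d))
    data.frame(node = names(d)[ord], degree = unname(d[ord]))
  }
  list(degree = deg,
       nEdges = nEdges,
       meanTargetsPerCompound = nEdges / length(net@compounds),
       meanCompoundsPerTarget = nEdges / length(net@targets),
       hubs = list(compound = rankSide(deg$compound),
                   target = rankSide(deg$target)))
}

#' Count nodes on one side with at least a given degree
#'
#' @param net a [CPINetwork-class].
#' @param side `"compound"` or `"target"`.
#' @param k minimum degree (interaction edges only).
#' @return integer count.
#' @export
countNodesWithMinDegree <- function(net, side = c("compound", "target"), k) {
  side <- match.arg(side)
  deg <- interactionDegrees(net)[[side]]
  sum(deg >= k)
}

setMethod("show", "CPINetwork", function(object) {
  deg <- interactionDegrees(object)
  cat(sprintf(
    "CPINetwork: %d compounds, %d targets, %d mechanisms, %d interaction edges\n",
    length(object@compounds), length(object@targets),
    length(object@mechanisms), sum(deg$compound)))
  invisible(NULL)
})

#' Export a network as SIF (and the mechanism memberships)
#'
#' Writes `compound<TAB>interacts<TAB>target` lines followed by
#' `target<TAB>member_of<TAB>mechanism` lines, in sorted order so output is
#' byte-stable.
#'
#' @param net a [CPINetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportSIF <- function(net, path) {
  g <- net@graph
  el <- igraph::as_edgelist(g)
  rel <- igraph::E(g)$relation
  lines <- sprintf("%s\t%s\t%s", el[, 1], rel, el[, 2])
  writeLines(lines[order(rel, lines)], path)
  invisible(path)
}

#' Export a network as GraphML with node-type attributes
#'
#' @param net a [CPINetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(net, path) {
  igraph::write_graph(net@graph, path, format = "graphml")
  invisible(path)
}
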