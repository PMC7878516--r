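#' Built-in polyhedral graphs
#'
#' Edge lists of the convex polyhedra used as CCPO cage scaffolds. Vertices
#' are labelled so that apex vertices (when the solid has them) come first.
#'
#' @keywords internal
#' @noRd
.builtin_polyhedra <- function() {
  list(
    tetrahedron = list(
      vertices = c("A", "B", "C", "D"),
      edges = rbind(
        c("A", "B"), c("A", "C"), c("A", "D"),
        c("B", "C"), c("B", "D"), c("C", "D")
      )
    ),
    # two apexes U (top) and W (bottom) over the equatorial triangle A-B-C
    trigonal_bipyramid = list(
      vertices = c("U", "W", "A", "B", "C"),
      edges = rbind(
        c("U", "A"), c("U", "B"), c("U", "C"),
        c("W", "A"), c("W", "B"), c("W", "C"),
        c("A", "B"), c("B", "C"), c("A", "C")
      )
    ),
    square_pyramid = list(
      vertices = c("U", "A", "B", "C", "D"),
      edges = rbind(
        c("U", "A"), c("U", "B"), c("U", "C"), c("U", "D"),
        c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")
      )
    ),
    octahedron = list(
      vertices = c("U", "W", "A", "B", "C", "D"),
      edges = rbind(
        c("U", "A"), c("U", "B"), c("U", "C"), c("U", "D"),
        c("W", "A"), c("W", "B"), c("W", "C"), c("W", "D"),
        c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")
      )
    ),
    trigonal_prism = list(
      vertices = c("A", "B", "C", "D", "E", "F"),
      edges = rbind(
        c("A", "B"), c("B", "C"), c("A", "C"),
        c("D", "E"), c("E", "F"), c("D", "F"),
        c("A", "D"), c("B", "E"), c("C", "F")
      )
    )
  )
}

#' Construct a polyhedral graph
#'
#' Builds the graph scaffold of a CCPO cage, either from a built-in polyhedron
#' name or from an explicit edge list. The graph must be simple (no self-loops,
#' no duplicate edges) and connected; each edge will ultimately carry one
#' coiled-coil dimer of the cage.
#'
#' @param spec Either the name of a built-in polyhedron (`"tetrahedron"`,
#'   `"trigonal_bipyramid"`, `"square_pyramid"`, `"octahedron"`,
#'   `"trigonal_prism"`) or a two-column matrix / data frame of vertex-label
#'   pairs, one row per edge.
#' @param name Optional label for the graph (defaults to the built-in name or
#'   `"custom"`).
#'
#' @return An object of class `polyhedral_graph`: a list with elements
#'   `name`, `vertices` (character vector) and `edges` (integer matrix,
#'   one row per edge, indices into `vertices`).
#' @examples
#' g <- build_polyhedron("trigonal_bipyramid")
#' length(g$vertices)  # 5
#' nrow(g$edges)       # 9
#' @export
build_polyhedron <- function(spec, name = NULL) {
  if (is.character(spec) && length(spec) == 1) {
    builtin <- .builtin_polyhedra()
    if (!spec %in% names(builtin)) {
      stop("unknown built-in polyhedron: ", spec,
           " (available: ", paste(names(builtin), collapse = ", "), ")")
    }
    def <- builtin[[spec]]
    return(.make_polyhedral_graph(def$vertices, def$edges,
                                  name = if (is.null(name)) spec else name))
  }
  edges <- as.matrix(spec)
  if (ncol(edges) != 2) stop("edge listing must have two columns")
  storage.mode(edges) <- "character"
  vertices <- sort(unique(as.vector(edges)))
  .make_polyhedral_graph(vertices, edges,
                         name = if (is.null(name)) "custom" else name)
}

.make_polyhedral_graph <- function(vertices, edge_labels, name) {
  if (nrow(edge_labels) < 1) stop("edge count must be >= 1")
  ei <- cbind(match(edge_labels[, 1], vertices), match(edge_labels[, 2], vertices))
  if (anyNA(ei)) stop("edge references unknown vertex")
  if (any(ei[, 1] == ei[, 2])) stop("self-loop not allowed")
  key <- paste(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2]))
  if (anyDuplicated(key)) stop("duplicate edge not allowed")
  g <- igraph::graph_from_edgelist(ei, directed = FALSE)
  if (igraph::vcount(g) < length(vertices) ||
      !igraph::is_connected(g)) {
    stop("graph must be connected")
  }
  structure(
    list(name = name, vertices = vertices,
         edges = matrix(as.integer(ei), ncol = 2)),
    class = "polyhedral_graph"
  )
}

#' @export
print.polyhedral_graph <- function(x, ...) {
  cat(sprintf("polyhedral_graph '%s': %d vertices, %d edges\n",
              x$name, length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a polyhedral graph
#' @param graph A `polyhedral_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

# Map an unordered vertex-index pair to its edge row index (NA if absent).
.edge_index <- function(graph, u, v) {
  a <- pmin(u, v); b <- pmax(u, v)
  ga <- pmin(graph$edges[, 1], graph$edges[, 2])
  gb <- pmax(graph$edges[, 1], graph$edges[, 2])
  match(paste(a, b), paste(ga, gb))
}

#' Read or write a polyhedral graph as JSON
#'
#' The JSON layout is `{"name": ..., "vertices": [...], "edges": [[u,v], ...]}`
#' with vertex labels (not indices) in the edge list.
#'
#' @param graph A `polyhedral_graph`.
#' @param path File path.
#' @return `write_polyhedron_json` returns `path` invisibly;
#'   `read_polyhedron_json` returns a `polyhedral_graph`.
#' @export
write_polyhedron_json <- function(graph, path) {
  obj <- list(
    name = graph$name,
    vertices = graph$vertices,
    edges = lapply(seq_len(nrow(graph$edges)), function(i) {
      graph$vertices[graph$edges[i, ]]
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_polyhedron_json
#' @export
read_polyhedron_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  g <- build_polyhedron(edges, name = obj$name)
  # preserve the stored vertex ordering when it is a permutation of ours
  if (!is.null(obj$vertices) && setequal(obj$vertices, g$vertices)) {
    remap <- match(g$vertices, obj$vertices)
    ord <- order(remap)
    new_vertices <- g$vertices[ord]
    idx <- match(g$vertices, new_vertices)
    g$vertices <- new_vertices
    g$edges <- matrix(idx[g$edges], ncol = 2)
  }
  g
}
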