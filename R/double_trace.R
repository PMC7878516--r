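#' Double traces of polyhedral graphs
#'
#' A double trace is a closed walk that traverses every edge of the graph
#' exactly twice; the two traversals of an edge supply the two helices of that
#' edge's coiled-coil dimer. Admissible traces are additionally
#' non-backtracking: a step `u -> v` is never followed immediately by
#' `v -> u` (cyclically), which would place both helices of a dimer on a
#' zero-length loop.
#'
#' @name double_trace
NULL

# Encode a closed walk as its cyclic vertex sequence of length 2|E|
# (step i runs w[i] -> w[i+1], cyclically).
.trace_new <- function(graph, w) {
  m <- length(w)
  to <- c(w[-1], w[1])
  structure(
    list(graph = graph,
         vertices = as.integer(w),
         steps = cbind(from = as.integer(w), to = as.integer(to)),
         edge_ids = .edge_index(graph, w, to),
         closed = TRUE),
    class = "double_trace"
  )
}

#' @export
print.double_trace <- function(x, ...) {
  lab <- x$graph$vertices[c(x$vertices, x$vertices[1])]
  cat(sprintf("double_trace on '%s' (%d steps): %s\n",
              x$graph$name, nrow(x$steps), paste(lab, collapse = "-")))
  invisible(x)
}

.min_rotation <- function(w) {
  m <- length(w)
  best <- w
  for (s in seq_len(m - 1)) {
    r <- c(w[(s + 1):m], w[1:s])
    for (k in seq_len(m)) {
      if (r[k] < best[k]) { best <- r; break }
      if (r[k] > best[k]) break
    }
  }
  best
}

# All vertex permutations preserving adjacency (brute force; built-in cages
# have at most 6 vertices).
.graph_automorphisms <- function(graph) {
  n <- length(graph$vertices)
  adj <- matrix(FALSE, n, n)
  adj[graph$edges] <- TRUE
  adj[graph$edges[, 2:1, drop = FALSE]] <- TRUE
  perms <- pracma::perms(seq_len(n))
  keep <- apply(perms, 1, function(p) identical(adj[p, p], adj))
  perms[keep, , drop = FALSE]
}

#' Enumerate closed double traces
#'
#' Depth-first enumeration of admissible closed double traces (every edge
#' covered exactly twice, no immediate reversal, cyclically). Each trace is
#' reported once per cyclic equivalence class, as its lexicographically
#' smallest rotation; traversal reversals count as distinct traces unless
#' `reduce_symmetry = TRUE`. The ordering is deterministic for a fixed vertex
#' labelling.
#'
#' @param graph A `polyhedral_graph`.
#' @param max_traces Stop after this many traces have been collected. When the
#'   limit is hit the result carries `attr(, "complete") = FALSE`, which
#'   distinguishes a truncated enumeration from "no admissible trace exists"
#'   (an empty, complete result).
#' @param reduce_symmetry If `TRUE`, traces equivalent under graph
#'   automorphisms and/or walk reversal are reported once. Off by default so
#'   that raw counts are reproducible.
#' @param prefix_filter Optional pluggable predicate, called with the integer
#'   vertex prefix of the growing walk; returning `FALSE` prunes that branch.
#'   This is the hook for stability or design constraints beyond plain double
#'   traceability.
#' @return List of `double_trace` objects with attribute `complete`.
#' @examples
#' tr <- enumerate_double_traces(build_polyhedron("tetrahedron"), max_traces = 5)
#' length(tr[[1]]$vertices)  # 12 = 2 x 6 edges
#' @export
enumerate_double_traces <- function(graph, max_traces = Inf,
                                    reduce_symmetry = FALSE,
                                    prefix_filter = NULL) {
  E <- n_edges(graph)
  m <- 2L * E
  # adjacency with edge ids
  nb <- vector("list", length(graph$vertices))
  for (e in seq_len(E)) {
    u <- graph$edges[e, 1]; v <- graph$edges[e, 2]
    nb[[u]] <- rbind(nb[[u]], c(v, e))
    nb[[v]] <- rbind(nb[[v]], c(u, e))
  }
  nb <- lapply(nb, function(x) x[order(x[, 1]), , drop = FALSE])
  deg <- vapply(nb, nrow, integer(1))

  out <- list()
  usage <- integer(E)
  walk <- integer(m)
  walk[1] <- 1L
  complete <- TRUE
  stopped <- FALSE

  rec <- function(pos) {
    if (stopped) return()
    cur <- walk[pos]
    if (pos == m) {
      # closing step back to vertex 1 must exist, be unused once more, and
      # introduce no cyclic reversal
      e <- .edge_index(graph, cur, 1L)
      if (is.na(e) || usage[e] >= 2L) return()
      # cyclic backtrack checks (reversal is only forbidden where the vertex
      # offers an alternative, i.e. degree >= 2; a degree-1 vertex must turn)
      if (deg[cur] > 1L && walk[pos - 1L] == 1L) return()
      if (deg[1L] > 1L && walk[2L] == cur) return()
      w <- walk
      # With a prefix filter the canonical rotation of an admissible trace may
      # itself be filtered out, so canonicity cannot be used for deduplication;
      # duplicates are removed after the search instead.
      if (is.null(prefix_filter) && !identical(w, .min_rotation(w))) return()
      if (length(out) >= max_traces) {
        # one more exists beyond the cap: mark truncated and unwind
        complete <<- FALSE
        stopped <<- TRUE
        return()
      }
      out[[length(out) + 1L]] <<- .trace_new(graph, w)
      return()
    }
    cand <- nb[[cur]]
    for (k in seq_len(nrow(cand))) {
      if (stopped) return()
      v <- cand[k, 1]; e <- cand[k, 2]
      if (usage[e] >= 2L) next
      if (pos > 1L && v == walk[pos - 1L] && deg[cur] > 1L) next  # reversal
      walk[pos + 1L] <<- v
      if (!is.null(prefix_filter) &&
          !isTRUE(prefix_filter(walk[seq_len(pos + 1L)]))) next
      usage[e] <<- usage[e] + 1L
      rec(pos + 1L)
      usage[e] <<- usage[e] - 1L
    }
  }
  rec(1L)

  if (!is.null(prefix_filter) && length(out) > 1) {
    key <- vapply(out, function(tr) paste(.min_rotation(tr$vertices),
                                          collapse = "."), character(1))
    out <- out[!duplicated(key)]
  }

  if (reduce_symmetry && length(out) > 1) {
    autos <- .graph_automorphisms(graph)
    key <- vapply(out, function(tr) {
      w <- tr$vertices
      cands <- character(0)
      for (i in seq_len(nrow(autos))) {
        p <- autos[i, ]
        for (ww in list(p[w], rev(p[w]))) {
          cands <- c(cands, paste(.min_rotation(ww), collapse = "."))
        }
      }
      min(cands)
    }, character(1))
    out <- out[!duplicated(key)]
  }
  attr(out, "complete") <- complete
  out
}

#' Validate a double trace
#'
#' Checks the defining invariants: consecutive steps share a vertex, every
#' edge of the graph appears exactly twice, length is `2 |E|`, and the walk is
#' non-backtracking (cyclically).
#'
#' @param trace A `double_trace`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_double_trace <- function(trace) {
  g <- trace$graph
  m <- nrow(trace$steps)
  if (m != 2L * n_edges(g)) stop("trace length must be 2|E|")
  if (any(trace$steps[-m, "to"] != trace$steps[-1, "from"]) ||
      trace$steps[m, "to"] != trace$steps[1, "from"]) {
    stop("consecutive steps must share a vertex")
  }
  if (anyNA(trace$edge_ids)) stop("step along a non-edge")
  cnt <- tabulate(trace$edge_ids, nbins = n_edges(g))
  if (any(cnt != 2L)) stop("every edge must appear exactly twice")
  # reversal at vertex w[i+1] is only illegal when that vertex has degree >= 2
  deg <- tabulate(as.vector(g$edges), nbins = length(g$vertices))
  w <- trace$vertices
  turn_vertex <- c(w[-1], w[1])
  nxt <- c(w[-(1:2)], w[1:2])
  bad <- nxt == w & deg[turn_vertex] > 1L
  if (any(bad)) stop("immediate edge reversal in trace")
  invisible(TRUE)
}

#' Classify edge orientations of a double trace
#'
#' An edge whose two traversals run in the same vertex direction forms a
#' parallel coiled-coil dimer; opposite directions form an antiparallel dimer.
#'
#' @param trace A `double_trace`.
#' @return Character vector (`"parallel"` / `"antiparallel"`), one entry per
#'   graph edge, named by the edge's vertex labels.
#' @export
classify_orientations <- function(trace) {
  g <- trace$graph
  E <- n_edges(g)
  cnt <- tabulate(trace$edge_ids, nbins = E)
  if (any(cnt != 2L)) stop("edge not traversed exactly twice")
  ori <- character(E)
  for (e in seq_len(E)) {
    hits <- which(trace$edge_ids == e)
    same <- trace$steps[hits[1], "from"] == trace$steps[hits[2], "from"]
    ori[e] <- if (same) "parallel" else "antiparallel"
  }
  names(ori) <- paste(g$vertices[g$edges[, 1]], g$vertices[g$edges[, 2]],
                      sep = "-")
  ori
}
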