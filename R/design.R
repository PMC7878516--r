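#' Design the single-chain trigonal bipyramid topology
#'
#' Reconstructs the bipyramidal cage chain topology from its stated design
#' constraints. The trigonal bipyramid graph (5 vertices, 9 edges) is traced
#' as a closed double trace restricted so that the chain decomposes into two
#' tetrahedral halves of nine segments each with pseudo-mirror symmetry: the
#' first nine steps cover one apex's tetrahedron (its three apex edges twice,
#' the three equatorial edges once) and the last nine the other. The three
#' equatorial (interface) edges are required to form parallel dimers, and the
#' second half must be the mirror image of the first under the apex-swapping
#' graph symmetry. Among the admissible traces the one whose seam-opened
#' single-chain permutation has the lowest topological contact order is
#' selected (ties broken by trace enumeration order).
#'
#' @param permutation Opening position of the selected closed trace (0-based
#'   step index, default 0 = the seam between the two halves, which keeps the
#'   two tetrahedral halves contiguous in sequence).
#' @param all_candidates If `TRUE`, return the full list of admissible traces
#'   instead of the selected topology.
#' @return A single-chain `chain_topology` with 18 segments (or a list of
#'   `double_trace` when `all_candidates = TRUE`).
#' @examples
#' topo <- design_bipyramid()
#' n_segments(topo)                  # 18
#' table(topo$orientations) / 2      # parallel and antiparallel dimer counts
#' @export
design_bipyramid <- function(permutation = 0, all_candidates = FALSE) {
  # vertex order puts the equatorial triangle first so the enumerator's start
  # vertex (index 1) lies on the seam between the two halves
  g <- build_polyhedron(
    rbind(c("A", "B"), c("B", "C"), c("A", "C"),
          c("U", "A"), c("U", "B"), c("U", "C"),
          c("W", "A"), c("W", "B"), c("W", "C")),
    name = "trigonal_bipyramid")
  vid <- stats::setNames(seq_along(g$vertices), g$vertices)
  u <- vid["U"]; w <- vid["W"]
  eq_edges <- which(apply(g$edges, 1, function(e) !(u %in% e) && !(w %in% e)))
  u_edges <- which(apply(g$edges, 1, function(e) u %in% e))
  w_edges <- which(apply(g$edges, 1, function(e) w %in% e))

  # multiplicity caps per half: apex edges twice, equatorial edges once
  cap_first <- integer(n_edges(g)); cap_second <- integer(n_edges(g))
  cap_first[u_edges] <- 2L; cap_first[eq_edges] <- 1L
  cap_second[w_edges] <- 2L; cap_second[eq_edges] <- 1L

  half_filter <- function(prefix) {
    k <- length(prefix) - 1L          # steps so far
    if (k < 1L) return(TRUE)
    eids <- .edge_index(g, prefix[-length(prefix)], prefix[-1])
    first <- eids[seq_len(min(k, 9L))]
    if (any(tabulate(first, n_edges(g)) > cap_first)) return(FALSE)
    if (k > 9L) {
      second <- eids[10:k]
      if (any(tabulate(second, n_edges(g)) > cap_second)) return(FALSE)
    }
    TRUE
  }

  traces <- enumerate_double_traces(g, prefix_filter = half_filter)

  # interface dimers must be parallel
  traces <- Filter(function(tr) {
    ori <- classify_orientations(tr)
    all(ori[eq_edges] == "parallel")
  }, traces)

  # pseudo-mirror symmetry: under some automorphism swapping the two apexes,
  # the edge sequence of the second half equals that of the first half,
  # either in the same or in reversed order
  autos <- .graph_automorphisms(g)
  swap <- autos[autos[, u] == w, , drop = FALSE]
  mirror_ok <- function(tr) {
    eids <- tr$edge_ids
    h1 <- eids[1:9]; h2 <- eids[10:18]
    for (i in seq_len(nrow(swap))) {
      p <- swap[i, ]
      mapped <- .edge_index(g,
                            p[tr$steps[1:9, "from"]],
                            p[tr$steps[1:9, "to"]])
      if (identical(unname(mapped), unname(h2)) ||
          identical(unname(rev(mapped)), unname(h2))) return(TRUE)
    }
    FALSE
  }
  traces <- Filter(mirror_ok, traces)
  if (length(traces) == 0) stop("no admissible bipyramid trace found")
  if (all_candidates) return(traces)

  score <- vapply(traces, function(tr) {
    tco(circular_permutations(tr)[[1]])$value
  }, numeric(1))
  # tie-break by antiparallel usage: orthogonal antiparallel modules are the
  # scarce resource in the dimer toolkit (they are homodimers), so designs
  # spend as few antiparallel edges as possible
  n_anti <- vapply(traces, function(tr) {
    sum(classify_orientations(tr) == "antiparallel")
  }, numeric(1))
  best <- traces[[order(score, n_anti)[1]]]
  perms <- circular_permutations(best)
  perms[[permutation + 1L]]
}

#' Pseudo-symmetric two-chain bipyramid designs
#'
#' Splits the single-chain bipyramid into two 9-segment tetrahedral subunits
#' (three parallel interface pairs) and chooses the circular permutation of
#' each subunit:
#' \describe{
#'   \item{`"interface"` (the b-style permutation)}{termini at the trigonal
#'     binding interface, so the unpaired interfacial segments are terminal
#'     and conformationally free.}
#'   \item{`"apex"` (the a-style permutation)}{each subunit re-opened at the
#'     vertex opposite the interface, so all interfacial segments are
#'     constrained in internal loops.}
#' }
#'
#' @param permutation `"interface"` or `"apex"`.
#' @return A two-chain `chain_topology` (9 + 9 segments).
#' @export
design_split_bipyramid <- function(permutation = c("interface", "apex")) {
  permutation <- match.arg(permutation)
  topo <- split_topology(design_bipyramid(), "symmetric_split")
  if (permutation == "apex") {
    ip <- interface_pairs(topo)
    iface_segs <- as.vector(ip)
    for (c_id in unique(chain_of(topo))) {
      segs <- topo$segments[chain_of(topo) == c_id, , drop = FALSE]
      iface_v <- unique(c(segs$from, segs$to)[
        rep(topo$segments$index[chain_of(topo) == c_id], 2) %in%
          c(iface_segs, iface_segs)])
      # the apex is the chain vertex that no interface edge touches
      iv <- topo$segments[intersect(which(chain_of(topo) == c_id),
                                    iface_segs), , drop = FALSE]
      apex <- setdiff(unique(c(segs$from, segs$to)),
                      unique(c(iv$from, iv$to)))
      if (length(apex) != 1) stop("could not identify the apex vertex")
      topo <- reopen_chain(topo, c_id, apex)
    }
  }
  topo
}
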