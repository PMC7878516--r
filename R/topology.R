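#' Chain topologies
#'
#' A chain topology is a double trace opened into one or more linear
#' polypeptide chains: an ordered sequence of coiled-coil-forming segment
#' slots, a pairing map (which two slots form each dimer), per-pair
#' orientations, and the chain-break positions splitting the slot sequence
#' into chains.
#'
#' @name chain_topology
NULL

.topology_new <- function(graph, segments, pairing, orientations,
                          chain_breaks = integer(0), termini_vertex = NA,
                          cleavage_sites = NULL) {
  n <- nrow(segments)
  stopifnot(length(pairing) == n, length(orientations) == n)
  structure(
    list(graph = graph,
         segments = segments,
         pairing = as.integer(pairing),
         orientations = orientations,
         chain_breaks = as.integer(chain_breaks),
         termini_vertex = termini_vertex,
         cleavage_sites = cleavage_sites),
    class = "chain_topology"
  )
}

#' @export
print.chain_topology <- function(x, ...) {
  sz <- chain_sizes(x)
  cat(sprintf(
    "chain_topology on '%s': %d segments, %d pairs, %d chain(s) [%s]\n",
    x$graph$name, n_segments(x), sum(!is.na(x$pairing)) / 2,
    length(sz), paste(sz, collapse = "+")))
  invisible(x)
}

#' Segment count of a topology
#' @param topology A `chain_topology`.
#' @return Integer.
#' @export
n_segments <- function(topology) nrow(topology$segments)

#' Chain membership and chain sizes
#'
#' @param topology A `chain_topology`.
#' @return `chain_of` returns an integer vector mapping each segment slot to
#'   its chain; `chain_sizes` the number of segments per chain.
#' @export
chain_of <- function(topology) {
  n <- n_segments(topology)
  findInterval(seq_len(n), c(1, topology$chain_breaks + 1))
}

#' @rdname chain_of
#' @export
chain_sizes <- function(topology) as.integer(table(chain_of(topology)))

#' Inter-chain (interface) pairs of a topology
#'
#' @param topology A `chain_topology`.
#' @return Two-column integer matrix of segment index pairs whose members lie
#'   on different chains.
#' @export
interface_pairs <- function(topology) {
  ch <- chain_of(topology)
  p <- topology$pairing
  idx <- which(!is.na(p) & seq_along(p) < p)
  cross <- idx[ch[idx] != ch[p[idx]]]
  cbind(i = cross, j = p[cross])
}

#' Open a closed double trace at every position
#'
#' Generates one single-chain topology per opening position of the closed
#' trace (the circular permutations scored during design). The opening
#' position is the step placed at the N-terminus, 0-based in the reported
#' `permutation` attribute; the vertex where the trace is opened becomes the
#' shared N/C-terminus vertex.
#'
#' @param trace A `double_trace`.
#' @return List of `chain_topology`, length `2 |E|`.
#' @export
circular_permutations <- function(trace) {
  validate_double_trace(trace)
  m <- nrow(trace$steps)
  ori_edge <- classify_orientations(trace)
  lapply(seq_len(m), function(s) {
    idx <- ((seq_len(m) + s - 2L) %% m) + 1L
    topo <- .topology_from_steps(trace$graph,
                                 trace$steps[idx, , drop = FALSE],
                                 trace$edge_ids[idx], ori_edge)
    topo$termini_vertex <- trace$graph$vertices[trace$steps[s, "from"]]
    attr(topo, "permutation") <- s - 1L
    topo
  })
}

.topology_from_steps <- function(graph, steps, edge_ids, ori_edge) {
  n <- nrow(steps)
  pairing <- integer(n)
  for (e in unique(edge_ids)) {
    hits <- which(edge_ids == e)
    pairing[hits[1]] <- hits[2]
    pairing[hits[2]] <- hits[1]
  }
  segments <- data.frame(
    index = seq_len(n),
    from = graph$vertices[steps[, "from"]],
    to = graph$vertices[steps[, "to"]],
    edge = names(ori_edge)[edge_ids],
    stringsAsFactors = FALSE
  )
  .topology_new(graph, segments, pairing,
                orientations = unname(ori_edge[edge_ids]))
}

#' Topological contact order
#'
#' TCO of a topology: the mean separation in the segment sequence between the
#' two members of each intra-chain coiled-coil pair, normalised by the total
#' number of segments. Lower values correspond to chains whose edge-forming
#' modules sit closer in the primary structure and are expected to fold more
#' efficiently. Inter-chain (interface) pairs have no intra-chain separation
#' and are excluded from the mean; their count is reported separately.
#'
#' @param topology A `chain_topology`.
#' @param strict Error on unpaired segments (default `TRUE`).
#' @return List with `value` (dimensionless), `per_pair` (raw intra-chain
#'   separations), `n_interface` (pairs excluded as inter-chain).
#' @examples
#' # a 2-segment hairpin has one pair at separation 1 -> TCO = 1/2
#' @export
tco <- function(topology, strict = TRUE) {
  p <- topology$pairing
  if (strict && (anyNA(p) || any(p == 0))) {
    stop("topology has unpaired segments")
  }
  ch <- chain_of(topology)
  idx <- which(!is.na(p) & p > 0 & seq_along(p) < p)
  intra <- idx[ch[idx] == ch[p[idx]]]
  per_pair <- abs(intra - p[intra])
  list(value = if (length(per_pair)) mean(per_pair) / n_segments(topology)
               else NA_real_,
       per_pair = as.numeric(per_pair),
       n_interface = length(idx) - length(intra))
}

#' Rank the circular permutations of a trace by TCO
#'
#' @param trace A `double_trace`.
#' @return Data frame with columns `permutation` (0-based opening position),
#'   `termini_vertex` and `tco`, ordered by increasing TCO with ties broken
#'   by permutation index.
#' @export
rank_permutations <- function(trace) {
  perms <- circular_permutations(trace)
  df <- data.frame(
    permutation = vapply(perms, function(t) attr(t, "permutation"), integer(1)),
    termini_vertex = vapply(perms, function(t) t$termini_vertex, character(1)),
    tco = vapply(perms, function(t) tco(t)$value, numeric(1))
  )
  df[order(df$tco, df$permutation), , drop = FALSE]
}

#' Split a single-chain topology into a multi-chain one
#'
#' Implements the three deconstruction strategies used for two-chain cage
#' variants:
#' \describe{
#'   \item{`trim_terminal`}{cut off the `k` C-terminal segments as a separate
#'     short chain (asymmetric split, e.g. 16 + 2).}
#'   \item{`symmetric_split`}{cut the chain where exactly three coiled-coil
#'     pairs become inter-chain, producing two pseudo-symmetric subunits that
#'     meet at a trigonal interface.}
#'   \item{`masked_switch`}{perform the symmetric split, then append to each
#'     subunit two terminal masking segments that occupy two of its three
#'     interface segments intramolecularly, leaving a single complementary
#'     interface edge exposed; a protease cleavage site is annotated between
#'     the 9th and 10th segments of each chain so the masks can be trimmed
#'     off.}
#' }
#'
#' @param topology Single-chain `chain_topology`.
#' @param mode One of `"trim_terminal"`, `"symmetric_split"`,
#'   `"masked_switch"`.
#' @param k Number of C-terminal segments to trim (`trim_terminal`).
#' @param at Cut position for `symmetric_split` (break after this segment);
#'   by default the admissible cut is searched automatically.
#' @param n_interface Required number of inter-chain pairs for the symmetric
#'   split (default 3, a trigonal interface).
#' @return A multi-chain `chain_topology`.
#' @export
split_topology <- function(topology,
                           mode = c("trim_terminal", "symmetric_split",
                                    "masked_switch"),
                           k = 2, at = NULL, n_interface = 3) {
  mode <- match.arg(mode)
  if (length(topology$chain_breaks) != 0) {
    stop("split_topology expects a single-chain topology")
  }
  n <- n_segments(topology)
  if (mode == "trim_terminal") {
    if (k < 1 || k >= n) stop("k out of range")
    cut <- n - k
    topo <- topology
    topo$chain_breaks <- cut
    return(topo)
  }
  if (mode == "symmetric_split") {
    cuts <- if (is.null(at)) seq_len(n - 1) else at
    ok <- cuts[vapply(cuts, function(cc) {
      p <- topology$pairing
      sum(p[seq_len(cc)] > cc) == n_interface
    }, logical(1))]
    if (length(ok) == 0) {
      stop("no cut position leaves exactly ", n_interface,
           " inter-chain pairs")
    }
    # prefer an even split, then the earliest cut
    ok <- ok[order(abs(ok - n / 2), ok)]
    topo <- topology
    topo$chain_breaks <- ok[1]
    return(topo)
  }
  # masked_switch
  sym <- split_topology(topology, "symmetric_split", n_interface = n_interface)
  cut <- sym$chain_breaks
  ip <- interface_pairs(sym)
  if (nrow(ip) != n_interface) stop("unexpected interface structure")
  # exposed edge: the interface pair whose chain-1 member is most C-terminal
  exposed <- ip[which.max(ip[, "i"]), ]
  masked <- ip[setdiff(seq_len(nrow(ip)), which.max(ip[, "i"])), , drop = FALSE]
  n1 <- cut; n2 <- n - cut; nm <- nrow(masked)

  old <- sym$segments
  # new global order: chain1 segments, chain1 masks, chain2 segments, chain2 masks
  map <- integer(n)                      # old index -> new index
  map[seq_len(n1)] <- seq_len(n1)
  map[(n1 + 1):n] <- n1 + nm + seq_len(n2)
  seg_row <- function(old_i, tag) {
    r <- old[old_i, , drop = FALSE]
    r$edge <- paste0(r$edge, tag)
    r
  }
  segs <- rbind(
    old[seq_len(n1), , drop = FALSE],
    do.call(rbind, lapply(rev(masked[, "j"]), seg_row, tag = "*")),
    old[(n1 + 1):n, , drop = FALSE],
    do.call(rbind, lapply(rev(masked[, "i"]), seg_row, tag = "*"))
  )
  ntot <- nrow(segs)
  segs$index <- seq_len(ntot)
  rownames(segs) <- NULL

  pairing <- integer(ntot)
  ori <- character(ntot)
  # intra-subunit pairs keep their partners
  for (i in seq_len(n)) {
    j <- sym$pairing[i]
    pairing[map[i]] <- map[j]
    ori[map[i]] <- sym$orientations[i]
  }
  # masks copy the orientation of the edge they occupy (parallel interface)
  mask1 <- n1 + seq_len(nm)                  # mask slots on chain 1
  mask2 <- n1 + nm + n2 + seq_len(nm)        # mask slots on chain 2
  for (t in seq_len(nm)) {
    i <- masked[nm + 1 - t, "i"]; j <- masked[nm + 1 - t, "j"]
    # chain-1 mask binds the chain-1 interface segment i
    pairing[map[i]] <- mask1[t]; pairing[mask1[t]] <- map[i]
    ori[mask1[t]] <- sym$orientations[i]
    # chain-2 mask binds the chain-2 interface segment j
    pairing[map[j]] <- mask2[t]; pairing[mask2[t]] <- map[j]
    ori[mask2[t]] <- sym$orientations[j]
  }
  # exposed pair stays inter-chain
  pairing[map[exposed["i"]]] <- map[exposed["j"]]
  pairing[map[exposed["j"]]] <- map[exposed["i"]]

  cleave_at <- n1  # between the n1-th and (n1+1)-th segment of each chain
  .topology_new(sym$graph, segs, pairing, ori,
                chain_breaks = n1 + nm,
                termini_vertex = sym$termini_vertex,
                cleavage_sites = data.frame(
                  chain = c(1L, 2L),
                  after_segment = c(cleave_at, cleave_at)))
}

#' Re-open one chain of a multi-chain topology at a different vertex
#'
#' A chain whose segment walk is closed (it starts and ends at the same
#' vertex) can be opened at any vertex it visits; this chooses the circular
#' permutation of that subunit and therefore the location of its termini.
#'
#' @param topology A `chain_topology`.
#' @param chain Chain index to re-open.
#' @param at_vertex Vertex label where the new termini should sit.
#' @return A `chain_topology` with the chain's segments rotated and the
#'   pairing map remapped accordingly.
#' @export
reopen_chain <- function(topology, chain, at_vertex) {
  ch <- chain_of(topology)
  idx <- which(ch == chain)
  segs <- topology$segments[idx, , drop = FALSE]
  if (segs$from[1] != segs$to[nrow(segs)]) {
    stop("chain walk is not closed; it cannot be re-opened")
  }
  hits <- which(segs$from == at_vertex)
  if (!length(hits)) stop("chain does not visit vertex ", at_vertex)
  r <- hits[1]
  if (r > 1) {
    rot <- c(r:nrow(segs), 1:(r - 1))
    perm <- seq_len(n_segments(topology))
    perm[idx] <- idx[rot]              # new global order
    inv <- match(seq_along(perm), perm)
    topology$segments <- topology$segments[perm, , drop = FALSE]
    topology$segments$index <- seq_along(perm)
    rownames(topology$segments) <- NULL
    topology$pairing <- inv[topology$pairing[perm]]
    topology$orientations <- topology$orientations[perm]
  }
  topology
}

#' Merge all chains of a topology back into one
#'
#' Inverse of a split at the break positions: removes all chain breaks and
#' returns the single-chain topology with the identical pairing map.
#'
#' @param topology A `chain_topology`.
#' @return Single-chain `chain_topology`.
#' @export
merge_chains <- function(topology) {
  topology$chain_breaks <- integer(0)
  topology
}

#' Topology JSON round trip
#'
#' @param topology A `chain_topology`.
#' @param path File path.
#' @return `write_topology_json` returns `path` invisibly;
#'   `read_topology_json` a `chain_topology`.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    graph = list(
      name = topology$graph$name,
      vertices = topology$graph$vertices,
      edges = lapply(seq_len(nrow(topology$graph$edges)), function(i) {
        topology$graph$vertices[topology$graph$edges[i, ]]
      })
    ),
    segments = topology$segments,
    pairing = topology$pairing,
    orientations = topology$orientations,
    chain_breaks = topology$chain_breaks,
    termini_vertex = topology$termini_vertex,
    cleavage_sites = topology$cleavage_sites
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$graph$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  g <- build_polyhedron(edges, name = obj$graph$name)
  if (setequal(obj$graph$vertices, g$vertices)) {
    idx <- match(g$vertices, obj$graph$vertices)
    ord <- order(idx)
    new_vertices <- g$vertices[ord]
    g$edges <- matrix(match(g$vertices, new_vertices)[g$edges], ncol = 2)
    g$vertices <- new_vertices
  }
  cs <- obj$cleavage_sites
  if (!is.null(cs) && length(cs) == 0) cs <- NULL
  .topology_new(g, as.data.frame(obj$segments), obj$pairing,
                obj$orientations,
                chain_breaks = if (length(obj$chain_breaks)) obj$chain_breaks
                               else integer(0),
                termini_vertex = obj$termini_vertex,
                cleavage_sites = cs)
}

#' Export a TCO ranking table as TSV
#'
#' @param ranking Data frame from [rank_permutations()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tco_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
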