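#' Assign coiled-coil pairs to the edges of a topology
#'
#' Finds an orthogonality-respecting mapping from the topology's edges to CC
#' pairs in a library. Each edge receives one pair whose orientation matches
#' the edge's dimer orientation; the two segment slots traversing the edge
#' receive the pair's complementary roles (`a` for the first traversal, `b`
#' for the second). Within each folding scope no orthogonality group may be
#' used twice (cross-talking peptides would mis-pair), while different scopes
#' may reuse the same modules — this is what lets a pseudo-symmetric design
#' mirror one module set in its two independently folding halves.
#'
#' @param topology A `chain_topology`.
#' @param library A `cc_library`.
#' @param policy List of options:
#'   \describe{
#'     \item{`scopes`}{integer vector, one folding-scope id per segment slot.
#'       Defaults to the chain index, i.e. each chain folds independently.
#'       Edges whose slots span two scopes (interface edges) count against
#'       both.}
#'     \item{`interface_variant`}{preferred toolkit variant (e.g. `"SH"`) for
#'       inter-scope edges; intra-scope edges prefer `"SN"`. `NULL` disables
#'       the preference.}
#'   }
#' @return A `segment_assignment`: list with `table` (data frame: segment,
#'   edge, pair, role, sequence), `edges` (edge-level data frame) and the
#'   policy used.
#' @export
assign_segments <- function(topology, library, policy = list()) {
  n <- n_segments(topology)
  scopes <- policy$scopes
  if (is.null(scopes)) scopes <- chain_of(topology)
  if (length(scopes) != n) stop("policy$scopes must have one entry per segment")
  pref_variant <- policy$interface_variant

  p <- topology$pairing
  idx <- which(!is.na(p) & p > 0 & seq_along(p) < p)
  edges <- data.frame(
    i = idx, j = p[idx],
    edge = topology$segments$edge[idx],
    orientation = topology$orientations[idx],
    stringsAsFactors = FALSE
  )
  edges$scope_i <- scopes[edges$i]
  edges$scope_j <- scopes[edges$j]
  ne <- nrow(edges)

  # candidate libraries per edge, deterministic preference order
  cand <- lapply(seq_len(ne), function(k) {
    ok <- which(library$orientation == edges$orientation[k])
    if (!is.null(pref_variant)) {
      inter <- edges$scope_i[k] != edges$scope_j[k]
      want <- if (inter) pref_variant else "SN"
      ok <- ok[order(library$variant[ok] != want, ok)]
    }
    ok
  })

  # most-constrained-first ordering keeps backtracking shallow
  ord <- order(vapply(cand, length, integer(1)))
  used <- list()   # scope id -> character vector of groups in use
  assign_vec <- integer(ne)

  try_edge <- function(t) {
    if (t > ne) return(TRUE)
    k <- ord[t]
    sc <- unique(c(edges$scope_i[k], edges$scope_j[k]))
    for (li in cand[[k]]) {
      grp <- library$group[li]
      conflict <- any(vapply(sc, function(s) {
        grp %in% used[[as.character(s)]]
      }, logical(1)))
      if (conflict) next
      assign_vec[k] <<- li
      for (s in sc) {
        used[[as.character(s)]] <<- c(used[[as.character(s)]], grp)
      }
      if (try_edge(t + 1)) return(TRUE)
      for (s in sc) {
        u <- used[[as.character(s)]]
        used[[as.character(s)]] <<- u[-length(u)]
      }
      assign_vec[k] <<- 0L
    }
    FALSE
  }
  if (!try_edge(1)) {
    stop("infeasible assignment: not enough orthogonal pairs of the ",
         "required orientations for the given scopes")
  }

  edges$pair <- library$name[assign_vec]
  edges$variant <- library$variant[assign_vec]
  tab <- data.frame(
    segment = c(edges$i, edges$j),
    edge = c(edges$edge, edges$edge),
    pair = c(edges$pair, edges$pair),
    role = rep(c("a", "b"), each = ne),
    sequence = c(library$seq_a[assign_vec], library$seq_b[assign_vec]),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$segment), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, edges = edges, policy = policy,
                 scopes = scopes),
            class = "segment_assignment")
}

#' @export
print.segment_assignment <- function(x, ...) {
  cat(sprintf("segment_assignment: %d segments, %d edges, %d scope(s)\n",
              nrow(x$table), nrow(x$edges), length(unique(x$scopes))))
  invisible(x)
}
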