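# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with different algorithms than the package code.

# All closed double traces of a graph by exhaustive walk search: start from
# every vertex, take every admissible step, keep closed walks covering each
# edge twice with no immediate reversal (cyclically; degree-1 vertices are
# allowed to turn back), and canonicalise by the lexicographically smallest
# rotation of the vertex sequence.
oracle_double_traces <- function(graph) {
  E <- nrow(graph$edges)
  m <- 2L * E
  nv <- length(graph$vertices)
  adj <- matrix(FALSE, nv, nv)
  adj[graph$edges] <- TRUE
  adj[graph$edges[, 2:1, drop = FALSE]] <- TRUE
  deg <- rowSums(adj)
  ekey <- function(u, v) paste(pmin(u, v), pmax(u, v))
  all_keys <- ekey(graph$edges[, 1], graph$edges[, 2])

  found <- character(0)
  walks <- list()
  grow <- function(path, used) {
    k <- length(path)
    if (k == m + 1) {
      if (path[1] != path[m + 1]) return(invisible(NULL))
      cnt <- table(factor(used, levels = all_keys))
      if (any(cnt != 2)) return(invisible(NULL))
      w <- path[1:m]
      # cyclic no-backtrack check
      nxt2 <- c(w[-(1:2)], w[1:2])
      turn <- c(w[-1], w[1])
      if (any(nxt2 == w & deg[turn] > 1)) return(invisible(NULL))
      canon <- paste(min_rotation_chr(w), collapse = ".")
      if (!(canon %in% found)) {
        found <<- c(found, canon)
        walks[[length(walks) + 1]] <<- w
      }
      return(invisible(NULL))
    }
    cur <- path[k]
    for (v in seq_len(nv)) {
      if (!adj[cur, v]) next
      if (k >= 2 && v == path[k - 1] && deg[cur] > 1) next
      key <- ekey(cur, v)
      if (sum(used == key) >= 2) next
      grow(c(path, v), c(used, key))
    }
  }
  for (s in seq_len(nv)) grow(s, character(0))
  walks
}

min_rotation_chr <- function(w) {
  m <- length(w)
  rots <- vapply(seq_len(m), function(s) {
    paste(c(w[s:m], w[seq_len(s - 1)]), collapse = ",")
  }, character(1))
  as.integer(strsplit(sort(rots)[1], ",")[[1]])
}

trace_canon <- function(trace) {
  paste(min_rotation_chr(trace$vertices), collapse = ".")
}

# exhaustive search deciding whether an orthogonality-respecting assignment
# exists (used to cross-check assign_segments feasibility)
oracle_assignment_feasible <- function(topology, library, scopes) {
  p <- topology$pairing
  idx <- which(!is.na(p) & p > 0 & seq_along(p) < p)
  ori <- topology$orientations[idx]
  sc <- cbind(scopes[idx], scopes[p[idx]])
  ne <- length(idx)
  rec <- function(k, used) {
    if (k > ne) return(TRUE)
    for (li in seq_len(nrow(library))) {
      if (library$orientation[li] != ori[k]) next
      grp <- library$group[li]
      scopes_k <- unique(sc[k, ])
      if (any(paste(scopes_k, grp) %in% used)) next
      if (rec(k + 1, c(used, paste(scopes_k, grp)))) return(TRUE)
    }
    FALSE
  }
  rec(1, character(0))
}

# a deterministic small random-positive profile pair on a shared grid
random_positive_profiles <- function(seed) {
  set.seed(seed)
  q <- seq(0.12, 1.8, by = 0.01)
  mk <- function() {
    base <- exp(-q * runif(1, 0.5, 2)) * runif(1, 1, 10) +
      runif(1, 0.05, 0.2)
    saxs_profile(q, base * exp(rnorm(length(q), 0, 0.03)),
                 sigma = 0.02 * base)
  }
  list(a = mk(), b = mk())
}

# fast, low-quality build parameters for tests that only exercise the
# mechanics (determinism, schemas); quality assertions use defaults
light_params <- function(...) {
  build_params(moves_per_temp = 10, n_temps = 5, polish_sweeps = 40, ...)
}

bipyramid_assignment <- function(topo = design_bipyramid()) {
  assign_segments(topo, cc_fixture_library(),
                  policy = list(scopes = rep(1:2, each = 9)))
}
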