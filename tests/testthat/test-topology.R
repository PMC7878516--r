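test_that("built-in polyhedra have the expected sizes and validation catches bad graphs", {
  expect_equal(length(build_polyhedron("tetrahedron")$vertices), 4)
  expect_equal(n_edges(build_polyhedron("tetrahedron")), 6)
  g <- build_polyhedron("trigonal_bipyramid")
  expect_equal(length(g$vertices), 5)
  expect_equal(n_edges(g), 9)
  expect_equal(n_edges(build_polyhedron("square_pyramid")), 8)
  expect_equal(n_edges(build_polyhedron("octahedron")), 12)
  expect_equal(n_edges(build_polyhedron("trigonal_prism")), 9)

  expect_error(build_polyhedron(rbind(c("a", "b"), c("b", "a"))),
               "duplicate")
  expect_error(build_polyhedron(rbind(c("a", "a"))), "self-loop")
  expect_error(build_polyhedron(rbind(c("a", "b"), c("c", "d"))),
               "connected")
})

test_that("graph JSON round-trips", {
  g <- build_polyhedron("trigonal_bipyramid")
  path <- withr::local_tempfile(fileext = ".json")
  write_polyhedron_json(g, path)
  g2 <- read_polyhedron_json(path)
  expect_setequal(g2$vertices, g$vertices)
  expect_equal(n_edges(g2), n_edges(g))
  key <- function(gg) sort(apply(matrix(gg$vertices[gg$edges], ncol = 2), 1,
                                 function(r) paste(sort(r), collapse = "-")))
  expect_equal(key(g2), key(g))
})

test_that("double-trace enumeration matches brute-force walk search on small graphs", {
  graphs <- list(
    single_edge = rbind(c("u", "v")),
    path2 = rbind(c("u", "v"), c("v", "w")),
    triangle = rbind(c("a", "b"), c("b", "c"), c("a", "c")),
    star3 = rbind(c("c", "x"), c("c", "y"), c("c", "z")),
    triangle_pendant = rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                             c("c", "d"))
  )
  for (nm in names(graphs)) {
    g <- build_polyhedron(graphs[[nm]], name = nm)
    got <- enumerate_double_traces(g)
    want <- oracle_double_traces(g)
    expect_true(attr(got, "complete"), info = nm)
    got_keys <- sort(vapply(got, trace_canon, character(1)))
    want_keys <- sort(vapply(want, function(w) {
      paste(min_rotation_chr(w), collapse = ".")
    }, character(1)))
    expect_equal(got_keys, want_keys, info = nm)
  }
})

test_that("a single edge has exactly one closed double trace with 2 segments", {
  tr <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]$steps), 2)
  expect_equal(unname(classify_orientations(tr[[1]])), "antiparallel")
})

test_that("every enumerated trace satisfies the double-trace invariants", {
  for (name in c("tetrahedron", "square_pyramid")) {
    g <- build_polyhedron(name)
    traces <- enumerate_double_traces(g, max_traces = 25)
    expect_gt(length(traces), 0)
    for (tr in traces) {
      expect_silent(validate_double_trace(tr))
      expect_equal(nrow(tr$steps), 2 * n_edges(g))
      ori <- classify_orientations(tr)
      expect_equal(sum(ori == "parallel") + sum(ori == "antiparallel"),
                   n_edges(g))
    }
  }
})

test_that("the enumeration cap is reported distinctly from an exhausted search", {
  g <- build_polyhedron("tetrahedron")
  capped <- enumerate_double_traces(g, max_traces = 3)
  expect_length(capped, 3)
  expect_false(attr(capped, "complete"))
  all_of_them <- enumerate_double_traces(g)
  expect_true(attr(all_of_them, "complete"))
  expect_gt(length(all_of_them), 3)
})

test_that("orientation classification follows traversal directions", {
  g <- build_polyhedron(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  traces <- enumerate_double_traces(g)
  # the double cycle a-b-c-a-b-c traverses every edge twice the same way
  keys <- vapply(traces, trace_canon, character(1))
  double_cycle <- traces[[which(keys == "1.2.3.1.2.3")]]
  expect_true(all(classify_orientations(double_cycle) == "parallel"))
})

test_that("circular permutations open a closed trace at every step", {
  tr1 <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))[[1]]
  expect_length(circular_permutations(tr1), 2)

  g <- build_polyhedron(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  tr <- enumerate_double_traces(g)[[1]]
  perms <- circular_permutations(tr)
  expect_length(perms, 2 * n_edges(g))
  # distinct rotations of the step sequence, counted independently
  seqs <- vapply(perms, function(p) {
    paste(p$segments$from, p$segments$to, collapse = ";")
  }, character(1))
  w <- tr$vertices
  want <- vapply(seq_along(w), function(s) {
    ww <- c(w[s:length(w)], w[seq_len(s - 1)])
    paste(tr$graph$vertices[ww], tr$graph$vertices[c(ww[-1], ww[1])],
          collapse = ";")
  }, character(1))
  expect_setequal(seqs, want)
})

test_that("TCO matches its definition and is invariant under reversal and relabeling", {
  # 2-segment hairpin: single pair at separation 1
  tr <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))[[1]]
  hairpin <- circular_permutations(tr)[[1]]
  sc <- tco(hairpin)
  expect_equal(sc$per_pair, 1)
  expect_equal(sc$value, 1 / 2)

  topo <- design_bipyramid()
  # reversal: flip the segment order and remap the pairing
  n <- n_segments(topo)
  rev_topo <- topo
  rev_idx <- rev(seq_len(n))
  rev_topo$segments <- topo$segments[rev_idx, ]
  rev_topo$pairing <- (n + 1L) - topo$pairing[rev_idx]
  rev_topo$orientations <- topo$orientations[rev_idx]
  expect_equal(tco(rev_topo)$value, tco(topo)$value)

  # relabeling vertices leaves the score untouched (it only uses indices)
  relab <- topo
  relab$segments$from <- chartr("UWABC", "ZYXWV", relab$segments$from)
  relab$segments$to <- chartr("UWABC", "ZYXWV", relab$segments$to)
  expect_equal(tco(relab)$value, tco(topo)$value)

  # ranking agrees with an independent recomputation of the mean separation
  trace <- design_bipyramid(all_candidates = TRUE)[[1]]
  ranking <- rank_permutations(trace)
  recompute <- vapply(circular_permutations(trace), function(p) {
    pr <- p$pairing
    seps <- abs(which(seq_along(pr) < pr) - pr[seq_along(pr) < pr])
    mean(seps) / n_segments(p)
  }, numeric(1))
  expect_equal(ranking$tco, sort(recompute)[seq_len(nrow(ranking))])
})

test_that("splits produce the documented chain structures", {
  topo <- design_bipyramid()

  trim <- split_topology(topo, "trim_terminal", k = 2)
  expect_setequal(chain_sizes(trim), c(16, 2))

  sym <- split_topology(topo, "symmetric_split")
  expect_equal(chain_sizes(sym), c(9, 9))
  expect_equal(nrow(interface_pairs(sym)), 3)
  expect_true(all(sym$orientations[interface_pairs(sym)] == "parallel"))

  # re-merging restores the original single-chain pairing exactly
  expect_identical(merge_chains(sym)$pairing, topo$pairing)

  masked <- split_topology(topo, "masked_switch")
  expect_equal(chain_sizes(masked), c(11, 11))
  expect_equal(masked$cleavage_sites$after_segment, c(9, 9))
  # exactly one inter-chain (exposed) pair remains before proteolysis
  expect_equal(nrow(interface_pairs(masked)), 1)
  # pairing is an involution without fixed points
  p <- masked$pairing
  expect_true(all(p[p] == seq_along(p)))
  expect_true(all(p != seq_along(p)))
})

test_that("topology JSON round-trips including splits", {
  topo <- split_topology(design_bipyramid(), "masked_switch")
  path <- withr::local_tempfile(fileext = ".json")
  write_topology_json(topo, path)
  topo2 <- read_topology_json(path)
  expect_equal(topo2$pairing, topo$pairing)
  expect_equal(topo2$orientations, topo$orientations)
  expect_equal(topo2$chain_breaks, topo$chain_breaks)
  expect_equal(topo2$segments$edge, topo$segments$edge)
  expect_equal(topo2$cleavage_sites$after_segment,
               topo$cleavage_sites$after_segment)
})

test_that("reopening a chain moves its termini without changing the pairing structure", {
  sym <- design_split_bipyramid("interface")
  apex <- design_split_bipyramid("apex")
  expect_equal(chain_sizes(apex), chain_sizes(sym))
  expect_equal(nrow(interface_pairs(apex)), 3)
  # chain 1 of the apex permutation starts and ends at the same apex vertex
  segs <- apex$segments[chain_of(apex) == 1, ]
  expect_equal(segs$from[1], segs$to[nrow(segs)])
  iface <- interface_pairs(apex)
  iv <- apex$segments[iface[, "i"], ]
  expect_false(segs$from[1] %in% c(iv$from, iv$to))
})
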