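test_that("the packaged CC library loads, validates and round-trips", {
  lib <- cc_fixture_library()
  expect_s3_class(lib, "cc_library")
  expect_true(all(c("name", "seq_a", "seq_b", "orientation", "group",
                    "variant", "homodimer") %in% names(lib)))
  # the toolkit names referenced by the cage designs are all present
  for (pep in c("P4SN", "P6SN", "P5SH", "P6SH", "P10SH", "BCRSH", "BCR",
                "P7SH")) {
    expect_true(any(grepl(pep, lib$name)), info = pep)
  }
  expect_true(all(lib$homodimer == (lib$seq_a == lib$seq_b)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cc_library(lib, path)
  lib2 <- load_cc_library(path)
  expect_equal(lib2, lib, ignore_attr = TRUE)

  bad <- lib
  bad$seq_a[2] <- "ACDEFGX1"
  badpath <- withr::local_tempfile(fileext = ".tsv")
  write_cc_library(bad, badpath)
  expect_error(load_cc_library(badpath), "non-amino-acid")
})

test_that("assignment respects orientation, complementary roles and orthogonality scopes", {
  lib <- cc_fixture_library()
  topo <- design_bipyramid()
  asg <- assign_segments(topo, lib,
                         policy = list(scopes = rep(1:2, each = 9)))
  # every edge gets a pair whose orientation matches the topology
  expect_true(all(asg$edges$orientation ==
                    lib$orientation[match(asg$edges$pair, lib$name)]))
  # paired segments carry complementary roles of the same pair
  tab <- asg$table
  p <- topo$pairing
  for (i in seq_len(n_segments(topo))) {
    expect_equal(tab$pair[tab$segment == i], tab$pair[tab$segment == p[i]])
    expect_false(tab$role[tab$segment == i] == tab$role[tab$segment == p[i]])
  }
  # within one scope no orthogonality group repeats
  for (s in 1:2) {
    touch <- asg$edges$scope_i == s | asg$edges$scope_j == s
    grp <- lib$group[match(asg$edges$pair[touch], lib$name)]
    expect_false(anyDuplicated(grp) > 0)
  }
  # the two halves reuse the same intra-half module multiset (mirrored)
  intra1 <- sort(asg$edges$pair[asg$edges$scope_i == 1 &
                                  asg$edges$scope_j == 1])
  intra2 <- sort(asg$edges$pair[asg$edges$scope_i == 2 &
                                  asg$edges$scope_j == 2])
  expect_equal(intra1, intra2)
  # the trigonal interface is three distinct parallel heterodimers
  iface <- asg$edges[asg$edges$scope_i != asg$edges$scope_j, ]
  expect_equal(nrow(iface), 3)
  expect_true(all(iface$orientation == "parallel"))
  expect_false(any(lib$homodimer[match(iface$pair, lib$name)]))
})

test_that("interface variant substitution swaps SN modules for SH at the interface", {
  lib <- cc_fixture_library()
  topo <- design_split_bipyramid("interface")
  asg <- assign_segments(topo, lib, policy = list(interface_variant = "SH"))
  iface <- asg$edges[asg$edges$scope_i != asg$edges$scope_j, ]
  expect_true(all(iface$variant == "SH"))
  intra <- asg$edges[asg$edges$scope_i == asg$edges$scope_j, ]
  expect_true(all(intra$variant == "SN"))
})

test_that("a homodimer-only library assigns the same sequence to both hairpin segments", {
  tr <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))[[1]]
  topo <- circular_permutations(tr)[[1]]
  lib <- cc_fixture_library()
  homo <- lib[lib$homodimer & lib$orientation == "antiparallel", ][1, ]
  class(homo) <- class(lib)
  asg <- assign_segments(topo, homo)
  expect_equal(asg$table$sequence[1], asg$table$sequence[2])
})

test_that("assignment feasibility agrees with an exhaustive search on small topologies", {
  lib <- cc_fixture_library()
  tr3 <- enumerate_double_traces(
    build_polyhedron(rbind(c("a", "b"), c("b", "c"), c("a", "c"))))
  for (tr in tr3) {
    for (perm in circular_permutations(tr)[c(1, 3)]) {
      for (libsub in list(lib[1:2, ], lib[lib$orientation == "parallel", ][1:3, ],
                          lib[lib$orientation == "antiparallel", ])) {
        class(libsub) <- class(lib)
        scopes <- chain_of(perm)
        feasible <- oracle_assignment_feasible(perm, libsub, scopes)
        got <- tryCatch({
          assign_segments(perm, libsub)
          TRUE
        }, error = function(e) FALSE)
        expect_equal(got, feasible)
      }
    }
  }
})

test_that("infeasible assignments report the violated constraint", {
  topo <- design_bipyramid()
  lib <- cc_fixture_library()[1:3, ]   # too few orthogonal pairs
  class(lib) <- c("cc_library", "data.frame")
  expect_error(assign_segments(topo, lib), "orthogonal")
})

test_that("sequence assembly tiles chains with consistent annotations", {
  topo <- design_bipyramid()
  asg <- bipyramid_assignment(topo)
  seqs <- assemble_sequence(asg, topo, n_tag = "MHHHHHHGS")
  expect_length(seqs, 1)
  s <- seqs[[1]]
  ann <- s$annotations
  # intervals tile the sequence without overlap
  expect_equal(ann$start[1], 1)
  expect_equal(ann$end[nrow(ann)], nchar(s$residues))
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)] + 1))
  # extracting segment intervals returns the library sequences verbatim
  segs <- extract_intervals(s, "segment")
  expect_length(segs, 18)
  expect_equal(unname(segs),
               asg$table$sequence[order(asg$table$segment)])
})

test_that("a two-segment chain with no linkers is the plain concatenation", {
  tr <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))[[1]]
  topo <- circular_permutations(tr)[[1]]
  lib <- cc_fixture_library()
  homo <- lib[lib$homodimer & lib$orientation == "antiparallel", ][1, ]
  class(homo) <- class(lib)
  asg <- assign_segments(topo, homo)
  seqs <- assemble_sequence(asg, topo, linker = "")
  expect_equal(seqs[[1]]$residues, paste0(homo$seq_a, homo$seq_a))
})

test_that("molecular weight matches residue tables, additivity and an independent oracle", {
  expect_equal(molecular_weight("G"), 0.0750672, tolerance = 1e-6)
  expect_equal(molecular_weight("GG"), 0.1321191, tolerance = 1e-6)
  expect_error(molecular_weight("GZX"), "unknown residue")
  set.seed(42)
  for (k in 1:5) {
    aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                       replace = TRUE), collapse = "")
    bb <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 25,
                       replace = TRUE), collapse = "")
    # additivity: fusing two peptides releases one water
    expect_equal(molecular_weight(paste0(aa, bb)),
                 molecular_weight(aa) + molecular_weight(bb) - 0.0180153,
                 tolerance = 1e-9)
    # independent oracle: seqinr's protein molecular weight
    expect_equal(molecular_weight(aa) * 1000,
                 seqinr::pmw(strsplit(aa, "")[[1]]),
                 tolerance = 1e-3)
  }
})

test_that("TEV cleavage cuts after Gln of ENLYFQ(G|S) and conserves residues", {
  topo <- split_topology(design_bipyramid(), "masked_switch")
  asg <- assign_segments(topo, cc_fixture_library(),
                         policy = list(interface_variant = "SH"))
  seqs <- assemble_sequence(asg, topo)
  for (s in seqs) {
    # the cleavage annotation sits between the 9th and 10th segments
    ann <- s$annotations
    segs <- which(ann$type == "segment")
    cleave <- which(ann$type == "cleavage")
    expect_length(cleave, 1)
    expect_true(cleave > segs[9] && cleave < segs[10])

    frags <- tev_cleave(s)
    expect_length(frags, 2)
    expect_equal(sum(nchar(vapply(frags, function(f) f$residues,
                                  character(1)))),
                 nchar(s$residues))
    # mass conservation: fragments gain one water per cut
    expect_equal(sum(vapply(frags, molecular_weight, numeric(1))),
                 molecular_weight(s) + 0.0180153, tolerance = 1e-9)
    # the N-terminal fragment ends on the recognition Gln
    expect_match(frags[[1]]$residues, "ENLYFQ$")
  }
  # no annotated site: identity
  plain <- structure(list(chain_id = "x", residues = "MAAAG",
                          annotations = data.frame(
                            start = 1L, end = 5L, type = "segment",
                            label = "seg", stringsAsFactors = FALSE)),
                     class = "annotated_sequence")
  expect_identical(tev_cleave(plain)[[1]], plain)
  # annotation that does not sit on a recognition site errors
  lying <- plain
  lying$annotations$type <- "cleavage"
  expect_error(tev_cleave(lying), "recognition")
})

test_that("FASTA round trip preserves chains", {
  topo <- design_split_bipyramid("interface")
  asg <- assign_segments(topo, cc_fixture_library(),
                         policy = list(interface_variant = "SH"))
  seqs <- assemble_sequence(asg, topo)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_chains_fasta(seqs, path)
  back <- read_fasta_sequences(path)
  expect_equal(unname(back),
               vapply(seqs, function(s) s$residues, character(1)))
  expect_equal(names(back), vapply(seqs, function(s) s$chain_id,
                                   character(1)))
})
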