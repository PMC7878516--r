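test_that("the ideal helix template has canonical alpha-helical geometry", {
  seg <- make_ideal_segment(28)
  xyz <- seg$template
  # axial extent ~ 1.5 A per rise over 27 steps
  expect_equal(diff(range(xyz[, 3])), 27 * 1.5, tolerance = 0.5 / 40.5)
  # consecutive CA distances ~3.8 A
  d <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  # radius of gyration agrees with the direct second-moment formula
  ctr <- colMeans(xyz)
  rg_direct <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  expect_equal(model_rg(xyz), rg_direct)
  expect_error(make_ideal_segment(5), ">= 7")
})

test_that("parallel dimers converge onto the target interhelical distance", {
  # the double cycle of a triangle makes every edge a parallel dimer
  g <- build_polyhedron(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  traces <- enumerate_double_traces(g)
  ori <- lapply(traces, classify_orientations)
  pick <- which(vapply(ori, function(o) all(o == "parallel"), logical(1)))[1]
  topo <- circular_permutations(traces[[pick]])[[1]]
  m <- build_model(topo, params = light_params(), seed = 3)
  expect_true(all(m$restraint_residuals < 1.0))
  # parallel pair: residue i against residue i at the target distance
  p <- topo$pairing
  i <- which(topo$orientations == "parallel")[1]
  A <- m$segment_coords[[i]]; B <- m$segment_coords[[p[i]]]
  d <- sqrt(rowSums((A - B)^2))
  expect_equal(mean(d), 10, tolerance = 0.5 / 10)
})

test_that("an antiparallel dimer pairs residue i with residue n+1-i", {
  tr <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))[[1]]
  topo <- circular_permutations(tr)[[1]]
  m <- build_model(topo, params = light_params(), seed = 5)
  A <- m$segment_coords[[1]]; B <- m$segment_coords[[2]]
  d_anti <- sqrt(rowSums((A - B[nrow(B):1, ])^2))
  expect_true(all(abs(d_anti - 10) < 1.0))
  expect_equal(m$clash_count, 0)
})

test_that("builds are bitwise deterministic under the seed", {
  topo <- design_split_bipyramid("interface")
  asg <- assign_segments(topo, cc_fixture_library(),
                         policy = list(interface_variant = "SH"))
  m1 <- build_model(topo, asg, params = light_params(), seed = 7)
  m2 <- build_model(topo, asg, params = light_params(), seed = 7)
  expect_identical(m1$chains, m2$chains)
  expect_identical(m1$restraint_residuals, m2$restraint_residuals)
  m3 <- build_model(topo, asg, params = light_params(), seed = 8)
  expect_false(identical(m1$chains, m3$chains))
})

test_that("segments move as rigid bodies and the final energy does not exceed the initial one", {
  topo <- design_bipyramid()
  asg <- bipyramid_assignment(topo)
  m <- build_model(topo, asg, params = light_params(), seed = 9)
  for (s in c(1, 5, 18)) {
    tmpl <- m$templates[[s]]
    xyz <- m$segment_coords[[s]]
    expect_equal(as.vector(stats::dist(xyz)), as.vector(stats::dist(tmpl)),
                 tolerance = 1e-6)
  }
  expect_lte(m$energy, m$energy_initial)
})

test_that("converged models satisfy restraints and chain connectivity bounds", {
  topo <- design_bipyramid()
  asg <- bipyramid_assignment(topo)
  m <- build_model(topo, asg, seed = 11)   # default (study) schedule
  expect_true(m$converged)
  expect_true(all(m$restraint_residuals <= m$params$tolerance))
  expect_true(all(m$junction_gaps <=
                    m$params$linker_residues * m$params$linker_bond_length +
                    1e-6))
})

test_that("cavity radius matches geometry and a brute-force radial scan", {
  # beads on a spherical shell: cavity = R - probe
  set.seed(1)
  X <- matrix(rnorm(3 * 500), ncol = 3)
  X <- X / sqrt(rowSums(X^2)) * 30
  # the sampled centroid sits slightly off the true centre, so allow a few
  # percent around R - probe
  expect_equal(cavity_radius(X, probe = 2), 28, tolerance = 0.03)
  # brute-force oracle: scan radii and test emptiness around the centroid
  probe <- 2
  ctr <- colMeans(X)
  dists <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  scan <- seq(0, 40, by = 0.05)
  empty <- vapply(scan, function(r) all(dists >= r + probe), logical(1))
  oracle <- max(scan[empty])
  expect_equal(cavity_radius(X, probe = 2), oracle, tolerance = 0.05)
  # collinear beads: degenerate, no cavity
  line <- cbind(seq_len(10) * 3.8, 0, 0)
  expect_equal(cavity_radius(line), 0)
  # a single dimer encloses no meaningful cavity
  tr <- enumerate_double_traces(build_polyhedron(rbind(c("u", "v"))))[[1]]
  m <- build_model(circular_permutations(tr)[[1]],
                   params = light_params(), seed = 2)
  expect_lt(cavity_radius(m), 4)
})

test_that("ensembles are reproducible, dispersed and fully summarised", {
  topo <- design_bipyramid()
  asg <- bipyramid_assignment(topo)
  p <- light_params(replicas = 3)
  e1 <- generate_ensemble(topo, asg, p, seed = 20)
  e2 <- generate_ensemble(topo, asg, p, seed = 20)
  expect_identical(lapply(e1$models, `[[`, "chains"),
                   lapply(e2$models, `[[`, "chains"))
  expect_gt(stats::sd(e1$summary$rg_nm), 0)
  expect_true(all(c("replica", "seed", "energy", "restraint_rms_max",
                    "clash_count", "converged", "rg_nm", "dmax_nm",
                    "cavity_A") %in% names(e1$summary)))
  expect_error(generate_ensemble(topo, asg, light_params(replicas = 1001)),
               "replicas")
})

test_that("PDB export writes CA traces, chains, residuals and MODEL blocks", {
  topo <- design_split_bipyramid("interface")
  asg <- assign_segments(topo, cc_fixture_library(),
                         policy = list(interface_variant = "SH"))
  p <- light_params(replicas = 2)
  ens <- generate_ensemble(topo, asg, p, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(ens$models, path, assignment = asg)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 2)
  expect_equal(sum(grepl("^ENDMDL", lines)), 2)
  expect_true(any(grepl("^REMARK.*PAIR", lines)))
  atoms <- grep("^ATOM", lines, value = TRUE)
  n_beads <- nrow(model_beads(ens$models[[1]]))
  expect_equal(length(atoms), 2 * n_beads)
  expect_setequal(unique(substr(atoms, 22, 22)), c("A", "B"))
  # coordinates survive the fixed-width round trip
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(xyz1, unname(model_beads(ens$models[[1]])), tolerance = 1e-3)
})
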