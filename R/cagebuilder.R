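#' Coarse-grained cage model building
#'
#' Cage models are built at one-bead-per-residue (CA) resolution. Every
#' coiled-coil-forming segment is an ideal rigid alpha-helix; a seeded,
#' staged Metropolis rigid-body annealing satisfies the CC pairing
#' restraints (one harmonic restraint per aligned residue pair, activated
#' one dimer at a time), chain-connectivity springs at the linker junctions,
#' and a soft-sphere clash penalty. A deterministic rigid-fit polish then
#' drives the restraint residuals to convergence. The whole procedure is a
#' pure function of its inputs and the seed.
#'
#' @name cagebuilder
NULL

#' Ideal CA helix template
#'
#' Straight alpha-helix CA trace: 1.5 A rise per residue, 2.3 A helix
#' radius, 100 degrees twist per residue, which reproduces the canonical
#' ~3.8 A consecutive-CA distance.
#'
#' @param length Number of residues (>= 7, a full heptad).
#' @return A `rigid_segment` template: list with `template` (length x 3
#'   matrix, centred at the origin, axis along z) and `length`.
#' @export
make_ideal_segment <- function(length) {
  if (length < 7) stop("segment length must be >= 7 residues")
  i <- seq_len(length) - 1
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  structure(list(template = xyz, length = length), class = "rigid_segment")
}

#' Build parameters
#'
#' Defaults: 10 A pairing target (typical coiled-coil interhelical CA-CA
#' distance), a 4 A hard-core contact radius with a 5.5 A soft repulsion
#' radius, a geometric 8-step cooling ladder from T = 30 to 0.25 (energy
#' units), and 30 replicas per ensemble.
#'
#' @param pairing_target_distance Target CA-CA distance within a dimer (A).
#' @param pairing_force_constant Restraint force constant (energy / A^2).
#' @param linker_bond_length Maximum span per linker residue (A).
#' @param linker_force_constant Junction spring constant (energy / A^2).
#' @param clash_radius Hard-core contact radius used for clash counting (A).
#' @param soft_radius Soft-sphere repulsion radius used during optimisation
#'   (A); contacts between beads of segments that are neither chain
#'   neighbours nor dimer partners are penalised below this distance.
#' @param clash_force_constant Clash penalty constant (energy / A^2).
#' @param t_hi,t_lo,n_temps Annealing temperature ladder.
#' @param moves_per_temp Monte-Carlo moves per segment per temperature.
#' @param polish_sweeps Maximum deterministic rigid-fit sweeps.
#' @param junction_weight Weight of a junction anchor point in the polish
#'   superposition, relative to one restraint bead.
#' @param tolerance Per-pair restraint RMS defining convergence (A).
#' @param linker_residues Linker length assumed between consecutive
#'   segments (residues).
#' @param interpolate_linkers Include straight-line linker beads in the
#'   output chains (so scattering sees the full residue count).
#' @param replicas Ensemble size.
#' @return List of class `build_params`.
#' @export
build_params <- function(pairing_target_distance = 10,
                         pairing_force_constant = 1,
                         linker_bond_length = 3.8,
                         linker_force_constant = 5,
                         clash_radius = 4.0,
                         soft_radius = 5.5,
                         clash_force_constant = 4,
                         t_hi = 30, t_lo = 0.25, n_temps = 8,
                         moves_per_temp = 40,
                         polish_sweeps = 120,
                         junction_weight = 10,
                         tolerance = 1.0,
                         linker_residues = 5,
                         interpolate_linkers = TRUE,
                         replicas = 30) {
  p <- as.list(environment())
  stopifnot(all(unlist(p[c("pairing_target_distance", "pairing_force_constant",
                           "linker_bond_length", "clash_radius",
                           "t_hi", "t_lo")]) > 0), replicas >= 1)
  class(p) <- "build_params"
  p
}

# run expr with a private RNG stream; global RNG state untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.random_rotation <- function() {
  # uniform random rotation via quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  .quat_to_mat(q)
}

.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  .quat_to_mat(c(cos(angle / 2), sin(angle / 2) * axis))
}

# Weighted Kabsch: rigid transform mapping X onto Y (rows correspond)
.kabsch <- function(X, Y, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(X))
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc * w) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}

# ---- internal builder state helpers -------------------------------------

.seg_coords <- function(tmpl, pose) {
  sweep(tmpl %*% t(pose$R), 2, pose$t, "+")
}

.pair_table <- function(topology, seg_len, d0) {
  p <- topology$pairing
  idx <- which(!is.na(p) & p > 0 & seq_along(p) < p)
  lapply(idx, function(i) {
    j <- p[i]
    n <- min(seg_len[i], seg_len[j])
    anti <- topology$orientations[i] == "antiparallel"
    list(i = i, j = j,
         ki = seq_len(n),
         kj = if (anti) seg_len[j] + 1 - seq_len(n) else seq_len(n),
         d0 = d0)
  })
}

.junction_table <- function(topology) {
  ch <- chain_of(topology)
  n <- n_segments(topology)
  out <- list()
  for (s in seq_len(n - 1)) {
    if (ch[s] == ch[s + 1]) out[[length(out) + 1]] <- c(s, s + 1)
  }
  out
}

.pair_energy <- function(co, pr, k) {
  A <- co[[pr$i]][pr$ki, , drop = FALSE]
  B <- co[[pr$j]][pr$kj, , drop = FALSE]
  d <- sqrt(rowSums((A - B)^2))
  k * sum((d - pr$d0)^2)
}

.pair_rms <- function(co, pr) {
  A <- co[[pr$i]][pr$ki, , drop = FALSE]
  B <- co[[pr$j]][pr$kj, , drop = FALSE]
  d <- sqrt(rowSums((A - B)^2))
  sqrt(mean((d - pr$d0)^2))
}

.junction_energy <- function(co, jn, lmax, k) {
  a <- co[[jn[1]]]; b <- co[[jn[2]]]
  gap <- sqrt(sum((a[nrow(a), ] - b[1, ])^2))
  if (gap <= lmax) 0 else k * (gap - lmax)^2
}

# Cached-state local energy: `st` holds the flat bead matrix, squared row
# norms and the per-segment row indices, so a move touches one matrix slice
# instead of re-binding segment matrices.
.local_energy_fast <- function(st, s, params, parts = FALSE) {
  e <- 0
  for (pi in st$active_idx) {
    pr <- st$pairs[[pi]]
    if (pr$i == s || pr$j == s) {
      A <- st$co[[pr$i]][pr$ki, , drop = FALSE]
      B <- st$co[[pr$j]][pr$kj, , drop = FALSE]
      d <- sqrt(rowSums((A - B)^2))
      e <- e + params$pairing_force_constant * sum((d - pr$d0)^2)
    }
  }
  for (jn in st$juncs_of[[s]]) {
    a <- st$co[[jn[1]]]; b <- st$co[[jn[2]]]
    gap <- sqrt(sum((a[nrow(a), ] - b[1, ])^2))
    if (gap > st$lmax) {
      e <- e + params$linker_force_constant * (gap - st$lmax)^2
    }
  }
  # soft-sphere term on strided beads against a cached flat matrix of all
  # other (non-adjacent) strided beads
  rc <- params$soft_radius
  rows <- st$sallowed[[s]]
  ec <- 0
  if (length(rows)) {
    X <- st$co[[s]][st$stride_i[[s]], , drop = FALSE]
    d2 <- outer(rowSums(X^2), st$ssq[rows], "+") -
      2 * X %*% t(st$smat[rows, , drop = FALSE])
    close <- d2 < rc^2
    if (any(close)) {
      d2c <- d2[close]; d2c[d2c < 0] <- 0
      # striding samples 1/clash_scale of the bead pairs; rescale so the
      # effective stiffness matches the full-resolution term
      ec <- st$clash_scale * params$clash_force_constant *
        sum((rc - sqrt(d2c))^2)
    }
  }
  if (parts) list(restraint = e, clash = ec) else e + ec
}

#' Build a coarse-grained cage model
#'
#' Staged restrained rigid-body optimisation (see [cagebuilder]). Identical
#' inputs and seed give bitwise-identical models. A model whose final
#' restraint RMS exceeds the tolerance on any pair is still returned, with
#' `converged = FALSE`.
#'
#' @param topology A `chain_topology`.
#' @param assignment Optional `segment_assignment`; segment lengths are taken
#'   from its sequences (otherwise a uniform 32-residue default is used).
#' @param params A [build_params()] list.
#' @param seed Integer seed (required for reproducibility).
#' @return A `cg_model`: list with `chains` (per-chain CA coordinate
#'   matrices, linker beads interpolated if requested), `segments` (poses and
#'   templates), `restraint_residuals` (per-pair RMS, A), `clash_count`,
#'   `converged`, `energy` and build metadata.
#' @export
build_model <- function(topology, assignment = NULL, params = build_params(),
                        seed = 1) {
  n <- n_segments(topology)
  seg_len <- rep(32L, n)
  if (!is.null(assignment)) {
    m <- match(seq_len(n), assignment$table$segment)
    seg_len <- nchar(assignment$table$sequence[m])
  }
  tmpl <- lapply(seg_len, function(L) make_ideal_segment(L)$template)
  pairs <- .pair_table(topology, seg_len, params$pairing_target_distance)
  juncs <- .junction_table(topology)
  ch <- chain_of(topology)
  adj <- lapply(seq_len(n), function(s) {
    a <- integer(0)
    if (s > 1 && ch[s - 1] == ch[s]) a <- c(a, s - 1L)
    if (s < n && ch[s + 1] == ch[s]) a <- c(a, s + 1L)
    a
  })
  # stage order: pairs sorted by first chain appearance
  pair_ord <- order(vapply(pairs, function(p) min(p$i, p$j), numeric(1)))

  .with_seed(seed, {
    helix_len <- max(seg_len) * 1.5
    box <- helix_len * 1.6
    poses <- vector("list", n)
    co <- vector("list", n)
    for (s in seq_len(n)) {
      for (try in 1:60) {
        pose <- list(R = .random_rotation(),
                     t = stats::runif(3, -box, box))
        xyz <- .seg_coords(tmpl[[s]], pose)
        ok <- TRUE
        for (t2 in seq_len(s - 1)) {
          d2 <- outer(rowSums(xyz^2), rowSums(co[[t2]]^2), "+") -
            2 * xyz %*% t(co[[t2]])
          if (min(d2) < params$soft_radius^2) { ok <- FALSE; break }
        }
        if (ok || try == 60) { poses[[s]] <- pose; co[[s]] <- xyz; break }
      }
    }

    # reference energy of the random starting configuration
    lmax0 <- params$linker_bond_length * params$linker_residues
    etot0 <- 0
    for (pr in pairs) {
      etot0 <- etot0 + .pair_energy(co, pr, params$pairing_force_constant)
    }
    for (jn in juncs) {
      etot0 <- etot0 + .junction_energy(co, jn, lmax0,
                                        params$linker_force_constant)
    }

    # cached builder state shared by the annealing and polish phases
    st <- new.env(parent = emptyenv())
    st$co <- co
    st$pairs <- pairs
    st$active_idx <- integer(0)
    st$adj <- adj
    # the spring engages below the admissible span so that pairing tension
    # cannot stretch a junction past the connectivity bound
    st$lmax <- 0.7 * params$linker_bond_length * params$linker_residues
    st$juncs_of <- lapply(seq_len(n), function(s) {
      Filter(function(jn) jn[1] == s || jn[2] == s, juncs)
    })
    # strided bead subsets for the soft-sphere term, cached as one flat matrix
    st$stride_i <- lapply(seg_len, function(L) seq(1, L, by = 2))
    st$clash_scale <- 4
    ns <- vapply(st$stride_i, length, integer(1))
    srows <- split(seq_len(sum(ns)), rep(seq_len(n), ns))
    st$smat <- do.call(rbind, lapply(seq_len(n), function(s) {
      co[[s]][st$stride_i[[s]], , drop = FALSE]
    }))
    st$ssq <- rowSums(st$smat^2)
    partner <- rep(NA_integer_, n)
    for (pr in pairs) { partner[pr$i] <- pr$j; partner[pr$j] <- pr$i }
    excl <- lapply(seq_len(n), function(s) {
      stats::na.omit(c(s, adj[[s]], partner[s]))
    })
    st$sallowed <- lapply(seq_len(n), function(s) {
      unlist(srows[setdiff(seq_len(n), excl[[s]])], use.names = FALSE)
    })
    sync_seg <- function(s, xyz) {
      st$co[[s]] <- xyz
      sx <- xyz[st$stride_i[[s]], , drop = FALSE]
      st$smat[srows[[s]], ] <- sx
      st$ssq[srows[[s]]] <- rowSums(sx^2)
    }

    mc_pass <- function(temps_vec, moves_per_temp) {
      for (Tcur in temps_vec) {
        scale <- sqrt(Tcur / params$t_hi)
        for (mv in seq_len(moves_per_temp * n)) {
          s <- sample.int(n, 1)
          e0 <- .local_energy_fast(st, s, params)
          old_pose <- poses[[s]]; old_xyz <- st$co[[s]]
          rot <- .axis_angle(stats::rnorm(3), stats::rnorm(1, 0, 0.5 * scale))
          ctr <- colMeans(old_xyz)
          newR <- rot %*% old_pose$R
          newt <- as.vector(rot %*% (old_pose$t - ctr)) + ctr +
            stats::rnorm(3, 0, 3 * scale)
          poses[[s]] <<- list(R = newR, t = newt)
          sync_seg(s, .seg_coords(tmpl[[s]], poses[[s]]))
          e1 <- .local_energy_fast(st, s, params)
          dE <- e1 - e0
          if (dE > 0 && stats::runif(1) > exp(-dE / Tcur)) {
            poses[[s]] <<- old_pose
            sync_seg(s, old_xyz)
          }
        }
      }
    }

    # deterministic rigid-fit polish: alternately superpose each segment onto
    # the positions implied by its restraints and junction anchors
    lmax <- st$lmax
    polish_pass <- function(n_sweeps) {
      for (sweep_i in seq_len(n_sweeps)) {
        shift <- 0
        for (s in seq_len(n)) {
          src <- NULL; dst <- NULL; wt <- NULL
          for (pr in pairs) {
            if (pr$i != s && pr$j != s) next
            if (pr$i == s) { ks <- pr$ki; kp <- pr$kj; p2 <- pr$j }
            else { ks <- pr$kj; kp <- pr$ki; p2 <- pr$i }
            P <- st$co[[p2]][kp, , drop = FALSE]
            S <- st$co[[s]][ks, , drop = FALSE]
            u <- colMeans(S) - colMeans(P)
            nu <- sqrt(sum(u^2))
            u <- if (nu < 1e-8) c(0, 0, 1) else u / nu
            src <- rbind(src, S)
            dst <- rbind(dst, sweep(P, 2, pr$d0 * u, "+"))
            wt <- c(wt, rep(1, nrow(S)))
          }
          for (jn in juncs) {
            if (jn[1] == s) {           # s precedes: anchor its last bead
              other <- st$co[[jn[2]]][1, ]
              mine <- st$co[[s]][nrow(st$co[[s]]), ]
              gap <- sqrt(sum((mine - other)^2))
              if (gap > lmax) {
                tgt <- other + (mine - other) / gap * lmax
                src <- rbind(src, mine); dst <- rbind(dst, tgt)
                wt <- c(wt, params$junction_weight)
              }
            } else if (jn[2] == s) {    # s follows: anchor its first bead
              other <- st$co[[jn[1]]][nrow(st$co[[jn[1]]]), ]
              mine <- st$co[[s]][1, ]
              gap <- sqrt(sum((mine - other)^2))
              if (gap > lmax) {
                tgt <- other + (mine - other) / gap * lmax
                src <- rbind(src, mine); dst <- rbind(dst, tgt)
                wt <- c(wt, params$junction_weight)
              }
            }
          }
          if (is.null(src) || nrow(src) < 3) next
          e0 <- .local_energy_fast(st, s, params, parts = TRUE)
          old_pose <- poses[[s]]; old_xyz <- st$co[[s]]
          fit <- .kabsch(src, dst, wt)
          poses[[s]] <<- list(R = fit$R %*% poses[[s]]$R,
                              t = as.vector(fit$R %*% poses[[s]]$t) + fit$t)
          newxyz <- .seg_coords(tmpl[[s]], poses[[s]])
          sync_seg(s, newxyz)
          # the rigid fit only sees restraints and junction anchors; accept
          # it if those improve and the extra clash cost stays well below
          # the gain, so restraints converge without the cage collapsing
          # through its own walls
          e1 <- .local_energy_fast(st, s, params, parts = TRUE)
          gain <- e0$restraint - e1$restraint
          clash_up <- e1$clash - e0$clash
          if (gain <= 1e-9 || clash_up > 0.5 * gain) {
            poses[[s]] <<- old_pose
            sync_seg(s, old_xyz)
          } else {
            shift <- max(shift, max(abs(newxyz - old_xyz)))
          }
        }
        if (shift < 1e-4) break
      }
    }

    # staged annealing: one additional dimer restraint set per stage
    temps <- exp(seq(log(params$t_hi), log(params$t_lo),
                     length.out = params$n_temps))
    for (stage in seq_along(pair_ord)) {
      st$active_idx <- pair_ord[seq_len(stage)]
      mc_pass(temps, params$moves_per_temp)
    }
    polish_pass(params$polish_sweeps)
    # refinement cycles: a low-temperature shake frees frustrated local
    # minima that the coordinate-descent polish cannot leave on its own
    for (cycle in 1:2) {
      mc_pass(c(1, 0.4), params$moves_per_temp)
      polish_pass(max(20, params$polish_sweeps %/% 3))
    }
    co <- st$co

    residuals <- vapply(pairs, function(pr) .pair_rms(co, pr), numeric(1))
    names(residuals) <- vapply(pairs, function(pr) {
      paste0("seg", pr$i, ":seg", pr$j)
    }, character(1))
    gaps <- vapply(juncs, function(jn) {
      a <- co[[jn[1]]]; b <- co[[jn[2]]]
      sqrt(sum((a[nrow(a), ] - b[1, ])^2))
    }, numeric(1))
    # converged = restraints within tolerance AND chain connectivity holds
    gap_bound <- params$linker_bond_length * params$linker_residues
    converged <- all(residuals <= params$tolerance) &&
      (length(gaps) == 0 || max(gaps) <= gap_bound + 1e-6)

    # clash count: bead pairs of non-adjacent segments below the radius
    clash <- 0L
    for (s in seq_len(n - 1)) {
      for (t2 in (s + 1):n) {
        if (t2 %in% excl[[s]]) next
        d2 <- outer(rowSums(co[[s]]^2), rowSums(co[[t2]]^2), "+") -
          2 * co[[s]] %*% t(co[[t2]])
        clash <- clash + sum(d2 < params$clash_radius^2)
      }
    }

    chains <- .assemble_chains(co, ch, params)

    etot <- 0
    for (pr in pairs) etot <- etot + .pair_energy(co, pr,
                                                  params$pairing_force_constant)
    for (jn in juncs) etot <- etot + .junction_energy(co, jn, lmax,
                                                      params$linker_force_constant)

    structure(
      list(chains = chains,
           segment_coords = co,
           poses = poses,
           templates = tmpl,
           segment_lengths = seg_len,
           topology = topology,
           restraint_residuals = residuals,
           clash_count = as.integer(clash),
           converged = converged,
           energy = etot,
           energy_initial = etot0,
           junction_gaps = gaps,
           params = params,
           seed = seed),
      class = "cg_model")
  })
}

.assemble_chains <- function(co, ch, params) {
  lapply(unique(ch), function(c_id) {
    segs <- which(ch == c_id)
    rows <- NULL
    seg_of_bead <- integer(0)
    for (k in seq_along(segs)) {
      s <- segs[k]
      rows <- rbind(rows, co[[s]])
      seg_of_bead <- c(seg_of_bead, rep(s, nrow(co[[s]])))
      if (k < length(segs) && params$interpolate_linkers &&
          params$linker_residues > 0) {
        a <- co[[s]][nrow(co[[s]]), ]
        b <- co[[segs[k + 1]]][1, ]
        f <- seq_len(params$linker_residues) / (params$linker_residues + 1)
        lb <- t(vapply(f, function(fr) a + fr * (b - a), numeric(3)))
        rows <- rbind(rows, lb)
        seg_of_bead <- c(seg_of_bead, rep(0L, nrow(lb)))
      }
    }
    attr(rows, "segment") <- seg_of_bead
    rows
  })
}

#' All beads of a model as one matrix
#' @param model A `cg_model`.
#' @return Numeric matrix (beads x 3, A).
#' @export
model_beads <- function(model) do.call(rbind, model$chains)

#' Radius of gyration of a model
#' @param model A `cg_model` (or bead matrix).
#' @param units `"A"` or `"nm"`.
#' @return Rg.
#' @export
model_rg <- function(model, units = c("A", "nm")) {
  units <- match.arg(units)
  X <- if (is.matrix(model)) model else model_beads(model)
  Xc <- sweep(X, 2, colMeans(X))
  rg <- sqrt(mean(rowSums(Xc^2)))
  if (units == "nm") rg / 10 else rg
}

#' Maximum intramolecular distance of a model
#' @inheritParams model_rg
#' @return D_max.
#' @export
model_dmax <- function(model, units = c("A", "nm")) {
  units <- match.arg(units)
  X <- if (is.matrix(model)) model else model_beads(model)
  dm <- max(stats::dist(X))
  if (units == "nm") dm / 10 else dm
}

#' Internal cavity radius
#'
#' Radius of the largest sphere centred at the bead centroid that contains no
#' bead closer than the probe distance: the centroid-to-nearest-bead
#' distance minus the probe radius, floored at zero. Degenerate (collinear)
#' bead sets have no cavity.
#'
#' @param model A `cg_model` or bead matrix (>= 4 beads).
#' @param probe Probe radius (A), default 2.
#' @return Cavity radius in A.
#' @export
cavity_radius <- function(model, probe = 2) {
  X <- if (is.matrix(model)) model else model_beads(model)
  if (nrow(X) < 4) stop("need at least 4 beads")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-6 * sv[1]) return(0)
  max(0, min(sqrt(rowSums(Xc^2))) - probe)
}

#' Generate a seeded conformational ensemble
#'
#' Runs `params$replicas` independent seeded builds (replica seeds are
#' derived deterministically from the master seed) and summarises each
#' model.
#'
#' @inheritParams build_model
#' @param seed Master seed.
#' @return List with `models` (list of `cg_model`) and `summary` (data frame:
#'   replica, seed, energy, max restraint RMS, clash count, converged, Rg and
#'   D_max in nm, cavity radius in A).
#' @export
generate_ensemble <- function(topology, assignment = NULL,
                              params = build_params(), seed = 1) {
  if (params$replicas < 1 || params$replicas > 1000) {
    stop("replicas must be in [1, 1000]")
  }
  seeds <- seed + 1009L * (seq_len(params$replicas) - 1L)
  models <- lapply(seeds, function(sd) {
    build_model(topology, assignment, params, seed = sd)
  })
  summary <- data.frame(
    replica = seq_along(models),
    seed = seeds,
    energy = vapply(models, function(m) m$energy, numeric(1)),
    restraint_rms_max = vapply(models, function(m)
      max(m$restraint_residuals), numeric(1)),
    clash_count = vapply(models, function(m) m$clash_count, integer(1)),
    converged = vapply(models, function(m) m$converged, logical(1)),
    rg_nm = vapply(models, function(m) model_rg(m, "nm"), numeric(1)),
    dmax_nm = vapply(models, function(m) model_dmax(m, "nm"), numeric(1)),
    cavity_A = vapply(models, function(m) cavity_radius(m), numeric(1))
  )
  list(models = models, summary = summary)
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf(
    "cg_model: %d chain(s), %d beads | Rg %.1f nm, Dmax %.1f nm | max restraint RMS %.2f A | clashes %d | %s\n",
    length(x$chains), nrow(model_beads(x)), model_rg(x, "nm"),
    model_dmax(x, "nm"), max(x$restraint_residuals), x$clash_count,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# ---- PDB export ----------------------------------------------------------

.model_pdb_lines <- function(model) {
  chains <- model$chains
  chain_ids <- LETTERS[seq_along(chains)]
  xyz <- NULL; cid <- character(0); bfac <- numeric(0)
  # per-bead residual: its pair's RMS (0 for linker beads)
  res_of_seg <- rep(0, n_segments(model$topology))
  for (nm in names(model$restraint_residuals)) {
    ij <- as.integer(sub("seg", "", strsplit(nm, ":")[[1]]))
    res_of_seg[ij] <- model$restraint_residuals[[nm]]
  }
  for (k in seq_along(chains)) {
    xyz <- rbind(xyz, chains[[k]])
    cid <- c(cid, rep(chain_ids[k], nrow(chains[[k]])))
    seg <- attr(chains[[k]], "segment")
    bfac <- c(bfac, ifelse(seg == 0, 0, res_of_seg[pmax(seg, 1)]))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(xyz)),
                   resno = seq_len(nrow(xyz)), chain = cid,
                   resid = rep("ALA", nrow(xyz)),
                   elety = rep("CA", nrow(xyz)), b = round(bfac, 2))
  grep("^(ATOM|TER)", readLines(tmp), value = TRUE)
}

#' Write a model (or ensemble) as a CA-trace PDB file
#'
#' One chain ID per topology chain; the B-factor column carries the
#' per-residue restraint residual (0 for linker beads). Ensembles are
#' written as multi-MODEL files. REMARK records document segments and
#' build metadata.
#'
#' @param model A `cg_model`, or a list of them (an ensemble).
#' @param path Output path.
#' @param assignment Optional `segment_assignment` whose pair names are
#'   echoed in the REMARKs.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path, assignment = NULL) {
  models <- if (inherits(model, "cg_model")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  m1 <- models[[1]]
  writeLines(sprintf("REMARK   6 CCPO coarse-grained CA model, %d chain(s)",
                     length(m1$chains)), con)
  if (!is.null(assignment)) {
    for (r in seq_len(nrow(assignment$edges))) {
      e <- assignment$edges[r, ]
      writeLines(sprintf("REMARK   6 PAIR seg%d:seg%d %s %s (%s)",
                         e$i, e$j, e$edge, e$pair, e$orientation), con)
    }
  }
  writeLines(sprintf("REMARK   6 B-FACTOR = per-pair restraint RMS (A)"), con)
  for (k in seq_along(models)) {
    if (length(models) > 1) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(.model_pdb_lines(models[[k]]), con)
    if (length(models) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
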