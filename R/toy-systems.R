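#' Specification of a dual-pose toy system
#'
#' A toy system stands in for a protein-ligand complex with two mutually
#' exclusive binding modes: a set of *fixed* environment anchor atoms (the
#' "protein") and, for each of the two poses, a small set of mobile particles
#' held by well potentials (the "ligand" in that pose) and coupled to the
#' anchors through alchemically scaled soft-core pair interactions. The two
#' poses share no interaction term, mirroring the exclusion of nonbonded
#' terms between substituents in a dual-topology setup; only restraints may
#' reference atoms of both poses.
#'
#' Keeping each pose at three or fewer degrees of freedom makes the
#' configuration integrals exactly computable by deterministic quadrature
#' ([exact_deltaG_quadrature()]), which is the oracle every estimator in the
#' package is tested against.
#'
#' @param dim Spatial dimension (1-3).
#' @param pose_wells List of exactly two elements, one per pose; each a list
#'   of per-particle well definitions. A well is either
#'   `list(type = "harmonic", center = <Å vector>, k = <kcal/mol/Å²>)`
#'   (energy `k/2 |x - c|²`) or, in 1D,
#'   `list(type = "quartic", center, a, b)` (double well
#'   `a ((x - c)² - b²)²` with minima at `c ± b`).
#' @param interactions Tibble/data.frame with columns
#'   `pose, particle, env_atom, epsilon, sigma` (and optionally `alpha`)
#'   listing soft-core pair interactions between pose particles and
#'   environment anchors. May be empty.
#' @param env_coords Matrix `n_env x dim` of fixed anchor positions in Å, or
#'   `NULL` to place `n_env_atoms` anchors deterministically from `seed`.
#' @param n_env_atoms Number of anchors to auto-place when `env_coords` is
#'   `NULL`.
#' @param masses List of two numeric vectors of per-particle masses (amu);
#'   default 12 amu per particle.
#' @param temperature Temperature in K.
#' @param seed Integer seed controlling any generated geometry.
#' @return A `toy_system_spec` object.
#' @export
toy_system_spec <- function(dim = 1,
                            pose_wells,
                            interactions = NULL,
                            env_coords = NULL,
                            n_env_atoms = 4,
                            masses = NULL,
                            temperature = DEFAULT_TEMPERATURE,
                            seed = 1L) {
  if (!is.list(pose_wells) || length(pose_wells) != 2) {
    stop("a toy system has exactly two poses: `pose_wells` must be a list of length 2")
  }
  stopifnot(dim %in% 1:3, temperature > 0)
  for (p in 1:2) {
    for (w in pose_wells[[p]]) {
      stopifnot(length(w$center) == dim)
      if (identical(w$type, "harmonic")) {
        if (!is.numeric(w$k) || w$k <= 0) stop("well force constants must be > 0")
      } else if (identical(w$type, "quartic")) {
        if (dim != 1) stop("quartic double wells are only supported in 1D")
        stopifnot(w$a > 0, w$b > 0)
      } else stop("unknown well type: ", w$type)
    }
  }
  if (is.null(interactions)) {
    interactions <- tibble::tibble(pose = integer(), particle = integer(),
                                   env_atom = integer(), epsilon = numeric(),
                                   sigma = numeric(), alpha = numeric())
  }
  interactions <- tibble::as_tibble(interactions)
  if (nrow(interactions) > 0 && !"alpha" %in% names(interactions)) {
    interactions$alpha <- 0.5
  }
  structure(list(dim = dim, pose_wells = pose_wells,
                 interactions = interactions, env_coords = env_coords,
                 n_env_atoms = n_env_atoms, masses = masses,
                 temperature = temperature, seed = as.integer(seed)),
            class = "toy_system_spec")
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a dual-pose particle system from its specification
#'
#' Materializes a [toy_system_spec()] into a `particle_system`: anchors are
#' placed (deterministically from the seed when not given), pose particles
#' start at their well centers, and per-pose interaction lists plus the
#' cross-pose exclusion list are assembled. At the alchemical end state
#' `lambda = (1, 0)` the potential contains only pose-1 interactions plus
#' unscaled within-pose well terms; at `(0, 1)` only pose-2 interactions.
#'
#' @param spec A [toy_system_spec()].
#' @return A `particle_system` object.
#' @export
make_dual_pose_toy <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  dim <- spec$dim
  env <- spec$env_coords
  if (is.null(env)) {
    env <- with_local_seed(spec$seed, {
      matrix(stats::runif(spec$n_env_atoms * dim, -15, 15),
             ncol = dim)
    })
  } else {
    env <- matrix(as.numeric(env), ncol = dim)
  }
  poses <- vector("list", 2)
  n_prev <- nrow(env)
  for (p in 1:2) {
    wells <- spec$pose_wells[[p]]
    coords <- do.call(rbind, lapply(wells, function(w) as.numeric(w$center)))
    ia <- dplyr::filter(spec$interactions, .data$pose == p)
    if (nrow(ia) > 0) {
      stopifnot(all(ia$particle >= 1), all(ia$particle <= nrow(coords)),
                all(ia$env_atom >= 1), all(ia$env_atom <= nrow(env)))
    }
    poses[[p]] <- list(coords = coords, wells = wells, interactions = ia,
                       atom_offset = n_prev)
    n_prev <- n_prev + nrow(coords)
  }
  masses <- spec$masses
  if (is.null(masses)) {
    masses <- lapply(poses, function(po) rep(12, nrow(po$coords)))
  }
  # explicit record of the pose-pose exclusions (all cross pairs)
  excl <- expand.grid(
    pose1_atom = poses[[1]]$atom_offset + seq_len(nrow(poses[[1]]$coords)),
    pose2_atom = poses[[2]]$atom_offset + seq_len(nrow(poses[[2]]$coords))
  )
  structure(list(dim = dim, env_coords = env, poses = poses, masses = masses,
                 exclusions = tibble::as_tibble(excl),
                 temperature = spec$temperature, seed = spec$seed),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system> dim =", x$dim, "|", nrow(x$env_coords),
      "env anchors |", nrow(x$poses[[1]]$coords), "+",
      nrow(x$poses[[2]]$coords), "pose particles | T =",
      x$temperature, "K\n")
  invisible(x)
}

n_atoms <- function(system) {
  nrow(system$env_coords) + nrow(system$poses[[1]]$coords) +
    nrow(system$poses[[2]]$coords)
}

#' Map a global 1-based atom index to its coordinates
#'
#' Atom numbering is: environment anchors first, then pose-1 particles, then
#' pose-2 particles. `coords` holds the current mobile coordinates as a list
#' of two matrices (one per pose); when omitted the system's starting
#' coordinates are used.
#' @keywords internal
atom_position <- function(system, idx, coords = NULL) {
  n_env <- nrow(system$env_coords)
  n1 <- nrow(system$poses[[1]]$coords)
  if (is.null(coords)) {
    coords <- list(system$poses[[1]]$coords, system$poses[[2]]$coords)
  }
  if (idx <= n_env) system$env_coords[idx, ]
  else if (idx <= n_env + n1) coords[[1]][idx - n_env, ]
  else {
    j <- idx - n_env - n1
    if (j > nrow(coords[[2]])) stop("unknown atom index ", idx)
    coords[[2]][j, ]
  }
}

#' Return a copy of the system with the two pose labels exchanged
#'
#' Used by the antisymmetry test suites: every free-energy difference must
#' negate when the pose labels are swapped.
#'
#' @param system A `particle_system`.
#' @return A `particle_system` with poses 1 and 2 exchanged.
#' @export
swap_poses <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  out <- system
  out$poses <- system$poses[c(2, 1)]
  out$masses <- system$masses[c(2, 1)]
  n_env <- nrow(system$env_coords)
  out$poses[[1]]$atom_offset <- n_env
  out$poses[[2]]$atom_offset <- n_env + nrow(out$poses[[1]]$coords)
  for (p in 1:2) {
    if (nrow(out$poses[[p]]$interactions) > 0) {
      out$poses[[p]]$interactions$pose <- p
    }
  }
  out
}

#' Serialize a toy system to JSON
#'
#' @param system A `particle_system`.
#' @param path Output file path.
#' @export
write_system_json <- function(system, path) {
  x <- list(
    dim = system$dim,
    env_coords = system$env_coords,
    temperature = system$temperature,
    seed = system$seed,
    poses = lapply(system$poses, function(p) {
      list(coords = p$coords, wells = p$wells,
           interactions = as.data.frame(p$interactions),
           atom_offset = p$atom_offset)
    }),
    masses = system$masses
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_system_json
#' @export
read_system_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  dim <- as.integer(x$dim)
  as_mat <- function(lst) {
    if (length(lst) == 0) return(matrix(numeric(0), ncol = dim))
    do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r))))
  }
  empty_ia <- tibble::tibble(pose = integer(), particle = integer(),
                             env_atom = integer(), epsilon = numeric(),
                             sigma = numeric(), alpha = numeric())
  poses <- lapply(1:2, function(p) {
    pp <- x$poses[[p]]
    wells <- lapply(pp$wells, function(w) {
      w$center <- as.numeric(unlist(w$center))
      for (f in c("k", "a", "b")) if (!is.null(w[[f]])) w[[f]] <- as.numeric(w[[f]])
      w
    })
    ia <- if (length(pp$interactions) == 0) empty_ia else {
      dplyr::bind_rows(lapply(pp$interactions, tibble::as_tibble)) |>
        dplyr::mutate(pose = as.integer(.data$pose),
                      particle = as.integer(.data$particle),
                      env_atom = as.integer(.data$env_atom))
    }
    list(coords = as_mat(pp$coords), wells = wells, interactions = ia,
         atom_offset = as.integer(pp$atom_offset))
  })
  sys <- structure(list(dim = dim, env_coords = as_mat(x$env_coords),
                        poses = poses,
                        masses = lapply(x$masses,
                                        function(m) as.numeric(unlist(m))),
                        temperature = as.numeric(x$temperature),
                        seed = as.integer(x$seed)),
                   class = "particle_system")
  excl <- expand.grid(
    pose1_atom = poses[[1]]$atom_offset + seq_len(nrow(poses[[1]]$coords)),
    pose2_atom = poses[[2]]$atom_offset + seq_len(nrow(poses[[2]]$coords))
  )
  sys$exclusions <- tibble::as_tibble(excl)
  sys
}

# ---------------------------------------------------------------------------
# Ready-made study systems

#' Standard toy systems
#'
#' Ready-made [toy_system_spec()]s used throughout the package's tests,
#' vignette and acceptance runs:
#'
#' * `toy_spec_symmetric()`: two identical 1D poses (harmonic wells, equal
#'   anchor coupling). The exact pose free-energy difference is 0 by
#'   symmetry.
#' * `toy_spec_asymmetric()`: the default study system. Both poses share
#'   the same soft well (so their decoupled states match, as for two poses
#'   of one molecule) but couple with different strengths and geometries to
#'   their anchors, giving an exact nonzero pose free-energy difference of
#'   order 1 kcal/mol. Thermal fluctuations (about 1.1 Å) are small
#'   against the +-4 Å flat-bottom restraint band, the regime in which the
#'   one-step restraint corrections converge (mirroring heavy-atom
#'   fluctuations against the same 4 Å band in a real complex). A ring of distal
#'   anchors 10-16 Å away provides candidates for the multiple-distance
#'   restraint selection.
#' * `toy_spec_barrier()`: strong anchor attraction for both poses
#'   (epsilon about 3 kBT with wells at the pair-potential minimum), which
#'   produces a free-energy barrier of several kBT at intermediate lambda —
#'   the regime where adaptive flattening is required for transitions.
#'
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @return A [toy_system_spec()].
#' @export
toy_spec_symmetric <- function(temperature = DEFAULT_TEMPERATURE, seed = 1L) {
  toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 0, k = 0.3)),
      list(list(type = "harmonic", center = 0, k = 0.3))
    ),
    interactions = tibble::tibble(
      pose = c(1L, 2L), particle = c(1L, 1L), env_atom = c(1L, 1L),
      epsilon = c(0.3, 0.3), sigma = c(3.0, 3.0), alpha = c(0.5, 0.5)
    ),
    env_coords = matrix(c(4.0, 12.0, -12.5, 13.5), ncol = 1),
    temperature = temperature, seed = seed
  )
}

#' @rdname toy_spec_symmetric
#' @export
toy_spec_asymmetric <- function(temperature = DEFAULT_TEMPERATURE, seed = 1L) {
  # anchors: 1 and 7 are the near coupling partners of poses 1 and 2;
  # anchors 2-6 form a distal ring 10-16 Å from the well centers for
  # restraint selection. Wells are identical across poses by design.
  toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 0, k = 0.5)),
      list(list(type = "harmonic", center = 0, k = 0.5))
    ),
    interactions = tibble::tibble(
      pose = c(1L, 2L), particle = c(1L, 1L), env_atom = c(1L, 7L),
      epsilon = c(0.25, 1.0), sigma = c(3.0, 3.0), alpha = c(0.5, 0.5)
    ),
    env_coords = matrix(c(4.0, 12.0, -12.5, 13.5, -11.0, 16.5, -3.6),
                        ncol = 1),
    temperature = temperature, seed = seed
  )
}

#' @rdname toy_spec_symmetric
#' @export
toy_spec_barrier <- function(temperature = DEFAULT_TEMPERATURE, seed = 1L) {
  # each pose's well sits exactly on its anchor, so coupling forces the
  # particle out of the well against a harmonic penalty; the penalty
  # saturates well before lambda = 0.5, leaving a free-energy barrier of
  # several kBT at intermediate lambda (the overlap-repulsion mechanism
  # behind real alchemical barriers)
  toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 4.0, k = 0.8)),
      list(list(type = "harmonic", center = 4.0, k = 0.8))
    ),
    interactions = tibble::tibble(
      pose = c(1L, 2L), particle = c(1L, 1L), env_atom = c(1L, 1L),
      epsilon = c(1.0, 1.0), sigma = c(2.5, 2.5), alpha = c(0.5, 0.5)
    ),
    env_coords = matrix(c(4.0, 12.0, -12.5, 13.5), ncol = 1),
    temperature = temperature, seed = seed
  )
}

# ---------------------------------------------------------------------------
# Distance fixtures for the restraint-selection algorithm

#' Generate a distance-trajectory fixture
#'
#' Draws per-frame ligand-protein atom-pair distances independently from
#' normal laws truncated at zero, as a stand-in for the distance statistics
#' of an equilibrium trajectory. Used to test the multiple-distance
#' restraint-selection algorithm at scale.
#'
#' @param n_frames Number of frames.
#' @param pairs Tibble/data.frame with columns `ligand_atom`, `protein_atom`,
#'   `mean` (Å) and `std` (Å, `>= 0`).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @return A `distance_fixture` tibble with columns
#'   `frame, pair_id, ligand_atom, protein_atom, distance`.
#' @export
make_distance_fixture <- function(n_frames, pairs, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(n_frames >= 1, nrow(pairs) >= 1,
            all(c("ligand_atom", "protein_atom", "mean", "std") %in% names(pairs)))
  if (any(pairs$std < 0)) stop("pair `std` values must be >= 0")
  out <- with_local_seed(seed, {
    purrr::imap_dfr(seq_len(nrow(pairs)), function(i, ...) {
      m <- pairs$mean[i]; s <- pairs$std[i]
      if (s == 0) {
        d <- rep(m, n_frames)
      } else {
        d <- stats::rnorm(n_frames, m, s)
        while (any(d < 0)) {
          bad <- d < 0
          d[bad] <- stats::rnorm(sum(bad), m, s)
        }
      }
      tibble::tibble(frame = seq_len(n_frames), pair_id = i,
                     ligand_atom = pairs$ligand_atom[i],
                     protein_atom = pairs$protein_atom[i],
                     distance = d)
    })
  })
  class(out) <- c("distance_fixture", class(out))
  out
}

#' Write / read a plain-text distance table
#'
#' Whitespace-separated columns `frame pair_id ligand_atom protein_atom
#' distance`, '#' comments, 1-based indices.
#'
#' @param fixture A [make_distance_fixture()] tibble.
#' @param path File path.
#' @export
write_distance_table <- function(fixture, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame pair_id ligand_atom protein_atom distance_A", con)
  utils::write.table(
    as.data.frame(fixture)[, c("frame", "pair_id", "ligand_atom",
                               "protein_atom", "distance")],
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("frame", "pair_id", "ligand_atom",
                                        "protein_atom", "distance"))
  tibble::as_tibble(df)
}
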