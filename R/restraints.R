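#' Flat-bottom distance restraints
#'
#' A restraint set is a tibble with one row per restraint and columns
#' `kind` (`"inter_pose"` or `"protein_ligand"`), `atom_i`, `atom_j`
#' (1-based global atom indices), `r_min`, `r_max` (Å) and `k`
#' (kcal/mol/Å²). The energy is zero while the distance lies inside
#' `[r_min, r_max]` and grows as `k * violation²` outside — note the absence
#' of a 1/2 factor, matching the NOE-style "force constant" phrasing; halve
#' `k` if your convention includes the 1/2. Restraints are *never* scaled by
#' lambda: both poses feel their restraints at the full force constant at
#' every alchemical state, which is exactly why the cycle needs end-point
#' restraint corrections.
#'
#' @param kind Character vector: `"inter_pose"` or `"protein_ligand"`.
#' @param atom_i,atom_j Integer atom indices (1-based).
#' @param r_min,r_max Band edges in Å, `r_min <= r_max`.
#' @param k Force constants in kcal/mol/Å², `> 0`.
#' @return A `restraint_set` tibble.
#' @export
restraint_set <- function(kind = character(), atom_i = integer(),
                          atom_j = integer(), r_min = numeric(),
                          r_max = numeric(), k = numeric()) {
  out <- tibble::tibble(kind = as.character(kind),
                        atom_i = as.integer(atom_i),
                        atom_j = as.integer(atom_j),
                        r_min = as.numeric(r_min), r_max = as.numeric(r_max),
                        k = as.numeric(k))
  validate_restraints(out)
  class(out) <- c("restraint_set", class(out))
  out
}

validate_restraints <- function(r) {
  if (nrow(r) == 0) return(invisible(r))
  stopifnot(all(r$kind %in% c("inter_pose", "protein_ligand")),
            all(r$r_min <= r$r_max), all(r$k > 0))
  invisible(r)
}

#' Flat-bottom restraint energy
#'
#' @param d Distance in Å (vectorized), `>= 0`.
#' @param r_min,r_max Band edges in Å.
#' @param k Force constant in kcal/mol/Å² (no 1/2 factor; see
#'   [restraint_set()]).
#' @return Energy in kcal/mol; 0 inside the band, `k (d - r_max)²` above,
#'   `k (r_min - d)²` below, with a continuous first derivative at the edges.
#' @examples
#' flat_bottom_energy(17, r_min = 8, r_max = 16, k = 40) # 40
#' @export
flat_bottom_energy <- function(d, r_min, r_max, k) {
  if (any(d < 0)) stop("`d` must be non-negative")
  over <- pmax(d - r_max, 0)
  under <- pmax(r_min - d, 0)
  k * (over^2 + under^2)
}

flat_bottom_deriv <- function(d, r_min, r_max, k) {
  2 * k * (pmax(d - r_max, 0) - pmax(r_min - d, 0))
}

#' Distance statistics per ligand-protein atom pair
#'
#' Computes the mean and population standard deviation of every
#' ligand-protein inter-atomic distance over all frames of a trajectory, the
#' input of the multiple-distance restraint selection.
#'
#' @param traj Either a `distance_fixture` tibble (see
#'   [make_distance_fixture()]) or a list of per-frame coordinate matrices
#'   (`n_atoms x dim`, global atom numbering).
#' @param ligand_atoms,protein_atoms Integer atom indices (only used for the
#'   coordinate-trajectory form; must be non-empty and disjoint).
#' @return A `pair_stats` tibble with columns
#'   `ligand_atom, protein_atom, mean, std, n_frames`.
#' @export
compute_pair_stats <- function(traj, ligand_atoms = NULL,
                               protein_atoms = NULL) {
  if (inherits(traj, "distance_fixture") ||
      (is.data.frame(traj) && all(c("ligand_atom", "protein_atom",
                                    "distance") %in% names(traj)))) {
    out <- traj |>
      dplyr::group_by(.data$ligand_atom, .data$protein_atom) |>
      dplyr::summarise(
        mean = mean(.data$distance),
        std = stats::sd(.data$distance) *
          sqrt((dplyr::n() - 1) / dplyr::n()),
        n_frames = dplyr::n(), .groups = "drop")
    out$std[out$n_frames == 1] <- 0
  } else {
    if (length(traj) < 1) stop("trajectory must contain at least one frame")
    if (is.null(ligand_atoms) || length(ligand_atoms) == 0 ||
        is.null(protein_atoms) || length(protein_atoms) == 0) {
      stop("ligand and protein atom selections must be non-empty")
    }
    grid <- expand.grid(ligand_atom = ligand_atoms,
                        protein_atom = protein_atoms)
    dmat <- vapply(traj, function(fr) {
      sqrt(rowSums((fr[grid$ligand_atom, , drop = FALSE] -
                      fr[grid$protein_atom, , drop = FALSE])^2))
    }, numeric(nrow(grid)))
    dmat <- matrix(dmat, nrow = nrow(grid))
    n <- ncol(dmat)
    mu <- rowMeans(dmat)
    std <- sqrt(pmax(rowMeans(dmat^2) - mu^2, 0))
    out <- tibble::tibble(ligand_atom = grid$ligand_atom,
                          protein_atom = grid$protein_atom,
                          mean = mu, std = std, n_frames = n)
  }
  class(out) <- c("pair_stats", class(out))
  out
}

#' Select multiple-distance restraints from trajectory statistics
#'
#' Implements the trajectory-statistics selection rules for protein-ligand
#' flat-bottom restraints:
#'
#' 1. keep candidate pairs whose mean distance lies inside `band`
#'    (default 10-15 Å);
#' 2. for each ligand atom, keep the candidate with the smallest standard
#'    deviation;
#' 3. make the pairs globally unique greedily in ascending-std order (ties
#'    broken by ligand then protein index), so every ligand and protein atom
#'    appears in at most one restraint;
#' 4. set `r_min = mean - half_width`, `r_max = mean + half_width` and assign
#'    the force constant `k`.
#'
#' With `single_frame = TRUE` (the flipped-pose variant, where statistics
#' come from a single minimized structure and every std is 0), the per-ligand
#' choice in step 2 and the greedy order in step 3 use the distance of the
#' mean from the band center as the selection score instead — this package's
#' documented tie rule for the degenerate all-zero-std case.
#'
#' @param stats A `pair_stats` tibble ([compute_pair_stats()]).
#' @param band Length-2 numeric, the admissible mean-distance window in Å.
#' @param half_width Half-width of the flat bottom in Å (default 4).
#' @param k Force constant in kcal/mol/Å² (default 40).
#' @param single_frame Use the band-center tie rule (see above).
#' @return A `restraint_set` of kind `"protein_ligand"`. Empty (with a
#'   warning) when no candidate mean falls inside the band.
#' @export
select_multiple_distance_restraints <- function(stats, band = c(10, 15),
                                                half_width = 4, k = 40,
                                                single_frame = FALSE) {
  stopifnot(nrow(stats) >= 1, length(band) == 2, band[1] <= band[2])
  cand <- dplyr::filter(stats, .data$mean >= band[1], .data$mean <= band[2])
  if (nrow(cand) == 0) {
    warning("no candidate pair with mean distance inside [",
            band[1], ", ", band[2], "] Å; returning an empty restraint set")
    return(restraint_set())
  }
  score <- if (single_frame) abs(cand$mean - mean(band)) else cand$std
  cand$._score <- score
  # rule 2: per-ligand-atom minimum score (deterministic tie-break)
  cand <- cand |>
    dplyr::arrange(.data$._score, .data$ligand_atom, .data$protein_atom) |>
    dplyr::distinct(.data$ligand_atom, .keep_all = TRUE)
  # rule 3: global uniqueness, greedy in ascending score
  cand <- dplyr::arrange(cand, .data$._score, .data$ligand_atom,
                         .data$protein_atom)
  used_lig <- integer(); used_prot <- integer(); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$ligand_atom[i] %in% used_lig) &&
        !(cand$protein_atom[i] %in% used_prot)) {
      keep[i] <- TRUE
      used_lig <- c(used_lig, cand$ligand_atom[i])
      used_prot <- c(used_prot, cand$protein_atom[i])
    }
  }
  sel <- cand[keep, ]
  restraint_set(kind = rep("protein_ligand", nrow(sel)),
                atom_i = sel$ligand_atom, atom_j = sel$protein_atom,
                r_min = sel$mean - half_width, r_max = sel$mean + half_width,
                k = rep(k, nrow(sel)))
}

#' Build inter-pose tether restraints
#'
#' Tethers corresponding atoms of the two poses to each other with stiff
#' flat-bottom restraints (force constant 100-150 kcal/mol/Å² by
#' convention) so the decoupled pose cannot wander off. Because the tethers
#' act symmetrically on the two poses, their free-energy contribution
#' cancels between the end states on a pose-symmetric system.
#'
#' @param pose1_atoms,pose2_atoms Integer vectors of global atom indices,
#'   2-4 atoms per pose, equal lengths; `pairing` pairs them positionally.
#' @param k Force constant in kcal/mol/Å²; values outside `(0, 1e4)` are
#'   rejected.
#' @param width Flat-bottom full width in Å (the band is `0 .. width`, so
#'   tethered atoms may separate freely up to `width`).
#' @return A `restraint_set` of kind `"inter_pose"` with one restraint per
#'   atom pair.
#' @export
build_interpose_tethers <- function(pose1_atoms, pose2_atoms, k = 100,
                                    width = 2) {
  n <- length(pose1_atoms)
  if (n < 2 || n > 4) stop("pick 2-4 tether atoms per pose")
  if (length(pose2_atoms) != n) stop("pose atom lists must pair one-to-one")
  if (k <= 0 || k >= 1e4) stop("tether force constant outside sane range (0, 1e4)")
  restraint_set(kind = rep("inter_pose", n),
                atom_i = as.integer(pose1_atoms),
                atom_j = as.integer(pose2_atoms),
                r_min = rep(0, n), r_max = rep(width, n), k = rep(k, n))
}

#' Total restraint energy for a configuration
#'
#' @param system A `particle_system`.
#' @param coords List of two pose coordinate matrices.
#' @param restraints A [restraint_set()].
#' @param scale Optional multiplier on every force constant (used by the
#'   windowed restraint-coupling path); default 1.
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(system, coords, restraints, scale = 1) {
  if (is.null(restraints) || nrow(restraints) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(restraints))) {
    xi <- atom_position(system, restraints$atom_i[i], coords)
    xj <- atom_position(system, restraints$atom_j[i], coords)
    d <- sqrt(sum((xi - xj)^2))
    total <- total + flat_bottom_energy(d, restraints$r_min[i],
                                        restraints$r_max[i],
                                        scale * restraints$k[i])
  }
  total
}

#' Write / read a restraint table file
#'
#' Plain-text interface: whitespace-separated columns
#' `kind atom_i atom_j r_min r_max k`, 1-based indices, Å and kcal/mol/Å²,
#' `#` comments.
#'
#' @param restraints A [restraint_set()].
#' @param path File path.
#' @export
write_restraint_table <- function(restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# kind atom_i atom_j r_min_A r_max_A k_kcal_mol_A2", con)
  utils::write.table(as.data.frame(restraints), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_restraint_table
#' @export
read_restraint_table <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("kind", "atom_i", "atom_j",
                                        "r_min", "r_max", "k"))
  restraint_set(kind = df$kind, atom_i = df$atom_i, atom_j = df$atom_j,
                r_min = df$r_min, r_max = df$r_max, k = df$k)
}
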