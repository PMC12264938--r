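# Shared fixtures and independent oracles used across the test files.

# two identical 1D poses without any coupling: every free-energy difference
# is exactly zero
uncoupled_symmetric_spec <- function(k = 0.4) {
  toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 0, k = k)),
      list(list(type = "harmonic", center = 0, k = k))),
    env_coords = matrix(12.0, ncol = 1))
}

# 1D poses with well stiffness ratio r: exact pose dG = kBT/2 * log(r)
stiffness_ratio_spec <- function(k1 = 0.15, r = 4) {
  toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 0, k = k1)),
      list(list(type = "harmonic", center = 0, k = k1 * r))),
    env_coords = matrix(12.0, ncol = 1))
}

# restraints used for the one-step-correction accuracy checks: the pose-1
# restraint bites softly (its cost is estimable from the restrained
# reference), the pose-2 restraint is wide and never violated
osp_test_restraints <- function() {
  restraint_set(
    kind = c("protein_ligand", "protein_ligand"),
    atom_i = c(8L, 9L), atom_j = c(2L, 4L),
    r_min = c(12 - 1.5, 14.3 - 4), r_max = c(12 + 1.5, 14.3 + 4),
    k = c(0.5, 40))
}

# independent brute-force implementation of the restraint-selection rules,
# written as literal scans so it shares no code with the package path
brute_force_selection <- function(stats, band = c(10, 15), half_width = 4,
                                  k = 40) {
  df <- as.data.frame(stats)
  cand <- df[df$mean >= band[1] & df$mean <= band[2], , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  # rule 2: per ligand atom, minimum std (ties: lowest ligand then protein)
  kept <- do.call(rbind, lapply(unique(cand$ligand_atom), function(la) {
    sub <- cand[cand$ligand_atom == la, , drop = FALSE]
    sub <- sub[order(sub$std, sub$ligand_atom, sub$protein_atom), ,
               drop = FALSE]
    sub[1, , drop = FALSE]
  }))
  # rule 3: repeatedly accept the globally best remaining candidate and
  # discard everything sharing an atom with it
  out <- NULL
  while (nrow(kept) > 0) {
    kept <- kept[order(kept$std, kept$ligand_atom, kept$protein_atom), ,
                 drop = FALSE]
    best <- kept[1, , drop = FALSE]
    out <- rbind(out, best)
    kept <- kept[kept$ligand_atom != best$ligand_atom &
                   kept$protein_atom != best$protein_atom, , drop = FALSE]
  }
  out <- out[order(out$ligand_atom), , drop = FALSE]
  data.frame(ligand_atom = out$ligand_atom,
             protein_atom = out$protein_atom,
             r_min = out$mean - half_width, r_max = out$mean + half_width,
             k = k)
}

expect_within_sigma <- function(value, reference, sigma, n_sigma = 3) {
  expect_lt(abs(value - reference), n_sigma * max(sigma, 1e-12))
}
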