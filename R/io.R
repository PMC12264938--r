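#' Write / read XYZ trajectories
#'
#' Plain-text XYZ: per frame an atom-count line, a comment line
#' (`frame=<i> time_ps=<t>`), then one `label x y z` line per atom.
#' Coordinates in dimensions below 3 are zero-padded. Atom labels are `EN`
#' for environment anchors, `P1`/`P2` for pose particles.
#'
#' @param frames List of frames; each frame is a list of two pose coordinate
#'   matrices (as produced by [run_lambda_dynamics()]).
#' @param system The `particle_system` the frames belong to.
#' @param path Output file path.
#' @param times Optional per-frame times in ps.
#' @export
write_xyz <- function(frames, system, path, times = NULL) {
  d <- system$dim
  pad <- function(m) cbind(m, matrix(0, nrow(m), 3 - d))
  env <- pad(system$env_coords)
  n_at <- n_atoms(system)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(as.character(n_at), con)
    t_i <- if (is.null(times)) NA else times[i]
    writeLines(sprintf("frame=%d time_ps=%s", i, format(t_i)), con)
    co <- rbind(env, pad(frames[[i]][[1]]), pad(frames[[i]][[2]]))
    lab <- c(rep("EN", nrow(system$env_coords)),
             rep("P1", nrow(frames[[i]][[1]])),
             rep("P2", nrow(frames[[i]][[2]])))
    writeLines(sprintf("%s %.8f %.8f %.8f", lab, co[, 1], co[, 2], co[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @param n_env,n1 Atom counts used to split frames back into environment
#'   and pose blocks (taken from the file's labels when `NULL`).
#' @return `read_xyz()` returns a list of frames in the same nested format.
#' @export
read_xyz <- function(path, n_env = NULL, n1 = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n_at <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n_at)]
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[[`, "", 1)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    p1 <- co[lab == "P1", , drop = FALSE]
    p2 <- co[lab == "P2", , drop = FALSE]
    frames[[length(frames) + 1]] <- list(p1, p2)
    i <- i + 2 + n_at
  }
  frames
}

#' Write / read a lambda-trace text file
#'
#' Plain-text with a header line: columns `time_ps lambda_xray lambda_flip`.
#'
#' @param trace A `lambda_trace` tibble.
#' @param path File path.
#' @export
write_lambda_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# replica_id=%s seed=%s",
                     format(attr(trace, "replica_id")),
                     format(attr(trace, "seed"))), con)
  writeLines("time_ps lambda_xray lambda_flip", con)
  utils::write.table(as.data.frame(trace), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lambda_trace
#' @export
read_lambda_trace <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  df <- utils::read.table(path, skip = 2,
                          col.names = c("time_ps", "lambda_xray",
                                        "lambda_flip"))
  get <- function(key) {
    m <- grep(paste0("^", key, "="), meta, value = TRUE)
    if (length(m)) sub(".*=", "", m) else NA
  }
  new_lambda_trace(df$time_ps, as.matrix(df[, 2:3]),
                   replica_id = suppressWarnings(as.integer(get("replica_id"))),
                   seed = suppressWarnings(as.integer(get("seed"))))
}

#' Read ATOM/HETATM records from a PDB file
#'
#' Thin wrapper around `bio3d::read.pdb()` returning a tibble of atom
#' records (serial, element/atom name, residue, chain, coordinates in Å).
#' Only the atom table is exposed; 1-based serials follow the PDB
#' convention.
#'
#' @param path Path to a PDB file.
#' @return Tibble with columns `serial, atom, resid, chain, resno, x, y, z,
#'   element`.
#' @export
read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  tibble::tibble(serial = a$eleno, atom = a$elety, resid = a$resid,
                 chain = a$chain, resno = a$resno,
                 x = a$x, y = a$y, z = a$z, element = a$elesy)
}

#' Run manifest for provenance
#'
#' Writes a small JSON manifest (seed, config hash, package and R versions)
#' alongside simulation outputs.
#'
#' @param cfg A [simulation_config()] (or any serializable list).
#' @param path Output JSON path.
#' @param extra Named list of extra fields.
#' @export
write_run_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(list(
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    package_version = as.character(utils::packageVersion("lambdapose")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
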