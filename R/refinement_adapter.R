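# ---------------------------------------------------------------------------
# Coarse-grained refinement adapter: emits the SimRNA protocol (config file,
# run script with trajectory clustering) for an ensemble without executing
# the external program, and ranks returned cluster centers.
# ---------------------------------------------------------------------------

SIMRNA_CONFIG <- c(
  "NUMBER_OF_ITERATIONS 2000000",
  "TRA_WRITE_IN_EVERY_N_ITERATIONS 200000",
  "INIT_TEMP 1.15",
  "FINAL_TEMP 0.9",
  "BONDS_WEIGHT 1.0",
  "ANGLES_WEIGHT 1.0",
  "TORS_ANGLES_WEIGHT 0.0",
  "ETA_THETA_WEIGHT 0.40")

#' Write the coarse-grained refinement configuration file
#'
#' Emits the eight fixed key/value pairs of the refinement protocol
#' (iteration count, trajectory stride, temperature ramp and term weights).
#' Byte-stable across runs.
#'
#' @param path output file (conventionally `config.dat`).
#' @return the path, invisibly.
#' @export
write_simrna_config <- function(path) {
  writeLines(SIMRNA_CONFIG, path)
  invisible(path)
}

#' Write the refinement + clustering shell script for an ensemble
#'
#' For each candidate PDB the script runs the refinement engine under
#' `config.dat` with 1000 repetition runs, concatenates the trajectory
#' files, and invokes trajectory clustering with an energy cutoff of 0.25
#' and cluster radii 5.0 10.0 15.0 20.0 25.0 Angstrom, yielding five
#' cluster centers.
#'
#' @param ensemble_pdbs character vector of candidate PDB filenames.
#' @param workdir directory receiving `config.dat` and `run.sh`.
#' @param tag trajectory basename (default `"ensemble"`).
#' @param n_repeats repetition runs per structure.
#' @return path of the script, invisibly.
#' @export
write_refinement_script <- function(ensemble_pdbs, workdir,
                                    tag = "ensemble", n_repeats = 1000L) {
  if (length(ensemble_pdbs) == 0) stop("empty ensemble")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  write_simrna_config(file.path(workdir, "config.dat"))
  lines <- c(
    "#!/bin/sh",
    "# refinement protocol for the sampled structural ensemble",
    unlist(lapply(ensemble_pdbs, function(p) c(
      sprintf("for i in $(seq 1 %d); do", n_repeats),
      sprintf("  ./SimRNA %s -c config.dat", p),
      "done"))),
    sprintf("cat *.trafl > %s.trafl", tag),
    sprintf("./clustering %s.trafl 0.25 5.0 10.0 15.0 20.0 25.0", tag),
    "# -> 5 cluster centers")
  path <- file.path(workdir, "run.sh")
  writeLines(lines, path)
  invisible(path)
}

#' Rank refinement cluster centers with the score model
#'
#' Delegates to [rank_ensemble]; warns when the number of centers differs
#' from the expected five but ranks whatever is given.
#'
#' @param center_maps list of `class_map` (cluster centers re-encoded
#'   through the VQ-VAE).
#' @param seq sequence string.
#' @param score_net trained `score_net`.
#' @return ranking as from [rank_ensemble].
#' @export
rank_cluster_centers <- function(center_maps, seq, score_net) {
  if (length(center_maps) != 5)
    warning("expected 5 cluster centers, got ", length(center_maps))
  rank_ensemble(score_net, center_maps, seq)
}
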