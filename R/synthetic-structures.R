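#' Rigid pose specification
#'
#' @param rotation Euler angles in degrees (z, y, x), length 3.
#' @param translation Translation vector in Å, length 3.
#' @param label Free-text label.
#' @return Object of class `"pose_spec"`.
#' @export
pose_spec <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                      label = "") {
  if (length(rotation) != 3L || length(translation) != 3L ||
      any(!is.finite(c(rotation, translation))))
    stop("'rotation' and 'translation' must be finite length-3 vectors",
         call. = FALSE)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation), label = label),
            class = "pose_spec")
}

#' Toy homodimer with pseudo-residue label sites
#'
#' Builds a minimal two-chain dimer for pipeline testing: two parallel
#' rod-like chains of pseudo-residues (CA plus CB per residue, 3.8 Å rise
#' along the chain axis, chains offset perpendicular to it), numbered so
#' that every requested label-site position exists. Coordinates are
#' deterministic given the seed; the seed only matters when
#' `side_chains = TRUE`, which decorates each residue with two dummy
#' side-chain atoms at seeded pseudo-random offsets so that atom-level
#' contact analysis has something to find.
#'
#' The rod geometry means intra-chain distances grow linearly with residue
#' separation (`rise` Å per residue), so compact residue ranges — not the
#' real proteins' 600-residue spans — should be used when donor–acceptor
#' distances in the tens-of-Å regime are wanted.
#'
#' @param protein `"agp1"` or `"agp2"` (recorded in the provenance).
#' @param site_positions Residue numbers that must exist (unique).
#' @param chain_ids Two chain identifiers.
#' @param n_residues If given, chains carry residues `1:n_residues`
#'   (must cover all site positions); otherwise only the site residues are
#'   materialised.
#' @param rise Translation per residue number along the chain axis (Å).
#' @param chain_sep Distance between the two chain axes (Å).
#' @param side_chains Add dummy side-chain atoms (default `FALSE`).
#' @param seed Integer seed for the side-chain decoration.
#' @return A [structure_model()].
#' @export
make_toy_dimer <- function(protein = c("agp1", "agp2"),
                           site_positions = NULL,
                           chain_ids = NULL, n_residues = NULL,
                           rise = 3.8, chain_sep = 20,
                           side_chains = FALSE, seed = 1) {
  protein <- match.arg(protein)
  if (is.null(site_positions))
    site_positions <- if (protein == "agp1")
      c(122, 362, 517, 535, 554, 603) else c(29, 33, 47, 249, 277, 353, 647)
  if (is.null(chain_ids))
    chain_ids <- if (protein == "agp1") c("A", "B") else c("C", "D")
  if (!length(site_positions))
    stop("'site_positions' must be nonempty", call. = FALSE)
  if (anyDuplicated(site_positions))
    stop("duplicate residue numbers in 'site_positions'", call. = FALSE)
  stopifnot(length(chain_ids) == 2L)
  resnos <- if (is.null(n_residues)) sort(as.integer(site_positions)) else {
    if (max(site_positions) > n_residues)
      stop("'n_residues' must cover all site positions", call. = FALSE)
    seq_len(n_residues)
  }
  rows <- list()
  set.seed(seed)  # only consumed by the side-chain decoration
  for (ci in 1:2) {
    y0 <- (ci - 1) * chain_sep
    for (r in resnos) {
      x <- rise * (r - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain_ids[ci], resno = r, resid = "ALA",
        elety = c("CA", "CB"), x = x, y = y0, z = c(0, 1.5),
        stringsAsFactors = FALSE)
      if (side_chains) {
        off <- matrix(stats::rnorm(6, sd = 1.2), 2, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain_ids[ci], resno = r, resid = "ALA",
          elety = c("SC1", "SC2"),
          x = x + off[, 1], y = y0 + off[, 2], z = 1.5 + off[, 3] + 1.0,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure_model(do.call(rbind, rows),
                  model_id = paste0("toy_", protein),
                  provenance = sprintf("synthetic toy %s dimer (seed %d)",
                                       protein, seed))
}

#' Synthetic docking-pose ensemble
#'
#' One complex at the stated true pose plus `n_decoys` complexes at random
#' rigid placements of the ligand around the receptor: uniform Euler
#' rotations, ligand centroid placed at a uniform distance within
#' `shell` Å of the receptor centroid in a uniform random direction.
#' Placements bringing any ligand atom within `clash_distance` Å of a
#' receptor atom are rejected and redrawn (bounded retries). Deterministic
#' given `seed`.
#'
#' Pose semantics: the ligand is rotated about its own centroid, then its
#' centroid is moved by the pose translation (true pose) or to the sampled
#' shell point (decoys).
#'
#' @param receptor,ligand [structure_model()] objects with disjoint chains.
#' @param n_decoys Number of decoy poses (>= 0).
#' @param true_pose A [pose_spec()] for the true complex.
#' @param seed Integer seed.
#' @param shell Length-2 range of centroid–centroid distances for decoys (Å).
#' @param clash_distance Minimum allowed inter-protein atom distance (Å).
#' @param max_retries Retries per decoy before giving up.
#' @return List of `list(model, pose)`; the first element is the true pose
#'   (model_id `"true"`), decoys are `"decoy.01"`, `"decoy.02"`, ...
#' @export
make_pose_ensemble <- function(receptor, ligand, n_decoys, true_pose,
                               seed = 1, shell = c(30, 80),
                               clash_distance = 2, max_retries = 200) {
  stopifnot(inherits(receptor, "structure_model"),
            inherits(ligand, "structure_model"),
            inherits(true_pose, "pose_spec"), n_decoys >= 0)
  rec_xyz <- as.matrix(receptor$atoms[c("x", "y", "z")])
  rec_cen <- colMeans(rec_xyz)
  lig_cen <- colMeans(as.matrix(ligand$atoms[c("x", "y", "z")]))

  place <- function(rotation, centroid_target, id) {
    lg <- transform_structure(ligand, rotation = rotation,
                              translation = centroid_target - lig_cen)
    merge_structures(receptor, lg, model_id = id)
  }
  min_sep <- function(model) {
    at <- model$atoms
    x1 <- as.matrix(at[at$chain %in% unique(receptor$atoms$chain),
                       c("x", "y", "z")])
    x2 <- as.matrix(at[at$chain %in% unique(ligand$atoms$chain),
                       c("x", "y", "z")])
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
    sqrt(max(0, min(d2)))
  }

  set.seed(seed)
  out <- vector("list", n_decoys + 1L)
  true_model <- place(true_pose$rotation, lig_cen + true_pose$translation,
                      "true")
  out[[1L]] <- list(model = true_model, pose = true_pose)
  for (k in seq_len(n_decoys)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      rot <- stats::runif(3, 0, 360)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      dist <- stats::runif(1, shell[1], shell[2])
      target <- rec_cen + dir * dist
      m <- place(rot, target, sprintf("decoy.%02d", k))
      if (min_sep(m) >= clash_distance) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place decoy ", k, " without clashes after ",
           max_retries, " retries", call. = FALSE)
    out[[k + 1L]] <- list(model = m,
                          pose = pose_spec(rot, target - lig_cen,
                                           label = sprintf("decoy.%02d", k)))
  }
  out
}

#' Simulate a noisy measured-efficiency table
#'
#' Per label position, draws `n_replicates` Gaussian replicates around the
#' noiseless efficiency (clamped to `[0, 1]`, mimicking that measured
#' efficiencies are reported on the physical scale) and reports their mean
#' and standard error. Deterministic given `seed`.
#'
#' @param truth Named numeric vector of noiseless efficiencies, keyed by
#'   label position.
#' @param noise_sd Replicate-level Gaussian noise SD (>= 0).
#' @param n_replicates Number of replicates per position (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `position`, `efficiency`, `se` (for
#'   `n_replicates = 1` the known `noise_sd` is reported as the SE).
#' @export
simulate_measurements <- function(truth, noise_sd = 0.03, n_replicates = 4,
                                  seed = 1) {
  truth <- unclass_efficiency(truth)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  set.seed(seed)
  rows <- lapply(names(truth), function(p) {
    reps <- pmin(pmax(stats::rnorm(n_replicates, truth[[p]], noise_sd), 0), 1)
    data.frame(position = as.integer(p), efficiency = mean(reps),
               se = if (n_replicates > 1)
                      stats::sd(reps) / sqrt(n_replicates) else noise_sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Complete synthetic complex with ground truth
#'
#' Convenience generator bundling a compact toy receptor/ligand pair, a
#' seeded random (or supplied) pose, the resulting complex model, the
#' ground-truth donor–acceptor distances, and the noiseless efficiency
#' set. The noiseless efficiencies are computed with
#' [predict_position_efficiency()] itself, so generator and predictor can
#' never drift apart.
#'
#' @param seed Integer seed controlling the pose (and decoration).
#' @param acceptor_positions,donor_positions Label positions on the toy
#'   chains.
#' @param n_residues Residues per toy chain.
#' @param pose A [pose_spec()], or `NULL` to draw one from the seed
#'   (shell-placed like the decoys of [make_pose_ensemble()]).
#' @param params A [fret_params()].
#' @param side_chains Passed to [make_toy_dimer()].
#' @return List with `model`, `receptor`, `ligand`, `scheme`, `pose`,
#'   `distances` (per position), `efficiencies` (noiseless, named by
#'   position) and `seed`.
#' @export
synthetic_complex <- function(seed = 1,
                              acceptor_positions = c(5, 12, 18, 22, 25, 28),
                              donor_positions = c(2, 4, 6, 13, 16, 20, 29),
                              n_residues = 30, pose = NULL,
                              params = fret_params(), side_chains = FALSE) {
  receptor <- make_toy_dimer("agp1", site_positions = acceptor_positions,
                             chain_ids = c("A", "B"), n_residues = n_residues,
                             side_chains = side_chains, seed = seed)
  ligand <- make_toy_dimer("agp2", site_positions = donor_positions,
                           chain_ids = c("C", "D"), n_residues = n_residues,
                           side_chains = side_chains, seed = seed + 1)
  if (is.null(pose)) {
    set.seed(seed)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pose <- pose_spec(stats::runif(3, 0, 360),
                      colMeans(as.matrix(receptor$atoms[c("x", "y", "z")])) +
                        dir * stats::runif(1, 30, 60) -
                        colMeans(as.matrix(ligand$atoms[c("x", "y", "z")])),
                      label = "truth")
  }
  lig_placed <- transform_structure(ligand, rotation = pose$rotation,
                                    translation = pose$translation)
  model <- merge_structures(receptor, lig_placed,
                            model_id = sprintf("synthetic.%d", seed))
  scheme <- labeling_scheme(donor_positions = donor_positions,
                            acceptor_positions = acceptor_positions)
  dists <- lapply(stats::setNames(acceptor_positions, acceptor_positions),
                  function(p) distance_matrix(model,
                                              labeling_scheme_at(scheme, p)))
  eff <- predict_position_efficiency(model, scheme, params,
                                     positions = acceptor_positions)
  list(model = model, receptor = receptor, ligand = lig_placed,
       scheme = scheme, pose = pose, distances = dists,
       efficiencies = eff, seed = seed)
}
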