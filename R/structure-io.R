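#' Construct a structure model
#'
#' A light container for the atomic coordinates of one candidate complex
#' pose: a data frame of atoms (chain, residue number, residue name, atom
#' name, x/y/z in Å) plus an identifier and free-text provenance.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`. No duplicate (chain, resno, elety) triple; finite
#'   coordinates.
#' @param model_id Identifier string.
#' @param provenance Free text describing where the coordinates came from.
#' @return An object of class `"structure_model"`.
#' @export
structure_model <- function(atoms, model_id = "model", provenance = "") {
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop("'atoms' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  atoms <- atoms[req]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("atom coordinates must be finite", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate atom record (chain residue atom): ", d, call. = FALSE)
  }
  structure(list(model_id = model_id, atoms = atoms, provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s': %d atoms, chains %s>\n", x$model_id,
              nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = ",")))
  invisible(x)
}

#' Read a PDB coordinate file into a structure model
#'
#' Parses ATOM records of a PDB v3.3 coordinate file (the dialect written
#' by docking and structure-prediction servers). Insertion codes are
#' rejected; alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by altloc letter order); duplicate atoms are an
#' error; a file with fewer than two chains triggers a warning since a
#' complex pose is expected.
#'
#' @param path Path to a PDB file.
#' @param model_id Identifier; defaults to the file name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(model_id))
    model_id <- sub("\\.(pdb|ent)$", "", basename(path))
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  ins <- at$insert
  if (any(!is.na(ins) & ins != ""))
    stop("insertion codes are not supported (residue ",
         at$resno[which(!is.na(ins) & ins != "")[1]], ")", call. = FALSE)
  at <- resolve_altloc(at)
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  out <- structure_model(atoms, model_id = model_id,
                         provenance = paste("read from", path))
  if (length(unique(atoms$chain)) < 2L)
    warning("structure ", model_id, " has fewer than 2 chains", call. = FALSE)
  out
}

# Cheap per-line sanity scan so that malformed coordinate records are
# reported with a line number rather than silently mangled downstream.
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) return(invisible(TRUE))
  idx <- which(rec)
  bad_len <- nchar(lines[idx]) < 54
  coords <- suppressWarnings(
    cbind(as.numeric(substr(lines[idx], 31, 38)),
          as.numeric(substr(lines[idx], 39, 46)),
          as.numeric(substr(lines[idx], 47, 54))))
  bad <- bad_len | apply(is.na(coords), 1, any)
  if (any(bad))
    stop("unparseable coordinate record at line ", idx[which(bad)[1]],
         " of ", path, call. = FALSE)
  invisible(TRUE)
}

resolve_altloc <- function(at) {
  alt <- at$alt
  has_alt <- !is.na(alt) & alt != ""
  if (!any(has_alt)) return(at)
  key <- paste(at$chain, at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
    if (length(i) == 1L) return(i)
    o <- at$o[i]
    o[is.na(o)] <- 1
    i <- i[o == max(o)]
    a <- alt[i]
    a[is.na(a) | a == ""] <- " "
    i[order(a)][1]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Write a structure model as a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Coordinate of a label attachment site
#'
#' Returns the Cβ position of the stated residue as the fluorophore proxy
#' (the label itself sits a few Å further out; no linker correction is
#' attempted). Glycine — or any residue missing a Cβ — falls back to the Cα
#' position with a warning.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier.
#' @param resno Residue number (construct numbering).
#' @return Numeric length-3 vector (x, y, z) in Å, with attribute `"atom"`
#'   naming the atom actually used (`"CB"` or `"CA"`).
#' @export
site_coordinate <- function(model, chain, resno) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel))
    stop("missing site: residue ", resno, " on chain ", chain,
         " not present in model '", model$model_id, "'", call. = FALSE)
  res <- a[sel, , drop = FALSE]
  row <- res[res$elety == "CB", , drop = FALSE]
  used <- "CB"
  if (nrow(row) == 0L) {
    row <- res[res$elety == "CA", , drop = FALSE]
    used <- "CA"
    if (nrow(row) == 0L)
      stop("residue ", resno, " on chain ", chain,
           " has neither CB nor CA atom", call. = FALSE)
    warning("residue ", resno, " chain ", chain,
            ": no CB atom, using CA position", call. = FALSE)
  }
  structure(c(row$x[1], row$y[1], row$z[1]), atom = used)
}

#' Donor–acceptor distance matrix for a labeling scheme
#'
#' Euclidean Cβ–Cβ distances between every acceptor site and every donor
#' site of the scheme (rows: acceptor sites, columns: donor sites). For the
#' default scheme — two acceptor copies (one per acceptor-protein chain)
#' against 7 donor positions on each of two donor-protein chains — the
#' matrix has 2 x 14 = 28 entries.
#'
#' @param model A [structure_model()].
#' @param scheme A [labeling_scheme()].
#' @return Numeric matrix of distances in Å with informative dimnames.
#'   Unresolvable sites are collected and reported in a single error.
#' @export
distance_matrix <- function(model, scheme) {
  stopifnot(inherits(model, "structure_model"), inherits(scheme, "labeling_scheme"))
  don <- scheme$donor_sites
  acc <- scheme$acceptor_sites
  coords <- function(sites) {
    errs <- character(0)
    m <- matrix(NA_real_, nrow(sites), 3)
    for (i in seq_len(nrow(sites))) {
      p <- tryCatch(site_coordinate(model, sites$chain[i], sites$model_resno[i]),
                    error = function(e) conditionMessage(e))
      if (is.character(p)) errs <- c(errs, p) else m[i, ] <- p
    }
    list(m = m, errs = errs)
  }
  dc <- coords(don); ac <- coords(acc)
  errs <- c(ac$errs, dc$errs)
  if (length(errs))
    stop("unresolvable label sites in model '", model$model_id, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  d <- matrix(0, nrow(acc), nrow(don),
              dimnames = list(site_ids(acc), site_ids(don)))
  for (i in seq_len(nrow(acc)))
    d[i, ] <- sqrt(colSums((t(dc$m) - ac$m[i, ])^2))
  d
}

site_ids <- function(sites) paste0(sites$chain, sites$resno)

#' Apply a rigid-body transform to a structure model
#'
#' Rotates the coordinates by ZYX Euler angles about the model centroid (or
#' a given center) and then translates them. Used to build docking-pose
#' ensembles and to verify that distance-derived quantities are invariant
#' under rigid motion.
#'
#' @param model A [structure_model()].
#' @param rotation Euler angles (degrees), length 3: rotation about z, y, x.
#' @param translation Translation vector (Å), length 3.
#' @param center Rotation center; defaults to the model centroid.
#' @return The transformed [structure_model()].
#' @export
transform_structure <- function(model, rotation = c(0, 0, 0),
                                translation = c(0, 0, 0), center = NULL) {
  stopifnot(inherits(model, "structure_model"),
            length(rotation) == 3L, length(translation) == 3L)
  xyz <- as.matrix(model$atoms[c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(xyz)
  R <- euler_matrix(rotation)
  new <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + translation, "+")
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}

euler_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Merge two structure models into one complex
#'
#' @param a,b [structure_model()] objects with disjoint chain identifiers.
#' @param model_id Identifier for the combined model.
#' @return A [structure_model()] holding both sets of atoms.
#' @export
merge_structures <- function(a, b, model_id = paste(a$model_id, b$model_id,
                                                    sep = "+")) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  if (length(intersect(unique(a$atoms$chain), unique(b$atoms$chain))))
    stop("chain identifiers of the two models overlap", call. = FALSE)
  structure_model(rbind(a$atoms, b$atoms), model_id = model_id,
                  provenance = paste(a$provenance, b$provenance, sep = "; "))
}
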