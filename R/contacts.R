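#' Inter-protein residue contact pairs
#'
#' Finds every cross-protein residue pair whose minimum atom–atom distance
#' is at or below `cutoff` Å (3 Å by default). Distances are over all
#' atoms present in the model — docking and prediction output normally
#' contains heavy atoms only; if hydrogens are present they participate
#' unless `include_hydrogens = FALSE`. One row is reported per residue
#' pair (not per atom pair), sorted by the first protein's residue number.
#'
#' @param model A [structure_model()] of the complex.
#' @param chain_map Named list mapping the two proteins to chain
#'   identifiers, e.g. `list(agp1 = c("A","B"), agp2 = c("C","D"))`.
#' @param cutoff Contact distance cutoff in Å.
#' @param include_hydrogens Keep hydrogen atoms in the distance search
#'   (default `TRUE`, which is a no-op for heavy-atom-only models).
#' @return Data frame with columns `agp1_resid`, `agp1_resno`,
#'   `agp1_chain`, `agp2_resid`, `agp2_resno`, `agp2_chain`,
#'   `min_distance`. Column name prefixes follow `names(chain_map)`.
#' @export
find_contacts <- function(model, chain_map = list(agp1 = c("A", "B"),
                                                  agp2 = c("C", "D")),
                          cutoff = 3.0, include_hydrogens = TRUE) {
  stopifnot(inherits(model, "structure_model"), is.list(chain_map),
            length(chain_map) == 2L)
  p1 <- names(chain_map)[1]; p2 <- names(chain_map)[2]
  if (!length(chain_map[[p1]]) || !length(chain_map[[p2]]))
    stop("both sides of 'chain_map' must name at least one chain", call. = FALSE)
  at <- model$atoms
  if (!include_hydrogens)
    at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  a1 <- at[at$chain %in% chain_map[[p1]], , drop = FALSE]
  a2 <- at[at$chain %in% chain_map[[p2]], , drop = FALSE]
  if (nrow(a1) == 0L || nrow(a2) == 0L)
    stop("model has no atoms for one side of the chain map", call. = FALSE)

  x1 <- as.matrix(a1[c("x", "y", "z")])
  x2 <- as.matrix(a2[c("x", "y", "z")])
  # all-pairs squared distances via the expansion |u-v|^2 = |u|^2+|v|^2-2u.v
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  d2[d2 < 0] <- 0

  # minimum over the atoms of each residue pair, aggregated one axis at a time
  f1 <- factor(paste(a1$chain, a1$resno, a1$resid, sep = "|"))
  f2 <- factor(paste(a2$chain, a2$resno, a2$resid, sep = "|"))
  nm1 <- levels(f1); nm2 <- levels(f2)
  by_res1 <- t(vapply(split(seq_along(f1), f1),
                      function(i) apply(d2[i, , drop = FALSE], 2, min),
                      numeric(ncol(d2))))
  dmin <- vapply(split(seq_along(f2), f2),
                 function(j) apply(by_res1[, j, drop = FALSE], 1, min),
                 numeric(nrow(by_res1)))
  dim(dmin) <- c(length(nm1), length(nm2))
  dimnames(dmin) <- list(nm1, nm2)
  hits <- which(sqrt(dmin) <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    out <- data.frame(a = character(), b = integer(), c = character(),
                      d = character(), e = integer(), f = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
    names(out) <- c(paste0(p1, c("_resid", "_resno", "_chain")),
                    paste0(p2, c("_resid", "_resno", "_chain")), "min_distance")
    return(out)
  }
  split1 <- do.call(rbind, strsplit(nm1[hits[, 1]], "|", fixed = TRUE))
  split2 <- do.call(rbind, strsplit(nm2[hits[, 2]], "|", fixed = TRUE))
  out <- data.frame(split1[, 3], as.integer(split1[, 2]), split1[, 1],
                    split2[, 3], as.integer(split2[, 2]), split2[, 1],
                    min_distance = sqrt(dmin[hits]),
                    stringsAsFactors = FALSE)
  names(out) <- c(paste0(p1, c("_resid", "_resno", "_chain")),
                  paste0(p2, c("_resid", "_resno", "_chain")), "min_distance")
  out <- out[order(out[[paste0(p1, "_resno")]], out[[paste0(p1, "_chain")]],
                   out[[paste0(p2, "_resno")]]), ]
  rownames(out) <- NULL
  out
}

#' Group interface residues into sequence regions
#'
#' Residues of the chosen protein are merged — per chain — into one region
#' whenever at most `gap_threshold` residues lie between consecutive sorted
#' members (so `gap_threshold = 0` merges only runs of consecutive residue
#' numbers). Regions with a single member are reported separately
#' as solo residues: isolated interface positions are the ones most likely
#' to reflect specific (co-evolved) rather than incidental surface
#' contacts.
#'
#' @param contacts A contact table from [find_contacts()].
#' @param protein Which side to group: a prefix present in the contact
#'   table's column names (e.g. `"agp1"`).
#' @param gap_threshold Maximum residue-number gap bridged within one
#'   region (default 15).
#' @return List with `groups` (data frame: chain, first, last, n_residues,
#'   residues) and `solo` (data frame: chain, resno).
#' @export
group_contacts <- function(contacts, protein = "agp1", gap_threshold = 15) {
  rescol <- paste0(protein, "_resno"); chcol <- paste0(protein, "_chain")
  if (!all(c(rescol, chcol) %in% names(contacts)))
    stop("contact table has no columns for protein '", protein, "'",
         call. = FALSE)
  if (gap_threshold < 0) stop("'gap_threshold' must be >= 0", call. = FALSE)
  groups <- list(); solo <- list()
  if (nrow(contacts)) {
    for (ch in sort(unique(contacts[[chcol]]))) {
      res <- sort(unique(contacts[[rescol]][contacts[[chcol]] == ch]))
      brk <- c(0, cumsum(diff(res) - 1 > gap_threshold))
      for (g in split(res, brk)) {
        if (length(g) >= 2L) {
          groups[[length(groups) + 1L]] <-
            data.frame(chain = ch, first = min(g), last = max(g),
                       n_residues = length(g),
                       residues = paste(g, collapse = ","),
                       stringsAsFactors = FALSE)
        } else {
          solo[[length(solo) + 1L]] <-
            data.frame(chain = ch, resno = g, stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_groups <- data.frame(chain = character(), first = integer(),
                             last = integer(), n_residues = integer(),
                             residues = character(), stringsAsFactors = FALSE)
  empty_solo <- data.frame(chain = character(), resno = integer(),
                           stringsAsFactors = FALSE)
  list(groups = if (length(groups)) do.call(rbind, groups) else empty_groups,
       solo = if (length(solo)) do.call(rbind, solo) else empty_solo)
}

#' Residues at the alignment column homologous to a reference position
#'
#' Maps an ungapped residue position of a reference sequence through that
#' sequence's alignment gaps to an alignment column, and returns every
#' sequence's character at that column — the standard check for whether a
#' position of interest is conserved across homologs.
#'
#' @param msa A named character vector of equal-length aligned sequences
#'   (gaps as `-`), or a path to an aligned FASTA file (read with
#'   `Biostrings::readAAStringSet()`).
#' @param ref_id Name of the reference sequence.
#' @param ref_position 1-based position in the ungapped reference.
#' @return Named character vector of single residues (or `-`) per
#'   sequence, with attribute `"column"` giving the alignment column.
#' @export
conservation_column <- function(msa, ref_id, ref_position) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA alignments requires the Biostrings package",
           call. = FALSE)
    aln <- Biostrings::readAAStringSet(msa)
    msa <- stats::setNames(as.character(aln), names(aln))
  }
  if (is.null(names(msa)) || !is.character(msa))
    stop("'msa' must be a named character vector of aligned sequences",
         call. = FALSE)
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned sequences must all have the same length", call. = FALSE)
  if (!ref_id %in% names(msa))
    stop("reference sequence '", ref_id, "' not in the alignment", call. = FALSE)
  if (!is.numeric(ref_position) || ref_position < 1)
    stop("'ref_position' must be a positive integer", call. = FALSE)
  ref <- strsplit(msa[[ref_id]], "")[[1]]
  ungapped <- which(ref != "-")
  if (ref_position > length(ungapped))
    stop("'ref_position' (", ref_position, ") exceeds the ungapped length ",
         "of the reference (", length(ungapped), ")", call. = FALSE)
  col <- ungapped[ref_position]
  out <- vapply(msa, function(s) substr(s, col, col), character(1))
  structure(out, column = col)
}
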