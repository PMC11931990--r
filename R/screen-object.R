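#' Screen candidate complex poses against measured FRET efficiencies
#'
#' The central entry point of the package. For every candidate pose it
#' predicts the per-position FRET efficiencies implied by the labeling
#' scheme ([predict_position_efficiency()]), scores the prediction against
#' the measured efficiency set by sum of squared differences
#' ([score_model()]), derives interface domain-involvement flags from a
#' residue contact analysis ([find_contacts()],
#' [classify_domain_involvement()]) and applies the three qualitative
#' selection criteria ([apply_selection_criteria()]).
#'
#' @param models A named list of [structure_model()] objects, or a
#'   character vector of PDB file paths (read via [read_structure()]).
#' @param measured Measured efficiencies: a named numeric vector keyed by
#'   label position, or a data frame with columns `position` and
#'   `efficiency` (e.g. `load_fixture("table3_measured")` subset).
#' @param scheme A [labeling_scheme()].
#' @param params A [fret_params()].
#' @param ranges A [domain_ranges()], or `NULL` to skip the contact-based
#'   criterion C3 (its column is then `NA`).
#' @param contact_cutoff Contact distance cutoff in Å (default 3).
#' @param ssd_space Passed to [score_model()].
#' @param ... Further arguments passed to [apply_selection_criteria()]
#'   (`c1_positions`, `c2_positions`, `c1_margin`, `c2_ratio`).
#' @return An object of class `"fret_screen"`: a list with the scores data
#'   frame (`$scores`: model_id, one `e<position>` column per measured
#'   position, `ssd`, involvement flags, criterion verdicts, `selected`,
#'   `eliminated_by`), the measured set, and the call parameters.
#' @examples
#' rec <- make_toy_dimer("agp1", site_positions = c(5, 12, 25),
#'                       chain_ids = c("A", "B"), n_residues = 30)
#' lig <- make_toy_dimer("agp2", site_positions = c(2, 8, 20),
#'                       chain_ids = c("C", "D"), n_residues = 30)
#' ens <- make_pose_ensemble(rec, lig, n_decoys = 3,
#'                           true_pose = pose_spec(c(0, 90, 0), c(40, 25, 0)),
#'                           seed = 7)
#' sch <- labeling_scheme(donor_positions = c(2, 8, 20),
#'                        acceptor_positions = c(5, 12, 25))
#' truth <- predict_position_efficiency(ens[[1]]$model, sch)
#' scr <- fret_screen(lapply(ens, `[[`, "model"), truth, sch,
#'                    c1_positions = c(5, 25), c2_positions = c(12, 25))
#' scr
#' @export
fret_screen <- function(models, measured, scheme = labeling_scheme(),
                        params = fret_params(), ranges = domain_ranges(),
                        contact_cutoff = 3,
                        ssd_space = c("efficiency", "distance"), ...) {
  ssd_space <- match.arg(ssd_space)
  if (is.character(models)) {
    paths <- models
    models <- lapply(paths, read_structure)
    names(models) <- vapply(models, `[[`, "", "model_id")
  }
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, `[[`, "", "model_id")
  measured <- unclass_efficiency(measured)
  positions <- as.numeric(names(measured))

  rows <- lapply(names(models), function(id) {
    m <- models[[id]]
    pred <- predict_position_efficiency(m, scheme, params,
                                        positions = positions)
    flags <- if (!is.null(ranges)) {
      contacts <- find_contacts(m, chain_map = scheme$chain_map,
                                cutoff = contact_cutoff)
      classify_domain_involvement(contacts, ranges)
    } else {
      c(agp1_pcm = NA, agp1_hk = NA, agp2_pcm = NA, agp2_hk = NA)
    }
    stats::setNames(
      data.frame(id, as.list(as.numeric(pred)), score_model(pred, measured,
                                                            space = ssd_space),
                 as.list(flags), stringsAsFactors = FALSE),
      c("model_id", paste0("e", names(pred)), "ssd", names(flags)))
  })
  scores <- do.call(rbind, rows)
  scores <- apply_selection_criteria(scores, ...)
  structure(list(scores = scores, measured = measured, params = params,
                 scheme = scheme, ssd_space = ssd_space,
                 survivors = attr(scores, "survivors"),
                 call = match.call()),
            class = "fret_screen")
}

#' @export
print.fret_screen <- function(x, ...) {
  cat("FRET-restraint pose screen\n")
  cat(sprintf("  %d pose(s), %d measured position(s), SSD in %s space\n",
              nrow(x$scores), length(x$measured), x$ssd_space))
  cat(sprintf("  selected by C1 & C2 & C3: %s\n",
              if (length(x$survivors)) paste(x$survivors, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
summary.fret_screen <- function(object, ...) {
  s <- object$scores
  ord <- order(s$ssd)
  out <- s[ord, c("model_id", grep("^e[0-9]+$", names(s), value = TRUE),
                  "ssd", "c1", "c2", "c3", "selected", "eliminated_by")]
  rownames(out) <- NULL
  structure(list(scores = out, measured = object$measured,
                 survivors = object$survivors),
            class = "summary.fret_screen")
}

#' @export
print.summary.fret_screen <- function(x, ...) {
  cat("Pose ranking by SSD against measured efficiencies:\n\n")
  print(x$scores, digits = 3)
  cat("\nMeasured: ",
      paste(sprintf("E(%s)=%.3f", names(x$measured), x$measured),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot predicted against measured efficiencies
#'
#' One line per pose across the label positions, with the measured values
#' overlaid as filled points; selected poses are drawn in colour, rejected
#' ones in grey.
#'
#' @param x A `"fret_screen"` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fret_screen <- function(x, ...) {
  s <- x$scores
  ecols <- grep("^e[0-9]+$", names(s), value = TRUE)
  pos <- as.numeric(sub("^e", "", ecols))
  pred <- t(as.matrix(s[ecols]))
  sel <- s$selected
  graphics::matplot(pos, pred, type = "l", lty = 1,
                    col = ifelse(sel, "firebrick", "grey70"),
                    xlab = "acceptor label position",
                    ylab = "FRET efficiency", ...)
  graphics::points(as.numeric(names(x$measured)), x$measured,
                   pch = 19, cex = 1.2)
  graphics::legend("topleft", bty = "n",
                   legend = c("measured", "selected pose", "rejected pose"),
                   pch = c(19, NA, NA), lty = c(NA, 1, 1),
                   col = c("black", "firebrick", "grey70"))
  invisible(x)
}
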