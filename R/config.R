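#' Validated run configuration
#'
#' Collects every tunable of the screening pipeline in one validated
#' object, so that a whole analysis can be parameterised from a single
#' YAML/JSON file ([read_run_config()]). Defaults are the values the
#' package was calibrated against: Förster radius 50 Å, excitation
#' 470 nm, contact cutoff 3 Å, grouping gap 15 residues, robustness
#' resampling over a 40-fold occupancy range.
#'
#' @param forster_radius Förster radius in Å.
#' @param excitation_wavelength Excitation wavelength in nm.
#' @param scheme A [labeling_scheme()].
#' @param ranges A [domain_ranges()].
#' @param contact_cutoff Contact cutoff in Å (> 0).
#' @param gap_threshold Region-grouping gap threshold (>= 0 residues).
#' @param ssd_space `"efficiency"` or `"distance"`.
#' @param robustness List with `n_samples`, `max_fold`, `seed`.
#' @param band_params Spectra band definitions, see [default_band_params()].
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(forster_radius = 50, excitation_wavelength = 470,
                       scheme = labeling_scheme(), ranges = domain_ranges(),
                       contact_cutoff = 3, gap_threshold = 15,
                       ssd_space = c("efficiency", "distance"),
                       robustness = list(n_samples = 100, max_fold = 40,
                                         seed = 1),
                       band_params = default_band_params()) {
  ssd_space <- match.arg(ssd_space)
  params <- fret_params(forster_radius, excitation_wavelength)
  stopifnot(inherits(scheme, "labeling_scheme"), inherits(ranges, "domain_ranges"))
  if (contact_cutoff <= 0) stop("'contact_cutoff' must be > 0", call. = FALSE)
  if (gap_threshold < 0) stop("'gap_threshold' must be >= 0", call. = FALSE)
  if (!all(c("n_samples", "max_fold", "seed") %in% names(robustness)))
    stop("'robustness' needs fields n_samples, max_fold, seed", call. = FALSE)
  if (robustness$max_fold < 1) stop("robustness max_fold must be >= 1",
                                    call. = FALSE)
  structure(list(params = params, scheme = scheme, ranges = ranges,
                 contact_cutoff = contact_cutoff,
                 gap_threshold = gap_threshold, ssd_space = ssd_space,
                 robustness = robustness, band_params = band_params),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: R =", x$params$forster_radius, "A, cutoff",
      x$contact_cutoff, "A, gap", x$gap_threshold,
      ", SSD in", x$ssd_space, "space\n")
  invisible(x)
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level scalar fields (`forster_radius`, `excitation_wavelength`,
#' `contact_cutoff`, `gap_threshold`, `ssd_space`, `robustness`) map
#' directly onto [run_config()] arguments; a `scheme` block is passed to
#' [labeling_scheme()] and a `domain_ranges` block to [domain_ranges()].
#'
#' @param path Path to the config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (f in c("forster_radius", "excitation_wavelength", "contact_cutoff",
              "gap_threshold", "ssd_space"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$robustness)) args$robustness <- cfg$robustness
  if (!is.null(cfg$scheme)) {
    if (!is.null(cfg$scheme$numbering_offset))
      cfg$scheme$numbering_offset <- unlist(cfg$scheme$numbering_offset)
    args$scheme <- do.call(labeling_scheme, cfg$scheme)
  }
  if (!is.null(cfg$domain_ranges))
    args$ranges <- do.call(domain_ranges, lapply(cfg$domain_ranges, unlist))
  unknown <- setdiff(names(cfg), c("forster_radius", "excitation_wavelength",
                                   "contact_cutoff", "gap_threshold",
                                   "ssd_space", "robustness", "scheme",
                                   "domain_ranges"))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, args)
}
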