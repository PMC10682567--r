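# End-to-end analysis workflows composing the record filters, range
# geometry, covariate construction and GLM fitting.

#' Geographic analysis pipeline for a single species
#'
#' Runs the full within-species workflow: the range model (center +
#' convex hull) is built from ALL coordinate-bearing records of the
#' species before any trait filtering; records are then filtered for the
#' requested model (elevation required, since it is a covariate); range
#' marginality is computed for the retained records against the
#' pre-filter range model; and the binomial presence model
#' (`which_model = "binary"`) or Poisson exserted-flower-count model
#' (`which_model = "count"`) is fitted on z-scored covariates.
#'
#' @param records Occurrence records of one species (a `species` column
#'   with a single value, or pass `species` to subset).
#' @param which_model `"binary"` or `"count"`.
#' @param species Optional species code used to subset `records`.
#' @param radius Sphere radius in meters for the distance computations.
#' @return List with `fit` (a `glm_fit`), `design`, `range_model`,
#'   `marginalities` (per retained record), `filter_report` and
#'   `records` (retained rows).
#' @export
run_geo_pipeline <- function(records, which_model = c("binary", "count"),
                             species = NULL, radius = earth_radius) {
  which_model <- match.arg(which_model)
  if (!is.null(species)) records <- records[records$species == species, , drop = FALSE]
  sp <- unique(records$species)
  if (length(sp) != 1) {
    stop("geographic models are per-species; got ", length(sp),
         " species (use the species argument)", call. = FALSE)
  }
  rmodel <- build_range_model(records, species = sp)
  flt <- apply_filters(records, which_model = which_model, require_elevation = TRUE)
  if (nrow(flt$records) == 0) stop("no records retained after filtering", call. = FALSE)
  marg <- marginality(flt$records$longitude, flt$records$latitude, rmodel, radius)
  design <- build_design(flt$records,
                         model = if (which_model == "binary") "geo_binary" else "geo_count",
                         marginalities = marg)
  fit <- fit_glm(design, family = if (which_model == "binary") "binomial" else "poisson")
  list(fit = fit, design = design, range_model = rmodel, marginalities = marg,
       filter_report = flt$report, records = flt$records)
}

#' Among-species analysis pipeline
#'
#' Filters all species' records for the requested model, fits the
#' species-effect model (species indicators with reference level
#' `inflata`, group-centered day of year, fruiting indicator, plus the
#' visible-flower control for counts), and computes estimated marginal
#' means and multiplicity-adjusted pairwise species contrasts.
#'
#' @param records Occurrence records of one or more species.
#' @param which_model `"binary"` or `"count"`.
#' @param adjust Contrast adjustment: `"mvn"` (single-step multivariate
#'   normal) or `"bonferroni"`.
#' @param seed Seed for the Monte-Carlo contrast adjustment.
#' @return List with `fit`, `design`, `filter_report`, `emmeans`
#'   (per-species marginal means) and `contrasts`.
#' @export
run_species_pipeline <- function(records, which_model = c("binary", "count"),
                                 adjust = c("mvn", "bonferroni"),
                                 seed = 20231127) {
  which_model <- match.arg(which_model)
  adjust <- match.arg(adjust)
  flt <- apply_filters(records, which_model = which_model, require_elevation = FALSE)
  if (nrow(flt$records) == 0) stop("no records retained after filtering", call. = FALSE)
  design <- build_design(flt$records,
                         model = if (which_model == "binary") "species_binary" else "species_count")
  fit <- fit_glm(design, family = if (which_model == "binary") "binomial" else "poisson")
  em <- marginal_means(fit)
  ct <- if (length(fit$params$species_levels) >= 2) {
    tukey_contrasts(fit, adjust = adjust, seed = seed)
  } else NULL
  list(fit = fit, design = design, filter_report = flt$report,
       emmeans = em, contrasts = ct)
}
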