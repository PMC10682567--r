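# Model covariates: day of year, z-score standardization (global and
# species-group-centered), and design matrices for the binary and count
# models.

#' Day of the year of a calendar date
#'
#' Ordinal day within the year, 1-based; leap years run to 366.
#'
#' @param date A `Date` vector or ISO-8601 (`YYYY-MM-DD`) character vector.
#' @return Integer vector of days of the year.
#' @export
day_of_year <- function(date) {
  if (is.character(date)) {
    parsed <- as.Date(date, format = "%Y-%m-%d")
    if (any(is.na(parsed) & !is.na(date))) stop("invalid date", call. = FALSE)
    date <- parsed
  }
  if (!inherits(date, "Date")) stop("invalid date", call. = FALSE)
  as.integer(lubridate::yday(date))
}

#' Z-score standardization with reusable parameters
#'
#' Centers and scales by the sample mean and sample standard deviation
#' (n - 1 denominator). When `params` is supplied the stored mean and sd
#' are applied instead of being re-estimated — this is how prediction
#' grids are put on the fitting-time scale.
#'
#' @param values Numeric vector.
#' @param params Optional list with `mean` and `sd` (e.g. from a previous
#'   call).
#' @param name Variable name used in error messages and stored in params.
#' @return List with `z` (standardized vector) and `params`
#'   (`name`, `scope`, `mean`, `sd`).
#' @export
zscore <- function(values, params = NULL, name = deparse(substitute(values))) {
  if (is.null(params)) {
    if (sum(!is.na(values)) < 2) {
      stop("need at least 2 values to standardize '", name, "'", call. = FALSE)
    }
    m <- mean(values, na.rm = TRUE)
    s <- stats::sd(values, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero standard deviation for '", name, "'", call. = FALSE)
    }
    params <- list(name = name, scope = "global", mean = m, sd = s,
                   min = min(values, na.rm = TRUE), max = max(values, na.rm = TRUE))
  }
  list(z = (values - params$mean) / params$sd, params = params)
}

#' Invert a z-score transform
#' @param z Standardized values.
#' @param params Parameter list from [zscore()].
#' @return Raw-scale values.
#' @export
unzscore <- function(z, params) z * params$sd + params$mean

#' Species-group-centered z-score standardization
#'
#' Standardizes within each group independently (each species' values are
#' centered and scaled by that species' own mean and sd), removing
#' between-species differences in, e.g., growing-season timing.
#'
#' @param values Numeric vector.
#' @param groups Group labels (species codes), same length as `values`.
#' @param params Optional list of per-group params from a previous call.
#' @param name Variable name for error messages.
#' @return List with `z` and `params` (named list of per-group
#'   mean/sd parameter lists; `scope = "by_species"`).
#' @export
group_zscore <- function(values, groups, params = NULL,
                         name = deparse(substitute(values))) {
  groups <- as.character(groups)
  z <- rep(NA_real_, length(values))
  if (is.null(params)) {
    params <- list()
    for (g in unique(groups)) {
      idx <- groups == g
      fit <- tryCatch(zscore(values[idx], name = paste0(name, "[", g, "]")),
                      error = function(e) stop(conditionMessage(e), call. = FALSE))
      z[idx] <- fit$z
      params[[g]] <- fit$params
    }
  } else {
    for (g in unique(groups)) {
      if (is.null(params[[g]])) stop("no stored params for group '", g, "'",
                                     call. = FALSE)
      idx <- groups == g
      z[idx] <- (values[idx] - params[[g]]$mean) / params[[g]]$sd
    }
  }
  attr(params, "scope") <- "by_species"
  list(z = z, params = params)
}

design_model_types <- c("geo_binary", "geo_count", "species_binary", "species_count")

#' Build a model design matrix from filtered records
#'
#' Constructs the response and standardized predictor columns for the
#' four model families:
#' \describe{
#'   \item{geo_binary}{response = exsertion present (0/1); predictors
#'     z_latitude, z_marginality, z_longitude, z_elevation, z_day_of_year,
#'     fruit_indicator.}
#'   \item{geo_count}{response = number of exserted flowers on present
#'     records; geo_binary predictors plus z_total_visible_flowers.}
#'   \item{species_binary}{response as geo_binary; predictors species
#'     indicators (reference level `inflata`), species-group-centered
#'     z_day_of_year, fruit_indicator.}
#'   \item{species_count}{species_binary predictors plus
#'     z_total_visible_flowers.}
#' }
#' All numeric predictors are z-scored on the model's own fitting subset;
#' day of year is group-centered by species in the species models. The
#' fruit indicator is kept 0/1 (not standardized). Standardization
#' parameters are returned so prediction grids can reuse them.
#'
#' @param records Records already filtered for the requested model (see
#'   [apply_filters()]).
#' @param model One of `"geo_binary"`, `"geo_count"`, `"species_binary"`,
#'   `"species_count"`.
#' @param marginalities For geo models: tibble from [marginality()]
#'   aligned row-for-row with `records` (or a numeric vector of `r`).
#' @return A list of class `design_matrix`: `response`, `X` (numeric
#'   matrix without intercept), `model`, `params` (named list of
#'   standardization parameter sets plus `fruit_mean`), `species`
#'   (per-row labels), `records`.
#' @export
build_design <- function(records, model = design_model_types, marginalities = NULL) {
  model <- match.arg(model)
  is_geo <- model %in% c("geo_binary", "geo_count")
  is_count <- model %in% c("geo_count", "species_count")
  n <- nrow(records)
  if (n == 0) stop("no records to build a design from", call. = FALSE)

  response <- if (is_count) {
    if (any(records$exsertion_score != "present") || any(is.na(records$n_exserted_flowers))) {
      stop("count models require present records with recorded exserted counts; ",
           "run apply_filters(which_model = 'count') first", call. = FALSE)
    }
    as.numeric(records$n_exserted_flowers)
  } else {
    as.numeric(records$exsertion_score == "present")
  }

  doy <- day_of_year(records$observation_date)
  fruit <- as.numeric(records$fruit_present == "yes")
  params <- list(fruit_mean = mean(fruit))
  cols <- list()

  if (is_geo) {
    if (any(is.na(records$elevation))) {
      stop("geographic models use elevation as a covariate; filter with ",
           "require_elevation = TRUE first", call. = FALSE)
    }
    marg <- if (is.null(marginalities)) {
      stop("geo models need per-record marginalities", call. = FALSE)
    } else if (is.data.frame(marginalities)) marginalities$r else marginalities
    if (length(marg) != n) {
      stop("marginalities must align row-for-row with records", call. = FALSE)
    }
    for (spec in list(list("z_latitude", records$latitude),
                      list("z_marginality", marg),
                      list("z_longitude", records$longitude),
                      list("z_elevation", records$elevation),
                      list("z_day_of_year", doy))) {
      zs <- zscore(spec[[2]], name = spec[[1]])
      cols[[spec[[1]]]] <- zs$z
      params[[spec[[1]]]] <- zs$params
    }
    cols$fruit_indicator <- fruit
  } else {
    sp <- factor(records$species, levels = lobelia_species)
    sp <- droplevels(sp)
    if (!"inflata" %in% levels(sp)) {
      sp <- factor(sp, levels = levels(sp))
    } else {
      sp <- stats::relevel(sp, ref = "inflata")
    }
    if (nlevels(sp) > 1) {
      mm <- stats::model.matrix(~sp)[, -1, drop = FALSE]
      colnames(mm) <- paste0("species_", levels(sp)[-1])
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    }
    gz <- group_zscore(doy, records$species, name = "z_day_of_year")
    cols$z_day_of_year <- gz$z
    params$z_day_of_year <- gz$params
    cols$fruit_indicator <- fruit
    params$species_levels <- levels(sp)
  }

  if (is_count) {
    zs <- zscore(as.numeric(records$n_visible_flowers), name = "z_total_visible_flowers")
    cols$z_total_visible_flowers <- zs$z
    params$z_total_visible_flowers <- zs$params
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X) || anyNA(response)) {
    stop("design matrix contains missing values", call. = FALSE)
  }
  structure(list(response = response, X = X, model = model, params = params,
                 species = records$species, records = records),
            class = "design_matrix")
}

#' Serialize standardization parameters to a JSON sidecar
#'
#' Saves (or restores) the fitting-time standardization parameters so
#' prediction grids can be put on the identical scale later.
#'
#' @param params The `params` element of a [build_design()] result.
#' @param path File path.
#' @return `path` invisibly for write; the parameter list for read.
#' @export
write_standardization <- function(params, path) {
  # 17 significant digits round-trip IEEE doubles bit-identically
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
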