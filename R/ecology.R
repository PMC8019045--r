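# Monthly food-availability indices from phenology scores and species basal
# areas, aligned with rainfall and standardized for modeling.
#
# FAI(month, part) = sum over species of mean monthly phenology score for
# that part times the species' total basal area. "fruit" pools ripe and
# unripe fruit with equal weight (a ripeness weighting is available);
# "young_leaf" uses young leaves only.

part_group_levels <- function(part_group, ripe_weight = 1, unripe_weight = 1) {
  switch(part_group,
    fruit = c(ripe_fruit = ripe_weight, unripe_fruit = unripe_weight),
    young_leaf = c(young_leaf = 1),
    stop("unknown part group: ", part_group, call. = FALSE)
  )
}

#' Mean monthly phenology score for one species
#'
#' Mean score over the species' sampled trees for the month, pooling the
#' plant parts of the group (`"fruit"` = ripe + unripe fruit,
#' `"young_leaf"` = young leaves). A species-month with no records is
#' missing (`NA`), not zero.
#'
#' @param phenology phenology tibble (see [read_phenology()]).
#' @param species species identifier.
#' @param month `"YYYY-MM"`.
#' @param part_group `"fruit"` or `"young_leaf"`.
#' @param ripe_weight,unripe_weight optional ripeness weights for the fruit
#'   pool.
#' @return mean score in `[0, 4]` (weights 1), or `NA` if unsampled.
#' @export
monthly_species_score <- function(phenology, species, month, part_group,
                                  ripe_weight = 1, unripe_weight = 1) {
  w <- part_group_levels(part_group, ripe_weight, unripe_weight)
  rows <- phenology[phenology$species == species & phenology$month == month &
                      phenology$plant_part %in% names(w), ]
  if (!nrow(rows)) return(NA_real_)
  mean(rows$score * unname(w[rows$plant_part]))
}

#' Food availability index for one month
#'
#' Sum over species of mean monthly phenology score times the species' total
#' basal area. Species scored in the phenology but missing a basal area are
#' an error under `strict = TRUE`; species without a score that month
#' contribute 0 with a warning (a tree bearing nothing adds nothing).
#'
#' @inheritParams monthly_species_score
#' @param basal_areas basal-area tibble (see [read_basal_areas()]).
#' @param strict error on species missing from the basal-area table.
#' @return FAI, a non-negative real (score scale x m^2).
#' @export
food_availability_index <- function(phenology, basal_areas, part_group, month,
                                    strict = TRUE, ripe_weight = 1,
                                    unripe_weight = 1) {
  w <- part_group_levels(part_group, ripe_weight, unripe_weight)
  species <- unique(phenology$species[phenology$plant_part %in% names(w)])
  unknown <- setdiff(species, basal_areas$species)
  if (length(unknown)) {
    if (strict) {
      stop("species without basal area: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    species <- setdiff(species, unknown)
  }
  scores <- vapply(species, monthly_species_score, 1, phenology = phenology,
                   month = month, part_group = part_group,
                   ripe_weight = ripe_weight, unripe_weight = unripe_weight)
  if (anyNA(scores)) {
    warning(sprintf("%d species without a %s score in %s contribute 0",
                    sum(is.na(scores)), part_group, month), call. = FALSE)
    scores[is.na(scores)] <- 0
  }
  ba <- basal_areas$basal_area_m2[match(species, basal_areas$species)]
  sum(scores * ba)
}

#' Build the monthly covariate table
#'
#' Joins fruit FAI, young-leaf FAI and rainfall by month and standardizes
#' each over the included months (z-scores with population SD). Months
#' missing from any series are an error unless `interpolate = TRUE`, which
#' fills gaps linearly. Pairwise covariate correlations above |r| = 0.7 --
#' the usual multicollinearity threshold -- trigger a warning.
#'
#' @param phenology,basal_areas,rainfall input tibbles.
#' @param months `"YYYY-MM"` months to cover (defaults to the rainfall months).
#' @param interpolate linearly fill missing months instead of failing.
#' @param strict passed to [food_availability_index()].
#' @return tibble `month`, `fruit_fai`, `leaf_fai`, `rainfall_mm`, `z_fruit`,
#'   `z_leaf`, `z_rain`, with the correlation matrix in attribute
#'   `"covariate_cor"`. A constant series yields `NA` z-scores with a warning.
#' @export
build_covariates <- function(phenology, basal_areas, rainfall, months = NULL,
                             interpolate = FALSE, strict = TRUE) {
  if (is.null(months)) months <- sort(unique(rainfall$month))
  months <- as.character(months)
  fai <- function(part_group) {
    vapply(months, function(m) {
      has <- any(phenology$month == m)
      if (!has) return(NA_real_)
      food_availability_index(phenology, basal_areas, part_group, m,
                              strict = strict)
    }, 1)
  }
  out <- tibble::tibble(
    month = months,
    fruit_fai = unname(fai("fruit")),
    leaf_fai = unname(fai("young_leaf")),
    rainfall_mm = rainfall$rainfall_mm[match(months, rainfall$month)]
  )
  for (col in c("fruit_fai", "leaf_fai", "rainfall_mm")) {
    if (anyNA(out[[col]])) {
      if (!interpolate) {
        stop("month gaps in `", col,
             "`; set interpolate = TRUE to fill linearly", call. = FALSE)
      }
      ok <- which(!is.na(out[[col]]))
      if (!length(ok)) stop("`", col, "` has no observed months", call. = FALSE)
      out[[col]] <- if (length(ok) == 1) {
        rep(out[[col]][ok], length(months))
      } else {
        stats::approx(seq_along(months), out[[col]],
                      xout = seq_along(months), rule = 2)$y
      }
    }
  }
  out$z_fruit <- unname(z_pop(out$fruit_fai))
  out$z_leaf <- unname(z_pop(out$leaf_fai))
  out$z_rain <- unname(z_pop(out$rainfall_mm))
  if (anyNA(out$z_fruit) || anyNA(out$z_leaf) || anyNA(out$z_rain)) {
    warning("constant covariate series: z-scores undefined", call. = FALSE)
  }
  cm <- stats::cor(as.matrix(out[, c("fruit_fai", "leaf_fai", "rainfall_mm")]))
  off <- abs(cm[upper.tri(cm)])
  if (any(off > 0.7, na.rm = TRUE)) {
    warning(sprintf(
      "covariate correlation |r| = %.2f exceeds 0.7: multicollinearity risk",
      max(off, na.rm = TRUE)), call. = FALSE)
  }
  attr(out, "covariate_cor") <- cm
  out
}

#' @rdname build_covariates
#' @param covariates covariate tibble.
#' @param path output CSV path.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(as.data.frame(covariates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
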