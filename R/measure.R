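#' Measure one rosette
#'
#' Converts a damage mask and a rosette mask into physical areas: the damage
#' mask is first intersected with the rosette mask (damage outside the plant
#' cannot count), then `DA = damaged pixels x pixel area` and
#' `TA = rosette pixels x pixel area`.
#'
#' @param damage_mask Logical damage mask (same shape as the rosette mask).
#' @param rosette A `rosette_mask` from [segment_rosette()].
#' @param dpi Resolution; defaults to the rosette mask's.
#' @param rosette_id,genotype,treatment,condition_id,background Metadata
#'   carried into the measurement row.
#' @return One-row tibble: `rosette_id`, `genotype`, `treatment`
#'   (`"control"` or `"infested"`), `condition_id`, `background`,
#'   `total_area_mm2`, `damage_area_mm2`.
#' @export
measure <- function(damage_mask, rosette, dpi = rosette$dpi,
                    rosette_id = NA_character_, genotype = NA_character_,
                    treatment = c("control", "infested"),
                    condition_id = NA_character_,
                    background = NA_character_) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(rosette, "rosette_mask"),
            identical(dim(damage_mask), dim(rosette$mask)))
  if (!any(rosette$mask)) abort("empty rosette mask.", class = "mitedamage_no_plant")
  pa <- pixel_area_mm2(dpi)
  tibble::tibble(
    rosette_id = rosette_id,
    genotype = genotype,
    treatment = treatment,
    condition_id = condition_id,
    background = background,
    total_area_mm2 = sum(rosette$mask) * pa,
    damage_area_mm2 = sum(damage_mask & rosette$mask) * pa
  )
}

#' Fit the control-rosette correction
#'
#' Controls carry no real damage, so whatever fraction of their area a method
#' marks damaged is systematic error. The correction model is the mean
#' control damage fraction
#' `x_bar_c = mean(DA_ci / TA_ci)` over the `n` control rosettes of one
#' (genotype, condition, background) group — controls must have been analysed
#' under the same thresholds and conditions as the treated plants they
#' correct, so mixed groups are rejected.
#'
#' @param controls Measurement tibble (see [measure()]) of control rosettes
#'   only, from a single (genotype, condition_id, background) group.
#' @return A `correction_model`: `mean_control_fraction`, `n_controls`, plus
#'   the group keys.
#' @export
fit_correction <- function(controls) {
  if (!is.data.frame(controls) || nrow(controls) == 0L) {
    abort("`controls` must be a non-empty measurement table.")
  }
  if (!all(controls$treatment == "control")) {
    abort("all rows must be control measurements.")
  }
  for (key in c("genotype", "condition_id", "background")) {
    if (dplyr::n_distinct(controls[[key]]) > 1L) {
      abort(
        sprintf("controls span several `%s` values; fit one model per group.", key),
        class = "mitedamage_mixed_group"
      )
    }
  }
  structure(
    list(
      mean_control_fraction = mean(controls$damage_area_mm2 / controls$total_area_mm2),
      n_controls = nrow(controls),
      genotype = controls$genotype[1],
      condition_id = controls$condition_id[1],
      background = controls$background[1]
    ),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> %s / %s / %s: mean control fraction %.4f (n = %d)\n",
    x$genotype, x$condition_id, x$background,
    x$mean_control_fraction, x$n_controls
  ))
  invisible(x)
}

#' @export
tidy.correction_model <- function(x, ...) {
  tibble::tibble(
    genotype = x$genotype,
    condition_id = x$condition_id,
    background = x$background,
    mean_control_fraction = x$mean_control_fraction,
    n_controls = x$n_controls
  )
}

#' Apply the control correction to treated measurements
#'
#' Each treated rosette's corrected damaged area is
#' `A_i = DA_ti - x_bar_c * TA_ti`: the mean control damage fraction scaled
#' by the rosette's own total area is subtracted from its uncorrected damage.
#' When the subtraction is non-positive — the method found more damage in the
#' controls than here — the value cannot be interpreted and the rosette is
#' retained as an explicit missing record with status
#' `dropped_nonpositive`, so downstream statistics can report attrition
#' rather than silently losing rows.
#'
#' @param treated Measurement tibble of infested rosettes from the model's
#'   (genotype, condition_id, background) group.
#' @param model A [fit_correction()] model.
#' @return The input tibble plus `corrected_area_mm2` (NA when dropped) and
#'   `status` (`"ok"` or `"dropped_nonpositive"`).
#' @export
apply_correction <- function(treated, model) {
  stopifnot(inherits(model, "correction_model"))
  if (!all(treated$treatment == "infested")) {
    abort("all rows must be infested measurements.")
  }
  for (key in c("genotype", "condition_id", "background")) {
    both <- c(treated[[key]], model[[key]])
    if (dplyr::n_distinct(both[!is.na(both)]) > 1L) {
      abort(
        sprintf("treated `%s` does not match the correction model's group.", key),
        class = "mitedamage_mixed_group"
      )
    }
  }
  a <- treated$damage_area_mm2 - model$mean_control_fraction * treated$total_area_mm2
  dplyr::mutate(
    treated,
    corrected_area_mm2 = ifelse(a > 0, a, NA_real_),
    status = ifelse(a > 0, "ok", "dropped_nonpositive")
  )
}

#' Group-wise control correction
#'
#' Convenience wrapper over [fit_correction()] / [apply_correction()]: for
#' every (genotype, condition_id, background) group a correction model is
#' fitted on the group's controls and applied to its infested rosettes.
#' Groups without controls are an error (they cannot be corrected).
#'
#' @param measurements Measurement tibble mixing control and infested rows.
#' @return Corrected tibble of the infested rows (see [apply_correction()]),
#'   with the per-group mean control fraction joined on as
#'   `mean_control_fraction`.
#' @export
correct_damage <- function(measurements) {
  grp <- dplyr::group_split(
    dplyr::group_by(measurements, .data$genotype, .data$condition_id,
                    .data$background)
  )
  out <- purrr::map(grp, function(g) {
    ctl <- dplyr::filter(g, .data$treatment == "control")
    trt <- dplyr::filter(g, .data$treatment == "infested")
    if (nrow(trt) == 0L) return(NULL)
    if (nrow(ctl) == 0L) {
      abort(
        sprintf(
          "no controls for group %s / %s / %s.",
          g$genotype[1], g$condition_id[1], g$background[1]
        ),
        class = "mitedamage_no_controls"
      )
    }
    model <- fit_correction(ctl)
    dplyr::mutate(
      apply_correction(trt, model),
      mean_control_fraction = model$mean_control_fraction
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    warning("no infested measurements to correct; returning an empty table.")
  }
  res
}
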