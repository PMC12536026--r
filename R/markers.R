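#' DTI-ALPS index
#'
#' Diffusivity ratio "analysis along the perivascular space". At the level
#' of the lateral ventricle body, perivascular spaces run along the x axis,
#' perpendicular to both projection fibers (z) and association fibers (y);
#' free water movement along the perivascular space inflates x-axis
#' diffusivity in those two fiber regions relative to the diffusivities
#' across the fibers:
#'
#' `ALPS = (Dxx_proj + Dxx_assoc) / (Dyy_proj + Dzz_assoc)`
#'
#' A lower index indicates restricted perivascular flow. The index is
#' unit-free; inputs are conventionally in 10^-3 mm^2/s.
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc Positive diffusivities.
#'   Each may be a vector of length 1 (single ROI set) or 2 (left and right
#'   hemisphere); vectors of equal length > 1 are treated as hemispheres /
#'   repeated ROI sets.
#' @param mode `"per_hemisphere_mean"` (default): one ratio per hemisphere,
#'   then the mean; `"pooled"`: average each diffusivity across hemispheres
#'   first, then a single ratio. The two agree exactly when hemispheres are
#'   identical.
#' @return The ALPS index (dimensionless scalar).
#' @examples
#' alps_index(1.4, 1.2, 1.0, 1.0)  # 1.3
#' @export
alps_index <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc,
                       mode = c("per_hemisphere_mean", "pooled")) {
  mode <- match.arg(mode)
  d <- cbind(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (anyNA(d) || any(d <= 0)) stop("all diffusivities must be positive")
  if (mode == "per_hemisphere_mean") {
    mean((d[, 1] + d[, 2]) / (d[, 3] + d[, 4]))
  } else {
    m <- colMeans(d)
    (m[[1]] + m[[2]]) / (m[[3]] + m[[4]])
  }
}

#' Choroid plexus volume fraction
#'
#' Choroid plexus volume as a percentage of total intracranial volume,
#' `100 * cpv / tiv`. Normalizing by TIV removes head-size differences; the
#' choroid plexus produces CSF, and an enlarged fraction accompanies
#' glymphatic dysfunction.
#'
#' @param cpv Choroid plexus volume in ml (> 0, < `tiv`).
#' @param tiv Total intracranial volume in ml (> 0).
#' @return CPV fraction in percent.
#' @examples
#' cpv_fraction(1.6, 1600)  # 0.1
#' @export
cpv_fraction <- function(cpv, tiv) {
  if (anyNA(c(cpv, tiv)) || any(cpv <= 0) || any(tiv <= 0)) {
    stop("volumes must be positive")
  }
  if (any(cpv >= tiv)) stop("choroid plexus volume must be smaller than TIV")
  100 * cpv / tiv
}

#' ALS progression rate (delta FS)
#'
#' `(48 - ALSFRS-R) / disease duration`: functional points lost per month
#' since symptom onset, assuming a full score of 48 at onset.
#'
#' @param alsfrs_r ALSFRS-R score in points, within \[0, 48\].
#' @param duration_months Disease duration in months (> 0).
#' @return Progression rate in points per month.
#' @examples
#' progression_rate(33.2, 14.8)  # 1.0
#' @export
progression_rate <- function(alsfrs_r, duration_months) {
  if (anyNA(c(alsfrs_r, duration_months))) stop("inputs must not be missing")
  if (any(alsfrs_r < 0 | alsfrs_r > 48)) {
    stop("ALSFRS-R must lie within [0, 48]")
  }
  if (any(duration_months <= 0)) stop("disease duration must be positive")
  (48 - alsfrs_r) / duration_months
}

#' ALPS indices for a per-hemisphere diffusivity table
#'
#' Applies [alps_index()] subject by subject to a long-format ROI
#' diffusivity table.
#'
#' @param diffusivities A data.frame with columns `subject_id`,
#'   `hemisphere`, `dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc` (one row
#'   per subject and hemisphere).
#' @param mode Bilateral combining rule, see [alps_index()].
#' @return A data.frame `subject_id`, `alps_index`.
#' @export
alps_table <- function(diffusivities, mode = c("per_hemisphere_mean", "pooled")) {
  mode <- match.arg(mode)
  need <- c("subject_id", "hemisphere", "dxx_proj", "dxx_assoc",
            "dyy_proj", "dzz_assoc")
  miss <- setdiff(need, names(diffusivities))
  if (length(miss)) {
    stop("diffusivity table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ids <- unique(diffusivities$subject_id)
  alps <- vapply(ids, function(id) {
    d <- diffusivities[diffusivities$subject_id == id, , drop = FALSE]
    alps_index(d$dxx_proj, d$dxx_assoc, d$dyy_proj, d$dzz_assoc, mode = mode)
  }, numeric(1))
  data.frame(subject_id = ids, alps_index = unname(alps))
}
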