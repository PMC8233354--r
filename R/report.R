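#' Log-linear richness-biomass fit
#'
#' Ordinary least squares of community biomass on the natural log of species
#' richness. Fitted at the community-composition level by default (each
#' unique composition contributes its mean plot total as one point), with
#' plot-level fitting available.
#'
#' @param records Either a long table with `community_id`, `richness`,
#'   `replicate`, `biomass_g` (summed to plot totals, then averaged per
#'   community) or a data.frame already holding one `total_g` per
#'   `community_id` with `richness`.
#' @param level `"community"` (default) or `"plot"`.
#' @return A list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `F`, `df1`, `df2`, `p_value`, `n`, plus
#'   `predicted` (per-richness predicted means).
#' @export
loglinear_richness_fit <- function(records, level = c("community", "plot")) {
  level <- match.arg(level)
  if (!"total_g" %in% names(records)) {
    tot <- stats::aggregate(biomass_g ~ community_id + richness + replicate,
                            records, sum)
    names(tot)[names(tot) == "biomass_g"] <- "total_g"
  } else tot <- records
  if (level == "community")
    tot <- stats::aggregate(total_g ~ community_id + richness, tot, mean)
  if (length(unique(tot$richness)) < 2)
    stop("need at least two richness levels to fit")
  fit <- stats::lm(total_g ~ log(richness), data = tot)
  out <- regression_fit(fit, tot$total_g)
  levels <- sort(unique(tot$richness))
  out$predicted <- data.frame(
    richness = levels,
    total_g = as.numeric(stats::predict(fit,
                                        data.frame(richness = levels))))
  out
}

# package lm output into the flat fit structure used throughout
regression_fit <- function(fit, y) {
  s <- summary(fit)
  fstat <- s$fstatistic
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    n = length(y)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.3f x + %.3f  (R2 = %.3f, F%d,%d = %.2f, P = %.3g, RMSE = %.2f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$df1, x$df2, x$F,
              x$p_value, x$rmse, x$n))
  invisible(x)
}

#' Predicted-versus-observed regression
#'
#' OLS of observed community biomass on model-predicted biomass, paired by
#' community; reports slope, intercept, R^2, RMSE of the residuals and the
#' slope F-test. Optionally refits after dropping the communities with the
#' largest observed biomass.
#'
#' @param predicted,observed Paired numeric vectors (same community order).
#' @param drop_largest Number of largest-observed communities to exclude
#'   before fitting (default 0).
#' @return A `regression_fit`.
#' @export
predicted_vs_observed <- function(predicted, observed, drop_largest = 0L) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must be paired (equal length)")
  if (drop_largest > 0) {
    keep <- rank(-observed, ties.method = "first") > drop_largest
    predicted <- predicted[keep]; observed <- observed[keep]
  }
  fit <- stats::lm(observed ~ predicted)
  regression_fit(fit, observed)
}

#' Cover-to-biomass conversion
#'
#' Calibrates a per-species through-origin regression `biomass = beta *
#' cover` on paired cover/biomass observations (zero cover must mean zero
#' biomass) and applies it to new cover values. Species with fewer than
#' `min_pairs` calibration pairs fall back to the pooled slope.
#'
#' @param cover_pct Cover values to convert.
#' @param species Species code for each element of `cover_pct`.
#' @param calibration data.frame `species`, `cover_pct`, `biomass_g`.
#' @param min_pairs Minimum calibration pairs for a species-specific slope.
#' @return Numeric vector of biomass (g); attribute `"beta"` holds the
#'   per-species slopes used.
#' @export
#' @examples
#' cal <- data.frame(species = "Ag", cover_pct = c(10, 20, 30),
#'                   biomass_g = c(20, 40, 60))
#' cover_to_biomass(15, "Ag", cal)  # 30
cover_to_biomass <- function(cover_pct, species, calibration,
                             min_pairs = 3L) {
  if (all(calibration$cover_pct == 0))
    stop("calibration cover values are all zero")
  beta_of <- function(cv, bm) {
    if (sum(cv^2) == 0) return(NA_real_)
    max(0, sum(cv * bm) / sum(cv^2))  # through-origin OLS, slope >= 0
  }
  pooled <- beta_of(calibration$cover_pct, calibration$biomass_g)
  betas <- vapply(split(calibration, calibration$species), function(d) {
    if (nrow(d) < min_pairs) return(pooled)
    b <- beta_of(d$cover_pct, d$biomass_g)
    if (is.na(b)) pooled else b
  }, numeric(1))
  b <- ifelse(species %in% names(betas), betas[species], pooled)
  out <- unname(b) * cover_pct
  attr(out, "beta") <- betas
  out
}

#' Overyielding arithmetic for a report
#'
#' The plain arithmetic a results section reports from a monoculture mean
#' and a high-richness mean: the absolute difference and the percent
#' increase in biomass production.
#'
#' @param monoculture_mean,mixture_mean Mean community biomass (g m^-2).
#' @return List: `difference`, `percent_increase`.
#' @export
#' @examples
#' overyielding_summary(55.6, 187.3)  # +131.7 g, +237%
overyielding_summary <- function(monoculture_mean, mixture_mean) {
  if (monoculture_mean <= 0) stop("monoculture mean must be positive")
  d <- mixture_mean - monoculture_mean
  list(difference = d, percent_increase = 100 * d / monoculture_mean)
}

#' Share of observed overyielding explained by a model
#'
#' @param predicted_gain Model-predicted mixture-minus-monoculture gain.
#' @param observed_gain Observed gain (or mean of gains across experiments).
#' @return Percent of the observed overyielding the prediction accounts for.
#' @export
share_of_overyielding <- function(predicted_gain, observed_gain) {
  if (observed_gain == 0) stop("observed gain is zero")
  100 * predicted_gain / observed_gain
}

#' Reported biomass means of the original field study (synthesis table)
#'
#' Mean monoculture and 16-species community biomass (g m^-2) and the
#' 16-species complementarity and selection components reported by the
#' tallgrass-prairie field study this package's methods are designed around:
#' its two biodiversity-productivity experiments (established 2014 and
#' 1997, both harvested after four years) and its feedback and null
#' simulation-model predictions. Used by the reporting layer to reproduce
#' the study's summary arithmetic; all other numbers in this package are
#' computed, not stored.
#'
#' @return data.frame: `dataset`, `monoculture_g`, `sixteen_species_g`,
#'   `complementarity_16_g`, `selection_16_g`.
#' @export
field_summary <- function() {
  data.frame(
    dataset = c("field_2014", "field_1997", "psf_model", "null_model"),
    monoculture_g = c(55.6, 78.5, 60.1, 60.7),
    sixteen_species_g = c(187.3, 183.4, 76.1, 70.7),
    complementarity_16_g = c(172.5, 84.5, 15.0, -1.5),
    selection_16_g = c(-40.8, 10.5, 1.0, 11.8),
    stringsAsFactors = FALSE
  )
}

#' Overyielding report across datasets
#'
#' Applies [overyielding_summary()] to each row of a summary table and
#' computes each model dataset's gain as a share of the mean observed field
#' gain.
#'
#' @param summary_table A table shaped like [field_summary()].
#' @return data.frame with `difference`, `percent_increase` and (for model
#'   rows) `share_of_observed_pct` per dataset.
#' @export
overyielding_report <- function(summary_table = field_summary()) {
  rows <- lapply(seq_len(nrow(summary_table)), function(i) {
    o <- overyielding_summary(summary_table$monoculture_g[i],
                              summary_table$sixteen_species_g[i])
    data.frame(dataset = summary_table$dataset[i],
               difference = o$difference,
               percent_increase = o$percent_increase,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  obs <- grepl("^field", out$dataset)
  mean_obs_gain <- mean(out$difference[obs])
  out$share_of_observed_pct <- ifelse(
    obs, NA_real_,
    vapply(out$difference,
           share_of_overyielding, numeric(1), observed_gain = mean_obs_gain))
  out
}
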