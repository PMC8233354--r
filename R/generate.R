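#' Generate a synthetic factorial PSF experiment
#'
#' Produces one plot-level biomass record per replicate plot of the
#' soil-training design, for both response years. Biomass is
#' `base_biomass * effect * lognormal noise`; untrained control soils have
#' effect 1, and first-year effects are attenuated towards 1 by the model's
#' `year_attenuation`, so feedbacks strengthen from the first to the second
#' response year. A `cover_pct` column is included, proportional to biomass
#' within species, so the cover-to-biomass calibration can be exercised.
#'
#' @param model A [true_psf_model()].
#' @param design A [default_design()] (or modified copy).
#' @param years Two response years; the first uses attenuated effects.
#' @return A data.frame with columns `experiment` (`"psf"`), `species`,
#'   `soil_type` (a training-species code, `"self"` or `"control"`),
#'   `replicate`, `year`, `biomass_g`, `cover_pct`. Deterministic given
#'   `model$seed`.
#' @export
#' @examples
#' rec <- generate_psf_experiment(true_psf_model(seed = 1), default_design())
#' head(rec)
generate_psf_experiment <- function(model, design = default_design(),
                                    years = c(2017L, 2018L)) {
  stopifnot(inherits(model, "true_psf_model"), inherits(design, "psf_design"))
  codes <- model$pool$code
  sigma <- model$noise_sigma
  att <- model$year_attenuation

  # one design row per plot: species, soil_type, replicate
  plots <- rbind(
    data.frame(species = rep(codes, design$self_replicates[codes]),
               soil_type = "self", stringsAsFactors = FALSE),
    do.call(rbind, lapply(codes, function(sp) {
      soils <- setdiff(codes, sp)
      data.frame(species = rep(sp, sum(design$other_replicates[sp, soils])),
                 soil_type = rep(soils, design$other_replicates[sp, soils]),
                 stringsAsFactors = FALSE)
    })),
    data.frame(species = rep(codes, design$control_replicates[codes]),
               soil_type = "control", stringsAsFactors = FALSE)
  )
  plots$replicate <- stats::ave(seq_len(nrow(plots)),
                                plots$species, plots$soil_type,
                                FUN = seq_along)

  eff <- function(sp, soil, attenuation) {
    col <- ifelse(soil == "self", sp, soil)
    col[soil == "control"] <- sp[soil == "control"]  # dummy; effect forced to 1
    e <- model$effect[cbind(sp, col)]
    e[soil == "control"] <- 1
    1 + attenuation * (e - 1)
  }
  out <- with_seed(model$seed, {
    do.call(rbind, lapply(seq_along(years), function(k) {
      a <- if (k == 1L) att else 1
      mu <- model$base_biomass[plots$species] *
        eff(plots$species, plots$soil_type, a)
      noise <- if (sigma > 0) exp(stats::rnorm(nrow(plots), 0, sigma)) else 1
      data.frame(experiment = "psf", plots[, c("species", "soil_type",
                                               "replicate")],
                 year = years[k], biomass_g = unname(mu * noise),
                 stringsAsFactors = FALSE)
    }))
  })
  # cover proportional to biomass within species (per-species slope)
  beta <- model$base_biomass / 50
  out$cover_pct <- out$biomass_g / beta[out$species]
  rownames(out) <- NULL
  out
}

#' Growth parameters implied by the ground-truth model
#'
#' The parameter set the community generator runs forward, and the target
#' the analysis-side rate derivation should recover on noiseless data:
#' per-soil rates inverted from `base_biomass * effect` over one season,
#' species-level carrying capacities at twice the base biomass.
#'
#' @inheritParams generate_community_experiment
#' @param b0 Total seeded biomass (g).
#' @return A [growth_params()] set.
#' @export
true_growth_params <- function(model, schedule = sim_schedule(),
                               conversion = 0.01, b0 = 1) {
  codes <- model$pool$code
  n <- length(codes)
  phase2 <- model$effect * matrix(model$base_biomass, n, n)  # 2-yr biomass
  r <- (phase2 / b0)^(1 / schedule$steps_per_season) - 1
  r <- cbind(r, background = (model$base_biomass / b0)^
               (1 / schedule$steps_per_season) - 1)
  growth_params(r, K = 2 * model$base_biomass, K_mode = "species_K",
                conversion = conversion, b0 = b0)
}

#' Generate a synthetic biodiversity-productivity experiment
#'
#' Runs the soil-conditioning community simulator forward under the
#' ground-truth model's growth rates (species-level carrying capacities at
#' twice the base biomass) for every community in the design, then adds
#' multiplicative lognormal plot noise to each species' biomass in each
#' replicate plot.
#'
#' @inheritParams generate_psf_experiment
#' @param schedule Simulation schedule (see [sim_schedule()]).
#' @param conversion Plant-to-microbe conversion factor of the ground truth.
#' @param year Calendar year stamped on the records.
#' @return A data.frame with columns `experiment` (`"community"`),
#'   `community_id`, `richness`, `replicate`, `species`, `year`,
#'   `biomass_g`, `plot_total_g`. Deterministic given `model$seed`.
#' @export
generate_community_experiment <- function(model, design = default_design(),
                                          schedule = sim_schedule(),
                                          conversion = 0.01, year = 2018L) {
  stopifnot(inherits(model, "true_psf_model"), inherits(design, "psf_design"))
  unknown <- setdiff(design$membership$species, model$pool$code)
  if (length(unknown))
    stop("unknown species in community design: ",
         paste(unknown, collapse = ", "))
  params <- true_growth_params(model, schedule, conversion)
  comm <- design$communities
  sigma <- model$noise_sigma

  pred <- lapply(comm$community_id, function(id) {
    sp <- design$membership$species[design$membership$community_id == id]
    simulate_community(sp, params, schedule)
  })
  names(pred) <- comm$community_id

  out <- with_seed(model$seed + 1L, {
    do.call(rbind, lapply(seq_len(nrow(comm)), function(i) {
      id <- comm$community_id[i]
      B <- pred[[id]]
      reps <- comm$n_replicates[i]
      df <- data.frame(
        experiment = "community", community_id = id,
        richness = comm$richness[i],
        replicate = rep(seq_len(reps), each = length(B)),
        species = rep(names(B), times = reps),
        year = year,
        biomass_g = rep(unname(B), times = reps),
        stringsAsFactors = FALSE
      )
      if (sigma > 0)
        df$biomass_g <- df$biomass_g * exp(stats::rnorm(nrow(df), 0, sigma))
      df
    }))
  })
  tot <- stats::ave(out$biomass_g, out$community_id, out$replicate, FUN = sum)
  out$plot_total_g <- tot
  rownames(out) <- NULL
  out
}
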