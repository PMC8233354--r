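#' Simulation schedule
#'
#' Two growing seasons of discrete timesteps, with standing biomass cut to a
#' small fraction between seasons (senescence/harvest); soil training state
#' persists through the reset.
#'
#' @param steps_per_season Timesteps per season (default 52).
#' @param n_seasons Number of seasons (default 2, i.e. 104 steps).
#' @param reset_fraction Fraction of biomass carried across a season
#'   boundary (default 0.01).
#' @return An object of class `sim_schedule`.
#' @export
sim_schedule <- function(steps_per_season = 52L, n_seasons = 2L,
                         reset_fraction = 0.01) {
  stopifnot(steps_per_season >= 1, n_seasons >= 1,
            reset_fraction > 0, reset_fraction <= 1)
  structure(list(steps_per_season = as.integer(steps_per_season),
                 n_seasons = as.integer(n_seasons),
                 reset_fraction = reset_fraction),
            class = "sim_schedule")
}

#' Growth parameter set for the community simulator
#'
#' @param r Species x soil-type matrix of per-timestep relative growth
#'   rates. Columns are the training-soil types (species codes) plus a
#'   `"background"` column for untrained soil. All entries must satisfy
#'   `1 + r > 0`.
#' @param K Carrying capacity (g per plot): a single community-level value
#'   (`K_mode = "constant_K"`) or a named per-species vector
#'   (`K_mode = "species_K"`).
#' @param K_mode `"species_K"` or `"constant_K"`.
#' @param conversion Plant-to-microbe conversion factor c (fraction of soil
#'   converted per gram of plant biomass per timestep); `0` disables soil
#'   training.
#' @param b0 Total seeded biomass per plot (g), split equally among the
#'   seeded species.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(r, K, K_mode = c("species_K", "constant_K"),
                          conversion = 0.01, b0 = 1) {
  K_mode <- match.arg(K_mode)
  stopifnot(is.matrix(r), !is.null(rownames(r)), !is.null(colnames(r)))
  if (!"background" %in% colnames(r))
    stop("rate matrix needs a 'background' soil column")
  if (any(1 + r <= 0)) stop("all rates must satisfy 1 + r > 0")
  if (any(K <= 0)) stop("carrying capacities must be positive")
  if (K_mode == "species_K" && is.null(names(K)))
    stop("species-level K must be a named vector")
  if (conversion < 0) stop("conversion factor must be >= 0")
  if (b0 <= 0) stop("initial seed biomass must be positive")
  structure(list(r = r, K = K, K_mode = K_mode, conversion = conversion,
                 b0 = b0),
            class = "growth_params")
}

#' Derive per-timestep growth rates from PSF plot records
#'
#' Inverts discrete exponential growth over one season: the rate solves
#' `b0 * (1 + r)^steps = B_obs`, where `B_obs` is the mean observed
#' second-year biomass on the relevant soil. Three parameterizations:
#' `"per_soil"` (feedback model - one rate per species per training soil,
#' from the factorial data), `"control"` (null model - a single rate per
#' species from untrained control plots) and `"self"` (null model - a single
#' rate per species from self-trained plots). The background-soil column
#' uses the control rate when control plots exist, otherwise the species'
#' mean trained-soil rate.
#'
#' @param psf_records Long PSF plot records.
#' @param mode `"per_soil"`, `"control"` or `"self"`.
#' @param year Year whose biomass anchors the rates.
#' @param steps_per_season Timesteps a season's growth is spread over.
#' @param b0 Seed biomass the observed growth started from.
#' @return Species x soil rate matrix suitable for [growth_params()].
#' @export
derive_growth_rates <- function(psf_records,
                                mode = c("per_soil", "control", "self"),
                                year = 2018L, steps_per_season = 52L,
                                b0 = 1) {
  mode <- match.arg(mode)
  if ("experiment" %in% names(psf_records))
    psf_records <- psf_records[psf_records$experiment == "psf", ]
  psf_records <- psf_records[psf_records$year == year, ]
  if (!nrow(psf_records)) stop("no PSF records for year ", year)
  species <- sort(unique(psf_records$species))
  mean_on <- function(sp, soil) {
    b <- psf_records$biomass_g[psf_records$species == sp &
                                 psf_records$soil_type == soil]
    if (!length(b)) NA_real_ else mean(b)
  }
  rate <- function(B) {
    r <- (B / b0)^(1 / steps_per_season) - 1
    if (any(bad <- !is.na(B) & B == 0)) {
      warning("zero observed biomass; rate floored at -1 + 1e-8")
      r[bad] <- -1 + 1e-8
    }
    r
  }
  soils <- c(species, "background")
  r <- matrix(NA_real_, length(species), length(soils),
              dimnames = list(species, soils))
  if (mode == "per_soil") {
    for (sp in species) {
      for (soil in species) {
        B <- if (soil == sp) mean_on(sp, "self") else mean_on(sp, soil)
        if (is.na(B)) stop("no records for species ", sp, " on soil ", soil)
        r[sp, soil] <- rate(B)
      }
      Bc <- mean_on(sp, "control")
      r[sp, "background"] <- if (is.na(Bc)) mean(r[sp, species])
                             else rate(Bc)
    }
  } else {
    src <- if (mode == "control") "control" else "self"
    for (sp in species) {
      B <- mean_on(sp, src)
      if (is.na(B)) stop("no ", src, " records for species ", sp)
      r[sp, ] <- rate(B)
    }
  }
  r
}

#' The five carrying-capacity definitions
#'
#' Extracts five alternative biomass ceilings from the two experiments:
#' \describe{
#'   \item{K1}{maximum observed plot total in the community experiment
#'     (community-level).}
#'   \item{K2}{maximum over communities of the mean plot total
#'     (community-level).}
#'   \item{K3}{per-species maximum biomass observed in any community plot
#'     (species-level).}
#'   \item{K4}{maximum biomass observed in any PSF plot (community-level).}
#'   \item{K5}{per-species maximum biomass in any PSF plot (species-level).}
#' }
#'
#' @param psf_records,community_records Long plot records.
#' @return Named list `K1`..`K5`; each element is a list with `K` (scalar or
#'   named vector) and `mode`. A species absent from the relevant plots
#'   falls back to the pool median with a warning.
#' @export
carrying_capacities <- function(psf_records, community_records) {
  if ("experiment" %in% names(psf_records))
    psf_records <- psf_records[psf_records$experiment == "psf", ]
  if ("experiment" %in% names(community_records))
    community_records <- community_records[
      community_records$experiment == "community", ]
  if (!nrow(psf_records) || !nrow(community_records))
    stop("both record tables must be non-empty")
  cr <- community_records
  plot_tot <- tapply(cr$biomass_g,
                     paste(cr$community_id, cr$replicate), sum)
  K1 <- max(plot_tot)
  comm_of_plot <- tapply(cr$community_id,
                         paste(cr$community_id, cr$replicate),
                         function(x) x[1])
  K2 <- max(tapply(as.numeric(plot_tot), unlist(comm_of_plot), mean))
  sp_max <- tapply(cr$biomass_g, cr$species, max)
  K4 <- max(psf_records$biomass_g)
  sp_max_psf <- tapply(psf_records$biomass_g, psf_records$species, max)
  fill <- function(v, species) {
    out <- stats::setNames(rep(NA_real_, length(species)), species)
    out[names(v)] <- as.numeric(v)
    if (anyNA(out)) {
      warning("species with no plots fall back to the pool median K: ",
              paste(names(out)[is.na(out)], collapse = ", "))
      out[is.na(out)] <- stats::median(as.numeric(v))
    }
    out
  }
  species <- sort(unique(c(cr$species, psf_records$species)))
  list(K1 = list(K = K1, mode = "constant_K"),
       K2 = list(K = K2, mode = "constant_K"),
       K3 = list(K = fill(sp_max, species), mode = "species_K"),
       K4 = list(K = K4, mode = "constant_K"),
       K5 = list(K = fill(sp_max_psf, species), mode = "species_K"))
}

#' Initial simulation state
#'
#' @param species Character vector of species codes in the community.
#' @param params A [growth_params()] set.
#' @return A `sim_state`: biomass vector `B` (total `b0` split equally) and
#'   soil-fraction vector `f` over the training types (all mass initially in
#'   `"background"`).
#' @export
sim_init <- function(species, params) {
  if (!length(species)) stop("composition must contain at least one species")
  if (any(!species %in% rownames(params$r)))
    stop("no growth rates for: ",
         paste(setdiff(species, rownames(params$r)), collapse = ", "))
  f <- stats::setNames(rep(0, ncol(params$r)), colnames(params$r))
  f["background"] <- 1
  structure(list(t = 0L,
                 B = stats::setNames(rep(params$b0 / length(species),
                                         length(species)), species),
                 f = f),
            class = "sim_state")
}

#' Advance the community simulator one timestep
#'
#' Three sub-steps: (i) each species' effective growth rate is the
#' soil-fraction-weighted mean of its per-soil rates; (ii) biomass grows
#' logistically, `B_i <- B_i + B_i * r_i * max(0, 1 - L)` with load
#' `L = sum(B) / K` (constant-K) or `L_i = B_i / K_i` (species-K); (iii)
#' each species converts soil towards its own training type at rate
#' `conversion * B_i`, after which fractions are renormalized to sum to 1.
#' Untrained background soil is only ever diluted, never regenerated.
#'
#' @param state A `sim_state`.
#' @param params A [growth_params()] set.
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, params) {
  B <- state$B
  f <- state$f
  r_eff <- as.numeric(params$r[names(B), names(f), drop = FALSE] %*% f)
  L <- if (params$K_mode == "constant_K") sum(B) / params$K
       else B / params$K[names(B)]
  B <- B + B * r_eff * pmax(0, 1 - L)
  B[B < 0] <- 0
  if (params$conversion > 0) {
    f[names(B)] <- f[names(B)] + params$conversion * B
    f <- f / sum(f)
  }
  structure(list(t = state$t + 1L, B = B, f = f), class = "sim_state")
}

#' Simulate one plant community
#'
#' Seeds the composition at equal shares of `b0` on untrained soil and runs
#' the schedule: each season is `steps_per_season` calls of [sim_step()];
#' between seasons biomass is multiplied by `reset_fraction` while soil
#' fractions persist (soil memory is the mechanism under study).
#'
#' @param species Character vector of species codes.
#' @param params A [growth_params()] set.
#' @param schedule A [sim_schedule()].
#' @param trajectory If `TRUE`, also return the full biomass trajectory.
#' @return Named vector of final per-species biomass (g per plot); with
#'   `trajectory = TRUE`, a list `final`, `B` (steps x species matrix), `f`.
#' @export
#' @examples
#' r <- matrix(0.08, 1, 2, dimnames = list("Ag", c("Ag", "background")))
#' p <- growth_params(r, K = c(Ag = 100), "species_K", conversion = 0)
#' simulate_community("Ag", p)
simulate_community <- function(species, params, schedule = sim_schedule(),
                               trajectory = FALSE) {
  state <- sim_init(species, params)
  n_steps <- schedule$steps_per_season * schedule$n_seasons
  if (trajectory) {
    Bt <- matrix(NA_real_, n_steps, length(species),
                 dimnames = list(NULL, species))
    ft <- matrix(NA_real_, n_steps, length(state$f),
                 dimnames = list(NULL, names(state$f)))
  }
  k <- 0L
  for (season in seq_len(schedule$n_seasons)) {
    if (season > 1L) state$B <- state$B * schedule$reset_fraction
    for (i in seq_len(schedule$steps_per_season)) {
      state <- sim_step(state, params)
      k <- k + 1L
      if (trajectory) { Bt[k, ] <- state$B; ft[k, ] <- state$f }
    }
  }
  if (trajectory) list(final = state$B, B = Bt, f = ft) else state$B
}

#' Ensemble community predictions under the feedback or null model
#'
#' Runs the simulator for every community composition under every member of
#' the model ensemble and averages. The feedback ("psf") ensemble crosses
#' the per-soil rate parameterization with the five carrying-capacity
#' definitions (5 runs); the null ensemble crosses the control- and
#' self-soil rate parameterizations with the five capacities (10 runs).
#' Null runs use a single soil type (no soil conditioning,
#' `conversion = 0`).
#'
#' @param design A [default_design()] (its `communities`/`membership`
#'   define the compositions), or a list with those two elements.
#' @param model `"psf"` or `"null"`.
#' @param psf_records,community_records Long plot records used to derive
#'   rates and capacities.
#' @param schedule A [sim_schedule()].
#' @param conversion Plant-to-microbe conversion factor for feedback runs.
#' @param b0 Total seeded biomass (g).
#' @param year Year anchoring the derived rates.
#' @return A list with `mean` (data.frame `community_id`, `richness`,
#'   `species`, `biomass_g` - ensemble means), `total` (per-community
#'   ensemble-mean totals) and `runs` (per-run per-species detail with
#'   `K_variant` and `rate_mode`).
#' @export
run_ensemble <- function(design, model = c("psf", "null"), psf_records,
                         community_records, schedule = sim_schedule(),
                         conversion = 0.01, b0 = 1, year = 2018L) {
  model <- match.arg(model)
  Ks <- carrying_capacities(psf_records, community_records)
  modes <- if (model == "psf") "per_soil" else c("control", "self")
  comm <- design$communities
  memb <- design$membership
  runs <- list()
  for (mode in modes) {
    r <- derive_growth_rates(psf_records, mode = mode, year = year,
                             steps_per_season = schedule$steps_per_season,
                             b0 = b0)
    conv <- if (mode == "per_soil") conversion else 0
    for (kv in names(Ks)) {
      params <- growth_params(r, Ks[[kv]]$K, Ks[[kv]]$mode,
                              conversion = conv, b0 = b0)
      pred <- do.call(rbind, lapply(seq_len(nrow(comm)), function(i) {
        id <- comm$community_id[i]
        sp <- memb$species[memb$community_id == id]
        B <- simulate_community(sp, params, schedule)
        data.frame(community_id = id, richness = comm$richness[i],
                   species = names(B), biomass_g = unname(B),
                   rate_mode = mode, K_variant = kv,
                   stringsAsFactors = FALSE)
      }))
      runs[[paste(mode, kv, sep = ".")]] <- pred
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  key <- paste(runs$community_id, runs$species)
  mean_df <- runs[!duplicated(key), c("community_id", "richness", "species")]
  mean_df$biomass_g <- as.numeric(
    tapply(runs$biomass_g, key, mean)[paste(mean_df$community_id,
                                            mean_df$species)])
  rownames(mean_df) <- NULL
  tot <- stats::aggregate(biomass_g ~ community_id + richness, mean_df, sum)
  tot <- tot[order(tot$community_id), ]
  rownames(tot) <- NULL
  list(mean = mean_df, total = tot, runs = runs, model = model)
}
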