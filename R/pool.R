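#' The 16-species tallgrass-prairie pool
#'
#' Returns the default species pool used throughout the package: 16 prairie
#' species in four functional groups (C3 grasses, C4 grasses, forbs and
#' legumes, four species each), identified by two-letter codes.
#'
#' @return A data.frame with columns `code`, `species` and `group`
#'   (one of `"C3"`, `"C4"`, `"Forb"`, `"Legume"`).
#' @export
#' @examples
#' pool <- species_pool()
#' table(pool$group)
species_pool <- function() {
  data.frame(
    code = c("Ac", "Ag", "Am", "Dp", "Ec", "Km", "La", "Lc",
             "Lp", "Mf", "Pp", "Ps", "Pv", "Sn", "Sr", "Ss"),
    species = c("Amorpha canescens", "Andropogon gerardii",
                "Achillea millefolium", "Dalea purpurea",
                "Elymus canadensis", "Koeleria macrantha",
                "Liatris aspera", "Lespedeza capitata",
                "Lupinus perennis", "Monarda fistulosa",
                "Poa pratensis", "Pascopyrum smithii",
                "Panicum virgatum", "Sorghastrum nutans",
                "Solidago rigida", "Schizachyrium scoparium"),
    group = c("Legume", "C4", "Forb", "Legume", "C3", "C3", "Forb",
              "Legume", "Legume", "Forb", "C3", "C3", "C4", "C4",
              "Forb", "C4"),
    stringsAsFactors = FALSE
  )
}

# run an expression with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ground-truth plant-soil feedback model for the synthetic-data generator
#'
#' Defines the "true" state of a factorial soil-training experiment: a base
#' biomass for each species and a matrix of multiplicative soil effects.
#' `effect[i, j]` multiplies species `i`'s biomass when it grows on soil
#' trained by species `j`; the diagonal holds the self-soil effect and
#' untrained (control) soil has effect 1. The implied PSF index of cell
#' (i, j) is `(e_ii - e_ij) / max(e_ii, e_ij)`.
#'
#' By default the self effect is fixed at 1 and the off-diagonal effects are
#' back-solved from cell-level true index values drawn from a truncated
#' normal distribution, so the ground truth has a configurable net mean PSF
#' (default -0.10) and spread (default sd 0.30, truncated to (-0.9, 0.9)).
#' These defaults, together with `noise_sigma = 0.4` and the default
#' replication, place the 2018 sample statistics near a mean absolute PSF of
#' 0.27 and a net mean of -0.10.
#'
#' @param pool Species pool data.frame (see [species_pool()]).
#' @param base_biomass Optional named vector of per-species mean monoculture
#'   biomass (g per plot). Drawn uniformly from `base_range` when `NULL`.
#' @param effect Optional full effect matrix (species x soil). When supplied
#'   it overrides `psf_mean`/`psf_sd`.
#' @param psf_mean,psf_sd Mean and sd of the true cell-level PSF index
#'   distribution used to construct `effect`.
#' @param noise_sigma Lognormal plot-noise sd on the log scale.
#' @param year_attenuation Scalar in (0, 1]; first-year effects are
#'   `1 + year_attenuation * (effect - 1)`, emulating feedbacks that
#'   strengthen over the response phase.
#' @param base_range Range (g) from which base biomasses are drawn.
#' @param seed Integer seed; the model and everything generated from it are
#'   deterministic given this seed.
#' @return An object of class `true_psf_model`.
#' @export
#' @examples
#' m <- true_psf_model(seed = 1)
#' round(mean(implied_psf(m), na.rm = TRUE), 2)
true_psf_model <- function(pool = species_pool(), base_biomass = NULL,
                           effect = NULL, psf_mean = -0.10, psf_sd = 0.30,
                           noise_sigma = 0.4, year_attenuation = 0.85,
                           base_range = c(20, 160), seed = 1L) {
  stopifnot(is.data.frame(pool), !anyDuplicated(pool$code))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  n <- nrow(pool)
  codes <- pool$code
  with_seed(seed, {
    if (is.null(base_biomass)) {
      base_biomass <- stats::runif(n, base_range[1], base_range[2])
      names(base_biomass) <- codes
    }
    if (is.null(effect)) {
      # draw true cell-level index values, then back-solve the multiplier
      idx <- matrix(0, n, n, dimnames = list(codes, codes))
      off <- row(idx) != col(idx)
      t_ij <- pmin(pmax(stats::rnorm(sum(off), psf_mean, psf_sd), -0.9), 0.9)
      idx[off] <- t_ij
      effect <- matrix(1, n, n, dimnames = list(codes, codes))
      effect[off] <- ifelse(idx[off] <= 0, 1 / (1 + idx[off]), 1 - idx[off])
    }
  })
  if (is.null(names(base_biomass))) names(base_biomass) <- codes
  if (any(base_biomass <= 0)) stop("base biomass must be positive")
  if (any(effect <= 0)) stop("soil effect multipliers must be positive")
  structure(
    list(pool = pool, base_biomass = base_biomass, effect = effect,
         noise_sigma = noise_sigma, year_attenuation = year_attenuation,
         seed = as.integer(seed)),
    class = "true_psf_model"
  )
}

#' True PSF index values implied by a ground-truth model
#'
#' @param model A `true_psf_model`.
#' @return A species x soil matrix of implied index values; the diagonal is
#'   `NA` (a self-versus-self cell is undefined).
#' @export
implied_psf <- function(model) {
  e <- model$effect
  self <- matrix(diag(e), nrow(e), ncol(e))  # recycle self effect across row
  idx <- (self - e) / pmax(self, e)
  dimnames(idx) <- dimnames(e)
  diag(idx) <- NA_real_
  idx
}

#' Experimental design of the factorial PSF and community experiments
#'
#' Builds the default two-experiment design: a 16 x 15 factorial soil
#' training design (27-35 'self' replicates per species, 5-9 replicates per
#' 'other' soil, 5-9 untrained control plots) and 63 unique plant communities
#' at richness 1, 2, 4, 8, 14 and 16 (16, 14, 9, 9, 14 and 1 unique
#' compositions; monocultures x4 replicate plots, the 16-species community
#' x30, all others x3 - 232 community plots in total).
#'
#' @param pool Species pool data.frame.
#' @param seed Integer seed fixing replicate counts and community
#'   compositions; the default gives one fixed canonical design.
#' @return An object of class `psf_design`: a list with `self_replicates`
#'   (named integer vector), `other_replicates` (species x soil matrix, NA
#'   diagonal), `control_replicates`, `communities` (one row per unique
#'   community: `community_id`, `richness`, `n_replicates`) and `membership`
#'   (long table `community_id`, `species`).
#' @export
#' @examples
#' d <- default_design()
#' nrow(d$communities)                      # 63 unique communities
#' sum(d$communities$n_replicates)          # 232 plots
default_design <- function(pool = species_pool(), seed = 2015L) {
  codes <- pool$code
  n <- length(codes)
  with_seed(seed, {
    self_rep <- stats::setNames(sample(27:35, n, replace = TRUE), codes)
    other_rep <- matrix(sample(5:9, n * n, replace = TRUE), n, n,
                        dimnames = list(codes, codes))
    diag(other_rep) <- NA_integer_
    control_rep <- stats::setNames(sample(5:9, n, replace = TRUE), codes)

    levels <- c(1, 2, 4, 8, 14, 16)
    counts <- c(16, 14, 9, 9, 14, 1)
    comps <- list()
    for (k in seq_along(levels)) {
      rich <- levels[k]
      if (rich == 1) {
        sets <- as.list(codes)
      } else if (rich == n) {
        sets <- list(codes)
      } else {
        sets <- list()
        while (length(sets) < counts[k]) {
          cand <- sort(sample(codes, rich))
          key <- paste(cand, collapse = "+")
          if (!key %in% names(sets)) sets[[key]] <- cand
        }
        sets <- unname(sets)
      }
      comps <- c(comps, sets)
    }
  })
  richness <- vapply(comps, length, integer(1))
  communities <- data.frame(
    community_id = sprintf("C%02d", seq_along(comps)),
    richness = richness,
    n_replicates = ifelse(richness == 1, 4L, ifelse(richness == n, 30L, 3L)),
    stringsAsFactors = FALSE
  )
  membership <- data.frame(
    community_id = rep(communities$community_id, richness),
    species = unlist(comps),
    stringsAsFactors = FALSE
  )
  structure(
    list(pool = pool, self_replicates = self_rep,
         other_replicates = other_rep, control_replicates = control_rep,
         communities = communities, membership = membership,
         seed = as.integer(seed)),
    class = "psf_design"
  )
}

#' @export
print.psf_design <- function(x, ...) {
  cat("Factorial PSF + biodiversity-productivity design\n")
  cat(sprintf("  species: %d; self reps %d-%d; other reps %d-%d\n",
              nrow(x$pool), min(x$self_replicates), max(x$self_replicates),
              min(x$other_replicates, na.rm = TRUE),
              max(x$other_replicates, na.rm = TRUE)))
  tab <- table(x$communities$richness)
  cat(sprintf("  communities: %d unique (%s plots total)\n",
              nrow(x$communities), sum(x$communities$n_replicates)))
  cat("  richness levels:", paste(names(tab), tab, sep = "x", collapse = ", "),
      "\n")
  invisible(x)
}
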