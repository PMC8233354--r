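#' Plant-soil feedback index
#'
#' `PSF = (S - O) / max(S, O)`, where `S` is mean biomass on 'self' soil and
#' `O` is mean biomass on an 'other' soil. The index is bounded in
#' \[-1, 1\] and reads as the proportional change in growth between soil
#' types: -0.5 means the plant grew half as much on its own soil.
#'
#' @param S,O Non-negative mean biomasses (vectorised; recycled).
#' @return Numeric vector of index values in \[-1, 1\]. A cell with
#'   `S == O == 0` is degenerate and returns 0 with a warning.
#' @export
#' @examples
#' psf_index(15, 10)   #  0.333...
#' psf_index(5, 10)    # -0.5
psf_index <- function(S, O) {
  if (any(S < 0, na.rm = TRUE) || any(O < 0, na.rm = TRUE))
    stop("biomass must be non-negative")
  n <- max(length(S), length(O))
  S <- rep_len(as.numeric(S), n)
  O <- rep_len(as.numeric(O), n)
  den <- pmax(S, O)
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning("S and O both zero in ", sum(zero), " cell(s); index set to 0")
    den[zero] <- 1
  }
  (S - O) / den
}

#' Percentile bootstrap confidence interval for the PSF index
#'
#' Resamples the raw self and other replicate biomasses independently with
#' replacement, recomputes group means and the index for each draw, and
#' returns the percentile interval.
#'
#' @param self_biomass,other_biomass Replicate biomass vectors (length >= 2).
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param conf Confidence level.
#' @param seed Optional seed; when supplied the interval is deterministic
#'   without disturbing the caller's RNG stream.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
psf_bootstrap_ci <- function(self_biomass, other_biomass, n_boot = 10000L,
                             conf = 0.95, seed = NULL) {
  if (length(self_biomass) < 2 || length(other_biomass) < 2)
    stop("bootstrap needs >= 2 replicates in each group (self n = ",
         length(self_biomass), ", other n = ", length(other_biomass), ")")
  if (n_boot < 1) stop("n_boot must be >= 1")
  draw <- function() {
    ns <- length(self_biomass); no <- length(other_biomass)
    Sm <- rowMeans(matrix(sample(self_biomass, ns * n_boot, replace = TRUE),
                          n_boot, ns))
    Om <- rowMeans(matrix(sample(other_biomass, no * n_boot, replace = TRUE),
                          n_boot, no))
    psf_index(Sm, Om)
  }
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(idx, c(alpha, 1 - alpha), names = FALSE))
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Species-by-soil PSF matrix
#'
#' Computes one PSF index per ordered (species, training-soil) pair from
#' long plot records for one response year: the 16-species pool yields 240
#' cells. Each cell carries the mean self and other biomass, replicate
#' counts, the index, a bootstrap 95% interval and a significance flag (CI
#' excludes zero).
#'
#' @param records Long plot records (see [generate_psf_experiment()] for the
#'   schema); rows with `experiment != "psf"` are ignored if the column is
#'   present.
#' @param year Response year to use.
#' @param n_boot Bootstrap draws per cell; `0` skips the bootstrap (interval
#'   columns set to `NA`), useful for large calibration sweeps.
#' @param conf Confidence level for the interval.
#' @param seed Seed for the bootstrap.
#' @return A data.frame of class `psf_matrix` with one row per cell:
#'   `species`, `soil_species`, `year`, `S`, `O`, `n_self`, `n_other`,
#'   `psf`, `ci_low`, `ci_high`, `significant`. Missing (species, soil)
#'   combinations are flagged with `NA` and a warning, and are excluded from
#'   summaries.
#' @export
psf_matrix <- function(records, year = 2018L, n_boot = 10000L, conf = 0.95,
                       seed = NULL) {
  if ("experiment" %in% names(records))
    records <- records[records$experiment == "psf", ]
  records <- records[records$year == year, ]
  if (!nrow(records)) stop("no PSF records for year ", year)
  species <- sort(unique(records$species))
  soils <- sort(unique(c(setdiff(records$soil_type, c("self", "control")),
                         records$species[records$soil_type == "self"])))
  cells <- expand.grid(soil_species = soils, species = species,
                       stringsAsFactors = FALSE)[, c("species", "soil_species")]
  cells <- cells[cells$species != cells$soil_species, ]
  cells <- cells[order(cells$species, cells$soil_species), ]

  if (!is.null(seed)) {
    cell_seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(cells)))
  } else cell_seeds <- rep(list(NULL), nrow(cells))

  res <- lapply(seq_len(nrow(cells)), function(k) {
    sp <- cells$species[k]; soil <- cells$soil_species[k]
    sb <- records$biomass_g[records$species == sp &
                              records$soil_type == "self"]
    ob <- records$biomass_g[records$species == sp &
                              records$soil_type == soil]
    if (!length(sb) || !length(ob))
      return(data.frame(S = NA_real_, O = NA_real_, n_self = length(sb),
                        n_other = length(ob), psf = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        significant = NA))
    S <- mean(sb); O <- mean(ob)
    p <- psf_index(S, O)
    if (n_boot > 0 && length(sb) >= 2 && length(ob) >= 2) {
      ci <- psf_bootstrap_ci(sb, ob, n_boot = n_boot, conf = conf,
                             seed = cell_seeds[[k]])
      sig <- ci[1] > 0 || ci[2] < 0
    } else {
      ci <- c(NA_real_, NA_real_); sig <- NA
    }
    data.frame(S = S, O = O, n_self = length(sb), n_other = length(ob),
               psf = p, ci_low = ci[1], ci_high = ci[2], significant = sig)
  })
  out <- cbind(cells, year = year, do.call(rbind, res))
  rownames(out) <- NULL
  if (anyNA(out$psf))
    warning(sum(is.na(out$psf)), " (species, soil) combination(s) missing; ",
            "flagged NA and excluded from summaries")
  class(out) <- c("psf_matrix", "data.frame")
  out
}

#' Summary statistics of a PSF matrix
#'
#' The mean absolute index (size of feedbacks regardless of sign - large
#' positive and negative feedbacks would otherwise cancel) and the net mean
#' index (direction of the aggregate feedback).
#'
#' @param matrix A [psf_matrix()].
#' @return A list with `mean_abs_psf`, `net_mean_psf` and `n_cells`.
#' @export
psf_summary <- function(matrix) {
  v <- matrix$psf[!is.na(matrix$psf)]
  if (!length(v)) stop("PSF matrix has no non-missing cells")
  list(mean_abs_psf = mean(abs(v)), net_mean_psf = mean(v),
       n_cells = length(v))
}

#' Species-level PSF values
#'
#' Averages each species' 15 cell values into one species-level PSF, with a
#' standard error taken over the soil types and a one-sample t-test against
#' zero.
#'
#' @param matrix A [psf_matrix()].
#' @param alpha Significance level.
#' @return data.frame: `species`, `mean_psf`, `se`, `t_stat`, `p_value`,
#'   `significant`, `n_soils`.
#' @export
psf_species_summary <- function(matrix, alpha = 0.05) {
  out <- do.call(rbind, lapply(split(matrix, matrix$species), function(d) {
    v <- d$psf[!is.na(d$psf)]
    n <- length(v)
    se <- stats::sd(v) / sqrt(n)
    tt <- one_sample_t(v)
    data.frame(species = d$species[1], mean_psf = mean(v), se = se,
               t_stat = tt$t, p_value = tt$p, significant = tt$p < alpha,
               n_soils = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# one-sample t vs 0 that tolerates zero-variance input
one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 2 || is.na(s)) return(list(t = NA_real_, df = n - 1, p = NA_real_))
  if (s == 0) {
    t <- if (mean(x) == mu) 0 else Inf * sign(mean(x) - mu)
    return(list(t = t, df = n - 1, p = if (t == 0) 1 else 0))
  }
  t <- (mean(x) - mu) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# paired t that tolerates constant differences
paired_t <- function(x, y) {
  d <- x - y
  res <- one_sample_t(d)
  c(list(mean_diff = mean(d)), res)
}

#' Between-year comparison of PSF values
#'
#' Pairs the species-by-soil cells of the two response years and runs paired
#' t-tests on the net index and on its absolute value, testing whether
#' feedbacks strengthened over the response phase.
#'
#' @param records Long PSF plot records containing both years.
#' @param years The two years to compare (earlier first).
#' @return data.frame with one row per metric (`"net"`, `"abs"`): means in
#'   each year, `t`, `df`, `p_value`. Degenerate (constant-difference) input
#'   is handled without error.
#' @export
psf_year_comparison <- function(records, years = c(2017L, 2018L)) {
  m1 <- psf_matrix(records, year = years[1], n_boot = 0)
  m2 <- psf_matrix(records, year = years[2], n_boot = 0)
  key <- function(m) paste(m$species, m$soil_species)
  if (!identical(sort(key(m1)), sort(key(m2)))) {
    miss <- c(setdiff(key(m1), key(m2)), setdiff(key(m2), key(m1)))
    stop("cell sets differ between years; unmatched: ",
         paste(miss, collapse = ", "))
  }
  m2 <- m2[match(key(m1), key(m2)), ]
  ok <- !is.na(m1$psf) & !is.na(m2$psf)
  rows <- lapply(c(net = "net", abs = "abs"), function(metric) {
    x1 <- if (metric == "abs") abs(m1$psf[ok]) else m1$psf[ok]
    x2 <- if (metric == "abs") abs(m2$psf[ok]) else m2$psf[ok]
    tt <- paired_t(x1, x2)
    data.frame(metric = metric, mean_year1 = mean(x1), mean_year2 = mean(x2),
               t = tt$t, df = tt$df, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Functional-group tests of PSF values
#'
#' One-sample t-tests of the cell values within each functional group
#' against zero, plus a one-way ANOVA of cell values across groups.
#'
#' @param matrix A [psf_matrix()].
#' @param pool Species pool assigning each species a functional group.
#' @return A list with `group_tests` (data.frame per group: mean, t, df, p)
#'   and `anova` (one row: F, df1, df2, p). Groups with fewer than two cells
#'   are skipped with a warning.
#' @export
psf_group_tests <- function(matrix, pool = species_pool()) {
  grp <- pool$group[match(matrix$species, pool$code)]
  if (anyNA(grp)) stop("pool does not assign a group to every species")
  d <- data.frame(psf = matrix$psf, group = grp)[!is.na(matrix$psf), ]
  tests <- lapply(split(d$psf, d$group), function(v) {
    if (length(v) < 2) return(NULL)
    tt <- one_sample_t(v)
    data.frame(mean_psf = mean(v), t = tt$t, df = tt$df, p_value = tt$p)
  })
  skipped <- names(tests)[vapply(tests, is.null, logical(1))]
  if (length(skipped))
    warning("group(s) with < 2 cells skipped: ",
            paste(skipped, collapse = ", "))
  tests <- tests[!vapply(tests, is.null, logical(1))]
  gt <- cbind(data.frame(group = names(tests), stringsAsFactors = FALSE),
              do.call(rbind, tests))
  rownames(gt) <- NULL
  fit <- stats::aov(psf ~ group, data = d)
  s <- summary(fit)[[1]]
  an <- data.frame(F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                   p_value = s$`Pr(>F)`[1])
  list(group_tests = gt, anova = an)
}

#' Regression of PSF values on pairwise species distance
#'
#' Tests whether feedbacks weaken (or strengthen) with relatedness by
#' regressing the cell values on a pairwise distance between the responding
#' species and the soil-training species (e.g. phylogenetic distance; the
#' distance matrix is taken as given).
#'
#' @param matrix A [psf_matrix()].
#' @param distance Symmetric species x species distance matrix with
#'   dimnames, or a long data.frame `species`, `soil_species`, `distance`.
#' @return data.frame: `r` (signed correlation), `slope`, `F`, `df1`, `df2`,
#'   `p_value`, `n`.
#' @export
psf_distance_test <- function(matrix, distance) {
  if (is.matrix(distance)) {
    idx <- cbind(matrix$species, matrix$soil_species)
    if (any(!matrix$species %in% rownames(distance)) ||
        any(!matrix$soil_species %in% colnames(distance)))
      stop("distance matrix is missing species present in the PSF matrix")
    d <- distance[idx]
  } else {
    key <- paste(distance$species, distance$soil_species)
    m <- match(paste(matrix$species, matrix$soil_species), key)
    if (anyNA(m)) stop("distance table is missing (species, soil) pairs")
    d <- distance$distance[m]
  }
  ok <- !is.na(matrix$psf) & !is.na(d)
  y <- matrix$psf[ok]; x <- d[ok]
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(data.frame(r = 0, slope = 0, F = 0, df1 = 1, df2 = length(y) - 2,
                      p_value = 1, n = length(y)))
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  data.frame(r = sign(stats::coef(fit)[2]) * sqrt(s$r.squared),
             slope = unname(stats::coef(fit)[2]),
             F = unname(s$fstatistic[1]), df1 = unname(s$fstatistic[2]),
             df2 = unname(s$fstatistic[3]),
             p_value = unname(stats::pf(s$fstatistic[1], s$fstatistic[2],
                                        s$fstatistic[3], lower.tail = FALSE)),
             n = length(y))
}
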