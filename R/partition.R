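#' Additive partition of the net biodiversity effect
#'
#' Splits a mixture's deviation from its monoculture-based expectation into
#' complementarity and selection components (the Loreau-Hector additive
#' partition, a modified Price equation). With `dRY_i = Y_i / M_i - RYe_i`:
#' \deqn{net = \sum_i Y_i - \sum_i RYe_i M_i,}
#' \deqn{complementarity = N \,\overline{dRY}\, \overline{M}, \qquad
#'       selection = N \,\mathrm{cov}(dRY, M),}
#' where the covariance is the population covariance (divide by N) so that
#' `net = complementarity + selection` holds exactly.
#'
#' @param M Monoculture biomass per species (g m^-2), positive.
#' @param Y Observed per-species biomass in the mixture (g m^-2).
#' @param RY_E Expected relative yields; default equal seeding `1/N`. Must
#'   sum to 1.
#' @return A list of class `partition_result`: `net`, `complementarity`,
#'   `selection`, `n_species`, `dRY`.
#' @export
#' @examples
#' # pure complementarity: both species overyield equally
#' loreau_hector(M = c(100, 100), Y = c(60, 60))
#' # pure selection: the big species wins exactly what the small one loses
#' loreau_hector(M = c(200, 100), Y = c(120, 40))
loreau_hector <- function(M, Y, RY_E = NULL) {
  N <- length(M)
  if (N < 2) stop("a nontrivial partition needs at least 2 species")
  if (length(Y) != N) stop("M and Y must have the same length")
  if (is.null(RY_E)) RY_E <- rep(1 / N, N)
  if (abs(sum(RY_E) - 1) > 1e-8) stop("expected relative yields must sum to 1")
  if (any(M <= 0)) {
    bad <- if (!is.null(names(M))) paste(names(M)[M <= 0], collapse = ", ")
           else paste(which(M <= 0), collapse = ", ")
    stop("non-positive monoculture biomass for: ", bad)
  }
  dRY <- Y / M - RY_E
  comp <- N * mean(dRY) * mean(M)
  sel <- N * (mean(dRY * M) - mean(dRY) * mean(M))  # population covariance
  structure(list(net = comp + sel, complementarity = comp, selection = sel,
                 n_species = N, dRY = dRY),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Net biodiversity effect: %.3f (complementarity %.3f + selection %.3f), N = %d\n",
              x$net, x$complementarity, x$selection, x$n_species))
  invisible(x)
}

#' Impute missing monoculture biomass from bicultures
#'
#' Species that never grew in monoculture are assigned twice their biculture
#' biomass; with several bicultures available, twice the mean across them.
#'
#' @param M Named monoculture vector with `NA` for missing species.
#' @param biculture_biomass data.frame `species`, `biomass_g` of per-species
#'   biomass observed in two-species communities.
#' @return `M` with missing entries filled.
#' @export
impute_monocultures <- function(M, biculture_biomass) {
  miss <- names(M)[is.na(M)]
  for (sp in miss) {
    b <- biculture_biomass$biomass_g[biculture_biomass$species == sp]
    if (!length(b))
      stop("no biculture observation to impute monoculture for ", sp)
    M[sp] <- 2 * mean(b)
  }
  M
}

#' Flag outlier communities by their net biodiversity effect
#'
#' A community is an outlier when its net effect lies more than
#' `k` interquartile ranges from the median of all net effects. With zero
#' IQR (all values identical) nothing is removed.
#'
#' @param net Named numeric vector of per-community net effects.
#' @param k IQR multiplier (default 5).
#' @return List with `kept` and `removed` (both named vectors).
#' @export
#' @examples
#' remove_outlier_communities(c(a = 1, b = 2, c = 3, d = 4, e = 1000))
remove_outlier_communities <- function(net, k = 5) {
  if (length(net) < 4) stop("IQR rule needs at least 4 communities")
  iqr <- stats::IQR(net)
  out <- iqr > 0 & abs(net - stats::median(net)) > k * iqr
  list(kept = net[!out], removed = net[out])
}

#' Partition every community and summarize by richness
#'
#' The full partitioning pipeline applied to long per-plot per-species
#' records (observed data or simulator predictions): (1) monoculture means
#' per species, with missing monocultures imputed as twice biculture
#' biomass; (2) per-species mixture means within each community of richness
#' >= 2; (3) the additive partition per community; (4) removal of
#' communities whose net effect exceeds `k_outlier` IQRs from the median;
#' (5) per-richness means over the retained communities.
#'
#' @param records Long table with columns `community_id`, `richness`,
#'   `species`, `biomass_g` (a `replicate` column is averaged over).
#' @param k_outlier IQR multiplier of the outlier rule.
#' @return List with `community` (per-community data.frame: `community_id`,
#'   `richness`, `net`, `complementarity`, `selection`, `outlier`),
#'   `richness` (per-richness means over retained communities) and
#'   `monoculture` (the monoculture vector used, after imputation).
#' @export
partition_by_richness <- function(records, k_outlier = 5) {
  need <- c("community_id", "richness", "species", "biomass_g")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  mono_rec <- records[records$richness == 1, ]
  species <- sort(unique(records$species))
  M <- stats::setNames(rep(NA_real_, length(species)), species)
  if (nrow(mono_rec)) {
    mm <- tapply(mono_rec$biomass_g, mono_rec$species, mean)
    M[names(mm)] <- as.numeric(mm)
  }
  if (anyNA(M)) {
    bic <- records[records$richness == 2, c("species", "biomass_g")]
    M <- impute_monocultures(M, bic)
  }
  mix <- records[records$richness >= 2, ]
  if (!nrow(mix)) {
    warning("no communities with richness >= 2; nothing to partition")
    return(list(community = data.frame(), richness = data.frame(),
                monoculture = M))
  }
  ids <- unique(mix$community_id)
  res <- do.call(rbind, lapply(ids, function(id) {
    d <- mix[mix$community_id == id, ]
    Y <- tapply(d$biomass_g, d$species, mean)
    p <- loreau_hector(M[names(Y)], as.numeric(Y))
    data.frame(community_id = id, richness = d$richness[1], net = p$net,
               complementarity = p$complementarity, selection = p$selection,
               stringsAsFactors = FALSE)
  }))
  flt <- remove_outlier_communities(
    stats::setNames(res$net, res$community_id), k = k_outlier)
  res$outlier <- res$community_id %in% names(flt$removed)
  kept <- res[!res$outlier, ]
  rich <- do.call(rbind, lapply(split(kept, kept$richness), function(d) {
    data.frame(richness = d$richness[1], n = nrow(d),
               net = mean(d$net), complementarity = mean(d$complementarity),
               selection = mean(d$selection))
  }))
  rownames(res) <- rownames(rich) <- NULL
  list(community = res, richness = rich, monoculture = M)
}
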