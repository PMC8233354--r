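# small fixtures built in code: a 4-species pool with a hand-sized design,
# used where the full 16-species layout would only add runtime

small_pool <- function() {
  data.frame(code = c("Aa", "Bb", "Cc", "Dd"),
             species = paste("sp", 1:4),
             group = c("C3", "C4", "Forb", "Legume"),
             stringsAsFactors = FALSE)
}

small_design <- function(pool = small_pool(), self_rep = 6L, other_rep = 4L,
                         control_rep = 4L) {
  codes <- pool$code
  n <- length(codes)
  other <- matrix(other_rep, n, n, dimnames = list(codes, codes))
  diag(other) <- NA_integer_
  comps <- c(as.list(codes),                         # 4 monocultures
             list(codes[1:2], codes[3:4], codes[c(1, 3)]),  # 3 bicultures
             list(codes))                            # full community
  richness <- vapply(comps, length, integer(1))
  communities <- data.frame(
    community_id = sprintf("C%02d", seq_along(comps)),
    richness = richness,
    n_replicates = ifelse(richness == 1, 3L, ifelse(richness == n, 6L, 2L)),
    stringsAsFactors = FALSE)
  structure(list(pool = pool,
                 self_replicates = stats::setNames(rep(self_rep, n), codes),
                 other_replicates = other,
                 control_replicates = stats::setNames(rep(control_rep, n),
                                                      codes),
                 communities = communities,
                 membership = data.frame(
                   community_id = rep(communities$community_id, richness),
                   species = unlist(comps), stringsAsFactors = FALSE),
                 seed = 0L),
            class = "psf_design")
}

# effect matrix with a chosen uniform self effect and unit other effects
diag_effect <- function(pool, self = 0.9) {
  n <- nrow(pool)
  e <- matrix(1, n, n, dimnames = list(pool$code, pool$code))
  diag(e) <- self
  e
}

# a single-species rate matrix for direct simulator checks
one_species_params <- function(r, K = 1e12, K_mode = "species_K",
                               conversion = 0, code = "Aa", b0 = 1) {
  rm <- matrix(r, 1, 2, dimnames = list(code, c(code, "background")))
  K <- if (K_mode == "species_K") stats::setNames(K, code) else K
  growth_params(rm, K, K_mode, conversion = conversion, b0 = b0)
}

# independent scalar discrete-logistic recurrence (oracle for monocultures)
scalar_logistic <- function(b0, r, K, steps_per_season, n_seasons,
                            reset_fraction) {
  B <- b0
  for (season in seq_len(n_seasons)) {
    if (season > 1) B <- B * reset_fraction
    for (i in seq_len(steps_per_season))
      B <- B + B * r * max(0, 1 - B / K)
  }
  B
}

# brute-force evaluation of the additive-partition definition (oracle)
brute_partition <- function(M, Y, RY_E = rep(1 / length(M), length(M))) {
  N <- length(M)
  dRY <- Y / M - RY_E
  net <- sum(Y) - sum(RY_E * M)
  comp <- N * mean(dRY) * mean(M)
  sel <- sum((dRY - mean(dRY)) * (M - mean(M)))
  list(net = net, complementarity = comp, selection = sel)
}
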