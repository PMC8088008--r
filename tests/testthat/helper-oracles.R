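# Independent oracles and fixture builders shared across tests.

# Brute-force O(n^2) DBSCAN oracle, written directly from the definition:
# cores have >= min_points neighbours (self included) within eps; clusters
# are connected components of the core-core adjacency graph, labelled in
# ascending order of their smallest core index; border points join the
# earliest-labelled cluster among their core neighbours; the rest is noise.
dbscan_oracle <- function(x, eps, min_points) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_points

  comp <- rep(0L, n)
  comp_id <- 0L
  for (i in which(core)) {
    if (comp[i] != 0L) next
    comp_id <- comp_id + 1L
    stack <- i
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- comp_id
      nxt <- which(core & nb[v, ] & comp == 0L)
      stack <- c(stack, nxt)
    }
  }
  labels <- integer(n)
  labels[core] <- comp[core]
  for (i in which(!core)) {
    cand <- comp[core & nb[i, ]]
    if (length(cand) > 0) labels[i] <- min(cand)
  }
  labels
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration (sum of all table probabilities <= observed probability).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tiny synthetic scan table on the Garbhini-GA1 curve, no noise.
exact_curve_df <- function(n = 50, ga = seq(7, 13.5, length.out = n)) {
  crl <- invert_formula("garbhini_ga1", ga)
  base <- as.Date("2020-01-01")
  data.frame(participant_id = sprintf("C%03d", seq_len(n)),
             scan_index = 1L,
             scan_date = base + round(ga * 7),
             lmp_date = base,
             crl_cm = crl,
             delivery_date = base + round(39 * 7),
             stringsAsFactors = FALSE)
}

quiet_cfg <- function(n, seed, ...) {
  synthetic_config(n_participants = n, seed = seed, crl_noise_sd_cm = 0,
                   lmp_bias_days = 0, lmp_noise_sd_days = 0,
                   gross_error_frac = 0, ...)
}
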