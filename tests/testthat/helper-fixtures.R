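# compact cohort configurations and independent oracles shared across tests

# a small panel (one family, all retained) for fast replicate simulations
small_config <- function(n_pairs = 16L, seed = NULL, retained = 4L,
                         total = retained, effect_spec = NULL) {
  panel <- data.frame(family = "amino acids", total = as.integer(total),
                      retained = as.integer(retained))
  if (is.null(effect_spec))
    effect_spec <- data.frame(name = character(), lvr_mean = numeric(),
                              lvr_sd = numeric(), ctrl_mean = numeric(),
                              ctrl_sd = numeric())
  cohort_config(n_pairs = n_pairs, panel_spec = panel,
                effect_spec = effect_spec, pair_correlation = 0.3,
                seed = seed)
}

# paired data matrix with an optional planted mean shift in the first
# n_informative columns of the case group
make_paired_data <- function(n_pairs, p, shift = 0, n_informative = 0,
                             seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_pairs * p), 2 * n_pairs, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  group <- rep(c("LVR", "noLVR"), n_pairs)
  if (n_informative > 0)
    x[group == "LVR", seq_len(n_informative)] <-
      x[group == "LVR", seq_len(n_informative)] + shift
  list(x = x, pair = rep(sprintf("p%02d", seq_len(n_pairs)), each = 2L),
       group = group)
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# brute-force AUROC by pair counting with half-credit ties
auroc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
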