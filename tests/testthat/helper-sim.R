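# NB data simulator for single-gene differential-expression fits
sim_gene <- function(fc = 2, sigma_mouse = 0, n_per_mouse = 50,
                     n_mice_per_cond = 3, base = 3e-4, size = 1,
                     total = 3000, seed = 1) {
  set.seed(seed)
  n_mice <- 2 * n_mice_per_cond
  mice <- rep(paste0("m", seq_len(n_mice)), each = n_per_mouse)
  cond <- factor(rep(c("Y", "O"), each = n_mice_per_cond * n_per_mouse),
                 levels = c("Y", "O"))
  m_eff <- stats::setNames(exp(rnorm(n_mice, 0, sigma_mouse)),
                           unique(mice))
  totals <- rep(total, length(mice))
  mu <- total * base * ifelse(cond == "O", fc, 1) * m_eff[mice]
  list(y = rnbinom(length(mu), size = size, mu = mu), cond = cond,
       mouse = mice, totals = totals)
}

# demo-scale pipeline configuration shared across tests
demo_config <- function(seed = 11L, ...) {
  run_config(seed = seed,
             sim = tiny_config(seed = stemtraj:::stage_seed(seed,
                                                            "simulate")),
             gsea_n_perm = 200, ...)
}
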