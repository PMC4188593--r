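# Cohort generation: per-cell multiplicative jitter on conductances around
# the phenotype presets, fully reproducible from one seed.

#' Generate a two-group cohort of simulated cells
#'
#' Draws `n_per_group` cells per phenotype ("vehicle", "mk801").  Each cell's
#' maximal conductances (membrane and synaptic) receive independent
#' multiplicative log-normal jitter; the leak reversal is recalibrated per
#' cell so every cell rests near its preset resting potential (itself
#' jittered by `v_rest_sd`).  With `jitter_cv = 0` and `v_rest_sd = 0` the
#' two preset cells are returned exactly.
#'
#' @param n_per_group Integer, or length-2 vector `c(n_vehicle, n_mk801)`.
#' @param seed Integer seed; the same seed yields an identical cohort and
#'   manifest.
#' @param jitter_cv Log-normal sdlog of the conductance jitter.
#' @param v_rest_sd SD of the resting-potential jitter (mV).
#' @return List of class `fsi_cohort`: `cells` (each with `cell_id`,
#'   `group`, `params`, `syn`, `cell_seed`) and `manifest` (data frame).
#' @export
generate_cohort <- function(n_per_group, seed = 1L, jitter_cv = 0.15,
                            v_rest_sd = 1.5) {
  if (any(n_per_group < 1)) fsi_error("n_per_group must be >= 1",
                                      "invalid_params")
  n <- if (length(n_per_group) == 1) rep(n_per_group, 2) else n_per_group[1:2]
  set.seed(seed)
  groups <- rep(c("vehicle", "mk801"), n)
  cells <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    p <- fsi_params(g)
    s <- synaptic_params(g)
    jit <- function(x) x * rlnorm(1, 0, jitter_cv)
    for (nm in c("g_L", "g_Na", "g_Kv3", "g_Kd")) p[[nm]] <- jit(p[[nm]])
    p$v_rest <- p$v_rest + rnorm(1, 0, v_rest_sd)
    p$E_L <- calibrate_E_L(p, p$v_rest)
    for (nm in c("g_AMPA", "g_NMDA", "g_spont_exc", "g_spont_inh"))
      s[[nm]] <- jit(s[[nm]])
    cell_seed <- sample.int(2147483646L, 1)
    cells[[i]] <- list(
      cell_id = sprintf("%s_%02d", g, sum(groups[1:i] == g)),
      group = g, params = p, syn = s, cell_seed = cell_seed)
  }
  manifest <- data.frame(
    cell_id = vapply(cells, `[[`, character(1), "cell_id"),
    group_label = groups,
    cell_seed = vapply(cells, `[[`, numeric(1), "cell_seed"))
  structure(list(cells = cells, manifest = manifest, seed = seed,
                 jitter_cv = jitter_cv),
            class = "fsi_cohort")
}
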