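#' Preamplification reaction condition
#'
#' Carries a candidate preamplification condition. Annealing temperature and
#' Mg2+ concentration are metadata describing the wet-lab condition; the
#' amplification model itself is parameterised directly by the per-cycle
#' efficiencies `E_m` (methylated template) and `E_u` (unmethylated
#' template). Bias-favouring conditions have `E_u <= E_m`; the constructor
#' warns when that ordering is violated.
#'
#' @param annealing_temp degrees Celsius (metadata).
#' @param mg_mM MgCl2 concentration, mM (metadata).
#' @param cycles preamplification cycle count (default 12, the cycle number
#'   at which the bias statistic is defined).
#' @param E_m,E_u per-cycle amplification efficiencies in [0, 1].
#' @param amplitude_proxy_m,amplitude_proxy_u expected relative fluorescence
#'   proxies for downstream droplet signals.
#' @return An object of class `preamp_condition`.
#' @export
preamp_condition <- function(annealing_temp = 58.2, mg_mM = 3.5, cycles = 12L,
                             E_m = 0.95, E_u = 0.4,
                             amplitude_proxy_m = 1, amplitude_proxy_u = 1) {
  if (cycles < 0) stop("cycles must be >= 0")
  if (E_m < 0 || E_m > 1 || E_u < 0 || E_u > 1)
    stop("efficiencies must lie in [0, 1]")
  if (E_u > E_m)
    warning("E_u > E_m: condition does not favour methylated template")
  structure(list(annealing_temp = annealing_temp, mg_mM = mg_mM,
                 cycles = as.integer(cycles), E_m = E_m, E_u = E_u,
                 amplitude_proxy_m = amplitude_proxy_m,
                 amplitude_proxy_u = amplitude_proxy_u),
            class = "preamp_condition")
}

#' Deterministic amplification and PCR bias
#'
#' Exponential-growth model of the preamplification: after `c` cycles the
#' expected copy numbers are `N_m = N0_m (1 + E_m)^c` and
#' `N_u = N0_u (1 + E_u)^c`. The PCR bias is the percentage of methylated
#' fragments relative to the total target after the preamplification
#' cycles, `B = 100 N_m / (N_m + N_u)`.
#'
#' @param N0_m,N0_u starting copies (>= 0, not both zero).
#' @param cond a [preamp_condition()].
#' @return List with `N_m`, `N_u`, and `bias_pct`.
#' @export
amplify_deterministic <- function(N0_m, N0_u, cond = preamp_condition()) {
  stopifnot(inherits(cond, "preamp_condition"))
  if (N0_m < 0 || N0_u < 0) stop("starting copies must be >= 0")
  if (N0_m + N0_u == 0)
    stop("bias undefined: both starting copy numbers are zero")
  N_m <- N0_m * (1 + cond$E_m)^cond$cycles
  N_u <- N0_u * (1 + cond$E_u)^cond$cycles
  list(N_m = N_m, N_u = N_u, bias_pct = 100 * N_m / (N_m + N_u))
}

#' Stochastic amplification (branching process)
#'
#' One realisation of the same model as [amplify_deterministic()]: in each
#' cycle every molecule duplicates independently with probability `E`, so a
#' cycle maps `N` to `N + Binomial(N, E)`. The expectation after `c` cycles
#' is `N0 (1 + E)^c`.
#'
#' @inheritParams amplify_deterministic
#' @return List with `N_m`, `N_u`, and `bias_pct` for this realisation.
#' @export
amplify_stochastic <- function(N0_m, N0_u, cond = preamp_condition()) {
  stopifnot(inherits(cond, "preamp_condition"))
  if (N0_m < 0 || N0_u < 0) stop("starting copies must be >= 0")
  if (N0_m + N0_u == 0)
    stop("bias undefined: both starting copy numbers are zero")
  grow <- function(n, eff) {
    for (i in seq_len(cond$cycles)) n <- n + stats::rbinom(1L, n, eff)
    n
  }
  N_m <- grow(as.integer(round(N0_m)), cond$E_m)
  N_u <- grow(as.integer(round(N0_u)), cond$E_u)
  bias <- if (N_m + N_u > 0) 100 * N_m / (N_m + N_u) else NA_real_
  list(N_m = N_m, N_u = N_u, bias_pct = bias)
}

#' Screen a grid of preamplification conditions
#'
#' Applies the feasibility criteria for a usable bias-based
#' preamplification: (1) PCR bias above 90 percent, so methylated template
#' dominates; (2) methylated amplification and fluorescence amplitude near
#' their optimum (amplitude proxies above configurable floors); (3) at
#' least 500 unmethylated copies remaining after the preamplification
#' cycles, so the unmethylated channel stays detectable as an internal
#' control against false positives from exclusively methylation-specific
#' amplification.
#'
#' @param grid list of [preamp_condition()] objects, or a data.frame with
#'   columns `temp_C`, `mg_mM`, `cycles`, `E_m`, `E_u` (and optionally the
#'   amplitude proxies).
#' @param N0_m,N0_u starting copies of the 50 percent methylation standard
#'   (about 50 + 50 by default).
#' @param min_bias_pct bias floor, percent (default 90; strict >).
#' @param min_copies_u unmethylated-copy floor (default 500; >=).
#' @param min_amplitude_m,min_amplitude_u amplitude-proxy floors (default
#'   0: criterion inactive unless proxies are configured).
#' @return data.frame, one row per condition: metadata, `N_m`, `N_u`,
#'   `bias_pct`, per-criterion pass flags, overall `feasible`, and a
#'   `rejected_on` string naming every failed criterion (empty when
#'   feasible).
#' @export
screen_conditions <- function(grid, N0_m = 50, N0_u = 50,
                              min_bias_pct = 90, min_copies_u = 500,
                              min_amplitude_m = 0, min_amplitude_u = 0) {
  if (is.data.frame(grid)) grid <- conditions_from_df(grid)
  if (!length(grid)) stop("condition grid is empty")
  rows <- lapply(grid, function(cond) {
    res <- amplify_deterministic(N0_m, N0_u, cond)
    pass_bias <- res$bias_pct > min_bias_pct
    pass_amp <- cond$amplitude_proxy_m >= min_amplitude_m &&
      cond$amplitude_proxy_u >= min_amplitude_u
    pass_u <- res$N_u >= min_copies_u
    fails <- c(if (!pass_bias) sprintf("bias<=%g%%", min_bias_pct),
               if (!pass_amp) "amplitude_below_floor",
               if (!pass_u) sprintf("unmethylated_copies<%g", min_copies_u))
    data.frame(temp_C = cond$annealing_temp, mg_mM = cond$mg_mM,
               cycles = cond$cycles, E_m = cond$E_m, E_u = cond$E_u,
               N_m = res$N_m, N_u = res$N_u, bias_pct = res$bias_pct,
               pass_bias = pass_bias, pass_amplitude = pass_amp,
               pass_unmeth_copies = pass_u,
               feasible = pass_bias && pass_amp && pass_u,
               rejected_on = paste(fails, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build condition objects from a grid data.frame
#' @param df data.frame with `temp_C`, `mg_mM`, `cycles`, `E_m`, `E_u`, and
#'   optionally `amplitude_proxy_m`, `amplitude_proxy_u`.
#' @return List of [preamp_condition()] objects.
#' @export
conditions_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    preamp_condition(annealing_temp = df$temp_C[i], mg_mM = df$mg_mM[i],
                     cycles = df$cycles[i], E_m = df$E_m[i], E_u = df$E_u[i],
                     amplitude_proxy_m =
                       if ("amplitude_proxy_m" %in% names(df))
                         df$amplitude_proxy_m[i] else 1,
                     amplitude_proxy_u =
                       if ("amplitude_proxy_u" %in% names(df))
                         df$amplitude_proxy_u[i] else 1))
}

#' Copies-per-droplet safety check
#'
#' The mean occupancy `CPD = copies / n_droplets` must stay strictly below 6
#' for the droplet count to remain informative after the preamplification.
#'
#' @param copies_in_reaction template copies loaded into the partitioned
#'   reaction.
#' @param n_droplets droplets (> 0).
#' @param max_cpd occupancy ceiling (default 6; strict <).
#' @return List with `cpd` and logical `ok`.
#' @export
cpd_check <- function(copies_in_reaction, n_droplets, max_cpd = 6) {
  if (n_droplets <= 0) stop("n_droplets must be > 0")
  cpd <- copies_in_reaction / n_droplets
  list(cpd = cpd, ok = cpd < max_cpd)
}
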