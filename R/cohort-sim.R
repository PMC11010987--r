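#' Marker panel used throughout the package
#'
#' The five CpG-island targets quantified by the methylation-specific
#' preamplification ddPCR assay. Column names in sample sheets and
#' quantification tables use these identifiers (dashes replaced by
#' underscores, so the miR-129-2 host locus is `MIR129_2`).
#'
#' @return Character vector of marker identifiers.
#' @export
panel_markers <- function() {
  c("RASSF1A", "CCDC181", "MIR129_2", "NRIP3", "SOX8")
}

#' Group labels recognised by the simulator and the scoring layer
#' @return Character vector of the four cohort groups.
#' @export
cohort_groups <- function() {
  c("control", "BPH", "indolent_PCa", "cs_PCa")
}

#' Per-group simulation parameters
#'
#' Bundles the clinical and marker-level distribution parameters for one
#' cohort group. Marker copies/mL and cfDNA ng/mL are modelled as
#' zero-inflated log-normals parameterised by their overall mean and SD
#' (printed SDs exceed the means, which rules out a normal model); ages are
#' truncated normals; tPSA is uniform on `tpsa_range`; QfPSA (percent free
#' PSA) is a truncated normal on [1, 95].
#'
#' @param group_label one of [cohort_groups()].
#' @param age_mean,age_sd years.
#' @param age_range truncation interval in years.
#' @param tpsa_range total PSA interval, ng/mL (`lower < upper`).
#' @param qfpsa_mean,qfpsa_sd percent.
#' @param cfdna_mean,cfdna_sd plasma cfDNA, ng/mL.
#' @param marker_params named list, one `c(mean, sd)` pair of methylated
#'   copies/mL plasma per marker.
#' @param zero_fraction probability that a marker is truly absent in a
#'   sample (point mass at zero mixed into the log-normal).
#' @return An object of class `group_params`.
#' @export
group_params <- function(group_label, age_mean, age_sd, age_range,
                         tpsa_range, qfpsa_mean, qfpsa_sd,
                         cfdna_mean, cfdna_sd, marker_params,
                         zero_fraction = 0) {
  group_label <- match.arg(group_label, cohort_groups())
  stopifnot(is.numeric(tpsa_range), length(tpsa_range) == 2L)
  vals <- c(age_mean, age_sd, qfpsa_mean, qfpsa_sd, cfdna_mean, cfdna_sd,
            tpsa_range, age_range, zero_fraction,
            unlist(marker_params, use.names = FALSE))
  if (any(!is.finite(vals)))
    stop("non-finite group parameter for group '", group_label, "'")
  if (age_mean < 0 || age_sd < 0 || cfdna_mean < 0 || cfdna_sd < 0)
    stop("means and sds must be >= 0")
  if (zero_fraction < 0 || zero_fraction > 1)
    stop("zero_fraction must lie in [0, 1]")
  if (tpsa_range[1] >= tpsa_range[2])
    stop("tpsa_range lower bound must be below its upper bound")
  for (mk in names(marker_params)) {
    p <- marker_params[[mk]]
    if (length(p) != 2L || any(p < 0))
      stop("marker_params[['", mk, "']] must be c(mean, sd) with values >= 0")
  }
  structure(list(group_label = group_label,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 tpsa_range = tpsa_range,
                 qfpsa_mean = qfpsa_mean, qfpsa_sd = qfpsa_sd,
                 cfdna_mean = cfdna_mean, cfdna_sd = cfdna_sd,
                 marker_params = marker_params,
                 zero_fraction = zero_fraction),
            class = "group_params")
}

#' Default group parameters for the simulated screening cohort
#'
#' Encodes the study conditions the simulator emulates: healthy controls are
#' young blood donors (age <= 30), patient groups are elderly men in the
#' diagnostic grey zone of total PSA (2-15 ng/mL; indolent disease < 10
#' ng/mL). Where a group summary is printed in the source cohort (ages
#' 67.4 +/- 10.5 / 71.8 +/- 9.7 years, cfDNA 22.0 +/- 17.7 / 47.4 +/- 84.0 /
#' 75.0 +/- 135.6 ng/mL, MIR129_2 107.7 +/- 151.1 / 172.0 +/- 206.4
#' copies/mL, CCDC181 128.6 +/- 529.9 / 108.5 +/- 399.7 copies/mL) those
#' values are used verbatim; the remaining marker/group means are package
#' defaults chosen to respect the observed ordering control < BPH < PCa for
#' the informative markers, and the inversion BPH > PCa for CCDC181 (the
#' marker that fails to discriminate). See the methods vignette.
#'
#' @return Named list of [group_params()] objects, one per group.
#' @export
default_group_params <- function() {
  mk <- function(RASSF1A, CCDC181, MIR129_2, NRIP3, SOX8)
    list(RASSF1A = RASSF1A, CCDC181 = CCDC181, MIR129_2 = MIR129_2,
         NRIP3 = NRIP3, SOX8 = SOX8)
  list(
    control = group_params(
      "control", age_mean = 24, age_sd = 3, age_range = c(18, 30),
      tpsa_range = c(0.2, 2.0), qfpsa_mean = 30, qfpsa_sd = 10,
      cfdna_mean = 22.0, cfdna_sd = 17.7,
      marker_params = mk(c(10, 20), c(30, 60), c(15, 30), c(8, 15), c(5, 12)),
      zero_fraction = 0.50),
    BPH = group_params(
      "BPH", age_mean = 67.4, age_sd = 10.5, age_range = c(40, 95),
      tpsa_range = c(2, 15), qfpsa_mean = 22, qfpsa_sd = 8,
      cfdna_mean = 47.4, cfdna_sd = 84.0,
      marker_params = mk(c(60, 90), c(128.6, 529.9), c(107.7, 151.1),
                         c(50, 80), c(40, 70)),
      zero_fraction = 0.25),
    indolent_PCa = group_params(
      "indolent_PCa", age_mean = 71.8, age_sd = 9.7, age_range = c(40, 95),
      tpsa_range = c(2, 10), qfpsa_mean = 18, qfpsa_sd = 8,
      cfdna_mean = 75.0, cfdna_sd = 135.6,
      marker_params = mk(c(80, 120), c(110, 400), c(120, 160),
                         c(70, 100), c(60, 90)),
      zero_fraction = 0.15),
    cs_PCa = group_params(
      "cs_PCa", age_mean = 71.8, age_sd = 9.7, age_range = c(40, 95),
      tpsa_range = c(2, 15), qfpsa_mean = 14, qfpsa_sd = 6,
      cfdna_mean = 75.0, cfdna_sd = 135.6,
      marker_params = mk(c(150, 200), c(108.5, 399.7), c(172.0, 206.4),
                         c(130, 180), c(120, 170)),
      zero_fraction = 0.10)
  )
}

#' Droplet-generation parameters for a simulated ddPCR well
#'
#' @param n_droplets droplets per well; the instrument class emulated
#'   partitions a reaction into about 20,000 droplets.
#' @param droplet_volume_nl droplet volume in nanolitres (0.85 nL typical).
#' @param cluster_mean_neg,cluster_mean_pos negative/positive cluster centres
#'   per channel (length-2: FAM, HEX), relative fluorescence units.
#' @param cluster_sd within-cluster amplitude SD (RFU).
#' @param rain_fraction proportion of droplets with intermediate ("rain")
#'   amplitudes, drawn between the inter-cluster midpoint and the droplet's
#'   own cluster centre; must lie in [0, 0.2].
#' @param baseline_sd SD of the per-well, per-channel baseline offset added
#'   to every droplet (removed again by [normalize_well()]).
#' @param reaction_input_fraction fraction of the concentrated eluate loaded
#'   per well (4 uL of a 12 uL eluate by default).
#' @param preamp_gain_m,preamp_gain_u effective fold-amplification of
#'   methylated/unmethylated targets during preamplification. The defaults
#'   are deliberately modest effective gains that keep well occupancy in the
#'   countable range (copies per droplet below 6).
#' @return An object of class `ddpcr_params`.
#' @export
ddpcr_params <- function(n_droplets = 20000L, droplet_volume_nl = 0.85,
                         cluster_mean_neg = c(1000, 1000),
                         cluster_mean_pos = c(5000, 4200),
                         cluster_sd = 100, rain_fraction = 0.02,
                         baseline_sd = 50,
                         reaction_input_fraction = 4 / 12,
                         preamp_gain_m = 64, preamp_gain_u = 4) {
  if (n_droplets <= 0) stop("n_droplets must be > 0")
  if (any(cluster_mean_pos <= cluster_mean_neg))
    stop("cluster_mean_pos must exceed cluster_mean_neg on both channels")
  if (rain_fraction < 0 || rain_fraction > 0.2)
    stop("rain_fraction must lie in [0, 0.2]")
  structure(list(n_droplets = as.integer(n_droplets),
                 droplet_volume_nl = droplet_volume_nl,
                 cluster_mean_neg = cluster_mean_neg,
                 cluster_mean_pos = cluster_mean_pos,
                 cluster_sd = cluster_sd, rain_fraction = rain_fraction,
                 baseline_sd = baseline_sd,
                 reaction_input_fraction = reaction_input_fraction,
                 preamp_gain_m = preamp_gain_m,
                 preamp_gain_u = preamp_gain_u),
            class = "ddpcr_params")
}

#' Simulation configuration
#'
#' @param group_sizes named integer vector over [cohort_groups()]; the
#'   defaults are the screening-study sizes 90/40/7/32.
#' @param groups named list of [group_params()] (default
#'   [default_group_params()]).
#' @param ddpcr a [ddpcr_params()] object.
#' @param markers marker subset to simulate.
#' @param seed integer seed; a fixed seed makes cohorts and wells
#'   bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(control = 90L, BPH = 40L,
                                       indolent_PCa = 7L, cs_PCa = 32L),
                       groups = default_group_params(),
                       ddpcr = ddpcr_params(),
                       markers = panel_markers(),
                       seed = 1L) {
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  if (!all(names(group_sizes) %in% cohort_groups()))
    stop("unknown group label in group_sizes")
  if (!all(names(group_sizes) %in% names(groups)))
    stop("missing group_params for some group in group_sizes")
  structure(list(group_sizes = group_sizes, groups = groups, ddpcr = ddpcr,
                 markers = markers, seed = as.integer(seed)),
            class = "sim_config")
}

# truncated-normal draw by inverse-CDF; degenerate sd collapses to the
# (clamped) mean
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# zero-inflated log-normal reparameterised so the *mixture* mean and SD equal
# (m, s). Requires zero_fraction < s^2/(s^2+m^2) for a positive log-normal
# variance; validated at draw time.
rzilnorm <- function(n, m, s, zero_fraction = 0) {
  if (m == 0) return(numeric(n))
  if (s == 0) {
    out <- rep(m, n)
    if (zero_fraction > 0) out[stats::runif(n) < zero_fraction] <- 0
    return(out)
  }
  q <- 1 - zero_fraction
  mu_c <- m / q                       # mean of the positive component
  var_c <- (s^2 + m^2) / q - mu_c^2   # variance of the positive component
  if (var_c <= 0)
    stop("zero_fraction too large for the requested mean/sd ",
         "(needs zero_fraction < s^2/(s^2+m^2))")
  sdlog2 <- log(1 + var_c / mu_c^2)
  meanlog <- log(mu_c) - sdlog2 / 2
  out <- stats::rlnorm(n, meanlog, sqrt(sdlog2))
  if (zero_fraction > 0) out[stats::runif(n) < zero_fraction] <- 0
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per simulated patient: age, total and free PSA, QfPSA
#' (percent free PSA), plasma volume, plasma cfDNA load, and methylated
#' copies/mL plasma for each marker, with the group label retained as ground
#' truth. Marker levels are zero-inflated log-normals whose mixture mean/SD
#' equal the configured values, so group-wise sample moments converge to the
#' `group_params` entries.
#'
#' @param config a [sim_config()].
#' @return A `data.frame`, one row per patient, with columns `sample_id`,
#'   `group`, `age`, `tPSA`, `fPSA`, `QfPSA`, `cfDNA_ng_ml`, `plasma_ml` and
#'   one copies/mL column per simulated marker.
#' @examples
#' coh <- generate_cohort(sim_config(seed = 7))
#' aggregate(MIR129_2 ~ group, coh, mean)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pieces <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0L) return(NULL)
    gp <- config$groups[[g]]
    age <- rnorm_trunc(n, gp$age_mean, gp$age_sd,
                       gp$age_range[1], gp$age_range[2])
    tpsa <- stats::runif(n, gp$tpsa_range[1], gp$tpsa_range[2])
    qfpsa <- rnorm_trunc(n, gp$qfpsa_mean, gp$qfpsa_sd, 1, 95)
    df <- data.frame(
      sample_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      age = age,
      tPSA = tpsa,
      fPSA = qfpsa / 100 * tpsa,
      QfPSA = qfpsa,
      cfDNA_ng_ml = rzilnorm(n, gp$cfdna_mean, gp$cfdna_sd, 0),
      plasma_ml = stats::runif(n, 2, 5),
      stringsAsFactors = FALSE)
    for (mk in config$markers) {
      p <- gp$marker_params[[mk]]
      df[[mk]] <- rzilnorm(n, p[1], p[2], gp$zero_fraction)
    }
    df
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = cohort_groups())
  out
}

#' Stochastic loss between plasma and preamplification input
#'
#' Extraction recovery and bisulphite survival act as a single binomial
#' thinning of the plasma copies: each molecule survives independently with
#' probability `recovery_fraction * bisulphite_survival`.
#'
#' @param copies_plasma_per_ml methylated copies per mL plasma (>= 0).
#' @param plasma_volume_ml processed plasma volume (> 0 unless copies are 0).
#' @param recovery_fraction,bisulphite_survival survival probabilities in
#'   [0, 1].
#' @return Integer copy count entering preamplification.
#' @export
simulate_preamp_input <- function(copies_plasma_per_ml, plasma_volume_ml,
                                  recovery_fraction = 0.8,
                                  bisulphite_survival = 0.7) {
  if (plasma_volume_ml < 0) stop("plasma volume must be >= 0")
  if (recovery_fraction < 0 || recovery_fraction > 1 ||
      bisulphite_survival < 0 || bisulphite_survival > 1)
    stop("recovery_fraction and bisulphite_survival must lie in [0, 1]")
  if (copies_plasma_per_ml < 0) stop("copies must be >= 0")
  n0 <- round(copies_plasma_per_ml * plasma_volume_ml)
  stats::rbinom(1L, n0, recovery_fraction * bisulphite_survival)
}

# amplitudes for one channel given per-droplet molecule counts
.channel_amplitudes <- function(counts, mean_neg, mean_pos, sd, rain_fraction) {
  n <- length(counts)
  pos <- counts > 0L
  amp <- stats::rnorm(n, ifelse(pos, mean_pos, mean_neg), sd)
  if (rain_fraction > 0) {
    rain <- which(stats::runif(n) < rain_fraction)
    if (length(rain)) {
      mid <- (mean_neg + mean_pos) / 2
      # rain stays on the droplet's own side of the midpoint: positives
      # drizzle down towards it, negatives lift up towards it
      lo <- ifelse(pos[rain], mid, mean_neg)
      hi <- ifelse(pos[rain], mean_pos, mid)
      amp[rain] <- stats::runif(length(rain), lo, hi)
    }
  }
  amp
}

#' Simulate one two-channel ddPCR well
#'
#' Distributes the methylated (FAM/ch1) and unmethylated (HEX/ch2) template
#' molecules over the droplets by uniform multinomial partitioning; droplets
#' holding at least one molecule of a channel's target emit that channel's
#' positive-cluster amplitude, the rest the negative-cluster amplitude. A
#' per-well baseline offset is added to every droplet of each channel, and a
#' configurable fraction of droplets shows intermediate "rain" amplitudes.
#'
#' @param copies_m,copies_u true template copies per channel in the well.
#' @param params a [ddpcr_params()].
#' @param well_id,sample_id,marker,replicate metadata carried on the well.
#' @return An object of class `droplet_well`: list with `ch1`, `ch2`
#'   amplitude vectors, `n_droplets`, metadata, and the true per-droplet
#'   molecule counts in `counts_m`/`counts_u` (simulation ground truth).
#' @export
simulate_well <- function(copies_m, copies_u, params = ddpcr_params(),
                          well_id = "A01", sample_id = "S1",
                          marker = "RASSF1A", replicate = 1L) {
  stopifnot(inherits(params, "ddpcr_params"))
  if (copies_m < 0 || copies_u < 0) stop("copies must be >= 0")
  n <- params$n_droplets
  if (n <= 0) stop("n_droplets must be > 0")
  part <- function(copies) {
    if (copies == 0) return(integer(n))
    tabulate(sample.int(n, copies, replace = TRUE), nbins = n)
  }
  cm <- part(round(copies_m))
  cu <- part(round(copies_u))
  base1 <- stats::rnorm(1, 0, params$baseline_sd)
  base2 <- stats::rnorm(1, 0, params$baseline_sd)
  ch1 <- .channel_amplitudes(cm, params$cluster_mean_neg[1],
                             params$cluster_mean_pos[1], params$cluster_sd,
                             params$rain_fraction) + base1
  ch2 <- .channel_amplitudes(cu, params$cluster_mean_neg[2],
                             params$cluster_mean_pos[2], params$cluster_sd,
                             params$rain_fraction) + base2
  structure(list(well_id = well_id, sample_id = sample_id, marker = marker,
                 replicate = as.integer(replicate), ch1 = ch1, ch2 = ch2,
                 n_droplets = n, counts_m = cm, counts_u = cu,
                 normalized = FALSE),
            class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat("ddPCR well", x$well_id, "- sample", x$sample_id, "marker", x$marker,
      "replicate", x$replicate, "\n")
  cat(sprintf("  %d droplets; ch1 range [%.0f, %.0f], ch2 range [%.0f, %.0f]%s\n",
              x$n_droplets, min(x$ch1), max(x$ch1), min(x$ch2), max(x$ch2),
              if (isTRUE(x$normalized)) " (baseline-normalized)" else ""))
  invisible(x)
}

#' Simulate the duplicate ddPCR wells for one patient and marker
#'
#' Applies the plasma-to-well chain: binomial thinning for extraction and
#' bisulphite survival, loading of the eluate fraction per well, effective
#' preamplification gain per channel, then droplet partitioning. The two
#' replicate wells are independent partitioning realisations of the same
#' underlying sample (each with its own loading draw). The unmethylated
#' channel carries the genomic background inferred from the sample's cfDNA
#' load (`ge_per_ng` haploid genome equivalents per ng).
#'
#' @param record one cohort row (see [generate_cohort()]).
#' @param marker marker name (a column of `record`).
#' @param params [ddpcr_params()].
#' @param recovery_fraction,bisulphite_survival see
#'   [simulate_preamp_input()].
#' @param ge_per_ng genome equivalents per ng cfDNA (default 303).
#' @param replicates number of replicate wells (duplicates by default).
#' @return List of `droplet_well` objects.
#' @export
simulate_patient_wells <- function(record, marker, params = ddpcr_params(),
                                   recovery_fraction = 0.8,
                                   bisulphite_survival = 0.7,
                                   ge_per_ng = 303, replicates = 2L) {
  pre_m <- simulate_preamp_input(record[[marker]], record$plasma_ml,
                                 recovery_fraction, bisulphite_survival)
  u_per_ml <- record$cfDNA_ng_ml * ge_per_ng
  pre_u <- simulate_preamp_input(u_per_ml, record$plasma_ml,
                                 recovery_fraction, bisulphite_survival)
  lapply(seq_len(replicates), function(r) {
    in_m <- stats::rbinom(1L, pre_m, params$reaction_input_fraction)
    in_u <- stats::rbinom(1L, pre_u, params$reaction_input_fraction)
    simulate_well(in_m * params$preamp_gain_m,
                  in_u * params$preamp_gain_u,
                  params,
                  well_id = sprintf("%s_%s_r%d", record$sample_id, marker, r),
                  sample_id = record$sample_id, marker = marker,
                  replicate = r)
  })
}

#' Write a cohort sample sheet
#' @param cohort data.frame from [generate_cohort()].
#' @param path output CSV path.
#' @export
write_sample_sheet <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet
#' @param path CSV written by [write_sample_sheet()].
#' @return data.frame with `group` as a factor over [cohort_groups()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = cohort_groups())
  df
}

#' Write droplet-level well data as CSV
#'
#' One row per droplet with columns `well_id`, `sample_id`, `marker`,
#' `replicate`, `ch1_amplitude`, `ch2_amplitude` — the dialect the
#' quantification layer reads back.
#'
#' @param wells a `droplet_well` or list of them.
#' @param path output CSV path.
#' @export
write_droplet_csv <- function(wells, path) {
  if (inherits(wells, "droplet_well")) wells <- list(wells)
  dfs <- lapply(wells, function(w)
    data.frame(well_id = w$well_id, sample_id = w$sample_id,
               marker = w$marker, replicate = w$replicate,
               ch1_amplitude = w$ch1, ch2_amplitude = w$ch2))
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read droplet-level CSV into well objects
#'
#' Reads the dialect written by [write_droplet_csv()]. Instrument-style
#' exports with other column names (e.g. `Ch1 Amplitude`) are supported via
#' `col_map`, a named character vector mapping the expected names to the
#' file's names.
#'
#' @param path CSV path.
#' @param col_map optional mapping, e.g.
#'   `c(ch1_amplitude = "Ch1.Amplitude", ch2_amplitude = "Ch2.Amplitude")`.
#' @return List of `droplet_well` objects (one per distinct well_id).
#' @export
read_droplet_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      have <- col_map[[std]]
      if (!have %in% names(df))
        stop("column '", have, "' not found in ", path)
      names(df)[names(df) == have] <- std
    }
  }
  need <- c("well_id", "ch1_amplitude", "ch2_amplitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("droplet CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(df)) df$sample_id <- df$well_id
  if (!"marker" %in% names(df)) df$marker <- NA_character_
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  lapply(split(df, df$well_id), function(d)
    structure(list(well_id = d$well_id[1], sample_id = d$sample_id[1],
                   marker = d$marker[1], replicate = as.integer(d$replicate[1]),
                   ch1 = d$ch1_amplitude, ch2 = d$ch2_amplitude,
                   n_droplets = nrow(d), counts_m = NULL, counts_u = NULL,
                   normalized = FALSE),
              class = "droplet_well"))
}
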