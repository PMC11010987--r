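#' Volume model linking reaction-level copies to copies per mL plasma
#'
#' The sample chain concentrates the cfDNA of `plasma_ml` millilitres of
#' plasma into a final eluate of `eluate_ul` microlitres, of which
#' `input_ul` are loaded per well. Copies measured in the reaction are
#' scaled back by the eluate/input ratio, divided by the preamplification
#' gain, and divided by the plasma volume. With the default `preamp_gain = 1`
#' the reported value is the reaction-level quantity rescaled by volumes
#' only; an explicit gain expresses the alternative convention of reporting
#' pre-amplification template numbers.
#'
#' @param plasma_ml processed plasma volume, mL.
#' @param eluate_ul final concentrated eluate volume, uL (default 12).
#' @param input_ul eluate loaded per well, uL (default 4).
#' @param preamp_gain fold-gain divisor per channel (scalar or length-2
#'   c(methylated, unmethylated)).
#' @return An object of class `volume_model`.
#' @export
volume_model <- function(plasma_ml = 3, eluate_ul = 12, input_ul = 4,
                         preamp_gain = 1) {
  if (any(c(plasma_ml, eluate_ul, input_ul, preamp_gain) <= 0))
    stop("all volumes and gains must be > 0")
  if (length(preamp_gain) == 1L) preamp_gain <- rep(preamp_gain, 2L)
  structure(list(plasma_ml = plasma_ml, eluate_ul = eluate_ul,
                 input_ul = input_ul, preamp_gain = preamp_gain),
            class = "volume_model")
}

#' Baseline-normalize a droplet well
#'
#' Fluorescence amplitudes are re-expressed relative to the well-specific
#' baseline so wells can be compared across runs. The baseline of each
#' channel is estimated in two passes: the median of the droplets below the
#' channel's 60th amplitude percentile locates the negative cluster (which
#' dominates at the low occupancies typical for cfDNA work), and the median
#' over all droplets within five MADs of that location re-centres the
#' estimate without the truncation bias of the first pass. The baseline is
#' subtracted from every droplet.
#'
#' @param well a `droplet_well`.
#' @param quantile_cut percentile below which droplets are used for the
#'   baseline estimate (default 0.60).
#' @return The well with baseline-relative amplitudes and
#'   `normalized = TRUE`.
#' @export
normalize_well <- function(well, quantile_cut = 0.60) {
  stopifnot(inherits(well, "droplet_well"))
  if (well$n_droplets < 100)
    warning("fewer than 100 droplets: baseline estimate is low-confidence")
  for (ch in c("ch1", "ch2")) {
    a <- well[[ch]]
    # pass 1: a coarse location inside the negative cluster
    cut <- stats::quantile(a, quantile_cut, names = FALSE)
    rough <- stats::median(a[a <= cut])
    # pass 2: re-centre on all droplets near the rough location, undoing
    # the downward truncation bias of pass 1
    spread <- stats::mad(a[a <= cut])
    keep <- if (spread > 0) abs(a - rough) <= 5 * spread else a <= cut
    base <- stats::median(a[keep])
    well[[ch]] <- a - base
  }
  well$normalized <- TRUE
  well
}

# 2-centre split of one channel's normalized amplitudes; returns the
# midpoint threshold, or +Inf when the well is single-cluster (no positives
# distinguishable from noise). Cluster locations/spreads are medians/MADs
# of the k-means assignment so that intermediate "rain" droplets cannot
# drag the centres or blow up the separation gate.
.channel_threshold <- function(amp, min_separation_sd = 10) {
  rng <- range(amp)
  spread_sd <- stats::mad(amp)
  if (spread_sd == 0) spread_sd <- stats::sd(amp)
  if (!is.finite(spread_sd) || spread_sd == 0) return(Inf)
  km <- suppressWarnings(stats::kmeans(amp, centers = rng, iter.max = 50))
  lower <- km$cluster == which.min(km$centers)
  c_lo <- stats::median(amp[lower]); c_hi <- stats::median(amp[!lower])
  mad_lo <- stats::mad(amp[lower]); mad_hi <- stats::mad(amp[!lower])
  within_sd <- max(mad_lo, mad_hi, 1e-8)
  if (c_hi - c_lo < min_separation_sd * max(within_sd, spread_sd))
    return(Inf)                      # one cluster: call nothing positive
  (c_lo + c_hi) / 2
}

#' Classify droplets as positive/negative per channel
#'
#' Counts droplets strictly above the classification threshold of each
#' channel. By default the threshold is placed at the midpoint between the
#' two k-means cluster centres of the normalized amplitudes; wells whose
#' amplitude distribution shows no second cluster (separation below
#' `min_separation_sd` within-cluster SDs) yield zero positives. A fixed RFU
#' threshold per channel can be supplied instead.
#'
#' @param well a normalized `droplet_well`.
#' @param threshold optional fixed threshold(s), length 1 or 2 (FAM, HEX),
#'   in baseline-relative RFU; must be >= 0.
#' @param min_separation_sd cluster-separation gate for the automatic
#'   threshold.
#' @return List with `k_m`, `k_u` (positive counts per channel), `n`
#'   (droplets), and the thresholds used.
#' @export
classify_droplets <- function(well, threshold = NULL, min_separation_sd = 5) {
  stopifnot(inherits(well, "droplet_well"))
  if (!isTRUE(well$normalized))
    warning("classifying a well that has not been baseline-normalized")
  if (is.null(threshold)) {
    thr <- c(.channel_threshold(well$ch1, min_separation_sd),
             .channel_threshold(well$ch2, min_separation_sd))
  } else {
    if (any(threshold < 0))
      stop("threshold below 0 after normalization is invalid")
    thr <- rep(threshold, length.out = 2L)
  }
  list(k_m = sum(well$ch1 > thr[1]), k_u = sum(well$ch2 > thr[2]),
       n = well$n_droplets, threshold = thr)
}

#' Invert a positive-droplet count to a Poisson concentration
#'
#' Under uniform random partitioning the number of target molecules per
#' droplet is Poisson(lambda); a droplet is positive when it holds at least
#' one molecule, so the positive fraction estimates `1 - exp(-lambda)` and
#' `lambda = -log(1 - k/n)`. The total copies in the partitioned reaction
#' are `lambda * n`.
#'
#' @param k positive droplets (0 <= k <= n).
#' @param n total droplets (> 0).
#' @return List with `lambda`, `copies_reaction`, `k`, `n`, `p_hat`.
#' @export
poisson_concentration <- function(k, n) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (k == n)
    stop("saturated well (every droplet positive): dilute the sample and re-run")
  lambda <- -log(1 - k / n)
  list(lambda = lambda, copies_reaction = lambda * n, k = k, n = n,
       p_hat = k / n)
}

#' Convert reaction-level copies to copies per mL plasma
#'
#' `copies_reaction * (eluate_ul / input_ul) / preamp_gain / plasma_ml`.
#'
#' @param copies_reaction copies in the partitioned reaction.
#' @param vm a [volume_model()].
#' @param channel 1 (methylated) or 2 (unmethylated); selects the gain
#'   divisor.
#' @return Copies per mL plasma.
#' @export
copies_per_ml <- function(copies_reaction, vm = volume_model(), channel = 1L) {
  stopifnot(inherits(vm, "volume_model"))
  if (vm$plasma_ml <= 0) stop("plasma volume must be > 0")
  copies_reaction * (vm$eluate_ul / vm$input_ul) /
    vm$preamp_gain[channel] / vm$plasma_ml
}

#' Positive-call rule over replicate wells
#'
#' A sample x marker combination is called positive when at least two
#' replicate wells each show more than five positive droplets on the
#' methylated channel. The stringent rule guards against over-calling
#' marginal amounts of methylated template after the strongly
#' methylation-biased preamplification.
#'
#' @param k_m_replicates integer vector of methylated-channel positive
#'   counts, one per replicate well.
#' @param min_droplets positivity floor per well (a well counts when
#'   `k_m > min_droplets`; default 5).
#' @param min_wells wells required above the floor (default 2).
#' @return Logical call, or `NA` (flagged indeterminate) with fewer than two
#'   replicates.
#' @export
call_sample <- function(k_m_replicates, min_droplets = 5L, min_wells = 2L) {
  if (length(k_m_replicates) < 2L) {
    warning("single replicate: positive call is indeterminate")
    return(NA)
  }
  sum(k_m_replicates > min_droplets) >= min_wells
}

#' Fractional abundance of methylated fragments
#'
#' `100 * m / (m + u)` percent; undefined when both channels are zero.
#'
#' @param copies_m,copies_u methylated/unmethylated copies (>= 0).
#' @return Percent in [0, 100].
#' @export
fractional_abundance <- function(copies_m, copies_u) {
  if (copies_m < 0 || copies_u < 0) stop("copies must be >= 0")
  if (copies_m + copies_u == 0)
    stop("fractional abundance undefined: both channels are zero")
  100 * copies_m / (copies_m + copies_u)
}

#' Spike-in recovery
#'
#' Percent recovery of a known amount of external standard DNA spiked into
#' plasma before extraction and bisulphite conversion. Values above
#' `qc_ceiling` are flagged (possible quantification artefact), as is a zero
#' recovery.
#'
#' @param measured_copies,expected_copies measured and spiked copies;
#'   `expected_copies > 0`.
#' @param qc_ceiling flag threshold in percent (default 120).
#' @return List with `recovery_pct` and `qc_pass`.
#' @export
spike_recovery <- function(measured_copies, expected_copies,
                           qc_ceiling = 120) {
  if (expected_copies <= 0) stop("expected_copies must be > 0")
  pct <- 100 * measured_copies / expected_copies
  list(recovery_pct = pct, qc_pass = pct > 0 && pct <= qc_ceiling)
}

#' Quantify one droplet well end to end
#'
#' Normalizes, classifies, and inverts both channels of a well to
#' copies/mL plasma plus fractional abundance.
#'
#' @param well a `droplet_well`.
#' @param vm a [volume_model()].
#' @param threshold optional fixed classification threshold(s).
#' @return One-row data.frame: `well_id`, `sample_id`, `marker`,
#'   `replicate`, `k_m`, `k_u`, `n`, `lambda_m`, `lambda_u`,
#'   `copies_per_ml_m`, `copies_per_ml_u`, `FA`.
#' @export
quantify_well <- function(well, vm = volume_model(), threshold = NULL) {
  w <- if (isTRUE(well$normalized)) well else normalize_well(well)
  cl <- classify_droplets(w, threshold)
  qm <- poisson_concentration(cl$k_m, cl$n)
  qu <- poisson_concentration(cl$k_u, cl$n)
  cm <- copies_per_ml(qm$copies_reaction, vm, channel = 1L)
  cu <- copies_per_ml(qu$copies_reaction, vm, channel = 2L)
  fa <- if (cm + cu > 0) 100 * cm / (cm + cu) else NA_real_
  data.frame(well_id = w$well_id, sample_id = w$sample_id, marker = w$marker,
             replicate = w$replicate, k_m = cl$k_m, k_u = cl$k_u, n = cl$n,
             lambda_m = qm$lambda, lambda_u = qu$lambda,
             copies_per_ml_m = cm, copies_per_ml_u = cu, FA = fa,
             stringsAsFactors = FALSE)
}

#' Quantify replicate wells into per-sample marker results
#'
#' Aggregates the replicate wells of each sample x marker combination:
#' copies/mL are averaged over replicates and the positive call applies the
#' two-wells-above-five-droplets rule.
#'
#' @param wells list of `droplet_well` objects.
#' @param vm a [volume_model()]; its `plasma_ml` is overridden per sample
#'   when `sample_sheet` (with `sample_id`, `plasma_ml`) is given.
#' @param sample_sheet optional cohort sheet supplying per-sample plasma
#'   volumes.
#' @param threshold optional fixed classification threshold(s).
#' @return data.frame, one row per sample x marker: mean copies/mL per
#'   channel, fractional abundance, replicate count, and `positive_call`.
#' @export
quantify_samples <- function(wells, vm = volume_model(), sample_sheet = NULL,
                             threshold = NULL) {
  per_well <- do.call(rbind, lapply(wells, function(w) {
    v <- vm
    if (!is.null(sample_sheet)) {
      i <- match(w$sample_id, sample_sheet$sample_id)
      if (!is.na(i)) v$plasma_ml <- sample_sheet$plasma_ml[i]
    }
    quantify_well(w, v, threshold)
  }))
  key <- interaction(per_well$sample_id, per_well$marker, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_well, key), function(d) {
    data.frame(sample_id = d$sample_id[1], marker = d$marker[1],
               n_replicates = nrow(d),
               copies_per_ml_m = mean(d$copies_per_ml_m),
               copies_per_ml_u = mean(d$copies_per_ml_u),
               FA = mean(d$FA),
               positive_call = if (nrow(d) >= 2L)
                 call_sample(d$k_m) else NA,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a per-sample quantification table
#' @param quant data.frame from [quantify_samples()].
#' @param path output CSV path.
#' @export
write_quant_csv <- function(quant, path) {
  utils::write.csv(quant, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
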