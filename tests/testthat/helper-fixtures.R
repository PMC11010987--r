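# shared fixture builders (everything generated in code; no stored data)

# a bare droplet well built directly from amplitude vectors
make_well <- function(ch1, ch2 = ch1, normalized = FALSE, well_id = "W1") {
  structure(list(well_id = well_id, sample_id = "S1", marker = "RASSF1A",
                 replicate = 1L, ch1 = ch1, ch2 = ch2,
                 n_droplets = length(ch1), counts_m = NULL, counts_u = NULL,
                 normalized = normalized),
            class = "droplet_well")
}

# a tiny labelled cohort data.frame from explicit component values
make_tiny_cohort <- function(group, ...) {
  vals <- list(...)
  df <- data.frame(sample_id = sprintf("P%02d", seq_along(group)),
                   group = factor(group, levels = cohort_groups()),
                   stringsAsFactors = FALSE)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  df
}

# independent brute-force calibration oracle: exhaustive loop over the
# midpoint candidate grids of each component, keeping the admissible
# combination with the best BPH specificity. Written as plain nested loops,
# no shared code with the implementation.
oracle_best_spe <- function(data, components, direction, tau,
                            target_groups) {
  grids <- lapply(seq_along(components), function(j) {
    v <- sort(unique(data[[components[j]]]))
    if (length(v) == 1L) c(v - 1, v + 1)
    else c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  })
  grp <- as.character(data$group)
  is_t <- grp %in% target_groups
  is_b <- grp == "BPH"
  best <- -1
  idx <- rep(1L, length(components))
  sizes <- vapply(grids, length, 0L)
  repeat {
    theta <- mapply(function(g, i) g[i], grids, idx)
    s <- rep(0L, nrow(data))
    for (j in seq_along(components)) {
      x <- data[[components[j]]]
      fl <- if (direction[j] == "below") x < theta[j] else x > theta[j]
      s <- s + fl
    }
    pos <- s >= tau
    if (all(pos[is_t])) {
      spe <- mean(!pos[is_b])
      if (spe > best) best <- spe
    }
    # odometer increment
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) break
  }
  100 * best
}

# concordant-pair AUC oracle (Mann-Whitney identity, half credit for ties)
oracle_pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
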