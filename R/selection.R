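#' Tissue labels recognised by the selection layer
#' @return Character vector of valid tissue labels.
#' @export
tissue_labels <- function() {
  c("PCa_tissue", "prostate_normal", "bladder", "kidney", "liver", "lung",
    "WBC", "serum_ctrl", "serum_PCa")
}

#' Construct a beta-value matrix with tissue labels
#'
#' Container for array-style methylation beta values (probes x samples, all
#' in [0, 1] or missing) with one tissue label per sample. This is the
#' Level-3-preprocessed shape: no raw-intensity normalisation happens here.
#'
#' @param beta numeric matrix, probes in rows, samples in columns;
#'   `rownames` are probe ids, `colnames` sample ids.
#' @param tissue character/factor of length `ncol(beta)` over
#'   [tissue_labels()].
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, tissue) {
  if (!is.matrix(beta)) beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%08d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%04d", seq_len(ncol(beta)))
  if (length(tissue) != ncol(beta))
    stop("tissue labels must cover every sample")
  tissue <- as.character(tissue)
  bad <- setdiff(unique(tissue), tissue_labels())
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  vals <- beta[is.finite(beta)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("beta values must lie in [0, 1] (or be missing)")
  structure(list(beta = beta, tissue = tissue), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples\n")
  print(table(x$tissue))
  invisible(x)
}

#' Drop masked probes from a beta matrix
#'
#' Removes probes listed in a mask (general-exclusion lists of the array
#' manifest: cross-reactive probes, SNP overlaps, and similar) while
#' preserving the original probe order.
#'
#' @param bm a [beta_matrix()].
#' @param mask character vector of probe ids to exclude.
#' @return The filtered `beta_matrix`; warns when every probe is masked.
#' @export
apply_probe_mask <- function(bm, mask) {
  stopifnot(inherits(bm, "beta_matrix"))
  keep <- !(rownames(bm$beta) %in% mask)
  if (!any(keep)) warning("probe mask removed every probe")
  bm$beta <- bm$beta[keep, , drop = FALSE]
  bm
}

# two-sample p-value on beta values: Welch t by default, label-permutation
# fallback when either group is small. Constant data => p = 1 by convention.
.two_group_p <- function(x, y, n_perm = 999L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(c(x, y)) == 0) return(1)
  if (min(length(x), length(y)) < 5L) {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    nx <- length(x)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nx)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
        cnt <- cnt + 1L
    }
    return((cnt + 1L) / (n_perm + 1L))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Per-probe tumour-vs-tissue contrasts
#'
#' For every probe and every normal tissue, computes the methylation
#' difference `delta_beta = mean(tumour) - mean(tissue)` and a two-sample
#' p-value (Welch's t by default; an exact-style label-permutation test when
#' a group has fewer than five samples). Mean beta values of the white-blood
#' -cell and control-serum samples are attached as the cfDNA background of
#' each probe. Missing betas are dropped pairwise per probe, never imputed.
#'
#' @param bm a [beta_matrix()].
#' @param tumour_label tissue label of the tumour group (default
#'   `"PCa_tissue"`).
#' @param normal_labels tissue labels contrasted against the tumour.
#' @param perm_seed seed for the permutation fallback (deterministic
#'   contrasts).
#' @return data.frame, one row per probe x contrast: `probe_id`, `tissue`,
#'   `delta_beta`, `p_value`, `background_beta_WBC`,
#'   `background_beta_serum_ctrl`.
#' @export
probe_contrasts <- function(bm, tumour_label = "PCa_tissue",
                            normal_labels = c("prostate_normal", "bladder",
                                              "kidney", "liver", "lung"),
                            perm_seed = 1L) {
  stopifnot(inherits(bm, "beta_matrix"))
  for (lb in c(tumour_label, normal_labels))
    if (!lb %in% bm$tissue) stop("tissue label absent from matrix: ", lb)
  for (lb in c(tumour_label, normal_labels))
    if (sum(bm$tissue == lb) < 2L)
      stop("tissue label needs >= 2 samples: ", lb)
  set.seed(perm_seed)
  tum <- bm$beta[, bm$tissue == tumour_label, drop = FALSE]
  bg_wbc <- if ("WBC" %in% bm$tissue)
    rowMeans(bm$beta[, bm$tissue == "WBC", drop = FALSE], na.rm = TRUE)
  else rep(NA_real_, nrow(bm$beta))
  bg_ser <- if ("serum_ctrl" %in% bm$tissue)
    rowMeans(bm$beta[, bm$tissue == "serum_ctrl", drop = FALSE], na.rm = TRUE)
  else rep(NA_real_, nrow(bm$beta))
  rows <- lapply(normal_labels, function(lb) {
    nrm <- bm$beta[, bm$tissue == lb, drop = FALSE]
    data.frame(
      probe_id = rownames(bm$beta),
      tissue = lb,
      delta_beta = rowMeans(tum, na.rm = TRUE) - rowMeans(nrm, na.rm = TRUE),
      p_value = vapply(seq_len(nrow(bm$beta)), function(i)
        .two_group_p(tum[i, ], nrm[i, ]), numeric(1)),
      background_beta_WBC = bg_wbc,
      background_beta_serum_ctrl = bg_ser,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection criteria for candidate markers
#'
#' @param alpha per-contrast significance level (default 0.001, applied to
#'   raw p-values; set `bonferroni = TRUE` to divide by the number of
#'   probes).
#' @param min_delta_beta minimum tumour-minus-tissue methylation gain per
#'   contrast (default 0.2).
#' @param max_background_beta ceiling on the WBC and control-serum mean
#'   betas (default 0.10; healthy cfDNA backgrounds of usable markers sit
#'   well below 10 percent methylation).
#' @param allowed_exceptions data.frame with columns `probe_id`, `tissue`:
#'   contrasts exempt from the significance/delta requirements (records an
#'   explicitly tolerated tissue, e.g. a marker elevated in one non-target
#'   tissue that is still carried forward).
#' @param bonferroni apply a Bonferroni correction across probes (off by
#'   default; the selection operates on raw p-values).
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(alpha = 0.001, min_delta_beta = 0.2,
                               max_background_beta = 0.10,
                               allowed_exceptions = NULL,
                               bonferroni = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, min_delta_beta = min_delta_beta,
                 max_background_beta = max_background_beta,
                 allowed_exceptions = allowed_exceptions,
                 bonferroni = bonferroni),
            class = "selection_criteria")
}

#' Select and rank candidate marker probes
#'
#' Keeps probes that are (i) significantly hypermethylated in tumour versus
#' every contrasted normal tissue (`p < alpha` and
#' `delta_beta > min_delta_beta`, except contrasts listed in
#' `allowed_exceptions`) and (ii) show low cfDNA background (WBC and
#' control-serum means `<= max_background_beta`). Survivors are ranked by
#' their worst-case margin — the minimum `delta_beta` across non-exempt
#' contrasts — in descending order, ties broken by probe id.
#'
#' @param contrasts data.frame from [probe_contrasts()].
#' @param criteria a [selection_criteria()].
#' @return data.frame of selected probes: `probe_id`, `min_delta_beta`,
#'   `max_p_value`, backgrounds, `rank`.
#' @export
select_markers <- function(contrasts, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  if (!nrow(contrasts)) stop("contrasts are empty")
  alpha <- criteria$alpha
  if (criteria$bonferroni)
    alpha <- alpha / length(unique(contrasts$probe_id))
  ex <- criteria$allowed_exceptions
  exempt <- if (!is.null(ex) && nrow(ex))
    paste(contrasts$probe_id, contrasts$tissue) %in% paste(ex$probe_id, ex$tissue)
  else rep(FALSE, nrow(contrasts))
  ok <- exempt |
    (!is.na(contrasts$p_value) & contrasts$p_value < alpha &
       contrasts$delta_beta > criteria$min_delta_beta)
  keep_rows <- lapply(split(seq_len(nrow(contrasts)), contrasts$probe_id),
                      function(idx) {
    if (!all(ok[idx])) return(NULL)
    bg_w <- contrasts$background_beta_WBC[idx[1]]
    bg_s <- contrasts$background_beta_serum_ctrl[idx[1]]
    if (!is.na(bg_w) && bg_w > criteria$max_background_beta) return(NULL)
    if (!is.na(bg_s) && bg_s > criteria$max_background_beta) return(NULL)
    used <- idx[!exempt[idx]]
    if (!length(used)) used <- idx
    data.frame(probe_id = contrasts$probe_id[idx[1]],
               min_delta_beta = min(contrasts$delta_beta[used]),
               max_p_value = max(contrasts$p_value[used]),
               background_beta_WBC = bg_w,
               background_beta_serum_ctrl = bg_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, keep_rows)
  if (is.null(out))
    return(data.frame(probe_id = character(), min_delta_beta = numeric(),
                      max_p_value = numeric(),
                      background_beta_WBC = numeric(),
                      background_beta_serum_ctrl = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  ord <- order(-out$min_delta_beta, out$probe_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a beta matrix from TSV plus a sample-label CSV
#'
#' The TSV holds probes in rows (first column = probe id) and samples in
#' columns; the label CSV has columns `sample_id`, `tissue`.
#'
#' @param beta_path TSV path.
#' @param labels_path CSV path.
#' @return A [beta_matrix()].
#' @export
read_beta_tsv <- function(beta_path, labels_path) {
  tab <- utils::read.delim(beta_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  beta <- as.matrix(tab[, -1, drop = FALSE])
  rownames(beta) <- tab[[1]]
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  idx <- match(colnames(beta), labels$sample_id)
  if (anyNA(idx)) stop("label file missing samples: ",
                       paste(colnames(beta)[is.na(idx)], collapse = ", "))
  beta_matrix(beta, labels$tissue[idx])
}

#' Write a beta matrix as TSV plus a sample-label CSV
#' @param bm a [beta_matrix()].
#' @param beta_path,labels_path output paths.
#' @export
write_beta_tsv <- function(bm, beta_path, labels_path) {
  tab <- data.frame(probe_id = rownames(bm$beta), bm$beta,
                    check.names = FALSE)
  utils::write.table(tab, beta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(data.frame(sample_id = colnames(bm$beta),
                              tissue = bm$tissue),
                   labels_path, row.names = FALSE, quote = FALSE)
  invisible(beta_path)
}

#' Simulate a beta-value matrix with planted differential probes
#'
#' Generates array-like beta values from Beta distributions per tissue:
#' background probes share a low methylation level everywhere; planted
#' probes are hypermethylated in tumour tissue only (and optionally in one
#' exception tissue), with low WBC/serum background — the structure the
#' selection filter is designed to detect.
#'
#' @param n_probes total probes.
#' @param planted character vector of probe indices/names to plant, or an
#'   integer count.
#' @param n_per_tissue named integer vector of samples per tissue label.
#' @param tumour_beta,normal_beta mean beta of planted probes in tumour and
#'   elsewhere.
#' @param precision Beta-distribution precision (a+b); larger = tighter.
#' @param seed RNG seed.
#' @return List with the [beta_matrix()] `bm` and `planted` probe ids.
#' @export
simulate_beta_matrix <- function(n_probes = 50, planted = 5,
                                 n_per_tissue = c(PCa_tissue = 30,
                                                  prostate_normal = 20,
                                                  bladder = 10, kidney = 20,
                                                  liver = 15, lung = 15,
                                                  WBC = 40, serum_ctrl = 5),
                                 tumour_beta = 0.6, normal_beta = 0.05,
                                 precision = 50, seed = 1L) {
  set.seed(seed)
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  if (length(planted) == 1L && is.numeric(planted))
    planted <- probe_ids[seq_len(planted)]
  tissue <- rep(names(n_per_tissue), n_per_tissue)
  n_samp <- length(tissue)
  rbeta_mu <- function(n, mu) stats::rbeta(n, mu * precision,
                                           (1 - mu) * precision)
  beta <- matrix(rbeta_mu(n_probes * n_samp, normal_beta),
                 nrow = n_probes, dimnames = list(probe_ids, NULL))
  tum_cols <- which(tissue == "PCa_tissue")
  for (p in planted)
    beta[p, tum_cols] <- rbeta_mu(length(tum_cols), tumour_beta)
  list(bm = beta_matrix(beta, tissue), planted = planted)
}
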