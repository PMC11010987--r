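#' Sensitivity and specificity from confusion counts
#'
#' `SEN = 100 TP / (TP + FN)`, `SPE = 100 TN / (TN + FP)`. A metric whose
#' denominator class is empty is returned as `NA` (undefined).
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return List with `sen_pct` and `spe_pct`.
#' @export
sen_spe <- function(TP = 0, FP = 0, TN = 0, FN = 0) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be >= 0")
  list(sen_pct = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
       spe_pct = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_)
}

#' Confusion counts from calls and labels
#'
#' @param calls logical biopsy calls (TRUE = positive).
#' @param labels logical disease status (TRUE = case).
#' @return List of `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(calls, labels) {
  stopifnot(length(calls) == length(labels))
  list(TP = sum(calls & labels), FP = sum(calls & !labels),
       TN = sum(!calls & !labels), FN = sum(!calls & labels))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (positive =
#' score strictly above threshold), so tied scores move along the curve as
#' one simultaneous step; the AUC is the trapezoidal area. On integer
#' composite scores the curve is coarse and stepwise; the AUC equals the
#' concordant-pair fraction with half-credit for ties (the rank-sum
#' identity).
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels binary labels (1/TRUE = case); both classes must be
#'   present.
#' @return List with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for a ROC curve")
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) sum(scores > t & labels == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores > t & labels == 0L) / n_neg, 0)
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1); tpr <- c(0, tpr[ord], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       points = data.frame(threshold = c(Inf, thr[ord], -Inf),
                           fpr = fpr, tpr = tpr))
}

# Games-Howell post hoc: pairwise Welch t statistics referred to the
# studentized-range distribution
.games_howell <- function(values, groups) {
  gs <- split(values, groups)
  k <- length(gs)
  nm <- names(gs)
  res <- NULL
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    xi <- gs[[i]]; xj <- gs[[j]]
    vi <- stats::var(xi) / length(xi); vj <- stats::var(xj) / length(xj)
    se <- sqrt(vi + vj)
    t_ij <- abs(mean(xi) - mean(xj)) / se
    df <- (vi + vj)^2 / (vi^2 / (length(xi) - 1) + vj^2 / (length(xj) - 1))
    p <- stats::ptukey(t_ij * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    res <- rbind(res, data.frame(group1 = nm[i], group2 = nm[j],
                                 p_value = p, stringsAsFactors = FALSE))
  }
  res
}

# Conover-Iman post hoc on ranks after Kruskal-Wallis (tie-corrected)
.conover <- function(values, groups, H) {
  r <- rank(values)
  gs <- split(r, groups)
  N <- length(values); k <- length(gs)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  denom_scale <- S2 * (N - 1 - H) / (N - k)
  nm <- names(gs)
  res <- NULL
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ni <- length(gs[[i]]); nj <- length(gs[[j]])
    t_ij <- (mean(gs[[i]]) - mean(gs[[j]])) /
      sqrt(denom_scale * (1 / ni + 1 / nj))
    p <- 2 * stats::pt(abs(t_ij), df = N - k, lower.tail = FALSE)
    res <- rbind(res, data.frame(group1 = nm[i], group2 = nm[j],
                                 p_value = p, stringsAsFactors = FALSE))
  }
  res
}

#' Group comparison via the normality/homoscedasticity decision tree
#'
#' Gates: per-group Shapiro-Wilk normality and Levene's test (median-
#' centred) for equal variances. All groups normal and homoscedastic:
#' one-way ANOVA with Tukey's post hoc. Normal but heteroscedastic: Welch's
#' ANOVA with Games-Howell. Any group non-normal: Kruskal-Wallis with
#' Conover's post hoc (non-normal homoscedastic data take this conservative
#' route as well). Post hoc tests run only when the omnibus test is
#' significant at 0.05. Significance tiers 0.05/0.01/0.001.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 groups, each with >= 3 values).
#' @param alpha_gate significance level of the gate tests (default 0.05).
#' @return An object of class `group_test`: chosen `path`, per-group
#'   normality p-values, Levene p, omnibus p, pairwise p-value table (NULL
#'   when the omnibus is not significant), and the tier string of the
#'   omnibus p.
#' @export
group_test <- function(values, groups, alpha_gate = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  gs <- split(values, groups)
  if (any(vapply(gs, length, 0L) < 3L))
    stop("every group needs n >= 3")
  if (any(vapply(gs, function(g) stats::sd(g) == 0, TRUE)))
    stop("degenerate (constant) group: comparison is undefined")
  shapiro_p <- vapply(gs, function(g)
    stats::shapiro.test(g)$p.value, numeric(1))
  levene_p <- car::leveneTest(values ~ groups, center = "median")[1, "Pr(>F)"]
  normal <- all(shapiro_p >= alpha_gate)
  homosced <- levene_p >= alpha_gate
  if (normal && homosced) {
    path <- "anova_tukey"
    fit <- stats::aov(values ~ groups)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pairwise <- if (omnibus_p < alpha_gate) {
      tk <- stats::TukeyHSD(fit)$groups
      data.frame(comparison = rownames(tk), p_value = tk[, "p adj"],
                 row.names = NULL, stringsAsFactors = FALSE)
    }
  } else if (normal) {
    path <- "welch_gameshowell"
    omnibus_p <- stats::oneway.test(values ~ groups,
                                    var.equal = FALSE)$p.value
    pairwise <- if (omnibus_p < alpha_gate) .games_howell(values, groups)
  } else {
    path <- "kruskal_conover"
    kw <- stats::kruskal.test(values, groups)
    omnibus_p <- kw$p.value
    pairwise <- if (omnibus_p < alpha_gate)
      .conover(values, groups, unname(kw$statistic))
  }
  if (omnibus_p >= alpha_gate) pairwise <- NULL
  tier <- if (omnibus_p < 0.001) "***" else if (omnibus_p < 0.01) "**"
          else if (omnibus_p < 0.05) "*" else "n.s."
  structure(list(path = path, shapiro_p = shapiro_p, levene_p = levene_p,
                 omnibus_p = omnibus_p, pairwise = pairwise, tier = tier),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("group comparison path:", x$path, "\n")
  cat(sprintf("  omnibus p = %.4g (%s); Levene p = %.4g\n",
              x$omnibus_p, x$tier, x$levene_p))
  if (!is.null(x$pairwise)) {
    cat("  post hoc:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Biopsy-avoidance summary
#'
#' Counts negative calls (biopsies that could be avoided) within an
#' optional cohort filter; for labelled cohorts also reports how many
#' clinically significant tumours those avoided biopsies would miss.
#'
#' @param calls logical biopsy calls.
#' @param labels optional group labels aligned with `calls`.
#' @param filter optional logical vector restricting the cohort (e.g. a
#'   tPSA window).
#' @return List with `avoided`, `total`, `fraction_pct`, and (when labels
#'   are given) `missed_cs`.
#' @export
biopsy_avoidance <- function(calls, labels = NULL, filter = NULL) {
  if (is.null(filter)) filter <- rep(TRUE, length(calls))
  calls <- calls[filter]
  if (anyNA(calls)) stop("calls must be defined for every patient in filter")
  avoided <- sum(!calls)
  out <- list(avoided = avoided, total = length(calls),
              fraction_pct = if (length(calls)) 100 * avoided / length(calls)
                             else NA_real_)
  if (!is.null(labels)) {
    labels <- labels[filter]
    out$missed_cs <- sum(!calls & as.character(labels) == "cs_PCa")
  }
  out
}

#' Evaluate fitted risk models on a labelled cohort
#'
#' Convenience wrapper producing the confusion counts, SEN/SPE and AUC of
#' one or more fitted models on a cohort, using the standard convention:
#' sensitivity on the clinically significant group, specificity on BPH,
#' indolent tumours reported separately.
#'
#' @param models named list of fitted [risk_model()] objects.
#' @param data labelled cohort.
#' @param tpsa_window optional `c(lo, hi)` total-PSA filter applied to the
#'   patient groups first.
#' @return data.frame, one row per model: SEN (cs), SPE (BPH), fraction of
#'   indolent tumours called negative, and the score AUC of BPH+indolent
#'   versus clinically significant patients.
#' @export
evaluate_models <- function(models, data, tpsa_window = NULL) {
  if (!is.null(tpsa_window))
    data <- data[data$group == "control" |
                   (data$tPSA >= tpsa_window[1] & data$tPSA <= tpsa_window[2]),
                 , drop = FALSE]
  grp <- as.character(data$group)
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    rs <- risk_score(data, m)
    cs <- grp == "cs_PCa"; bph <- grp == "BPH"; ind <- grp == "indolent_PCa"
    cc <- confusion_counts(rs$call[cs | bph], cs[cs | bph])
    ss <- sen_spe(cc$TP, cc$FP, cc$TN, cc$FN)
    roc_set <- bph | ind | cs
    auc <- roc_auc(rs$score[roc_set], cs[roc_set])$auc
    data.frame(model = nm, sen_pct = ss$sen_pct, spe_pct = ss$spe_pct,
               indolent_negative_pct = if (any(ind))
                 100 * mean(!rs$call[ind]) else NA_real_,
               auc = auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
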