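#' Percent free PSA (QfPSA)
#'
#' `100 * fPSA / tPSA`. A low percentage of free PSA indicates a higher
#' prostate-cancer risk.
#'
#' @param fPSA,tPSA free/total PSA, ng/mL; `tPSA > 0`.
#' @return Percent.
#' @export
qfpsa <- function(fPSA, tPSA) {
  if (any(tPSA <= 0)) stop("tPSA must be > 0")
  100 * fPSA / tPSA
}

.variant_defaults <- function(variant) {
  base <- c("RASSF1A", "MIR129_2", "NRIP3", "SOX8", "cfDNA_ng_ml", "age")
  switch(variant,
    piRISK1 = list(components = base, tau = 3L,
                   target = c("cs_PCa", "indolent_PCa")),
    piRISK2 = list(components = base, tau = 3L, target = "cs_PCa"),
    PRISK1 = list(components = c(base, "QfPSA"), tau = 4L,
                  target = c("cs_PCa", "indolent_PCa")),
    PRISK2 = list(components = c(base, "QfPSA"), tau = 4L, target = "cs_PCa"))
}

.component_directions <- function(components) {
  # QfPSA scores a point when BELOW its cutoff; every other component when
  # strictly ABOVE (age, cfDNA load, and methylated copies are risk factors
  # at high values)
  ifelse(components == "QfPSA", "below", "above")
}

# flag matrix: n x k logical, strict exceedance in the risk direction
.flag_matrix <- function(data, components, theta, direction) {
  miss <- setdiff(components, names(data))
  if (length(miss))
    stop("record lacks component(s): ", paste(miss, collapse = ", "))
  out <- sapply(seq_along(components), function(j) {
    x <- data[[components[j]]]
    if (anyNA(x)) stop("missing values in component ", components[j])
    if (direction[j] == "below") x < theta[j] else x > theta[j]
  })
  matrix(out, ncol = length(components),
         dimnames = list(NULL, components))
}

#' Per-component risk flags for patient records
#'
#' A component scores one point when it exceeds its cutoff in the risk
#' direction: strictly above the cutoff for age, cfDNA/mL and methylated
#' copies/mL, strictly below the cutoff for QfPSA.
#'
#' @param data data.frame of patient records containing the model's
#'   component columns.
#' @param model a fitted [risk_model()].
#' @return Logical matrix, one row per record, one column per component.
#' @export
component_flags <- function(data, model) {
  stopifnot(inherits(model, "risk_model"))
  .flag_matrix(data, model$components, model$theta, model$direction)
}

#' Composite risk score and biopsy call
#'
#' The score is the count of components exceeding their cutoffs in the risk
#' direction; the call is positive (biopsy indicated) when the score
#' reaches the decision threshold `tau`, so "score below tau" defines the
#' biopsy-avoidable class.
#'
#' @inheritParams component_flags
#' @return data.frame with `score` (integer) and `call` (logical).
#' @export
risk_score <- function(data, model) {
  fl <- component_flags(data, model)
  s <- as.integer(rowSums(fl))
  data.frame(score = s, call = s >= model$tau)
}

# candidate cutoffs between order statistics, plus flanking values that
# flag everyone / no-one
.candidate_cutoffs <- function(x) {
  v <- sort(unique(x))
  if (length(v) == 1L) return(c(v - 1, v + 1))
  c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
}

# conservative-tie key: larger theta preferred for "above" components,
# smaller for "below" (both mean fewer flags raised)
.tie_key <- function(theta, direction) {
  ifelse(direction == "below", theta, -theta)
}

.eval_model <- function(flags_sum, tau, is_target, is_bph) {
  pos <- flags_sum >= tau
  list(sen_ok = all(pos[is_target]),
       spe = if (any(is_bph)) mean(!pos[is_bph]) else NA_real_)
}

#' Fit (calibrate) a composite risk-score model
#'
#' Calibrates per-component cutoffs for one of the four score variants on a
#' labelled cohort. The admissible parameterisations are those whose score
#' detects every patient of the sensitivity-target set (100 percent
#' sensitivity): all clinically significant and indolent tumours for
#' variants 1 (piRISK1/PRISK1), clinically significant tumours only for
#' variants 2. Among admissible cutoffs the calibration maximises
#' specificity on the BPH group; ties are broken towards more conservative
#' positivity (larger cutoffs for "above"-direction components, smaller for
#' QfPSA), then by component order.
#'
#' Cutoff candidates are the midpoints between consecutive order statistics
#' of each component (plus flanking values): for a step-function score the
#' optimum always lies between observed values. The search is exhaustive
#' when the candidate grid is small (`<= exact_limit` combinations) and a
#' deterministic coordinate descent otherwise, started from the
#' all-flags-raised parameterisation (which is always admissible) and
#' accepting only admissible moves, so the fitted model satisfies the
#' sensitivity constraint by construction.
#'
#' @param data data.frame with a `group` column over [cohort_groups()] and
#'   the component columns.
#' @param variant one of `"piRISK1"`, `"piRISK2"`, `"PRISK1"`, `"PRISK2"`.
#' @param components,tau,sensitivity_target override the variant defaults.
#' @param exact_limit exhaustive-search ceiling on the number of cutoff
#'   combinations (default 20000).
#' @param max_sweeps coordinate-descent sweep limit.
#' @return An object of class `risk_model` with elements `variant`,
#'   `components`, `direction`, `theta`, `tau`, `sensitivity_target`,
#'   `achieved` (training SEN/SPE and counts), and `search` (method used).
#' @examples
#' coh <- generate_cohort(sim_config(seed = 3))
#' fit <- risk_model(coh, "PRISK2")
#' fit
#' head(predict(fit, coh))
#' @export
risk_model <- function(data, variant = c("PRISK2", "PRISK1", "piRISK1",
                                         "piRISK2"),
                       components = NULL, tau = NULL,
                       sensitivity_target = NULL,
                       exact_limit = 20000, max_sweeps = 20L) {
  variant <- match.arg(variant)
  def <- .variant_defaults(variant)
  if (is.null(components)) components <- def$components
  if (is.null(tau)) tau <- def$tau
  if (is.null(sensitivity_target)) sensitivity_target <- def$target
  if (grepl("^PRISK", variant) && !"QfPSA" %in% components)
    stop("PRISK variants include QfPSA")
  if (grepl("^piRISK", variant) && "QfPSA" %in% components)
    stop("piRISK variants exclude QfPSA")
  if (tau < 1) stop("tau must be >= 1")
  if (!"group" %in% names(data)) stop("data needs a 'group' column")
  direction <- .component_directions(components)
  k <- length(components)
  grp <- as.character(data$group)
  is_target <- grp %in% sensitivity_target
  is_bph <- grp == "BPH"
  for (g in sensitivity_target)
    if (!any(grp == g)) stop("cohort has no patients of target class ", g)
  if (!any(is_bph)) stop("cohort has no BPH patients to set specificity")
  if (tau > k)
    stop("no parameterisation can achieve 100% sensitivity: tau (", tau,
         ") exceeds the component count (", k, ") for patients ",
         paste(data$sample_id[is_target], collapse = ", "))

  cands <- lapply(components, function(cp) .candidate_cutoffs(data[[cp]]))
  names(cands) <- components
  n_comb <- prod(vapply(cands, length, numeric(1)))

  # per-component flag matrices over all candidates (patients x candidates)
  flag_list <- lapply(seq_len(k), function(j) {
    x <- data[[components[j]]]
    if (anyNA(x)) stop("missing values in component ", components[j])
    th <- cands[[j]]
    if (direction[j] == "below") outer(x, th, "<") else outer(x, th, ">")
  })

  pick_best <- function(theta_idx_a, theta_idx_b) {
    # deterministic tie-break between two candidate index vectors with
    # equal SPE: compare conservative-tie keys component by component
    ta <- vapply(seq_len(k), function(j) cands[[j]][theta_idx_a[j]], 0)
    tb <- vapply(seq_len(k), function(j) cands[[j]][theta_idx_b[j]], 0)
    ka <- .tie_key(ta, direction); kb <- .tie_key(tb, direction)
    for (j in seq_len(k)) {
      if (ka[j] < kb[j]) return(theta_idx_a)
      if (kb[j] < ka[j]) return(theta_idx_b)
    }
    theta_idx_a
  }

  if (n_comb <= exact_limit) {
    search <- "exhaustive"
    grid <- as.matrix(expand.grid(lapply(cands, seq_along),
                                  KEEP.OUT.ATTRS = FALSE))
    best_idx <- NULL; best_spe <- -1
    for (r in seq_len(nrow(grid))) {
      idx <- grid[r, ]
      s <- rowSums(vapply(seq_len(k), function(j) flag_list[[j]][, idx[j]],
                          logical(nrow(data))))
      ev <- .eval_model(s, tau, is_target, is_bph)
      if (!ev$sen_ok) next
      if (ev$spe > best_spe) {
        best_spe <- ev$spe; best_idx <- idx
      } else if (ev$spe == best_spe) {
        best_idx <- pick_best(best_idx, idx)
      }
    }
  } else {
    search <- "coordinate_descent"
    # one-dimensional move objective, lexicographic: (1) BPH specificity,
    # (2) fewer total flags raised on BPH patients. The secondary term
    # gives tied moves a direction — pulling cutoffs up drains BPH scores
    # towards the decision threshold even while the flipped-patient count
    # is momentarily flat — and decreases monotonically, so the descent
    # terminates.
    descend <- function(start_idx) {
      idx <- start_idx
      flag_cur <- vapply(seq_len(k), function(j) flag_list[[j]][, idx[j]],
                         logical(nrow(data)))
      for (sweep in seq_len(max_sweeps)) {
        changed <- FALSE
        for (j in seq_len(k)) {
          others <- rowSums(flag_cur[, -j, drop = FALSE])
          th <- cands[[j]]
          spe_j <- rep(-Inf, length(th))
          load_j <- rep(Inf, length(th))
          for (ci in seq_along(th)) {
            s <- others + flag_list[[j]][, ci]
            ev <- .eval_model(s, tau, is_target, is_bph)
            if (ev$sen_ok) {
              spe_j[ci] <- ev$spe
              load_j[ci] <- sum(flag_list[[j]][is_bph, ci])
            }
          }
          best <- which(spe_j == max(spe_j))
          best <- best[load_j[best] == min(load_j[best])]
          key <- .tie_key(th[best], rep(direction[j], length(best)))
          pick <- best[which.min(key)]
          better <- spe_j[pick] > spe_j[idx[j]] ||
            (spe_j[pick] == spe_j[idx[j]] && load_j[pick] < load_j[idx[j]])
          if (pick != idx[j] && better) {
            idx[j] <- pick
            flag_cur[, j] <- flag_list[[j]][, pick]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      idx
    }
    # start 1: every flag raised (always admissible since tau <= k)
    start_allflags <- vapply(seq_len(k), function(j)
      if (direction[j] == "below") length(cands[[j]]) else 1L, integer(1))
    # start 2: marginal 100%-sensitivity cutoffs — the tightest cutoff per
    # component that still flags every sensitivity-target patient
    start_marginal <- vapply(seq_len(k), function(j) {
      admissible <- which(colSums(!flag_list[[j]][is_target, , drop = FALSE])
                          == 0L)
      key <- .tie_key(cands[[j]][admissible],
                      rep(direction[j], length(admissible)))
      admissible[which.min(key)]
    }, integer(1))
    # starts 3..(k+2): single-component rules — component j at its marginal
    # 100%-sensitivity cutoff decides alone, tau-1 other components flag
    # everyone (filling the score up to the threshold), the rest flag
    # no-one. Any one-marker decision rule is representable this way, so
    # the fitted score can never do worse than the best single component.
    idx_allflag <- start_allflags
    idx_noflag <- vapply(seq_len(k), function(j)
      if (direction[j] == "below") 1L else length(cands[[j]]), integer(1))
    start_single <- lapply(seq_len(k), function(j) {
      idx <- idx_noflag
      fill <- setdiff(seq_len(k), j)[seq_len(tau - 1)]
      idx[fill] <- idx_allflag[fill]
      idx[j] <- start_marginal[j]
      idx
    })
    # pair starts: two components decide jointly at their marginal cutoffs
    # (tau-2 fillers flag everyone, the rest no-one); lets the descent
    # escape single-component optima it cannot leave by one-coordinate
    # moves
    pairs <- if (k >= 2 && tau >= 2)
      utils::combn(k, 2, simplify = FALSE) else list()
    start_pair <- lapply(pairs, function(pr) {
      idx <- idx_noflag
      fill <- setdiff(seq_len(k), pr)[seq_len(tau - 2)]
      idx[fill] <- idx_allflag[fill]
      idx[pr] <- start_marginal[pr]
      idx
    })
    starts <- c(list(start_marginal, start_allflags), start_single,
                start_pair)
    fits <- lapply(starts, descend)
    spe_of <- function(idx) {
      s <- rowSums(vapply(seq_len(k), function(j) flag_list[[j]][, idx[j]],
                          logical(nrow(data))))
      .eval_model(s, tau, is_target, is_bph)$spe
    }
    spes <- vapply(fits, spe_of, numeric(1))
    top <- which(spes == max(spes))
    best_idx <- fits[[top[1]]]
    for (t2 in top[-1]) best_idx <- pick_best(best_idx, fits[[t2]])
  }

  theta <- vapply(seq_len(k), function(j) cands[[j]][best_idx[j]], numeric(1))
  names(theta) <- components
  s <- rowSums(.flag_matrix(data, components, theta, direction))
  pos <- s >= tau
  achieved <- list(
    sen_pct = 100 * mean(pos[is_target]),
    spe_pct = 100 * mean(!pos[is_bph]),
    n_target = sum(is_target), n_bph = sum(is_bph))
  stopifnot(achieved$sen_pct == 100)  # constraint holds by construction
  structure(list(variant = variant, components = components,
                 direction = direction, theta = theta, tau = tau,
                 sensitivity_target = sensitivity_target,
                 achieved = achieved, search = search,
                 call = match.call()),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Composite risk-score model:", x$variant, "\n")
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  cat("  decision threshold: score >=", x$tau, "is biopsy-positive\n")
  cat(sprintf("  training SEN %.1f%% (n=%d, target: %s), SPE %.1f%% (n=%d BPH)\n",
              x$achieved$sen_pct, x$achieved$n_target,
              paste(x$sensitivity_target, collapse = "+"),
              x$achieved$spe_pct, x$achieved$n_bph))
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  structure(list(model = object), class = "summary.risk_model")
}

#' @export
print.summary.risk_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-component cutoffs (a point is scored when the value is",
      "strictly on the risk side):\n")
  print(data.frame(component = m$components,
                   cutoff = unname(m$theta),
                   risk_side = m$direction), row.names = FALSE)
  cat("\ncalibration search:", m$search, "\n")
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$theta

#' Predict risk scores and biopsy calls
#'
#' @param object a fitted [risk_model()].
#' @param newdata data.frame with the model's component columns.
#' @param type `"response"` (data.frame with score and call), `"score"`,
#'   `"call"`, or `"flags"`.
#' @param ... unused.
#' @export
predict.risk_model <- function(object, newdata,
                               type = c("response", "score", "call", "flags"),
                               ...) {
  type <- match.arg(type)
  if (type == "flags") return(component_flags(newdata, object))
  rs <- risk_score(newdata, object)
  switch(type, response = rs, score = rs$score, call = rs$call)
}

#' ROC curve of a fitted risk model on a labelled cohort
#'
#' Plots the stepwise ROC of the integer score for BPH (+ optionally
#' indolent) versus the sensitivity-target class, with the calibrated
#' operating point marked.
#'
#' @param x a fitted [risk_model()].
#' @param data labelled cohort.
#' @param negative_groups groups forming the negative class (default BPH and
#'   indolent tumours, mirroring the evaluation convention).
#' @param ... passed to [graphics::plot()].
#' @export
plot.risk_model <- function(x, data,
                            negative_groups = c("BPH", "indolent_PCa"), ...) {
  grp <- as.character(data$group)
  keep <- grp %in% c(negative_groups, x$sensitivity_target)
  sc <- risk_score(data[keep, , drop = FALSE], x)
  lab <- as.integer(grp[keep] %in% x$sensitivity_target)
  r <- roc_auc(sc$score, lab)
  graphics::plot(r$points$fpr, r$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("%s (AUC = %.2f)", x$variant, r$auc), ...)
  graphics::abline(0, 1, lty = 3)
  op <- c(1 - x$achieved$spe_pct / 100, x$achieved$sen_pct / 100)
  graphics::points(op[1], op[2], pch = 19)
  invisible(r)
}

#' Simulate cohorts from a fitted model's training conditions
#'
#' Draws `nsim` fresh synthetic cohorts under a simulation configuration and
#' returns the model's calls on each — useful for checking call stability
#' under resampling.
#'
#' @param object a fitted [risk_model()].
#' @param nsim number of simulated cohorts.
#' @param seed integer seed for the first cohort (incremented per cohort).
#' @param config a [sim_config()] describing the cohort distribution.
#' @param ... unused.
#' @return List of data.frames (`score`, `call`, `group`), one per cohort.
#' @export
simulate.risk_model <- function(object, nsim = 1, seed = 1L,
                                config = sim_config(), ...) {
  lapply(seq_len(nsim), function(i) {
    config$seed <- as.integer(seed + i - 1L)
    coh <- generate_cohort(config)
    cbind(risk_score(coh, object), group = coh$group)
  })
}

#' Best achievable specificity of a single component at 100% sensitivity
#'
#' For a one-component decision rule (positive strictly above the cutoff,
#' or strictly below for QfPSA-like markers), computes the maximum BPH
#' specificity over all cutoffs that still detect every sensitivity-target
#' patient. This is the single-marker baseline that composite scores are
#' measured against.
#'
#' @param data labelled cohort.
#' @param component column name.
#' @param direction `"above"` or `"below"` (risk side).
#' @param target_groups sensitivity-target classes.
#' @return List with `spe_pct` and the limiting `cutoff`.
#' @export
single_component_spe <- function(data, component = "QfPSA",
                                 direction = c("below", "above"),
                                 target_groups = "cs_PCa") {
  direction <- match.arg(direction)
  x <- data[[component]]
  grp <- as.character(data$group)
  tv <- x[grp %in% target_groups]
  bv <- x[grp == "BPH"]
  if (!length(tv) || !length(bv)) stop("need target and BPH patients")
  if (direction == "below") {
    cutoff <- max(tv)               # positive iff x < cutoff + eps
    spe <- 100 * mean(bv > cutoff)
  } else {
    cutoff <- min(tv)               # positive iff x > cutoff - eps
    spe <- 100 * mean(bv < cutoff)
  }
  list(spe_pct = spe, cutoff = cutoff)
}

#' Write a fitted risk model as JSON
#' @param model a [risk_model()].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(variant = model$variant, components = model$components,
         direction = model$direction, theta = as.list(model$theta),
         tau = model$tau, sensitivity_target = model$sensitivity_target,
         achieved = model$achieved),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted risk model from JSON
#' @param path JSON written by [write_model_json()].
#' @return A `risk_model` object.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- unlist(j$theta)
  structure(list(variant = j$variant, components = j$components,
                 direction = j$direction, theta = theta, tau = j$tau,
                 sensitivity_target = j$sensitivity_target,
                 achieved = j$achieved, search = "loaded", call = NULL),
            class = "risk_model")
}
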