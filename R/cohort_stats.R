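# Circuit-level summaries and cohort statistics: connectivity/suppression
# proportions, Kruskal-Wallis comparisons with two-stage adaptive FDR
# control, and location-based connectivity regression.

# integer percent, rounding half away from zero (matches printed proportions)
percent_round <- function(k, n) floor(100 * k / n + 0.5)

#' Summarize one circuit's cohort
#'
#' Counts and integer-rounded percentages of connected and suppressed cells
#' (each over the cells for which that assay was performed and classifiable),
#' plus amplitude (reported in nA) and latency summaries over connected cells.
#' Cells excluded by QC must be removed upstream.
#'
#' @param cell_results Data frame of per-cell results for one circuit, with
#'   logical columns `connected` and `suppressed` (NA = not assayed) and
#'   numeric `mean_amplitude_pA`, `mean_latency_ms`.
#' @return A one-row tibble of class `cohort_summary`.
#' @export
summarize_cohort <- function(cell_results) {
  cell_results <- as.data.frame(cell_results)
  if (nrow(cell_results) == 0L) stop("zero cells in cohort")
  circuit <- unique(cell_results$circuit)
  if (length(circuit) != 1L) stop("cell results span more than one circuit")
  conn <- cell_results$connected[!is.na(cell_results$connected)]
  supp <- cell_results$suppressed[!is.na(cell_results$suppressed)]
  amps_na <- cell_results$mean_amplitude_pA[
    !is.na(cell_results$connected) & cell_results$connected] / 1000
  lats <- cell_results$mean_latency_ms[
    !is.na(cell_results$connected) & cell_results$connected]
  stat4 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(mean(x), stats::sd(x), min(x), max(x))
  }
  a <- stat4(amps_na); l <- stat4(lats)
  out <- tibble::tibble(
    circuit = circuit,
    n_cells_connectivity = length(conn),
    n_connected = sum(conn),
    pct_connected = if (length(conn)) percent_round(sum(conn), length(conn))
                    else NA_integer_,
    n_cells_suppression = length(supp),
    n_suppressed = sum(supp),
    pct_suppressed = if (length(supp)) percent_round(sum(supp), length(supp))
                     else NA_integer_,
    amplitude_mean_nA = a[1], amplitude_sd_nA = a[2],
    amplitude_min_nA = a[3], amplitude_max_nA = a[4],
    latency_mean_ms = l[1], latency_sd_ms = l[2],
    latency_min_ms = l[3], latency_max_ms = l[4]
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Kruskal-Wallis test across circuit configurations
#'
#' Tie-corrected H statistic with the chi-square approximation, as the
#' non-parametric one-way comparison of a per-cell measurement across groups.
#'
#' @param groups List (>= 2) of numeric vectors, one per group.
#' @return List with `test`, `statistic` (H), `df`, `p_value`, `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
       df = unname(kt$parameter), p_value = kt$p.value,
       n_per_group = vapply(groups, length, integer(1)))
}

# Benjamini-Hochberg step-up at level alpha: reject the hypotheses with the
# smallest k p-values, where k is the largest index with p_(k) <= k*alpha/m.
bh_step_up <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= alpha * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Two-stage adaptive step-up FDR procedure (Benjamini-Krieger-Yekutieli)
#'
#' Stage one runs Benjamini-Hochberg at the corrected level q' = q/(1+q); the
#' number of non-rejections estimates the number of true nulls m0. If stage
#' one rejects nothing, no hypothesis is discovered; if it rejects everything,
#' all are. Otherwise stage two reruns BH at level q' * m / m0. The adaptive
#' second stage makes at least as many discoveries as plain BH at q'.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return Logical vector of discovery flags.
#' @export
bky_two_stage_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  q1 <- q / (1 + q)
  stage1 <- bh_step_up(p_values, q1)
  r1 <- sum(stage1)
  if (r1 == 0L) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  bh_step_up(p_values, q1 * m / m0)
}

#' Pairwise post-hoc comparisons with two-stage FDR control
#'
#' Rank-based (Wilcoxon) pairwise comparisons between all groups, with
#' discoveries flagged by [bky_two_stage_fdr()] at rate `q`.
#'
#' @param groups Named list of numeric vectors.
#' @param q Target FDR.
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `p_value`, `discovery`.
#' @export
pairwise_posthoc <- function(groups, q = 0.05) {
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[pr[1]]],
                                              groups[[pr[2]]], exact = FALSE))
    c(statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    statistic = res["statistic", ], p_value = res["p_value", ]
  )
  out$discovery <- bky_two_stage_fdr(out$p_value, q)
  out
}

# logistic regression by IRLS with an optional ridge penalty on the
# non-intercept coefficients (used as the flagged fallback under separation)
ridge_logistic <- function(X, y, lambda = 0.5, max_iter = 50, tol = 1e-8) {
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Logistic regression of connection probability on cell location
#'
#' Fits a binomial logistic model (the two-class case of the multinomial) of
#' the connected/not-connected outcome on the antero-posterior, medio-lateral
#' and dorso-ventral coordinates. Reports per-coordinate Wald p-values and a
#' likelihood-ratio test against the intercept-only model. Complete or
#' quasi-complete separation (likely in small cohorts) is detected from the
#' glm fit and handled by a ridge-penalized refit, flagged in the output with
#' Wald p-values withheld.
#'
#' @param locations Matrix or data frame with columns AP, ML, DV (mm), one
#'   row per cell.
#' @param connected Logical vector of connectivity calls.
#' @param min_cells Minimum number of cells required.
#' @return List with `coefficients` (tibble: term, estimate, std_error,
#'   p_value), `lr_statistic`, `lr_p_value`, `separation`, `n`.
#' @export
location_connection_regression <- function(locations, connected,
                                           min_cells = 10) {
  locations <- as.data.frame(locations)
  if (ncol(locations) != 3L) stop("locations must have 3 columns (AP, ML, DV)")
  names(locations) <- c("AP", "ML", "DV")
  connected <- as.logical(connected)
  if (length(connected) != nrow(locations))
    stop("locations and connected lengths differ")
  if (nrow(locations) < min_cells)
    stop("need at least ", min_cells, " cells")
  if (length(unique(connected)) < 2L)
    stop("both connected and unconnected cells are required")
  dat <- cbind(locations, y = connected)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ AP + ML + DV, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!separation && any(abs(stats::coef(fit)) > 50)) separation <- TRUE
  if (separation) {
    warning("separation detected; reporting ridge-penalized estimates")
    X <- cbind(1, as.matrix(locations))
    beta <- ridge_logistic(X, as.numeric(connected))
    coefs <- tibble::tibble(
      term = c("(Intercept)", "AP", "ML", "DV"),
      estimate = beta, std_error = NA_real_, p_value = NA_real_
    )
    lr_stat <- NA_real_; lr_p <- NA_real_
  } else {
    sm <- summary(fit)$coefficients
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      std_error = sm[, "Std. Error"], p_value = sm[, "Pr(>|z|)"]
    )
    lr_stat <- fit$null.deviance - fit$deviance
    lr_p <- stats::pchisq(lr_stat, df = 3, lower.tail = FALSE)
  }
  list(coefficients = coefs, lr_statistic = lr_stat, lr_p_value = lr_p,
       separation = separation, n = nrow(locations))
}
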