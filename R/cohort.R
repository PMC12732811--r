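# Patient-cohort stage: target/marker Spearman correlations, extreme-group
# construction, median-split stratification, and Kaplan-Meier / log-rank
# survival comparison.

# All permutations of 1..n as a matrix (n! rows). Guarded to small n; used
# for exact Spearman p values.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, factorial(n), n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * nrow(sub) + 1):(i * nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

spearman_one <- function(xv, yv) {
  n <- length(xv)
  rx <- rank(xv)
  ry <- rank(yv)
  sdx <- stats::sd(rx); sdy <- stats::sd(ry)
  if (sdx == 0 || sdy == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cov(rx, ry) / (sdx * sdy)
  if (n <= 9) {
    # exact two-sided p by exhaustive permutation of one variable's ranks
    perms <- all_permutations(n)
    cx <- rx - mean(rx)
    cy <- ry - mean(ry)
    rho_perm <- (matrix(cy[perms], nrow(perms), n) %*% cx) /
      ((n - 1) * sdx * sdy)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Spearman correlations of a target gene with marker genes
#'
#' Average-rank Spearman rho of the target against each marker; exact
#' permutation p values for n < 10, the t approximation otherwise; BH
#' correction across markers.
#'
#' @param x An [expr_matrix].
#' @param target Target gene symbol.
#' @param markers Character vector of marker symbols.
#' @return A data.frame of class `correlation_table` with columns `marker`,
#'   `rho`, `p`, `q`.
#' @export
marker_correlations <- function(x, target, markers) {
  stopifnot(inherits(x, "expr_matrix"))
  target <- toupper(target)
  markers <- toupper(markers)
  present <- rownames(x$values)
  miss <- setdiff(c(target, markers), present)
  if (length(miss)) stopf("genes missing from the matrix: %s",
                          paste(miss, collapse = ", "))
  if (ncol(x$values) < 3) stopf("at least 3 samples required")
  tv <- x$values[target, ]
  rows <- lapply(markers, function(m) {
    r <- spearman_one(tv, x$values[m, ])
    data.frame(marker = m, rho = r$rho, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  structure(out, class = c("correlation_table", "data.frame"))
}

#' Extreme expression groups
#'
#' The `k` samples with the highest target expression form the `"high"` group
#' and the `k` lowest the `"low"` group (ties broken by sample id, with a
#' warning when ties cross a group boundary).
#'
#' @param x An [expr_matrix].
#' @param target Target gene symbol.
#' @param k Samples per group (2k must not exceed the sample count).
#' @return List with character vectors `high` and `low`.
#' @export
extreme_groups <- function(x, target, k = 20) {
  stopifnot(inherits(x, "expr_matrix"))
  target <- toupper(target)
  if (!target %in% rownames(x$values)) stopf("target '%s' not found", target)
  k <- check_count(k, "k")
  n <- ncol(x$values)
  if (2 * k > n) stopf("2k = %d exceeds the sample count %d", 2 * k, n)
  e <- x$values[target, ]
  ids <- colnames(x$values)
  hi_ord <- order(-e, ids)
  lo_ord <- order(e, ids)
  if (e[hi_ord[k]] == e[hi_ord[min(k + 1, n)]] && k < n) {
    warnf("ties at the high-group boundary broken by sample id")
  }
  if (e[lo_ord[k]] == e[lo_ord[min(k + 1, n)]] && k < n) {
    warnf("ties at the low-group boundary broken by sample id")
  }
  list(high = ids[hi_ord[seq_len(k)]], low = ids[lo_ord[seq_len(k)]])
}

#' Median-split group labels
#'
#' Samples with target expression strictly above the median are `"high"`;
#' samples at or below the median are `"low"`.
#'
#' @param x An [expr_matrix].
#' @param target Target gene symbol.
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(x, target) {
  stopifnot(inherits(x, "expr_matrix"))
  target <- toupper(target)
  if (!target %in% rownames(x$values)) stopf("target '%s' not found", target)
  if (ncol(x$values) < 2) stopf("at least 2 samples required")
  e <- x$values[target, ]
  med <- stats::median(e)
  lab <- ifelse(e > med, "high", "low")
  if (all(lab == "low")) warnf("all samples at or below the median; everyone is 'low'")
  stats::setNames(lab, colnames(x$values))
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survival estimates per group and the asymptotic chi-square
#' log-rank test (hypergeometric variance summed over event times; subjects
#' censored at an event time count as at risk at that time).
#'
#' @param survival_table Data frame with columns `time` (non-negative),
#'   `event` (0/1) and `group` (exactly two levels, each non-empty).
#' @return An object of class `km_logrank`: `curves` (data.frame: group,
#'   time, n_risk, n_event, survival), `chisq`, `p`, `observed`, `expected`.
#' @export
km_logrank <- function(survival_table) {
  st <- as.data.frame(survival_table)
  need <- c("time", "event", "group")
  if (!all(need %in% names(st))) stopf("survival table needs columns time/event/group")
  if (any(st$time < 0) || any(!is.finite(st$time))) stopf("times must be finite and non-negative")
  if (!all(st$event %in% c(0, 1))) stopf("event must be 0/1")
  groups <- sort(unique(as.character(st$group)))
  if (length(groups) != 2) stopf("exactly 2 groups required, got %d", length(groups))
  if (any(table(factor(st$group, levels = groups)) == 0)) {
    stopf("each group needs at least one subject")
  }
  st$group <- factor(st$group, levels = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = st)
  sm <- summary(fit, censored = TRUE)
  grp <- sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  if (sum(st$event) == 0) {
    obs <- c(0, 0); expd <- c(0, 0); chisq <- 0; p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = st)
    obs <- unname(sd$obs); expd <- unname(sd$exp)
    v <- if (is.matrix(sd$var)) sd$var[1, 1] else sd$var[1]
    chisq <- if (is.finite(v) && v > 0) (obs[1] - expd[1])^2 / v else 0
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, chisq = chisq, p = p,
                 observed = stats::setNames(obs, groups),
                 expected = stats::setNames(expd, groups),
                 groups = groups),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("<km_logrank>\n")
  for (i in 1:2) {
    cat(sprintf("  %s: observed %g, expected %.3f\n", x$groups[i],
                x$observed[i], x$expected[i]))
  }
  cat(sprintf("  log-rank chi-square = %.4f, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}
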