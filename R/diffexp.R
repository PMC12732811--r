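# Two-group differential expression with optional empirical-Bayes variance
# moderation, Benjamini-Hochberg correction, DEG selection and set
# intersection.

#' DEG selection thresholds
#'
#' @param min_abs_lfc Minimum absolute log2 fold change (inclusive bound).
#' @param max_q Maximum BH-adjusted p value (strict bound).
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(min_abs_lfc = 1.5, max_q = 0.05) {
  structure(list(
    min_abs_lfc = check_number(min_abs_lfc, "min_abs_lfc", lower = 0),
    max_q = check_number(max_q, "max_q", lower = 0, upper = 1,
                         open_lower = TRUE, open_upper = TRUE)
  ), class = "de_thresholds")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: p values are validated to lie in
#' [0, 1] and adjusted with the BH procedure, returned in input order.
#'
#' @param pvalues Numeric vector of p values in [0, 1].
#' @return Adjusted p values (same length and order).
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stopf("p values must be numeric in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Newton solver for trigamma(y) = x, used by the moment-matched prior.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment-matched empirical-Bayes prior (d0, s0^2) for gene-wise sample
# variances s^2 on d degrees of freedom, using the moments of log s^2.
squeeze_variances <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stopf("every gene has zero within-group variance; the comparison is degenerate")
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  mean_e <- mean(e)
  var_e <- stats::var(e)
  gap <- var_e - trigamma(d / 2)
  if (is.finite(gap) && gap > 0) {
    d0 <- 2 * trigamma_inverse(gap)
    s02 <- exp(mean_e + digamma(d0 / 2) - log(d0 / 2))
    s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
  } else {
    # no excess spread in log variances: infinite prior df, common variance
    d0 <- Inf
    s02 <- mean(s2[ok])
    s2_tilde <- rep(s02, length(s2))
  }
  list(s2_tilde = s2_tilde, d0 = d0, s02 = s02)
}

#' Two-group differential expression
#'
#' Per-gene two-sided t test on a log2-scale matrix. The log2 fold change is
#' `mean(group_a) - mean(group_b)`. By default the pooled gene-wise variances
#' are shrunk toward a common prior with an empirical-Bayes posterior
#' `s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)` whose prior degrees of
#' freedom `d0` and prior variance `s0^2` are moment-matched from the observed
#' distribution of log sample variances; `moderated = FALSE` gives the plain
#' pooled-variance t test. BH-adjusted p values are attached. Duplicate gene
#' symbols are collapsed to the highest-variance row before testing.
#'
#' @param x An [expr_matrix] on the log2 scale.
#' @param group_a,group_b Group labels to compare (`log2FC = A - B`).
#' @param moderated Logical; apply empirical-Bayes variance moderation.
#' @return A data.frame of class `de_result` with columns `gene`, `log2FC`,
#'   `t`, `p`, `q`. Attributes record the groups, the moderation setting and
#'   the fitted prior.
#' @export
differential_expression <- function(x, group_a = "treated",
                                    group_b = "control", moderated = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$log2) stopf("expression must be log2 scale; see log_normalize()")
  for (g in c(group_a, group_b)) {
    if (!g %in% x$groups) stopf("unknown group label '%s'", g)
  }
  x <- collapse_duplicate_genes(x)
  ia <- which(x$groups == group_a)
  ib <- which(x$groups == group_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stopf("both groups need at least 2 samples")
  a <- x$values[, ia, drop = FALSE]
  b <- x$values[, ib, drop = FALSE]
  lfc <- rowMeans(a) - rowMeans(b)
  d <- na + nb - 2
  s2 <- ((na - 1) * row_vars(a) + (nb - 1) * row_vars(b)) / d
  if (all(s2 == 0)) {
    stopf("every gene has zero within-group variance; the comparison is degenerate")
  }
  d0 <- 0; s02 <- NA_real_
  if (moderated) {
    sq <- squeeze_variances(s2, d)
    s2_use <- sq$s2_tilde
    # total df capped at the summed residual df across genes
    df <- min(d + sq$d0, d * length(s2))
    d0 <- sq$d0; s02 <- sq$s02
  } else {
    s2_use <- s2
    df <- d
  }
  se <- sqrt(s2_use * (1 / na + 1 / nb))
  tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  pp <- 2 * stats::pt(-abs(tt), df = df)
  res <- data.frame(gene = rownames(x$values), log2FC = unname(lfc),
                    t = unname(tt), p = unname(pp),
                    q = bh_adjust(unname(pp)), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            groups = c(group_a, group_b), moderated = moderated,
            df_residual = d, df_prior = d0, var_prior = s02)
}

#' @export
print.de_result <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("<de_result> %d genes, %s vs %s (%s t test)\n", nrow(x),
              gr[1], gr[2],
              if (attr(x, "moderated")) "moderated" else "pooled-variance"))
  print.data.frame(utils::head(x[order(x$p), ], 6))
  invisible(x)
}

#' Select differentially expressed genes
#'
#' Genes with `|log2FC| >= min_abs_lfc` (inclusive) and adjusted `p < max_q`
#' (strict), each tagged up/down by the fold-change sign.
#'
#' @param result A [differential_expression] result.
#' @param thresholds A [de_thresholds] object.
#' @return A data.frame with columns `gene`, `log2FC`, `q`, `direction`.
#' @export
select_degs <- function(result, thresholds = de_thresholds()) {
  stopifnot(inherits(result, "de_result"), inherits(thresholds, "de_thresholds"))
  keep <- abs(result$log2FC) >= thresholds$min_abs_lfc &
    result$q < thresholds$max_q
  out <- result[keep, c("gene", "log2FC", "q")]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Venn partition of named gene sets
#'
#' Computes every region of the inclusion-exclusion partition of two or more
#' named sets: regions are disjoint and their union is the union of the
#' inputs.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return An object of class `venn_partition`: list with `regions` (named
#'   list of member vectors, names like `"A&B"` for genes in exactly A and B)
#'   and `counts`.
#' @export
intersect_deg_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) stopf("at least 2 sets required")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stopf("sets must have unique names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  regions <- split(all_genes, key)
  # include empty named regions for completeness of the partition
  k <- length(sets)
  patterns <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, FUN = paste, collapse = "&", simplify = FALSE)
  }))
  missing <- setdiff(patterns, names(regions))
  regions[missing] <- list(character(0))
  regions <- regions[patterns]
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 union_size = length(all_genes)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>", x$union_size, "genes in union\n")
  print(x$counts)
  invisible(x)
}
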