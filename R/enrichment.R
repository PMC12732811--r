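# Pre-ranked GSEA and single-sample ssGSEA with GMT gene-set I/O.

#' Parse a GMT gene-set file
#'
#' Tab-separated lines: set name, description, members. Members are
#' uppercased and de-duplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short)) {
    stopf("GMT lines with fewer than 3 fields: %s",
          paste(short, collapse = ", "))
  }
  nms <- vapply(parts, `[[`, character(1), 1)
  dup <- which(duplicated(nms) | duplicated(nms, fromLast = TRUE))
  if (length(dup)) {
    stopf("duplicate set name '%s' on lines %s", nms[dup[1]],
          paste(dup, collapse = " and "))
  }
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- nms
  if (any(vapply(sets, length, integer(1)) == 0)) stopf("empty gene set in GMT")
  structure(sets, descriptions = vapply(parts, `[[`, character(1), 2),
            class = "gene_set_collection")
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (recycled `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a ranked gene list
#'
#' Orders genes by a real-valued metric (e.g. log2 fold change), strictly
#' descending, with ties broken lexicographically by symbol for determinism.
#'
#' @param genes Character vector of unique gene symbols.
#' @param metric Numeric ranking metric, same length.
#' @return Named numeric vector (class `ranked_list`) sorted descending.
#' @export
ranked_list <- function(genes, metric) {
  genes <- toupper(as.character(genes))
  if (anyDuplicated(genes)) stopf("ranked list genes must be unique")
  if (length(genes) != length(metric) || anyNA(metric)) {
    stopf("metric must be a complete numeric vector matching genes")
  }
  ord <- order(-metric, genes)
  structure(stats::setNames(as.numeric(metric[ord]), genes[ord]),
            class = "ranked_list")
}

# Signed maximum deviation of the GSEA running sum, from hit positions.
# pos: sorted hit positions (1-based); w: |metric|^weight at those positions;
# N: total genes. Returns ES and the leading-edge hit index range.
gsea_running_extreme <- function(pos, w, N) {
  nh <- length(pos)
  nm <- N - nh
  sw <- sum(w)
  cum_hit <- if (sw > 0) cumsum(w) / sw else seq_len(nh) / nh
  miss_at <- (pos - seq_len(nh)) / nm       # misses strictly before each hit
  dev_up <- cum_hit - miss_at               # running sum at each hit
  prev_hit <- c(0, cum_hit[-nh])
  dev_dn <- prev_hit - (pos - 1 - (seq_len(nh) - 1)) / nm # just before each hit
  if (nm == 0) {                            # set covers the whole list
    dev_up <- cum_hit
    dev_dn <- prev_hit
  }
  i_up <- which.max(dev_up)
  i_dn <- which.min(dev_dn)
  if (dev_up[i_up] >= -dev_dn[i_dn]) {
    list(es = dev_up[i_up], leading = seq_len(i_up))
  } else {
    list(es = dev_dn[i_dn], leading = seq(i_dn, nh))
  }
}

#' Pre-ranked GSEA for one gene set
#'
#' Running-sum enrichment statistic over a ranked list: hits add
#' `|r|^weight / sum(|r|^weight over hits)`, misses subtract `1/(N - Nhit)`;
#' the enrichment score (ES) is the signed maximum deviation. The null
#' distribution comes from `n_perm` random same-size gene draws (gene-label
#' permutation); when `choose(N, Nhit) <= n_perm` every placement is
#' enumerated instead, giving an exact null. The normalized ES divides by the
#' mean |null ES| of matching sign and the nominal p value is the
#' matching-sign exceedance fraction, with the +1/(n+1) continuity convention
#' in the sampled case. The leading edge contains the hits at
#' or before the ES extremum (at or after it for negative ES).
#'
#' @param ranked A [ranked_list].
#' @param set Character vector of gene symbols.
#' @param weight Exponent on the ranking metric (default 1; 0 gives the
#'   classical Kolmogorov-Smirnov statistic).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed for the permutation draw.
#' @return List with `es`, `nes`, `p`, `size`, `leading_edge`.
#' @export
gsea_preranked <- function(ranked, set, weight = 1, n_perm = 1000,
                           seed = NULL) {
  stopifnot(inherits(ranked, "ranked_list"))
  n_perm <- check_count(n_perm, "n_perm")
  genes <- names(ranked)
  N <- length(genes)
  pos <- sort(match(unique(toupper(set)), genes))
  pos <- pos[!is.na(pos)]
  nh <- length(pos)
  if (nh == 0) stopf("gene set has no overlap with the ranked list")
  absr <- abs(unname(ranked))^weight
  obs <- gsea_running_extreme(pos, absr[pos], N)
  exhaustive <- choose(N, nh) <= n_perm
  null_es <- if (exhaustive) {
    # small problems: enumerate every same-size placement exactly
    apply(utils::combn(N, nh), 2, function(rp) {
      gsea_running_extreme(rp, absr[rp], N)$es
    })
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        rp <- sort(sample.int(N, nh))
        gsea_running_extreme(rp, absr[rp], N)$es
      }, numeric(1))
    })
  }
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p <- if (exhaustive) {
    sum(abs(same) >= abs(obs$es) - 1e-12) / length(same)
  } else {
    (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  }
  nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
    obs$es / mean(abs(same))
  } else {
    NA_real_
  }
  list(es = obs$es, nes = nes, p = p, size = nh,
       leading_edge = genes[pos[obs$leading]])
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Sets are filtered by their post-intersection size (defaults 25-500), each
#' tested with [gsea_preranked], and BH-corrected across the tested sets.
#'
#' @param ranked A [ranked_list].
#' @param collection Named list of gene sets (e.g. from [read_gmt]).
#' @param min_size,max_size Inclusive bounds on the set size after
#'   intersection with the ranked list.
#' @param weight Metric exponent.
#' @param n_perm Permutations per set.
#' @param seed Seed for the whole collection run.
#' @param p_cutoff Nominal p-value significance cutoff.
#' @return A data.frame of class `enrichment_result` with one row per tested
#'   set: `set`, `size`, `es`, `nes`, `p`, `q`, `significant`,
#'   `leading_edge` (comma-separated).
#' @export
gsea_collection <- function(ranked, collection, min_size = 25, max_size = 500,
                            weight = 1, n_perm = 1000, seed = NULL,
                            p_cutoff = 0.05) {
  stopifnot(inherits(ranked, "ranked_list"))
  genes <- names(ranked)
  sizes <- vapply(collection, function(s) sum(toupper(s) %in% genes),
                  integer(1))
  tested <- names(collection)[sizes >= min_size & sizes <= max_size]
  if (length(tested) == 0) {
    warnf("no gene set passes the size filter [%d, %d]", min_size, max_size)
    return(structure(data.frame(set = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                p = numeric(0), q = numeric(0),
                                significant = logical(0),
                                leading_edge = character(0)),
                     class = c("enrichment_result", "data.frame")))
  }
  rows <- with_seed(seed, {
    lapply(tested, function(nm) {
      r <- gsea_preranked(ranked, collection[[nm]], weight = weight,
                          n_perm = n_perm, seed = NULL)
      data.frame(set = nm, size = r$size, es = r$es, nes = r$nes, p = r$p,
                 q = NA_real_,
                 leading_edge = paste(r$leading_edge, collapse = ","),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < p_cutoff
  out <- out[, c("set", "size", "es", "nes", "p", "q", "significant",
                 "leading_edge")]
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending, ties broken
#' lexicographically by symbol); the score of a set is the sum over list
#' positions of the difference between the weighted cumulative hit
#' distribution (hit weights `rank^alpha`, normalized within the set, where
#' the top gene has rank N) and the uniform cumulative miss distribution.
#' No cross-sample normalization is applied unless `normalize = TRUE`
#' (min-max per set).
#'
#' @param x An [expr_matrix], a genes x samples numeric matrix, or an
#'   [sc_dataset] with a normalized layer.
#' @param collection Named list of gene sets.
#' @param alpha Rank-weight exponent (default 0.25; 0 gives uniform weights).
#' @param normalize Min-max normalize each set's scores across samples.
#' @return Numeric matrix, sets x samples.
#' @export
ssgsea_scores <- function(x, collection, alpha = 0.25, normalize = FALSE) {
  mat <- if (inherits(x, "expr_matrix")) {
    x$values
  } else if (inherits(x, "sc_dataset")) {
    if (is.null(x$normalized)) stopf("sc_dataset has no normalized layer; run normalize_and_hvg()")
    as.matrix(x$normalized)
  } else {
    as.matrix(x)
  }
  genes <- toupper(rownames(mat))
  N <- nrow(mat)
  sets <- lapply(collection, function(s) which(genes %in% toupper(s)))
  empty <- names(collection)[vapply(sets, length, integer(1)) == 0]
  if (length(empty) == length(sets)) {
    stopf("no gene set overlaps the expression matrix")
  }
  if (length(empty)) {
    warnf("sets with no overlap get NA scores: %s",
          paste(empty, collapse = ", "))
  }
  out <- matrix(NA_real_, length(sets), ncol(mat),
                dimnames = list(names(collection), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    ord <- order(-mat[, j], genes)
    rnk_of <- integer(N)
    rnk_of[ord] <- seq_len(N)          # position in the sorted list
    rho <- (N - seq_len(N) + 1)^alpha  # rank weight at each position
    for (si in seq_along(sets)) {
      idx <- sets[[si]]
      nh <- length(idx)
      if (nh == 0) next
      p <- sort(rnk_of[idx])
      w <- rho[p]
      hit_term <- sum(w * (N - p + 1)) / sum(w)
      miss_term <- if (N > nh) {
        (sum(N - seq_len(N) + 1) - sum(N - p + 1)) / (N - nh)
      } else {
        0
      }
      out[si, j] <- hit_term - miss_term
    }
  }
  if (normalize) {
    out <- t(apply(out, 1, function(r) {
      rng <- range(r, na.rm = TRUE)
      if (diff(rng) == 0) r - rng[1] else (r - rng[1]) / diff(rng)
    }))
  }
  out
}
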