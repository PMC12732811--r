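# Independent brute-force oracles used to validate the centrality, GSEA and
# multiple-testing implementations on small inputs. These deliberately share
# no code with the package: distances and path counts come from exhaustive
# simple-path enumeration, cliques from subset enumeration, and trees from
# explicit parent construction.

# ---- graph helpers (adjacency matrix representation) ------------------------

random_small_graph <- function(n_max = 7, p = 0.4) {
  n <- sample(2:n_max, 1)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
    }
  }
  dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
  A
}

graph_from_adj <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::E(g)$confidence <- rep(1, igraph::ecount(g))
  g
}

# Enumerate all simple paths between s and t; keep the shortest ones.
# Returns list(len, paths) where paths is a list of vertex index vectors.
all_shortest_paths_brute <- function(A, s, t) {
  n <- nrow(A)
  best <- list(len = Inf, paths = list())
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1
      if (len < best$len) {
        best$len <<- len
        best$paths <<- list(path)
      } else if (len == best$len) {
        best$paths <<- c(best$paths, list(path))
      }
      return()
    }
    if (length(path) - 1 >= best$len) return()
    for (w in which(A[v, ] == 1)) {
      if (!w %in% path) recurse(c(path, w))
    }
  }
  recurse(s)
  best
}

# All ten path-based and neighborhood metrics by direct evaluation of their
# definitions; returns a data.frame aligned with rownames(A).
brute_centralities <- function(A, dmnc_epsilon = 1.7,
                               bottleneck_fraction = 0.25) {
  n <- nrow(A)
  nodes <- rownames(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  through <- array(0, c(n, n, n)) # sigma_st(v)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      b <- all_shortest_paths_brute(A, s, t)
      if (is.finite(b$len)) {
        D[s, t] <- b$len
        sigma[s, t] <- length(b$paths)
        for (p in b$paths) {
          inner <- setdiff(p, c(s, t))
          through[s, t, inner] <- through[s, t, inner] + 1
        }
      }
    }
  }
  closeness <- sapply(seq_len(n), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)])
  })
  ecc <- sapply(seq_len(n), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / max(d)
  })
  comp_id <- integer(n); cid <- 0
  for (v in seq_len(n)) {
    if (comp_id[v] == 0) {
      cid <- cid + 1
      comp_id[is.finite(D[v, ])] <- cid
    }
  }
  radiality <- sapply(seq_len(n), function(v) {
    idx <- which(comp_id == comp_id[v])
    if (length(idx) < 2) return(0)
    delta <- max(D[idx, idx])
    sum(delta + 1 - D[v, setdiff(idx, v)]) / (length(idx) - 1)
  })
  betweenness <- sapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || sigma[s, t] == 0) next
      tot <- tot + through[s, t, v] / sigma[s, t]
    }
    tot
  })
  stress <- sapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      tot <- tot + through[s, t, v]
    }
    tot
  })
  degree <- rowSums(A)
  neigh <- lapply(seq_len(n), function(v) which(A[v, ] == 1))
  mnc <- numeric(n); dmnc <- numeric(n); cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- neigh[[v]]
    if (length(nb) == 0) next
    sub <- A[nb, nb, drop = FALSE]
    # components of the neighborhood by repeated expansion
    left <- seq_along(nb); comps <- list()
    while (length(left)) {
      cur <- left[1]; grown <- TRUE
      while (grown) {
        nxt <- unique(c(cur, unlist(lapply(cur, function(i) which(sub[i, ] == 1)))))
        grown <- length(nxt) > length(cur)
        cur <- nxt
      }
      comps <- c(comps, list(cur))
      left <- setdiff(left, cur)
    }
    sizes <- lengths(comps)
    big <- comps[[which.max(sizes)]]
    mnc[v] <- length(big)
    if (length(big) >= 2) {
      m_edges <- sum(sub[big, big]) / 2
      dmnc[v] <- m_edges / length(big)^dmnc_epsilon
    }
    k <- length(nb)
    if (k >= 2) cc[v] <- sum(sub) / (k * (k - 1))
  }
  # MCC by exhaustive subset enumeration of maximal cliques
  mcc_v <- numeric(n)
  subsets <- unlist(lapply(2:n, function(k) {
    utils::combn(n, k, simplify = FALSE)
  }), recursive = FALSE)
  is_clique <- function(s) all(A[s, s][upper.tri(diag(length(s)))] == 1)
  cliques <- Filter(is_clique, subsets)
  for (cl in cliques) {
    maximal <- !any(vapply(setdiff(seq_len(n), cl), function(w) {
      all(A[w, cl] == 1)
    }, logical(1)))
    if (maximal) mcc_v[cl] <- mcc_v[cl] + factorial(length(cl) - 1)
  }
  # BottleNeck by explicit rooted tree construction
  bneck <- numeric(n)
  for (s in seq_len(n)) {
    idx <- which(comp_id == comp_id[s])
    if (length(idx) < 2) next
    parent <- rep(NA_integer_, n)
    for (v in idx) {
      if (v == s) next
      cand <- neigh[[v]][D[s, neigh[[v]]] == D[s, v] - 1]
      parent[v] <- cand[order(nodes[cand])][1]
    }
    subtree <- sapply(idx, function(v) {
      1 + sum(sapply(setdiff(idx, v), function(w) {
        u <- w
        while (!is.na(parent[u])) {
          u <- parent[u]
          if (u == v) return(TRUE)
        }
        FALSE
      }))
    })
    names(subtree) <- nodes[idx]
    for (v in idx) {
      if (v != s && subtree[nodes[v]] > bottleneck_fraction * length(idx)) {
        bneck[v] <- bneck[v] + 1
      }
    }
  }
  data.frame(node = nodes, Degree = degree, MCC = mcc_v, DMNC = dmnc,
             MNC = mnc, BottleNeck = bneck, EcCentricity = ecc,
             Closeness = closeness, Radiality = radiality,
             Betweenness = betweenness, Stress = stress,
             ClusteringCoefficient = cc, stringsAsFactors = FALSE,
             row.names = NULL)
}

# ---- other oracles ----------------------------------------------------------

# Direct evaluation of the BH step-up formula.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Classical two-CDF Kolmogorov-Smirnov running-sum ES (GSEA at weight 0).
ks_es_oracle <- function(ranked_genes, set) {
  N <- length(ranked_genes)
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  running <- cumsum(ifelse(hit, 1 / nh, -1 / (N - nh)))
  running[which.max(abs(running))]
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  ct <- table(a, b)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  n2 <- choose(sum(ct), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Empirical survivor function (no censoring): P(T > t).
empirical_survivor <- function(times, t) mean(times > t)
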