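# Independent brute-force implementations of every graph metric, used as
# oracles. Deliberately naive (Floyd-Warshall, explicit path enumeration,
# dense matrix algebra): slow but transparently correct on small graphs.

# all-pairs shortest path distances by Floyd-Warshall
o_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

o_char_path <- function(A) {
  D <- o_dist(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

o_global_eff <- function(A) {
  if (nrow(A) < 2) return(0)
  D <- o_dist(A)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

o_clustering <- function(A) {
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)
  ifelse(k < 2, 0, tri / (k * (k - 1)))
}

o_local_eff <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    o_global_eff(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

# betweenness by explicit enumeration of all shortest paths
o_betweenness <- function(A) {
  n <- nrow(A)
  D <- o_dist(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (!is.finite(D[s, t])) next
    paths <- list()
    walk <- function(v, path) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible(NULL))
      }
      for (u in which(A[v, ] == 1))
        if (is.finite(D[u, t]) && D[v, t] == D[u, t] + 1) walk(u, c(path, u))
    }
    walk(s, s)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      cnt <- tabulate(inner, n)
      bc <- bc + cnt / length(paths)
    }
  }
  bc
}

# Newman modularity of a given membership vector
o_modularity <- function(A, memb) {
  m <- sum(A) / 2
  k <- rowSums(A)
  same <- outer(memb, memb, `==`)
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}
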