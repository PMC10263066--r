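# Independent oracles used to validate the native implementations.

# Brute-force Ward agglomeration on Euclidean points: at every step merge
# the pair of clusters with the minimal increase in total within-cluster
# sum of squares, ties broken towards the lowest member index.  Returns the
# sequence of merged leaf sets.
brute_force_ward_sets <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  out <- vector("list", n - 1L)
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }
  for (s in seq_len(n - 1L)) {
    best <- Inf
    pick <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best - 1e-12) {
          best <- delta
          pick <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[pick[1]]], clusters[[pick[2]]]))
    out[[s]] <- merged
    clusters[[pick[1]]] <- merged
    clusters <- clusters[-pick[2]]
  }
  out
}

# merged leaf sets of an hclust object, step by step
hclust_merge_sets <- function(hc) {
  n <- length(hc$height) + 1L
  sets <- vector("list", n - 1L)
  expand <- function(k) {
    if (k < 0) return(-k)
    sets[[k]]
  }
  for (s in seq_len(n - 1L)) {
    sets[[s]] <- sort(c(expand(hc$merge[s, 1]), expand(hc$merge[s, 2])))
  }
  sets
}

# direct ARI formula evaluation from a contingency table
ari_from_table <- function(tab) {
  n <- sum(tab)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(n, 2)
  m <- (b + cc) / 2
  (a - e) / (m - e)
}
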