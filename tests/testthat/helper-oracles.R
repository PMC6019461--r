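# Independent oracles, deliberately written with different algorithms than
# the implementation they check.

# full dynamic-programming edit distance (O(nm) table, no library calls)
lev_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
    }
  }
  d[n + 1, m + 1]
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, using hypergeometric probabilities
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# expected rarefied richness by exhaustive enumeration of replicate subsets
rarefy_enum <- function(mat, t) {
  m <- ncol(mat)
  subs <- utils::combn(m, t)
  mean(apply(subs, 2, function(cols)
    sum(rowSums(mat[, cols, drop = FALSE]) > 0)))
}

# independent O(n^3) agglomerative clustering oracle with the package's
# tie-break contract (min distance; ties -> smallest first index pair),
# written as repeated full scans over an active-cluster list
agglom_oracle <- function(d, h, linkage) {
  act <- lapply(seq_len(nrow(d)), identity)
  repeat {
    if (length(act) < 2) break
    pick <- NULL
    pick_d <- Inf
    for (i in seq_along(act)) {
      for (j in seq_along(act)) {
        if (j <= i) next
        vals <- as.vector(d[act[[i]], act[[j]]])
        dd <- if (linkage == "complete") max(vals) else min(vals)
        if (dd < pick_d - 1e-12) { pick_d <- dd; pick <- c(i, j) }
      }
    }
    if (pick_d > h + 1e-12) break
    act[[pick[1]]] <- c(act[[pick[1]]], act[[pick[2]]])
    act[[pick[2]]] <- NULL
  }
  out <- integer(nrow(d))
  for (i in seq_along(act)) out[act[[i]]] <- i
  out
}

# canonical form of a partition for comparison
canon_partition <- function(assign_) {
  match(assign_, unique(assign_))
}
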