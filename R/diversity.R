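# Incidence-based clonal diversity across cellular replicates: Chao2
# richness estimation with a log-normal confidence interval, sample-based
# rarefaction, extrapolation, and accumulation curves.

#' Tally incidence counts from a clonotype x replicate presence matrix
#'
#' @param mat logical (or 0/1) matrix, rows = clonotypes, columns =
#'   replicates; every row must be present somewhere
#' @return object of class `incidence_counts`: m (replicates), S_obs
#'   (observed clonotypes) and Q (Q\[j\] = clonotypes present in exactly j
#'   replicates)
#' @export
incidence_counts <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1 || nrow(mat) < 1) {
    stop_maf("incidence matrix must be non-empty", "mafseq_validation_error")
  }
  mode(mat) <- "logical"
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    stop_maf("clonotype absent from every replicate", "mafseq_validation_error")
  }
  structure(list(m = ncol(mat), S_obs = nrow(mat),
                 Q = tabulate(rs, nbins = ncol(mat))),
            class = "incidence_counts")
}

#' @export
print.incidence_counts <- function(x, ...) {
  cat("incidence_counts: m =", x$m, ", S_obs =", x$S_obs,
      ", Q1 =", x$Q[1], ", Q2 =", if (x$m > 1) x$Q[2] else 0, "\n")
  invisible(x)
}

#' Chao2 incidence-based richness estimate
#'
#' Standard form: S_obs + ((m-1)/m) Q1^2 / (2 Q2); when Q2 = 0 the
#' bias-corrected fallback S_obs + ((m-1)/m) Q1 (Q1-1) / 2 is used. The
#' variance follows the classic incidence-based formulas for the
#' corresponding case, and the confidence interval uses the log-normal
#' transformation of the estimated number of undetected clonotypes, which
#' keeps the lower bound at or above S_obs. The small-sample-corrected
#' form (Q2 + 1 in the denominator) is available via `form`.
#'
#' @param counts an `incidence_counts`
#' @param conf confidence level (default 0.95)
#' @param form "standard" (default) or "bias_corrected"
#' @return object of class `diversity_estimate`: estimator, point, se,
#'   ci (lower, upper), counts
#' @export
chao2 <- function(counts, conf = 0.95, form = c("standard", "bias_corrected")) {
  form <- match.arg(form)
  if (counts$m < 2) stop_maf("chao2 requires m >= 2 replicates",
                             "mafseq_validation_error")
  S <- counts$S_obs
  Q1 <- counts$Q[1]
  Q2 <- counts$Q[2]
  A <- (counts$m - 1) / counts$m
  if (form == "bias_corrected") {
    point <- S + A * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
    r <- Q1 / (Q2 + 1)
    var_ <- A * Q1 * (Q1 - 1) / 2 / (Q2 + 1) +
      A^2 * Q1 * (2 * Q1 - 1)^2 / (4 * (Q2 + 1)^2) +
      A^2 * Q1^2 * Q2 * (Q1 - 1)^2 / (4 * (Q2 + 1)^4)
  } else if (Q2 > 0) {
    point <- S + A * Q1^2 / (2 * Q2)
    r <- Q1 / Q2
    var_ <- Q2 * (A / 2 * r^2 + A^2 * r^3 + A^2 / 4 * r^4)
  } else {
    point <- S + A * Q1 * (Q1 - 1) / 2
    var_ <- A * Q1 * (Q1 - 1) / 2 + A^2 * Q1 * (2 * Q1 - 1)^2 / 4 -
      A^2 * Q1^4 / (4 * point)
  }
  if (Q1 == 0) var_ <- 0
  var_ <- max(var_, 0)
  se <- sqrt(var_)
  T_ <- point - S
  z <- qnorm(1 - (1 - conf) / 2)
  if (T_ > 0 && se > 0) {
    K <- exp(z * sqrt(log(1 + var_ / T_^2)))
    ci <- c(lower = S + T_ / K, upper = S + T_ * K)
  } else {
    ci <- c(lower = S, upper = S + z * se)
  }
  structure(list(estimator = paste0("chao2_", form), point = point, se = se,
                 ci = ci, conf = conf, counts = counts),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f (se %.2f, %g%% CI %.2f-%.2f)\n", x$estimator,
              x$point, x$se, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Sample-based rarefaction of incidence data
#'
#' Expected richness in t of the m replicates:
#' E\[S(t)\] = S_obs - sum_j Q\[j\] C(m-j, t) / C(m, t).
#' @param counts an `incidence_counts`
#' @param t number of replicates, 1 <= t <= m (vectorized)
#' @return expected richness (numeric)
#' @export
rarefy_incidence <- function(counts, t) {
  if (any(t < 1 | t > counts$m)) {
    stop_maf("t must lie in [1, m]", "mafseq_validation_error")
  }
  vapply(t, function(ti) {
    miss <- sum(counts$Q * choose(counts$m - seq_len(counts$m), ti))
    counts$S_obs - miss / choose(counts$m, ti)
  }, numeric(1))
}

#' Extrapolate richness beyond the observed replicates
#'
#' S(m + t*) = S_obs + Q0_hat (1 - (1 - Q1 / (Q1 + m Q0_hat))^t*), where
#' Q0_hat is the Chao2 estimate of undetected clonotypes. Approaches the
#' Chao2 asymptote as t* grows; returns S_obs for all t* when Q1 = 0.
#' @param counts an `incidence_counts`
#' @param t_star additional replicates (vectorized, >= 0)
#' @return expected richness
#' @export
extrapolate_incidence <- function(counts, t_star) {
  if (any(t_star < 0)) stop_maf("t_star must be >= 0", "mafseq_validation_error")
  Q1 <- counts$Q[1]
  Q0 <- chao2(counts)$point - counts$S_obs
  vapply(t_star, function(ts) {
    if (Q1 == 0 || Q0 <= 0 || ts == 0) return(counts$S_obs + 0)
    counts$S_obs + Q0 * (1 - (1 - Q1 / (Q1 + counts$m * Q0))^ts)
  }, numeric(1))
}

#' Clonotype accumulation curve
#'
#' Expected number of newly discovered clonotypes contributed by each
#' additional replicate. `exact_mean` differences the rarefaction curve;
#' `permutation` averages over random replicate orders.
#' @param mat incidence matrix (clonotype x replicate)
#' @param mode "exact_mean" or "permutation"
#' @param n_perm permutations (permutation mode)
#' @param seed RNG seed (permutation mode)
#' @return data.frame: t, expected_new, cumulative
#' @export
accumulation_curve <- function(mat, mode = c("exact_mean", "permutation"),
                               n_perm = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  mode(mat) <- "logical"
  m <- ncol(mat)
  if (mode == "exact_mean") {
    counts <- incidence_counts(mat)
    cum <- rarefy_incidence(counts, seq_len(m))
    new_ <- c(cum[1], diff(cum))
  } else {
    acc <- matrix(0, n_perm, m)
    with_seed(seed, {
      for (p in seq_len(n_perm)) {
        ord <- sample.int(m)
        seen <- rep(FALSE, nrow(mat))
        for (t in seq_len(m)) {
          now <- seen | mat[, ord[t]]
          acc[p, t] <- sum(now) - sum(seen)
          seen <- now
        }
      }
    })
    new_ <- colMeans(acc)
    cum <- cumsum(new_)
  }
  data.frame(t = seq_len(m), expected_new = new_, cumulative = cumsum(new_))
}

#' Write / read an incidence matrix as TSV
#' @param mat logical clonotype x replicate matrix
#' @param path file path
#' @export
write_incidence_tsv <- function(mat, path) {
  df <- data.frame(clonotype_id = rownames(mat) %||%
                     sprintf("CT%05d", seq_len(nrow(mat))),
                   as.data.frame(mat * 1L), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence_tsv
#' @export
read_incidence_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- df[[1]]
  m
}
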