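# Edge-wise group statistics: age-adjusted permutation ANCOVA,
# Benjamini-Hochberg FDR, permutation-corrected Tukey pairwise
# contrasts, and score correlations.

#' Build a design table for the group comparison
#'
#' @param group factor or character with levels HC, SCD, MCI.
#' @param age numeric vector of ages (years).
#' @param subject_ids optional identifiers.
#' @return a `design` data.frame.
#' @export
make_design <- function(group, age, subject_ids = NULL) {
  group <- factor(as.character(group), levels = GROUPS)
  if (anyNA(group)) stop("group labels must be HC, SCD or MCI", call. = FALSE)
  if (anyNA(age)) stop("ages must not be missing", call. = FALSE)
  if (any(table(group) < 2L)) stop("every group needs at least 2 subjects", call. = FALSE)
  df <- data.frame(
    subject_id = subject_ids %||% sprintf("S%03d", seq_along(age)),
    group = group, age = as.numeric(age), stringsAsFactors = FALSE
  )
  class(df) <- c("design", "data.frame")
  df
}

# Model matrices for y ~ age (reduced) and y ~ age + group (full).
design_matrices <- function(design) {
  g <- design$group
  X_red <- cbind(1, design$age)
  X_full <- cbind(X_red, stats::model.matrix(~g)[, -1, drop = FALSE])
  if (qr(X_full)$rank < ncol(X_full)) {
    stop("rank-deficient design (age confounded with group indicators?)",
         call. = FALSE)
  }
  list(red = X_red, full = X_full, df1 = nlevels(g) - 1L,
       df2 = nrow(X_full) - ncol(X_full))
}

#' ANCOVA F-statistic for the group factor, adjusting for age
#'
#' F for adding the group factor to the linear model `value ~ age`
#' (group sum of squares after age, i.e. Type-II). Vectorized over the
#' columns of a value matrix. The degenerate 0/0 case (no residual
#' variance and no group effect) is returned as F = 0.
#'
#' @param values numeric vector (one edge) or matrix
#'   `subjects x edges`.
#' @param design a [make_design] table.
#' @return numeric vector of F statistics (one per edge).
#' @export
ancova_f <- function(values, design) {
  Y <- as.matrix(values)
  if (nrow(Y) != nrow(design)) stop("values and design sizes disagree", call. = FALSE)
  dm <- design_matrices(design)
  if (nrow(Y) <= nlevels(design$group) + 2L) {
    stop("need more subjects than groups + 2", call. = FALSE)
  }
  f_from_matrices(Y, dm)
}

f_from_matrices <- function(Y, dm) {
  rss0 <- colSums(as.matrix(stats::lm.fit(dm$red, Y)$residuals)^2)
  rss1 <- colSums(as.matrix(stats::lm.fit(dm$full, Y)$residuals)^2)
  num <- (rss0 - rss1) / dm$df1
  den <- rss1 / dm$df2
  f <- num / den
  f[den <= .Machine$double.eps * pmax(1, rss0) & num <= .Machine$double.eps] <- 0
  f[is.nan(f)] <- 0
  unname(f)
}

#' Edge-wise permutation ANCOVA
#'
#' Null distribution of the group F-statistic by random relabeling:
#' group labels are permuted over subjects while each subject keeps its
#' own age and values (group sizes are preserved by construction). The
#' permutation p-value uses the add-one correction
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)` and is therefore never
#' exactly zero.
#'
#' @param values matrix `subjects x edges` (or vector).
#' @param design a [make_design] table.
#' @param n_perm number of permutations (>= 100; 10,000 for a full run).
#' @param seed integer seed.
#' @return list with `F` (observed), `p` (per edge), `n_perm`.
#' @export
permutation_ancova <- function(values, design, n_perm = 10000L, seed = NULL) {
  if (n_perm < 100L) stop("`n_perm` must be at least 100", call. = FALSE)
  Y <- as.matrix(values)
  dm <- design_matrices(design)
  f_obs <- f_from_matrices(Y, dm)
  count <- numeric(length(f_obs))
  n <- nrow(Y)
  local_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      d_perm <- design
      d_perm$group <- design$group[perm]
      dmp <- design_matrices(d_perm)
      f_b <- f_from_matrices(Y, dmp)
      count <- count + (f_b >= f_obs)
    }
  })
  list(F = f_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at rate `Q`: reject the hypotheses with the `k`
#' smallest p-values where `k` is the largest rank with
#' `p_(k) <= k Q / m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param Q target false discovery rate (default 0.05).
#' @return list with `rejected` (logical mask), `threshold` (largest
#'   rejected p-value, 0 if none), `Q`.
#' @export
fdr_bh <- function(p_values, Q = 0.05) {
  if (length(p_values) == 0L) {
    return(list(rejected = logical(0), threshold = 0, Q = Q))
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  rejected <- stats::p.adjust(p_values, method = "BH") <= Q
  list(rejected = rejected,
       threshold = if (any(rejected)) max(p_values[rejected]) else 0,
       Q = Q)
}

# Age-adjusted group means (at the sample-mean age), residual MSE and
# per-group sizes for Tukey statistics; vectorized over edge columns.
adjusted_group_stats <- function(Y, design) {
  g <- design$group
  X <- cbind(1, design$age, stats::model.matrix(~g)[, -1, drop = FALSE])
  fit <- stats::lm.fit(X, Y)
  coef <- as.matrix(fit$coefficients)
  mse <- colSums(as.matrix(fit$residuals)^2) / (nrow(Y) - ncol(X))
  mean_age <- mean(design$age)
  base <- coef[1, ] + coef[2, ] * mean_age
  mu <- rbind(HC = base,
              SCD = base + coef[3, ],
              MCI = base + coef[4, ])
  list(mu = mu, mse = mse, n_g = table(g))
}

tukey_q <- function(stats_, pair) {
  se <- sqrt(stats_$mse / 2 * (1 / stats_$n_g[[pair[1]]] + 1 / stats_$n_g[[pair[2]]]))
  (stats_$mu[pair[2], ] - stats_$mu[pair[1], ]) / se
}

#' Permutation-corrected Tukey pairwise contrasts
#'
#' For each edge (typically those surviving FDR), computes the
#' age-adjusted mean difference and studentized-range statistic
#' `q = diff / sqrt(MSE/2 (1/n_a + 1/n_b))` for the three group pairs
#' HC-SCD, HC-MCI and SCD-MCI, and corrects each against the
#' permutation null of the maximum |q| across pairs (family = the three
#' contrasts of that edge), mirroring Tukey's honestly-significant-
#' difference control.
#'
#' @param values matrix `subjects x edges` (columns named by edge).
#' @param design a [make_design] table.
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame with `edge`, `pair`, `difference` (second minus
#'   first group, age-adjusted), `q`, `p_corrected`.
#' @export
tukey_pairwise_permuted <- function(values, design, n_perm = 10000L, seed = NULL) {
  if (n_perm < 100L) stop("`n_perm` must be at least 100", call. = FALSE)
  Y <- as.matrix(values)
  edges <- colnames(Y) %||% sprintf("edge%03d", seq_len(ncol(Y)))
  pairs <- list(c("HC", "SCD"), c("HC", "MCI"), c("SCD", "MCI"))
  obs <- adjusted_group_stats(Y, design)
  q_obs <- lapply(pairs, function(pr) tukey_q(obs, pr))
  count <- matrix(0, length(pairs), ncol(Y))
  n <- nrow(Y)
  local_seed(seed, {
    for (b in seq_len(n_perm)) {
      d_perm <- design
      d_perm$group <- design$group[sample.int(n)]
      st <- adjusted_group_stats(Y, d_perm)
      qmax <- do.call(pmax, lapply(pairs, function(pr) abs(tukey_q(st, pr))))
      for (k in seq_along(pairs)) {
        count[k, ] <- count[k, ] + (qmax >= abs(q_obs[[k]]))
      }
    }
  })
  out <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    data.frame(
      edge = edges,
      pair = paste(pairs[[k]], collapse = "-"),
      difference = obs$mu[pairs[[k]][2], ] - obs$mu[pairs[[k]][1], ],
      q = unname(q_obs[[k]]),
      p_corrected = unname((1 + count[k, ]) / (1 + n_perm)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Edge-wise group comparison: permutation ANCOVA + FDR + Tukey
#'
#' Convenience wrapper running the full edge-statistics stage and
#' returning one row per edge.
#'
#' @param values matrix `subjects x edges`.
#' @param design a [make_design] table.
#' @param n_perm permutations.
#' @param Q FDR level.
#' @param seed integer seed.
#' @return list with `table` (edge, F, p, fdr_rejected), `pairwise`
#'   (Tukey table for FDR-surviving edges, `NULL` if none), `threshold`.
#' @export
edge_stats <- function(values, design, n_perm = 10000L, Q = 0.05, seed = NULL) {
  Y <- as.matrix(values)
  edges <- colnames(Y) %||% sprintf("edge%03d", seq_len(ncol(Y)))
  pa <- permutation_ancova(Y, design, n_perm, seed = derive_seed(seed %||% 0L, 1L))
  fdr <- fdr_bh(pa$p, Q)
  tab <- data.frame(edge = edges, F = pa$F, p = pa$p,
                    fdr_rejected = fdr$rejected, stringsAsFactors = FALSE)
  pairwise <- NULL
  if (any(fdr$rejected)) {
    pairwise <- tukey_pairwise_permuted(
      Y[, fdr$rejected, drop = FALSE], design, n_perm,
      seed = derive_seed(seed %||% 0L, 2L))
  }
  list(table = tab, pairwise = pairwise, threshold = fdr$threshold, Q = Q)
}

#' Pearson correlations between edge values and scores, with FDR
#'
#' Correlates every (edge, score) pair over subjects, two-sided t-test
#' p-values, jointly corrected across the whole family with
#' Benjamini-Hochberg.
#'
#' @param edge_values matrix `subjects x edges`.
#' @param scores matrix or data.frame `subjects x scores`.
#' @param Q FDR level.
#' @return data.frame with `edge`, `score`, `r`, `p`, `fdr_rejected`.
#' @export
correlate_scores <- function(edge_values, scores, Q = 0.05) {
  E <- as.matrix(edge_values)
  S <- as.matrix(scores)
  if (nrow(E) != nrow(S)) stop("subject counts disagree", call. = FALSE)
  if (nrow(E) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (any(apply(E, 2, stats::sd) == 0) || any(apply(S, 2, stats::sd) == 0)) {
    stop("zero-variance input: correlation undefined", call. = FALSE)
  }
  edge_names <- colnames(E) %||% sprintf("edge%03d", seq_len(ncol(E)))
  score_names <- colnames(S) %||% sprintf("score%d", seq_len(ncol(S)))
  r <- stats::cor(E, S)
  n <- nrow(E)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  df <- data.frame(
    edge = rep(edge_names, times = ncol(S)),
    score = rep(score_names, each = ncol(E)),
    r = as.vector(r), p = as.vector(p), stringsAsFactors = FALSE
  )
  df$fdr_rejected <- fdr_bh(df$p, Q)$rejected
  df
}

#' Group comparison of a single subject-level scalar
#'
#' Permutation ANCOVA (age-adjusted) plus permutation-corrected Tukey
#' pairwise contrasts for one variable, e.g. the normalized hippocampal
#' volume or a resting-state-network mean PLV. No multiplicity
#' correction is applied across variables.
#'
#' @param x numeric vector, one value per subject.
#' @param design a [make_design] table.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param name label used in the output tables.
#' @return list with `F`, `p`, `pairwise`.
#' @export
compare_scalar_ancova <- function(x, design, n_perm = 10000L, seed = NULL,
                                  name = "value") {
  Y <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, name))
  pa <- permutation_ancova(Y, design, n_perm, seed = derive_seed(seed %||% 0L, 1L))
  pw <- tukey_pairwise_permuted(Y, design, n_perm, seed = derive_seed(seed %||% 0L, 2L))
  list(F = pa$F, p = pa$p, pairwise = pw)
}
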