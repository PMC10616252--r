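#' Alpha-diversity indices per sample
#'
#' Shannon (natural log by default) and Simpson (Gini-Simpson,
#' `1 - sum(p_i^2)`) are computed from relative abundances; Chao1
#' requires integer counts (singleton/doubleton based) and is only
#' computed when a count table is supplied:
#' `S_obs + F1^2 / (2 F2)`, falling back to
#' `S_obs + F1 (F1 - 1) / 2` when there are no doubletons.
#'
#' @param table Abundance tibble (rows summing to one).
#' @param counts Optional count tibble (`sample_id` + genus columns of
#'   non-negative integers) for Chao1.
#' @param base Log base for Shannon: `"e"` (nats, default) or `"2"`.
#' @return Tibble with `sample_id`, `shannon`, `simpson` and, when
#'   counts are given, `chao1`.
#' @export
alpha_diversity <- function(table, counts = NULL, base = c("e", "2")) {
  base <- match.arg(base)
  m <- feature_matrix(validate_abundance(table))
  sh <- vegan::diversity(m, index = "shannon", base = if (base == "e") exp(1) else 2)
  si <- vegan::diversity(m, index = "simpson")
  out <- tibble::tibble(sample_id = rownames(m), shannon = unname(sh), simpson = unname(si))
  if (!is.null(counts)) {
    cm <- feature_matrix(counts)
    cm <- cm[match(out$sample_id, rownames(cm)), , drop = FALSE]
    out$chao1 <- unname(apply(cm, 1, chao1_index))
  }
  out
}

# Classic Chao1 estimator from a vector of counts.
chao1_index <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in `[0, 1]` for
#' relative abundances. Used as the beta-diversity distance throughout;
#' any precomputed dissimilarity (see [read_distance()]) can be
#' substituted downstream.
#'
#' @param table Abundance tibble.
#' @return A `dist` object labelled by sample ID.
#' @export
bray_curtis <- function(table) {
  m <- feature_matrix(validate_abundance(table))
  vegan::vegdist(m, method = "bray")
}

#' One-factor PERMANOVA (Adonis) on a distance matrix
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and tests the pseudo-F statistic by random
#' relabelling: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`,
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`,
#' `R^2 = SS_between / SS_total`, and
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' With `n_permutations = "exhaustive"` every distinct assignment of
#' the observed group sizes to samples is enumerated (N <= 10) and the
#' p-value is the exact fraction of assignments with `F >= F_obs`.
#'
#' @param dist A `dist` object or square distance matrix.
#' @param grouping Categorical variable, one value per sample, in
#'   distance-matrix order.
#' @param n_permutations Number of random relabellings (>= 99), or
#'   `"exhaustive"`.
#' @param seed Integer seed for the permutations.
#' @param variable Name recorded in the result (default the expression).
#' @return One-row tibble: `variable`, `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`.
#' @export
permanova <- function(dist, grouping, n_permutations = 999, seed = NULL,
                      variable = NULL) {
  if (is.null(variable)) variable <- deparse(substitute(grouping))[1]
  D2 <- as.matrix(dist)^2
  n <- nrow(D2)
  g <- factor(grouping)
  if (length(g) != n) abort("grouping length must match the distance matrix")
  a <- nlevels(g)
  if (a < 2) abort("PERMANOVA needs at least two groups")
  exhaustive <- identical(n_permutations, "exhaustive")
  if (!exhaustive && n_permutations < 99) abort("n_permutations must be >= 99")

  ss_total <- sum(D2) / (2 * n)
  ss_within_of <- function(gi) {
    # gi: integer group ids (vector) or matrix with one permutation per column
    if (is.matrix(gi)) {
      ssw <- numeric(ncol(gi))
      for (lev in seq_len(a)) {
        Z <- gi == lev
        n_g <- sum(Z[, 1])
        ssw <- ssw + colSums(Z * (D2 %*% Z)) / (2 * n_g)
      }
      ssw
    } else {
      ssw <- 0
      for (lev in seq_len(a)) {
        z <- gi == lev
        ssw <- ssw + sum(D2[z, z]) / (2 * sum(z))
      }
      ssw
    }
  }
  gi <- as.integer(g)
  ssw_obs <- ss_within_of(gi)
  ssb_obs <- ss_total - ssw_obs
  f_of <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- f_of(ssw_obs)

  if (exhaustive) {
    if (n > 10) abort("exhaustive enumeration is limited to N <= 10")
    perms <- all_permutations(n)
    gi_all <- matrix(gi[perms], nrow = n)
    f_all <- f_of(ss_within_of(gi_all))
    p <- mean(f_all >= f_obs - 1e-12)
    n_perm_out <- ncol(perms)
  } else {
    perm_fun <- function() {
      gp <- matrix(0L, n, n_permutations)
      for (b in seq_len(n_permutations)) gp[, b] <- gi[sample.int(n)]
      gp
    }
    gp <- if (is.null(seed)) perm_fun() else withr::with_seed(as.integer(seed), perm_fun())
    f_perm <- f_of(ss_within_of(gp))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_perm_out <- n_permutations
  }

  tibble::tibble(
    variable = variable,
    r_squared = ssb_obs / ss_total,
    pseudo_f = f_obs,
    p_value = p,
    n_permutations = n_perm_out
  )
}

# All n! permutations of 1..n as an n x n! matrix (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (i in seq_len(n)) {
    idx <- k + seq_len(ncol(sub))
    out[1, idx] <- i
    rest <- seq_len(n)[-i]
    out[-1, idx] <- rest[sub]
    k <- k + ncol(sub)
  }
  out
}

#' Effect-size scan of host variables on community composition
#'
#' Runs a single-factor PERMANOVA per variable and ranks variables by
#' their R-squared (effect size), descending, ties broken by name.
#' Continuous `age` and `bmi` are binned with the one-hot encoding
#' bins before testing; variables with a single observed level are
#' skipped with a warning.
#'
#' @param dist Distance matrix (`dist` or square matrix) over samples.
#' @param meta Metadata tibble, rows in distance-matrix order.
#' @param variables Metadata column names to scan.
#' @inheritParams permanova
#' @return Tibble of [permanova()] rows, sorted by `r_squared`
#'   descending; classed `se_effect_scan` for `autoplot()`.
#' @export
effect_size_scan <- function(dist, meta, variables, n_permutations = 999, seed = NULL) {
  rows <- list()
  for (i in seq_along(variables)) {
    v <- variables[i]
    if (!v %in% names(meta)) abort(paste0("variable not in metadata: ", v))
    val <- meta[[v]]
    if (v == "age") val <- bin_age(val)
    if (v == "bmi") val <- bin_bmi(val)
    if (length(unique(val)) < 2) {
      warn(paste0("skipping variable with a single level: ", v))
      next
    }
    sd_i <- if (is.null(seed)) NULL else as.integer(seed) + i
    rows[[v]] <- permanova(dist, val, n_permutations = n_permutations,
                           seed = sd_i, variable = v)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$r_squared), .data$variable)
  class(out) <- c("se_effect_scan", class(out))
  out
}

#' Spearman correlation and Wilcoxon rank-sum test
#'
#' Thin, contract-checked wrappers over the standard rank-based tests
#' (average ranks for ties, two-sided p). A constant input to the
#' correlation yields an undefined rho, returned as `NA` with
#' `degenerate = TRUE` rather than an error.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return `spearman_cor()`: one-row tibble `rho`, `p_value`,
#'   `degenerate`; `wilcoxon_rank_sum()`: two-sided p-value.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) abort("x and y must be paired, length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant input: Spearman rho undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, degenerate = FALSE)
}

#' @rdname spearman_cor
#' @param a,b Numeric samples for the two groups (each non-empty).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))$p.value
}
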