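# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as naive loops, independent of the
# package's vectorised implementations.

# Pairwise Mann-Whitney AUC: loop over every (HE, LE) pair; wins count
# 1, ties 0.5.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "HE"]
  neg <- scores[labels == "LE"]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# One-factor PERMANOVA statistics by direct summation over pairs.
oracle_permanova_stats <- function(d, grouping) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  g <- as.factor(grouping)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + D2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
        s <- s + D2[idx[a], idx[b]]
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  a <- nlevels(g)
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(ss_total = ss_total, ss_within = ss_within, ss_between = ss_between,
       f = f, r2 = ss_between / ss_total)
}

# Exact permutation p by enumerating every ordering of the labels.
oracle_permanova_exact_p <- function(d, grouping) {
  g <- as.factor(grouping)
  n <- length(g)
  f_obs <- oracle_permanova_stats(d, g)$f
  perms <- sehybrid_all_perms(n)
  hits <- 0
  for (k in seq_len(ncol(perms))) {
    f_k <- oracle_permanova_stats(d, g[perms[, k]])$f
    if (f_k >= f_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(perms)
}

# Recursive enumeration of all orderings of 1..n (test-side copy,
# independent of the package internals).
sehybrid_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- sehybrid_all_perms(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(i) {
    rbind(i, matrix(seq_len(n)[-i][sub], nrow = n - 1L))
  }))
}

# Small single-batch cohort with labelled before-stage profiles and
# five planted genera.
small_cohort <- function(seed = 1, n = 80, signal_effect = 0.7,
                         signal_genera = 1:5, ...) {
  spec <- synthetic_spec(n_samples_per_batch = n, batch_to_region = 1,
                         stages = "before", signal_effect = signal_effect,
                         signal_genera = signal_genera,
                         region_specific_signal = integer(0),
                         seed = seed, ...)
  co <- generate_cohort(spec)
  lab <- derive_absorption_labels(co$metadata)
  list(abundance = co$abundance[match(lab$sample_id, co$abundance$sample_id), ],
       metadata = lab, y = lab$efficiency, truth = co$truth)
}

# Metadata fixture with explicit covariate values.
meta_fixture <- function(gender = "Male", age = 40, bmi = 22,
                         probiotics = "no", health_status = "healthy") {
  n <- max(lengths(list(gender, age, bmi, probiotics, health_status)))
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    gender = rep_len(gender, n), age = rep_len(age, n), bmi = rep_len(bmi, n),
    probiotics = rep_len(probiotics, n), health_status = rep_len(health_status, n)
  )
}

# A tiny abundance tibble from a matrix of values.
abundance_fixture <- function(m, genera = NULL) {
  if (is.null(genera)) genera <- sprintf("g__g%d", seq_len(ncol(m)))
  colnames(m) <- genera
  rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  tibble::as_tibble(m, rownames = "sample_id")
}
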