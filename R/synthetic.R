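#' Specify a synthetic multi-batch, multi-region cohort
#'
#' Defines the generative model for a selenium-supplementation cohort:
#' genus-level compositions are drawn from a logistic-normal model
#' (per-genus log-baselines plus additive log-scale effects, softmax,
#' renormalised), with planted class-discriminative genera, categorical
#' host-variable effects, and per-batch / per-region compositional
#' shifts. Hair-selenium values are constructed so that the relative
#' change (after - before) / before crosses the 10% threshold exactly
#' for high-efficiency (HE) subjects.
#'
#' Defaults mirror a realistic two-city cohort: 49 genera and three
#' sequencing batches of 156, 43 and 7 subjects, the first two batches
#' from one region and the third from another.
#'
#' @param n_genera Number of genera (default 49).
#' @param n_samples_per_batch Integer vector of subjects per batch.
#' @param batch_to_region Region index (1-based) of each batch.
#' @param signal_genera Indices of planted class-discriminative genera
#'   (default ten, of which three are region-stable — see
#'   `region_specific_signal`).
#' @param signal_effect Log-fold shift between HE and LE classes on the
#'   signal genera (alternating sign across them).
#' @param region_specific_signal Subset of `signal_genera` whose class
#'   effect holds only in the home region (the region of batch 1);
#'   elsewhere these genera carry no class signal and receive an extra
#'   destabilising region shift. Models markers that fail to transfer
#'   across regions.
#' @param host_effect_sizes Named numeric vector of per-variable
#'   log-fold effect scales for `gender`, `age`, `bmi`, `probiotics`,
#'   `health_status` (categorical effects drawn once per category).
#' @param batch_shift_sd Std-dev of per-genus log-scale batch offsets.
#' @param region_shift_sd Std-dev of per-genus log-scale region offsets.
#' @param intervention_effect Log-fold shift applied to signal genera in
#'   the after-intervention stage.
#' @param class_balance Fraction of HE subjects, in (0, 1).
#' @param dispersion Concentration of the logistic-normal noise
#'   (per-genus log-scale noise has sd `1/sqrt(dispersion)`); larger
#'   means tighter, less overdispersed compositions.
#' @param stages Which intervention stages to emit profiles for.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return An object of class `se_spec`.
#' @export
synthetic_spec <- function(n_genera = 49,
                           n_samples_per_batch = c(156, 43, 7),
                           batch_to_region = c(1, 1, 2),
                           signal_genera = 1:10,
                           signal_effect = 0.7,
                           region_specific_signal = 4:10,
                           host_effect_sizes = c(gender = 0.25, age = 0.3, bmi = 0.25,
                                                 probiotics = 0.25, health_status = 0.2),
                           batch_shift_sd = 1.6,
                           region_shift_sd = 0.7,
                           intervention_effect = 0.3,
                           class_balance = 0.5,
                           dispersion = 2,
                           stages = c("before", "after"),
                           seed = 1L) {
  spec <- list(
    n_genera = as.integer(n_genera),
    n_samples_per_batch = as.integer(n_samples_per_batch),
    n_batches = length(n_samples_per_batch),
    batch_to_region = as.integer(batch_to_region),
    n_regions = length(unique(as.integer(batch_to_region))),
    signal_genera = as.integer(signal_genera),
    signal_effect = signal_effect,
    region_specific_signal = as.integer(region_specific_signal),
    host_effect_sizes = host_effect_sizes,
    batch_shift_sd = batch_shift_sd,
    region_shift_sd = region_shift_sd,
    intervention_effect = intervention_effect,
    class_balance = class_balance,
    dispersion = dispersion,
    stages = match.arg(stages, c("before", "after"), several.ok = TRUE),
    seed = as.integer(seed)
  )
  class(spec) <- "se_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_genera < 1) abort("n_genera must be >= 1")
    if (any(n_samples_per_batch < 1)) abort("every batch must have >= 1 subject")
    if (length(batch_to_region) != n_batches) {
      abort("batch_to_region must have one region per batch (n_batches inconsistent with n_samples_per_batch)")
    }
    if (length(signal_genera) &&
        (min(signal_genera) < 1 || max(signal_genera) > n_genera)) {
      abort("signal_genera indices must lie in [1, n_genera]")
    }
    if (length(setdiff(region_specific_signal, signal_genera))) {
      abort("region_specific_signal must be a subset of signal_genera")
    }
    if (class_balance <= 0 || class_balance >= 1) abort("class_balance must be in (0, 1)")
    if (dispersion <= 0) abort("dispersion must be positive")
  })
  invisible(spec)
}

host_variable_categories <- function() {
  list(
    gender        = c("Male", "Female"),
    age           = c("Young", "Middle", "Old"),
    bmi           = c("Low", "Middle", "High"),
    probiotics    = c("yes", "no"),
    health_status = c("healthy", "unhealthy")
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws subjects batch by batch under the generative model of
#' [synthetic_spec()]: per-subject log-scale genus intensities are the
#' cohort baseline, plus the class effect on signal genera, plus
#' categorical host-variable effects, plus batch and region offsets,
#' plus Gaussian noise; softmax then yields a composition summing to
#' one. One before-intervention profile is emitted per subject and,
#' when requested, an after-intervention profile shifted on the signal
#' genera.
#'
#' @param spec An `se_spec` from [synthetic_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list of class `se_cohort` with elements `abundance`
#'   (tibble, one row per sample), `metadata` (tibble, one row per
#'   sample) and `truth` (planted signal genera, per-subject true
#'   class, batch/region offset matrices).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  validate_spec(spec)
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  withr::with_seed(seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  G <- spec$n_genera
  genera <- sprintf("%sGenus%03d", GENUS_PREFIX, seq_len(G))
  n_subj <- sum(spec$n_samples_per_batch)
  batch <- rep(seq_len(spec$n_batches), spec$n_samples_per_batch)
  region <- spec$batch_to_region[batch]
  home_region <- spec$batch_to_region[1]
  cats <- host_variable_categories()

  # cohort-level draws (once)
  baseline <- rnorm(G, 0, 1.5)
  class_dir <- rep_len(c(1, -1), length(spec$signal_genera))
  batch_off <- matrix(rnorm(spec$n_batches * G, 0, spec$batch_shift_sd), spec$n_batches, G)
  region_off <- matrix(rnorm(spec$n_regions * G, 0, spec$region_shift_sd), spec$n_regions, G)
  # region-unstable markers get an extra compositional disruption away from home
  if (length(spec$region_specific_signal) && spec$n_regions > 1) {
    other <- setdiff(seq_len(spec$n_regions), home_region)
    region_off[other, spec$region_specific_signal] <-
      region_off[other, spec$region_specific_signal] +
      rnorm(length(other) * length(spec$region_specific_signal), 0, 2 * max(spec$region_shift_sd, 0.5))
  }
  host_off <- lapply(names(cats), function(v) {
    k <- length(cats[[v]])
    m <- matrix(rnorm(k * G, 0, spec$host_effect_sizes[[v]]), k, G,
                dimnames = list(cats[[v]], genera))
    m
  })
  names(host_off) <- names(cats)

  # per-subject covariates and class
  cls <- ifelse(runif(n_subj) < spec$class_balance, "HE", "LE")
  gender <- sample(cats$gender, n_subj, replace = TRUE)
  age <- round(runif(n_subj, 20, 75))
  bmi <- round(pmin(pmax(rnorm(n_subj, 23, 3), 16), 35), 1)
  probiotics <- sample(cats$probiotics, n_subj, replace = TRUE, prob = c(0.3, 0.7))
  health_status <- sample(cats$health_status, n_subj, replace = TRUE, prob = c(0.8, 0.2))
  age_cat <- bin_age(age)
  bmi_cat <- bin_bmi(bmi)

  # hair selenium consistent with the class at the 10% threshold
  se_before <- rlnorm(n_subj, log(0.45), 0.3)
  rate <- ifelse(cls == "HE", runif(n_subj, 10, 40), runif(n_subj, -8, 9.9))
  se_after <- se_before * (1 + rate / 100)

  noise_sd <- 1 / sqrt(spec$dispersion)
  sig <- spec$signal_genera
  stable <- setdiff(sig, spec$region_specific_signal)

  one_stage <- function(stage) {
    eta <- matrix(rep(baseline, each = n_subj), n_subj, G)
    if (length(sig)) {
      eff <- matrix(0, n_subj, G)
      he <- cls == "HE"
      eff[he, stable] <- eff[he, stable] +
        rep(spec$signal_effect * class_dir[match(stable, sig)], each = sum(he))
      unstable <- intersect(sig, spec$region_specific_signal)
      at_home <- he & region == home_region
      if (length(unstable) && any(at_home)) {
        eff[at_home, unstable] <- eff[at_home, unstable] +
          rep(spec$signal_effect * class_dir[match(unstable, sig)], each = sum(at_home))
      }
      eta <- eta + eff
      if (stage == "after") {
        eta[, sig] <- eta[, sig] +
          rep(spec$intervention_effect * class_dir, each = n_subj)
      }
    }
    for (v in names(cats)) {
      val <- switch(v, gender = gender, age = age_cat, bmi = bmi_cat,
                    probiotics = probiotics, health_status = health_status)
      eta <- eta + host_off[[v]][val, , drop = FALSE]
    }
    eta <- eta + batch_off[batch, , drop = FALSE] + region_off[region, , drop = FALSE]
    eta <- eta + matrix(rnorm(n_subj * G, 0, noise_sd), n_subj, G)
    p <- exp(eta - apply(eta, 1, max))
    p / rowSums(p)
  }

  subj_id <- sprintf("S%04d", seq_len(n_subj))
  ab_list <- list(); meta_list <- list()
  for (stage in spec$stages) {
    p <- one_stage(stage)
    rownames(p) <- paste0(subj_id, "_", stage)
    colnames(p) <- genera
    ab_list[[stage]] <- matrix_to_tbl(p)
    meta_list[[stage]] <- tibble::tibble(
      sample_id = rownames(p), subject_id = subj_id, stage = stage,
      gender = gender, age = age, bmi = bmi, probiotics = probiotics,
      health_status = health_status,
      batch = paste0("Batch", batch), region = paste0("Region", region),
      selenium_before = se_before, selenium_after = se_after
    )
  }

  out <- list(
    abundance = dplyr::bind_rows(ab_list),
    metadata = dplyr::bind_rows(meta_list),
    truth = list(
      class = stats::setNames(cls, subj_id),
      signal_genera = genera[sig],
      region_stable_genera = genera[stable],
      batch_offsets = batch_off,
      region_offsets = region_off
    )
  )
  class(out) <- "se_cohort"
  out
}

#' @export
print.se_cohort <- function(x, ...) {
  cat(sprintf("<se_cohort> %d samples x %d genera; %d subjects; stages: %s\n",
              nrow(x$abundance), length(genus_columns(x$abundance)),
              length(x$truth$class),
              paste(unique(x$metadata$stage), collapse = "/")))
  invisible(x)
}

#' Label samples by selenium-absorption efficiency
#'
#' Computes the absorption rate
#' `(selenium_after - selenium_before) / selenium_before * 100` and
#' labels a sample high-efficiency (`HE`) when the rate reaches the
#' threshold (boundary inclusive: rate >= threshold), low-efficiency
#' (`LE`) otherwise. Samples missing either selenium value are dropped
#' with a warning, mirroring cohort curation of unpaired subjects.
#'
#' @param metadata Host-metadata tibble with `selenium_before` and
#'   `selenium_after` columns.
#' @param threshold_pct Absorption-rate threshold in percent (default 10).
#' @return The metadata tibble with `absorption_rate` (percent) and
#'   `efficiency` (factor LE/HE) columns appended; incomplete rows
#'   removed.
#' @export
derive_absorption_labels <- function(metadata, threshold_pct = 10) {
  miss <- is.na(metadata$selenium_before) | is.na(metadata$selenium_after)
  if (any(miss)) {
    warn(sprintf("excluded %d sample(s) lacking paired selenium measurements", sum(miss)))
    metadata <- metadata[!miss, ]
  }
  if (any(metadata$selenium_before <= 0)) abort("selenium_before must be positive")
  rate <- (metadata$selenium_after - metadata$selenium_before) / metadata$selenium_before * 100
  # inclusive boundary, with a tiny tolerance so rates that are exactly
  # the threshold up to floating-point rounding land in HE
  dplyr::mutate(metadata,
    absorption_rate = rate,
    efficiency = factor(ifelse(rate >= threshold_pct - 1e-9, "HE", "LE"),
                        levels = c("LE", "HE"))
  )
}

#' Write a synthetic cohort to a directory
#'
#' Emits `abundance.tsv`, `metadata.tsv`, a `truth.tsv` of per-subject
#' true classes and a `truth.json` sidecar naming the planted genera.
#'
#' @param cohort An `se_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(tibble::tibble(subject_id = names(cohort$truth$class),
                                  class = unname(cohort$truth$class)),
                   file.path(dir, "truth.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(signal_genera = cohort$truth$signal_genera,
         region_stable_genera = cohort$truth$region_stable_genera),
    file.path(dir, "truth.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
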