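# Shared fixtures, all generated in code.

# a gap-free deterministic series: smooth glucose wave crossing several
# bands, no events unless supplied
wave_series <- function(n = 60, amp = 3.5, centre = 7, bolus = NULL,
                        meal = NULL, split_at = n) {
  t <- (seq_len(n) - 1L) * 5
  g <- centre + amp * sin(t / 180 * pi)
  grid <- data.frame(t = t, glucose = g, bolus = 0, basal = 0, meal = 0,
                     split = rep(c("train", "test"),
                                 c(split_at, n - split_at)),
                     stringsAsFactors = FALSE)
  if (!is.null(bolus)) grid$bolus[match(bolus$t, t)] <- bolus$value
  if (!is.null(meal)) grid$meal[match(meal$t, t)] <- meal$value
  patient_series("wave", grid)
}

# small simulated cohort for EA tests: no missing readings, fixed seed
fast_cohort <- function(n_patients = 2, days = 1, seed = 101, ...) {
  simulate_cohort(cohort_config(n_patients = n_patients, days = days,
                                seed = seed, missing_rate = 0, ...))
}

# small training sample set
fast_train <- function(seed = 101, days = 1) {
  s <- simulate_patient(cohort_config(n_patients = 1, days = days,
                                      seed = seed, missing_rate = 0), 1)
  sample_split(build_samples(s), "train")
}

# samples whose target is exactly the anchor glucose (identity-recoverable)
identity_target_samples <- function(samples) {
  samples$target_glucose <- samples$g0
  samples$target_class <- to_class(samples$g0)
  samples
}

# brute-force one-vs-rest weighted F1, independent of the package's
# vectorised implementation
bf_weighted_f1 <- function(cm) {
  nc <- nrow(cm)
  total <- sum(cm)
  out <- 0
  for (i in seq_len(nc)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    f1 <- if (tp + 0.5 * (fp + fn) > 0) tp / (tp + 0.5 * (fp + fn)) else 0
    out <- out + (sum(cm[i, ]) / total) * f1
  }
  out
}

random_cm <- function(nc = 7) matrix(rpois(nc * nc, 3), nc, nc)
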