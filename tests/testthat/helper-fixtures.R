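# Fixtures built in code.

# Tiny perfectly separated two-class cohort: `p_sep` separating probes with
# disjoint class supports plus `p_noise` flat probes.
make_separable_cohort <- function(n_per_class = 8, p_sep = 2, p_noise = 4,
                                  seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  p <- p_sep + p_noise
  x <- matrix(rnorm(p * n, mean = 5, sd = 0.3), p, n,
              dimnames = list(sprintf("pr%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  sep <- seq_len(p_sep)
  x[sep, seq_len(n_per_class)] <- rnorm(p_sep * n_per_class, 2, 0.2)
  x[sep, n_per_class + seq_len(n_per_class)] <- rnorm(p_sep * n_per_class, 8, 0.2)
  list(expr = x,
       classes = rep(c("1", "3"), each = n_per_class),
       sep_probes = rownames(x)[sep])
}

# A grade_calls data frame realizing given confusion counts, paired with the
# matching histologic grades.
calls_from_counts <- function(hg1_fmg1, hg1_fmg3, hg3_fmg1, hg3_fmg3) {
  label <- c(rep("fMG1", hg1_fmg1), rep("fMG3", hg1_fmg3),
             rep("fMG1", hg3_fmg1), rep("fMG3", hg3_fmg3))
  grade <- c(rep("1", hg1_fmg1 + hg1_fmg3), rep("3", hg3_fmg1 + hg3_fmg3))
  n <- length(label)
  calls <- data.frame(sample_id = sprintf("t%03d", seq_len(n)),
                      gad1 = 0.5, gad3 = 0.5, score = 0.5,
                      label = label, equivocal = FALSE,
                      stringsAsFactors = FALSE)
  class(calls) <- c("grade_calls", "data.frame")
  list(calls = calls, grades = stats::setNames(grade, calls$sample_id))
}

# One-probe LAMDA model with prescribed binomial prototypes; at x = 1 the
# score is rho3 / (rho1 + rho3), so boundary scores can be engineered exactly.
one_probe_model <- function(rho1, rho3, alpha = 1) {
  bounds <- structure(list(min = c(pr = 0), max = c(pr = 1),
                           degenerate = c(pr = FALSE)),
                      class = "standardization_bounds")
  params <- structure(list(family = "binomial", classes = c("fMG1", "fMG3"),
                           params = list(fMG1 = list(rho = c(pr = rho1)),
                                         fMG3 = list(rho = c(pr = rho3)))),
                      class = "membership_params")
  structure(list(probes = "pr", family = "binomial", connective = "minmax",
                 alpha = alpha, nic = FALSE, bounds = bounds, params = params,
                 classes = c("fMG1", "fMG3")),
            class = "lamda_model")
}

# Hand-built selection trace (for choose_signature contract tests).
make_trace <- function(k, sens, spec, err = 1 - (sens + spec) / 2,
                       ranking = sprintf("pr%03d", seq_len(max(k)))) {
  structure(list(metrics = data.frame(k = k, error = err, sensitivity = sens,
                                      specificity = spec),
                 k_grid = k, ranking = ranking, family = "binomial",
                 connective = "minmax", alpha_grid = seq(0.5, 1, 0.1)),
            class = "selection_trace")
}
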