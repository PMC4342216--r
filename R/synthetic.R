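# Synthetic expression cohorts with known ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults describe a balanced
#' two-class microarray-like cohort on the log2-intensity scale: 60 grade 1,
#' 60 grade 3 and 60 grade 2 tumors; 20 grade-informative probes shifted
#' upward in grade 3 by `effect` within-class standard deviations among 980
#' noise probes; grade 2 tumors drawn from the two archetypes in proportion
#' `grade2_mix`, with an `equivocal_fraction` of them placed midway between
#' the archetype means (intermediate, truly equivocal profiles).
#'
#' @param n_grade1,n_grade3,n_grade2 Sample counts per histologic grade.
#' @param n_informative,n_noise Probe counts.
#' @param effect Between-class mean shift of informative probes, in units of
#'   the within-class SD.
#' @param noise_sd Within-class SD (log2 intensity units).
#' @param grade2_mix Fraction of grade 2 tumors drawn from the grade-3
#'   archetype.
#' @param equivocal_fraction Fraction of grade 2 tumors generated midway
#'   between the archetype means.
#' @param er_positive_fraction Probability a tumor is ER positive.
#' @param baseline_mean,baseline_sd Distribution of per-probe baseline
#'   intensities.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_grade1 = 60L, n_grade3 = 60L, n_grade2 = 60L,
                       n_informative = 20L, n_noise = 980L,
                       effect = 2, noise_sd = 0.5,
                       grade2_mix = 0.5, equivocal_fraction = 0.1,
                       er_positive_fraction = 0.7,
                       baseline_mean = 8, baseline_sd = 1.5,
                       seed = 1L) {
  cfg <- list(n_grade1 = as.integer(n_grade1), n_grade3 = as.integer(n_grade3),
              n_grade2 = as.integer(n_grade2),
              n_informative = as.integer(n_informative),
              n_noise = as.integer(n_noise),
              effect = effect, noise_sd = noise_sd,
              grade2_mix = grade2_mix,
              equivocal_fraction = equivocal_fraction,
              er_positive_fraction = er_positive_fraction,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_grade1 < 1L || n_grade3 < 1L || n_grade2 < 0L ||
        n_informative < 1L || n_noise < 0L)
      stop("sample and probe counts must be positive")
    if (effect < 0) stop("effect must be >= 0")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (grade2_mix < 0 || grade2_mix > 1) stop("grade2_mix must lie in [0, 1]")
    if (equivocal_fraction < 0 || equivocal_fraction > 1)
      stop("equivocal_fraction must lie in [0, 1]")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate an expression cohort with known ground truth
#'
#' Informative probes: grade-1 samples ~ Normal(m, noise_sd^2) and grade-3
#' samples ~ Normal(m + effect * noise_sd, noise_sd^2), with per-probe random
#' baselines m. Noise probes share one distribution across all samples. Each
#' grade 2 tumor is drawn from one of the two archetypes according to a
#' latent assignment (Bernoulli `grade2_mix`); a fraction of them
#' (`equivocal_fraction`) is instead generated midway between the archetype
#' means, emulating truly intermediate profiles. ER status is Bernoulli per
#' sample.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (probes x samples matrix), `labels` (data frame:
#'   `sample_id`, `grade`, `er`) and `truth` (list: `informative_probes`,
#'   `grade2_archetype` named `"1"`/`"3"`, `grade2_midpoint` named logical,
#'   `config`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_informative + config$n_noise
  probes <- sprintf("probe_%04d", seq_len(p))
  informative <- sort(sample(probes, config$n_informative))
  n1 <- config$n_grade1; n3 <- config$n_grade3; n2 <- config$n_grade2
  n <- n1 + n3 + n2
  ids <- sprintf("sample_%03d", seq_len(n))
  grade <- rep(c("1", "3", "2"), c(n1, n3, n2))

  m <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  names(m) <- probes
  shift <- config$effect * config$noise_sd

  # per-sample shift multiplier on informative probes: 0 (grade-1 archetype),
  # 1 (grade-3 archetype), 0.5 (midpoint)
  arch2 <- ifelse(stats::runif(n2) < config$grade2_mix, "3", "1")
  mid2 <- seq_len(n2) %in%
    sample(seq_len(n2), round(config$equivocal_fraction * n2))
  mult <- c(rep(0, n1), rep(1, n3),
            ifelse(mid2, 0.5, ifelse(arch2 == "3", 1, 0)))

  expr <- matrix(stats::rnorm(p * n, sd = config$noise_sd), p, n,
                 dimnames = list(probes, ids)) + m
  inf_idx <- match(informative, probes)
  expr[inf_idx, ] <- expr[inf_idx, ] +
    matrix(shift * mult, length(inf_idx), n, byrow = TRUE)

  er <- ifelse(stats::runif(n) < config$er_positive_fraction, "pos", "neg")
  labels <- data.frame(sample_id = ids, grade = grade, er = er,
                       stringsAsFactors = FALSE)
  ids2 <- ids[grade == "2"]
  truth <- list(informative_probes = informative,
                grade2_archetype = stats::setNames(arch2, ids2),
                grade2_midpoint = stats::setNames(mid2, ids2),
                config = config)
  list(expr = expr, labels = labels, truth = truth)
}

#' Simulate a matched two-platform cohort pair
#'
#' The same simulated tumors measured on two platforms with disjoint probe
#' namespaces: platform 1 carries one probe per gene (the cohort from
#' [simulate_cohort()]); platform 2 carries `probes_per_gene` probes per gene,
#' each an affine-distorted, noise-perturbed replicate of the gene signal with
#' its own measurement-quality jitter. Supports testing cross-platform
#' signature adaptation, where the best probe per gene must be re-picked on
#' the new platform.
#'
#' @param config A [sim_config()] (its seed also drives the platform-2 draw).
#' @param probes_per_gene Probes per gene on platform 2 (>= 1).
#' @param scale_range Range of per-probe multiplicative distortions.
#' @param offset_sd SD of per-probe additive offsets.
#' @param jitter_sd Upper bound of the per-probe noise SD, drawn uniformly
#'   from `[0, jitter_sd]`. Set `scale_range = c(1, 1)`, `offset_sd = 0`,
#'   `jitter_sd = 0` for undistorted replicates.
#' @return List with `platform1` (the [simulate_cohort()] result), `platform2`
#'   (list: `expr`, `labels`, `probe_map` data frame with `probe_id`, `gene`,
#'   `scale`, `offset`, `jitter`).
#' @export
make_two_platform_pair <- function(config = sim_config(), probes_per_gene = 3L,
                                   scale_range = c(0.8, 1.25),
                                   offset_sd = 0.3, jitter_sd = 0.3) {
  stopifnot(probes_per_gene >= 1L)
  p1 <- simulate_cohort(config)
  genes <- rownames(p1$expr)
  np <- length(genes) * probes_per_gene
  set.seed(config$seed + 1L)
  gene_of <- rep(genes, each = probes_per_gene)
  probe_id <- sprintf("%s_p2_%02d", gene_of, rep(seq_len(probes_per_gene),
                                                 times = length(genes)))
  sc <- stats::runif(np, scale_range[1], scale_range[2])
  off <- if (offset_sd > 0) stats::rnorm(np, 0, offset_sd) else rep(0, np)
  jit <- if (jitter_sd > 0) stats::runif(np, 0, jitter_sd) else rep(0, np)
  g <- p1$expr[gene_of, , drop = FALSE]
  noise <- matrix(stats::rnorm(np * ncol(g)), np, ncol(g)) * jit
  expr2 <- g * sc + off + noise
  rownames(expr2) <- probe_id
  probe_map <- data.frame(probe_id = probe_id, gene = gene_of,
                          scale = sc, offset = off, jitter = jit,
                          stringsAsFactors = FALSE)
  list(platform1 = p1,
       platform2 = list(expr = expr2, labels = p1$labels,
                        probe_map = probe_map, truth = p1$truth))
}
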