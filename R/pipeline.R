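# End-to-end signature construction: cohort splitting, incremental LOOCV,
# minimal-signature choice, deployment classification, agreement metrics,
# cross-platform probe adaptation.

#' Split a cohort into training and deployment sets
#'
#' Training samples are the histologic grade 1 and grade 3 tumors (the classes
#' that define the fMG1/fMG3 profiles); grade 2 and unknown-grade tumors form
#' the deployment set to be graded molecularly. With
#' `er_mode = "er_positive_only"` the ER-negative grade 1/3 tumors are dropped
#' from training (the deployment set is never ER-filtered).
#'
#' @param labels Data frame with columns `sample_id`, `grade` (values
#'   `1`/`2`/`3`/`"unknown"`; `NA` counts as unknown) and, when ER filtering
#'   is requested, `er` (`"pos"`/`"neg"`/`"unknown"`).
#' @param er_mode `"all"` or `"er_positive_only"`.
#' @return List with character vectors `training`, `deployment` and `dropped`
#'   (ER-filtered training candidates).
#' @export
split_cohort <- function(labels, er_mode = c("all", "er_positive_only")) {
  er_mode <- match.arg(er_mode)
  stopifnot(is.data.frame(labels), all(c("sample_id", "grade") %in% names(labels)))
  grade <- as.character(labels$grade)
  grade[is.na(grade)] <- "unknown"
  bad <- setdiff(unique(grade), c("1", "2", "3", "unknown"))
  if (length(bad)) stop("invalid grade value(s): ", paste(bad, collapse = ", "))
  is_train <- grade %in% c("1", "3")
  dropped <- character(0)
  if (er_mode == "er_positive_only") {
    if (!"er" %in% names(labels))
      stop("er_mode = 'er_positive_only' requires an 'er' column")
    drop <- is_train & as.character(labels$er) != "pos"
    dropped <- labels$sample_id[drop]
    is_train <- is_train & !drop
  }
  n1 <- sum(is_train & grade == "1")
  n3 <- sum(is_train & grade == "3")
  if (n1 < 5L || n3 < 5L)
    stop(sprintf("too few training samples (grade 1: %d, grade 3: %d; need >= 5 each)",
                 n1, n3))
  list(training = labels$sample_id[is_train],
       deployment = labels$sample_id[grade %in% c("2", "unknown")],
       dropped = dropped)
}

# Running t-norm/t-conorm aggregates down the ranked probes of a membership
# matrix (probes x samples). Row k holds the aggregate over the first k probes.
running_aggregates <- function(m, connective) {
  if (nrow(m) == 1L) return(list(lo = m, hi = m))
  if (connective == "minmax") {
    list(lo = apply(m, 2L, cummin), hi = apply(m, 2L, cummax))
  } else {
    list(lo = apply(m, 2L, cumprod),
         hi = 1 - apply(1 - m, 2L, cumprod))
  }
}

# Default candidate signature sizes: every k up to 200, then log-spaced to p.
default_k_grid <- function(p, dense_to = 200L, log_points = 25L) {
  ks <- seq_len(min(p, dense_to))
  if (p > dense_to) {
    lg <- round(10^seq(log10(dense_to + 1), log10(p), length.out = log_points))
    ks <- c(ks, lg)
  }
  sort(unique(pmin(ks, p)))
}

#' Incremental leave-one-out cross-validation over signature sizes
#'
#' For every candidate size `k` and every training sample: the sample is held
#' out; bounds, per-class membership parameters and the exigency `alpha` are
#' re-estimated on the remaining samples restricted to the top-`k` ranked
#' probes (`alpha` by resubstitution accuracy on those remaining samples, ties
#' toward the stricter larger value); the held-out sample is then classified.
#' Sensitivity is the fraction of grade 3 tumors called fMG3, specificity the
#' fraction of grade 1 tumors called fMG1, and the global error the overall
#' misclassification fraction.
#'
#' With `per_fold_ranking = TRUE` the MEMBAS ranking itself is also re-derived
#' within each fold from the retained samples (slower, strictly leakage-free
#' ranking); by default the supplied global ranking is used for all folds.
#'
#' @param x Raw expression matrix (probes x training samples), complete values
#'   on the ranked probes.
#' @param classes Grade labels (1/3) for the columns of `x`.
#' @param ranking Probe ids in descending relevance, e.g.
#'   `membas_weights(x, classes)$ranking`.
#' @param k_grid Candidate sizes; default [default_k_grid()] over the ranking.
#' @param family,connective,alpha_grid Classifier settings, see [lamda_fit()].
#' @param per_fold_ranking Re-rank probes inside every fold.
#' @return A `selection_trace`: `metrics` data frame (`k`, `error`,
#'   `sensitivity`, `specificity`), `probes` (list of the evaluated probe list
#'   per `k`), per-sample held-out `scores` and `labels` matrices
#'   (samples x sizes), and the settings used.
#' @export
loocv_curve <- function(x, classes, ranking, k_grid = NULL,
                        family = c("binomial", "gaussian"),
                        connective = c("minmax", "prodprobsum"),
                        alpha_grid = seq(0.5, 1, 0.1),
                        per_fold_ranking = FALSE) {
  family <- match.arg(family)
  connective <- match.arg(connective)
  x <- .as_expr_matrix(x)
  cls <- as_grade_classes(classes)
  n <- ncol(x)
  if (length(cls) != n) stop("length(classes) must equal ncol(x)")
  if (any(table(cls) < 3L))
    stop("each class needs >= 3 samples so every fold retains >= 2 per class")
  miss <- setdiff(ranking, rownames(x))
  if (length(miss)) stop("ranking contains unknown probe(s)")
  if (is.null(k_grid)) k_grid <- default_k_grid(length(ranking))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (min(k_grid) < 1L || max(k_grid) > length(ranking))
    stop("k_grid must lie within [1, length(ranking)]")
  K <- max(k_grid)
  nk <- length(k_grid)
  na <- length(alpha_grid)
  truth3 <- cls == "fMG3"
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(n))

  scores <- matrix(NA_real_, n, nk, dimnames = list(ids, k_grid))
  xtop_global <- x[ranking[seq_len(K)], , drop = FALSE]

  for (j in seq_len(n)) {
    tr <- setdiff(seq_len(n), j)
    if (per_fold_ranking) {
      mw <- membas_weights(x[, tr, drop = FALSE], cls[tr], family)
      xt <- x[mw$ranking[seq_len(K)], , drop = FALSE]
    } else {
      xt <- xtop_global
    }
    b <- fit_bounds(xt[, tr, drop = FALSE])
    zs <- standardize(xt, b)
    pars <- fit_membership_params(zs[, tr, drop = FALSE], cls[tr], family)
    agg1 <- running_aggregates(membership_matrix(zs, pars, "fMG1"), connective)
    agg3 <- running_aggregates(membership_matrix(zs, pars, "fMG3"), connective)
    # score matrices (k_grid x n) per candidate alpha
    acc <- matrix(NA_real_, nk, na)
    s_by_alpha <- vector("list", na)
    for (ai in seq_len(na)) {
      a <- alpha_grid[ai]
      g1 <- a * agg1$lo[k_grid, , drop = FALSE] +
        (1 - a) * agg1$hi[k_grid, , drop = FALSE]
      g3 <- a * agg3$lo[k_grid, , drop = FALSE] +
        (1 - a) * agg3$hi[k_grid, , drop = FALSE]
      s <- g3 / (g1 + g3)
      s[g1 + g3 == 0] <- 0.5
      s_by_alpha[[ai]] <- s
      pred3 <- s[, tr, drop = FALSE] >= 0.5
      acc[, ai] <- rowMeans(pred3 == matrix(truth3[tr], nk, n - 1L, byrow = TRUE))
    }
    best_ai <- max.col(acc, ties.method = "last")  # ties -> larger alpha
    for (ki in seq_len(nk))
      scores[j, ki] <- s_by_alpha[[best_ai[ki]]][ki, j]
  }

  labels <- ifelse(scores >= 0.5, "fMG3", "fMG1")
  sens <- colMeans(labels[truth3, , drop = FALSE] == "fMG3")
  spec <- colMeans(labels[!truth3, , drop = FALSE] == "fMG1")
  err <- colMeans(labels != matrix(as.character(cls), n, nk))
  metrics <- data.frame(k = k_grid, error = unname(err),
                        sensitivity = unname(sens), specificity = unname(spec))
  structure(list(metrics = metrics, k_grid = k_grid,
                 probes = lapply(k_grid, function(k) ranking[seq_len(k)]),
                 scores = scores, labels = labels,
                 ranking = ranking, classes = cls, sample_ids = ids,
                 family = family, connective = connective,
                 alpha_grid = alpha_grid,
                 per_fold_ranking = per_fold_ranking),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("LOOCV selection trace over", nrow(x$metrics), "signature sizes (",
      x$family, "/", x$connective, ")\n")
  best <- x$metrics[which.min(x$metrics$error), ]
  cat(sprintf("lowest error %.3f at k = %d (sens %.3f, spec %.3f)\n",
              best$error, best$k, best$sensitivity, best$specificity))
  invisible(x)
}

#' Choose the minimal signature from a selection trace
#'
#' Among sizes whose LOOCV specificity reaches `min_specificity`, takes those
#' with maximal sensitivity and, among them, the smallest `k` (high
#' sensitivity is privileged so that high-risk tumors are not missed). If no
#' size meets the specificity floor, the maximal-sensitivity size is used with
#' a warning. The final model is then refitted on the full training set at the
#' chosen size.
#'
#' @param trace A `selection_trace` from [loocv_curve()].
#' @param x The training expression matrix the trace was computed on.
#' @param classes Its grade labels.
#' @param min_specificity Specificity floor, default 0.67.
#' @param nic Passed to [lamda_fit()].
#' @return A `gene_signature`: ordered `probes`, chosen `k`, the refitted
#'   frozen `model`, the `trace`, and `meta`.
#' @export
choose_signature <- function(trace, x, classes, min_specificity = 0.67,
                             nic = FALSE) {
  stopifnot(inherits(trace, "selection_trace"))
  m <- trace$metrics
  ok <- m$specificity >= min_specificity
  if (!any(ok)) {
    warning("no signature size reaches the specificity floor; ",
            "falling back to the maximal-sensitivity size")
    ok <- rep(TRUE, nrow(m))
  }
  cand <- m[ok, , drop = FALSE]
  cand <- cand[cand$sensitivity == max(cand$sensitivity), , drop = FALSE]
  k <- min(cand$k)
  probes <- trace$ranking[seq_len(k)]
  model <- lamda_fit(x, classes, probes = probes, family = trace$family,
                     connective = trace$connective,
                     alpha_grid = trace$alpha_grid, nic = nic)
  row <- m[m$k == k, ]
  structure(list(probes = probes, k = k, model = model, trace = trace,
                 meta = list(min_specificity = min_specificity,
                             loocv_error = row$error,
                             loocv_sensitivity = row$sensitivity,
                             loocv_specificity = row$specificity)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature:", x$k, "probes (", x$model$family, "memberships,",
      "alpha =", x$model$alpha, ")\n")
  cat(sprintf("LOOCV error %.3f, sensitivity %.3f, specificity %.3f\n",
              x$meta$loocv_error, x$meta$loocv_sensitivity,
              x$meta$loocv_specificity))
  invisible(x)
}

#' Full signature selection on a cohort
#'
#' Runs the whole construction: grade-1/3 training split (optionally ER
#' stratified), MEMBAS ranking, incremental LOOCV, minimal-signature choice.
#' With `er_mode = "auto"` both the all-tumors and ER-positive-only training
#' sets are tried; with `family = "auto"` both membership families are tried.
#' The signature with the best discriminant power — lowest LOOCV global error
#' at its chosen size, ties broken by higher sensitivity — is returned.
#'
#' @param expr Raw expression matrix (probes x samples), all cohort samples.
#' @param labels Sample annotation data frame (see [split_cohort()]).
#' @param er_mode `"auto"`, `"pos"` (ER-positive training only) or `"all"`.
#' @param family `"auto"`, `"binomial"` or `"gaussian"`.
#' @param min_specificity Specificity floor for [choose_signature()].
#' @param k_grid Candidate sizes; default [default_k_grid()].
#' @param connective,alpha_grid,per_fold_ranking See [loocv_curve()].
#' @return The winning `gene_signature`; `meta` additionally records the
#'   `er_mode` and `family` used, the training/deployment sample ids, and a
#'   `candidates` data frame summarizing every configuration tried.
#' @export
select_signature <- function(expr, labels, er_mode = c("auto", "pos", "all"),
                             family = c("auto", "binomial", "gaussian"),
                             min_specificity = 0.67, k_grid = NULL,
                             connective = c("minmax", "prodprobsum"),
                             alpha_grid = seq(0.5, 1, 0.1),
                             per_fold_ranking = FALSE) {
  er_mode <- match.arg(er_mode)
  family <- match.arg(family)
  connective <- match.arg(connective)
  expr <- .as_expr_matrix(expr)
  stopifnot(all(labels$sample_id %in% colnames(expr)))
  er_modes <- switch(er_mode, auto = c("all", "er_positive_only"),
                     pos = "er_positive_only", all = "all")
  families <- if (family == "auto") c("binomial", "gaussian") else family

  best <- NULL
  rows <- list()
  for (em in er_modes) {
    sp <- tryCatch(split_cohort(labels, em), error = function(e) e)
    if (inherits(sp, "error")) {
      if (length(er_modes) > 1L) {
        message("skipping er_mode '", em, "': ", conditionMessage(sp))
        next
      }
      stop(sp)
    }
    xtr <- expr[, sp$training, drop = FALSE]
    cls <- labels$grade[match(sp$training, labels$sample_id)]
    for (fam in families) {
      mw <- membas_weights(xtr, cls, fam)
      kg <- if (is.null(k_grid)) default_k_grid(length(mw$ranking)) else k_grid
      tr <- loocv_curve(xtr, cls, mw$ranking, k_grid = kg, family = fam,
                        connective = connective, alpha_grid = alpha_grid,
                        per_fold_ranking = per_fold_ranking)
      sig <- choose_signature(tr, xtr, cls, min_specificity = min_specificity)
      sig$meta$er_mode <- em
      sig$meta$family <- fam
      sig$meta$training_ids <- sp$training
      sig$meta$deployment_ids <- sp$deployment
      rows[[length(rows) + 1L]] <- data.frame(
        er_mode = em, family = fam, k = sig$k,
        error = sig$meta$loocv_error,
        sensitivity = sig$meta$loocv_sensitivity,
        specificity = sig$meta$loocv_specificity)
      if (is.null(best) ||
          sig$meta$loocv_error < best$meta$loocv_error ||
          (sig$meta$loocv_error == best$meta$loocv_error &&
           sig$meta$loocv_sensitivity > best$meta$loocv_sensitivity))
        best <- sig
    }
  }
  if (is.null(best)) stop("no feasible training configuration")
  best$meta$candidates <- do.call(rbind, rows)
  best
}

#' Classify deployment samples with a frozen signature
#'
#' Applies the signature's frozen model to grade-2 / unknown-grade samples,
#' producing one [grade call][classify_samples] per sample. A summary of the
#' fMG1-like / fMG3-like split and the equivocal fraction is attached as
#' attribute `"summary"`.
#'
#' @param signature A `gene_signature`.
#' @param expr Expression matrix containing the deployment samples.
#' @param sample_ids Columns to classify; default: the deployment ids recorded
#'   at selection time if available, otherwise all columns of `expr`.
#' @return A `grade_calls` data frame (possibly zero rows).
#' @export
classify_deployment <- function(signature, expr, sample_ids = NULL) {
  stopifnot(inherits(signature, "gene_signature"))
  expr <- .as_expr_matrix(expr)
  if (is.null(sample_ids))
    sample_ids <- signature$meta$deployment_ids %||% colnames(expr)
  sample_ids <- intersect(sample_ids, colnames(expr))
  if (!length(sample_ids)) {
    calls <- data.frame(sample_id = character(0), gad1 = numeric(0),
                        gad3 = numeric(0), score = numeric(0),
                        label = character(0), equivocal = logical(0),
                        stringsAsFactors = FALSE)
    class(calls) <- c("grade_calls", "data.frame")
    attr(calls, "summary") <- c(n = 0, fMG1 = 0, fMG3 = 0,
                                equivocal_fraction = NaN)
    return(calls)
  }
  calls <- classify_samples(signature$model, expr[, sample_ids, drop = FALSE])
  attr(calls, "summary") <- c(n = nrow(calls),
                              fMG1 = sum(calls$label == "fMG1"),
                              fMG3 = sum(calls$label == "fMG3"),
                              equivocal_fraction = mean(calls$equivocal))
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding (2.5 -> 3), the convention used for displayed percentages.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Agreement between molecular calls and histologic grades
#'
#' Cross-tabulates histologic grade (1/3) against the molecular call
#' (fMG1/fMG3) and derives sensitivity (fraction of grade 3 tumors called
#' fMG3), specificity (fraction of grade 1 tumors called fMG1) and the global
#' error. Raw fractions are returned alongside display percentages rounded
#' half-up to the integer.
#'
#' @param calls A `grade_calls` data frame.
#' @param grades Histologic grades (1/3) either named by sample id or in the
#'   order of `calls`.
#' @return A `grade_agreement` list: `counts` (2 x 2 integer matrix, rows HG1/
#'   HG3, columns fMG1/fMG3), `sensitivity`, `specificity`, `global_error`
#'   (fractions) and `percent` (integer display values).
#' @export
evaluate_agreement <- function(calls, grades) {
  stopifnot(is.data.frame(calls), all(c("sample_id", "label") %in% names(calls)))
  if (!is.null(names(grades))) {
    miss <- setdiff(calls$sample_id, names(grades))
    if (length(miss))
      stop("grade missing for sample(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    grades <- grades[calls$sample_id]
  } else if (length(grades) != nrow(calls)) {
    stop("grades must be named by sample id or match the calls row-for-row")
  }
  hg <- as_grade_classes(grades)  # validates 1/3 coding
  called <- factor(calls$label, levels = c("fMG1", "fMG3"))
  counts <- table(hg = hg, fMG = called)
  counts <- matrix(as.integer(counts), 2L, 2L,
                   dimnames = list(c("HG1", "HG3"), c("fMG1", "fMG3")))
  sens <- counts["HG3", "fMG3"] / sum(counts["HG3", ])
  spec <- counts["HG1", "fMG1"] / sum(counts["HG1", ])
  err <- (counts["HG1", "fMG3"] + counts["HG3", "fMG1"]) / sum(counts)
  structure(list(counts = counts, sensitivity = sens, specificity = spec,
                 global_error = err,
                 percent = c(sensitivity = round_half_up(100 * sens),
                             specificity = round_half_up(100 * spec),
                             global_error = round_half_up(100 * err))),
            class = "grade_agreement")
}

#' @export
print.grade_agreement <- function(x, ...) {
  print(x$counts)
  cat(sprintf("sensitivity %d%%, specificity %d%%, global error %d%%\n",
              x$percent["sensitivity"], x$percent["specificity"],
              x$percent["global_error"]))
  invisible(x)
}

#' Adapt a signature to a new microarray platform
#'
#' Multi-probe platforms offer several probes per signature gene. For each
#' gene, its candidate probes on the new platform are ranked by MEMBAS weight
#' computed on the new cohort's grade 1/3 training samples, and the top probe
#' is retained. Membership prototypes, bounds and exigency are then refitted
#' on the new cohort's training samples with the adapted probe list. Genes
#' with no probe on the new platform are dropped with a warning; adaptation
#' is refused if fewer than `min_gene_coverage` of the signature genes are
#' covered.
#'
#' @param signature The original `gene_signature`.
#' @param expr Expression matrix of the new cohort (new platform).
#' @param labels Annotation data frame of the new cohort (see
#'   [split_cohort()]).
#' @param probe_map Data frame with columns `probe_id`, `gene` describing the
#'   new platform.
#' @param signature_genes Genes of the original signature probes, in probe
#'   order; defaults to the probe ids themselves (one-probe-per-gene
#'   platforms).
#' @param min_gene_coverage Minimum covered gene fraction, default 0.8.
#' @return An adapted `gene_signature` (no selection trace; `meta` records
#'   the probe-per-gene choices).
#' @export
apply_cross_platform <- function(signature, expr, labels, probe_map,
                                 signature_genes = NULL,
                                 min_gene_coverage = 0.8) {
  stopifnot(inherits(signature, "gene_signature"),
            all(c("probe_id", "gene") %in% names(probe_map)))
  expr <- .as_expr_matrix(expr)
  if (is.null(signature_genes)) signature_genes <- signature$probes
  genes <- unique(as.character(signature_genes))
  pm <- probe_map[probe_map$probe_id %in% rownames(expr), , drop = FALSE]
  cand_by_gene <- split(as.character(pm$probe_id), as.character(pm$gene))
  covered <- genes[genes %in% names(cand_by_gene)]
  if (length(covered) < length(genes)) {
    warning("dropping ", length(genes) - length(covered),
            " signature gene(s) with no probe on the new platform")
  }
  if (length(covered) < min_gene_coverage * length(genes))
    stop(sprintf("only %d of %d signature genes have probes (need >= %.0f%%)",
                 length(covered), length(genes), 100 * min_gene_coverage))
  sp <- split_cohort(labels, "all")
  xtr <- expr[, sp$training, drop = FALSE]
  cls <- labels$grade[match(sp$training, labels$sample_id)]
  cands <- unique(unlist(cand_by_gene[covered]))
  mw <- membas_weights(xtr[cands, , drop = FALSE], cls,
                       family = signature$model$family)
  pick <- vapply(covered, function(g) {
    cc <- sort(cand_by_gene[[g]])
    cc[which.max(mw$weights[cc])]
  }, character(1))
  model <- lamda_fit(xtr, cls, probes = unname(pick),
                     family = signature$model$family,
                     connective = signature$model$connective,
                     nic = signature$model$nic)
  structure(list(probes = unname(pick), k = length(pick), model = model,
                 trace = NULL,
                 meta = list(adapted_from = signature$k,
                             gene = covered, probe = unname(pick),
                             training_ids = sp$training,
                             deployment_ids = sp$deployment)),
            class = "gene_signature")
}
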