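# LAMDA fuzzy classifier: marginal adequacy degrees (MAD), mixed-connective
# aggregation into global adequacy degrees (GAD), molecular grade score.

#' Fit a LAMDA fuzzy grading model
#'
#' Freezes, for the two molecular grade classes (fMG1 from histologic grade 1
#' training tumors, fMG3 from grade 3), the standardization bounds, per-class
#' per-probe membership parameters, the aggregation connective and the
#' exigency `alpha`. When `alpha` is `NULL` it is chosen from `alpha_grid` by
#' resubstitution accuracy on the training samples (ties broken toward the
#' larger, stricter alpha). The fitted model is frozen: classification never
#' mutates it.
#'
#' @param x Raw expression matrix (probes x training samples).
#' @param classes Grade labels for the columns of `x` (grade 1 / grade 3).
#' @param probes Probe ids to include (the signature); default all rows.
#' @param family Membership family, `"binomial"` or `"gaussian"`.
#' @param connective Aggregation pair: `"minmax"` (t-norm min, t-conorm max,
#'   classic) or `"prodprobsum"` (product / probabilistic sum).
#' @param alpha Exigency in \[0, 1\]; `NULL` to grid-search.
#' @param alpha_grid Candidate exigencies, default `seq(0.5, 1, 0.1)`.
#' @param nic Enable the non-informative class (all-0.5 MAD profile): calls
#'   with both class GADs below the NIC GAD are flagged low-confidence.
#' @return A `lamda_model` object.
#' @export
lamda_fit <- function(x, classes, probes = NULL,
                      family = c("binomial", "gaussian"),
                      connective = c("minmax", "prodprobsum"),
                      alpha = NULL, alpha_grid = seq(0.5, 1, 0.1),
                      nic = FALSE) {
  family <- match.arg(family)
  connective <- match.arg(connective)
  x <- .as_expr_matrix(x)
  if (is.null(probes)) probes <- rownames(x)
  if (!length(probes)) stop("probe list must be non-empty")
  miss <- setdiff(probes, rownames(x))
  if (length(miss))
    stop("probe(s) absent from matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  cls <- as_grade_classes(classes)
  xt <- x[probes, , drop = FALSE]
  bounds <- fit_bounds(xt)
  xs <- standardize(xt, bounds)
  params <- fit_membership_params(xs, cls, family)
  model <- structure(list(probes = probes, family = family,
                          connective = connective, alpha = NA_real_,
                          nic = nic, bounds = bounds, params = params,
                          classes = c("fMG1", "fMG3")),
                     class = "lamda_model")
  if (is.null(alpha)) {
    acc <- vapply(alpha_grid, function(a) {
      model$alpha <- a
      calls <- classify_samples(model, xt)
      mean(calls$label == as.character(cls))
    }, numeric(1))
    alpha <- alpha_grid[max(which(acc == max(acc)))]
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  model$alpha <- alpha
  model
}

#' Marginal adequacy degrees of a sample to one class
#'
#' The MAD of each probe is the membership of the sample's standardized value
#' to the class under the model's membership family.
#'
#' @param sample Standardized feature vector named by probe (restricted to,
#'   or a superset of, the model's probe list).
#' @param model A `lamda_model`.
#' @param class `"fMG1"` or `"fMG3"`.
#' @return Named numeric vector of MADs in \[0, 1\], one per model probe
#'   present in `sample` (absent probes are dropped).
#' @export
compute_mads <- function(sample, model, class) {
  stopifnot(inherits(model, "lamda_model"))
  class <- match.arg(class, model$classes)
  probes <- model$probes
  if (!is.null(names(sample))) {
    keep <- probes[probes %in% names(sample)]
    sample <- sample[keep]
  } else {
    if (length(sample) != length(probes))
      stop("unnamed sample must have one value per model probe")
    names(sample) <- probes
    keep <- probes
  }
  if (!length(keep)) stop("no model probes present in sample")
  xs <- matrix(sample, ncol = 1L, dimnames = list(keep, NULL))
  stats::setNames(membership_matrix(xs, model$params, class)[, 1L], keep)
}

#' Aggregate MADs into a global adequacy degree
#'
#' Mixed fuzzy connective: `GAD = alpha * T(mads) + (1 - alpha) * S(mads)`
#' where the t-norm/t-conorm pair is min/max (default) or
#' product/probabilistic sum. `alpha` is the exigency: 1 is fully strict
#' (t-norm only), 0 fully lenient. Missing MADs are excluded, i.e. the
#' aggregation runs over the present probes only.
#'
#' @param mads Numeric vector of MADs in \[0, 1\], length >= 1.
#' @param alpha Exigency in \[0, 1\].
#' @param connective `"minmax"` or `"prodprobsum"`.
#' @return GAD in \[0, 1\].
#' @examples
#' aggregate_gad(c(0.8, 0.6), alpha = 1)    # 0.6 (pure min)
#' aggregate_gad(c(0.8, 0.6), alpha = 0.5)  # 0.7
#' @export
aggregate_gad <- function(mads, alpha, connective = c("minmax", "prodprobsum")) {
  connective <- match.arg(connective)
  mads <- mads[!is.na(mads)]
  if (!length(mads)) stop("empty MAD vector")
  if (any(mads < 0 | mads > 1)) stop("MADs must lie in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (connective == "minmax") {
    alpha * min(mads) + (1 - alpha) * max(mads)
  } else {
    alpha * prod(mads) + (1 - alpha) * (1 - prod(1 - mads))
  }
}

#' Classify samples with a fitted LAMDA model
#'
#' For each sample: standardize with the model's frozen bounds (clipping into
#' the training range), compute per-class MADs, aggregate into GADs, and form
#' the molecular grade score `s = GAD3 / (GAD1 + GAD3)`. The label is fMG3
#' when `s >= 0.5` (boundary inclusive), fMG1 otherwise; scores in
#' \[0.48, 0.52\] are additionally flagged equivocal. If both GADs are zero
#' the score is set to 0.5 (equivocal) with a warning. Probes of the model
#' missing from `x` are excluded from aggregation; classification is refused
#' if more than `max_missing` of the signature probes are absent.
#'
#' @param model A `lamda_model`.
#' @param x Raw expression matrix (probes x samples) sharing the model's
#'   probe identifiers.
#' @param max_missing Maximum tolerated fraction of absent signature probes
#'   (default 0.2).
#' @return A `grade_calls` data frame with columns `sample_id`, `gad1`,
#'   `gad3`, `score`, `label`, `equivocal` (and `low_confidence` when the
#'   model's NIC flag is on).
#' @export
classify_samples <- function(model, x, max_missing = 0.2) {
  stopifnot(inherits(model, "lamda_model"))
  x <- .as_expr_matrix(x)
  present <- model$probes[model$probes %in% rownames(x)]
  frac_missing <- 1 - length(present) / length(model$probes)
  if (frac_missing > max_missing)
    stop(sprintf("%.0f%% of signature probes missing (limit %.0f%%)",
                 100 * frac_missing, 100 * max_missing))
  if (frac_missing > 0)
    message(sprintf("classify_samples: %d of %d signature probes absent; aggregating over the rest",
                    length(model$probes) - length(present), length(model$probes)))
  xt <- x[present, , drop = FALSE]
  xs <- standardize(xt, model$bounds)
  m1 <- membership_matrix(xs, model$params, "fMG1")
  m3 <- membership_matrix(xs, model$params, "fMG3")
  a <- model$alpha
  gad_col <- function(m) {
    apply(m, 2L, function(v) aggregate_gad(v, a, model$connective))
  }
  gad1 <- gad_col(m1)
  gad3 <- gad_col(m3)
  tot <- gad1 + gad3
  score <- ifelse(tot > 0, gad3 / tot, 0.5)
  if (any(tot == 0))
    warning("sample(s) with zero total GAD: score set to 0.5 (equivocal)")
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(ncol(x)))
  out <- data.frame(sample_id = ids,
                    gad1 = unname(gad1), gad3 = unname(gad3),
                    score = unname(score),
                    label = ifelse(score >= 0.5, "fMG3", "fMG1"),
                    equivocal = score >= 0.48 & score <= 0.52,
                    stringsAsFactors = FALSE)
  if (isTRUE(model$nic)) {
    k <- length(present)
    gad_nic <- aggregate_gad(rep(0.5, k), a, model$connective)
    out$low_confidence <- gad1 < gad_nic & gad3 < gad_nic
  }
  class(out) <- c("grade_calls", "data.frame")
  out
}

#' Write grade calls as TSV
#'
#' Fixed column order: `sample_id`, `gad1`, `gad3`, `score`, `label`,
#' `equivocal`.
#'
#' @param calls A `grade_calls` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- c("sample_id", "gad1", "gad3", "score", "label", "equivocal")
  stopifnot(all(cols %in% names(calls)))
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.lamda_model <- function(x, ...) {
  cat("LAMDA model:", length(x$probes), "probes,", x$family,
      "memberships,", x$connective, "connective, alpha =", x$alpha, "\n")
  invisible(x)
}

# --- serialization ---------------------------------------------------------

model_to_list <- function(model) {
  list(probes = model$probes, family = model$family,
       connective = model$connective, alpha = model$alpha, nic = model$nic,
       classes = model$classes,
       bounds = list(min = as.list(model$bounds$min),
                     max = as.list(model$bounds$max)),
       params = lapply(model$params$params, function(p) lapply(p, as.list)))
}

model_from_list <- function(l) {
  bmin <- unlist(l$bounds$min)
  bmax <- unlist(l$bounds$max)
  bounds <- structure(list(min = bmin, max = bmax, degenerate = bmax == bmin),
                      class = "standardization_bounds")
  params <- structure(list(family = l$family, classes = unlist(l$classes),
                           params = lapply(l$params, function(p) lapply(p, unlist))),
                      class = "membership_params")
  structure(list(probes = unlist(l$probes), family = l$family,
                 connective = l$connective, alpha = l$alpha,
                 nic = isTRUE(l$nic), bounds = bounds, params = params,
                 classes = unlist(l$classes)),
            class = "lamda_model")
}

#' Serialize a signature or model to JSON
#'
#' Stores the probe list, per-class per-probe membership parameters, the
#' standardization bounds, family, connective and exigency; for a
#' `gene_signature` also the selection trace metrics and metadata.
#'
#' @param object A `lamda_model` or `gene_signature`.
#' @param path Output JSON file path.
#' @return `path`, invisibly.
#' @seealso [read_signature()]
#' @export
write_signature <- function(object, path) {
  if (inherits(object, "gene_signature")) {
    l <- list(type = "gene_signature",
              model = model_to_list(object$model),
              k = object$k,
              trace = object$trace$metrics,
              meta = object$meta)
  } else if (inherits(object, "lamda_model")) {
    l <- list(type = "lamda_model", model = model_to_list(object))
  } else stop("object must be a lamda_model or gene_signature")
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized signature or model from JSON
#'
#' @param path JSON file written by [write_signature()].
#' @return A `lamda_model` or `gene_signature` (with the trace metrics
#'   restored; fold-level details are not serialized).
#' @export
read_signature <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- model_from_list(l$model)
  if (identical(l$type, "lamda_model")) return(model)
  metrics <- do.call(rbind, lapply(l$trace, function(r)
    data.frame(k = r$k, error = r$error, sensitivity = r$sensitivity,
               specificity = r$specificity)))
  trace <- structure(list(metrics = metrics, k_grid = metrics$k,
                          ranking = model$probes), class = "selection_trace")
  structure(list(probes = model$probes, k = l$k, model = model,
                 trace = trace,
                 meta = lapply(l$meta, function(v) if (is.list(v)) unlist(v) else v)),
            class = "gene_signature")
}
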