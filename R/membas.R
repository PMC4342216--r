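# MEMBAS: membership-margin based attribute selection.

#' Per-probe membership margin
#'
#' The margin of a sample for one probe is its membership to its own class
#' minus its membership to the competing class; informative probes give large
#' positive margins for correctly profiled samples.
#'
#' @param mu_own Memberships of the sample to its own class (named by probe).
#' @param mu_other Memberships to the other class, same probes.
#' @return Numeric vector of margins in \[-1, 1\].
#' @export
feature_margin <- function(mu_own, mu_other) {
  if (length(mu_own) != length(mu_other))
    stop("membership vectors differ in length")
  if (!is.null(names(mu_own)) && !is.null(names(mu_other)) &&
      !identical(names(mu_own), names(mu_other)))
    stop("membership vectors cover different probe sets")
  mu_own - mu_other
}

#' MEMBAS fuzzy feature weights and ranking
#'
#' Weights every probe by the membership margin it contributes, summed over
#' all training samples, and ranks probes by descending weight. The weight
#' vector solves `max w . m` subject to `||w||_2 = 1, w >= 0` where `m` is the
#' vector of per-probe margin sums: the analytical solution is
#' `w = max(m, 0) / ||max(m, 0)||_2`. When every margin sum is non-positive
#' the weights are all zero (with a warning) and the ranking falls back to the
#' raw margin order.
#'
#' Unless pre-fitted objects are supplied, bounds and membership parameters
#' are estimated from `x` itself (resubstitution), matching the use of the
#' selector ahead of the cross-validated classification loop.
#'
#' @param x Raw expression matrix (probes x training samples).
#' @param classes Two-class grade labels for the columns of `x`.
#' @param family Membership family, `"binomial"` (default) or `"gaussian"`.
#' @param bounds Optional pre-fitted [fit_bounds()] result.
#' @param params Optional pre-fitted [fit_membership_params()] result.
#' @return A `membas_weights` object: `weights` (unit L2 norm, named),
#'   `margins` (raw per-probe margin sums), `ranking` (probe ids, descending
#'   weight, ties broken by ascending probe id), `family`.
#' @examples
#' x <- rbind(sig = c(1, 2, 9, 10), noise = c(5, 6, 5, 6))
#' colnames(x) <- paste0("s", 1:4)
#' w <- membas_weights(x, c(1, 1, 3, 3))
#' w$ranking[1]  # "sig"
#' @export
membas_weights <- function(x, classes, family = c("binomial", "gaussian"),
                           bounds = NULL, params = NULL) {
  family <- match.arg(family)
  x <- .as_expr_matrix(x)
  cls <- as_grade_classes(classes)
  if (is.null(bounds)) bounds <- fit_bounds(x)
  xs <- standardize(x, bounds)
  if (is.null(params)) params <- fit_membership_params(xs, cls, family)
  m1 <- membership_matrix(xs, params, "fMG1")
  m3 <- membership_matrix(xs, params, "fMG3")
  own3 <- cls == "fMG3"
  margin <- m1 - m3
  margin[, own3] <- -margin[, own3, drop = FALSE]
  msum <- rowSums(margin, na.rm = TRUE)
  w <- pmax(msum, 0)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) {
    warning("all membership-margin sums are non-positive; returning zero weights")
    ord <- order(-msum, names(msum), method = "radix")
  } else {
    w <- w / nrm
    ord <- order(-w, names(w), method = "radix")
  }
  structure(list(weights = w, margins = msum, ranking = names(w)[ord],
                 family = family),
            class = "membas_weights")
}

#' Top-ranked probes
#'
#' @param weights A `membas_weights` object.
#' @param k Number of probes to take, `1 <= k <=` total probes.
#' @return Character vector: the first `k` probes of the descending ranking.
#' @export
rank_features <- function(weights, k) {
  stopifnot(inherits(weights, "membas_weights"))
  p <- length(weights$ranking)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > p)
    stop("k must be a single integer in [1, ", p, "]")
  weights$ranking[seq_len(as.integer(k))]
}

#' Write a weight vector as two-column TSV
#'
#' Columns `probe_id` and `weight`, rows in descending ranking order.
#'
#' @param weights A `membas_weights` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "membas_weights"))
  df <- data.frame(probe_id = weights$ranking,
                   weight = unname(weights$weights[weights$ranking]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.membas_weights <- function(x, ...) {
  cat("MEMBAS weights:", length(x$weights), "probes (", x$family,
      "memberships )\n")
  cat("top probes:", paste(utils::head(x$ranking, 5L), collapse = ", "), "\n")
  invisible(x)
}
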