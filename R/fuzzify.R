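# Fuzzification: min-max standardization and class membership functions.

#' Fit per-probe min-max standardization bounds
#'
#' Computes the per-probe minimum and maximum over the supplied training
#' samples. Bounds must be fitted on training samples only (histologic grade
#' 1 and 3); deployment samples standardized later are clipped into the
#' training range. Probes whose training values are constant are flagged
#' `degenerate` and are mapped to 0.5 by [standardize()] (non-informative).
#'
#' @param x Numeric matrix, probes in rows, training samples in columns.
#'   Row names identify probes.
#' @return An object of class `standardization_bounds`: a list with numeric
#'   vectors `min` and `max` (named by probe) and a logical vector
#'   `degenerate`.
#' @seealso [standardize()]
#' @examples
#' m <- matrix(c(2, 5, 8, 1, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("pA", "pB"), NULL))
#' b <- fit_bounds(m)
#' b$min; b$max; b$degenerate
#' @export
fit_bounds <- function(x) {
  x <- .as_expr_matrix(x)
  if (ncol(x) < 2L)
    stop("fit_bounds() needs at least 2 training samples")
  n_ok <- rowSums(is.finite(x))
  if (any(n_ok == 0L)) {
    bad <- rownames(x)[n_ok == 0L]
    stop("probe(s) with no finite training value: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  xmin <- suppressWarnings(apply(x, 1L, min, na.rm = TRUE))
  xmax <- suppressWarnings(apply(x, 1L, max, na.rm = TRUE))
  structure(list(min = xmin, max = xmax, degenerate = xmax == xmin),
            class = "standardization_bounds")
}

#' Min-max standardize expression values into the unit interval
#'
#' Linearly rescales each probe into \[0, 1\] with the fitted training bounds:
#' `(x - min) / (max - min)`. Values outside the training range (possible for
#' deployment samples) are clipped to \[0, 1\] so that downstream memberships
#' stay well defined. Degenerate probes (constant on training) map to 0.5.
#' Missing values are preserved.
#'
#' @param x Numeric matrix (probes x samples) or named numeric vector; probe
#'   names must match the fitted bounds.
#' @param bounds A `standardization_bounds` object from [fit_bounds()].
#' @return Standardized values of the same shape as `x`, in \[0, 1\].
#' @export
standardize <- function(x, bounds) {
  stopifnot(inherits(bounds, "standardization_bounds"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
  probes <- rownames(x)
  if (is.null(probes)) {
    if (nrow(x) != length(bounds$min))
      stop("unnamed input must have one row per fitted probe")
    probes <- names(bounds$min)
    rownames(x) <- probes
  }
  miss <- setdiff(probes, names(bounds$min))
  if (length(miss))
    stop("probe(s) without fitted bounds: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  lo <- bounds$min[probes]
  span <- bounds$max[probes] - lo
  span[span == 0] <- 1  # degenerate rows overwritten below
  z <- (x - lo) / span
  z[z < 0] <- 0
  z[z > 1] <- 1
  deg <- bounds$degenerate[probes]
  if (any(deg)) z[deg, ] <- ifelse(is.na(x[deg, , drop = FALSE]), NA_real_, 0.5)
  if (vec) z <- stats::setNames(z[, 1L], probes)
  z
}

#' Fuzzy-binomial membership function
#'
#' `rho^x * (1 - rho)^(1 - x)` for standardized value `x` and class prototype
#' `rho` (the class mean of standardized training values). The prototype is
#' clamped to `[eps, 1 - eps]` before the power form: the binomial form is
#' numerically unstable when the prototype reaches the interval ends (0^0 and
#' vanishing bases), and the clamp keeps the membership strictly positive.
#' `x` is clipped into \[0, 1\], where the power form is exact (no clamp
#' needed: at `x = 1` the membership is exactly `rho`).
#'
#' @param x Standardized value(s) in \[0, 1\] (vector or matrix; a matrix
#'   recycles `rho` along rows).
#' @param rho Class prototype(s) in \[0, 1\].
#' @param eps Clamp width, default `1e-6`.
#' @return Membership degree(s) in (0, 1\].
#' @examples
#' membership_binomial(0.3, 0.5)   # 0.5 for any x when rho = 0.5
#' membership_binomial(1, 0.8)     # 0.8
#' @export
membership_binomial <- function(x, rho, eps = 1e-6) {
  rho <- pmin(pmax(rho, eps), 1 - eps)
  xc <- pmin(pmax(x, 0), 1)
  out <- rho^xc * (1 - rho)^(1 - xc)
  out[is.na(x)] <- NA_real_
  out
}

#' Gaussian membership function
#'
#' `exp(-(x - center)^2 / (2 * spread^2))`, maximal (1) at the class center.
#'
#' @param x Standardized value(s).
#' @param center Class center(s) `mu_c` in \[0, 1\].
#' @param spread Class spread(s) `sigma_c`, strictly positive.
#' @return Membership degree(s) in (0, 1\].
#' @export
membership_gaussian <- function(x, center, spread) {
  if (any(spread <= 0, na.rm = TRUE)) stop("spread must be > 0")
  exp(-(x - center)^2 / (2 * spread^2))
}

#' Fit per-class membership parameters
#'
#' Estimates, per probe and per class, the parameters of the chosen membership
#' family from standardized training data: the binomial prototype `rho` is the
#' class mean; the Gaussian uses the class mean as center and the class
#' standard deviation as spread, floored at `sigma_floor` to avoid degenerate
#' spikes. Missing values are excluded from the estimates.
#'
#' @param xs Standardized matrix (probes x training samples), values in
#'   \[0, 1\].
#' @param classes Class assignment of the training samples; anything accepted
#'   by the grade-1/grade-3 coding (`1`/`3`, `"HG1"`/`"HG3"`,
#'   `"fMG1"`/`"fMG3"`).
#' @param family `"binomial"` or `"gaussian"`.
#' @param sigma_floor Lower bound for the Gaussian spread on the unit-interval
#'   scale; default 0.01.
#' @return A `membership_params` object: family, class levels, and a per-class
#'   list of parameter vectors (`rho`, or `mu` and `sigma`) named by probe.
#' @export
fit_membership_params <- function(xs, classes,
                                  family = c("binomial", "gaussian"),
                                  sigma_floor = 0.01) {
  family <- match.arg(family)
  xs <- .as_expr_matrix(xs)
  cls <- as_grade_classes(classes)
  if (length(cls) != ncol(xs))
    stop("length(classes) must equal ncol(xs)")
  sizes <- table(cls)
  if (any(sizes < 2L))
    stop("each class needs at least 2 training samples (got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), ")")
  est <- lapply(levels(cls), function(lv) {
    xc <- xs[, cls == lv, drop = FALSE]
    cnt <- rowSums(!is.na(xc))
    if (any(cnt == 0L))
      stop("probe with all-missing values in class ", lv, ": ",
           rownames(xc)[which(cnt == 0L)[1L]])
    mu <- rowMeans(xc, na.rm = TRUE)
    if (family == "binomial") return(list(rho = mu))
    ss <- rowSums(xc^2, na.rm = TRUE) - cnt * mu^2
    sigma <- sqrt(pmax(ss, 0) / pmax(cnt - 1L, 1L))
    list(mu = mu, sigma = pmax(sigma, sigma_floor))
  })
  names(est) <- levels(cls)
  structure(list(family = family, classes = levels(cls), params = est),
            class = "membership_params")
}

# Per-probe memberships of every column of a standardized matrix to one class.
membership_matrix <- function(xs, params, class) {
  stopifnot(inherits(params, "membership_params"))
  p <- params$params[[class]]
  if (is.null(p)) stop("unknown class: ", class)
  probes <- rownames(xs)
  if (params$family == "binomial") {
    membership_binomial(xs, p$rho[probes])
  } else {
    membership_gaussian(xs, p$mu[probes], p$sigma[probes])
  }
}

# Coerce grade labels to the canonical two-class factor fMG1/fMG3.
as_grade_classes <- function(g) {
  if (is.factor(g)) g <- as.character(g)
  g <- as.character(g)
  map <- c("1" = "fMG1", "HG1" = "fMG1", "G1" = "fMG1", "fMG1" = "fMG1",
           "3" = "fMG3", "HG3" = "fMG3", "G3" = "fMG3", "fMG3" = "fMG3")
  out <- map[g]
  if (anyNA(out))
    stop("unrecognized grade label(s): ",
         paste(utils::head(unique(g[is.na(out)]), 5L), collapse = ", "))
  factor(out, levels = c("fMG1", "fMG3"))
}

.as_expr_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric matrix (probes x samples)")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("probe_%05d", seq_len(nrow(x)))
  x
}
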