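# Bimodality detection and sample partitioning.
#
# Two complementary statistics are computed per gene:
#   * a bimodality index from a two-component equal-variance Gaussian
#     mixture fitted by EM: BI = sqrt(pi * (1 - pi)) * delta, with
#     delta = (mu_high - mu_low) / sigma, so BI rewards both separation of
#     the modes and balance of the sample split;
#   * a distribution midpoint located as the widest gap between consecutive
#     sorted expression values inside a tail-exclusion quantile band, which
#     stays informative for non-normal profiles where the mixture modes
#     overlap or one mode is small.
# The midpoint then partitions samples into low/high modes, with an adaptive
# window below the midpoint (up to 5% of the distance to the distribution
# floor) in which samples stay unassigned when the split is imbalanced.

#' Threshold presets for bimodal gene selection
#'
#' Four presets trade stringency against the expected dilution of bimodal
#' signal: homogeneous cell-line panels versus heterogeneous patient tumours,
#' each with a `_low` variant for datasets with fewer than ~200 samples
#' (stricter, to hold the false-positive rate down).
#'
#' @param name One of `"cell_line"`, `"cell_line_low"`, `"patient"`,
#'   `"patient_low"`.
#' @return List with components `name`, `bi_min`, `delta_min`.
#' @examples
#' bimodal_preset("cell_line")
#' @export
bimodal_preset <- function(name = c("cell_line", "cell_line_low",
                                    "patient", "patient_low")) {
  name <- match.arg(name)
  thr <- switch(name,
                cell_line     = c(0.7, 2.5),
                cell_line_low = c(1.1, 3.5),
                patient       = c(0.5, 2.5),
                patient_low   = c(0.9, 3.0))
  list(name = name, bi_min = thr[1], delta_min = thr[2])
}

#' Locate the midpoint of a (possibly diluted) bimodal distribution
#'
#' Sorts the values, computes every gap between consecutive sorted values,
#' and returns the centre of the widest gap whose lower flank lies inside
#' the rank-quantile band `[tail_exclusion, 1 - tail_exclusion]`. The band
#' keeps single outliers in either tail from masquerading as a mode gap.
#' Ties between equally wide gaps are broken toward the gap whose centre is
#' closest to the sample median (then the lower gap).
#'
#' @param values Numeric vector of log2 expression values (>= 10 finite).
#' @param tail_exclusion Fraction of ranks excluded from each tail when
#'   searching for the gap (default 0.10).
#' @return The midpoint (mean of the two values flanking the widest
#'   eligible gap), strictly between `min(values)` and `max(values)`.
#' @examples
#' big_midpoint(c(1.0, 1.2, 1.4, 5.0, 5.1, 5.3, 5.4, 5.5, 5.6, 5.7))
#' @export
big_midpoint <- function(values, tail_exclusion = 0.1) {
  v <- sort(values[is.finite(values)])
  n <- length(v)
  if (n < 10) stop_("insufficient samples: need at least 10 finite values")
  if (v[n] - v[1] < .Machine$double.eps) stop_("no gap: all values identical")
  gaps <- diff(v)
  lo <- max(1L, as.integer(ceiling(tail_exclusion * n)))
  hi <- min(n - 1L, as.integer(floor((1 - tail_exclusion) * n)))
  if (lo > hi) { lo <- 1L; hi <- n - 1L }
  idx <- lo:hi
  if (max(gaps[idx]) == 0) idx <- seq_len(n - 1L)  # flat interior: widen
  cand <- idx[gaps[idx] == max(gaps[idx])]
  if (length(cand) > 1L) {
    centres <- (v[cand] + v[cand + 1L]) / 2
    cand <- cand[order(abs(centres - stats::median(v)), cand)]
  }
  i <- cand[1L]
  (v[i] + v[i + 1L]) / 2
}

#' Fit the two-component mixture bimodality index to one gene
#'
#' Fits a two-component Gaussian mixture with a shared standard deviation by
#' expectation-maximization and summarizes it as a bimodality index. The
#' shared sigma is what makes delta a standardized mode separation. EM is
#' initialized deterministically from the hard split at the gap midpoint
#' ([big_midpoint()]), runs at most `max_iter` iterations and stops when the
#' log-likelihood moves by less than `tol`; a non-converged fit is flagged
#' and reported with `bi = 0`.
#'
#' @inheritParams big_midpoint
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @return Object of class `"bimodal_fit"`: a list with `mu_low`, `mu_high`
#'   (component means, `mu_low <= mu_high`), `sigma` (shared within-mode sd),
#'   `pi` (mixing weight of the lower component), `delta`
#'   (`(mu_high - mu_low)/sigma`), `bi` (`sqrt(pi*(1-pi))*delta`),
#'   `midpoint`, `converged`, `n`.
#' @examples
#' set.seed(1)
#' fit_bimodality_index(c(rnorm(100, 2, 0.5), rnorm(100, 8, 0.5)))
#' @export
fit_bimodality_index <- function(values, tail_exclusion = 0.1,
                                 max_iter = 500, tol = 1e-6) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 10) stop_("insufficient samples: need at least 10 finite values")
  rng <- diff(range(v))
  if (rng < .Machine$double.eps) {
    return(structure(list(mu_low = v[1], mu_high = v[1],
                          sigma = .Machine$double.eps, pi = 0.5,
                          delta = 0, bi = 0, midpoint = NA_real_,
                          converged = TRUE, n = n),
                     class = "bimodal_fit"))
  }
  mid <- big_midpoint(v, tail_exclusion)
  low <- v < mid
  mu1 <- mean(v[low]); mu2 <- mean(v[!low])
  s <- sqrt((sum((v[low] - mu1)^2) + sum((v[!low] - mu2)^2)) / n)
  s <- max(s, 1e-6 * rng)
  p1 <- min(max(mean(low), 1e-3), 1 - 1e-3)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- p1 * stats::dnorm(v, mu1, s)
    d2 <- (1 - p1) * stats::dnorm(v, mu2, s)
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    g <- d1 / tot
    sg <- sum(g)
    p1 <- min(max(sg / n, 1e-6), 1 - 1e-6)
    mu1 <- sum(g * v) / sg
    mu2 <- sum((1 - g) * v) / (n - sg)
    s <- sqrt(max((sum(g * (v - mu1)^2) + sum((1 - g) * (v - mu2)^2)) / n,
                  (1e-6 * rng)^2))
  }
  if (mu1 > mu2) { tmp <- mu1; mu1 <- mu2; mu2 <- tmp; p1 <- 1 - p1 }
  delta <- (mu2 - mu1) / s
  structure(list(mu_low = mu1, mu_high = mu2, sigma = s, pi = p1,
                 delta = delta,
                 bi = if (converged) sqrt(p1 * (1 - p1)) * delta else 0,
                 midpoint = mid, converged = converged, n = n),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "Two-component mixture fit (n = %d)\n  mu_low = %.3f  mu_high = %.3f  sigma = %.3f\n  pi = %.3f  delta = %.3f  BI = %.3f  midpoint = %.3f%s\n",
    x$n, x$mu_low, x$mu_high, x$sigma, x$pi, x$delta, x$bi, x$midpoint,
    if (x$converged) "" else "  [EM did not converge]"))
  invisible(x)
}

#' Partition samples into low/high expression modes with an adaptive window
#'
#' Samples above the midpoint are `high`, samples below the window band are
#' `low`, and samples inside the band `[midpoint - w, midpoint]` stay
#' `unassigned`. The band width is
#' `w = 0.05 * (1 - 2 * min(pi, 1 - pi)) * (midpoint - min(values))`:
#' a balanced split (`pi = 0.5`, clear separation) gives `w = 0` and plain
#' thresholding, while an extreme minority mode (mode overlap more likely)
#' pushes the window toward 5% of the distance from midpoint to the
#' distribution floor. The band sits below the midpoint only, where the
#' overlap of a diluted low mode lives.
#'
#' @param fit A `"bimodal_fit"` (needs `pi` and `midpoint`).
#' @param values Numeric vector of the gene's expression values.
#' @return Object of class `"sample_classification"`: list with `labels`
#'   (character vector in `low`/`high`/`unassigned`, named like `values`),
#'   `window_fraction` (realized fraction in `[0, 0.05]`), `window` (width
#'   in log2 units) and `midpoint`.
#' @export
classify_samples <- function(fit, values) {
  mid <- fit$midpoint
  if (!is.finite(mid)) stop_("fit has no midpoint")
  pim <- min(fit$pi, 1 - fit$pi)
  wfrac <- 0.05 * (1 - 2 * pim)
  w <- wfrac * (mid - min(values, na.rm = TRUE))
  labels <- ifelse(values > mid, "high",
                   ifelse(values < mid - w, "low", "unassigned"))
  names(labels) <- names(values)
  structure(list(labels = labels, window_fraction = wfrac, window = w,
                 midpoint = mid),
            class = "sample_classification")
}

#' Detect bimodal genes in an expression matrix
#'
#' Fits [fit_bimodality_index()] and [big_midpoint()] to every gene and
#' filters on `bi >= bi_min & delta >= delta_min`. All per-gene diagnostics
#' are kept in the returned object (`fits` with a `passes_filter` column);
#' sample mode labels are computed for the passing genes.
#'
#' @param m Numeric log2 expression matrix, genes x samples (>= 10 samples).
#' @param preset Preset name passed to [bimodal_preset()], or `NULL` when
#'   giving explicit thresholds.
#' @param bi_min,delta_min Explicit thresholds overriding the preset.
#' @param tail_exclusion Tail band for the midpoint search.
#' @return Object of class `"bisep"`: list with `fits` (data frame, one row
#'   per gene: `gene`, `mu_low`, `mu_high`, `sigma`, `pi`, `delta`, `bi`,
#'   `midpoint`, `converged`, `passes_filter`), `labels` (character matrix,
#'   passing genes x samples, values `low`/`high`/`unassigned`),
#'   `window_fraction` (named vector for passing genes), `thresholds`,
#'   `expr` (the input matrix).
#' @examples
#' set.seed(1)
#' m <- rbind(bim = c(rnorm(60, 2, 0.4), rnorm(60, 6, 0.4)),
#'            flat = rnorm(120, 5, 0.4))
#' colnames(m) <- paste0("s", 1:120)
#' bisep(m, preset = "cell_line")
#' @export
bisep <- function(m, preset = "cell_line", bi_min = NULL, delta_min = NULL,
                  tail_exclusion = 0.1) {
  if (is.null(bi_min) != is.null(delta_min))
    stop_("give both bi_min and delta_min, or neither")
  if (is.null(bi_min)) {
    ps <- bimodal_preset(preset)
  } else {
    ps <- list(name = "custom", bi_min = bi_min, delta_min = delta_min)
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_("expression matrix needs gene row names and sample column names")
  validate_ids(rownames(m), "gene")
  validate_ids(colnames(m), "sample")
  if (ncol(m) < 10) stop_("insufficient samples: need at least 10")
  fits <- lapply(seq_len(nrow(m)), function(i)
    fit_bimodality_index(m[i, ], tail_exclusion = tail_exclusion))
  df <- data.frame(
    gene = rownames(m),
    mu_low = vapply(fits, `[[`, 0, "mu_low"),
    mu_high = vapply(fits, `[[`, 0, "mu_high"),
    sigma = vapply(fits, `[[`, 0, "sigma"),
    pi = vapply(fits, `[[`, 0, "pi"),
    delta = vapply(fits, `[[`, 0, "delta"),
    bi = vapply(fits, `[[`, 0, "bi"),
    midpoint = vapply(fits, `[[`, 0, "midpoint"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  df$passes_filter <- df$converged & !is.na(df$midpoint) &
    df$bi >= ps$bi_min & df$delta >= ps$delta_min
  pass <- which(df$passes_filter)
  labels <- matrix(character(0), 0, ncol(m),
                   dimnames = list(NULL, colnames(m)))
  wfrac <- numeric(0)
  if (length(pass) > 0) {
    cls <- lapply(pass, function(i) classify_samples(fits[[i]], m[i, ]))
    labels <- do.call(rbind, lapply(cls, `[[`, "labels"))
    rownames(labels) <- df$gene[pass]
    wfrac <- stats::setNames(vapply(cls, `[[`, 0, "window_fraction"),
                             df$gene[pass])
  }
  structure(list(fits = df, labels = labels, window_fraction = wfrac,
                 thresholds = ps, expr = m),
            class = "bisep")
}

#' @export
print.bisep <- function(x, ...) {
  cat(sprintf(
    "Bimodality screen: %d/%d genes pass (preset %s: BI >= %.2f, delta >= %.2f) over %d samples\n",
    sum(x$fits$passes_filter), nrow(x$fits), x$thresholds$name,
    x$thresholds$bi_min, x$thresholds$delta_min, ncol(x$expr)))
  invisible(x)
}

#' @export
summary.bisep <- function(object, ...) {
  print(object)
  p <- object$fits[object$fits$passes_filter, ]
  if (nrow(p) > 0) {
    p <- p[order(-p$bi), ]
    cat("Top passing genes by BI:\n")
    print(utils::head(p[, c("gene", "pi", "delta", "bi", "midpoint")], 10),
          row.names = FALSE)
  }
  invisible(object)
}

#' Genes passing the bimodality filter
#'
#' @param x A `"bisep"` object.
#' @return Character vector of passing gene identifiers.
#' @export
bimodal_genes <- function(x) {
  stopifnot(inherits(x, "bisep"))
  x$fits$gene[x$fits$passes_filter]
}
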