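# Pan-transcriptome size estimation by rarefaction.
#
# Lines are subsampled in nested increments (a random permutation's
# prefixes, so "adding 20 lines at a time"), gene accumulation and core
# attrition are tracked across repetitions, and an exponential saturation
# curve y(n) = A - B exp(-n / C) is fitted to the increasing component to
# estimate its asymptote A.

#' Rarefaction of a presence matrix
#'
#' For each repetition a random permutation of lines is drawn and the
#' prefixes of size `step, 2 step, ..., max_n` are scored (samples are
#' nested within a repetition).  NA states count as absent.  Components:
#' `novel_pan` = genes present in at least one sampled line; `ref_core` =
#' genes present in more than `floor(0.95 n)` sampled lines;
#' `ref_dispensable` = pan minus core.
#'
#' @param presence Ternary matrix (genes x lines).
#' @param step Increment in lines (default 20).
#' @param max_n Largest subsample (default: all lines, rounded down to a
#'   multiple of `step`).
#' @param reps Number of repetitions (default 10).
#' @param core_frac Core presence fraction within a subsample
#'   (default 0.95).
#' @param seed Optional RNG seed for reproducible curves.
#' @return A data.frame of class `pan_curve` with columns `n_sampled`,
#'   `component`, `mean_count`, `sd_count`, `n_reps`; per-repetition
#'   counts are kept in attribute `"per_rep"` (a component-named list of
#'   reps x n matrices).
#' @export
rarefy <- function(presence, step = 20L, max_n = NULL, reps = 10L,
                   core_frac = 0.95, seed = NULL) {
  stopifnot(is.matrix(presence))
  n_lines <- ncol(presence)
  if (is.null(max_n)) max_n <- (n_lines %/% step) * step
  if (step > max_n) stop("step exceeds max_n")
  if (max_n > n_lines) stop("max_n exceeds the number of lines")
  if (!is.null(seed)) set.seed(seed)
  pres <- !is.na(presence) & presence == 1L
  sizes <- seq.int(step, max_n, by = step)
  comps <- c("novel_pan", "ref_core", "ref_dispensable")
  per <- lapply(comps, function(x)
    matrix(NA_real_, nrow = reps, ncol = length(sizes),
           dimnames = list(NULL, sizes)))
  names(per) <- comps
  for (r in seq_len(reps)) {
    perm <- sample.int(n_lines)
    counts <- rowSums(pres[, perm[seq_len(step)], drop = FALSE])
    for (j in seq_along(sizes)) {
      n <- sizes[j]
      if (j > 1L) {
        add <- perm[(sizes[j - 1L] + 1L):n]
        counts <- counts + rowSums(pres[, add, drop = FALSE])
      }
      pan <- sum(counts >= 1L)
      core <- sum(counts > floor(core_frac * n))
      per$novel_pan[r, j] <- pan
      per$ref_core[r, j] <- core
      per$ref_dispensable[r, j] <- pan - core
    }
  }
  out <- do.call(rbind, lapply(comps, function(cp)
    data.frame(n_sampled = sizes, component = cp,
               mean_count = colMeans(per[[cp]]),
               sd_count = apply(per[[cp]], 2L, stats::sd),
               n_reps = reps, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "per_rep") <- per
  class(out) <- c("pan_curve", "data.frame")
  out
}

#' Fit a saturation curve to an increasing rarefaction component
#'
#' Least-squares fit of `mean_count(n) = A - B exp(-n / C)` with
#' `A >= max(mean_count)`, `B > 0`, `C > 0`, using multi-start
#' Levenberg-Marquardt.  A Heaps-law power curve `y = a n^b` can be fitted
#' instead for openness diagnosis.
#'
#' @param points A `pan_curve` (one component will be selected) or any
#'   data.frame with `n_sampled` and `mean_count`.
#' @param component Component to fit when `points` is a full curve
#'   (default `"novel_pan"`).
#' @param model `"exponential"` (default) or `"power"`.
#' @return An object of class `asymptote_fit` with elements `A`, `B`, `C`
#'   (exponential) or `a`, `b` (power), `rss`, `converged`, `model`,
#'   `n`, `y`; methods: `print`, `coef`, `fitted`, `predict`,
#'   `residuals`.
#' @export
fit_asymptote <- function(points, component = "novel_pan",
                          model = c("exponential", "power")) {
  model <- match.arg(model)
  if ("component" %in% colnames(points))
    points <- points[points$component == component, , drop = FALSE]
  n <- points$n_sampled
  y <- points$mean_count
  if (length(unique(n)) < 4L)
    stop("need at least 4 distinct subsample sizes to fit")
  if (model == "power") {
    fit <- stats::lm(log(y) ~ log(n))
    a <- exp(stats::coef(fit)[[1L]]); b <- stats::coef(fit)[[2L]]
    res <- y - a * n^b
    return(structure(list(a = a, b = b, rss = sum(res^2), converged = TRUE,
                          model = model, n = n, y = y),
                     class = "asymptote_fit"))
  }
  ymax <- max(y)
  if (stats::sd(y) == 0) {
    return(structure(list(A = ymax, B = 0, C = 1, rss = 0, converged = TRUE,
                          model = model, n = n, y = y),
                     class = "asymptote_fit"))
  }
  best <- NULL
  span <- diff(range(n))
  for (C0 in span * c(0.05, 0.15, 0.3, 0.6, 1, 2)) {
    A0 <- ymax + max(1, 0.05 * ymax)
    B0 <- max(A0 - min(y), 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A - B * exp(-n / C),
                        start = list(A = A0, B = B0, C = C0),
                        lower = c(A = ymax, B = 1e-12, C = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss,
                   converged = fit$convInfo$isConv)
  }
  if (is.null(best))
    return(structure(list(A = NA_real_, B = NA_real_, C = NA_real_,
                          rss = NA_real_, converged = FALSE, model = model,
                          n = n, y = y), class = "asymptote_fit"))
  structure(list(A = best$coef[["A"]], B = best$coef[["B"]],
                 C = best$coef[["C"]], rss = best$rss,
                 converged = isTRUE(best$converged), model = model,
                 n = n, y = y),
            class = "asymptote_fit")
}

#' @export
coef.asymptote_fit <- function(object, ...) {
  if (object$model == "power") c(a = object$a, b = object$b)
  else c(A = object$A, B = object$B, C = object$C)
}

#' @export
predict.asymptote_fit <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$n else
    if (is.data.frame(newdata)) newdata$n_sampled else newdata
  if (object$model == "power") object$a * n^object$b
  else object$A - object$B * exp(-n / object$C)
}

#' @export
fitted.asymptote_fit <- function(object, ...) predict(object)

#' @export
residuals.asymptote_fit <- function(object, ...) object$y - predict(object)

#' @export
print.asymptote_fit <- function(x, ...) {
  if (x$model == "power")
    cat(sprintf("power-law gene accumulation fit: y = %.4g * n^%.4g (rss %.4g)\n",
                x$a, x$b, x$rss))
  else
    cat(sprintf(
      "saturation fit: y = %.5g - %.4g exp(-n/%.4g); asymptote A = %.5g (rss %.4g, %s)\n",
      x$A, x$B, x$C, x$A, x$rss,
      if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Compose the total pan-transcriptome size
#'
#' Sums the core, dispensable and novel components.  Each argument may be
#' a plain count or an [fit_asymptote()] result (whose asymptote `A` is
#' used).  The published composition 22,043 + 13,382 + ~28,000 sums to
#' 63,425, i.e. about 63,000 at nearest-thousand rounding.
#'
#' @param core Core-gene component (count or fit).
#' @param dispensable Dispensable-gene component (count or fit).
#' @param novel Novel-gene component (count or fit).
#' @return A list of class `pan_summary`: `components` (named numeric),
#'   `total` (exact sum) and `total_rounded_thousand`.
#' @export
pan_summary <- function(core, dispensable, novel) {
  val <- function(x) if (inherits(x, "asymptote_fit")) x$A else as.numeric(x)
  comp <- c(core = val(core), dispensable = val(dispensable),
            novel = val(novel))
  total <- sum(comp)
  structure(list(components = comp, total = total,
                 total_rounded_thousand = round(total / 1000) * 1000),
            class = "pan_summary")
}

#' @export
print.pan_summary <- function(x, ...) {
  cat(sprintf(
    "pan-transcriptome size: %0.f core + %0.f dispensable + %0.f novel = %0.f (~%0.f)\n",
    x$components[["core"]], x$components[["dispensable"]],
    x$components[["novel"]], x$total, x$total_rounded_thousand))
  invisible(x)
}
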