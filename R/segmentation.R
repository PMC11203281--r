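#' Least-squares parabola through portrait points
#'
#' Fits v = a2 x^2 + a1 x + a0.  For a sigmoid-stage portrait the
#' coefficients identify the stage parameters: a2 = -1/(tau D0),
#' a1 = 1/tau, a0 = 0.
#'
#' @param x,v numeric vectors of state and rate values; at least 3 distinct
#'   `x` values are required.
#' @return Named list with `a2`, `a1`, `a0`, `r2`, `rmse`.  `r2` is defined
#'   as 1 when zero-variance `v` is fitted exactly.
#' @export
fit_parabola <- function(x, v) {
  if (length(unique(x)) < 3)
    stopf("fit_parabola() needs at least 3 distinct x values, got %d",
          length(unique(x)))
  f <- polyfit_span(x, v, 2)
  list(a2 = unname(f$coef[3]), a1 = unname(f$coef[2]),
       a0 = unname(f$coef[1]), r2 = f$r2, rmse = f$rmse)
}

#' Least-squares line through portrait points
#'
#' Fits v = slope x + intercept.  For an exponential-saturation stage the
#' portrait line has slope -1/tau and intercept D0/tau.
#'
#' @param x,v numeric vectors; at least 2 distinct `x` values.
#' @return Named list with `slope`, `intercept`, `r2`, `rmse`.
#' @export
fit_line <- function(x, v) {
  if (length(unique(x)) < 2)
    stopf("fit_line() needs at least 2 distinct x values")
  f <- polyfit_span(x, v, 1)
  list(slope = unname(f$coef[2]), intercept = unname(f$coef[1]),
       r2 = f$r2, rmse = f$rmse)
}

# Internal polynomial fit used throughout segmentation.  Centers x for
# conditioning; returns coefficients in the raw basis.
polyfit_span <- function(x, v, degree) {
  n <- length(x)
  mx <- mean(x)
  xc <- x - mx
  X <- if (degree == 2) cbind(1, xc, xc * xc) else cbind(1, xc)
  f <- stats::lm.fit(X, v)
  b <- f$coefficients
  b[is.na(b)] <- 0
  coef <- if (degree == 2) {
    c(b[1] - b[2] * mx + b[3] * mx^2, b[2] - 2 * b[3] * mx, b[3])
  } else {
    c(b[1] - b[2] * mx, b[2])
  }
  rss <- sum(f$residuals^2)
  tss <- sum((v - mean(v))^2)
  vscale2 <- sum(v^2) + .Machine$double.xmin
  r2 <- if (tss <= 1e-24 * vscale2) {
    if (rss <= 1e-24 * vscale2) 1 else 0
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  list(coef = coef, rss = rss, r2 = r2, rmse = sqrt(rss / n), n = n)
}

#' Segmentation configuration
#'
#' Tuning parameters for [segment_portrait()].  All thresholds are
#' scale-free (R-squared, relative curvature, F statistics, noise-relative
#' mean squares), so stage counting is invariant under affine rescaling of
#' the measured axis and shifts of temperature.
#'
#' @param min_segment_length minimum points per classified fragment
#'   (>= 3; default 5).
#' @param r2_threshold minimum own-fit R-squared for a fragment to be
#'   classified parabolic or linear rather than intermediate (default
#'   0.98).  A fragment whose residual mean square matches its own
#'   flexible benchmark fit (see `lof_factor`) also classifies, even when
#'   noise depresses its R-squared.
#' @param model_selection `"bic"` (default) or `"f_test"`: how the line and
#'   parabola compete inside a fragment.
#' @param f_test_alpha significance level for the quadratic-term F test; the
#'   line is preferred whenever the quadratic term is not significant
#'   (parsimony: prevents every line being called a degenerate parabola).
#' @param merge_tolerance relative coefficient tolerance when merging
#'   adjacent same-kind fragments (default 0.1).
#' @param curvature_threshold minimum relative curvature for a parabolic
#'   call: the quadratic term's maximal deviation from a chord over the
#'   fragment, |a2| (x-range)^2 / 4, must exceed this fraction of the
#'   fragment's v-range (default 0.05).
#' @param min_stage_fraction minimum fraction of the portrait's points a
#'   classified fragment must contain (default 0.1): a stage supported by a
#'   negligible sliver of the curve is indistinguishable from a transition
#'   artifact.
#' @param lof_factor lack-of-fit allowance: a fragment whose residual mean
#'   square is at most `lof_factor` times that of a flexible benchmark fit
#'   on the same fragment (an orthogonal polynomial of degree up to 6) is
#'   considered fully explained by the model (default 2).  The benchmark
#'   absorbs whatever noise floor the portrait carries -- iid derivative
#'   noise or smoothing-correlated noise alike -- so the test needs no
#'   separate noise estimate.
#' @return An object of class `segment_config`.
#' @export
segment_config <- function(min_segment_length = 5, r2_threshold = 0.98,
                           model_selection = c("bic", "f_test"),
                           f_test_alpha = 0.05, merge_tolerance = 0.1,
                           curvature_threshold = 0.05,
                           min_stage_fraction = 0.1, lof_factor = 2) {
  model_selection <- match.arg(model_selection)
  if (min_segment_length < 3) stopf("min_segment_length must be >= 3")
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stopf("r2_threshold must be in (0, 1)")
  if (f_test_alpha <= 0 || f_test_alpha >= 1)
    stopf("f_test_alpha must be in (0, 1)")
  if (min_stage_fraction < 0 || min_stage_fraction >= 1)
    stopf("min_stage_fraction must be in [0, 1)")
  structure(list(min_segment_length = as.integer(min_segment_length),
                 r2_threshold = r2_threshold,
                 model_selection = model_selection,
                 f_test_alpha = f_test_alpha,
                 merge_tolerance = merge_tolerance,
                 curvature_threshold = curvature_threshold,
                 min_stage_fraction = min_stage_fraction,
                 lof_factor = lof_factor),
            class = "segment_config")
}

# Residual mean square of a flexible benchmark fit (orthogonal polynomial
# of degree up to 6) over one span.  Any smooth portrait shape -- and any
# noise floor, iid or smoothing-correlated -- is absorbed by the benchmark,
# so a candidate model whose residual mean square matches the benchmark's
# has no detectable lack of fit on that span.
benchmark_fit <- function(x, v) {
  n <- length(v)
  deg <- min(6L, n - 2L, length(unique(x)) - 1L)
  if (deg < 1L) return(list(rss = 0, df = 0L, ms = 0, p = 1L))
  f <- tryCatch(
    stats::lm.fit(cbind(1, stats::poly(x, degree = deg)), v),
    error = function(e) NULL)
  if (is.null(f)) return(list(rss = 0, df = 0L, ms = 0, p = 1L))
  df <- max(n - (deg + 1L), 1L)
  rss <- sum(f$residuals^2)
  list(rss = rss, df = df, ms = rss / df, p = deg + 1L)
}

# Classify one span of portrait points as parabolic / linear / NA
# (unclassifiable).  A span classifies under a model when its own-fit R2
# meets the threshold OR its residual mean square is within the
# lack-of-fit allowance of the span's benchmark fit (see benchmark_ms).  A
# parabolic call additionally requires a concave parabola (a2 < 0 -- the
# stage parabola dD/dT = (D/tau)(1 - D/D0) always opens downwards) with
# relative curvature above the discrimination threshold and a significant
# quadratic term; otherwise the line is preferred (parsimony).
classify_span <- function(x, v, cfg) {
  n <- length(x)
  xr <- diff(range(x))
  vr <- diff(range(v))
  lf <- polyfit_span(x, v, 1)
  bench <- benchmark_fit(x, v)
  vscale2 <- mean(v^2) + .Machine$double.xmin
  ok <- function(f, p) {
    if (f$r2 >= cfg$r2_threshold) return(TRUE)
    if (bench$df < 1 || bench$ms <= 1e-20 * vscale2) return(FALSE)
    if (f$rss / max(n - p, 1) > cfg$lof_factor * bench$ms) return(FALSE)
    extra_df <- max(bench$p - p, 1L)
    Fstat <- max(f$rss - bench$rss, 0) / extra_df / bench$ms
    stats::pf(Fstat, extra_df, bench$df, lower.tail = FALSE) >=
      cfg$f_test_alpha
  }
  line_res <- list(kind = "linear", fit = lf, degree = 1)
  if (xr <= 1e-12 * (1 + max(abs(x))) || n < 4 || length(unique(x)) < 4)
    return(if (ok(lf, 2)) line_res else NULL)
  pf <- polyfit_span(x, v, 2)
  curv <- abs(pf$coef[3]) * xr^2 / 4 / max(vr, 1e-300)
  p_quad <- if (pf$rss < lf$rss && n > 3) {
    Fstat <- (lf$rss - pf$rss) / max(pf$rss / (n - 3), 1e-300)
    stats::pf(Fstat, 1, n - 3, lower.tail = FALSE)
  } else 1
  bic <- function(rss, k) n * log(max(rss, .Machine$double.xmin) / n) +
    k * log(n)
  favored <- if (cfg$model_selection == "bic") {
    bic(pf$rss, 4) < bic(lf$rss, 3)
  } else TRUE
  parab_call <- favored && p_quad < cfg$f_test_alpha &&
    pf$coef[3] < 0 && curv > cfg$curvature_threshold && ok(pf, 3)
  if (parab_call) return(list(kind = "parabolic", fit = pf, degree = 2))
  if (ok(lf, 2)) return(line_res)
  NULL
}

# Longest classifiable sub-span inside [i0, j0]: for a deterministic set of
# start points, the maximal classifiable end is found by doubling plus
# bisection (classifiability is monotone-enough in span length for the
# smooth curves at hand).  Returns c(i, j) or NULL.
longest_classifiable <- function(x, v, i0, j0, min_len, cfg) {
  ok <- function(i, j) !is.null(classify_span(x[i:j], v[i:j], cfg))
  len <- j0 - i0 + 1
  if (len < min_len) return(NULL)
  stride <- max(1L, len %/% 80L)
  starts <- unique(c(seq(i0, j0 - min_len + 1, by = stride),
                     j0 - min_len + 1))
  best <- NULL
  for (i in starts) {
    jmax_possible <- j0
    j <- i + min_len - 1
    if (!ok(i, j)) next
    # doubling
    while (j < jmax_possible) {
      jn <- min(jmax_possible, i + (j - i + 1) * 2 - 1)
      if (ok(i, jn)) j <- jn else { jmax_possible <- jn - 1; break }
      if (j == jmax_possible) break
    }
    # bisection between j (ok) and jmax_possible + 1 (first not ok)
    lo <- j; hi <- min(j0, jmax_possible + 1)
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (ok(i, mid)) lo <- mid else hi <- mid
    }
    if (is.null(best) || (lo - i) > (best[2] - best[1]))
      best <- c(i, lo)
  }
  best
}

make_segment <- function(x, v, Tv, span, kind, cfg) {
  i <- span[1]; j <- span[2]
  cl <- classify_span(x[i:j], v[i:j], cfg)
  if (is.null(cl) || kind == "intermediate") {
    # report the better of the two fits for diagnostics
    lf <- polyfit_span(x[i:j], v[i:j], 1)
    pf <- if (length(unique(x[i:j])) >= 3) polyfit_span(x[i:j], v[i:j], 2)
          else lf
    cl <- if (pf$r2 > lf$r2 && length(pf$coef) == 3)
      list(kind = "intermediate", fit = pf, degree = 2)
    else list(kind = "intermediate", fit = lf, degree = 1)
    cl$kind <- "intermediate"
  }
  coeffs <- if (cl$degree == 2) {
    c(a2 = unname(cl$fit$coef[3]), a1 = unname(cl$fit$coef[2]),
      a0 = unname(cl$fit$coef[1]))
  } else {
    c(slope = unname(cl$fit$coef[2]), intercept = unname(cl$fit$coef[1]))
  }
  list(kind = if (kind == "intermediate") "intermediate" else cl$kind,
       span = c(i, j),
       T_range = c(Tv[i], Tv[j]),
       x_range = range(x[i:j]),
       coeffs = coeffs, r2 = cl$fit$r2, rmse = cl$fit$rmse,
       n = j - i + 1)
}

coeffs_compatible <- function(a, b, tol) {
  if (length(a$coeffs) != length(b$coeffs)) return(FALSE)
  scale <- pmax(abs(a$coeffs), abs(b$coeffs))
  all(abs(a$coeffs - b$coeffs) <= tol * pmax(scale, 1e-12))
}

#' Segment a phase portrait into classified fragments
#'
#' Splits the portrait (points ordered by temperature) into contiguous
#' fragments classified `parabolic` (abrupt sigmoid-like stage), `linear`
#' (smooth exponential-saturation stage) or `intermediate` (transition
#' regions between stages).  Fragments are found by greedy maximal-span
#' classification: repeatedly, the longest contiguous run of unassigned
#' points that a concave parabola or a straight line fits (own-fit
#' R-squared above `r2_threshold`, or residuals explained by the portrait's
#' estimated measurement noise) is assigned that kind, until no
#' classifiable run of at least `min_stage_fraction` of the portrait
#' remains; leftover gaps become intermediate fragments.  This mirrors how
#' portrait fragments are read off a plot — stages are the large coherent
#' pieces, and the short ambiguous joins between them are transition
#' regions — while remaining deterministic and scale-free.
#'
#' @param p a `phase_portrait` of length >= 2 * `min_segment_length`.
#' @param cfg a [segment_config()].
#' @return An object of class `portrait_segments`: a list of segments (each
#'   with `kind`, `span`, `T_range`, `x_range`, `coeffs`, `r2`, `rmse`),
#'   ordered by temperature and jointly covering the portrait without
#'   overlap.
#' @export
segment_portrait <- function(p, cfg = segment_config()) {
  stopifnot(inherits(p, "phase_portrait"), inherits(cfg, "segment_config"))
  x <- p$x; v <- p$v; Tv <- p$temperature
  n <- length(x)
  if (n < 2 * cfg$min_segment_length)
    stopf("portrait too short to segment: %d points (< %d)",
          n, 2 * cfg$min_segment_length)
  min_len <- max(cfg$min_segment_length,
                 as.integer(ceiling(cfg$min_stage_fraction * n)))

  assigned <- list()   # list of c(i, j, kind-code)
  gaps <- list(c(1L, n))
  repeat {
    best <- NULL; best_gap <- NULL
    for (g in seq_along(gaps)) {
      sp <- longest_classifiable(x, v, gaps[[g]][1], gaps[[g]][2],
                                 min_len, cfg)
      if (!is.null(sp) &&
          (is.null(best) || (sp[2] - sp[1]) > (best[2] - best[1]))) {
        best <- sp; best_gap <- g
      }
    }
    if (is.null(best)) break
    cl <- classify_span(x[best[1]:best[2]], v[best[1]:best[2]], cfg)
    assigned[[length(assigned) + 1]] <- list(span = best, kind = cl$kind)
    g <- gaps[[best_gap]]
    gaps[[best_gap]] <- NULL
    if (best[1] > g[1]) gaps[[length(gaps) + 1]] <- c(g[1], best[1] - 1L)
    if (best[2] < g[2]) gaps[[length(gaps) + 1]] <- c(best[2] + 1L, g[2])
  }
  for (g in gaps)
    assigned[[length(assigned) + 1]] <- list(span = g, kind = "intermediate")
  ord <- order(vapply(assigned, function(a) a$span[1], numeric(1)))
  assigned <- assigned[ord]

  segs <- lapply(assigned, function(a)
    make_segment(x, v, Tv, a$span, a$kind, cfg))

  # post-pass: merge directly adjacent same-kind fragments with compatible
  # coefficients, and coalesce adjacent intermediates
  repeat {
    changed <- FALSE
    if (length(segs) >= 2) {
      for (k in seq_len(length(segs) - 1)) {
        a <- segs[[k]]; b <- segs[[k + 1]]
        mergeable <- (a$kind == b$kind) &&
          (a$kind == "intermediate" ||
             coeffs_compatible(a, b, cfg$merge_tolerance))
        if (mergeable) {
          segs[[k]] <- make_segment(x, v, Tv, c(a$span[1], b$span[2]),
                                    a$kind, cfg)
          segs[[k]]$kind <- a$kind
          segs[[k + 1]] <- NULL
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  # short classified fragments are buffers, not stages
  for (k in seq_along(segs)) {
    if (segs[[k]]$kind != "intermediate" &&
        segs[[k]]$n < cfg$min_segment_length)
      segs[[k]]$kind <- "intermediate"
  }
  structure(segs, class = "portrait_segments", portrait = p, config = cfg)
}

#' Count the phase-transition stages of a segmented portrait
#'
#' Each parabolic or linear portrait fragment corresponds to one stage of
#' the phase transition; intermediate (transition-region) fragments are not
#' stages and are excluded.
#'
#' @param segments a [segment_portrait()] result, or any list of segments
#'   with a `kind` field.
#' @return Non-negative integer stage count.
#' @export
count_stages <- function(segments) {
  if (length(segments) == 0) return(0L)
  kinds <- vapply(segments, function(s) s$kind, character(1))
  sum(kinds %in% c("parabolic", "linear"))
}

#' @export
print.portrait_segments <- function(x, ...) {
  cat(sprintf("<portrait_segments> %d fragment(s), stage count %d\n",
              length(x), count_stages(x)))
  for (s in x) {
    cat(sprintf("  %-12s T in [%g, %g], x in [%.4g, %.4g], n = %d, R2 = %.4f\n",
                s$kind, s$T_range[1], s$T_range[2],
                s$x_range[1], s$x_range[2], s$n, s$r2))
  }
  invisible(x)
}

#' @export
as.data.frame.portrait_segments <- function(x, ...) {
  data.frame(kind = vapply(x, `[[`, character(1), "kind"),
             from = vapply(x, function(s) s$span[1], numeric(1)),
             to = vapply(x, function(s) s$span[2], numeric(1)),
             T_lo = vapply(x, function(s) s$T_range[1], numeric(1)),
             T_hi = vapply(x, function(s) s$T_range[2], numeric(1)),
             r2 = vapply(x, `[[`, numeric(1), "r2"))
}

#' JSON segmentation report
#'
#' Per-fragment kind, temperature range, state range, fit coefficients and
#' quality, with the stage count at top level.
#'
#' @param segments a [segment_portrait()] result.
#' @param path optional output path; when given the JSON is written there.
#' @return The report as a JSON string (invisibly when `path` is given).
#' @export
segmentation_report <- function(segments, path = NULL) {
  rep <- list(
    stage_count = count_stages(segments),
    segments = lapply(segments, function(s) {
      list(kind = s$kind, T_range = s$T_range, x_range = s$x_range,
           coefficients = as.list(s$coeffs), r2 = s$r2, rmse = s$rmse,
           n_points = s$n)
    }))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
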