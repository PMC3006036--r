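#' Circular mean and resultant length
#'
#' `mean = atan2(sum sin, sum cos)` and `Rbar = |sum exp(i theta)| / n`.
#' `Rbar` is 1 for perfectly concentrated angles and 0 for antipodally
#' balanced or uniform data; when `Rbar` is numerically 0 the mean
#' direction is undefined and reported as NA.
#'
#' @param angles Numeric vector of angles in degrees (nonempty).
#' @return An object of class `circular_stats`: a one-row tibble with `n`,
#'   `mean_deg` (in [0, 360)) and `Rbar`.
#' @export
circular_mean <- function(angles) {
  if (!length(angles) || !is.numeric(angles)) {
    stop("angles must be a nonempty numeric vector", call. = FALSE)
  }
  rad <- angles * pi / 180
  s <- sum(sin(rad)); c <- sum(cos(rad))
  rbar <- sqrt(s^2 + c^2) / length(angles)
  mean_deg <- if (rbar < 1e-12) NA_real_ else (atan2(s, c) * 180 / pi) %% 360
  out <- tibble::tibble(n = length(angles), mean_deg = mean_deg, Rbar = rbar)
  class(out) <- c("circular_stats", class(out))
  out
}

#' Split an angular sample into two modes
#'
#' Exhaustively searches thresholds midway between consecutive sorted
#' values and picks the split maximizing the count-weighted sum of the two
#' subsets' resultant lengths, `n1 * Rbar1 + n2 * Rbar2`. Used for Z-DNA,
#' whose backbone distributions are bimodal (dinucleotide repeat). When the
#' best split improves on the unsplit objective (`n * Rbar`) by less than
#' `min_gain` the data are flagged unimodal.
#'
#' @param angles Numeric vector of angles in degrees, `n >= 4`.
#' @param min_gain Relative improvement over no split required to call the
#'   sample bimodal (default 0.01).
#' @return A list with `threshold`, the two [circular_mean()] summaries
#'   (`stats1` for values below the threshold), the achieved `objective`,
#'   and `bimodal` (logical).
#' @export
split_bimodal <- function(angles, min_gain = 0.01) {
  if (length(angles) < 4) stop("need at least 4 angles", call. = FALSE)
  xs <- sort(angles)
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  cuts <- unique(cuts[xs[-1] > xs[-length(xs)]])
  base_obj <- length(angles) * circular_mean(angles)$Rbar
  best <- NULL
  for (thr in cuts) {
    lo <- angles[angles <= thr]; hi <- angles[angles > thr]
    if (!length(lo) || !length(hi)) next
    obj <- length(lo) * circular_mean(lo)$Rbar +
           length(hi) * circular_mean(hi)$Rbar
    if (is.null(best) || obj > best$objective) {
      best <- list(threshold = thr, objective = obj)
    }
  }
  if (is.null(best)) {
    return(list(threshold = NA_real_, stats1 = circular_mean(angles),
                stats2 = NULL, objective = base_obj, bimodal = FALSE))
  }
  lo <- angles[angles <= best$threshold]
  hi <- angles[angles > best$threshold]
  list(threshold = best$threshold,
       stats1 = circular_mean(lo),
       stats2 = circular_mean(hi),
       objective = best$objective,
       bimodal = (best$objective - base_obj) / base_obj >= min_gain)
}

#' Fit one or two Gaussian components to histogram data
#'
#' Nonlinear least squares of `a * exp(-(x - mu)^2 / (2 sigma^2))` (or the
#' sum of two such components) to histogram counts, by
#' Levenberg-Marquardt. Initial values come from the histogram moments; for
#' two components the histogram is first split at its antimode (the
#' lowest-count bin between the two dominant peaks) and each side
#' initialises one component.
#'
#' @param centres Bin centres (ascending).
#' @param counts Bin counts (same length).
#' @param n_components 1 or 2.
#' @return An object of class `gaussian_fit` with a `components` tibble
#'   (`a`, `mu`, `sigma`, sorted by `mu`), `rss`, `converged`, and the data.
#' @export
fit_gaussians <- function(centres, counts, n_components = 1) {
  stopifnot(length(centres) == length(counts), n_components %in% 1:2)
  pop <- counts > 0
  if (sum(pop) < ifelse(n_components == 2, 8, 5)) {
    stop("too few populated bins for a ", n_components, "-component fit",
         call. = FALSE)
  }
  df <- data.frame(x = centres, y = counts)
  mom <- function(x, w) {
    mu <- sum(x * w) / sum(w)
    sd <- sqrt(sum(w * (x - mu)^2) / sum(w))
    c(mu = mu, sd = max(sd, diff(range(x)) / length(x)))
  }
  if (n_components == 1) {
    m <- mom(centres, counts)
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)), data = df,
      start = list(a = max(counts), mu = unname(m["mu"]),
                   sigma = unname(m["sd"])),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    comp <- tibble::tibble(a = unname(cf["a"]), mu = unname(cf["mu"]),
                           sigma = abs(unname(cf["sigma"])))
  } else {
    cut <- histogram_antimode(centres, counts)
    left <- centres <= cut
    m1 <- mom(centres[left], pmax(counts[left], 1e-9))
    m2 <- mom(centres[!left], pmax(counts[!left], 1e-9))
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - mu1)^2 / (2 * s1^2)) +
          a2 * exp(-(x - mu2)^2 / (2 * s2^2)), data = df,
      start = list(a1 = max(counts[left]), mu1 = unname(m1["mu"]),
                   s1 = unname(m1["sd"]), a2 = max(counts[!left]),
                   mu2 = unname(m2["mu"]), s2 = unname(m2["sd"])),
      control = minpack.lm::nls.lm.control(maxiter = 400))
    cf <- stats::coef(fit)
    comp <- tibble::tibble(a = unname(c(cf["a1"], cf["a2"])),
                           mu = unname(c(cf["mu1"], cf["mu2"])),
                           sigma = abs(unname(c(cf["s1"], cf["s2"]))))
    comp <- comp[order(comp$mu), ]
  }
  conv <- fit$convInfo$isConv %||% TRUE
  if (!isTRUE(conv)) {
    stop("Gaussian fit failed to converge (", fit$convInfo$stopMessage, ")",
         call. = FALSE)
  }
  structure(list(components = comp,
                 rss = sum(stats::resid(fit)^2),
                 converged = TRUE,
                 data = tibble::as_tibble(df),
                 fitted = stats::fitted(fit)),
            class = "gaussian_fit")
}

# lowest-count bin strictly between the two strongest separated peaks
histogram_antimode <- function(centres, counts) {
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  n <- length(sm)
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  if (length(peaks) >= 2) {
    top <- peaks[order(-sm[peaks])][1:2]
    rng <- sort(top)
  } else {
    rng <- c(1, n)
  }
  inner <- seq(rng[1], rng[2])
  centres[inner[which.min(sm[inner])]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %d component(s), rss = %.4g\n",
              nrow(x$components), x$rss))
  print(as.data.frame(x$components), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  out <- x$components
  out$component <- seq_len(nrow(out))
  out[, c("component", "a", "mu", "sigma")]
}

#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$components), rss = x$rss,
                 n_bins = nrow(x$data), converged = x$converged)
}

#' @method autoplot gaussian_fit
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$y), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "bin centre", y = "count")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
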