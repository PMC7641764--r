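# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @export
tidy.fe_profile <- function(x, ...) {
  tibble(n_bp = x$n_bp, G = x$G, se = x$se)
}

#' @export
glance.fe_profile <- function(x, ...) {
  tibble(temperature = attr(x, "temperature"), n_states = nrow(x),
         dG0 = delta_G0(x), reference = attr(x, "reference"))
}

#' @export
autoplot.fe_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$n_bp, y = .data$G)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_errorbar(aes(ymin = .data$G - .data$se, ymax = .data$G + .data$se),
                  width = 0.15) +
    labs(x = "native base pairs formed",
         y = expression(G ~ "(" * k[B] * T * ")"),
         title = sprintf("Free-energy profile at %.0f K",
                         attr(object, "temperature"))) +
    theme_bw()
}

#' @export
tidy.melting_curve <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.melting_curve <- function(x, ...) {
  tm <- tryCatch(melting_temperature(x), crowdna_no_bracket = function(e) {
    tibble(tm = NA_real_, tm_se = NA_real_)
  })
  mutate(tm, kind = attr(x, "kind"))
}

#' @export
autoplot.melting_curve <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$temperature)) +
    geom_line(aes(y = .data$yield_bulk)) +
    geom_point(aes(y = .data$yield_bulk)) +
    geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    labs(x = "temperature (K)", y = "bound yield",
         title = sprintf("Melting curve (%s)", attr(object, "kind"))) +
    theme_bw()
}

#' @export
tidy.vant_hoff_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("dS", "dH"),
         estimate = c(x$dS, x$dH),
         se = c(s[1, 2] / 300, s[2, 2] / 300),
         unit = c("kB T0 / K", "kB T0"))
}

#' @export
glance.vant_hoff_fit <- function(x, ...) {
  tibble(dH = x$dH, dS = x$dS, residual_rms = x$residual_rms,
         r_squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' @export
autoplot.vant_hoff_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("lnK", "invT")
  ggplot(d, aes(x = .data$invT, y = .data$lnK)) +
    geom_point() +
    geom_line(aes(y = stats::fitted(object$fit)), colour = "grey40") +
    labs(x = "1 / T (1/K)", y = "ln K",
         title = sprintf("van't Hoff fit: dH = %.3g kBT0, dS = %.3g kBT0/K",
                         object$dH, object$dS)) +
    theme_bw()
}

#' @export
tidy.ffs_result <- function(x, ...) x$stages

#' @export
glance.ffs_result <- function(x, ...) {
  tibble(kind = x$kind, flux = x$flux$flux,
         n_crossings = x$flux$n_crossings, k = x$k, k_se = x$k_se,
         n_stages = nrow(x$stages), incomplete = x$incomplete)
}

#' @export
autoplot.ffs_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = factor(.data$to), y = .data$p)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.1) +
    labs(x = "interface reached", y = "transition probability",
         title = sprintf("FFS stages (%s): k = %.3g /ps", object$kind, object$k)) +
    theme_bw()
}

#' @export
tidy.spt_fit <- function(x, ...) x$parameters

#' @export
glance.spt_fit <- function(x, ...) {
  tibble(kind = x$kind, rss = x$rss, n = nrow(x$data),
         rms = sqrt(x$rss / nrow(x$data)), converged = x$converged)
}

#' @export
autoplot.spt_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot(d, aes(x = .data$r_c)) +
    geom_point(aes(y = .data$ddg)) +
    geom_line(aes(y = .data$fitted), colour = "grey40") +
    facet_wrap(~phi, labeller = "label_both") +
    labs(x = expression(r[c] ~ "(nm)"),
         y = expression(Delta * Delta * G ~ "(" * k[B] * T * ")"),
         title = "SPT fit of crowding-induced stabilisation") +
    theme_bw()
}
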