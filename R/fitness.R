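#' Maximum growth rate by the sliding 5-point log-linear rule
#'
#' Over all windows of `window` consecutive readings with OD strictly above
#' the blank (readings at or below blank are dropped before windows are
#' formed), fits ordinary least squares of `ln(OD - blank)` on time and
#' returns the largest slope among windows whose R-squared strictly exceeds
#' `r2_min`. Ties go to the earliest window.
#'
#' With noisy readings, taking the maximum over many windows is upward
#' biased when near-blank points enter the log: set `min_signal` to the
#' instrument's effective noise floor (about ten times the reader
#' repeatability) so that only readings with `od - blank > min_signal` form
#' windows. The default 0 keeps the strict `OD > blank` rule, appropriate
#' for clean or averaged curves.
#'
#' @param curve Data frame with columns `time` (hours, strictly increasing)
#'   and `od`.
#' @param blank OD of sterile medium subtracted before the log (default 0).
#' @param window Number of consecutive readings per fit (default 5).
#' @param r2_min R-squared a window must strictly exceed (default 0.9).
#' @param min_signal Background-subtracted OD a reading must strictly
#'   exceed to enter a window (default 0).
#' @return One-row tibble: `rate` (per hour; `NA` when no window
#'   qualifies), `r_squared`, `t_start`, `t_end`, `n_windows_tested`,
#'   `estimate_available`.
#' @examples
#' t <- seq(0, 4, by = 1/6)
#' max_growth_rate(tibble::tibble(time = t, od = 0.1 + 0.01 * exp(0.5 * t)),
#'                 blank = 0.1)
#' @export
max_growth_rate <- function(curve, blank = 0, window = 5, r2_min = 0.9,
                            min_signal = 0) {
  stopifnot(all(c("time", "od") %in% names(curve)), window >= 3,
            min_signal >= 0)
  if (is.unsorted(curve$time, strictly = TRUE)) {
    abort("`time` must be strictly increasing.")
  }
  keep <- curve$od - blank > min_signal & curve$od > blank
  tt <- curve$time[keep]
  yy <- log(curve$od[keep] - blank)
  no_est <- tibble(rate = NA_real_, r_squared = NA_real_,
                   t_start = NA_real_, t_end = NA_real_,
                   n_windows_tested = 0L, estimate_available = FALSE)
  if (length(tt) < window) return(no_est)
  n_win <- length(tt) - window + 1
  best <- NULL
  for (i in seq_len(n_win)) {
    idx <- i:(i + window - 1)
    x <- tt[idx]; y <- yy[idx]
    fit <- lm(y ~ x)
    slope <- coef(fit)[[2]]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    if (r2 > r2_min && (is.null(best) || slope > best$rate)) {
      best <- tibble(rate = slope, r_squared = r2,
                     t_start = x[1], t_end = x[window],
                     n_windows_tested = n_win, estimate_available = TRUE)
    }
  }
  if (is.null(best)) {
    no_est$n_windows_tested <- n_win
    return(no_est)
  }
  best
}

#' Carrying capacity as the maximum background-subtracted OD
#'
#' @param curve Data frame with column `od`.
#' @param blank Blank OD (default 0).
#' @return Maximum of `od - blank`, floored at 0.
#' @export
carrying_capacity <- function(curve, blank = 0) {
  stopifnot("od" %in% names(curve), nrow(curve) >= 1)
  max(max(curve$od - blank), 0)
}

#' Growth metrics relative to the matched ancestor
#'
#' Divides each evolved clone's maximum growth rate and carrying capacity by
#' the mean of its matched ancestor clone (matched by fluorescent label).
#'
#' @param evolved Data frame with columns `label` and one or more metric
#'   columns (e.g. `mu`, `k`).
#' @param ancestor Data frame with the same columns for ancestor replicate
#'   measurements.
#' @param metrics Metric column names to normalize (default: the shared
#'   numeric columns other than `label`).
#' @return `evolved` with each metric column replaced by its ratio to the
#'   per-label ancestor mean (columns suffixed `_rel`).
#' @export
relative_metrics <- function(evolved, ancestor,
                             metrics = setdiff(intersect(names(evolved),
                                                         names(ancestor)),
                                               "label")) {
  stopifnot("label" %in% names(evolved), "label" %in% names(ancestor),
            length(metrics) >= 1)
  anc_means <- ancestor %>%
    group_by(.data$label) %>%
    summarise(across(all_of(metrics), ~ mean(.x)), .groups = "drop")
  if (any(unlist(anc_means[metrics]) <= 0)) {
    abort("Ancestor means must be positive to form ratios.")
  }
  missing_labels <- setdiff(unique(evolved$label), anc_means$label)
  if (length(missing_labels)) {
    abort(paste("No ancestor measurements for label(s):",
                paste(missing_labels, collapse = ", ")))
  }
  out <- evolved %>%
    left_join(anc_means, by = "label", suffix = c("", "_anc"))
  for (m in metrics) {
    out[[paste0(m, "_rel")]] <- out[[m]] / out[[paste0(m, "_anc")]]
  }
  out %>% select(-all_of(paste0(metrics, "_anc")))
}

#' Selection coefficient from an in vivo competition series
#'
#' Fits, per mouse, ordinary least squares of the log competitive index
#' `ln(cfu_focal / cfu_reference)` on day; the slope is the per-day
#' selection coefficient of the focal clone. The pooled estimate is the
#' mean of per-mouse slopes, its SE the SD over sqrt(n mice), and the
#' per-generation value divides by `gens_per_day`. Days where either count
#' is zero are dropped with a warning; a mouse with fewer than two usable
#' days gets no estimate.
#'
#' @param series Data frame with columns `mouse_id`, `day`, `cfu_focal`,
#'   `cfu_reference`.
#' @param gens_per_day Generations per day for the conversion (default 18).
#' @return Object of class `"selection_fit"`; [tidy()] gives per-mouse
#'   slopes and SEs, [glance()] the pooled per-day and per-generation
#'   estimates (the latter also rounded to two decimals as conventionally
#'   reported).
#' @examples
#' s <- tidyr::expand_grid(mouse_id = 1:4, day = 0:4)
#' s$cfu_reference <- 1e6
#' s$cfu_focal <- 1e6 * exp(4 * s$day)
#' glance(selection_coefficient(s))
#' @export
selection_coefficient <- function(series, gens_per_day = 18) {
  need <- c("mouse_id", "day", "cfu_focal", "cfu_reference")
  stopifnot(all(need %in% names(series)), gens_per_day > 0)
  usable <- series$cfu_focal > 0 & series$cfu_reference > 0
  if (any(!usable)) {
    warn(sprintf("%d day(s) with a zero CFU count dropped from the competitive index.",
                 sum(!usable)))
  }
  ser <- series[usable, , drop = FALSE]
  per_mouse <- ser %>%
    mutate(log_ci = log(.data$cfu_focal / .data$cfu_reference)) %>%
    group_by(.data$mouse_id) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble(slope = NA_real_, se = NA_real_, n_days = nrow(df)))
      }
      fit <- lm(log_ci ~ day, data = df)
      nd <- nrow(df)
      sxx <- sum((df$day - mean(df$day))^2)
      se <- if (nd > 2) {
        sqrt(sum(fit$residuals^2) / (nd - 2) / sxx)
      } else {
        NA_real_
      }
      tibble(slope = coef(fit)[[2]], se = se, n_days = nd)
    }) %>%
    ungroup()
  structure(list(per_mouse = per_mouse, gens_per_day = gens_per_day),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  g <- glance(x)
  cat("<selection_fit>", g$n_mice, "mice; s =", signif(g$s_per_day, 3),
      "per day (SE", signif(g$se_per_day, 2), ") =",
      g$s_per_generation_rounded, "per generation\n")
  invisible(x)
}

#' Per-mouse competitive-index slopes
#' @param x A `"selection_fit"`.
#' @param ... Unused.
#' @return Tibble with `mouse_id`, `slope` (per day), `se`, `n_days`.
#' @exportS3Method generics::tidy
tidy.selection_fit <- function(x, ...) x$per_mouse

#' Pooled selection-coefficient estimate
#' @param x A `"selection_fit"`.
#' @param ... Unused.
#' @return One-row tibble: `s_per_day`, `se_per_day`, `s_per_generation`,
#'   `s_per_generation_rounded` (two decimals), `n_mice`, `gens_per_day`.
#' @exportS3Method generics::glance
glance.selection_fit <- function(x, ...) {
  sl <- x$per_mouse$slope[!is.na(x$per_mouse$slope)]
  n <- length(sl)
  if (n == 0) abort("No mouse has enough usable days for an estimate.")
  s_day <- mean(sl)
  tibble(s_per_day = s_day,
         se_per_day = if (n > 1) sd(sl) / sqrt(n) else NA_real_,
         s_per_generation = s_day / x$gens_per_day,
         s_per_generation_rounded = round_half_away(s_day / x$gens_per_day, 2),
         n_mice = n,
         gens_per_day = x$gens_per_day)
}

#' Plot log competitive index over time with per-mouse fits
#'
#' @param series Competition data frame (see [selection_coefficient()]).
#' @return A ggplot object.
#' @export
plot_competitive_index <- function(series) {
  df <- series %>%
    filter(.data$cfu_focal > 0, .data$cfu_reference > 0) %>%
    mutate(log_ci = log(.data$cfu_focal / .data$cfu_reference),
           mouse = factor(.data$mouse_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$log_ci,
                                   colour = .data$mouse)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
    ggplot2::labs(x = "Day", y = "ln(focal / reference)", colour = "Mouse")
}
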