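#' Map fluorescent markers to strains
#'
#' CFP and YFP label strain A; mCherry and sfGFP label strain B1.
#'
#' @param marker Character vector of marker names.
#' @return Character vector `"A"`/`"B1"`.
#' @export
marker_strain <- function(marker) {
  map <- c(CFP = "A", YFP = "A", mCherry = "B1", sfGFP = "B1")
  out <- unname(map[marker])
  if (anyNA(out)) abort("Unknown marker name(s); expected CFP, YFP, mCherry, sfGFP.")
  out
}

check_trajectory <- function(traj) {
  need <- c("mouse_id", "day", "marker", "cfu_per_g")
  miss <- setdiff(need, names(traj))
  if (length(miss)) abort(paste("Trajectory table lacks columns:",
                                paste(miss, collapse = ", ")))
  if (any(traj$cfu_per_g < 0)) abort("CFU values must be >= 0.")
  if (any(traj$day < 0)) abort("Days must be >= 0.")
  invisible(traj)
}

#' Within-strain marker frequencies from CFU counts
#'
#' For each (mouse, day, strain) the two marker frequencies are
#' `cfu_i / (cfu_1 + cfu_2)`. A zero CFU count is censored at the plating
#' detection limit: it is flagged `below_lod` and its frequency reported as
#' the upper bound `LOD / (LOD + cfu_other)`; the companion marker's
#' frequency is its uncensored value. If both markers are zero the strain is
#' flagged absent that day and no frequency is reported.
#'
#' @param traj Data frame with columns `mouse_id`, `day`, `marker`
#'   (CFP/YFP/mCherry/sfGFP), `cfu_per_g`.
#' @param detection_limit Plating detection limit in CFU/g (default 300).
#' @return Tibble with one row per (mouse, day, strain, marker):
#'   `cfu_per_g`, `frequency`, `below_lod`, `strain_absent`.
#' @examples
#' traj <- tibble::tibble(mouse_id = 1, day = c(1, 1),
#'   marker = c("CFP", "YFP"), cfu_per_g = c(0, 1e6))
#' within_strain_frequencies(traj)
#' @export
within_strain_frequencies <- function(traj, detection_limit = 300) {
  check_trajectory(traj)
  stopifnot(detection_limit > 0)
  traj %>%
    mutate(strain = marker_strain(.data$marker)) %>%
    group_by(.data$mouse_id, .data$day, .data$strain) %>%
    mutate(
      n_markers = n(),
      total = sum(.data$cfu_per_g),
      other = .data$total - .data$cfu_per_g,
      strain_absent = .data$total == 0,
      below_lod = .data$cfu_per_g == 0 & !.data$strain_absent,
      frequency = case_when(
        strain_absent ~ NA_real_,
        below_lod ~ detection_limit / (detection_limit + other),
        TRUE ~ cfu_per_g / total
      )
    ) %>%
    ungroup() %>%
    {
      if (any(.$n_markers != 2)) {
        abort("Each (mouse, day, strain) must have exactly its two markers measured.")
      }
      .
    } %>%
    select("mouse_id", "day", "strain", "marker", "cfu_per_g", "frequency",
           "below_lod", "strain_absent")
}

#' Classify marker-polymorphism maintenance per mouse and strain
#'
#' A strain has "lost" its marker polymorphism when exactly one of its two
#' markers is below the detection limit on each of the last `k` sampled
#' days; the surviving marker is reported as fixed. A strain is
#' "strain_not_colonized" when it is absent (both markers below LOD) on
#' every sampled day from `not_colonized_day` onward. Otherwise the
#' polymorphism is "maintained".
#'
#' @param traj Marker trajectory data frame (see
#'   [within_strain_frequencies()]).
#' @param k Number of final sampled days the loss must persist (default 2).
#' @param detection_limit CFU/g detection limit (default 300); a count below
#'   it is treated as unobserved.
#' @param not_colonized_day First day from which sustained absence counts as
#'   colonization failure (default 7).
#' @return Tibble with one row per (mouse, strain): `status`
#'   (`maintained`/`lost`/`strain_not_colonized`), `day_of_loss` (first of
#'   the final run of below-LOD days for the lost marker), `fixed_marker`.
#' @export
classify_polymorphism <- function(traj, k = 2, detection_limit = 300,
                                  not_colonized_day = 7) {
  check_trajectory(traj)
  wide <- traj %>%
    mutate(strain = marker_strain(.data$marker),
           detected = .data$cfu_per_g >= detection_limit)
  wide %>%
    group_by(.data$mouse_id, .data$strain) %>%
    dplyr::group_modify(function(df, key) {
      days <- sort(unique(df$day))
      if (length(days) < k) {
        abort(sprintf("Need at least k = %d sampled days per (mouse, strain).", k))
      }
      markers <- sort(unique(df$marker))
      det <- function(m, d) {
        any(df$detected[df$marker == m & df$day == d])
      }
      strain_present_by_day <- vapply(
        days, function(d) any(df$detected[df$day == d]), logical(1))
      late <- days >= not_colonized_day
      if (any(late) && !any(strain_present_by_day[late])) {
        return(tibble(status = "strain_not_colonized",
                      day_of_loss = NA_real_, fixed_marker = NA_character_))
      }
      last_k <- tail(days, k)
      below_last_k <- vapply(markers, function(m) {
        all(!vapply(last_k, function(d) det(m, d), logical(1)))
      }, logical(1))
      if (sum(below_last_k) == 1) {
        lost_marker <- markers[below_last_k]
        # day_of_loss: first day of the terminal run of below-LOD samples
        seen <- vapply(days, function(d) det(lost_marker, d), logical(1))
        run_start <- if (all(!seen)) days[1] else {
          last_seen <- max(which(seen))
          if (last_seen == length(days)) NA_real_ else days[last_seen + 1]
        }
        return(tibble(status = "lost", day_of_loss = run_start,
                      fixed_marker = markers[!below_last_k]))
      }
      tibble(status = "maintained", day_of_loss = NA_real_,
             fixed_marker = NA_character_)
    }) %>%
    ungroup()
}

#' Test whether polymorphism maintenance is strain dependent
#'
#' Exact test of equal maintenance proportions between the two strains,
#' built as a Fisher exact test on the 2x2 maintained/lost table.
#' Uncolonized strains (`strain_not_colonized`) are excluded.
#'
#' @param calls_A,calls_B1 Polymorphism-call tibbles for strain A and B1
#'   (output of [classify_polymorphism()] split by strain, or any data frame
#'   with a `status` column).
#' @return A single two-sided p-value.
#' @examples
#' a <- tibble::tibble(status = rep("lost", 8))
#' b <- tibble::tibble(status = rep("maintained", 8))
#' polymorphism_proportion_test(a, b) # 1 / choose(16, 8)
#' @export
polymorphism_proportion_test <- function(calls_A, calls_B1) {
  tab <- function(calls) {
    if (!nrow(calls)) abort("Empty call table.")
    st <- calls$status[calls$status != "strain_not_colonized"]
    c(maintained = sum(st == "maintained"), lost = sum(st == "lost"))
  }
  ta <- tab(calls_A); tb <- tab(calls_B1)
  fisher_exact_2x2(ta[1], ta[2], tb[1], tb[2])
}

#' Mean log10 bacterial load of a strain under coexistence
#'
#' Computes, over days where both strains are detected (>= LOD), the
#' per-mouse time-averaged log10 total CFU/g of the requested strain, then
#' the mean across mice with its standard error.
#'
#' @param traj Marker trajectory data frame.
#' @param strain `"A"` or `"B1"`.
#' @param detection_limit CFU/g detection limit (default 300).
#' @return One-row tibble: `strain`, `mean_log10_load`, `se`, `n_mice`.
#' @export
mean_log10_load <- function(traj, strain, detection_limit = 300) {
  check_trajectory(traj)
  stopifnot(strain %in% c("A", "B1"))
  loads <- traj %>%
    mutate(strain_ = marker_strain(.data$marker)) %>%
    group_by(.data$mouse_id, .data$day, .data$strain_) %>%
    summarise(total = sum(.data$cfu_per_g), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "strain_", values_from = "total") %>%
    filter(.data$A >= detection_limit, .data$B1 >= detection_limit)
  if (!nrow(loads)) abort("No days with both strains above the detection limit.")
  per_mouse <- loads %>%
    group_by(.data$mouse_id) %>%
    summarise(mean_log10 = mean(log10(.data[[strain]])), .groups = "drop")
  n <- nrow(per_mouse)
  tibble(strain = strain,
         mean_log10_load = mean(per_mouse$mean_log10),
         se = if (n > 1) sd(per_mouse$mean_log10) / sqrt(n) else NA_real_,
         n_mice = n)
}

#' Plot CFU trajectories of the four fluorescent markers
#'
#' @param traj Marker trajectory data frame.
#' @param detection_limit Plotted as a dashed horizontal line (default 300).
#' @return A ggplot object, log10 CFU/g over time faceted by mouse.
#' @export
plot_marker_trajectories <- function(traj, detection_limit = 300) {
  check_trajectory(traj)
  df <- traj %>%
    mutate(strain = marker_strain(.data$marker),
           cfu_plot = pmax(.data$cfu_per_g, detection_limit / 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$cfu_plot,
                                   colour = .data$marker,
                                   linetype = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = detection_limit, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$mouse_id)) +
    ggplot2::labs(x = "Day", y = "CFU/g feces", colour = "Marker",
                  linetype = "Strain")
}
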