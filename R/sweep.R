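# Two-sided p-values for every possible cell `a` given fixed margins:
# support of a is max(0, c1 - r2) .. min(r1, c1); the two-sided p for an
# observed a sums hypergeometric probabilities of all tables at least as
# extreme (probability <= that of the observed table, with a small relative
# slack for floating-point ties).
fisher_p_by_a <- function(r1, r2, c1) {
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  a_vals <- lo:hi
  d <- dhyper(a_vals, r1, r2, c1)
  p <- vapply(seq_along(a_vals), function(i) {
    cut <- d[i] * (1 + 1e-7) + 1e-12
    min(1, sum(d[d <= cut]))
  }, numeric(1))
  setNames(p, a_vals)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test used to compare the proportion of simulation
#' replicates compatible with the experimental outcome against the observed
#' proportion of mice, and to compare marker-polymorphism maintenance between
#' strains. The two-sided p-value sums the probabilities of all tables with
#' the same margins whose probability does not exceed that of the observed
#' table.
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]` (rows are the
#'   two groups, columns the two outcomes). All must be >= 0 and at least one
#'   margin positive; an all-zero table returns 1 by convention.
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(8, 0, 0, 10) # 1 / choose(18, 8)
#' fisher_exact_2x2(4, 4, 5, 5)  # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("All cell counts must be >= 0.")
  if (a + b + c + d == 0) return(1)
  p <- fisher_p_by_a(a + b, c + d, a + c)
  unname(p[as.character(a)])
}

#' Specify a (u, mean_s, DFE shape) sweep grid
#'
#' Explores the compatibility of the directional-selection model with the
#' experimentally observed marker pattern over log-spaced grids of mutation
#' rate and mean selective effect, for several DFE shapes. The experimental
#' reference outcome is 8 of 8 co-colonized mice showing the pattern (strain
#' A fixed one marker, strain B1 kept both).
#'
#' @param u_values Mutation rates (defaults: 5 log-spaced values in
#'   `[1e-8, 1e-4]`).
#' @param s_values Mean selective advantages (defaults: 4 log-spaced values
#'   in `[1e-4, 1e-1]`).
#' @param dfe_shapes Character/numeric vector from `"fixed"`, `100`, `10`,
#'   `1`.
#' @param replicates Simulation replicates per cell (default 10).
#' @param base_params A [sim_params()] object providing N, generations and
#'   initial fractions (its `u`, `dfe` and `seed` are overridden per cell).
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(u_values = 10^seq(-8, -4, length.out = 5),
                      s_values = 10^seq(-4, -1, length.out = 4),
                      dfe_shapes = c("fixed", "100", "10", "1"),
                      replicates = 10,
                      base_params = sim_params()) {
  stopifnot(all(u_values > 0), all(s_values > 0), replicates >= 1,
            inherits(base_params, "sim_params"))
  dfe_shapes <- as.character(dfe_shapes)
  bad <- setdiff(dfe_shapes, c("fixed", "100", "10", "1"))
  if (length(bad)) abort(paste("Unknown DFE shapes:", paste(bad, collapse = ", ")))
  structure(list(u_values = u_values, s_values = s_values,
                 dfe_shapes = dfe_shapes, replicates = as.integer(replicates),
                 base_params = base_params),
            class = "grid_spec")
}

cell_dfe <- function(shape, mean_s) {
  if (shape == "fixed") dfe_params("fixed", mean_s = mean_s)
  else dfe_params("gamma", mean_s = mean_s, shape = as.numeric(shape))
}

#' Run a compatibility sweep over the parameter grid
#'
#' For every (u, mean_s, shape) cell, runs `replicates` Wright-Fisher
#' simulations, classifies each against the experimental pattern with
#' [classify_outcome()], and tests the simulated compatible/incompatible
#' split against the experimental mice with [fisher_exact_2x2()]. A cell is
#' "starred" when the Fisher test does not reject (p > alpha), i.e. the
#' simulations are statistically compatible with the experiment.
#'
#' Replicate seeds are `seed + (cell_index - 1) * replicates + replicate`,
#' so the whole grid is reproducible and cells are independent.
#'
#' @param grid A [grid_spec()].
#' @param experimental Integer pair `(n_compatible_mice, n_mice)`; default
#'   `c(8, 8)`.
#' @param seed Base RNG seed.
#' @param alpha Significance level for starring (default 0.05).
#' @param loss_threshold,extinction_threshold Passed to [classify_outcome()].
#' @return A tibble of class `"sweep_grid"`: one row per cell with columns
#'   u, mean_s, shape, n_compatible, replicates, compatibility_fraction,
#'   fisher_p, starred.
#' @export
run_grid <- function(grid, experimental = c(8, 8), seed = 1,
                     alpha = 0.05, loss_threshold = 0.001,
                     extinction_threshold = 0) {
  stopifnot(inherits(grid, "grid_spec"), length(experimental) == 2,
            experimental[1] <= experimental[2], experimental[2] >= 1)
  cells <- tidyr::expand_grid(shape = grid$dfe_shapes,
                              u = grid$u_values,
                              mean_s = grid$s_values)
  bp <- grid$base_params
  res <- purrr::pmap(
    list(cells$shape, cells$u, cells$mean_s, seq_len(nrow(cells))),
    function(shape, u, mean_s, idx) {
      n_comp <- 0L
      for (r in seq_len(grid$replicates)) {
        p <- sim_params(n_total = bp$n_total, generations = bp$generations,
                        u = u, dfe = cell_dfe(shape, mean_s),
                        initial_fractions = bp$initial_fractions,
                        seed = seed + (idx - 1L) * grid$replicates + r,
                        record_every = bp$record_every)
        out <- classify_outcome(run_replicate(p),
                                loss_threshold = loss_threshold,
                                extinction_threshold = extinction_threshold)
        n_comp <- n_comp + as.integer(out$compatible)
      }
      fp <- fisher_exact_2x2(experimental[1],
                             experimental[2] - experimental[1],
                             n_comp, grid$replicates - n_comp)
      tibble(n_compatible = n_comp, replicates = grid$replicates,
             compatibility_fraction = n_comp / grid$replicates,
             fisher_p = fp, starred = fp > alpha)
    })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res)) %>%
    select("u", "mean_s", "shape", "n_compatible", "replicates",
           "compatibility_fraction", "fisher_p", "starred") %>%
    arrange(.data$shape, .data$u, .data$mean_s)
  class(out) <- c("sweep_grid", class(out))
  out
}

#' Export a sweep grid as a long-format TSV
#'
#' Rows are sorted by (shape, u, mean_s); values round-trip exactly through
#' [read_tsv_commented()].
#'
#' @param cells A `"sweep_grid"` tibble from [run_grid()].
#' @param path Output TSV path.
#' @return `cells`, invisibly.
#' @export
export_heatmap <- function(cells, path) {
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    abort("`cells` must be a non-empty sweep grid.")
  }
  cells %>%
    arrange(.data$shape, .data$u, .data$mean_s) %>%
    select("u", "mean_s", "shape", "compatibility_fraction", "fisher_p",
           "starred") %>%
    write_tsv_commented(path)
  invisible(cells)
}

#' Heatmap of compatibility fractions across the sweep grid
#'
#' @param cells A `"sweep_grid"` tibble.
#' @return A ggplot object: tiles of compatibility fraction over
#'   log10(u) x log10(mean_s), faceted by DFE shape, with stars where the
#'   Fisher test does not reject.
#' @export
plot_sweep_heatmap <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = factor(signif(.data$u, 3)),
                               y = factor(signif(.data$mean_s, 3)),
                               fill = .data$compatibility_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(cells, .data$starred),
                        shape = 8, colour = "black") +
    ggplot2::facet_wrap(ggplot2::vars(.data$shape)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Mutation rate u", y = "Mean selective effect s",
                  fill = "Compatible\nfraction")
}

#' @exportS3Method ggplot2::autoplot
autoplot.sweep_grid <- function(object, ...) plot_sweep_heatmap(object)
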