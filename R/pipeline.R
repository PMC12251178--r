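#' Run the full synthetic pipeline and write a report directory
#'
#' End-to-end driver over all modules: generates every synthetic input from
#' one seeded configuration, runs the marker-dynamics, variant, coverage,
#' HGT, and fitness analyses plus a (small, configurable) Wright-Fisher
#' compatibility sweep, and writes all stage tables as `#`-commented TSV
#' into `outdir` together with a one-stop `summary.tsv`. Byte-identical
#' outputs for identical `(cfg, sweep)` inputs.
#'
#' @param cfg A [synth_config()]; its `seed` drives every stage.
#' @param outdir Output directory (created if missing).
#' @param sweep Optional [grid_spec()] for the compatibility sweep; the
#'   default is a deliberately small smoke grid (one cell, reduced census)
#'   so the full pipeline stays fast. Pass a full grid for real sweeps.
#' @param gens_per_day Generations per day (default 18).
#' @return Tibble of written files (`stage`, `path`), invisibly.
#' @export
run_pipeline <- function(cfg = synth_config(),
                         outdir,
                         sweep = grid_spec(
                           u_values = 1e-4, s_values = 0.05,
                           dfe_shapes = "fixed", replicates = 2,
                           base_params = sim_params(n_total = 1e4,
                                                    generations = 360)),
                         gens_per_day = 18) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  files <- list()
  note <- function(stage, f) {
    files[[length(files) + 1]] <<- tibble(stage = stage, path = f)
  }

  # --- marker dynamics -------------------------------------------------
  mt <- gen_marker_trajectories(cfg)
  write_tsv_commented(mt$trajectory, pth("marker_trajectories.tsv"),
                      header = paste0("seed=", cfg$seed))
  write_tsv_commented(mt$truth, pth("marker_truth.tsv"))
  calls <- classify_polymorphism(mt$trajectory,
                                 detection_limit = cfg$detection_limit)
  write_tsv_commented(calls, pth("polymorphism_calls.tsv"))
  note("markers", pth("marker_trajectories.tsv"))
  note("markers", pth("polymorphism_calls.tsv"))
  prop_p <- polymorphism_proportion_test(
    calls %>% filter(.data$strain == "A"),
    calls %>% filter(.data$strain == "B1"))
  loads <- bind_rows(
    mean_log10_load(mt$trajectory, "A", cfg$detection_limit),
    mean_log10_load(mt$trajectory, "B1", cfg$detection_limit))
  write_tsv_commented(loads, pth("strain_loads.tsv"))
  note("markers", pth("strain_loads.tsv"))

  # --- variants --------------------------------------------------------
  vt <- gen_variant_tables(cfg)
  write_tsv_commented(vt$variants, pth("variants.tsv"))
  note("variants", pth("variants.tsv"))
  counts <- count_events(vt$variants, n_mice = cfg$n_mice)
  write_tsv_commented(counts, pth("event_counts.tsv"))
  note("variants", pth("event_counts.tsv"))
  dnds <- dn_ds(vt$variants)
  sweeps_found <- find_sweeps(vt$variants)
  write_tsv_commented(sweeps_found, pth("selective_sweeps.tsv"))
  note("variants", pth("selective_sweeps.tsv"))
  par_tab <- parallel_targets(vt$variants)
  write_tsv_commented(par_tab, pth("parallel_targets.tsv"))
  note("variants", pth("parallel_targets.tsv"))
  gens <- elapsed_generations(max(vt$variants$day), gens_per_day)
  rates <- purrr::map_dfr(c("A", "B1"), function(st) {
    g <- glance(mutation_rate(vt$variants %>% filter(.data$strain == st),
                              generations = gens, n_mice = cfg$n_mice))
    g$strain <- st
    g
  })
  write_tsv_commented(rates, pth("mutation_rates.tsv"))
  note("variants", pth("mutation_rates.tsv"))

  # --- coverage / element frequency ------------------------------------
  cov <- gen_coverage(cfg, presence_p = 0.5)
  freq <- element_presence_frequency(cov$coverage, cov$region,
                                     flank_size = cfg$flank_size)
  write_tsv_commented(freq, pth("element_frequency.tsv"))
  note("coverage", pth("element_frequency.tsv"))

  # --- HGT -------------------------------------------------------------
  rd <- gen_reads(cfg)
  in_tract <- rd$variant_sites[rd$variant_sites >= rd$tract[1] &
                                 rd$variant_sites < rd$tract[2]]
  hgt_calls <- purrr::map_dfr(in_tract, function(p) {
    classify_hgt_variant(rd$reads, rd$donor_ref, rd$recipient_ref, p)
  })
  flagged <- hgt_calls %>%
    filter(!.data$no_call, .data$hgt_flag) %>%
    arrange(.data$position)
  tracts <- hgt_tract_extent(flagged, max_gap = 4 * cfg$read_length)
  write_tsv_commented(hgt_calls, pth("hgt_calls.tsv"))
  write_tsv_commented(tracts, pth("hgt_tracts.tsv"))
  note("hgt", pth("hgt_calls.tsv"))
  note("hgt", pth("hgt_tracts.tsv"))

  # --- fitness ---------------------------------------------------------
  gw <- gen_growth(cfg)
  mu <- max_growth_rate(gw$curve, blank = cfg$growth$blank,
                        min_signal = 10 * cfg$growth$noise_sd)
  kcap <- carrying_capacity(gw$curve, blank = cfg$growth$blank)
  comp <- gen_competition(cfg)
  sel <- glance(selection_coefficient(comp$series,
                                      gens_per_day = gens_per_day))
  fitness_tab <- tibble(max_growth_rate = mu$rate,
                        growth_r_squared = mu$r_squared,
                        carrying_capacity = kcap,
                        s_per_day = sel$s_per_day,
                        s_per_day_se = sel$se_per_day,
                        s_per_generation = sel$s_per_generation_rounded)
  write_tsv_commented(fitness_tab, pth("fitness_estimates.tsv"))
  note("fitness", pth("fitness_estimates.tsv"))

  # --- compatibility sweep --------------------------------------------
  grid_cells <- run_grid(sweep, seed = cfg$seed)
  export_heatmap(grid_cells, pth("sweep_heatmap.tsv"))
  note("sweep", pth("sweep_heatmap.tsv"))

  # --- summary ---------------------------------------------------------
  summary_tab <- tibble(
    quantity = c("polymorphism_test_p",
                 "mean_log10_load_A", "mean_log10_load_B1",
                 "total_events_A", "total_events_B1",
                 "mean_events_per_mouse_A", "mean_events_per_mouse_B1",
                 "dnds_A", "dnds_B1",
                 "n_sweeps_A", "n_sweeps_B1",
                 "mean_m_t_A", "mean_m_t_B1",
                 "element_presence", "n_hgt_tracts",
                 "max_growth_rate", "s_per_generation"),
    value = c(prop_p,
              loads$mean_log10_load[loads$strain == "A"],
              loads$mean_log10_load[loads$strain == "B1"],
              sum(counts$n[counts$strain == "A"]),
              sum(counts$n[counts$strain == "B1"]),
              counts$mean_per_mouse[match("A", counts$strain)],
              counts$mean_per_mouse[match("B1", counts$strain)],
              dnds$dnds[dnds$strain == "A"],
              dnds$dnds[dnds$strain == "B1"],
              sum(sweeps_found$strain == "A"),
              sum(sweeps_found$strain == "B1"),
              rates$mean_m_t[rates$strain == "A"],
              rates$mean_m_t[rates$strain == "B1"],
              freq$presence,
              nrow(tracts),
              mu$rate,
              sel$s_per_generation_rounded))
  write_tsv_commented(summary_tab, pth("summary.tsv"),
                      header = paste0("seed=", cfg$seed))
  note("summary", pth("summary.tsv"))

  invisible(bind_rows(files))
}
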