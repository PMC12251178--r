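#' Distribution of fitness effects (DFE) of beneficial mutations
#'
#' Beneficial mutations receive a selective advantage `s` drawn either from a
#' gamma distribution with mean `mean_s` (scale = `mean_s / shape`, so the
#' mean is `mean_s` for every shape) or from a point mass at `mean_s`
#' ("fixed" effects, the shape-to-infinity limit of the gamma).
#'
#' @param kind `"fixed"` or `"gamma"`.
#' @param mean_s Mean selective advantage per mutation (> 0), dimensionless.
#' @param shape Gamma shape parameter (> 0); `shape = 1` is an exponential
#'   DFE, `shape = 100` is already close to fixed effects. Ignored for
#'   `kind = "fixed"`.
#' @return An object of class `"dfe_params"`.
#' @examples
#' dfe_params("gamma", mean_s = 0.01, shape = 1)
#' dfe_params("fixed", mean_s = 0.01)
#' @export
dfe_params <- function(kind = c("fixed", "gamma"), mean_s, shape = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(mean_s) || length(mean_s) != 1 || mean_s <= 0) {
    abort("`mean_s` must be a single positive number.")
  }
  if (kind == "gamma") {
    if (is.null(shape) || !is.numeric(shape) || length(shape) != 1 ||
        shape <= 0) {
      abort("`shape` must be a single positive number for a gamma DFE.")
    }
  } else {
    shape <- Inf
  }
  structure(list(kind = kind, mean_s = mean_s, shape = shape),
            class = "dfe_params")
}

#' Draw selective effects from a DFE
#'
#' @param n_draws Number of effects to draw (>= 0).
#' @param dfe A [dfe_params()] object.
#' @return Numeric vector of length `n_draws`, all positive. For a fixed DFE
#'   every draw equals `mean_s`; for a gamma DFE draws have mean `mean_s` and
#'   variance `mean_s^2 / shape`.
#' @examples
#' sample_effects(3, dfe_params("fixed", 0.01))
#' @export
sample_effects <- function(n_draws, dfe) {
  stopifnot(inherits(dfe, "dfe_params"), n_draws >= 0)
  if (n_draws == 0) return(numeric(0))
  if (dfe$kind == "fixed") {
    rep(dfe$mean_s, n_draws)
  } else {
    rgamma(n_draws, shape = dfe$shape, scale = dfe$mean_s / dfe$shape)
  }
}

#' Parameters for the two-strain Wright-Fisher simulation
#'
#' The total population (both strains together) has constant census size
#' `n_total` and is divided into four neutral marker types: markers 0 and 1
#' belong to strain A, markers 2 and 3 to strain B1. Each generation,
#' beneficial mutations arise (binomially per lineage, rate `u` per
#' individual) and the next generation is drawn by multinomial sampling with
#' probabilities proportional to `count * fitness`.
#'
#' Defaults mirror the experimental setting: `n_total = 1e6` bacteria
#' (a rough census of a fecal sample), 1600 generations (88 days at 18
#' generations/day), initial marker fractions (0.05, 0.05, 0.45, 0.45) so
#' strain A starts at 10% of the population.
#'
#' @param n_total Constant census size (>= 4).
#' @param generations Number of generations to simulate (>= 0).
#' @param u Beneficial mutation rate per individual per generation, in
#'   `[0, 1]`.
#' @param dfe A [dfe_params()] object.
#' @param initial_fractions Length-4 vector of initial marker fractions,
#'   ordered (A-marker0, A-marker1, B1-marker2, B1-marker3), summing to 1.
#' @param seed Integer RNG seed; the same `(params, seed)` always yields
#'   bit-identical results.
#' @param record_every Generations between trajectory snapshots (default 18,
#'   one per day).
#' @return An object of class `"sim_params"`.
#' @examples
#' sim_params(n_total = 1000, generations = 50, u = 0,
#'            dfe = dfe_params("fixed", 0.01))
#' @export
sim_params <- function(n_total = 1e6, generations = 1600, u = 1e-5,
                       dfe = dfe_params("gamma", mean_s = 0.01, shape = 1),
                       initial_fractions = c(0.05, 0.05, 0.45, 0.45),
                       seed = 1L, record_every = 18L) {
  if (n_total < 4) abort("`n_total` must be at least 4.")
  if (u < 0 || u > 1) abort("`u` must lie in [0, 1].")
  if (generations < 0) abort("`generations` must be >= 0.")
  if (length(initial_fractions) != 4 || any(initial_fractions < 0)) {
    abort("`initial_fractions` must be 4 non-negative numbers.")
  }
  if (abs(sum(initial_fractions) - 1) > 1e-12) {
    abort("`initial_fractions` must sum to 1 (within 1e-12).")
  }
  stopifnot(inherits(dfe, "dfe_params"), record_every >= 1)
  structure(list(n_total = as.numeric(n_total),
                 generations = as.integer(generations),
                 u = u, dfe = dfe,
                 initial_fractions = as.numeric(initial_fractions),
                 seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "sim_params")
}

strain_of_marker <- function(marker_id) ifelse(marker_id <= 1, "A", "B1")

# Largest-remainder apportionment of n_total among the four founder types.
largest_remainder_counts <- function(fractions, n_total) {
  exact <- fractions * n_total
  base <- floor(exact)
  rem <- exact - base
  short <- round(n_total - sum(base))
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  base
}

#' Found the initial four-lineage population
#'
#' Founder lineages all have relative fitness exactly 1; counts are
#' largest-remainder roundings of `fraction * n_total` summing exactly to
#' `n_total`. Lineages whose rounded count is 0 are pruned (with a warning if
#' their fraction was positive).
#'
#' @param params A [sim_params()] object.
#' @return A `"population_state"`: list with integer vectors `marker_id`
#'   (0..3), `fitness`, `count`, plus `generation` and `n_total`.
#' @examples
#' make_population(sim_params(n_total = 100, generations = 0, u = 0,
#'   initial_fractions = rep(0.25, 4)))
#' @export
make_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  counts <- largest_remainder_counts(params$initial_fractions, params$n_total)
  if (any(counts == 0 & params$initial_fractions > 0)) {
    warn("Some positive initial fractions rounded to a count of 0; those lineages are pruned.")
  }
  keep <- counts > 0
  structure(list(marker_id = (0:3)[keep],
                 fitness = rep(1, sum(keep)),
                 count = counts[keep],
                 generation = 0L,
                 n_total = params$n_total),
            class = "population_state")
}

#' @exportS3Method tibble::as_tibble
as_tibble.population_state <- function(x, ...) {
  tibble(marker_id = x$marker_id,
         strain = strain_of_marker(x$marker_id),
         fitness = x$fitness,
         count = x$count,
         frequency = x$count / x$n_total,
         generation = x$generation)
}

# One Wright-Fisher generation on raw vectors: mutation first (each mutant
# founds a new lineage with fitness parent * (1 + s)), then multinomial
# resampling with probabilities proportional to count * fitness, then pruning.
wf_step <- function(marker, fitness, count, params) {
  n_new <- 0L
  if (params$u > 0) {
    nm <- rbinom(length(count), size = count, prob = params$u)
    total_new <- sum(nm)
    if (total_new > 0) {
      parents <- rep.int(seq_along(count), nm)
      s <- sample_effects(total_new, params$dfe)
      count <- count - nm
      marker <- c(marker, marker[parents])
      fitness <- c(fitness, fitness[parents] * (1 + s))
      count <- c(count, rep.int(1, total_new))
      n_new <- total_new
    }
  }
  w <- count * fitness
  if (all(w == 0)) abort("All sampling weights are zero; cannot resample.")
  count <- as.numeric(rmultinom(1, size = params$n_total, prob = w))
  keep <- count > 0
  list(marker = marker[keep], fitness = fitness[keep], count = count[keep],
       n_new = n_new)
}

#' Advance the population by one generation
#'
#' Mutation precedes resampling: per lineage the number of new mutants is
#' Binomial(count, u), each mutant founds a lineage with fitness
#' `parent * (1 + s)` (multiplicative across successive mutations), then the
#' whole population is resampled multinomially with weights
#' `count * fitness`. Extinct lineages are pruned. Uses the current RNG
#' state; seed control lives in [run_replicate()].
#'
#' @param state A `"population_state"`.
#' @param params A [sim_params()] object.
#' @return The next `"population_state"`; attribute `"n_new_mutations"`
#'   carries the number of mutations that arose this generation.
#' @export
advance_generation <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            sum(state$count) == params$n_total)
  stp <- wf_step(state$marker_id, state$fitness, state$count, params)
  out <- structure(list(marker_id = stp$marker, fitness = stp$fitness,
                        count = stp$count,
                        generation = state$generation + 1L,
                        n_total = params$n_total),
                   class = "population_state")
  attr(out, "n_new_mutations") <- stp$n_new
  out
}

marker_counts4 <- function(marker, count) {
  vapply(0:3, function(m) sum(count[marker == m]), numeric(1))
}

#' Run one Wright-Fisher replicate
#'
#' Simulates `params$generations` generations from the founder population,
#' recording marker-frequency snapshots at generation 0, every
#' `record_every` generations, and the final generation. Fully deterministic
#' given `params` (including its `seed`).
#'
#' @param params A [sim_params()] object.
#' @return An object of class `"sim_result"` with elements
#'   `trajectory` (tibble: generation, marker_id, strain, count, frequency,
#'   within_strain_frequency -- `NA` when the strain is extinct),
#'   `n_mutations_arisen`, `final_state`, and `params`.
#' @examples
#' res <- run_replicate(sim_params(n_total = 1000, generations = 20, u = 0,
#'                                 seed = 42, record_every = 5))
#' tidy(res)
#' @export
run_replicate <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  state <- make_population(params)
  marker <- state$marker_id; fitness <- state$fitness; count <- state$count
  gens <- params$generations
  snap_at <- unique(c(seq(0L, gens, by = params$record_every), gens))
  snaps <- matrix(0, nrow = length(snap_at), ncol = 4)
  snaps[1, ] <- marker_counts4(marker, count)
  si <- 2L
  n_mut <- 0L
  if (gens > 0) {
    for (g in seq_len(gens)) {
      stp <- wf_step(marker, fitness, count, params)
      marker <- stp$marker; fitness <- stp$fitness; count <- stp$count
      n_mut <- n_mut + stp$n_new
      if (si <= length(snap_at) && g == snap_at[si]) {
        snaps[si, ] <- marker_counts4(marker, count)
        si <- si + 1L
      }
    }
  }
  n_total <- params$n_total
  strain_tot <- cbind(snaps[, 1] + snaps[, 2], snaps[, 1] + snaps[, 2],
                      snaps[, 3] + snaps[, 4], snaps[, 3] + snaps[, 4])
  wsf <- ifelse(strain_tot > 0, snaps / strain_tot, NA_real_)
  traj <- tibble(
    generation = rep(snap_at, times = 4),
    marker_id = rep(0:3, each = length(snap_at)),
    strain = strain_of_marker(rep(0:3, each = length(snap_at))),
    count = as.vector(snaps),
    frequency = as.vector(snaps) / n_total,
    within_strain_frequency = as.vector(wsf)
  ) %>% arrange(.data$generation, .data$marker_id)
  final_state <- structure(list(marker_id = marker, fitness = fitness,
                                count = count, generation = gens,
                                n_total = n_total),
                           class = "population_state")
  structure(list(trajectory = traj, n_mutations_arisen = n_mut,
                 final_state = final_state, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> N =", x$params$n_total,
      "generations =", x$params$generations,
      "u =", x$params$u,
      "DFE =", x$params$dfe$kind,
      if (x$params$dfe$kind == "gamma") paste0("(shape ", x$params$dfe$shape, ")"),
      "\n  mutations arisen:", x$n_mutations_arisen,
      "\n  lineages extant:", length(x$final_state$count), "\n")
  invisible(x)
}

#' Tidy the marker-frequency trajectory of a simulation
#'
#' @param x A `"sim_result"`.
#' @param ... Unused.
#' @return The snapshot trajectory as a tibble (one row per generation x
#'   marker).
#' @exportS3Method generics::tidy
tidy.sim_result <- function(x, ...) x$trajectory

#' One-row summary of a simulation replicate
#'
#' @param x A `"sim_result"`.
#' @param ... Unused.
#' @return Tibble with census parameters, mutation tally, and final marker
#'   frequencies.
#' @exportS3Method generics::glance
glance.sim_result <- function(x, ...) {
  fin <- x$trajectory %>% filter(.data$generation == max(.data$generation))
  tibble(n_total = x$params$n_total,
         generations = x$params$generations,
         u = x$params$u,
         dfe_kind = x$params$dfe$kind,
         dfe_shape = x$params$dfe$shape,
         mean_s = x$params$dfe$mean_s,
         seed = x$params$seed,
         n_mutations_arisen = x$n_mutations_arisen,
         final_freq_strain_A = sum(fin$frequency[fin$strain == "A"]),
         final_freq_strain_B1 = sum(fin$frequency[fin$strain == "B1"]))
}

#' Classify a replicate against the experimental coexistence pattern
#'
#' A marker is "maintained" if its final within-strain frequency is at least
#' `loss_threshold` (with threshold 0 meaning strict non-extinction); a
#' strain is extant if its final share of the total population is at least
#' `extinction_threshold`. A replicate is compatible with the experimental
#' pattern when both strains are extant, strain A (the minor strain) kept
#' exactly one marker, and strain B1 kept both.
#'
#' @param result A `"sim_result"`.
#' @param loss_threshold Within-strain frequency below which a marker counts
#'   as lost (default 0.001, roughly what CFU plating could still see).
#' @param extinction_threshold Total-population frequency below which a
#'   strain counts as extinct; the default 0 means literal extinction
#'   (zero individuals), the coexistence sense of the experimental pattern.
#' @return One-row tibble: `markers_maintained_A`, `markers_maintained_B1`,
#'   `strain_A_extant`, `strain_B1_extant`, `compatible`.
#' @export
classify_outcome <- function(result, loss_threshold = 0.001,
                             extinction_threshold = 0) {
  stopifnot(inherits(result, "sim_result"))
  fin <- result$trajectory %>%
    filter(.data$generation == max(.data$generation))
  strain_freq <- c(A = sum(fin$frequency[fin$strain == "A"]),
                   B1 = sum(fin$frequency[fin$strain == "B1"]))
  maintained <- function(st) {
    w <- fin$within_strain_frequency[fin$strain == st]
    sum(!is.na(w) & w > 0 & w >= loss_threshold)
  }
  extant <- function(f) if (extinction_threshold > 0) f >= extinction_threshold else f > 0
  extant_A <- extant(strain_freq[["A"]])
  extant_B1 <- extant(strain_freq[["B1"]])
  mA <- if (strain_freq[["A"]] > 0) maintained("A") else 0L
  mB1 <- if (strain_freq[["B1"]] > 0) maintained("B1") else 0L
  tibble(markers_maintained_A = mA,
         markers_maintained_B1 = mB1,
         strain_A_extant = extant_A,
         strain_B1_extant = extant_B1,
         compatible = extant_A && extant_B1 && mA == 1L && mB1 == 2L)
}

#' Write a simulation trajectory to TSV
#'
#' Columns generation, marker_id, strain, count, frequency,
#' within_strain_frequency; run parameters (including the seed) go into
#' `#`-prefixed header lines.
#'
#' @param result A `"sim_result"`.
#' @param path Output file.
#' @return `result`, invisibly.
#' @export
write_sim_result <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  p <- result$params
  hdr <- c(paste0("n_total=", p$n_total), paste0("generations=", p$generations),
           paste0("u=", p$u), paste0("dfe_kind=", p$dfe$kind),
           paste0("dfe_mean_s=", p$dfe$mean_s),
           paste0("dfe_shape=", p$dfe$shape),
           paste0("initial_fractions=",
                  paste(p$initial_fractions, collapse = ",")),
           paste0("seed=", p$seed),
           paste0("record_every=", p$record_every),
           paste0("n_mutations_arisen=", result$n_mutations_arisen))
  write_tsv_commented(result$trajectory, path, header = hdr)
  invisible(result)
}

#' Plot marker-frequency trajectories of a simulation
#'
#' @param object A `"sim_result"`.
#' @param within_strain Plot within-strain frequencies instead of
#'   total-population frequencies.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_result <- function(object, within_strain = FALSE, ...) {
  df <- object$trajectory %>%
    mutate(marker = factor(.data$marker_id))
  y <- if (within_strain) "within_strain_frequency" else "frequency"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data[[y]],
                                   colour = .data$marker)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = "Generation",
                  y = if (within_strain) "Within-strain marker frequency"
                      else "Marker frequency",
                  colour = "Marker")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
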