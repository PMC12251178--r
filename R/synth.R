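#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator; the defaults emulate the
#' two-strain gut-colonization experiment: strain B1 at ~10^8.5 CFU/g and
#' strain A at ~10^7.4 CFU/g with a ~300 CFU/g plating detection limit,
#' four neutral markers started at fractions (0.05, 0.05, 0.45, 0.45),
#' strain A losing one marker and strain B1 keeping both, per-mouse event
#' counts and class mix on the observed scale, 100x coverage, two
#' references diverged at ~2% with a planted transferred tract, logistic
#' growth on the ancestors' scale, and a competitive advantage of 4 per day.
#'
#' Each generator expands `seed` with a fixed stage offset (trajectories
#' +101, variants +202, coverage +303, reads +404, growth +505, competition
#' +606), so stages are independently reproducible.
#'
#' @param seed Integer base seed.
#' @param n_mice Number of co-colonized mice (default 8).
#' @param days Sampling days for CFU trajectories.
#' @param load_log10_mean Named log10 CFU/g means, `c(A = 7.4, B1 = 8.5)`.
#' @param load_log10_sd Between-observation log10 SD of loads (default 0.4).
#' @param detection_limit CFU/g plating limit (default 300).
#' @param initial_fractions Initial marker fractions.
#' @param p_loss Named probabilities that a strain loses one marker,
#'   `c(A = 1, B1 = 0)` by default (the modal experimental pattern).
#' @param events_mean Named per-mouse mean event counts,
#'   `c(A = 4.75, B1 = 10.25)` (38 and 82 events over 8 mice).
#' @param class_mix Named event-class probabilities (default: the strain B1
#'   breakdown, 34:4:16:8:9:11 over 82).
#' @param n_sweeps Named number of planted selective sweeps (> 0.95),
#'   `c(A = 9, B1 = 0)`.
#' @param parallelism_fraction Fraction of events drawn from a small shared
#'   target pool so they recur across mice (default 0.3).
#' @param coverage_depth Mean per-base depth (default 100).
#' @param region_length,flank_size Element and flank sizes in bp for
#'   coverage profiles.
#' @param ref_length,read_length,error_rate,divergence,tract,n_reads,
#'   donor_fraction Read-set parameters: reference length, read length,
#'   per-base substitution error rate, SNP density between the references,
#'   planted half-open HGT tract, read count, and the fraction of in-tract
#'   reads drawn from the donor.
#' @param growth Named list `r` (per hour), `k`, `x0`, `blank`, `noise_sd`
#'   for logistic OD curves (ancestor-B1 scale by default).
#' @param competition Named list `s_per_day`, `noise_sd`, `n_mice`, `days`,
#'   `ref_cfu` for competitive-index series.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1,
                         n_mice = 8,
                         days = c(0, 3, 7, 10, 14, 21, 28, 35, 43, 57, 71, 88),
                         load_log10_mean = c(A = 7.4, B1 = 8.5),
                         load_log10_sd = 0.4,
                         detection_limit = 300,
                         initial_fractions = c(0.05, 0.05, 0.45, 0.45),
                         p_loss = c(A = 1, B1 = 0),
                         events_mean = c(A = 4.75, B1 = 10.25),
                         class_mix = c(SNP_NS = 34, SNP_S = 4,
                                       SNP_intergenic = 16, IS_insertion = 8,
                                       small_indel = 9, large_deletion = 11) / 82,
                         n_sweeps = c(A = 9, B1 = 0),
                         parallelism_fraction = 0.3,
                         coverage_depth = 100,
                         region_length = 15000,
                         flank_size = 5000,
                         ref_length = 20000,
                         read_length = 150,
                         error_rate = 0,
                         divergence = 0.02,
                         tract = c(5000, 10000),
                         n_reads = 2000,
                         donor_fraction = 0.2,
                         growth = list(r = 1.08, k = 0.8, x0 = 1e-3,
                                       blank = 0.04, noise_sd = 0.003),
                         competition = list(s_per_day = 4.0, noise_sd = 0.3,
                                            n_mice = 4, days = 0:4,
                                            ref_cfu = 1e6)) {
  stopifnot(abs(sum(initial_fractions) - 1) < 1e-12,
            abs(sum(class_mix) - 1) < 1e-9,
            all(p_loss >= 0 & p_loss <= 1),
            load_log10_sd >= 0, error_rate >= 0, divergence > 0,
            detection_limit > 0, n_mice >= 1)
  structure(as.list(environment()), class = "synth_config")
}

stage_seed <- function(cfg, offset) as.integer(cfg$seed + offset)

marker_names <- c("CFP", "YFP", "mCherry", "sfGFP")

#' Generate synthetic marker CFU trajectories with known outcomes
#'
#' In `"parametric"` mode, each mouse's strain loads are lognormal around
#' the configured strain means; within a strain the two markers split the
#' load 50/50 when polymorphism is maintained, while a lost marker declines
#' linearly to zero by its (random) day of loss. In `"from_simulator"` mode
#' the within-strain marker fractions are taken from supplied
#' [run_replicate()] results (one per mouse, snapshot generations mapped to
#' days at 18 generations/day). Counts below the detection limit are
#' reported as 0.
#'
#' @param cfg A [synth_config()].
#' @param mode `"parametric"` or `"from_simulator"`.
#' @param sim_results List of `"sim_result"` objects (one per mouse) for
#'   `"from_simulator"` mode.
#' @return List with `trajectory` (tibble: mouse_id, day, marker,
#'   cfu_per_g) and `truth` (tibble per mouse x strain: `truth_status`,
#'   `truth_fixed_marker`, `truth_day_of_loss`).
#' @export
gen_marker_trajectories <- function(cfg, mode = c("parametric",
                                                  "from_simulator"),
                                    sim_results = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  mode <- match.arg(mode)
  set.seed(stage_seed(cfg, 101))
  strains <- c("A", "B1")
  strain_markers <- list(A = c("CFP", "YFP"), B1 = c("mCherry", "sfGFP"))
  if (mode == "from_simulator") {
    stopifnot(is.list(sim_results), length(sim_results) == cfg$n_mice)
  }
  traj <- list(); truth <- list()
  for (m in seq_len(cfg$n_mice)) {
    for (st in strains) {
      mk <- strain_markers[[st]]
      loads <- 10^rnorm(length(cfg$days), cfg$load_log10_mean[[st]],
                        cfg$load_log10_sd)
      if (mode == "parametric") {
        lose <- runif(1) < cfg$p_loss[[st]]
        if (lose) {
          lost_marker <- sample(mk, 1)
          day_loss <- sample(c(28, 35, 43), 1)
          f_lost <- pmax(0, 0.5 * (1 - cfg$days / day_loss))
        } else {
          lost_marker <- NA_character_
          day_loss <- NA_real_
          f_lost <- rep(0.5, length(cfg$days))
        }
        frac <- cbind(f_lost, 1 - f_lost)
        colnames(frac) <- c(mk[1], mk[2])
        if (!is.na(lost_marker) && lost_marker == mk[2]) {
          frac <- frac[, c(2, 1)]
          colnames(frac) <- c(mk[1], mk[2])
        }
        status <- if (lose) "lost" else "maintained"
        fixed <- if (lose) setdiff(mk, lost_marker) else NA_character_
      } else {
        sim <- sim_results[[m]]
        tr <- sim$trajectory
        ids <- if (st == "A") 0:1 else 2:3
        day_of <- function(g) g / 18
        sub <- tr %>% filter(.data$marker_id %in% ids)
        sim_days <- day_of(sort(unique(sub$generation)))
        frac <- matrix(NA_real_, nrow = length(cfg$days), ncol = 2,
                       dimnames = list(NULL, mk))
        for (j in 1:2) {
          w <- sub %>% filter(.data$marker_id == ids[j]) %>%
            arrange(.data$generation)
          idx <- vapply(cfg$days, function(d) which.min(abs(sim_days - d)),
                        integer(1))
          frac[, j] <- w$within_strain_frequency[idx]
        }
        frac[is.na(frac)] <- 0
        status <- NA_character_; fixed <- NA_character_
        day_loss <- NA_real_
      }
      cfu <- round(loads * frac)
      cfu[cfu < cfg$detection_limit] <- 0
      traj[[length(traj) + 1]] <- tibble(
        mouse_id = m,
        day = rep(cfg$days, 2),
        marker = rep(mk, each = length(cfg$days)),
        cfu_per_g = c(cfu[, mk[1]], cfu[, mk[2]]))
      truth[[length(truth) + 1]] <- tibble(
        mouse_id = m, strain = st, truth_status = status,
        truth_fixed_marker = fixed, truth_day_of_loss = day_loss)
    }
  }
  list(trajectory = bind_rows(traj) %>% arrange(.data$mouse_id, .data$day),
       truth = bind_rows(truth))
}

#' Generate synthetic variant tables with planted structure
#'
#' Per mouse and strain, event counts are Poisson around the configured
#' mean; a configurable fraction of events hits a small pool of shared
#' targets (creating gene-level parallelism), the rest hit unique targets.
#' Non-sweep frequencies are uniform on (0.02, 0.9); exactly `n_sweeps`
#' events per strain are planted above 0.95, spread over the mice.
#'
#' @param cfg A [synth_config()].
#' @param day Sampling day recorded in the table (default 88).
#' @return List with `variants` (tibble: strain, mouse_id, day, position,
#'   target, var_class, frequency, supporting_reads) and `truth` (list with
#'   `per_mouse` frequency sums, `parallel` planted shared targets,
#'   `n_sweeps` planted sweep counts per strain).
#' @export
gen_variant_tables <- function(cfg, day = 88) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg, 202))
  pool <- list(
    A = c("frlR", "fimE", "focA/ycaO", "mngB/cydA", "e14_region"),
    B1 = c("fimH", "yadA", "dpiB", "tdcA", "large_del_1", "large_del_2"))
  rows <- list()
  for (st in c("A", "B1")) {
    # round-robin allocation of the planted sweep quota across mice
    quota_per_mouse <- tabulate(rep_len(seq_len(cfg$n_mice),
                                        cfg$n_sweeps[[st]]), cfg$n_mice)
    n_ev <- pmax(rpois(cfg$n_mice, cfg$events_mean[[st]]), 1, quota_per_mouse)
    for (m in seq_len(cfg$n_mice)) {
      k <- n_ev[m]
      shared <- runif(k) < cfg$parallelism_fraction
      targets <- ifelse(shared,
                        sample(pool[[st]], k, replace = TRUE),
                        sprintf("%s_gene_%04d", st, sample.int(5000, k)))
      freq <- runif(k, 0.02, 0.9)
      quota <- quota_per_mouse[m]
      if (quota > 0) {
        freq[seq_len(quota)] <- runif(quota, 0.955, 0.995)
      }
      rows[[length(rows) + 1]] <- tibble(
        strain = st, mouse_id = m, day = day,
        position = sample.int(4.5e6, k),
        target = targets,
        var_class = sample(names(cfg$class_mix), k, replace = TRUE,
                           prob = cfg$class_mix),
        frequency = freq,
        supporting_reads = rpois(k, cfg$coverage_depth * freq) + 1L)
    }
  }
  variants <- bind_rows(rows)
  per_mouse <- variants %>%
    group_by(.data$strain, .data$mouse_id) %>%
    summarise(truth_freq_sum = sum(.data$frequency),
              truth_n_events = n(), .groups = "drop")
  planted_sweeps <- variants %>%
    group_by(.data$strain) %>%
    summarise(truth_n_sweeps = sum(.data$frequency > 0.95), .groups = "drop")
  list(variants = variants,
       truth = list(per_mouse = per_mouse,
                    parallel_pool = pool,
                    sweeps = planted_sweeps))
}

#' Generate a synthetic coverage profile for a partially present element
#'
#' Flank depths are Poisson around the mean depth; depths inside the element
#' are Poisson around `depth * presence_p`.
#'
#' @param cfg A [synth_config()].
#' @param presence_p Element presence frequency in `[0, 1]`.
#' @return List with `coverage` (tibble: contig, position, depth), `region`
#'   (half-open element span), and `truth` (one-row tibble).
#' @export
gen_coverage <- function(cfg, presence_p) {
  stopifnot(inherits(cfg, "synth_config"),
            presence_p >= 0, presence_p <= 1)
  set.seed(stage_seed(cfg, 303))
  fl <- cfg$flank_size; rl <- cfg$region_length
  total <- rl + 2 * fl
  pos <- 0:(total - 1)
  region <- c(fl, fl + rl)
  lambda <- ifelse(pos >= region[1] & pos < region[2],
                   cfg$coverage_depth * presence_p, cfg$coverage_depth)
  list(coverage = tibble(contig = "chr", position = pos,
                         depth = rpois(total, lambda)),
       region = region,
       truth = tibble(truth_presence = presence_p,
                      truth_depth = cfg$coverage_depth))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, at) {
  s <- strsplit(seq, NULL)[[1]]
  repl <- vapply(s[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 character(1))
  s[at] <- repl
  paste(s, collapse = "")
}

#' Generate a synthetic read set over two diverged references with a
#' planted HGT tract
#'
#' Builds a random recipient reference, derives the donor by substituting
#' bases at the configured SNP density, and draws reads uniformly along the
#' genome: reads falling entirely inside the planted tract come from the
#' donor with probability `donor_fraction`, all others from the recipient.
#' Optional per-base substitution errors are applied. Truth origin labels
#' accompany every read.
#'
#' @param cfg A [synth_config()].
#' @return List: `reads` (tibble: read_id, start, seq, truth_origin),
#'   `recipient_ref`, `donor_ref` (character), `variant_sites` (0-based
#'   positions where the references differ), `tract` (planted half-open
#'   span), `truth` (one-row tibble).
#' @export
gen_reads <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg, 404))
  L <- cfg$ref_length; rl <- cfg$read_length
  stopifnot(cfg$tract[1] >= 0, cfg$tract[2] <= L, cfg$tract[2] > cfg$tract[1])
  recipient <- random_seq(L)
  n_div <- max(1, round(L * cfg$divergence))
  sites <- sort(sample.int(L, n_div))            # 1-based internally
  donor <- mutate_bases(recipient, sites)
  starts <- sample.int(L - rl + 1, cfg$n_reads, replace = TRUE) - 1L # 0-based
  in_tract <- starts >= cfg$tract[1] & (starts + rl) <= cfg$tract[2]
  from_donor <- in_tract & runif(cfg$n_reads) < cfg$donor_fraction
  seqs <- vapply(seq_len(cfg$n_reads), function(i) {
    ref <- if (from_donor[i]) donor else recipient
    substr(ref, starts[i] + 1, starts[i] + rl)
  }, character(1))
  if (cfg$error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      at <- which(runif(nchar(s)) < cfg$error_rate)
      if (length(at)) mutate_bases(s, at) else s
    }, character(1), USE.NAMES = FALSE)
  }
  list(reads = tibble(read_id = sprintf("read_%05d", seq_len(cfg$n_reads)),
                      start = starts, seq = seqs,
                      truth_origin = ifelse(from_donor, "donor", "recipient")),
       recipient_ref = recipient, donor_ref = donor,
       variant_sites = sites - 1L,
       tract = cfg$tract,
       truth = tibble(truth_donor_fraction = cfg$donor_fraction,
                      truth_tract_start = cfg$tract[1],
                      truth_tract_end = cfg$tract[2]))
}

#' Write synthetic reads / references to FASTA
#'
#' Read descriptions carry the truth labels
#' (`origin=donor|recipient tract=start-end`). Requires Biostrings.
#'
#' @param readset Output of [gen_reads()].
#' @param reads_path,refs_path Output FASTA paths.
#' @return `readset`, invisibly.
#' @export
write_read_fasta <- function(readset, reads_path, refs_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA output.")
  }
  rs <- Biostrings::DNAStringSet(readset$reads$seq)
  names(rs) <- sprintf("%s origin=%s tract=%d-%d",
                       readset$reads$read_id, readset$reads$truth_origin,
                       readset$tract[1], readset$tract[2])
  Biostrings::writeXStringSet(rs, reads_path)
  refs <- Biostrings::DNAStringSet(c(recipient = readset$recipient_ref,
                                     donor = readset$donor_ref))
  Biostrings::writeXStringSet(refs, refs_path)
  invisible(readset)
}

#' Generate a synthetic logistic growth curve
#'
#' OD readings every 10 minutes for 24 h:
#' `od = blank + K / (1 + ((K - x0)/x0) * exp(-r t)) + noise`.
#'
#' @param cfg A [synth_config()]; growth parameters come from
#'   `cfg$growth`.
#' @return List with `curve` (tibble: time, od) and `truth` (one-row
#'   tibble of the generating parameters).
#' @export
gen_growth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg, 505))
  g <- cfg$growth
  t <- seq(0, 24, by = 1 / 6)
  od <- g$blank + g$k / (1 + ((g$k - g$x0) / g$x0) * exp(-g$r * t))
  if (g$noise_sd > 0) od <- od + rnorm(length(t), 0, g$noise_sd)
  list(curve = tibble(time = t, od = pmax(od, 0)),
       truth = tibble(truth_r = g$r, truth_k = g$k, truth_x0 = g$x0,
                      truth_blank = g$blank, truth_noise_sd = g$noise_sd))
}

#' Generate a synthetic in vivo competition series
#'
#' The log competitive index grows linearly at `s_per_day`; CFU counts get
#' independent lognormal noise (`noise_sd` on the natural-log scale).
#'
#' @param cfg A [synth_config()]; competition parameters come from
#'   `cfg$competition`.
#' @return List with `series` (tibble: mouse_id, day, cfu_focal,
#'   cfu_reference) and `truth` (one-row tibble).
#' @export
gen_competition <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg, 606))
  cc <- cfg$competition
  grid <- tidyr::expand_grid(mouse_id = seq_len(cc$n_mice), day = cc$days)
  n <- nrow(grid)
  ref <- cc$ref_cfu * exp(rnorm(n, 0, cc$noise_sd))
  foc <- cc$ref_cfu * exp(cc$s_per_day * grid$day + rnorm(n, 0, cc$noise_sd))
  list(series = grid %>% mutate(cfu_focal = foc, cfu_reference = ref),
       truth = tibble(truth_s_per_day = cc$s_per_day,
                      truth_noise_sd = cc$noise_sd))
}
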