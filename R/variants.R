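variant_classes <- c("SNP_NS", "SNP_S", "SNP_intergenic", "IS_insertion",
                     "small_indel", "large_deletion", "HGT")

check_variants <- function(tbl, require = c("position", "var_class",
                                            "frequency")) {
  miss <- setdiff(require, names(tbl))
  if (length(miss)) abort(paste("Variant table lacks columns:",
                                paste(miss, collapse = ", ")))
  if ("frequency" %in% names(tbl) &&
      any(tbl$frequency < 0 | tbl$frequency > 1, na.rm = TRUE)) {
    abort("Variant frequencies must lie in [0, 1].")
  }
  invisible(tbl)
}

#' Remove ancestral false positives from an evolved-population variant table
#'
#' Variants already segregating in the sequenced ancestral clones are
#' treated as false positives of the evolved populations. The blacklist is
#' every ancestral variant with frequency strictly above `freq_threshold`
#' AND supported by strictly more than `read_threshold` reads, plus every
#' ancestral consensus-mode call (rows whose `mode` column equals
#' `"consensus"`, when present). Evolved variants matching a blacklisted
#' site are removed; matching uses `position` plus `allele` and `contig`
#' when those columns exist in both tables.
#'
#' @param evolved,ancestral Variant data frames sharing a coordinate system.
#' @param freq_threshold Ancestral frequency above which a call is
#'   blacklisted (default 0.015, strict inequality).
#' @param read_threshold Supporting-read count above which a call is
#'   blacklisted (default 3, strict inequality).
#' @return The filtered evolved table (same columns, subset of rows).
#' @examples
#' anc <- tibble::tibble(position = 10, var_class = "SNP_NS",
#'                       frequency = 0.02, supporting_reads = 4)
#' ev <- tibble::tibble(position = c(10, 20), var_class = "SNP_NS",
#'                      frequency = c(0.3, 0.4), supporting_reads = c(30, 40))
#' filter_ancestral_false_positives(ev, anc) # keeps only position 20
#' @export
filter_ancestral_false_positives <- function(evolved, ancestral,
                                             freq_threshold = 0.015,
                                             read_threshold = 3) {
  check_variants(evolved)
  if (!nrow(ancestral)) return(as_tibble(evolved))
  check_variants(ancestral, require = c("position", "frequency"))
  consensus <- if ("mode" %in% names(ancestral)) {
    ancestral$mode == "consensus"
  } else {
    rep(FALSE, nrow(ancestral))
  }
  reads <- if ("supporting_reads" %in% names(ancestral)) {
    ancestral$supporting_reads
  } else {
    rep(Inf, nrow(ancestral))
  }
  blacklist <- ancestral[consensus |
                           (ancestral$frequency > freq_threshold &
                              reads > read_threshold), , drop = FALSE]
  keys <- intersect(c("contig", "position", "allele"),
                    intersect(names(evolved), names(blacklist)))
  anti_join(as_tibble(evolved), as_tibble(blacklist), by = keys)
}

#' Count mutational events per strain and class
#'
#' @param tbl Variant data frame with columns `strain`, `mouse_id`,
#'   `var_class`.
#' @param n_mice Number of successfully co-colonized mice used as the
#'   denominator of per-mouse means (default: distinct mice in `tbl`, per
#'   strain).
#' @return Tibble with one row per (strain, var_class): `n`, plus repeated
#'   per-strain columns `total`, `mean_per_mouse` (total / n_mice, rounded
#'   half away from zero to one decimal), `sd_per_mouse` (SD of per-mouse
#'   event counts, zero-count mice included).
#' @examples
#' tbl <- tibble::tibble(strain = "B1", mouse_id = rep(1:2, c(3, 5)),
#'                       var_class = "SNP_NS")
#' count_events(tbl, n_mice = 2)
#' @export
count_events <- function(tbl, n_mice = NULL) {
  if (!nrow(tbl)) {
    return(tibble(strain = character(), var_class = character(),
                  n = integer(), total = integer(),
                  mean_per_mouse = numeric(), sd_per_mouse = numeric()))
  }
  check_variants(tbl, require = c("strain", "mouse_id", "var_class"))
  counts <- tbl %>%
    dplyr::count(.data$strain, .data$var_class, name = "n")
  per_strain <- tbl %>%
    group_by(.data$strain) %>%
    summarise(total = n(), n_mice_obs = n_distinct(.data$mouse_id),
              .groups = "drop")
  per_mouse_sd <- tbl %>%
    dplyr::count(.data$strain, .data$mouse_id, name = "k") %>%
    group_by(.data$strain) %>%
    summarise(sd_obs = sd(.data$k), .groups = "drop")
  counts %>%
    left_join(per_strain, by = "strain") %>%
    left_join(per_mouse_sd, by = "strain") %>%
    mutate(denom = if (is.null(n_mice)) .data$n_mice_obs else n_mice,
           mean_per_mouse = round_half_away(.data$total / .data$denom, 1),
           sd_per_mouse = .data$sd_obs) %>%
    select("strain", "var_class", "n", "total", "mean_per_mouse",
           "sd_per_mouse")
}

#' dN/dS as the raw ratio of non-synonymous to synonymous SNP counts
#'
#' As used for pooled within-host populations: the count ratio, not a
#' substitution-model-corrected estimate. With zero synonymous SNPs the
#' ratio is undefined (flagged, dN/dS reported `NA`) but still indicates
#' NS > 0.
#'
#' @param tbl Variant data frame with columns `strain`, `var_class`.
#' @return Tibble per strain: `n_nonsyn`, `n_syn`, `dnds`, `undefined`.
#' @export
dn_ds <- function(tbl) {
  check_variants(tbl, require = c("strain", "var_class"))
  tbl %>%
    group_by(.data$strain) %>%
    summarise(n_nonsyn = sum(.data$var_class == "SNP_NS"),
              n_syn = sum(.data$var_class == "SNP_S"),
              .groups = "drop") %>%
    mutate(dnds = ifelse(.data$n_syn > 0, .data$n_nonsyn / .data$n_syn,
                         NA_real_),
           undefined = .data$n_syn == 0)
}

#' Find selective sweeps: variants above a frequency threshold in a mouse
#'
#' @param tbl Variant data frame with columns `mouse_id`, `frequency`.
#' @param threshold Frequency a variant must strictly exceed (default 0.95,
#'   the ">95%" sweep rule).
#' @return The qualifying rows, with an added logical `fixed` column
#'   (frequency reached 100%), grouped-by-mouse ordering.
#' @export
find_sweeps <- function(tbl, threshold = 0.95) {
  check_variants(tbl, require = c("mouse_id", "frequency"))
  tbl %>%
    filter(.data$frequency > threshold) %>%
    mutate(fixed = .data$frequency >= 1) %>%
    arrange(.data$mouse_id, desc(.data$frequency))
}

#' Targets of parallel evolution across mice
#'
#' A target shows gene-level parallelism when mutational events hit it in at
#' least two different mice; mutation-level parallelism additionally
#' requires the identical change (same position and class, and same allele
#' when an `allele` column is present).
#'
#' @param tbl Variant data frame with columns `mouse_id`, `target`,
#'   `position`, `var_class` (and optionally `strain`, `allele`), covering
#'   at least two mice.
#' @return Tibble: (`strain` if present,) `target`, `level` (`"gene"` or
#'   `"mutation"`), `n_mice`, `mice` (comma-joined ids), ordered by
#'   descending `n_mice` then target name.
#' @export
parallel_targets <- function(tbl) {
  check_variants(tbl, require = c("mouse_id", "target", "position",
                                  "var_class"))
  if (n_distinct(tbl$mouse_id) < 2) {
    abort("Parallelism needs variant calls from at least two mice.")
  }
  grp_strain <- intersect("strain", names(tbl))
  has_allele <- "allele" %in% names(tbl)
  gene <- tbl %>%
    group_by(across(all_of(c(grp_strain, "target")))) %>%
    summarise(n_mice = n_distinct(.data$mouse_id),
              mice = paste(sort(unique(.data$mouse_id)), collapse = ","),
              .groups = "drop") %>%
    filter(.data$n_mice >= 2) %>%
    mutate(level = "gene")
  mut_keys <- c(grp_strain, "target", "position", "var_class",
                if (has_allele) "allele")
  mutation <- tbl %>%
    group_by(across(all_of(mut_keys))) %>%
    summarise(n_mice = n_distinct(.data$mouse_id),
              mice = paste(sort(unique(.data$mouse_id)), collapse = ","),
              .groups = "drop") %>%
    filter(.data$n_mice >= 2) %>%
    mutate(level = "mutation") %>%
    select(all_of(c(grp_strain, "target")), "n_mice", "mice", "level")
  bind_rows(gene, mutation) %>%
    select(all_of(c(grp_strain, "target")), "level", "n_mice", "mice") %>%
    arrange(desc(.data$n_mice), .data$target, .data$level)
}

#' Targets of convergent evolution between the two strains
#'
#' Reports genes mutated in both strains (gene level) and, when a pathway
#' map is supplied, targets whose pathways are hit in both strains (pathway
#' level). Each convergent target is labeled with whether the two strains
#' were hit in at least one common mouse.
#'
#' @param table_A,table_B1 Variant data frames (columns `mouse_id`,
#'   `target`) for strains A and B1.
#' @param pathway_map Optional data frame with columns `target`, `pathway`.
#' @return Tibble: `target` (gene, or pathway name at pathway level),
#'   `level`, `targets_A`, `targets_B1`, `same_mouse`.
#' @export
convergent_targets <- function(table_A, table_B1, pathway_map = NULL) {
  check_variants(table_A, require = c("mouse_id", "target"))
  check_variants(table_B1, require = c("mouse_id", "target"))
  shared_genes <- intersect(unique(table_A$target), unique(table_B1$target))
  gene_rows <- purrr::map_dfr(shared_genes, function(g) {
    tibble(target = g, level = "gene", targets_A = g, targets_B1 = g,
           same_mouse = length(intersect(
             table_A$mouse_id[table_A$target == g],
             table_B1$mouse_id[table_B1$target == g])) > 0)
  })
  path_rows <- tibble(target = character(), level = character(),
                      targets_A = character(), targets_B1 = character(),
                      same_mouse = logical())
  if (!is.null(pathway_map) && nrow(pathway_map)) {
    pm <- as_tibble(pathway_map)
    pa <- table_A %>% dplyr::inner_join(pm, by = "target")
    pb <- table_B1 %>% dplyr::inner_join(pm, by = "target")
    shared_paths <- intersect(unique(pa$pathway), unique(pb$pathway))
    path_rows <- purrr::map_dfr(shared_paths, function(p) {
      tibble(target = p, level = "pathway",
             targets_A = paste(sort(unique(pa$target[pa$pathway == p])),
                               collapse = ","),
             targets_B1 = paste(sort(unique(pb$target[pb$pathway == p])),
                                collapse = ","),
             same_mouse = length(intersect(
               pa$mouse_id[pa$pathway == p],
               pb$mouse_id[pb$pathway == p])) > 0)
    })
  }
  bind_rows(gene_rows, path_rows) %>% arrange(.data$level, .data$target)
}

#' Genomic rate of mutation accumulation M(t)
#'
#' Per mouse, M(t) is the sum of the allele frequencies of all detected
#' mutations divided by the number of elapsed generations; the strain-level
#' estimate is the mean (with SD) across co-colonized mice. Optionally also
#' normalized per base pair by a genome size.
#'
#' @param tbl Variant data frame with columns `mouse_id`, `frequency`.
#' @param generations Elapsed generations (> 0), e.g.
#'   `elapsed_generations(88)`.
#' @param n_mice Mice over which the mean is taken; mice absent from `tbl`
#'   contribute M(t) = 0. Default: distinct mice in `tbl`.
#' @param genome_size Optional genome size in bp for the normalized rate.
#' @return Object of class `"rate_result"`; use [tidy()] for per-mouse
#'   rates and [glance()] for the mean +/- SD.
#' @examples
#' tbl <- tibble::tibble(mouse_id = 1, frequency = 1)
#' glance(mutation_rate(tbl, generations = 1584))
#' @export
mutation_rate <- function(tbl, generations, n_mice = NULL,
                          genome_size = NULL) {
  if (generations <= 0) abort("`generations` must be > 0.")
  if (nrow(tbl)) check_variants(tbl, require = c("mouse_id", "frequency"))
  per_mouse <- if (nrow(tbl)) {
    tbl %>%
      group_by(.data$mouse_id) %>%
      summarise(freq_sum = sum(.data$frequency), .groups = "drop")
  } else {
    tibble(mouse_id = integer(), freq_sum = numeric())
  }
  if (!is.null(n_mice) && n_mice > nrow(per_mouse)) {
    extra <- n_mice - nrow(per_mouse)
    per_mouse <- bind_rows(per_mouse,
                           tibble(mouse_id = rep(NA, extra), freq_sum = 0))
  }
  per_mouse <- per_mouse %>%
    mutate(m_t = .data$freq_sum / generations,
           m_t_per_bp = if (is.null(genome_size)) NA_real_
                        else .data$m_t / genome_size)
  structure(list(per_mouse = per_mouse, generations = generations,
                 genome_size = genome_size),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  g <- glance(x)
  cat("<rate_result> M(t) =", signif(g$mean_m_t, 3), "+/-",
      signif(g$sd_m_t, 3), "(SD) per generation over", g$n_mice,
      "mice,", x$generations, "generations\n")
  invisible(x)
}

#' Per-mouse mutation-accumulation rates
#' @param x A `"rate_result"`.
#' @param ... Unused.
#' @return Tibble with `mouse_id`, `freq_sum`, `m_t`, `m_t_per_bp`.
#' @exportS3Method generics::tidy
tidy.rate_result <- function(x, ...) x$per_mouse

#' Strain-level mutation-accumulation summary
#' @param x A `"rate_result"`.
#' @param ... Unused.
#' @return One-row tibble: mean and SD of M(t) across mice, optional
#'   genome-size-normalized mean, generations and mouse count used.
#' @exportS3Method generics::glance
glance.rate_result <- function(x, ...) {
  m <- x$per_mouse$m_t
  tibble(mean_m_t = if (length(m)) mean(m) else 0,
         sd_m_t = if (length(m) > 1) sd(m) else NA_real_,
         mean_m_t_per_bp = if (is.null(x$genome_size)) NA_real_
                           else mean(m) / x$genome_size,
         n_mice = length(m),
         generations = x$generations)
}
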