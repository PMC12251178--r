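#' Mobile-element presence frequency from coverage ratios
#'
#' Estimates the within-population frequency at which a genomic element
#' (prophage, large deletion region) is present, as the mean of the ratios
#' between the median read depth inside the element and the median depths of
#' its left and right flanks. The excision/deletion frequency is
#' `1 - presence`.
#'
#' @param coverage Data frame of per-base depth: columns `position`
#'   (0-based) and `depth` (and optionally `contig`).
#' @param region Length-2 numeric, half-open `[start, end)` element
#'   coordinates.
#' @param flank_size Flank width in bp on each side (default 5000).
#' @return One-row tibble: `median_region`, `median_left`, `median_right`,
#'   `presence_raw` (unclipped mean ratio), `presence` (clipped to [0, 1]),
#'   `deletion_frequency` (`1 - presence`).
#' @examples
#' cov <- tibble::tibble(position = 0:299, depth = rep(c(60, 30, 60), each = 100))
#' element_presence_frequency(cov, region = c(100, 200), flank_size = 100)
#' @export
element_presence_frequency <- function(coverage, region, flank_size = 5000) {
  stopifnot(all(c("position", "depth") %in% names(coverage)),
            length(region) == 2, region[2] > region[1], flank_size > 0)
  if (any(coverage$depth < 0)) abort("Depths must be >= 0.")
  pos <- coverage$position
  in_region <- pos >= region[1] & pos < region[2]
  in_left <- pos >= region[1] - flank_size & pos < region[1]
  in_right <- pos >= region[2] & pos < region[2] + flank_size
  if (!any(in_left) || !any(in_right)) {
    abort("Both flanks must contain coverage positions.")
  }
  med_r <- median(coverage$depth[in_region])
  med_l <- median(coverage$depth[in_left])
  med_rt <- median(coverage$depth[in_right])
  if (med_l <= 0 || med_rt <= 0) {
    abort("Flank median depth is zero; cannot form coverage ratios.")
  }
  raw <- mean(c(med_r / med_l, med_r / med_rt))
  presence <- min(max(raw, 0), 1)
  tibble(median_region = med_r, median_left = med_l, median_right = med_rt,
         presence_raw = raw, presence = presence,
         deletion_frequency = 1 - presence)
}

# does `seq` match `ref` exactly over [start, start + nchar) (0-based),
# in forward or reverse-complement orientation
matches_ref <- function(seq, start, ref) {
  len <- nchar(seq)
  end <- start + len
  if (start < 0 || end > nchar(ref)) return(FALSE)
  sub <- substr(ref, start + 1, end)
  seq == sub || revcomp(seq) == sub
}

#' Classify a variant as a potential horizontal gene transfer (HGT) event
#'
#' Emulates the read-level decision rule used on breseq variant calls: for
#' the reads overlapping a variant position, a read "matches" a reference
#' when it is identical to the reference sequence over its full span
#' (forward or reverse complement); the variant is flagged as a potential
#' HGT event when strictly more than `threshold` (default 1%) of the
#' overlapping reads match the non-equivalent ("donor") reference genome.
#' Reads matching neither reference are counted in neither tally.
#'
#' @param reads Data frame of reads with columns `start` (0-based leftmost
#'   position) and `seq`.
#' @param donor_ref,recipient_ref Reference sequences (single character
#'   strings) on a shared coordinate system.
#' @param position 0-based variant position.
#' @param threshold Donor-read fraction that must be strictly exceeded
#'   (default 0.01).
#' @return One-row tibble: `position`, `n_reads`, `n_match_donor`,
#'   `n_match_recipient`, `donor_fraction`, `hgt_flag`, `no_call` (TRUE when
#'   no read overlaps the position).
#' @export
classify_hgt_variant <- function(reads, donor_ref, recipient_ref, position,
                                 threshold = 0.01) {
  stopifnot(all(c("start", "seq") %in% names(reads)),
            is.character(donor_ref), is.character(recipient_ref))
  len <- nchar(reads$seq)
  ov <- reads$start <= position & position < reads$start + len
  n <- sum(ov)
  if (n == 0) {
    return(tibble(position = position, n_reads = 0L, n_match_donor = 0L,
                  n_match_recipient = 0L, donor_fraction = NA_real_,
                  hgt_flag = NA, no_call = TRUE))
  }
  sub <- reads[ov, , drop = FALSE]
  md <- vapply(seq_len(nrow(sub)), function(i) {
    matches_ref(sub$seq[i], sub$start[i], donor_ref)
  }, logical(1))
  mr <- vapply(seq_len(nrow(sub)), function(i) {
    matches_ref(sub$seq[i], sub$start[i], recipient_ref)
  }, logical(1))
  # a read identical in both references is uninformative for donor origin
  n_donor <- sum(md & !mr)
  n_recip <- sum(mr & !md)
  frac <- n_donor / n
  tibble(position = position, n_reads = n, n_match_donor = n_donor,
         n_match_recipient = n_recip, donor_fraction = frac,
         hgt_flag = frac > threshold, no_call = FALSE)
}

#' Merge flagged HGT variants into transferred tracts
#'
#' Flagged variant positions closer than `max_gap` are merged into
#' half-open tracts, each reported with its span and mean donor fraction.
#'
#' @param flagged Data frame of flagged variants with columns `position`
#'   and (optionally) `donor_fraction`, sorted by position.
#' @param max_gap Maximum gap in bp between variants of one tract
#'   (default 1000).
#' @return Tibble: `start`, `end` (half-open), `n_variants`,
#'   `mean_donor_fraction`.
#' @examples
#' hgt_tract_extent(tibble::tibble(position = c(100, 200, 5000)), 1000)
#' @export
hgt_tract_extent <- function(flagged, max_gap = 1000) {
  stopifnot("position" %in% names(flagged), max_gap >= 0)
  if (!nrow(flagged)) {
    return(tibble(start = numeric(), end = numeric(), n_variants = integer(),
                  mean_donor_fraction = numeric()))
  }
  if (is.unsorted(flagged$position)) {
    abort("Flagged variants must be sorted by position.")
  }
  df <- as_tibble(flagged)
  if (!"donor_fraction" %in% names(df)) df$donor_fraction <- NA_real_
  df %>%
    mutate(tract = cumsum(c(TRUE, diff(.data$position) > max_gap))) %>%
    group_by(.data$tract) %>%
    summarise(start = min(.data$position), end = max(.data$position) + 1,
              n_variants = n(),
              mean_donor_fraction = mean(.data$donor_fraction),
              .groups = "drop") %>%
    select(-"tract")
}
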