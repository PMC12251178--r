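#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; summary reports here follow the
#' convention of rounding halves away from zero (so 10.25 -> 10.3 at one
#' decimal), matching how per-mouse means are conventionally printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(10.25, 1) # 10.3
#' round_half_away(-0.5)     # -1
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Convert days of colonization to bacterial generations
#'
#' The gut-colonization literature for E. coli assumes roughly 18 generations
#' per day; 88 days of co-colonization correspond to 1584 generations and
#' 43 days to 774.
#'
#' @param days Number of days (>= 0).
#' @param gens_per_day Generations per day (default 18).
#' @return `days * gens_per_day`.
#' @examples
#' elapsed_generations(88) # 1584
#' elapsed_generations(43) # 774
#' @export
elapsed_generations <- function(days, gens_per_day = 18) {
  stopifnot(is.numeric(days), all(days >= 0), gens_per_day > 0)
  days * gens_per_day
}

#' Read a tab-separated table, allowing `#` comment lines
#'
#' All tabular interchange in this package is TSV with optional `#`-prefixed
#' comment/metadata lines.
#'
#' @param path File path.
#' @param ... Passed to [readr::read_tsv()].
#' @return A tibble.
#' @export
read_tsv_commented <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Write a tab-separated table with optional `#` comment header
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param header Optional character vector of metadata lines, written with a
#'   leading `"# "` before the column header.
#' @return `x`, invisibly.
#' @export
write_tsv_commented <- function(x, path, header = NULL) {
  if (length(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(x)
}

# reverse complement without requiring Biostrings for plain character data
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}
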