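# Recombination-breakpoint inference from variant tables: quality/depth
# filtering, per-site allele-depth-ratio genotype states, 50-kb window
# summaries, and run-based breakpoint calling at window-state transitions.

#' Read a single-sample VCF into a variant tibble
#'
#' Extracts GT, AD and DP from the FORMAT fields. Multiallelic records use
#' the first alternate allele's depth; the number of such records is
#' attached as the `n_multiallelic` attribute.
#'
#' @param path VCF path (plain text or gzipped).
#' @return a tibble with columns `contig`, `pos` (1-based), `qual`,
#'   `ref_depth`, `alt_depth`, `total_depth`, `gt`.
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  dp <- suppressWarnings(
    as.numeric(vcfR::extract.gt(vcf, element = "DP")[, 1])
  )
  ad_split <- strsplit(unname(ifelse(is.na(ad), "0,0", ad)), ",",
                       fixed = TRUE)
  ref_depth <- purrr::map_dbl(ad_split, ~ suppressWarnings(as.numeric(.x[1])))
  alt_depth <- purrr::map_dbl(
    ad_split,
    ~ if (length(.x) >= 2) suppressWarnings(as.numeric(.x[2])) else 0
  )
  out <- tibble(
    contig = fix$CHROM,
    pos = as.numeric(fix$POS),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    ref_depth = ref_depth,
    alt_depth = alt_depth,
    total_depth = ifelse(is.na(dp), ref_depth + alt_depth, dp),
    gt = unname(gt)
  )
  attr(out, "n_multiallelic") <- sum(lengths(ad_split) > 2)
  out
}

#' Read a variant table from TSV
#'
#' Columns `contig`, `pos`, `qual`, `ref_depth`, `alt_depth`,
#' `total_depth` (and optionally `gt`).
#'
#' @param path TSV path.
#' @return a variant tibble as in [read_variants_vcf()].
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Filter variants on quality and a depth-quantile band
#'
#' Keeps records with `qual > qual_min` and total depth inside the
#' inclusive quantile band of the input set's own depth distribution
#' (default the 25-75% range), the filtering applied to long-read variant
#' calls before genotype-state classification. Quantiles use R's default
#' linear-interpolation definition (type 7) unless overridden.
#'
#' @param records a variant tibble.
#' @param qual_min quality threshold; records must exceed it (default 30).
#' @param depth_quantiles lower/upper quantile probabilities (default
#'   `c(0.25, 0.75)`).
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return the filtered tibble; the depth band used is attached as the
#'   `depth_band` attribute. Empty input returns empty output with a
#'   warning.
#' @export
filter_variants <- function(records, qual_min = 30,
                            depth_quantiles = c(0.25, 0.75),
                            quantile_type = 7) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    warn("no variant records to filter")
    return(records)
  }
  band <- stats::quantile(records$total_depth, probs = depth_quantiles,
                          type = quantile_type, names = FALSE, na.rm = TRUE)
  out <- records[
    !is.na(records$qual) & records$qual > qual_min &
      records$total_depth >= band[1] & records$total_depth <= band[2],
  ]
  attr(out, "depth_band") <- band
  out
}

#' Alternate allele-depth ratio
#'
#' `alt / (ref + alt)`; undefined (NA) when both depths are zero.
#'
#' @param ref_depth,alt_depth per-allele read depths (vectorised).
#' @return the AD ratio in \[0, 1\], or `NA` where `ref + alt = 0`.
#' @export
#' @examples
#' ad_ratio(1, 9)
ad_ratio <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  ifelse(total > 0, alt_depth / total, NA_real_)
}

#' Classify a site's genotype state from its AD ratio
#'
#' Ratio `>= 0.9` is `alternate`, `<= 0.1` is `reference`, `[0.3, 0.7]`
#' is `heterozygous`; ratios in the open gaps `(0.1, 0.3)` and
#' `(0.7, 0.9)` — and undefined ratios — are `uncertain`. The four states
#' partition \[0, 1\].
#'
#' @param ratio AD ratio in \[0, 1\] (vectorised; NA allowed).
#' @param thresholds the four band edges
#'   `(reference_max, het_min, het_max, alternate_min)`.
#' @return a character vector of states.
#' @export
#' @examples
#' classify_state(c(0.95, 0.05, 0.5, 0.2))
classify_state <- function(ratio, thresholds = c(0.1, 0.3, 0.7, 0.9)) {
  stopifnot(length(thresholds) == 4, !is.unsorted(thresholds))
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE)) {
    abort("AD ratios must lie in [0, 1]")
  }
  dplyr::case_when(
    is.na(ratio) ~ "uncertain",
    ratio >= thresholds[4] ~ "alternate",
    ratio <= thresholds[1] ~ "reference",
    ratio >= thresholds[2] & ratio <= thresholds[3] ~ "heterozygous",
    TRUE ~ "uncertain"
  )
}

#' Attach AD ratios and genotype states to a variant table
#'
#' @param records a variant tibble (typically after [filter_variants()]).
#' @param thresholds passed to [classify_state()].
#' @return the tibble with `ad_ratio` and `state` columns added.
#' @export
site_states <- function(records, thresholds = c(0.1, 0.3, 0.7, 0.9)) {
  records <- as_tibble(records)
  records$ad_ratio <- ad_ratio(records$ref_depth, records$alt_depth)
  records$state <- classify_state(records$ad_ratio, thresholds)
  records
}

STATE_DOSE <- c(reference = 0, heterozygous = 0.5, alternate = 1)

#' Summarise genotype states in tiling windows
#'
#' Tiles the contig with fixed, non-overlapping windows and counts the
#' classified states in each. `alternate_frequency` is the fraction of
#' alternate-classified sites among classified (non-uncertain) sites;
#' `mean_dose` averages the allele dose (reference 0, heterozygous 0.5,
#' alternate 1) over the same sites and is what breakpoint calling labels
#' windows on. With `freq_method = "depth"` the alternate frequency is
#' instead computed from summed allele depths in the window.
#'
#' @param states output of [site_states()], sorted by position.
#' @param window_size window width in bp (default 50000).
#' @param contig_length contig length in bp; defaults to the last site's
#'   position.
#' @param freq_method `"site"` (count classified sites; default) or
#'   `"depth"` (sum allele depths).
#' @return a `window_summary` tibble: `window`, `start`, `end` (0-based
#'   half-open), per-state counts, `classified`, `alternate_frequency`,
#'   `mean_dose`, `empty`.
#' @export
window_states <- function(states, window_size = 50000, contig_length = NULL,
                          freq_method = c("site", "depth")) {
  freq_method <- match.arg(freq_method)
  if (window_size <= 0) abort("`window_size` must be positive")
  states <- as_tibble(states)
  contig_length <- contig_length %||%
    if (nrow(states)) max(states$pos) else window_size
  n_windows <- ceiling(contig_length / window_size)
  # VCF positions are 1-based; windows tile [0, w), [w, 2w), ...
  win_of <- pmin(floor((states$pos - 1) / window_size), n_windows - 1)
  grid <- tibble(
    window = seq_len(n_windows) - 1L,
    start = (seq_len(n_windows) - 1) * window_size,
    end = pmin(seq_len(n_windows) * window_size, contig_length)
  )
  per_state <- states |>
    dplyr::mutate(window = win_of) |>
    dplyr::count(.data$window, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L)
  for (s in c("reference", "heterozygous", "alternate", "uncertain")) {
    if (!s %in% names(per_state)) per_state[[s]] <- 0L
  }
  out <- dplyr::left_join(grid, per_state, by = "window") |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("reference", "heterozygous", "alternate", "uncertain")),
      ~ dplyr::coalesce(.x, 0L)
    ))
  out$classified <- out$reference + out$heterozygous + out$alternate
  if (freq_method == "site") {
    out$alternate_frequency <- ifelse(out$classified > 0,
                                      out$alternate / out$classified, NA_real_)
  } else {
    depth_sum <- states |>
      dplyr::mutate(window = win_of) |>
      dplyr::filter(.data$state != "uncertain") |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(alt = sum(.data$alt_depth),
                       tot = sum(.data$ref_depth + .data$alt_depth),
                       .groups = "drop")
    out <- dplyr::left_join(out, depth_sum, by = "window")
    out$alternate_frequency <- ifelse(
      !is.na(out$tot) & out$tot > 0, out$alt / out$tot, NA_real_
    )
    out$alt <- out$tot <- NULL
  }
  out$mean_dose <- ifelse(
    out$classified > 0,
    (out$alternate + 0.5 * out$heterozygous) / out$classified,
    NA_real_
  )
  out$empty <- out$classified == 0
  structure(out, contig = states$contig[1] %||% "contig",
            class = c("window_summary", class(tibble())))
}

label_windows <- function(windows, high, low, het_band) {
  dplyr::case_when(
    windows$empty | is.na(windows$mean_dose) ~ "empty",
    windows$mean_dose >= high ~ "alternate",
    windows$mean_dose <= low ~ "reference",
    windows$mean_dose >= het_band[1] & windows$mean_dose <= het_band[2] ~
      "heterozygous",
    TRUE ~ "ambiguous"
  )
}

#' Call recombination breakpoints from window-state transitions
#'
#' Labels each window by its mean allele dose (alternate-like at
#' `>= high`, reference-like at `<= low`, heterozygous-like inside the
#' per-site band), then emits a breakpoint between the last window of each
#' homogeneous run of at least `min_run` windows and the first window of
#' the next differing run. When the per-site states are supplied, the
#' interval is narrowed to the gap between the outermost classified sites
#' of the two flanking windows.
#'
#' @param windows a `window_summary` from [window_states()], in order.
#' @param high,low window mean-dose thresholds for alternate-like /
#'   reference-like labels (defaults 0.9 / 0.1).
#' @param het_band mean-dose band for heterozygous-like windows (default
#'   `c(0.3, 0.7)`, the per-site bands).
#' @param min_run minimum run length (windows) for a state to anchor a
#'   breakpoint (default 2).
#' @param states optional [site_states()] table used to narrow intervals.
#' @return a `breakpoints` tibble: `contig`, `start`, `end` (bp interval
#'   bracketing the transition), `left_state`, `right_state`,
#'   `left_window`, `right_window`. Fewer than `2 * min_run` windows give
#'   no calls, with a warning.
#' @export
call_breakpoints <- function(windows, high = 0.9, low = 0.1,
                             het_band = c(0.3, 0.7), min_run = 2,
                             states = NULL) {
  windows <- as_tibble(windows)
  contig <- attr(windows, "contig") %||% "contig"
  if (nrow(windows) < 2 * min_run) {
    warn("too few windows to call breakpoints")
    return(empty_breakpoints())
  }
  lab <- label_windows(windows, high, low, het_band)
  informative <- which(!lab %in% c("empty", "ambiguous"))
  if (length(informative) == 0) return(empty_breakpoints())
  r <- rle(lab[informative])
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  qual <- which(r$lengths >= min_run)
  if (length(qual) < 2) return(empty_breakpoints())
  calls <- purrr::map(seq_len(length(qual) - 1), function(i) {
    a <- qual[i]; b <- qual[i + 1]
    if (r$values[a] == r$values[b]) return(NULL)
    wl <- informative[run_end[a]]    # last window of left run
    wr <- informative[run_start[b]]  # first window of right run
    start <- windows$start[wl]
    end <- windows$end[wr]
    if (!is.null(states)) {
      st <- as_tibble(states)
      cl <- st[st$state != "uncertain", ]
      in_l <- cl$pos - 1 >= windows$start[wl] & cl$pos - 1 < windows$end[wl]
      in_r <- cl$pos - 1 >= windows$start[wr] & cl$pos - 1 < windows$end[wr]
      if (any(in_l)) start <- max(cl$pos[in_l]) - 1
      if (any(in_r)) end <- min(cl$pos[in_r])
    }
    tibble(
      contig = contig, start = start, end = end,
      left_state = r$values[a], right_state = r$values[b],
      left_window = windows$window[wl], right_window = windows$window[wr]
    )
  })
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0) return(empty_breakpoints())
  structure(out, class = c("breakpoints", class(tibble())))
}

empty_breakpoints <- function() {
  structure(
    tibble(contig = character(), start = numeric(), end = numeric(),
           left_state = character(), right_state = character(),
           left_window = integer(), right_window = integer()),
    class = c("breakpoints", class(tibble()))
  )
}

#' Write breakpoint intervals as BED
#'
#' @param breakpoints a `breakpoints` tibble from [call_breakpoints()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_breakpoints_bed <- function(breakpoints, path) {
  df <- tibble(
    contig = breakpoints$contig,
    start = format(breakpoints$start, scientific = FALSE, trim = TRUE),
    end = format(breakpoints$end, scientific = FALSE, trim = TRUE),
    name = paste0(breakpoints$left_state, ">", breakpoints$right_state)
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Plot window allele dose with called breakpoints
#'
#' @param object a `window_summary` tibble.
#' @param breakpoints optional `breakpoints` tibble to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot window_summary
#' @export
autoplot.window_summary <- function(object, breakpoints = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df[!df$empty, ],
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$mean_dose)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "mean allele dose") +
    ggplot2::theme_minimal()
  if (!is.null(breakpoints) && nrow(breakpoints)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(breakpoints),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "firebrick",
      inherit.aes = FALSE
    )
  }
  p
}
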