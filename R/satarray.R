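# Satellite-array representation: an ordered tibble of annotated units
# (repeat monomers, TE islands, flanks) over a 0-based half-open locus
# coordinate system, plus repeat classification, copy counting, copy-number
# change and qPCR relative abundance.

UNIT_CLASSES <- c(
  "repeat-left", "repeat-right", "repeat-variant", "repeat-truncated",
  "te-island", "flank-proximal", "flank-distal", "other"
)
REPEAT_CLASSES <- UNIT_CLASSES[1:4]

#' Construct a satellite array from a unit table
#'
#' A satellite array is an ordered, non-overlapping set of annotated units
#' (repeat monomers, transposable-element islands, flanking blocks) on one
#' contig, the in-memory form of a higher-order-repeat locus such as *Rsp*
#' with its tandem left/right dimers and interspersed TE islands. Units are
#' stored as a tibble with 0-based half-open coordinates; the optional locus
#' sequence travels as an attribute.
#'
#' @param units a data frame with columns `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`), `unit_class` (one of
#'   `r paste0('\x60', UNIT_CLASSES, '\x60', collapse = ", ")`), `family`
#'   (free-text family label, e.g. `"L-Rsp"`, `"G5"`, `"AAGAG"`), and
#'   optionally `identity` (fraction in \[0,1\] vs consensus) and `score`
#'   (alignment bitscore).
#' @param contig contig identifier.
#' @param sequence optional nucleotide string for the locus; when present,
#'   every unit must end at or before its length.
#' @return a `sat_array`: a tibble of units sorted by `start`, with
#'   attributes `contig` and `sequence`.
#' @export
#' @examples
#' sat_array(tibble::tibble(
#'   start = c(0, 120), end = c(120, 240), strand = "+",
#'   unit_class = c("repeat-left", "repeat-right"),
#'   family = c("L-Rsp", "R-Rsp")
#' ))
sat_array <- function(units, contig = "locus", sequence = NULL) {
  units <- as_tibble(units)
  required <- c("start", "end", "strand", "unit_class", "family")
  missing <- setdiff(required, names(units))
  if (length(missing)) {
    abort(paste0("unit table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"identity" %in% names(units)) units$identity <- NA_real_
  if (!"score" %in% names(units)) units$score <- NA_real_
  if (any(units$end <= units$start)) abort("every unit must satisfy start < end")
  bad_class <- setdiff(unique(units$unit_class), UNIT_CLASSES)
  if (length(bad_class)) {
    abort(paste0("unknown unit_class value(s): ", paste(bad_class, collapse = ", ")))
  }
  ok_id <- is.na(units$identity) | (units$identity >= 0 & units$identity <= 1)
  if (!all(ok_id)) abort("identity must lie in [0, 1] when present")
  units <- dplyr::arrange(units, .data$start, .data$end)
  if (nrow(units) > 1) {
    ov <- which(units$start[-1] < units$end[-nrow(units)])
    if (length(ov)) {
      pairs <- paste0(
        "[", units$start[ov], ",", units$end[ov], ") overlaps [",
        units$start[ov + 1], ",", units$end[ov + 1], ")"
      )
      abort(c("overlapping units are not allowed:", pairs))
    }
  }
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1)
    sequence <- toupper(sequence)
    if (nrow(units) && max(units$end) > nchar(sequence)) {
      abort("unit coordinates extend beyond the supplied sequence")
    }
  }
  structure(
    units,
    contig = contig, sequence = sequence,
    class = c("sat_array", class(tibble()))
  )
}

#' @export
print.sat_array <- function(x, ...) {
  seq_note <- if (is.null(attr(x, "sequence"))) "no sequence" else
    paste0(nchar(attr(x, "sequence")), " bp sequence")
  cat(sprintf(
    "# satellite array on %s: %d units, %s\n",
    attr(x, "contig"), nrow(x), seq_note
  ))
  NextMethod()
}

array_contig <- function(array) attr(array, "contig") %||% "locus"
array_sequence <- function(array) attr(array, "sequence")

#' Parse repeat annotations into a satellite array
#'
#' Reads BED (0-based half-open, native) or RepeatMasker `.out`-style records
#' (1-based inclusive, converted on read) and maps family labels to unit
#' classes. Overlapping units are an input error because the array model
#' requires a linear unit order.
#'
#' @param x a file path or a data frame. For `dialect = "bed"` the columns
#'   are chrom/start/end/name/score/strand (name = family label). For
#'   `dialect = "repeatmasker"` the standard 15-column `.out` table is
#'   expected (a data frame may instead carry columns `contig`, `begin`,
#'   `end`, `strand`, `family`, `score`).
#' @param dialect `"bed"` or `"repeatmasker"`.
#' @param class_map a data frame with columns `family` and `unit_class`
#'   mapping family labels to unit classes; labels not covered fall back to
#'   `"other"` (or to a class already present in a `unit_class` column).
#'   `default_class_map()` covers the common *Rsp*-locus labels.
#' @return a [sat_array()].
#' @export
parse_annotation <- function(x, dialect = c("bed", "repeatmasker"),
                             class_map = default_class_map()) {
  dialect <- match.arg(dialect)
  raw <- if (is.character(x) && length(x) == 1) {
    if (dialect == "bed") read_repeat_bed(x) else read_repeatmasker_out(x)
  } else {
    df <- as_tibble(x)
    if (dialect == "repeatmasker") {
      # a data frame in the repeatmasker dialect uses 1-based inclusive begin
      df <- dplyr::rename(df, start = "begin")
      df$start <- df$start - 1
    }
    df
  }
  contigs <- unique(raw$contig)
  if (length(contigs) > 1) {
    abort("annotation records reference more than one contig")
  }
  units <- dplyr::mutate(
    raw,
    unit_class = map_family_class(.data$family, class_map,
                                  existing = raw[["unit_class"]])
  )
  keep <- intersect(
    c("start", "end", "strand", "unit_class", "family", "identity", "score"),
    names(units)
  )
  sat_array(units[keep], contig = if (length(contigs)) contigs else "locus")
}

map_family_class <- function(family, class_map, existing = NULL) {
  if (!is.null(existing)) return(existing)
  cm <- as_tibble(class_map)
  cls <- cm$unit_class[match(family, cm$family)]
  dplyr::coalesce(cls, "other")
}

#' Default family-label to unit-class map for an *Rsp*-like locus
#'
#' @return a tibble with columns `family` and `unit_class`.
#' @export
default_class_map <- function() {
  tibble(
    family = c("L-Rsp", "R-Rsp", "Rsp-var", "Rsp-trunc",
               "G5", "Bari1", "AAGAG", "TE-distal"),
    unit_class = c("repeat-left", "repeat-right", "repeat-variant",
                   "repeat-truncated", "te-island", "te-island",
                   "flank-proximal", "flank-distal")
  )
}

#' Read a 6-column BED file of repeat units
#'
#' @param path BED file, 0-based half-open, with the family label in the
#'   name column.
#' @return a tibble with columns contig, start, end, family, score, strand.
#' @export
read_repeat_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(n < 3)[1]))
  }
  get <- function(i, default) {
    purrr::map_chr(fields, function(f) if (length(f) >= i) f[i] else default)
  }
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  }
  tibble(
    contig = get(1, "locus"),
    start = start, end = end,
    family = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = ifelse(get(6, "+") %in% c("+", "-"), get(6, "+"), "+")
  )
}

#' Read a RepeatMasker .out-style table
#'
#' Parses the whitespace-separated `.out` format (1-based inclusive query
#' coordinates, strand `C` meaning minus) and converts coordinates to
#' 0-based half-open.
#'
#' @param path path to the `.out` file; the up-to-3-line header is skipped.
#' @return a tibble with columns contig, start, end, strand, family, score,
#'   identity (fraction, from the divergence column).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # drop the banner lines (start with "SW" or "score" headers)
  lines <- lines[!grepl("^(SW|score|bit)", lines, ignore.case = TRUE)]
  fields <- strsplit(lines, "\\s+")
  n <- lengths(fields)
  if (any(n < 11)) {
    abort(sprintf("malformed RepeatMasker line %d: fewer than 11 fields",
                  which(n < 11)[1]))
  }
  f <- function(i) purrr::map_chr(fields, i)
  begin <- suppressWarnings(as.numeric(f(6)))
  end <- suppressWarnings(as.numeric(f(7)))
  bad <- which(is.na(begin) | is.na(end))
  if (length(bad)) {
    abort(sprintf("malformed RepeatMasker line %d: non-numeric coordinates",
                  bad[1]))
  }
  tibble(
    contig = f(5),
    start = begin - 1,  # 1-based inclusive -> 0-based half-open
    end = end,
    strand = ifelse(f(9) == "C", "-", "+"),
    family = f(10),
    score = suppressWarnings(as.numeric(f(1))),
    identity = pmax(0, 1 - suppressWarnings(as.numeric(f(2))) / 100)
  )
}

#' Write a satellite array as BED
#'
#' @param array a [sat_array()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_repeat_bed <- function(array, path) {
  df <- tibble(
    contig = array_contig(array),
    start = format(array$start, scientific = FALSE, trim = TRUE),
    end = format(array$end, scientific = FALSE, trim = TRUE),
    family = array$family,
    score = ifelse(is.na(array$score), 0, array$score),
    strand = array$strand
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write a satellite array as a RepeatMasker-style .out table
#'
#' Coordinates are emitted 1-based inclusive, strand `-` as `C`, matching
#' the `.out` convention read back by [read_repeatmasker_out()].
#'
#' @inheritParams write_repeat_bed
#' @return the path, invisibly.
#' @export
write_repeatmasker_out <- function(array, path) {
  div <- ifelse(is.na(array$identity), 0, (1 - array$identity) * 100)
  lines <- sprintf(
    "%s %.1f 0.0 0.0 %s %d %d (0) %s %s Unknown 1 %d (0) %d",
    ifelse(is.na(array$score), 0, array$score), div,
    array_contig(array),
    as.integer(array$start) + 1L, as.integer(array$end),
    ifelse(array$strand == "-", "C", "+"),
    array$family, as.integer(array$end - array$start), seq_len(nrow(array))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Classify alignment hits into repeat-unit classes
#'
#' Applies the length / identity / bitscore rules used for repeat curation:
#' hits shorter than `length_min` are `repeat-truncated` (truncation is a
#' structural property, so the length test has precedence); full-length hits
#' below the identity or bitscore-ratio threshold are `repeat-variant`; the
#' rest are `repeat-left` / `repeat-right` according to which consensus
#' (query label) produced the hit. The bitscore threshold is a ratio of the
#' hit bitscore to the bitscore of a perfect self-alignment of the consensus.
#'
#' @param hits a data frame of alignment hits with columns `query_label`
#'   (consensus name, e.g. `"L-Rsp"`), `subject_start`, `subject_end`
#'   (0-based half-open), `percent_identity` (0-100), `alignment_length`
#'   (bp), `bitscore` and `strand`.
#' @param consensus_length consensus length in bp (> 0).
#' @param length_min minimum alignment length in bp for a full-length unit
#'   (default 90).
#' @param identity_min minimum percent identity for a canonical unit
#'   (default 90).
#' @param bitscore_ratio_min minimum hit-bitscore / self-alignment-bitscore
#'   ratio for a canonical unit (default 0.7).
#' @param self_bitscore bitscore of a perfect self-alignment of the
#'   consensus; defaults to `2 * consensus_length`, the usual blastn
#'   approximation of ~2 bits per matched base.
#' @param query_classes named character vector mapping query labels to the
#'   canonical classes.
#' @return a unit tibble (columns start, end, strand, unit_class, family,
#'   identity, score, flagged) suitable for [sat_array()]; `flagged` marks
#'   hits longer than twice the consensus.
#' @export
#' @examples
#' hits <- tibble::tibble(
#'   query_label = c("L-Rsp", "R-Rsp", "L-Rsp"),
#'   subject_start = c(0, 120, 240), subject_end = c(120, 240, 300),
#'   percent_identity = c(95, 85, 99),
#'   alignment_length = c(120, 120, 60),
#'   bitscore = c(216, 150, 110), strand = "+"
#' )
#' classify_units(hits, consensus_length = 120)
classify_units <- function(hits, consensus_length,
                           length_min = 90, identity_min = 90,
                           bitscore_ratio_min = 0.7,
                           self_bitscore = 2 * consensus_length,
                           query_classes = c("L-Rsp" = "repeat-left",
                                             "R-Rsp" = "repeat-right")) {
  if (consensus_length <= 0) abort("`consensus_length` must be positive")
  hits <- as_tibble(hits)
  if (any(hits$alignment_length < 1)) abort("alignment_length must be >= 1")
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    abort("percent_identity must lie in [0, 100]")
  }
  ratio <- hits$bitscore / self_bitscore
  base_class <- unname(query_classes[hits$query_label])
  base_class[is.na(base_class)] <- ifelse(
    grepl("^L", hits$query_label[is.na(base_class)], ignore.case = TRUE),
    "repeat-left", "repeat-right"
  )
  cls <- dplyr::case_when(
    hits$alignment_length < length_min ~ "repeat-truncated",
    hits$percent_identity < identity_min | ratio < bitscore_ratio_min ~
      "repeat-variant",
    TRUE ~ base_class
  )
  tibble(
    start = hits$subject_start,
    end = hits$subject_end,
    strand = hits$strand,
    unit_class = cls,
    family = hits$query_label,
    identity = hits$percent_identity / 100,
    score = hits$bitscore,
    flagged = hits$alignment_length > 2 * consensus_length
  )
}

#' Count repeat copies per unit class
#'
#' Tallies units per class; `total_repeats` sums the four repeat classes
#' (left, right, variant, truncated) and excludes TE islands, flanks and
#' `other` units.
#'
#' @param array a [sat_array()] or a unit tibble with a `unit_class` column.
#' @return a one-row tibble with one count column per unit class
#'   (underscored names) plus `total_repeats`.
#' @export
#' @examples
#' count_copies(sat_array(tibble::tibble(
#'   start = c(0, 120), end = c(120, 240), strand = "+",
#'   unit_class = c("repeat-left", "te-island"),
#'   family = c("L-Rsp", "G5")
#' )))
count_copies <- function(array) {
  counts <- table(factor(array$unit_class, levels = UNIT_CLASSES))
  out <- as_tibble(as.list(as.integer(counts)), .name_repair = "minimal")
  names(out) <- gsub("-", "_", UNIT_CLASSES)
  out$total_repeats <- sum(counts[REPEAT_CLASSES])
  out
}

#' Percent copy-number change between a parent and a derived allele
#'
#' Signed percentage `100 * (subline - parent) / parent`; negative values
#' are deletions, positive values expansions.
#'
#' @param parent_total parent-allele repeat total (> 0).
#' @param subline_total derived-allele repeat total.
#' @return signed percent change (vectorised).
#' @export
#' @examples
#' percent_change(1756, 851)   # ~ -51.5
percent_change <- function(parent_total, subline_total) {
  if (any(parent_total <= 0)) abort("`parent_total` must be positive")
  100 * (subline_total - parent_total) / parent_total
}

#' qPCR relative abundance by the delta-delta-Ct method
#'
#' Fold-change of a target satellite relative to a single-copy reference
#' (e.g. *Rsp* normalised to *tRNA-Lys-CTT*), comparing a sample line to a
#' control (parent) line: `2^-((ct_ts - ct_rs) - (ct_tc - ct_rc))`, assuming
#' amplification efficiency 2 per cycle.
#'
#' @param ct_target_sample,ct_ref_sample target and reference Ct in the
#'   sample line.
#' @param ct_target_control,ct_ref_control target and reference Ct in the
#'   control line.
#' @return fold-ratio of target abundance, sample vs control (vectorised).
#' @export
#' @examples
#' relative_abundance(24, 20, 25, 20)  # one cycle earlier -> 2-fold
relative_abundance <- function(ct_target_sample, ct_ref_sample,
                               ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) abort("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Plot a satellite array as a colour-coded unit map
#'
#' @param object a [sat_array()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sat_array
#' @export
autoplot.sat_array <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = 1, fill = .data$unit_class)
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", array_contig(object)),
      y = NULL, fill = "unit class"
    ) +
    ggplot2::theme_minimal()
}
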