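# Guide-RNA target-site search: PAM-aware, IUPAC-aware, mismatch-tolerant
# scanning of both strands; spatial clustering of cut sites; target-site
# survival between parent and edited alleles.

#' Describe a guide RNA
#'
#' @param name guide name (e.g. `"Rsp-g1"`).
#' @param protospacer the 17-24 nt protospacer sequence (IUPAC codes
#'   allowed).
#' @param pam the PAM pattern immediately 3' of the protospacer, as IUPAC
#'   (default `"NGG"` for SpCas9).
#' @param max_mismatches maximum protospacer mismatches tolerated when
#'   counting target sites (default 0, i.e. perfect on-target matches).
#' @return a one-row `guide_spec` tibble.
#' @export
#' @examples
#' guide_spec("g1", "GATTACAGATTACAGATTAC")
guide_spec <- function(name, protospacer, pam = "NGG", max_mismatches = 0L) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) < 17 || nchar(protospacer) > 24) {
    abort("protospacer length must be 17-24 nt")
  }
  if (!is_iupac(protospacer) || !is_iupac(pam)) {
    abort("guide contains non-IUPAC characters")
  }
  check_count(max_mismatches, "max_mismatches")
  structure(
    tibble(name = name, protospacer = protospacer, pam = pam,
           max_mismatches = as.integer(max_mismatches)),
    class = c("guide_spec", class(tibble()))
  )
}

#' Read guides from a TSV file
#'
#' Expects columns `name`, `protospacer` and optionally `pam`,
#' `max_mismatches`.
#'
#' @param path TSV path.
#' @return a `guide_spec` tibble, one row per guide.
#' @export
read_guides_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"pam" %in% names(df)) df$pam <- "NGG"
  if (!"max_mismatches" %in% names(df)) df$max_mismatches <- 0L
  out <- purrr::pmap(df[c("name", "protospacer", "pam", "max_mismatches")],
                     guide_spec)
  dplyr::bind_rows(out)
}

as_guide <- function(guide) {
  g <- as.list(as_tibble(guide)[1, ])
  guide_spec(g$name %||% "guide", g$protospacer, g$pam %||% "NGG",
             g$max_mismatches %||% 0L)
}

# membership matrix: match_ok[pattern_char, sequence_char]; sequence N (or any
# ambiguity code in the subject) never counts as a match
iupac_match_matrix <- function() {
  pat <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(pat), 4, dimnames = list(pat, c("A", "C", "G", "T")))
  for (p in pat) m[p, IUPAC_SETS[[p]]] <- TRUE
  m
}

# per-offset protospacer mismatch counts and PAM matches on one strand
scan_strand <- function(seq_ch, proto_ch, pam_ch) {
  n <- length(seq_ch)
  m <- length(proto_ch)
  p <- length(pam_ch)
  if (n < m + p) {
    return(tibble(position = integer(), mismatches = integer()))
  }
  mm <- iupac_match_matrix()
  code <- match(seq_ch, c("A", "C", "G", "T"))  # NA for N / anything else
  starts <- seq_len(n - m - p + 1)
  mism <- integer(length(starts))
  for (j in seq_len(m)) {
    ok <- unname(mm[proto_ch[j], ])[code[starts + j - 1]]
    ok[is.na(ok)] <- FALSE
    mism <- mism + !ok
  }
  pam_ok <- rep(TRUE, length(starts))
  for (j in seq_len(p)) {
    ok <- unname(mm[pam_ch[j], ])[code[starts + m + j - 1]]
    ok[is.na(ok)] <- FALSE
    pam_ok <- pam_ok & ok
  }
  tibble(position = starts - 1L, mismatches = mism)[pam_ok, ]
}

#' Find guide-RNA target sites in a sequence
#'
#' Scans both strands for protospacer matches with at most
#' `max_mismatches` mismatches followed immediately 3' by an exact
#' IUPAC-pattern PAM match. `N` in the sequence never counts as a match.
#' Positions are reported as the 0-based start of the protospacer projected
#' onto the plus strand; the cut position is the blunt SpCas9 cut 3 bp 5'
#' of the PAM (between protospacer positions 17 and 18 for a 20-nt guide).
#'
#' @param sequence a nucleotide string (alphabet ACGTN).
#' @param guide a [guide_spec()] (or any one-row data frame with the same
#'   columns).
#' @return a tibble of target sites sorted by position: `guide`, `position`,
#'   `strand`, `mismatches`, `cut_position`.
#' @export
#' @examples
#' g <- guide_spec("g1", "ACGTACGTACGTACGTACGT")
#' find_target_sites(paste0("TTTT", "ACGTACGTACGTACGTACGT", "AGG", "TT"), g)
find_target_sites <- function(sequence, guide) {
  guide <- as_guide(guide)
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  seq_ch <- seq_chars(sequence)
  bad <- setdiff(unique(seq_ch), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    abort(paste0("sequence alphabet must be ACGTN; found: ",
                 paste(bad, collapse = ", ")))
  }
  proto <- seq_chars(guide$protospacer)
  pam <- seq_chars(guide$pam)
  m <- length(proto)
  p <- length(pam)
  n <- length(seq_ch)

  plus <- scan_strand(seq_ch, proto, pam)
  plus <- plus[plus$mismatches <= guide$max_mismatches, ]
  minus_raw <- scan_strand(rev(unname(COMPLEMENT[seq_ch])), proto, pam)
  minus_raw <- minus_raw[minus_raw$mismatches <= guide$max_mismatches, ]

  out <- dplyr::bind_rows(
    dplyr::mutate(plus, strand = "+",
                  cut_position = .data$position + m - 3L),
    dplyr::mutate(minus_raw,
                  position = n - .data$position - m,
                  strand = "-",
                  cut_position = .data$position + 3L)
  )
  out <- dplyr::arrange(out, .data$position, .data$strand)
  dplyr::select(
    dplyr::mutate(out, guide = guide$name),
    "guide", "position", "strand", "mismatches", "cut_position"
  )
}

#' Target-site survival between a parent and an edited allele
#'
#' Counts how many target sites of a guide remain in an edited sequence,
#' relative to the sites present on the parent allele — the readout used to
#' judge how completely an editing round consumed its target sites.
#'
#' @param parent_sites sites found on the parent allele with
#'   [find_target_sites()].
#' @param edited_sequence the edited allele sequence.
#' @param guide the [guide_spec()] used for both searches.
#' @return a one-row tibble: `remaining`, `parent`, `fraction`
#'   (`NA` when the parent had no sites).
#' @export
site_survival <- function(parent_sites, edited_sequence, guide) {
  remaining <- nrow(find_target_sites(edited_sequence, guide))
  parent <- nrow(parent_sites)
  tibble(
    remaining = remaining,
    parent = parent,
    fraction = if (parent > 0) remaining / parent else NA_real_
  )
}

#' Cluster target sites by cut-site proximity
#'
#' Single-linkage clustering of cut positions: consecutive sites whose cut
#' positions differ by at most `gap_threshold` join the same cluster;
#' clusters are maximal and ordered along the sequence. Distinct spatial
#' clusters of cut sites predict distinct deletion classes under multi-cut
#' repair.
#'
#' @param sites a site tibble from [find_target_sites()].
#' @param gap_threshold maximum gap (bp) between consecutive cut positions
#'   within one cluster (> 0).
#' @return a tibble with one row per cluster: `cluster`, `n_sites`,
#'   `cut_start`, `cut_end`, and a `sites` list-column of member sites;
#'   `gap_threshold` is attached as an attribute.
#' @export
#' @examples
#' s <- tibble::tibble(cut_position = c(100, 200, 300, 50000, 50100))
#' cluster_sites(s, gap_threshold = 1000)
cluster_sites <- function(sites, gap_threshold) {
  if (gap_threshold <= 0) abort("`gap_threshold` must be positive")
  sites <- dplyr::arrange(as_tibble(sites), .data$cut_position)
  if (nrow(sites) == 0) {
    return(tibble(cluster = integer(), n_sites = integer(),
                  cut_start = numeric(), cut_end = numeric(),
                  sites = list()))
  }
  id <- cumsum(c(1L, as.integer(diff(sites$cut_position) > gap_threshold)))
  sites$cluster <- id
  out <- sites |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      cut_start = min(.data$cut_position),
      cut_end = max(.data$cut_position),
      sites = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
  attr(out, "gap_threshold") <- gap_threshold
  out
}

#' Write target sites as BED
#'
#' One line per site over the protospacer span, mismatch count in the score
#' column and the guide name in the name column.
#'
#' @param sites a site tibble from [find_target_sites()].
#' @param path output path.
#' @param contig contig name for the first column.
#' @param protospacer_length protospacer length used to compute spans.
#' @return the path, invisibly.
#' @export
write_sites_bed <- function(sites, path, contig = "locus",
                            protospacer_length = 20) {
  df <- tibble(
    contig = contig,
    start = sites$position,
    end = sites$position + protospacer_length,
    name = sites$guide,
    score = sites$mismatches,
    strand = sites$strand
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
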