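# Multi-cut editing simulator: sample cleaved target sites, repair by an
# explicit end-joining rule (or recombination with a homolog), and report the
# surviving array. Exercises the cleavage-load idea that many simultaneous
# cuts produce a small set of discrete deletion classes determined by the
# spatial clusters of cut sites.

#' Specify an editing / repair model
#'
#' @param cleavage_prob probability that each target site is cleaved in one
#'   nucleus; a scalar or one value per site.
#' @param repair_rule how the cleaved ends re-join: `"adjacent-join"` drops
#'   each segment between consecutive cleaved cuts independently with
#'   probability 1/2 before religation; `"outermost-join"` deletes everything
#'   between the first and last cleaved cut; `"random-pair-join"` deletes
#'   between one uniformly chosen pair of cleaved cuts.
#' @param expansion_prob probability that a repair event resolves instead by
#'   recombination with a homologous array, splicing in the homolog's
#'   inter-cut segment (single crossover at the locus).
#' @param homolog a [sat_array()] carried by the homolog; required when
#'   `expansion_prob > 0`.
#' @param homolog_sites target sites on the homolog (from
#'   [find_target_sites()] on its sequence, or planted truth).
#' @param lethality_midpoint optional number of cuts at which half of the
#'   outcomes die (logistic dose response on cuts made); `NULL` (default)
#'   disables lethality.
#' @param lethality_steepness slope of the lethality logistic.
#' @return an `edit_model` list.
#' @export
edit_model <- function(cleavage_prob = 1,
                       repair_rule = c("adjacent-join", "outermost-join",
                                       "random-pair-join"),
                       expansion_prob = 0,
                       homolog = NULL, homolog_sites = NULL,
                       lethality_midpoint = NULL, lethality_steepness = 1) {
  repair_rule <- match.arg(repair_rule)
  check_prob(cleavage_prob, "cleavage_prob")
  check_prob(expansion_prob, "expansion_prob")
  if (expansion_prob > 0 && (is.null(homolog) || is.null(homolog_sites))) {
    abort("expansion requires `homolog` and `homolog_sites`")
  }
  structure(
    list(cleavage_prob = cleavage_prob, repair_rule = repair_rule,
         expansion_prob = expansion_prob, homolog = homolog,
         homolog_sites = homolog_sites,
         lethality_midpoint = lethality_midpoint,
         lethality_steepness = lethality_steepness),
    class = "edit_model"
  )
}

# site span on the + projection, PAM included
site_spans <- function(sites, protospacer_length, pam_length) {
  tibble(
    span_start = ifelse(sites$strand == "-",
                        sites$position - pam_length, sites$position),
    span_end = ifelse(sites$strand == "-",
                      sites$position + protospacer_length,
                      sites$position + protospacer_length + pam_length)
  )
}

# units fully clear of every deleted (open) interval, re-coordinated so the
# retained segments are contiguous
apply_deletions <- function(units, deleted) {
  if (nrow(deleted) == 0) return(units)
  keep <- rep(TRUE, nrow(units))
  shift <- rep(0, nrow(units))
  for (i in seq_len(nrow(deleted))) {
    a <- deleted$from[i]; b <- deleted$to[i]
    keep <- keep & (units$end <= a | units$start >= b)
    shift <- shift + ifelse(units$start >= b, b - a, 0)
  }
  out <- units[keep, ]
  out$start <- out$start - shift[keep]
  out$end <- out$end - shift[keep]
  out
}

count_surviving_spans <- function(spans, deleted) {
  if (nrow(deleted) == 0) return(nrow(spans))
  keep <- rep(TRUE, nrow(spans))
  for (i in seq_len(nrow(deleted))) {
    keep <- keep &
      (spans$span_end <= deleted$from[i] | spans$span_start >= deleted$to[i])
  }
  sum(keep)
}

#' Simulate post-CRISPR allele structures of a tandem array
#'
#' Each replicate independently cleaves every target site with the model's
#' cleavage probability. Fewer than two cuts leaves the array untouched
#' (`no-edit`); otherwise the cleaved ends re-join under the repair rule,
#' deleting the intervening units, or — with the model's expansion
#' probability — recombine with the homolog, splicing its segment between
#' the outermost cut pair in place of the deleted one (`expansion`).
#' Units partially overlapping a deleted interval are destroyed, not
#' retained as fragments.
#'
#' @param parent a [sat_array()].
#' @param sites target sites on the parent (from [find_target_sites()]);
#'   every cut position must lie inside the parent coordinates.
#' @param model an [edit_model()].
#' @param replicates number of independent outcomes to draw.
#' @param seed optional integer seed; fixed seeds give identical outcome
#'   lists.
#' @param protospacer_length,pam_length geometry used to decide which target
#'   sites survive (a site survives when its full protospacer+PAM span lies
#'   inside one retained contiguous block).
#' @return an `edit_outcomes` tibble with one row per (surviving) replicate:
#'   `replicate`, `event_class` (`no-edit`/`deletion`/`expansion`),
#'   `cuts_made`, `copy_total`, `surviving_sites`, and a `units` list-column
#'   of the surviving unit tibbles. The parent copy total is attached as an
#'   attribute.
#' @export
simulate_editing <- function(parent, sites, model, replicates,
                             seed = NULL,
                             protospacer_length = 20, pam_length = 3) {
  check_count(replicates, "replicates", min = 1L)
  units <- as_tibble(parent)
  locus_end <- if (!is.null(array_sequence(parent))) {
    nchar(array_sequence(parent))
  } else if (nrow(units)) max(units$end) else 0
  cuts <- sites$cut_position
  if (any(cuts < 0 | cuts > locus_end)) {
    abort("target site outside the parent array coordinates")
  }
  nsites <- length(cuts)
  p <- rep_len(model$cleavage_prob, nsites)
  spans <- site_spans(sites, protospacer_length, pam_length)
  parent_total <- count_copies(units)$total_repeats

  hom_units <- if (!is.null(model$homolog)) as_tibble(model$homolog) else NULL
  hom_cuts <- if (!is.null(model$homolog_sites)) {
    sort(model$homolog_sites$cut_position)
  } else NULL
  hom_spans <- if (!is.null(model$homolog_sites)) {
    site_spans(model$homolog_sites, protospacer_length, pam_length)
  } else NULL

  draw_one <- function(rep_i) {
    cleaved <- stats::runif(nsites) < p
    ncuts <- sum(cleaved)
    if (ncuts < 2) {
      return(tibble(
        replicate = rep_i, event_class = "no-edit", cuts_made = ncuts,
        copy_total = parent_total, surviving_sites = nsites,
        units = list(units)
      ))
    }
    cc <- sort(cuts[cleaved])
    expanded <- model$expansion_prob > 0 &&
      stats::runif(1) < model$expansion_prob
    if (expanded) {
      a <- cc[1]; b <- cc[ncuts]
      ha <- hom_cuts[1]; hb <- hom_cuts[length(hom_cuts)]
      left <- units[units$end <= a, ]
      right <- units[units$start >= b, ]
      mid <- hom_units[hom_units$start >= ha & hom_units$end <= hb, ]
      if (nrow(mid)) {
        mid$start <- mid$start - ha + a
        mid$end <- mid$end - ha + a
      }
      delta <- (hb - ha) - (b - a)
      if (nrow(right)) {
        right$start <- right$start + delta
        right$end <- right$end + delta
      }
      new_units <- dplyr::bind_rows(left, mid, right)
      surv <- count_surviving_spans(spans, tibble(from = a, to = b)) +
        sum(hom_spans$span_start >= ha & hom_spans$span_end <= hb)
      return(tibble(
        replicate = rep_i, event_class = "expansion", cuts_made = ncuts,
        copy_total = count_copies(new_units)$total_repeats,
        surviving_sites = surv, units = list(new_units)
      ))
    }
    deleted <- switch(
      model$repair_rule,
      "outermost-join" = tibble(from = cc[1], to = cc[ncuts]),
      "adjacent-join" = {
        drop <- stats::runif(ncuts - 1) < 0.5
        tibble(from = cc[-ncuts][drop], to = cc[-1][drop])
      },
      "random-pair-join" = {
        pair <- sort(sample.int(ncuts, 2))
        tibble(from = cc[pair[1]], to = cc[pair[2]])
      }
    )
    deleted <- deleted[deleted$to > deleted$from, ]
    new_units <- apply_deletions(units, deleted)
    tibble(
      replicate = rep_i, event_class = "deletion", cuts_made = ncuts,
      copy_total = count_copies(new_units)$total_repeats,
      surviving_sites = count_surviving_spans(spans, deleted),
      units = list(new_units)
    )
  }

  run <- function() {
    out <- dplyr::bind_rows(purrr::map(seq_len(replicates), draw_one))
    if (!is.null(model$lethality_midpoint)) {
      p_die <- stats::plogis(
        model$lethality_steepness *
          (out$cuts_made - model$lethality_midpoint)
      )
      out <- out[stats::runif(nrow(out)) >= p_die, ]
    }
    out
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, parent_total = parent_total,
            class = c("edit_outcomes", class(tibble())))
}

#' Histogram of outcome copy totals with modal classes
#'
#' Bins the copy totals of simulated (or observed) editing outcomes and
#' reports the occupied bins; the number of occupied bins is the number of
#' discrete outcome classes, and bins tied for the highest count are marked
#' modal.
#'
#' @param outcomes an `edit_outcomes` tibble (or any data frame with a
#'   `copy_total` column).
#' @param bin_width bin width in repeat copies (> 0).
#' @return a tibble with `bin_start`, `bin_mid`, `n`, `modal`; the class
#'   count equals the number of rows.
#' @export
outcome_classes <- function(outcomes, bin_width) {
  if (bin_width <= 0) abort("`bin_width` must be positive")
  if (nrow(outcomes) == 0) abort("`outcomes` must be non-empty")
  bin <- floor(outcomes$copy_total / bin_width) * bin_width
  out <- tibble(bin_start = bin) |>
    dplyr::count(.data$bin_start, name = "n") |>
    dplyr::mutate(bin_mid = .data$bin_start + bin_width / 2,
                  modal = .data$n == max(.data$n)) |>
    dplyr::select("bin_start", "bin_mid", "n", "modal")
  out
}

#' Plot the distribution of simulated allele sizes
#'
#' @param object an `edit_outcomes` tibble.
#' @param bin_width histogram bin width in copies.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot edit_outcomes
#' @export
autoplot.edit_outcomes <- function(object, bin_width = 25, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$copy_total,
                               fill = .data$event_class)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "parent_total"),
                        linetype = "dashed") +
    ggplot2::labs(x = "repeat copy total", y = "outcomes",
                  fill = "event class") +
    ggplot2::theme_minimal()
}

#' Write editing outcomes as TSV
#'
#' @param outcomes an `edit_outcomes` tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_outcomes_tsv <- function(outcomes, path) {
  readr::write_tsv(
    dplyr::select(as_tibble(outcomes), -dplyr::any_of("units")), path
  )
  invisible(path)
}
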