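# Meiotic-drive statistics: viability-corrected drive strength k from cross
# counts, exact binomial confidence intervals, and Fisher's exact comparison
# of drive sensitivity between genotypes.

#' Viability factor from a reciprocal cross
#'
#' In the reciprocal cross (heterozygous SD/+ mother) transmission is
#' Mendelian, so any departure of the SD:wild-type offspring ratio from 1:1
#' estimates the relative viability of SD-bearing offspring rather than
#' drive. That ratio is the correction factor applied to the male cross.
#'
#' @param n_sd,n_plus offspring counts from the reciprocal (female
#'   heterozygote) cross; both must be positive.
#' @return the viability factor `v = n_sd / n_plus`.
#' @export
#' @examples
#' viability_factor(48, 52)
viability_factor <- function(n_sd, n_plus) {
  if (any(n_plus <= 0) || any(n_sd <= 0)) {
    abort("both reciprocal counts must be positive for viability correction")
  }
  n_sd / n_plus
}

#' Viability-corrected drive strength k
#'
#' Drive strength `k` is the proportion of offspring from a heterozygous
#' SD/+ father that inherit SD: 0.5 is Mendelian segregation, 1.0 perfect
#' drive. The raw proportion is corrected for viability by rescaling the
#' SD count by `1/v`, where `v` comes from [viability_factor()] on the
#' reciprocal cross: `k_corrected = (n_sd/v) / (n_sd/v + n_plus)`. An
#' exact (Clopper-Pearson) confidence interval on the raw proportion is
#' reported alongside.
#'
#' @param n_sd,n_plus offspring counts from the male-heterozygote cross;
#'   the total must be positive.
#' @param v viability factor (default 1, i.e. no correction).
#' @param conf_level confidence level for the exact interval.
#' @return a one-row tibble: `n_sd`, `n_plus`, `v`, `k_raw`,
#'   `k_corrected`, `ci_lo`, `ci_hi`.
#' @export
#' @examples
#' k_value(96, 4, v = viability_factor(48, 52))
k_value <- function(n_sd, n_plus, v = 1, conf_level = 0.95) {
  if (n_sd < 0 || n_plus < 0 || n_sd + n_plus <= 0) {
    abort("offspring counts must be non-negative with a positive total")
  }
  if (v <= 0) abort("`v` must be positive")
  k_raw <- n_sd / (n_sd + n_plus)
  adj <- n_sd / v
  ci <- stats::binom.test(round(n_sd), round(n_sd + n_plus),
                          conf.level = conf_level)$conf.int
  tibble(
    n_sd = n_sd, n_plus = n_plus, v = v,
    k_raw = k_raw,
    k_corrected = adj / (adj + n_plus),
    ci_lo = ci[1], ci_hi = ci[2]
  )
}

#' Fisher's exact test between two crosses
#'
#' Two-sided exact test on the 2x2 table of (SD, wild-type) counts from two
#' crosses, by summing all hypergeometric table probabilities no larger
#' than that of the observed table (probability-mass rule, with the usual
#' 1 + 1e-7 rounding guard).
#'
#' @param counts_a,counts_b length-2 vectors `c(n_sd, n_plus)` for the two
#'   crosses.
#' @return the two-sided p-value. Degenerate margins give `p = 1` with a
#'   warning.
#' @export
#' @examples
#' drive_test(c(90, 10), c(50, 50))
drive_test <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2, length(counts_b) == 2)
  tab <- c(counts_a, counts_b)
  if (any(tab < 0) || any(tab != floor(tab))) {
    abort("counts must be non-negative integers")
  }
  n1 <- sum(counts_a)
  n2 <- sum(counts_b)
  kcol <- counts_a[1] + counts_b[1]
  if (n1 == 0 || n2 == 0 || kcol == 0 || kcol == n1 + n2) {
    warn("degenerate table margins; p = 1")
    return(1)
  }
  support <- max(0, kcol - n2):min(kcol, n1)
  probs <- stats::dhyper(support, n1, n2, kcol)
  p_obs <- stats::dhyper(counts_a[1], n1, n2, kcol)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Estimate drive strength per line from a cross-count table
#'
#' Pairs each line's male-heterozygote cross with its reciprocal
#' (female-heterozygote) cross, estimates the viability factor from the
#' reciprocal, and returns viability-corrected k per line. Lines without a
#' reciprocal cross get `v = 1`.
#'
#' @param crosses a data frame with columns `line_id`, `parent_sex`
#'   (`"male"` or `"female"`, the heterozygous parent), `n_sd`, `n_plus`.
#'   Replicate rows per line and sex are pooled.
#' @param conf_level confidence level for the exact intervals.
#' @return a `drive_fit` object; use [tidy()] for per-line estimates,
#'   [glance()] for a one-row summary, [drive_contrasts()] for exact-test
#'   comparisons, and [autoplot()] to plot.
#' @export
estimate_drive <- function(crosses, conf_level = 0.95) {
  crosses <- as_tibble(crosses)
  pooled <- crosses |>
    dplyr::group_by(.data$line_id, .data$parent_sex) |>
    dplyr::summarise(n_sd = sum(.data$n_sd), n_plus = sum(.data$n_plus),
                     .groups = "drop")
  males <- dplyr::filter(pooled, .data$parent_sex == "male")
  females <- dplyr::filter(pooled, .data$parent_sex == "female")
  est <- purrr::pmap(males, function(line_id, parent_sex, n_sd, n_plus) {
    rec <- females[females$line_id == line_id, ]
    v <- if (nrow(rec) == 1) viability_factor(rec$n_sd, rec$n_plus) else 1
    dplyr::bind_cols(tibble(line_id = line_id),
                     k_value(n_sd, n_plus, v, conf_level))
  })
  structure(
    list(estimates = dplyr::bind_rows(est), data = pooled,
         conf_level = conf_level),
    class = "drive_fit"
  )
}

#' @export
print.drive_fit <- function(x, ...) {
  cat(sprintf("# drive fit: %d line(s), %.0f%% exact CIs\n",
              nrow(x$estimates), 100 * x$conf_level))
  print(x$estimates)
  invisible(x)
}

#' @rdname estimate_drive
#' @param x a `drive_fit`.
#' @param ... unused.
#' @method tidy drive_fit
#' @export
tidy.drive_fit <- function(x, ...) x$estimates

#' @rdname estimate_drive
#' @method glance drive_fit
#' @export
glance.drive_fit <- function(x, ...) {
  tibble(
    n_lines = nrow(x$estimates),
    total_offspring = sum(x$estimates$n_sd + x$estimates$n_plus),
    mean_k = mean(x$estimates$k_corrected),
    max_k = max(x$estimates$k_corrected)
  )
}

#' Pairwise exact-test comparison of drive sensitivity against a baseline
#'
#' @param fit a `drive_fit` from [estimate_drive()].
#' @param baseline the `line_id` to compare every other line against.
#' @return a tibble with `line_id` and the two-sided Fisher exact
#'   `p_value` on the male-cross counts versus the baseline line.
#' @export
drive_contrasts <- function(fit, baseline) {
  est <- fit$estimates
  if (!baseline %in% est$line_id) abort("baseline line not found")
  base <- est[est$line_id == baseline, ]
  others <- est[est$line_id != baseline, ]
  tibble(
    line_id = others$line_id,
    baseline = baseline,
    p_value = purrr::map2_dbl(
      others$n_sd, others$n_plus,
      ~ drive_test(c(.x, .y), c(base$n_sd, base$n_plus))
    )
  )
}

#' Plot per-line drive estimates
#'
#' @param object a `drive_fit`.
#' @param ... unused.
#' @return a ggplot of corrected k per line with exact CIs on the raw
#'   proportion; the dashed line marks Mendelian segregation.
#' @method autoplot drive_fit
#' @export
autoplot.drive_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$line_id,
                                    y = .data$k_corrected)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "drive strength k (viability-corrected)") +
    ggplot2::theme_minimal()
}

#' Read a cross-count table from TSV
#'
#' Columns `line_id`, `parent_sex`, `n_sd`, `n_plus`.
#'
#' @param path TSV path.
#' @return a tibble.
#' @export
read_crosses_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
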