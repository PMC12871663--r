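# Seeded synthetic-data generators: satellite arrays with higher-order
# left/right dimer structure, variant tables with recombinant tracts, and
# cross-count tables under a known drive strength — every fixture carries its
# own truth so the rest of the pipeline can be tested without external data.

#' Specify a synthetic satellite array
#'
#' Describes an array of tandem left/right repeat dimers with mutational
#' divergence, occasional truncated units, interspersed TE islands, a
#' proximal simple-satellite flank (AAGAG by default) and a distal TE
#' block — the structural features of the *Rsp* locus. Defaults emulate
#' the parent array: 878 dimers (1756 repeat monomers of ~120 bp) with two
#' interior TE islands.
#'
#' @param n_dimers number of left/right dimers (default 878).
#' @param unit_length repeat monomer length in bp (default 120).
#' @param left_consensus,right_consensus consensus monomer sequences; when
#'   `NULL` they are generated from the seed.
#' @param mutation_rate per-base substitution probability per unit
#'   (default 0.02).
#' @param truncation_prob probability a unit is truncated (default 0.02).
#' @param truncation_range length range (bp) for truncated units.
#' @param te_islands tibble with columns `after_dimer` and `length`:
#'   TE blocks inserted after the given dimer indices.
#' @param proximal_motif simple-repeat motif of the proximal flank.
#' @param proximal_length,distal_length flank lengths in bp.
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return an `array_spec` list.
#' @export
array_spec <- function(n_dimers = 878, unit_length = 120,
                       left_consensus = NULL, right_consensus = NULL,
                       mutation_rate = 0.02, truncation_prob = 0.02,
                       truncation_range = c(30, 89),
                       te_islands = tibble(
                         after_dimer = c(293, 586), length = c(4000, 4000)
                       ),
                       proximal_motif = "AAGAG",
                       proximal_length = 1000, distal_length = 5000,
                       seed = 1L) {
  check_count(n_dimers, "n_dimers")
  check_prob(mutation_rate, "mutation_rate")
  check_prob(truncation_prob, "truncation_prob")
  if (!is.null(left_consensus) && !is.null(right_consensus) &&
      nchar(left_consensus) != nchar(right_consensus)) {
    abort("left and right consensus sequences must have equal length")
  }
  structure(
    list(n_dimers = n_dimers, unit_length = unit_length,
         left_consensus = left_consensus, right_consensus = right_consensus,
         mutation_rate = mutation_rate, truncation_prob = truncation_prob,
         truncation_range = truncation_range,
         te_islands = as_tibble(te_islands),
         proximal_motif = proximal_motif,
         proximal_length = proximal_length, distal_length = distal_length,
         seed = as.integer(seed)),
    class = "array_spec"
  )
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_unit <- function(consensus_ch, rate, trunc_len = NA) {
  L0 <- length(consensus_ch)
  ch <- if (is.na(trunc_len)) consensus_ch else consensus_ch[seq_len(trunc_len)]
  L <- length(ch)
  n_mut <- rbinom(1, L, rate)
  if (n_mut > 0) {
    at <- sample.int(L, n_mut)
    for (i in at) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
  }
  list(seq = paste(ch, collapse = ""), length = L, n_mut = n_mut)
}

#' Generate a synthetic satellite array with known truth
#'
#' Emits the locus sequence, a truth annotation classifying every unit by
#' the same length/identity/bitscore rules used by [classify_units()]
#' (match +2, mismatch -3, self-alignment 2 bits/bp), the truth copy
#' summary, and a truth alignment-hit table that reproduces those labels
#' when fed to [classify_units()]. Optionally plants a guide's
#' protospacer+PAM at the start of chosen dimers and records the planted
#' positions.
#'
#' @param spec an [array_spec()].
#' @param plant_guide optional [guide_spec()] whose protospacer+PAM is
#'   written into the left monomer of the dimers in `plant_at`.
#' @param plant_at integer dimer indices receiving a planted site.
#' @return a list: `array` (a [sat_array()] with the sequence attached),
#'   `sequence`, `truth` (copy summary), `hits` (truth alignment hits),
#'   `planted_sites` (tibble of planted 0-based positions and cut
#'   positions).
#' @export
gen_array <- function(spec, plant_guide = NULL, plant_at = integer()) {
  withr::with_seed(spec$seed, {
    ul <- spec$unit_length
    left <- spec$left_consensus %||% random_seq(ul)
    right <- spec$right_consensus %||% random_seq(ul)
    left_ch <- seq_chars(left)
    right_ch <- seq_chars(right)

    segs <- character()
    units <- list()
    hits <- list()
    pos <- 0

    add_unit <- function(seq, cls, family, identity, score) {
      units[[length(units) + 1]] <<- tibble(
        start = pos, end = pos + nchar(seq), strand = "+",
        unit_class = cls, family = family,
        identity = identity, score = score
      )
      segs[[length(segs) + 1]] <<- seq
      pos <<- pos + nchar(seq)
    }

    if (spec$proximal_length > 0) {
      flank <- strtrim(
        strrep(spec$proximal_motif,
               ceiling(spec$proximal_length / nchar(spec$proximal_motif))),
        spec$proximal_length
      )
      add_unit(flank, "flank-proximal", spec$proximal_motif, NA_real_,
               NA_real_)
    }

    te_after <- spec$te_islands$after_dimer %||% integer()
    for (d in seq_len(spec$n_dimers)) {
      for (side in c("L", "R")) {
        cons_ch <- if (side == "L") left_ch else right_ch
        label <- if (side == "L") "L-Rsp" else "R-Rsp"
        trunc <- runif(1) < spec$truncation_prob
        tl <- if (trunc) {
          sample(spec$truncation_range[1]:spec$truncation_range[2], 1)
        } else NA
        m <- mutate_unit(cons_ch, spec$mutation_rate, tl)
        pid <- 100 * (m$length - m$n_mut) / m$length
        bits <- 2 * (m$length - m$n_mut) - 3 * m$n_mut
        cls <- if (m$length < 90) {
          "repeat-truncated"
        } else if (pid < 90 || bits / (2 * ul) < 0.7) {
          "repeat-variant"
        } else if (side == "L") "repeat-left" else "repeat-right"
        hits[[length(hits) + 1]] <- tibble(
          query_label = label, subject_start = pos,
          subject_end = pos + m$length,
          percent_identity = pid, alignment_length = m$length,
          bitscore = bits, strand = "+"
        )
        add_unit(m$seq, cls, label, pid / 100, bits)
      }
      isl <- which(te_after == d)
      for (i in isl) {
        add_unit(random_seq(spec$te_islands$length[i]), "te-island", "G5",
                 NA_real_, NA_real_)
      }
    }

    if (spec$distal_length > 0) {
      add_unit(random_seq(spec$distal_length), "flank-distal", "Bari1",
               NA_real_, NA_real_)
    }

    sequence <- paste(segs, collapse = "")
    units <- dplyr::bind_rows(units)

    planted <- tibble(position = numeric(), cut_position = numeric())
    if (!is.null(plant_guide) && length(plant_at)) {
      g <- as_guide(plant_guide)
      pam <- gsub("N", "A", g$pam)  # a concrete PAM instance
      insert <- paste0(g$protospacer, pam)
      m <- nchar(g$protospacer)
      seq_ch <- seq_chars(sequence)
      left_starts <- units$start[units$family == "L-Rsp" &
                                   units$end - units$start >= nchar(insert)]
      at <- left_starts[plant_at]
      for (a in at) {
        seq_ch[(a + 1):(a + nchar(insert))] <- seq_chars(insert)
      }
      sequence <- paste(seq_ch, collapse = "")
      planted <- tibble(position = at, strand = "+",
                        cut_position = at + m - 3)
    }

    arr <- sat_array(units, contig = "satellite_locus", sequence = sequence)
    list(
      array = arr,
      sequence = sequence,
      truth = count_copies(arr),
      hits = dplyr::bind_rows(hits),
      planted_sites = planted
    )
  })
}

#' Specify a synthetic variant-table layout
#'
#' Describes a contig partitioned into genotype tracts (reference /
#' heterozygous / alternate), site density, a negative-binomial read-depth
#' model and per-site misclassification noise — emulating a recombinant
#' chromosome whose tract switches are the truth breakpoints.
#'
#' @param contig_length contig length in bp.
#' @param tracts tibble with columns `end` (increasing, last equal to
#'   `contig_length`) and `state` (`"reference"`, `"heterozygous"` or
#'   `"alternate"`).
#' @param sites_per_kb mean variant density (Poisson).
#' @param depth_mean,depth_dispersion negative-binomial depth model
#'   (mean and size).
#' @param error_rate sequencing error rate feeding stray alternate (or
#'   reference) reads at homozygous sites.
#' @param noise per-site probability that a site's true state is swapped
#'   to a different state before depths are drawn.
#' @param qual_mean,qual_sd normal model for the QUAL column.
#' @param seed integer seed.
#' @return a `tract_spec` list.
#' @export
tract_spec <- function(contig_length,
                       tracts = tibble(end = contig_length,
                                       state = "heterozygous"),
                       sites_per_kb = 1, depth_mean = 50,
                       depth_dispersion = 5, error_rate = 0.02,
                       noise = 0, qual_mean = 60, qual_sd = 15,
                       seed = 1L) {
  tracts <- as_tibble(tracts)
  if (is.unsorted(tracts$end, strictly = TRUE) ||
      utils::tail(tracts$end, 1) != contig_length) {
    abort("tract ends must increase and finish at `contig_length`")
  }
  if (!all(tracts$state %in% c("reference", "heterozygous", "alternate"))) {
    abort("tract states must be reference/heterozygous/alternate")
  }
  check_prob(noise, "noise")
  check_prob(error_rate, "error_rate")
  structure(
    list(contig_length = contig_length, tracts = tracts,
         sites_per_kb = sites_per_kb, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion, error_rate = error_rate,
         noise = noise, qual_mean = qual_mean, qual_sd = qual_sd,
         seed = as.integer(seed)),
    class = "tract_spec"
  )
}

#' Generate a synthetic variant table with known breakpoints
#'
#' Places sites by a Poisson process, assigns each its tract's genotype
#' state (optionally perturbed by the misclassification noise), draws
#' depths from the negative-binomial model and allele depths from the
#' state (reference: error-rate alternate reads; heterozygous: 0.5;
#' alternate: 1 - error rate). The truth breakpoints are the interior
#' tract boundaries.
#'
#' @param spec a [tract_spec()].
#' @return a list: `variants` (tibble with `contig`, `pos`, `qual`,
#'   `ref_depth`, `alt_depth`, `total_depth`, `gt`, plus the drawn
#'   `true_state`), `truth_breakpoints` (bp positions of tract switches).
#' @export
gen_variant_table <- function(spec) {
  withr::with_seed(spec$seed, {
    n <- rpois(1, spec$contig_length / 1000 * spec$sites_per_kb)
    pos <- sort(unique(ceiling(runif(n) * spec$contig_length)))
    n <- length(pos)
    tract_idx <- findInterval(pos - 1, c(0, spec$tracts$end),
                              rightmost.closed = TRUE)
    state <- spec$tracts$state[pmin(tract_idx, nrow(spec$tracts))]
    flip <- runif(n) < spec$noise
    all_states <- c("reference", "heterozygous", "alternate")
    state[flip] <- purrr::map_chr(
      state[flip], ~ sample(setdiff(all_states, .x), 1)
    )
    depth <- rnbinom(n, mu = spec$depth_mean,
                     size = spec$depth_dispersion) + 1L
    p_alt <- c(reference = spec$error_rate, heterozygous = 0.5,
               alternate = 1 - spec$error_rate)[state]
    alt <- rbinom(n, depth, p_alt)
    gt <- c(reference = "0/0", heterozygous = "0/1",
            alternate = "1/1")[state]
    variants <- tibble(
      contig = "chr2L_syn", pos = pos,
      qual = pmax(0, rnorm(n, spec$qual_mean, spec$qual_sd)),
      ref_depth = depth - alt, alt_depth = alt, total_depth = depth,
      gt = unname(gt), true_state = state
    )
    list(
      variants = variants,
      truth_breakpoints = utils::head(spec$tracts$end, -1)
    )
  })
}

#' Generate synthetic cross-count tables under a known drive strength
#'
#' For each cross, the male-heterozygote SD offspring count is binomial
#' with success probability `k v / (k v + (1 - k))` — drive `k` distorted
#' by the relative viability `v` of SD-bearing offspring — and the
#' reciprocal (female) cross is binomial with probability `v / (1 + v)`
#' (Mendelian transmission, viability only).
#'
#' @param true_k true drive strength in \[0, 1\].
#' @param viability relative viability of SD-bearing offspring (> 0).
#' @param n_offspring offspring per cross.
#' @param n_crosses number of independent cross pairs.
#' @param seed integer seed.
#' @return a tibble in the [estimate_drive()] layout: `line_id`,
#'   `parent_sex`, `n_sd`, `n_plus`, one male and one female row per
#'   cross.
#' @export
gen_cross_counts <- function(true_k, viability, n_offspring, n_crosses,
                             seed = 1L) {
  check_prob(true_k, "true_k")
  if (viability <= 0) abort("`viability` must be positive")
  withr::with_seed(seed, {
    p_male <- (true_k * viability) /
      (true_k * viability + (1 - true_k))
    p_fem <- viability / (1 + viability)
    male_sd <- rbinom(n_crosses, n_offspring, p_male)
    fem_sd <- rbinom(n_crosses, n_offspring, p_fem)
    dplyr::bind_rows(
      tibble(line_id = sprintf("cross%03d", seq_len(n_crosses)),
             parent_sex = "male", n_sd = male_sd,
             n_plus = n_offspring - male_sd),
      tibble(line_id = sprintf("cross%03d", seq_len(n_crosses)),
             parent_sex = "female", n_sd = fem_sd,
             n_plus = n_offspring - fem_sd)
    ) |> dplyr::arrange(.data$line_id, dplyr::desc(.data$parent_sex))
  })
}

#' Write a sequence as FASTA
#'
#' @param sequence nucleotide string.
#' @param path output path.
#' @param name record name.
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequence, path, name = "locus") {
  n <- nchar(sequence)
  starts <- seq(1, n, by = 70)
  writeLines(c(paste0(">", name),
               substring(sequence, starts, pmin(starts + 69, n))), path)
  invisible(path)
}

#' Read a single-record FASTA
#'
#' @param path FASTA path.
#' @return the sequence string (first record), named by its header.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0) abort("no FASTA header found")
  from <- headers[1] + 1
  to <- if (length(headers) > 1) headers[2] - 1 else length(lines)
  setNames(paste(toupper(lines[from:to]), collapse = ""),
           sub("^>\\s*", "", lines[headers[1]]))
}

#' Write a variant table as a minimal single-sample VCF
#'
#' Emits a minimal header and GT:AD:DP FORMAT fields; placeholder
#' REF/ALT alleles (A/T) since only depths, quality and genotype matter
#' downstream.
#'
#' @param variants a variant tibble (as from [gen_variant_table()]).
#' @param path output path.
#' @param sample sample name.
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(variants, path, sample = "sample1") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(variants$contig)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  gt <- variants$gt %||% rep("./.", nrow(variants))
  body <- sprintf(
    "%s\t%d\t.\tA\tT\t%.2f\t PASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
    variants$contig, as.integer(variants$pos), variants$qual,
    gt, as.integer(variants$ref_depth), as.integer(variants$alt_depth),
    as.integer(variants$total_depth)
  )
  body <- gsub("\t PASS", "\tPASS", body, fixed = TRUE)
  writeLines(c(header, body), path)
  invisible(path)
}
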