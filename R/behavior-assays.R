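cohort_columns <- c("worm_id", "genotype", "trial_id", "dye_filled_count",
                    "squares_entered", "escape_time_min", "censored")

check_cohort <- function(cohort) {
  check_that(is.data.frame(cohort), "cohort must be a data.frame")
  missing_cols <- setdiff(c("worm_id", "genotype"), names(cohort))
  check_that(length(missing_cols) == 0,
             paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")))
  invisible(cohort)
}

#' Dye-filling category frequencies
#'
#' Frequency of worms with dye uptake in 0 to 4 phasmid neurons for one
#' genotype, pooled over all trials (data from independent experiments are
#' combined). Worms without a dye score are excluded from this assay only.
#'
#' @param cohort behavioural cohort `data.frame` (see
#'   [simulate_behavior_cohort] for the schema).
#' @param genotype genotype to score.
#' @return A list with `frequencies` (named fractions for 0-4 filled
#'   neurons, summing to 1) and `n` (number of scored worms).
#' @export
dye_filling_frequency <- function(cohort, genotype) {
  check_cohort(cohort)
  x <- cohort$dye_filled_count[cohort$genotype == genotype]
  x <- x[!is.na(x)]
  if (!length(x))
    stop("no scored worms for genotype ", genotype, call. = FALSE)
  check_that(all(x %in% 0:4), "dye_filled_count values must be in 0..4")
  counts <- table(factor(x, levels = 0:4))
  freq <- setNames(as.vector(counts) / length(x), as.character(0:4))
  list(frequencies = freq, n = length(x))
}

#' Reference-normalised roaming index
#'
#' Each worm's grid-square count divided by the reference genotype's mean
#' count, so the reference group has mean 1 by construction.
#'
#' @inheritParams dye_filling_frequency
#' @param reference_genotype genotype defining the normalisation (usually
#'   wild type).
#' @return Numeric vector of per-worm normalised roaming indices.
#' @export
roaming_index <- function(cohort, genotype, reference_genotype) {
  check_cohort(cohort)
  ref <- cohort$squares_entered[cohort$genotype == reference_genotype]
  ref <- ref[!is.na(ref)]
  if (!length(ref))
    stop("no scored worms for reference genotype ", reference_genotype,
         call. = FALSE)
  x <- cohort$squares_entered[cohort$genotype == genotype]
  x <- x[!is.na(x)]
  if (!length(x))
    stop("no scored worms for genotype ", genotype, call. = FALSE)
  normalize_to_group(x, ref)
}

#' Osmotic-avoidance retention curve
#'
#' Fraction of worms still retained inside the high-osmolarity barrier at
#' each time point: worms with `escape_time_min > t` count as retained,
#' and censored worms (observed for the whole assay without escaping)
#' never escape. The curve starts at 1 and is monotone non-increasing; the
#' final-time values are the usual input to group comparisons.
#'
#' @inheritParams dye_filling_frequency
#' @param time_grid evaluation times in minutes within (0, censor time];
#'   default a 1-minute grid over the 10-minute assay.
#' @return A `data.frame` with columns `time_min` and `fraction_retained`,
#'   plus attribute `n` (number of scored worms).
#' @export
osmotic_retention_curve <- function(cohort, genotype, time_grid = 1:10) {
  check_cohort(cohort)
  check_that(all(time_grid > 0), "time_grid must be positive")
  keep <- cohort$genotype == genotype & !is.na(cohort$escape_time_min)
  t_obs <- cohort$escape_time_min[keep]
  cens <- cohort$censored[keep]
  if (!length(t_obs))
    stop("no scored worms for genotype ", genotype, call. = FALSE)
  frac <- vapply(time_grid,
                 function(t) mean(t_obs > t | cens), 0)
  out <- data.frame(time_min = time_grid, fraction_retained = frac)
  attr(out, "n") <- length(t_obs)
  out
}

#' Write / read a behavioural cohort CSV
#'
#' Plain-text serialisation of the cohort schema used across the package
#' (`worm_id, genotype, trial_id, dye_filled_count, squares_entered,
#' escape_time_min, censored`).
#'
#' @param cohort cohort `data.frame`.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  check_cohort(cohort)
  if (!is.null(cohort$censored)) cohort$censored <- as.logical(cohort$censored)
  cohort
}
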