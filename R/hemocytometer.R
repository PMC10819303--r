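# Hemocytometer targeting-efficiency arithmetic.
#
# Bench validation counts beads collected from the two outlet channels in a
# gridded counting chamber: four large squares per channel per sample. The
# standard 4-square formula gives the concentration (mean count per large
# square x 1e4 per mL); channel percentages within a sample are totals over
# the channel pair; the "+/-" value reported across samples is the standard
# error of the mean (for two samples, half the absolute difference).
# All arithmetic is done at full precision; rounding to two decimals is a
# presentation choice only.

#' Validate a hemocytometer count table
#'
#' Long-form table with one row per counted square: columns `condition`,
#' `sample`, `channel`, `square`, `count`. Each condition must have exactly
#' two channels, and every (sample, channel) at least one square.
#'
#' @param df A data frame in the long format above.
#' @return The validated table, classed `acoustonav_counts`.
#' @seealso [read_count_table()], [bench_counts()],
#'   [hemocytometer_stats()]
#' @export
count_table <- function(df) {
  need <- c("condition", "sample", "channel", "square", "count")
  if (!all(need %in% names(df)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers")
  for (cond in unique(df$condition)) {
    ch <- unique(df$channel[df$condition == cond])
    if (length(ch) != 2L)
      stop(sprintf("condition '%s' must have exactly 2 channels", cond))
  }
  class(df) <- c("acoustonav_counts", "data.frame")
  df
}

#' Read a count table from CSV
#'
#' @param path CSV file in the long format of [count_table()].
#' @return An `acoustonav_counts` table.
#' @export
read_count_table <- function(path) {
  count_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled bench-validation counts
#'
#' The packaged transcription of the gelatin-channel blocking experiment:
#' per-square bead counts for two samples and two outlet channels (A, B),
#' without (`no_field`) and with (`blocking`) the acoustic field.
#'
#' @return An `acoustonav_counts` table.
#' @export
bench_counts <- function() {
  read_count_table(system.file("extdata", "hemocytometer_counts.csv",
                               package = "acoustonav", mustWork = TRUE))
}

#' Bead concentration from square counts
#'
#' Standard hemocytometer formula: mean count per large square times 1e4
#' per mL, i.e. `sum(counts) * 1e4 / n_squares` (total x 2500 for the usual
#' four squares).
#'
#' @param square_counts Integer vector of per-square counts (>= 1 square).
#' @return Concentration in counts/mL.
#' @examples
#' concentration(c(47, 53, 40, 49))  # 472500
#' @export
concentration <- function(square_counts) {
  if (length(square_counts) < 1L) stop("need at least one square count")
  sum(square_counts) * 1e4 / length(square_counts)
}

#' Per-sample channel percentages
#'
#' For each (condition, sample): channel totals, concentrations, and the
#' channel percentage `100 * total_X / (total_A + total_B)` at full
#' precision.
#'
#' @param tbl An `acoustonav_counts` table.
#' @return Data frame `condition, sample, channel, total, concentration,
#'   percentage`.
#' @export
sample_percentages <- function(tbl) {
  tbl <- count_table(as.data.frame(tbl))
  agg <- stats::aggregate(count ~ condition + sample + channel, data = tbl,
                          FUN = sum)
  nsq <- stats::aggregate(count ~ condition + sample + channel, data = tbl,
                          FUN = length)
  agg$concentration <- agg$count * 1e4 / nsq$count
  agg$percentage <- NA_real_
  for (cond in unique(agg$condition)) {
    for (smp in unique(agg$sample[agg$condition == cond])) {
      i <- agg$condition == cond & agg$sample == smp
      tot <- sum(agg$count[i])
      if (tot == 0) stop(sprintf(
        "zero total count for condition '%s' sample '%s'", cond, smp))
      agg$percentage[i] <- 100 * agg$count[i] / tot
    }
  }
  names(agg)[names(agg) == "count"] <- "total"
  agg[order(agg$condition, agg$sample, agg$channel),
      c("condition", "sample", "channel", "total", "concentration",
        "percentage")]
}

#' Mean and standard error of sample percentages
#'
#' @param x Numeric vector of per-sample percentages.
#' @return List with `mean` and `sem` (`sd / sqrt(n)`; `NA` for a single
#'   sample).
#' @examples
#' mean_sem(c(78.82, 78.41))  # mean 78.61..., sem 0.205
#' @export
mean_sem <- function(x) {
  n <- length(x)
  if (n == 0L) stop("no samples")
  list(mean = mean(x),
       sem = if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_)
}

#' Full targeting-efficiency statistics
#'
#' Per-sample totals, concentrations and percentages plus the per-channel
#' mean and standard error across samples, for every condition. Within each
#' condition the channel means sum to 100 exactly (before any rounding) and
#' the two channels share the same standard error.
#'
#' @param tbl An `acoustonav_counts` table.
#' @return List with `samples` (see [sample_percentages()]) and `channels`
#'   (data frame `condition, channel, mean_pct, sem_pct, n_samples`).
#' @examples
#' stats <- hemocytometer_stats(bench_counts())
#' subset(stats$channels, condition == "blocking")
#' @export
hemocytometer_stats <- function(tbl) {
  per <- sample_percentages(tbl)
  rows <- list()
  for (cond in unique(per$condition)) {
    for (ch in unique(per$channel[per$condition == cond])) {
      i <- per$condition == cond & per$channel == ch
      ms <- mean_sem(per$percentage[i])
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, channel = ch, mean_pct = ms$mean,
                   sem_pct = ms$sem, n_samples = sum(i))
    }
  }
  list(samples = per, channels = do.call(rbind, rows))
}
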