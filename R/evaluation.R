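# Enrichment-factor evaluation of ranked retrieval.

#' Enrichment factor at one percentile
#'
#' `EF_x = (N_P^x / N_x) / (T_P / T_DB)`: the fraction of correct entries
#' among the top `x` percent of the ranking, relative to the fraction
#' expected when scanning the database at random.  1 means random, and
#' `T_DB / T_P` is the maximum.  The cutoff `N_x = ceiling(x/100 * T_DB)`.
#'
#' @param ranking Character vector of entry IDs, best first, covering the
#'   database.
#' @param correct_set IDs of the entries counted as correct (nonempty).
#' @param x Percent of the database scanned, in (0, 100].
#' @return An `ef_point`: list with x, N_x, N_P_x, T_P, T_DB and ef.
#' @export
enrichment_factor <- function(ranking, correct_set, x) {
  if (length(correct_set) == 0L) {
    stop("`correct_set` is empty: enrichment factor is undefined")
  }
  if (x <= 0 || x > 100) stop("`x` must be in (0, 100]")
  T_DB <- length(ranking)
  T_P <- sum(ranking %in% correct_set)
  if (T_P == 0L) {
    stop("no correct entries present in the ranking")
  }
  N_x <- ceiling(x / 100 * T_DB)
  N_P_x <- sum(ranking[seq_len(N_x)] %in% correct_set)
  ef <- (N_P_x / N_x) / (T_P / T_DB)
  structure(list(x = x, N_x = N_x, N_P_x = N_P_x, T_P = T_P, T_DB = T_DB,
                 ef = ef),
            class = "ef_point")
}

#' @export
print.ef_point <- function(x, ...) {
  cat(sprintf("EF@%g%% = %.3f (%d/%d correct in top %d of %d)\n",
              x$x, x$ef, x$N_P_x, x$T_P, x$N_x, x$T_DB))
  invisible(x)
}

#' Enrichment-factor curve over several percentiles
#'
#' @param ranking,correct_set As in [enrichment_factor()].
#' @param x_values Ascending percents.
#' @return Data frame with one row per percentile (x, N_x, N_P_x, T_P,
#'   T_DB, ef).
#' @export
ef_curve <- function(ranking, correct_set, x_values) {
  if (is.unsorted(x_values)) stop("`x_values` must be sorted ascending")
  do.call(rbind, lapply(x_values, function(x) {
    as.data.frame(unclass(enrichment_factor(ranking, correct_set, x)))
  }))
}

#' Mean enrichment factor across a query set
#'
#' Unweighted arithmetic mean of per-query EF values at each percentile,
#' the benchmark-style summary over a set of query rankings.
#'
#' @param rankings List of ranking vectors, one per query.
#' @param correct_sets List of correct-ID vectors, parallel to `rankings`.
#' @param x_values Ascending percents.
#' @return Data frame (x, mean_ef, n_queries).
#' @export
mean_ef <- function(rankings, correct_sets, x_values) {
  stopifnot(length(rankings) == length(correct_sets))
  curves <- Map(ef_curve, rankings, correct_sets,
                MoreArgs = list(x_values = x_values))
  data.frame(
    x = x_values,
    mean_ef = rowMeans(vapply(curves, `[[`, numeric(length(x_values)), "ef")),
    n_queries = length(rankings)
  )
}
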