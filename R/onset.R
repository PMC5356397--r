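#' Binned age-of-onset table
#'
#' Diagnosis counts by sex over half-open age bins `(lower, upper]`; the last
#' bin is open-ended above the final edge. This mirrors how breed health
#' surveys report onset ("> 3.5 to 4.5" years and so on), and all queries are
#' bin-granular: an age interior to a bin resolves to that bin's upper edge
#' rather than interpolating, which would invent precision the data do not
#' have.
#'
#' @param bin_edges strictly increasing numeric vector of bin boundaries in
#'   years; with `n` edges there are `n` bins, the last being
#'   `(bin_edges[n], Inf)`.
#' @param counts_by_sex named list (`male`, `female`, ...) of non-negative
#'   integer vectors, one count per bin.
#' @return an object of class `onset_table`.
#' @export
onset_table <- function(bin_edges, counts_by_sex) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 1L,
            all(diff(bin_edges) > 0), is.list(counts_by_sex),
            length(names(counts_by_sex)) == length(counts_by_sex))
  n_bins <- length(bin_edges)
  for (sx in names(counts_by_sex)) {
    cnt <- counts_by_sex[[sx]]
    if (length(cnt) != n_bins || any(cnt < 0) || any(cnt != round(cnt))) {
      stop("counts for ", sx, " must be ", n_bins, " non-negative integers")
    }
  }
  structure(list(bin_edges = bin_edges,
                 counts_by_sex = lapply(counts_by_sex, as.integer)),
            class = "onset_table")
}

#' Read an onset table from CSV
#'
#' Expected columns: `bin_low`, `bin_high`, then one count column per sex
#' (e.g. `male`, `female`). The last row may leave `bin_high` empty for the
#' open-ended bin.
#'
#' @param path CSV file path.
#' @return an [onset_table()].
#' @export
read_onset_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bin_low", "bin_high") %in% names(raw)))
  sexes <- setdiff(names(raw), c("bin_low", "bin_high"))
  edges <- raw$bin_low
  if (any(!is.na(raw$bin_high[-nrow(raw)]) &
          raw$bin_high[-nrow(raw)] != raw$bin_low[-1L])) {
    stop("bins must be contiguous: bin_high must equal the next bin_low")
  }
  onset_table(edges, stats::setNames(lapply(sexes, function(s) raw[[s]]), sexes))
}

.onset_counts <- function(table, sex) {
  if (!sex %in% names(table$counts_by_sex)) {
    stop("no onset counts for sex '", sex, "'")
  }
  table$counts_by_sex[[sex]]
}

#' Fraction of affected dogs diagnosed by an age
#'
#' Cumulative share of diagnoses of the given sex in bins whose upper edge is
#' at or below the (bin-resolved) age. Ages interior to a bin resolve to the
#' bin's upper edge; any age beyond the last edge returns 1.
#'
#' @param table an [onset_table()].
#' @param sex a sex present in the table.
#' @param age age in years, at or above the first bin edge.
#' @return fraction in `[0, 1]` at full precision (no display rounding).
#' @seealso [prob_onset_after()], [percent()]
#' @export
cumulative_onset_fraction <- function(table, sex, age) {
  stopifnot(inherits(table, "onset_table"))
  counts <- .onset_counts(table, sex)
  total <- sum(counts)
  if (total == 0L) stop("no diagnoses recorded for sex '", sex, "'")
  edges <- table$bin_edges
  if (age < edges[1L]) stop("age below the first bin edge")
  # enclosing bin: edges[i] < age <= edges[i + 1]; last bin is open-ended
  i <- findInterval(age, edges, left.open = TRUE)
  sum(counts[seq_len(min(i, length(counts)))]) / total
}

#' Probability of onset after a cutoff, given eventual disease
#'
#' Complement of [cumulative_onset_fraction()]; a cutoff below the first bin
#' edge returns 1 (no diagnosis can have happened yet).
#'
#' @inheritParams cumulative_onset_fraction
#' @param cutoff cutoff age in years.
#' @return fraction in `[0, 1]`.
#' @export
prob_onset_after <- function(table, sex, cutoff) {
  stopifnot(inherits(table, "onset_table"))
  if (cutoff < table$bin_edges[1L]) {
    .onset_counts(table, sex)  # still validate the sex
    return(1)
  }
  1 - cumulative_onset_fraction(table, sex, cutoff)
}

#' Lifetime incidence from survey counts
#'
#' @param affected number of dogs ever diagnosed.
#' @param total surveyed population size (> 0).
#' @return fraction `affected / total`.
#' @export
lifetime_incidence <- function(affected, total) {
  stopifnot(length(affected) == 1L, length(total) == 1L, affected >= 0)
  if (total <= 0) stop("total must be positive")
  if (affected > total) stop("affected cannot exceed total")
  affected / total
}

#' Probability of mislabeling a to-be-affected dog as unaffected
#'
#' A dog past the cutoff and disease-free is called unaffected, but it may
#' still develop the disease later. The chance of that mistake is the product
#' of the probability of late onset given eventual disease and the lifetime
#' incidence: `P(onset > cutoff | affected) * P(affected)`.
#'
#' @inheritParams prob_onset_after
#' @param incidence lifetime incidence for that sex, in `[0, 1]`.
#' @return fraction in `[0, 1]` at full precision.
#' @export
misclassification_prob <- function(table, sex, cutoff, incidence) {
  stopifnot(incidence >= 0, incidence <= 1)
  prob_onset_after(table, sex, cutoff) * incidence
}

#' Round a fraction to a whole percent for display
#'
#' Half-away-from-zero rounding, the convention used when quoting survey
#' percentages (e.g. 62.5% prints as 63%). Internal arithmetic everywhere in
#' the package is full precision; this is a display-layer helper only.
#'
#' @param x fraction(s).
#' @return integer percent value(s).
#' @export
percent <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5)
}
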