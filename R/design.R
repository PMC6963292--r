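#' Study design for a multi-wave ability/anxiety assessment
#'
#' Describes the layout of a longitudinal item-response study: the number of
#' test sessions (waves), the number of dichotomously scored ability items per
#' wave, the number of Likert-type anxiety items per wave, and the number of
#' response categories of the anxiety scale.  The empirical study the package
#' models used 7 waves, 13 binary figural-matrices items and 5 seven-point
#' fear-of-failure items, available as `study_design()`.
#'
#' @param n_waves Number of test sessions (>= 1).
#' @param n_ability_items Binary ability items per wave (>= 1).
#' @param n_anxiety_items Likert anxiety items per wave (>= 0).
#' @param anxiety_categories Number of anxiety response categories (>= 2).
#' @return An object of class `latsem_design`.
#' @examples
#' study_design()            # the 7 x 13 + 7 x 5 reference design
#' study_design(3, 4, 2, 5)  # a small custom design
#' @export
study_design <- function(n_waves = 7L, n_ability_items = 13L,
                         n_anxiety_items = 5L, anxiety_categories = 7L) {
  n_waves <- as.integer(n_waves)
  n_ability_items <- as.integer(n_ability_items)
  n_anxiety_items <- as.integer(n_anxiety_items)
  anxiety_categories <- as.integer(anxiety_categories)
  if (n_waves < 1L || n_ability_items < 1L || n_anxiety_items < 0L)
    ls_stop("n_waves and n_ability_items must be >= 1, n_anxiety_items >= 0",
            "latsem_design_error")
  if (n_anxiety_items > 0L && anxiety_categories < 2L)
    ls_stop("anxiety_categories must be >= 2", "latsem_design_error")
  structure(list(n_waves = n_waves, n_ability_items = n_ability_items,
                 n_anxiety_items = n_anxiety_items,
                 anxiety_categories = anxiety_categories),
            class = "latsem_design")
}

#' @export
print.latsem_design <- function(x, ...) {
  cat(sprintf(
    "Study design: %d waves x (%d binary ability items + %d %d-point anxiety items)\n",
    x$n_waves, x$n_ability_items, x$n_anxiety_items, x$anxiety_categories))
  invisible(x)
}

ability_colnames <- function(design) {
  as.vector(t(outer(seq_len(design$n_waves), seq_len(design$n_ability_items),
                    function(t, j) sprintf("w%d_a%d", t, j))))
}

anxiety_colnames <- function(design) {
  if (design$n_anxiety_items == 0L) return(character(0))
  as.vector(t(outer(seq_len(design$n_waves), seq_len(design$n_anxiety_items),
                    function(t, j) sprintf("w%d_f%d", t, j))))
}

#' Assemble and validate an item-response matrix
#'
#' The sole empirical input of the package: per person and wave, binary
#' ability-item scores (0/1) and ordinal anxiety-item scores
#' (1..`anxiety_categories`).  The contract is complete-case: any missing cell
#' is an error, never imputed.
#'
#' @param design A [study_design()].
#' @param ability Integer matrix, persons x (waves * ability items), columns
#'   ordered `w1_a1 ... w1_aJ, w2_a1, ...`.
#' @param anxiety Integer matrix, persons x (waves * anxiety items), columns
#'   `w1_f1 ...`; may be `NULL` when the design has no anxiety items.
#' @param person_ids Unique person identifiers (default `1..n`).
#' @return An object of class `latsem_data`.
#' @export
response_matrix <- function(design, ability, anxiety = NULL,
                            person_ids = NULL) {
  stopifnot(inherits(design, "latsem_design"))
  ability <- as.matrix(ability)
  if (ncol(ability) != design$n_waves * design$n_ability_items)
    ls_stop(sprintf("ability has %d columns; design implies %d",
                    ncol(ability), design$n_waves * design$n_ability_items),
            "latsem_format_error")
  if (design$n_anxiety_items > 0L) {
    if (is.null(anxiety))
      ls_stop("design includes anxiety items but none were supplied",
              "latsem_format_error")
    anxiety <- as.matrix(anxiety)
    if (ncol(anxiety) != design$n_waves * design$n_anxiety_items)
      ls_stop(sprintf("anxiety has %d columns; design implies %d",
                      ncol(anxiety), design$n_waves * design$n_anxiety_items),
              "latsem_format_error")
    if (nrow(anxiety) != nrow(ability))
      ls_stop("ability and anxiety have different person counts",
              "latsem_format_error")
  } else {
    anxiety <- matrix(integer(0), nrow(ability), 0)
  }
  if (is.null(person_ids)) person_ids <- seq_len(nrow(ability))
  if (anyDuplicated(person_ids))
    ls_stop("person_ids must be unique", "latsem_validation_error")

  check_cells <- function(m, lo, hi, what, labs) {
    if (ncol(m) == 0) return(invisible())
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      ls_stop(sprintf("missing %s cell for person '%s', column '%s' (complete cases required)",
                      what, person_ids[idx[1]], labs[idx[2]]),
              "latsem_incomplete_error")
    }
    bad <- m < lo | m > hi | m != round(m)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      ls_stop(sprintf("%s code %s out of range [%d, %d] for person '%s', column '%s'",
                      what, format(m[idx[1], idx[2]]), lo, hi,
                      person_ids[idx[1]], labs[idx[2]]),
              "latsem_validation_error")
    }
  }
  a_labs <- ability_colnames(design)
  f_labs <- anxiety_colnames(design)
  check_cells(ability, 0L, 1L, "ability", a_labs)
  check_cells(anxiety, 1L, design$anxiety_categories, "anxiety", f_labs)
  storage.mode(ability) <- "integer"
  colnames(ability) <- a_labs
  if (ncol(anxiety)) {
    storage.mode(anxiety) <- "integer"
    colnames(anxiety) <- f_labs
  }
  structure(list(design = design, person_ids = person_ids,
                 ability = ability, anxiety = anxiety),
            class = "latsem_data")
}

#' @export
print.latsem_data <- function(x, ...) {
  cat(sprintf("latsem_data: %d persons, %d waves, %d ability + %d anxiety items per wave\n",
              nrow(x$ability), x$design$n_waves, x$design$n_ability_items,
              x$design$n_anxiety_items))
  invisible(x)
}

#' Read a wide-format response CSV
#'
#' The file must be RFC-4180 CSV with a header row, one row per person, an
#' optional `person_id` column, and one integer column per (wave, item) named
#' `w{t}_a{j}` for ability items and `w{t}_f{j}` for anxiety items (1-based
#' wave and item indices).  Missing cells are rejected: the analysis contract
#' is complete cases only.
#'
#' @param path CSV file path.
#' @param design A [study_design()] the columns must match exactly.
#' @return A validated `latsem_data` object.
#' @seealso [write_responses()]
#' @export
read_responses <- function(path, design) {
  if (!file.exists(path))
    ls_stop(sprintf("file not found: %s", path), "latsem_format_error")
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  a_labs <- ability_colnames(design)
  f_labs <- anxiety_colnames(design)
  need <- c(a_labs, f_labs)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    ls_stop(sprintf("malformed header: missing column(s) %s",
                    paste(head(missing_cols, 5), collapse = ", ")),
            "latsem_format_error")
  ids <- if ("person_id" %in% names(df)) df$person_id else seq_len(nrow(df))
  to_int <- function(cols) {
    m <- as.matrix(df[cols])
    suppressWarnings(storage.mode(m) <- "numeric")
    m
  }
  response_matrix(design, to_int(a_labs),
                  if (length(f_labs)) to_int(f_labs) else NULL,
                  person_ids = ids)
}

#' Write a response matrix as CSV
#'
#' Emits the same dialect [read_responses()] consumes; a round trip
#' reproduces the data exactly up to header normalization.
#'
#' @param data A `latsem_data` object.
#' @param path Output CSV path.
#' @export
write_responses <- function(data, path) {
  stopifnot(inherits(data, "latsem_data"))
  df <- data.frame(person_id = data$person_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$ability))
  if (ncol(data$anxiety)) df <- cbind(df, as.data.frame(data$anxiety))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

wave_sums <- function(data, scale = c("ability", "anxiety")) {
  scale <- match.arg(scale)
  m <- data[[scale]]
  J <- if (scale == "ability") data$design$n_ability_items
       else data$design$n_anxiety_items
  vapply(seq_len(data$design$n_waves), function(t) {
    cols <- ((t - 1) * J + 1):(t * J)
    rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
}

#' Exclude persons with longitudinal ceiling effects
#'
#' A person is removed when their ability wave-sum reaches the maximum
#' possible score (a "perfect test score") in four or more waves, or in three
#' consecutive waves.  Both rules follow the completer-filtering practice for
#' repeated testing designs where score ceilings mask further gains.
#'
#' @param data A `latsem_data` object; the design must have at least 3 waves.
#' @return A list with elements `data` (the survivors, a `latsem_data`) and
#'   `excluded` (data frame with columns `person_id`, `rule`, where rule is
#'   `"four_or_more_perfect"` or `"three_in_a_row"`; the first rule that fires
#'   is reported).
#' @export
ceiling_filter <- function(data) {
  stopifnot(inherits(data, "latsem_data"))
  if (data$design$n_waves < 3L)
    ls_stop("ceiling_filter requires a design with >= 3 waves",
            "latsem_design_error")
  perfect <- wave_sums(data, "ability") == data$design$n_ability_items
  n_perfect <- rowSums(perfect)
  runs3 <- apply(perfect, 1, function(p) {
    r <- rle(p)
    any(r$values & r$lengths >= 3)
  })
  rule <- ifelse(n_perfect >= 4, "four_or_more_perfect",
                 ifelse(runs3, "three_in_a_row", NA_character_))
  drop <- !is.na(rule)
  excluded <- data.frame(person_id = data$person_ids[drop],
                         rule = rule[drop], stringsAsFactors = FALSE)
  keep <- which(!drop)
  survivors <- response_matrix(
    data$design, data$ability[keep, , drop = FALSE],
    if (ncol(data$anxiety)) data$anxiety[keep, , drop = FALSE] else NULL,
    person_ids = data$person_ids[keep])
  list(data = survivors, excluded = excluded)
}

# Kuder-Richardson formula 20 for binary items; Cronbach's alpha for
# polytomous ones.  Undefined (NA) when the sum score has zero variance.
internal_consistency <- function(items, binary) {
  k <- ncol(items)
  tot <- rowSums(items)
  vt <- var(tot)
  if (k < 2 || !is.finite(vt) || vt <= 0) return(NA_real_)
  if (binary) {
    p <- colMeans(items)
    (k / (k - 1)) * (1 - sum(p * (1 - p)) / (vt * (nrow(items) - 1) / nrow(items)))
  } else {
    (k / (k - 1)) * (1 - sum(apply(items, 2, var)) / vt)
  }
}

#' Per-wave descriptive statistics and sum-score correlations
#'
#' One row per (scale, wave) with the mean, SD, minimum and maximum of the
#' wave sum score and its internal consistency: KR-20 for the binary ability
#' scale and Cronbach's alpha for the Likert anxiety scale.  Also returns the
#' full cross-wave sum-score correlation matrix with the consistency
#' coefficients on the diagonal, the conventional layout for longitudinal
#' test batteries.
#'
#' @param data A `latsem_data` object with at least 2 persons.
#' @return A list with `summary` (data frame) and `correlations` (matrix).
#' @export
descriptives <- function(data) {
  stopifnot(inherits(data, "latsem_data"))
  if (nrow(data$ability) < 2)
    ls_stop("descriptives requires >= 2 persons", "latsem_validation_error")
  scales <- c("ability", if (ncol(data$anxiety)) "anxiety")
  rows <- list(); sums <- list()
  for (sc in scales) {
    J <- if (sc == "ability") data$design$n_ability_items
         else data$design$n_anxiety_items
    ws <- wave_sums(data, sc)
    colnames(ws) <- sprintf("%s_w%d", sc, seq_len(ncol(ws)))
    sums[[sc]] <- ws
    for (t in seq_len(data$design$n_waves)) {
      cols <- ((t - 1) * J + 1):(t * J)
      items <- data[[sc]][, cols, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        scale = sc, wave = t, mean = mean(ws[, t]), sd = sd(ws[, t]),
        min = min(ws[, t]), max = max(ws[, t]),
        consistency = internal_consistency(items, binary = sc == "ability"),
        consistency_type = if (sc == "ability") "KR-20" else "alpha",
        stringsAsFactors = FALSE)
    }
  }
  allsums <- do.call(cbind, sums)
  cm <- suppressWarnings(cor(allsums))
  diag(cm) <- unlist(lapply(rows, `[[`, "consistency"))
  list(summary = do.call(rbind, rows), correlations = cm)
}
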