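#' The ten-attribute postpartum questionnaire schema
#'
#' Returns the feature schema of the postpartum-depression screening
#' questionnaire: nine ordinal predictors plus the binary target
#' `"Feeling anxious"`. `Age` is coded on five bands (1 = 25-30 through
#' 5 = 45-50); the eight symptom attributes use three codes where
#' 1 = "yes", 2 = an intermediate answer ("sometimes", "often", ...),
#' 3 = "no"; the target uses 1 = yes, 2 = no. Internally the target is
#' recoded to 1 (anxious, the positive class) / 0, while CSV files keep
#' the 1/2 questionnaire codes.
#'
#' @return An object of class `ppd_schema`: a list with `attributes`
#'   (a tibble with columns `name`, `codes` (list of allowed integer codes)
#'   and `meanings` (list of named code descriptions)), `target_name` and
#'   `positive_code`.
#' @examples
#' sch <- ppd_schema()
#' sch$target_name
#' @export
ppd_schema <- function() {
  symptom3 <- function(mid) c("1" = "yes", "2" = mid, "3" = "no")
  attributes <- tibble(
    name = c(
      "Age",
      "Feeling sad or Tearful",
      "Irritable towards baby and partner",
      "Trouble sleeping at night",
      "Problems concentrating or making decision",
      "Overeating or loss of appetite",
      "Suicide attempt",
      "Feeling of guilt",
      "Problems of bonding with baby",
      "Feeling anxious"
    ),
    codes = c(list(1:5), rep(list(1:3), 8), list(1:2)),
    meanings = list(
      c("1" = "25-30", "2" = "30-35", "3" = "35-40", "4" = "40-45",
        "5" = "45-50"),
      symptom3("sometimes"),
      symptom3("sometimes"),
      symptom3("two or more days a week"),
      symptom3("often"),
      symptom3("not at all"),
      symptom3("not interested to say"),
      symptom3("maybe"),
      symptom3("sometimes"),
      c("1" = "yes", "2" = "no")
    )
  )
  structure(
    list(
      attributes = attributes,
      target_name = "Feeling anxious",
      positive_code = 1L
    ),
    class = "ppd_schema"
  )
}

#' @export
print.ppd_schema <- function(x, ...) {
  cat("<ppd_schema> ", nrow(x$attributes), " attributes, target \"",
      x$target_name, "\" (positive code ", x$positive_code, ")\n", sep = "")
  invisible(x)
}

feature_names <- function(schema) {
  setdiff(schema$attributes$name, schema$target_name)
}

# normalised header matching: case-insensitive, whitespace/punctuation-tolerant
normalise_name <- function(x) {
  gsub("[^a-z0-9]+", " ", tolower(trimws(x)))
}

schema_codes <- function(schema, name) {
  schema$attributes$codes[[match(name, schema$attributes$name)]]
}

#' Validate a PPD questionnaire dataset
#'
#' Checks that `data` carries the nine predictor columns of the schema plus
#' the target recoded to 0/1, that every entry is an allowed integer code,
#' and that there is at least one record.
#'
#' @param data A data frame as returned by [read_ppd()] or [generate_ppd()].
#' @param schema A [ppd_schema()].
#' @return `data` as a tibble, invisibly usable in pipes.
#' @export
validate_ppd <- function(data, schema = ppd_schema()) {
  data <- as_tibble(data)
  need <- schema$attributes$name
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ppd_schema_error")
  }
  if (nrow(data) < 1) {
    abort("dataset must contain at least one record",
          class = "ppd_validation_error")
  }
  for (nm in feature_names(schema)) {
    col <- data[[nm]]
    if (!is.numeric(col) || any(!is.finite(col)) || any(col != round(col))) {
      abort(paste0("column '", nm, "' contains non-integer or missing values"),
            class = "ppd_parse_error")
    }
    bad <- which(!(col %in% schema_codes(schema, nm)))
    if (length(bad) > 0) {
      abort(paste0("column '", nm, "' has out-of-range code ", col[bad[1]],
                   " at row ", bad[1]),
            class = "ppd_validation_error")
    }
  }
  y <- data[[schema$target_name]]
  bad <- which(!(y %in% c(0L, 1L)))
  if (length(bad) > 0) {
    abort(paste0("target column '", schema$target_name,
                 "' must be 0/1; bad value at row ", bad[1]),
          class = "ppd_validation_error")
  }
  data
}

#' Read a PPD questionnaire CSV
#'
#' Reads a comma-separated file whose header carries the ten schema
#' attribute names (matched case-insensitively, tolerant of whitespace,
#' order-insensitive; extra columns are dropped by name). All cells must be
#' integer codes in the attribute's allowed set. The target column's
#' questionnaire codes are mapped 1 -> 1 (anxious, positive) and 2 -> 0.
#'
#' @param path Path to a CSV file.
#' @param schema A [ppd_schema()].
#' @return A tibble with the nine predictor columns (integer codes) and the
#'   target column recoded to 0/1.
#' @seealso [write_ppd()] for the inverse operation.
#' @export
read_ppd <- function(path, schema = ppd_schema()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ppd_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  key <- normalise_name(names(raw))
  need <- schema$attributes$name
  idx <- match(normalise_name(need), key)
  if (anyNA(idx)) {
    abort(paste0("missing required column(s): ",
                 paste(need[is.na(idx)], collapse = ", ")),
          class = "ppd_schema_error")
  }
  if (anyDuplicated(idx)) {
    abort("duplicated schema columns in header", class = "ppd_schema_error")
  }
  out <- raw[idx]
  names(out) <- need
  for (nm in need) {
    col <- suppressWarnings(as.numeric(out[[nm]]))
    bad <- which(is.na(col) | col != round(col))
    if (length(bad) > 0) {
      abort(paste0("non-integer value '", out[[nm]][bad[1]], "' in column '",
                   nm, "' at row ", bad[1]),
            class = "ppd_parse_error")
    }
    out[[nm]] <- as.integer(col)
  }
  # questionnaire target codes {1,2} -> internal labels {1,0}
  tgt <- out[[schema$target_name]]
  bad <- which(!(tgt %in% schema_codes(schema, schema$target_name)))
  if (length(bad) > 0) {
    abort(paste0("target code ", tgt[bad[1]], " at row ", bad[1],
                 " outside {1,2}"),
          class = "ppd_validation_error")
  }
  out[[schema$target_name]] <- ifelse(tgt == schema$positive_code, 1L, 0L)
  validate_ppd(out, schema)
}

#' Write a PPD questionnaire CSV
#'
#' Inverse of [read_ppd()]: the internal 0/1 target is re-encoded to the
#' questionnaire codes (1 = yes, 2 = no) and the ten columns are written in
#' schema order. Round-trips bit-exactly through [read_ppd()].
#'
#' @inheritParams validate_ppd
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppd <- function(data, path, schema = ppd_schema()) {
  data <- validate_ppd(data, schema)
  out <- data[schema$attributes$name]
  y <- out[[schema$target_name]]
  out[[schema$target_name]] <- ifelse(y == 1L, schema$positive_code, 2L)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Serialize or load a feature schema
#'
#' The schema is stored as JSON so alternative encodings (other code sets or
#' attribute names) can be supplied through a config file.
#'
#' @param schema A [ppd_schema()].
#' @param path JSON file path.
#' @return `read_schema()` returns a `ppd_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  obj <- list(
    attributes = lapply(seq_len(nrow(schema$attributes)), function(i) {
      list(name = schema$attributes$name[i],
           codes = schema$attributes$codes[[i]],
           meanings = as.list(schema$attributes$meanings[[i]]))
    }),
    target_name = schema$target_name,
    positive_code = schema$positive_code
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path)
  attributes <- tibble(
    name = vapply(obj$attributes, `[[`, character(1), "name"),
    codes = lapply(obj$attributes, function(a) as.integer(unlist(a$codes))),
    meanings = lapply(obj$attributes, function(a) unlist(a$meanings))
  )
  structure(
    list(attributes = attributes,
         target_name = obj$target_name,
         positive_code = as.integer(obj$positive_code)),
    class = "ppd_schema"
  )
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Stratified train/test split
#'
#' Partitions a dataset into disjoint train and test sets. The test size is
#' `round(n * (1 - train_fraction))` with ties rounded half away from zero;
#' sizes depend only on `n` and `train_fraction`, never on the seed. When
#' `stratified = TRUE` (default) the per-class test counts are allocated by
#' largest remainder so class proportions are preserved to within rounding —
#' advisable here because the positive class dominates (~65/35) and small
#' test sets at a 9:1 ratio would otherwise be unstable.
#'
#' @inheritParams validate_ppd
#' @param train_fraction Fraction of records assigned to the training set,
#'   in (0, 1); e.g. 0.7 for the 7:3 ratio.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param stratified Preserve class proportions across the two sets?
#' @return A list with tibbles `train` and `test`.
#' @examples
#' d <- generate_ppd(ppd_generator_spec(n = 100, seed = 1))
#' s <- split_ppd(d, train_fraction = 0.7, seed = 1)
#' nrow(s$train); nrow(s$test)
#' @export
split_ppd <- function(data, train_fraction, seed = 1L,
                      stratified = TRUE, schema = ppd_schema()) {
  data <- validate_ppd(data, schema)
  n <- nrow(data)
  if (n < 2) abort("need at least 2 records to split",
                   class = "ppd_validation_error")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1",
          class = "ppd_config_error")
  }
  n_test <- as.integer(round_half_away(n * (1 - train_fraction)))
  if (n_test < 1 || n_test >= n) {
    abort("degenerate split: one side would be empty",
          class = "ppd_validation_error")
  }
  y <- data[[schema$target_name]]
  test_idx <- withr::with_seed(seed, {
    if (stratified) {
      cls <- split(seq_len(n), y)
      if (any(vapply(cls, length, integer(1)) < 1)) {
        abort("stratified split needs at least one record per class",
              class = "ppd_validation_error")
      }
      # largest-remainder allocation of the test quota across classes
      quota <- n_test * vapply(cls, length, integer(1)) / n
      take <- floor(quota)
      rem <- n_test - sum(take)
      if (rem > 0) {
        extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
        take[extra] <- take[extra] + 1
      }
      take <- pmin(take, vapply(cls, length, integer(1)))
      sort(unlist(Map(function(idx, k) {
        if (k == 0) integer(0) else sample(idx, k)
      }, cls, take), use.names = FALSE))
    } else {
      sort(sample.int(n, n_test))
    }
  })
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}
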