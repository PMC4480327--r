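## Core data model and I/O for the weed-traits database (WTDB).
##
## Records are kept in a long (tidy) layout: one row per (species, field,
## source) observation, with source-quality metadata.  Multi-source entries
## for the same species/field are first-class; aggregation to species level
## happens in summarize_species().

#' Legal WTDB field codes
#'
#' Returns the full set of database field codes, grouped by life-cycle
#' transition: seedbank-to-seedling (germination and emergence), seedling to
#' mature biomass (competition, juvenile phenology), biomass to fresh seed
#' (seed weight, allometric fecundity, flowering/maturation phenology) and
#' fresh seed back to seedbank (seed coat, seedbank persistence, emergence
#' depth).
#'
#' @return Character vector of field codes.
#' @export
wtdb_field_codes <- function() {
  c(
    "GERMBASE", "GERMCHILL", "GERMLIGHT",
    paste0("EMCAL_", 1:12),
    paste0("EMTOT_", 1:2),
    "COMPHEIGHT",
    paste0("COMPHYP_", 1:2),
    paste0("PHENJUV_", 1:4),
    "SEEDWEIGHT",
    paste0("FECUNDITY_", 1:2),
    paste0("PHENFLO_", 1:4),
    paste0("PHENMAT_", 1:4),
    "SEEDCOAT",
    paste0("SEEDPER_", 1:2),
    paste0("EMDEPTH_", 1:2)
  )
}

# codes whose value is a category token, and the legal tokens
wtdb_categorical_codes <- function() c("GERMCHILL", "GERMLIGHT")
wtdb_categories <- function() c("absolute", "partial", "none")

# codes whose numeric value must be strictly positive
wtdb_positive_codes <- function() {
  c("SEEDWEIGHT", "COMPHEIGHT", paste0("EMDEPTH_", 1:2), paste0("SEEDPER_", 1:2))
}

#' Source-quality categories
#' @return Character vector of the five recognised data-quality classes.
#' @export
wtdb_source_qualities <- function() {
  c("peer_reviewed", "conference", "report", "unpublished", "expert_opinion")
}

wtdb_mandatory_columns <- function() {
  c("species", "field_code", "value", "units", "source_quality")
}

wtdb_optional_columns <- function() c("crop", "location", "disturbed", "notes")

new_trait_records <- function(df) {
  df$value_num <- suppressWarnings(as.numeric(df$value))
  class(df) <- c("trait_records", "data.frame")
  df
}

# Row-level validation; returns character vector of "row N: problem" strings.
validate_trait_rows <- function(df) {
  problems <- character(0)
  add <- function(rows, msg) {
    if (length(rows)) c(problems, sprintf("row %d: %s", rows, msg)) else problems
  }
  codes <- wtdb_field_codes()
  bad_code <- which(!(df$field_code %in% codes))
  if (length(bad_code)) {
    problems <- c(problems, sprintf(
      "row %d: unknown field_code '%s' (legal codes: %s)",
      bad_code, df$field_code[bad_code], paste(codes, collapse = ", ")
    ))
  }
  ok_code <- df$field_code %in% codes
  is_cat <- df$field_code %in% wtdb_categorical_codes()
  bad_cat <- which(ok_code & is_cat & !(df$value %in% wtdb_categories()))
  problems <- add(bad_cat, sprintf(
    "categorical value '%s' not one of %s",
    df$value[bad_cat], paste(wtdb_categories(), collapse = "/")
  ))
  num <- suppressWarnings(as.numeric(df$value))
  bad_num <- which(ok_code & !is_cat & (is.na(num) | !is.finite(num)))
  problems <- add(bad_num, sprintf("non-numeric value '%s'", df$value[bad_num]))
  need_pos <- df$field_code %in% wtdb_positive_codes()
  bad_pos <- which(ok_code & need_pos & !is.na(num) & num <= 0)
  problems <- add(bad_pos, sprintf(
    "%s must be strictly positive, got %s", df$field_code[bad_pos], df$value[bad_pos]
  ))
  bad_q <- which(!(df$source_quality %in% wtdb_source_qualities()))
  problems <- add(bad_q, sprintf(
    "unknown source_quality '%s'", df$source_quality[bad_q]
  ))
  # emergence calendars must close to 100% across months within a source
  emcal <- ok_code & grepl("^EMCAL_", df$field_code) & !is.na(num)
  if (any(emcal)) {
    key <- interaction(df$species, df$source_quality, drop = TRUE)
    for (k in unique(key[emcal])) {
      idx <- which(emcal & key == k)
      s <- sum(num[idx])
      if (abs(s - 100) > 0.5) {
        problems <- c(problems, sprintf(
          "row %d: EMCAL percentages for '%s' sum to %.3f, expected 100 +/- 0.5",
          idx[1], df$species[idx[1]], s
        ))
      }
    }
  }
  problems
}

#' Read a trait table from delimited text
#'
#' Reads a comma-separated UTF-8 file (RFC-4180 quoting, header mandatory)
#' with columns `species`, `field_code`, `value`, `units`, `source_quality`
#' and optionally `crop`, `location`, `disturbed`, `notes`, and validates
#' every row against the WTDB schema.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default) any invalid row raises a validation
#'   error carrying row-numbered diagnostics; if `FALSE` invalid rows are
#'   dropped with a warning.
#' @return A `trait_records` data frame (long layout, one row per record)
#'   with a derived numeric column `value_num` (`NA` for categorical codes).
#' @export
read_trait_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) wf_io_error(sprintf("trait table '%s' does not exist", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(wtdb_mandatory_columns(), names(df))
  if (length(missing_cols)) {
    wf_format_error(sprintf(
      "trait table '%s' lacks mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in wtdb_optional_columns()) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
  }
  df <- df[c(wtdb_mandatory_columns(), wtdb_optional_columns())]
  df$disturbed <- as.logical(df$disturbed)
  if (nrow(df) == 0L) return(new_trait_records(df))
  problems <- validate_trait_rows(df)
  if (length(problems)) {
    if (strict) {
      wf_validation_error(paste0(
        "invalid trait record(s) in '", path, "':\n  ",
        paste(problems, collapse = "\n  ")
      ))
    }
    bad_rows <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", problems)))
    warning(sprintf("dropping %d invalid row(s): %s", length(bad_rows),
                    paste(problems, collapse = "; ")), call. = FALSE)
    df <- df[-bad_rows, , drop = FALSE]
    rownames(df) <- NULL
  }
  new_trait_records(df)
}

#' Validate an in-memory trait-record table
#'
#' @param records A data frame with at least the mandatory WTDB columns.
#' @return The validated `trait_records` object (invisible errors otherwise).
#' @export
as_trait_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(wtdb_mandatory_columns(), names(records))
  if (length(missing_cols)) {
    wf_format_error(paste("missing mandatory column(s):",
                          paste(missing_cols, collapse = ", ")))
  }
  for (col in wtdb_optional_columns()) {
    if (!col %in% names(records)) records[[col]] <- rep(NA, nrow(records))
  }
  records$value <- as.character(records$value)
  problems <- validate_trait_rows(records)
  if (length(problems)) {
    wf_validation_error(paste0("invalid trait record(s):\n  ",
                               paste(problems, collapse = "\n  ")))
  }
  new_trait_records(records)
}

#' Write a trait table to delimited text
#'
#' Inverse of [read_trait_table()]: records written with this function and
#' read back compare field-for-field.
#'
#' @param records A `trait_records` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path) {
  cols <- c(wtdb_mandatory_columns(), wtdb_optional_columns())
  out <- as.data.frame(records)[cols]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarise trait records by species and field
#'
#' Aggregates multi-source records to one row per (species, field_code):
#' count, mean, median, min, max and the within-field variability expressed
#' as the maximum value as a percentage of the minimum.  Categorical fields
#' carry the modal category and no numeric statistics.
#'
#' @param records A `trait_records` object with at least one row.
#' @param endpoint_only Label the result as computed from printed range
#'   endpoints rather than full raw data (see [load_table2_fixture()]).
#' @return A `species_trait_summary` data frame.
#' @export
summarize_species <- function(records, endpoint_only = isTRUE(attr(records, "endpoint_only"))) {
  if (nrow(records) == 0L) wf_validation_error("cannot summarise an empty record set")
  key <- interaction(records$species, records$field_code, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    sp <- records$species[idx[1]]
    fc <- records$field_code[idx[1]]
    if (fc %in% wtdb_categorical_codes()) {
      tab <- table(records$value[idx])
      data.frame(
        species = sp, field_code = fc, n_records = length(idx),
        mean = NA_real_, median = NA_real_, min = NA_real_, max = NA_real_,
        variability_pct = NA_real_,
        modal_category = names(tab)[which.max(tab)],
        stringsAsFactors = FALSE
      )
    } else {
      v <- records$value_num[idx]
      mn <- min(v); mx <- max(v)
      data.frame(
        species = sp, field_code = fc, n_records = length(idx),
        mean = mean(v), median = stats::median(v), min = mn, max = mx,
        variability_pct = if (mn > 0) 100 * mx / mn else NA_real_,
        modal_category = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "endpoint_only") <- isTRUE(endpoint_only)
  class(out) <- c("species_trait_summary", "data.frame")
  out
}

#' Species-by-field matrix of mean trait values
#'
#' @param summaries A `species_trait_summary`.
#' @param fields Field codes to include as columns.
#' @return Numeric matrix, species in rows.
#' @export
species_mean_matrix <- function(summaries, fields) {
  species <- sort(unique(summaries$species))
  m <- matrix(NA_real_, length(species), length(fields),
              dimnames = list(species, fields))
  for (f in fields) {
    sub <- summaries[summaries$field_code == f, ]
    m[sub$species, f] <- sub$mean
  }
  m
}

#' Pairwise correlation matrix of species-mean trait values
#'
#' Correlations are computed on species means, pairwise-complete.  Pairs
#' with fewer than `min_n` shared species, or with a zero-variance column,
#' are flagged absent rather than propagating `NaN`.
#'
#' @param summaries A `species_trait_summary`.
#' @param fields Field codes (or derived columns such as `"D5PCT"` added via
#'   [add_d5_summaries()]) to correlate.
#' @param min_n Minimum shared species per pair (default 3).
#' @return A `trait_correlations` object: list with `r` (correlations, `NA`
#'   where flagged), `n` (shared species per pair) and `status`
#'   (`"ok"`, `"insufficient_n"` or `"zero_variance"`).
#' @export
correlation_matrix <- function(summaries, fields, min_n = 3L) {
  m <- species_mean_matrix(summaries, fields)
  k <- length(fields)
  r <- diag(1, k); dimnames(r) <- list(fields, fields)
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  status <- matrix("ok", k, k, dimnames = dimnames(r))
  for (a in seq_len(k)) {
    n[a, a] <- sum(!is.na(m[, a]))
    for (b in seq_len(k)) {
      if (a >= b) next
      shared <- !is.na(m[, a]) & !is.na(m[, b])
      n[a, b] <- n[b, a] <- sum(shared)
      if (sum(shared) < min_n) {
        r[a, b] <- r[b, a] <- NA_real_
        status[a, b] <- status[b, a] <- "insufficient_n"
      } else if (stats::var(m[shared, a]) == 0 || stats::var(m[shared, b]) == 0) {
        r[a, b] <- r[b, a] <- NA_real_
        status[a, b] <- status[b, a] <- "zero_variance"
      } else {
        r[a, b] <- r[b, a] <- stats::cor(m[shared, a], m[shared, b])
      }
    }
  }
  structure(list(r = r, n = n, status = status, fields = fields),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  cat("Trait correlation matrix (species means, pairwise complete)\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Hyperbolic (Cousens) yield-loss function
#'
#' Percentage crop yield loss at weed density `d`:
#' `YL = i d / (1 + i d / m)`, where `i` is the percent loss per plant per
#' square metre as density approaches zero and `m` the asymptotic maximum
#' percent loss.
#'
#' @param i Percent yield loss per plant m^-2 at low density (> 0).
#' @param d Weed density, plants m^-2 (>= 0).
#' @param m Maximum percent yield loss at high density.
#' @return Percent yield loss, in `[0, m)`.
#' @export
yield_loss_hyperbolic <- function(i, d, m) {
  i * d / (1 + i * d / m)
}

#' Weed density causing a 5% yield loss
#'
#' Inverts the hyperbolic yield-loss function at 5%:
#' `D5 = 5 / (i (1 - 5/m))`.  `D5%` is used as a scalar index of
#' competitive ability; it exists only when the asymptote `m` exceeds 5%.
#'
#' @param i Percent yield loss per plant m^-2 at low density (> 0).
#' @param m Maximum percent yield loss (> 5).
#' @return Density in plants m^-2.
#' @export
d5_from_comphyp <- function(i, m) {
  if (any(!is.finite(i)) || any(i <= 0)) {
    wf_validation_error("`i` must be strictly positive and finite")
  }
  if (any(!is.finite(m) & !is.infinite(m))) {
    wf_validation_error("`m` must be numeric")
  }
  if (any(m <= 5)) {
    wf_validation_error("a 5% yield loss is unreachable when the asymptote m <= 5")
  }
  5 / (i * (1 - 5 / m))
}

#' Append derived D5% rows to a species summary
#'
#' Computes `D5%` from each species' mean hyperbolic-yield-loss parameters
#' (`COMPHYP_1` = i, `COMPHYP_2` = m) and appends it under the pseudo field
#' code `D5PCT`, so it can enter [correlation_matrix()] alongside raw fields.
#' Species lacking either parameter, or with mean `m <= 5`, are skipped.
#'
#' @param summaries A `species_trait_summary`.
#' @return The summary with `D5PCT` rows appended.
#' @export
add_d5_summaries <- function(summaries) {
  m <- species_mean_matrix(summaries, c("COMPHYP_1", "COMPHYP_2"))
  ok <- !is.na(m[, 1]) & !is.na(m[, 2]) & m[, 2] > 5 & m[, 1] > 0
  if (!any(ok)) return(summaries)
  d5 <- d5_from_comphyp(m[ok, 1], m[ok, 2])
  extra <- data.frame(
    species = rownames(m)[ok], field_code = "D5PCT",
    n_records = 1L, mean = d5, median = d5, min = d5, max = d5,
    variability_pct = 100, modal_category = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(summaries), extra)
  attr(out, "endpoint_only") <- attr(summaries, "endpoint_only")
  class(out) <- class(summaries)
  out
}
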