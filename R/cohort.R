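#' Cohort table schema
#'
#' Field-by-field contract for a tinnitus treatment-decision cohort: one row
#' per participant holding the yes/no treatment decisions, the candidate
#' decision drivers (hearing loss at 8 kHz worst ear in dB HL; baseline THI
#' score), outcome scores, and the auxiliary covariates consumed by the
#' imputation chain. Questionnaire scores live on 0-100; hearing loss on
#' [-10, 130] dB HL. `decision_sedu` (device purchase) is only meaningful
#' after a `decision_sedep = "yes"` evaluation period.
#'
#' @return A named list of field specifications (`type`, plus `range` or
#'   `levels`).
#' @export
cohort_schema <- function() {
  list(
    participant_id = list(type = "id"),
    age            = list(type = "numeric", range = c(0, 120)),
    sex            = list(type = "category",
                          levels = c("male", "female", "missing")),
    hearing_loss   = list(type = "numeric", range = c(-10, 130)),
    thi_baseline   = list(type = "numeric", range = c(0, 100)),
    thi_post       = list(type = "numeric", range = c(0, 100)),
    ghsi_baseline  = list(type = "numeric", range = c(0, 100)),
    decision_sedep = list(type = "decision",
                          levels = c("yes", "no", "missing")),
    decision_sedu  = list(type = "decision",
                          levels = c("yes", "no", "missing",
                                     "not_applicable")),
    decision_pcu   = list(type = "decision",
                          levels = c("yes", "no", "missing")),
    tinnitus_duration = list(type = "category",
                             levels = c("<=2mo", "2-6mo", ">6mo")),
    non_hearing_problems = list(type = "category",
                                levels = c("none", "family", "work",
                                           "personality")),
    tinnitus_type  = list(type = "category",
                          levels = c("tonal", "noise", "different",
                                     "missing")),
    referring_specialty = list(type = "category",
                               levels = c("GP", "ORL", "missing"))
  )
}

## fields whose missing values the imputation chain may fill
imputable_fields <- function() c("thi_baseline", "thi_post", "ghsi_baseline")

imputed_flag_cols <- function() paste0("imputed_", imputable_fields())

## deterministic 32-bit FNV-1a hash of a string, for provenance headers;
## arithmetic kept in doubles with a split multiply to stay exact mod 2^32
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31)) # low 31 bits rendered as hex
}

## hash of the scientific configuration; I/O locations are excluded so
## identical analyses written to different directories share a hash
config_hash <- function(config) {
  config$output <- NULL
  config$input <- NULL
  fnv1a_hash(paste(deparse(config), collapse = ""))
}

validate_cohort_rows <- function(df) {
  schema <- cohort_schema()
  problems <- character(0)
  for (fld in names(schema)) {
    spec <- schema[[fld]]
    if (!fld %in% names(df)) next
    col <- df[[fld]]
    if (spec$type == "numeric") {
      bad <- which(!is.na(col) & (col < spec$range[1] | col > spec$range[2]))
      for (i in bad) {
        problems <- c(problems, sprintf(
          "row %d, column '%s': value %s outside [%g, %g]",
          i, fld, format(col[i]), spec$range[1], spec$range[2]))
      }
    } else if (spec$type %in% c("category", "decision")) {
      bad <- which(!is.na(col) & !(col %in% spec$levels))
      for (i in bad) {
        problems <- c(problems, sprintf(
          "row %d, column '%s': unknown level '%s' (expected one of %s)",
          i, fld, col[i], paste(spec$levels, collapse = ", ")))
      }
    }
  }
  if (all(c("decision_sedep", "decision_sedu") %in% names(df))) {
    bad <- which(!is.na(df$decision_sedu) & df$decision_sedu == "yes" &
                   (is.na(df$decision_sedep) | df$decision_sedep != "yes"))
    for (i in bad) {
      problems <- c(problems, sprintf(
        "row %d: decision_sedu is 'yes' but decision_sedep is not 'yes'", i))
    }
  }
  problems
}

as_cohort_table <- function(df) {
  for (flag in imputed_flag_cols()) {
    if (!flag %in% names(df)) df[[flag]] <- rep(FALSE, nrow(df))
    df[[flag]] <- as.logical(df[[flag]])
  }
  problems <- validate_cohort_rows(df)
  if (length(problems)) {
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from delimited text
#'
#' Parses a delimited file into a validated cohort table. Lines starting
#' with `#` (provenance headers) are skipped. Column names are mapped onto
#' the schema either directly or through `config$column_map` (a named
#' character vector `schema_field = file_column`). Values equal to
#' `config$na_token` become missing; missingness flags for the imputable
#' score fields are initialized to `FALSE` unless the file carries
#' `imputed_*` columns.
#'
#' @param path Path to the delimited text file.
#' @param config List with optional `delimiter` (default `","`),
#'   `na_token` (default `"NA"`), `column_map`.
#' @return A `cohort_table` (data.frame subclass). Rows violating hard
#'   range/level invariants abort with row-indexed diagnostics.
#' @export
read_cohort <- function(path, config = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- config$delimiter %||% ","
  na_token <- config$na_token %||% "NA"
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          na.strings = na_token, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(config$column_map)) {
    cm <- config$column_map
    for (schema_field in names(cm)) {
      file_col <- cm[[schema_field]]
      if (!file_col %in% names(df)) {
        stop("column_map refers to absent file column '", file_col, "'")
      }
      names(df)[names(df) == file_col] <- schema_field
    }
  }
  schema <- cohort_schema()
  missing_cols <- setdiff(c("participant_id"), names(df))
  if (length(missing_cols)) {
    stop("required column(s) missing: ", paste(missing_cols, collapse = ", "))
  }
  for (fld in names(schema)) {
    if (fld %in% names(df) && schema[[fld]]$type == "numeric") {
      suppressWarnings(num <- as.numeric(df[[fld]]))
      bad <- which(is.na(num) & !is.na(df[[fld]]))
      if (length(bad)) {
        stop(sprintf("row %d, column '%s': non-numeric value '%s'",
                     bad[1], fld, df[[fld]][bad[1]]))
      }
      df[[fld]] <- num
    }
  }
  as_cohort_table(df)
}

#' Write a cohort table to delimited text with a provenance header
#'
#' Emits a single `#`-prefixed provenance line (package version, seed,
#' config hash) followed by a standard CSV, round-trippable through
#' [read_cohort()].
#'
#' @param table A `cohort_table`.
#' @param path Output path.
#' @param seed Integer seed recorded in the header (may be `NA`).
#' @param config The run configuration whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, seed = NA_integer_, config = list()) {
  stopifnot(inherits(table, "cohort_table"))
  version <- as.character(utils::packageVersion("sdtreat"))
  cfg_hash <- config_hash(config)
  header <- sprintf("# sdtreat %s | seed=%s | config=%s",
                    version, format(seed), cfg_hash)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(table), con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Label participants by minimal clinically important difference
#'
#' Assigns the S2 (improved) population label when the THI score decreased
#' by strictly more than `mcid` points after treatment, i.e.
#' `thi_post - thi_baseline < -mcid`; a change of exactly `-mcid` — or any
#' smaller improvement or deterioration — is S1. Vectorized.
#'
#' @param thi_baseline,thi_post Numeric THI scores (0-100), no missing
#'   values; impute first if needed.
#' @param mcid Minimal clinically important difference in THI points
#'   (default 7, must be > 0).
#' @return Character vector of `"S1"` / `"S2"`.
#' @examples
#' label_outcome(48, 30)  # "S2": improved by 18 points
#' label_outcome(48, 41)  # "S1": change of exactly -7 is not enough
#' @export
label_outcome <- function(thi_baseline, thi_post, mcid = 7) {
  stopifnot(mcid > 0)
  if (anyNA(thi_baseline) || anyNA(thi_post)) {
    stop("missing THI score(s): impute post-treatment and baseline scores ",
         "before labelling outcomes")
  }
  ifelse(thi_post - thi_baseline < -mcid, "S2", "S1")
}

#' Extract the marginal yes/no dataset for one decision and driver
#'
#' Collapses the joint structure of the two decisions over the non-target
#' decision: a participant contributes `y = 1` to the target decision iff
#' they answered yes to it, regardless of the other decision. Rows with a
#' missing or not-applicable value on the target decision are dropped (and
#' counted), mirroring per-analysis sample sizes. Outcome labels come from
#' [label_outcome()], so both THI scores must be present (impute first).
#'
#' @param table A `cohort_table`.
#' @param decision_id One of `"SEDEP"`, `"PCU"`, `"SEDU"`.
#' @param driver_id One of `"hearing_loss"`, `"thi_baseline"`.
#' @param x_min,x_max Optional fixed driver bounds; default to observed
#'   extrema.
#' @param mcid MCID passed to [label_outcome()].
#' @param min_per_population Minimum observations required in each of S1
#'   and S2.
#' @return A `decision_dataset`: data.frame with columns `x`, `y`,
#'   `population` and attributes `decision_id`, `driver_id`, `x_min`,
#'   `x_max`, `orientation` (`"as_is"`), `reversal_offset`, `n_dropped`.
#' @export
extract_decision_dataset <- function(table, decision_id, driver_id,
                                     x_min = NULL, x_max = NULL, mcid = 7,
                                     min_per_population = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  decision_id <- match.arg(decision_id, c("SEDEP", "PCU", "SEDU"))
  driver_id <- match.arg(driver_id, c("hearing_loss", "thi_baseline"))
  dec_col <- switch(decision_id,
                    SEDEP = "decision_sedep",
                    PCU = "decision_pcu",
                    SEDU = "decision_sedu")
  dec <- table[[dec_col]]
  keep <- !is.na(dec) & dec %in% c("yes", "no")
  n_dropped <- sum(!keep)
  sub <- table[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows with an observed '", decision_id,
                            "' decision")
  if (anyNA(sub[[driver_id]])) {
    stop("driver '", driver_id, "' has missing values among retained rows; ",
         "impute or drop them first")
  }
  population <- label_outcome(sub$thi_baseline, sub$thi_post, mcid = mcid)
  for (pop in c("S1", "S2")) {
    if (sum(population == pop) < min_per_population) {
      stop("population ", pop, " ",
           if (sum(population == pop) == 0L) "empty"
           else sprintf("has only %d observation(s), need >= %d",
                        sum(population == pop), min_per_population))
    }
  }
  obs <- data.frame(x = sub[[driver_id]],
                    y = as.integer(sub[[dec_col]] == "yes"),
                    population = population,
                    stringsAsFactors = FALSE)
  structure(obs,
            decision_id = decision_id,
            driver_id = driver_id,
            x_min = x_min %||% min(obs$x),
            x_max = x_max %||% max(obs$x),
            orientation = "as_is",
            reversal_offset = NA_real_,
            n_dropped = n_dropped,
            class = c("decision_dataset", "data.frame"))
}

#' Marginal yes/no counts from a 2x2 joint decision table
#'
#' Bookkeeping helper: collapses joint counts of the two decisions onto
#' each margin. Totals are conserved (yes + no on each margin equals the
#' joint total).
#'
#' @param joint Named numeric vector with elements `yy`, `yn`, `ny`, `nn`
#'   where the first letter is the SEDEP decision and the second the PCU
#'   decision.
#' @return List with elements `SEDEP` and `PCU`, each `c(yes =, no =)`,
#'   and `total`.
#' @examples
#' marginal_counts(c(yy = 43, yn = 63, ny = 12, nn = 25))
#' @export
marginal_counts <- function(joint) {
  stopifnot(all(c("yy", "yn", "ny", "nn") %in% names(joint)))
  list(
    SEDEP = c(yes = unname(joint["yy"] + joint["yn"]),
              no  = unname(joint["ny"] + joint["nn"])),
    PCU   = c(yes = unname(joint["yy"] + joint["ny"]),
              no  = unname(joint["yn"] + joint["nn"])),
    total = sum(joint[c("yy", "yn", "ny", "nn")])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
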