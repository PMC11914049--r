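#' Controlled vocabularies for benthic survey records
#'
#' The seven hard-coral taxon groups tracked throughout the package (six
#' genus/family groups plus a pooled "other hard corals" group), the five
#' survey methods, and the two substrate classes. Cover not accounted for by
#' these taxa is the coral-free base, `"other_benthic"`, which closes every
#' composition.
#'
#' @return A character vector of lower-case labels.
#' @export
reef_taxa <- function() {
  c("acropora", "pocillopora", "montipora", "porites",
    "faviidae", "millepora", "other_hard")
}

#' @rdname reef_taxa
#' @export
reef_methods <- function() {
  c("quadrat", "belt_transect", "spot_check", "manta", "snorkel")
}

#' @rdname reef_taxa
#' @export
reef_substrates <- function() c("artificial", "natural")

# column schema for survey CSV files; colony_<taxon> columns are optional
survey_required_cols <- function() {
  c("record_id", "site_id", "substrate", "year", "elevation_lwl_m",
    "slope_deg", "method", "total", reef_taxa())
}

survey_optional_cols <- function() {
  c(paste0("colony_", reef_taxa()), paste0("maxdiam_", reef_taxa()),
    "sedimentation_rank")
}

#' Parse semi-quantitative cover tokens
#'
#' Benthic cover cells in historical survey reports may hold a number, a
#' range ("20-30", en-dash accepted), the rarity symbol "R" (less than 1%
#' cover), "+" (1-5% cover), an explicit "0", or nothing at all. An empty
#' cell means the taxon was not surveyed ("no data") and is deliberately kept
#' distinct from a recorded zero. Ranges resolve to their midpoint (the
#' median of an interval). The symbols carry no stand-alone value at parse
#' time: in a *total*-cover cell they resolve via [resolve_total()]; in a
#' per-taxon cell they are resolved jointly by [allocate_taxon_cover()].
#'
#' @param tokens Character vector of raw cell contents.
#' @param cells Optional character vector of cell labels used in error
#'   messages (defaults to the token itself).
#' @return A tibble with columns `raw_token`, `kind` (one of `numeric`,
#'   `range`, `rare_symbol`, `plus_symbol`, `zero`, `missing`) and
#'   `resolved_percent` (`NA` for missing and for unresolved symbols).
#' @examples
#' parse_cover_entry(c("12", "20-30", "R", "+", "0", ""))
#' @export
parse_cover_entry <- function(tokens, cells = NULL) {
  tokens <- as.character(tokens)
  cells <- cells %||% ifelse(is.na(tokens), "<NA>", tokens)
  tok <- stringr::str_trim(tokens)
  tok[is.na(tok)] <- ""
  n <- length(tok)
  kind <- character(n)
  val <- rep(NA_real_, n)

  # normalize unicode dashes used in historical range entries
  norm <- stringr::str_replace_all(tok, "[‒–—―]", "-")
  is_range <- stringr::str_detect(norm, "^[0-9.]+\\s*-\\s*[0-9.]+$")

  for (i in seq_len(n)) {
    t <- norm[i]
    if (t == "") {
      kind[i] <- "missing"
    } else if (t %in% c("R", "r")) {
      kind[i] <- "rare_symbol"
    } else if (t == "+") {
      kind[i] <- "plus_symbol"
    } else if (is_range[i]) {
      bounds <- as.numeric(stringr::str_split_1(t, "\\s*-\\s*"))
      if (anyNA(bounds)) {
        abort(sprintf("Malformed range in cell '%s'", cells[i]))
      }
      if (bounds[1] > bounds[2]) {
        abort(sprintf("Inverted range (low > high) in cell '%s'", cells[i]))
      }
      kind[i] <- "range"
      val[i] <- mean(bounds)
    } else {
      x <- suppressWarnings(as.numeric(t))
      if (is.na(x)) {
        abort(sprintf("Malformed cover entry in cell '%s'", cells[i]))
      }
      if (x == 0) {
        kind[i] <- "zero"
        val[i] <- 0
      } else {
        kind[i] <- "numeric"
        val[i] <- x
      }
    }
    if (!is.na(val[i]) && (val[i] < 0 || val[i] > 100)) {
      abort(sprintf("Cover outside [0, 100] in cell '%s'", cells[i]))
    }
  }
  tibble(raw_token = tokens, kind = kind, resolved_percent = val)
}

#' Resolve a total-cover entry to percent
#'
#' In the total-cover column, "R" (rare, under 1% cover) is valued at 0.5%
#' and "+" (1-5% cover) at 3%; numbers and range midpoints pass through. A
#' missing entry means no survey was conducted and resolves to `NA`, which
#' downstream excludes the record from analyses needing a total.
#'
#' @param entry A tibble from [parse_cover_entry()], or a character vector of
#'   raw tokens.
#' @return Numeric vector of percents (`NA` for missing entries).
#' @examples
#' resolve_total(c("R", "+", "23", "20-30"))
#' @export
resolve_total <- function(entry) {
  if (is.character(entry)) entry <- parse_cover_entry(entry)
  stopifnot(all(c("kind", "resolved_percent") %in% names(entry)))
  dplyr::case_when(
    entry$kind == "rare_symbol" ~ 0.5,
    entry$kind == "plus_symbol" ~ 3.0,
    entry$kind == "missing" ~ NA_real_,
    TRUE ~ entry$resolved_percent
  )
}

#' Allocate symbolic per-taxon cover against the recorded total
#'
#' Historical records often mix numeric taxon covers with "R" and "+"
#' symbols, and the taxon sum need not match the recorded total. The
#' allocation rule values the symbols from the unexplained remainder: count
#' R-units over the symbolic cells ("+" counts as 6 R-units), take
#' `diff = total - sum(numeric taxon covers)`, and if `diff > 0` assign each
#' symbolic taxon `units * diff / n_units`; if `diff <= 0` every symbolic
#' taxon gets 0. Numeric entries are never rescaled. Missing cells stay
#' missing.
#'
#' @param taxon_entries Named character vector (or 1-row data frame) of raw
#'   tokens for the seven taxa in [reef_taxa()].
#' @param total_entry Raw token (or number) for the total-cover cell.
#' @return Named numeric vector of percent cover per taxon; `NA` where the
#'   cell was missing.
#' @examples
#' allocate_taxon_cover(
#'   c(acropora = "+", pocillopora = "R", montipora = "4", porites = "3",
#'     faviidae = "0", millepora = "", other_hard = "0"),
#'   total_entry = "10")
#' @export
allocate_taxon_cover <- function(taxon_entries, total_entry) {
  if (is.data.frame(taxon_entries)) {
    taxon_entries <- unlist(taxon_entries[1, , drop = TRUE])
  }
  taxa <- names(taxon_entries)
  if (is.null(taxa) || !all(taxa %in% reef_taxa())) {
    bad <- setdiff(taxa, reef_taxa())
    abort(sprintf("Unknown taxon entries: %s",
                  paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")))
  }
  parsed <- parse_cover_entry(as.character(taxon_entries), cells = taxa)
  total <- resolve_total(parse_cover_entry(as.character(total_entry), "total"))
  if (is.na(total)) {
    abort("Total cover is missing ('no data'): allocation refused")
  }

  units <- dplyr::case_when(
    parsed$kind == "rare_symbol" ~ 1,
    parsed$kind == "plus_symbol" ~ 6,
    TRUE ~ 0
  )
  out <- parsed$resolved_percent
  numeric_sum <- sum(out[units == 0], na.rm = TRUE)
  n_units <- sum(units)
  if (n_units > 0) {
    diff <- total - numeric_sum
    unit_value <- if (diff > 0) diff / n_units else 0
    out[units > 0] <- units[units > 0] * unit_value
  }
  setNames(out, taxa)
}

#' Read a benthic survey table
#'
#' Reads a long-format survey CSV (one row per cover record) and validates
#' it against the documented schema: closed site/method/substrate
#' vocabularies, the fixed seven-taxon column set, unique record ids.
#' Cover cells are kept as raw tokens; use [resolve_survey()] to obtain
#' numeric percent cover.
#'
#' @param path Path to a CSV file with columns `record_id`, `site_id`,
#'   `substrate`, `year`, `elevation_lwl_m` (signed metres relative to low
#'   water level, positive upward), `slope_deg`, `method`, `total`, one
#'   column per taxon in [reef_taxa()], and optionally `colony_<taxon>`,
#'   `maxdiam_<taxon>` and `sedimentation_rank` columns.
#' @param quiet Suppress the summary message.
#' @return A tibble of validated raw records (class `survey_table`).
#' @export
read_survey_table <- function(path, quiet = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  unknown <- setdiff(names(raw), c(survey_required_cols(), survey_optional_cols()))
  if (length(unknown)) {
    abort(sprintf("Unknown column(s) in survey table: %s",
                  paste(unknown, collapse = ", ")))
  }
  miss <- setdiff(survey_required_cols(), names(raw))
  if (length(miss)) {
    abort(sprintf("Missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(raw$record_id)) {
    dup <- raw$record_id[duplicated(raw$record_id)][1]
    abort(sprintf("Duplicate record_id '%s' (row %d)", dup,
                  which(raw$record_id == dup)[2]))
  }
  check_vocab <- function(col, vocab) {
    bad <- which(!raw[[col]] %in% vocab)
    if (length(bad)) {
      abort(sprintf("Row %d: %s '%s' not in {%s}", bad[1], col,
                    raw[[col]][bad[1]], paste(vocab, collapse = ", ")))
    }
  }
  check_vocab("substrate", reef_substrates())
  check_vocab("method", reef_methods())
  if ("sedimentation_rank" %in% names(raw)) {
    ok <- is.na(raw$sedimentation_rank) | raw$sedimentation_rank %in% c("I", "II", "III", "IV")
    if (!all(ok)) abort(sprintf("Row %d: invalid sedimentation_rank", which(!ok)[1]))
  }
  out <- raw |>
    mutate(
      year = as.integer(.data$year),
      elevation_lwl_m = as.numeric(.data$elevation_lwl_m),
      slope_deg = as.numeric(.data$slope_deg)
    )
  if (any(!is.na(out$slope_deg) & (out$slope_deg < 0 | out$slope_deg > 90))) {
    abort("slope_deg outside [0, 90]")
  }
  if (!quiet) {
    message(sprintf(
      "Read %d survey records: %d sites, years %d-%d, substrates {%s}, methods {%s}",
      nrow(out), dplyr::n_distinct(out$site_id), min(out$year), max(out$year),
      paste(sort(unique(out$substrate)), collapse = ","),
      paste(sort(unique(out$method)), collapse = ",")))
  }
  class(out) <- c("survey_table", class(out))
  out
}

#' Resolve a raw survey table to numeric percent cover
#'
#' Applies [resolve_total()] to the total column and [allocate_taxon_cover()]
#' row-wise to the taxon columns. Records whose total is missing keep `NA`
#' covers (no survey conducted). The resolved taxon sum is checked against
#' 100% plus `tolerance`.
#'
#' @param records A `survey_table` tibble from [read_survey_table()] (or any
#'   data frame with the same columns).
#' @param tolerance Permitted excess of the resolved taxon sum over 100%.
#' @return A tibble mirroring the input with numeric `total` and taxon
#'   columns, plus `depth_m` (depth below low water level, `-elevation_lwl_m`).
#' @export
resolve_survey <- function(records, tolerance = 1e-9) {
  taxa <- reef_taxa()
  totals <- resolve_total(parse_cover_entry(records$total, cells = paste0("total@", records$record_id)))
  mat <- matrix(NA_real_, nrow(records), length(taxa), dimnames = list(NULL, taxa))
  for (i in seq_len(nrow(records))) {
    if (is.na(totals[i])) next
    entries <- setNames(as.character(unlist(records[i, taxa])), taxa)
    mat[i, ] <- allocate_taxon_cover(entries, records$total[i])
    s <- sum(mat[i, ], na.rm = TRUE)
    if (s > 100 + tolerance) {
      abort(sprintf("Record '%s': resolved taxon covers sum to %.4f%% > 100%%",
                    records$record_id[i], s))
    }
  }
  bind_cols(
    records |> select(-dplyr::all_of(c("total", taxa))),
    tibble(total = totals),
    as_tibble(mat)
  ) |>
    mutate(depth_m = -.data$elevation_lwl_m) |>
    as_tibble()
}

#' Write a resolved survey table
#'
#' Mirrors the input schema with numeric-only cells.
#'
#' @param resolved Tibble from [resolve_survey()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_resolved_survey <- function(resolved, path) {
  readr::write_csv(resolved, path, progress = FALSE)
  invisible(path)
}
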