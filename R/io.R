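# CSV and config readers/writers for the pipeline's tabular formats.
# All files are UTF-8 CSV with a header row, "." decimal separator and
# empty fields for missing values.

#' Read transwell transport data
#'
#' Expected columns: `compound,replicate,time_min,compartment,`
#' `concentration_uM_or_amount_nmol`. `compartment` is one of
#' `basolateral` (timed receiver samples, uM), `apical_final` (terminal
#' donor concentration, uM; `time_min` ignored) or `cell` (cell-layer
#' amount, nmol).
#'
#' @param path CSV file path.
#' @return List of [transport_timecourse()] objects, one per
#'   compound-replicate pair.
#' @export
read_transport_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "replicate", "time_min", "compartment",
            "concentration_uM_or_amount_nmol")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("transport CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$compartment),
                 c("basolateral", "apical_final", "cell"))
  if (length(bad)) {
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(df[, c("compound", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compound == keys$compound[i] &
                df$replicate == keys$replicate[i], ]
    baso <- sub[sub$compartment == "basolateral", ]
    baso <- baso[order(baso$time_min), ]
    apical <- sub$concentration_uM_or_amount_nmol[
      sub$compartment == "apical_final"]
    cell <- sub$concentration_uM_or_amount_nmol[sub$compartment == "cell"]
    transport_timecourse(
      keys$compound[i], keys$replicate[i],
      baso$time_min, baso$concentration_uM_or_amount_nmol,
      final_apical_concentration =
        if (length(apical)) apical[1] else NA_real_,
      cell_associated_amount = if (length(cell)) cell[1] else NA_real_
    )
  })
}

#' Write transwell transport data
#'
#' Inverse of [read_transport_csv()].
#' @param timecourses List of [transport_timecourse()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transport_csv <- function(timecourses, path) {
  rows <- lapply(timecourses, function(tc) {
    out <- data.frame(
      compound = tc$compound_id, replicate = tc$replicate_id,
      time_min = tc$sample_times, compartment = "basolateral",
      concentration_uM_or_amount_nmol = tc$basolateral_concentrations,
      stringsAsFactors = FALSE)
    if (is.finite(tc$final_apical_concentration)) {
      out <- rbind(out, data.frame(
        compound = tc$compound_id, replicate = tc$replicate_id,
        time_min = max(tc$sample_times), compartment = "apical_final",
        concentration_uM_or_amount_nmol = tc$final_apical_concentration))
    }
    if (is.finite(tc$cell_associated_amount)) {
      out <- rbind(out, data.frame(
        compound = tc$compound_id, replicate = tc$replicate_id,
        time_min = max(tc$sample_times), compartment = "cell",
        concentration_uM_or_amount_nmol = tc$cell_associated_amount))
    }
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read differentiation plate data
#'
#' Expected columns:
#' `compound,experiment,concentration_uM,wells_total,wells_contracting`.
#'
#' @param path CSV file path.
#' @return List of [differentiation_run()] objects.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "experiment", "concentration_uM", "wells_total",
            "wells_contracting")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("plate CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(df[, c("compound", "experiment")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compound == keys$compound[i] &
                df$experiment == keys$experiment[i], ]
    differentiation_run(keys$compound[i], keys$experiment[i],
                        sub$concentration_uM, sub$wells_total,
                        sub$wells_contracting)
  })
}

#' Write differentiation plate data
#'
#' Inverse of [read_plate_csv()].
#' @param runs List of [differentiation_run()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(runs, path) {
  rows <- lapply(runs, function(r) {
    data.frame(compound = attr(r, "compound_id"),
               experiment = attr(r, "experiment_id"),
               concentration_uM = r$concentration,
               wells_total = r$wells_total,
               wells_contracting = r$wells_contracting,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read viability data
#'
#' Expected columns: `compound,exposure_days,concentration_uM` and either
#' `viability_percent` or `absorbance`. Absorbances are normalised to the
#' mean absorbance of the 0-uM (solvent control) rows of the same
#' compound and exposure duration.
#'
#' @param path CSV file path.
#' @return List of [viability_curve()] objects, one per compound-exposure
#'   pair.
#' @export
read_viability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "exposure_days", "concentration_uM")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("viability CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  has_pct <- "viability_percent" %in% names(df)
  if (!has_pct && !"absorbance" %in% names(df)) {
    stop("viability CSV needs a 'viability_percent' or 'absorbance' column",
         call. = FALSE)
  }
  keys <- unique(df[, c("compound", "exposure_days")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compound == keys$compound[i] &
                df$exposure_days == keys$exposure_days[i], ]
    if (has_pct) {
      viab <- sub$viability_percent
    } else {
      ctrl <- mean(sub$absorbance[sub$concentration_uM == 0])
      viab <- normalize_viability(sub$absorbance, ctrl)
    }
    keep <- sub$concentration_uM > 0
    viability_curve(keys$compound[i], keys$exposure_days[i],
                    sub$concentration_uM[keep], viab[keep])
  })
}

#' Read an external potency ranking
#'
#' One compound id per line, most toxic first; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Text file path.
#' @return Character vector, most toxic first.
#' @export
read_ranking_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("ranking file is empty", call. = FALSE)
  lines
}

#' Read a pipeline configuration file
#'
#' Parses a minimal flat TOML-style dialect: `[section]` headers,
#' `key = value` pairs with string (quoted), numeric or boolean values,
#' `#` comments. Nested tables and arrays are not supported. Parse errors
#' report the offending line number.
#'
#' @param path Config file path.
#' @return Nested named list (`section$key`); keys before any section
#'   header sit at the top level.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      stop(sprintf("%s:%d: cannot parse '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    key <- m[2]
    raw <- trimws(m[3])
    value <- if (grepl('^".*"$', raw) || grepl("^'.*'$", raw)) {
      substr(raw, 2, nchar(raw) - 1)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num)) {
        stop(sprintf("%s:%d: unquoted non-numeric value '%s'", path, i, raw),
             call. = FALSE)
      }
      num
    }
    if (is.null(section)) out[[key]] <- value
    else out[[section]][[key]] <- value
  }
  out
}
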