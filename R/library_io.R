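#' Read a compound table
#'
#' Reads a compound library from a SMILES file (`.smi`), a delimited table
#' (CSV/TSV) or an SDF (V2000) file into a data frame of compound records.
#' Rows whose SMILES cannot be parsed are retained and flagged rather than
#' dropped, so record counts are conserved; downstream operations skip them.
#'
#' The `.smi` dialect is whitespace-separated `SMILES id`; lines starting with
#' `#` are comments. For CSV/TSV the column names are configurable and default
#' to `id`, `smiles` and `year`. Records with an unrecognized or absent
#' molecule-type label are treated as small molecules (the count of such
#' records is reported via a message).
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"smi"`, `"csv"`, `"tsv"`, `"sdf"`;
#'   `"auto"` guesses from the file extension.
#' @param id_col,smiles_col,year_col column names for CSV/TSV input.
#' @param year_range plausible range for origin years; values outside it are
#'   replaced by `NA` with a warning.
#' @param sdf_year_tag SD data field holding the origin year for SDF input.
#' @param check_parse if `TRUE` (default) every SMILES is run through the
#'   toolkit and failures are flagged in `flag_parse_failed`.
#' @return a `data.frame` with columns `id`, `smiles`, `origin_year`,
#'   `mol_type_label` and logical flag columns (`flag_parse_failed`).
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 m1", "Cc1ccccc1 m2", "CCO m3"), f)
#' read_compound_table(f)
#' @export
read_compound_table <- function(path,
                                format = c("auto", "smi", "csv", "tsv", "sdf"),
                                id_col = "id", smiles_col = "smiles",
                                year_col = "year",
                                year_range = c(1700L, 2100L),
                                sdf_year_tag = "year",
                                check_parse = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", csv = "csv", tsv = "tsv",
                     txt = "tsv", sdf = "sdf",
                     stop("cannot guess format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  rec <- switch(format,
    smi = .read_smi(path),
    csv = ,
    tsv = .read_delim(path, sep = if (format == "csv") "," else "\t",
                      id_col = id_col, smiles_col = smiles_col,
                      year_col = year_col),
    sdf = .read_sdf_table(path, sdf_year_tag)
  )
  dup <- unique(rec$id[duplicated(rec$id)])
  if (length(dup)) {
    stop("duplicate ids in compound table: ", paste(head(dup, 10), collapse = ", "))
  }
  bad_year <- !is.na(rec$origin_year) &
    (rec$origin_year < year_range[1] | rec$origin_year > year_range[2])
  if (any(bad_year)) {
    warning(sum(bad_year), " origin year(s) outside [", year_range[1], ", ",
            year_range[2], "] set to NA")
    rec$origin_year[bad_year] <- NA_integer_
  }
  n_untyped <- sum(is.na(rec$mol_type_label) | rec$mol_type_label == "" |
                     !(tolower(rec$mol_type_label) %in% "small molecule"))
  if (n_untyped > 0 && any(!is.na(rec$mol_type_label))) {
    message(n_untyped, " record(s) with absent/unrecognized molecule-type ",
            "label treated as small molecules")
  }
  rec$flag_parse_failed <- FALSE
  if (check_parse && nrow(rec)) {
    rec$flag_parse_failed <- is.na(canonical_smiles(rec$smiles))
  }
  rec
}

.empty_records <- function() {
  data.frame(id = character(0), smiles = character(0),
             origin_year = integer(0), mol_type_label = character(0))
}

.read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(.empty_records())
  parts <- strsplit(lines, "[[:space:]]+")
  data.frame(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
    }, ""),
    smiles = vapply(parts, `[[`, "", 1L),
    origin_year = NA_integer_,
    mol_type_label = NA_character_
  )
}

.read_delim <- function(path, sep, id_col, smiles_col, year_col) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  for (col in c(id_col, smiles_col)) {
    if (!col %in% names(df)) {
      stop("mandatory column '", col, "' missing from ", path)
    }
  }
  yr <- if (year_col %in% names(df)) {
    suppressWarnings(as.integer(df[[year_col]]))
  } else {
    rep(NA_integer_, nrow(df))
  }
  lab <- if ("mol_type" %in% names(df)) as.character(df$mol_type) else NA_character_
  data.frame(
    id = as.character(df[[id_col]]),
    smiles = as.character(df[[smiles_col]]),
    origin_year = yr,
    mol_type_label = lab
  )
}

.read_sdf_table <- function(path, year_tag) {
  sdfset <- ChemmineR::read.SDFset(path)
  n <- length(sdfset)
  ids <- character(n); smi <- character(n); yr <- rep(NA_integer_, n)
  valid <- ChemmineR::validSDF(sdfset)
  # canonical SMILES straight from the file text so invalid records survive
  for (i in seq_len(n)) {
    sdf <- sdfset[[i]]
    hdr <- ChemmineR::header(sdf)
    ids[i] <- if (nzchar(trimws(hdr[["Molecule_Name"]]))) trimws(hdr[["Molecule_Name"]]) else paste0("mol", i)
    db <- ChemmineR::datablock(sdf)
    if (year_tag %in% names(db)) yr[i] <- suppressWarnings(as.integer(db[[year_tag]]))
    rec <- paste(c(as(sdf, "character"), "$$$$"), collapse = "\n")
    s <- if (valid[i]) .ob_convert(paste0(rec, "\n"), "SDF", "CAN") else ""
    s <- strsplit(s, "[\t\n]")[[1]]
    smi[i] <- if (length(s) && nzchar(s[1])) s[1] else "INVALID"
  }
  data.frame(id = ids, smiles = smi, origin_year = yr,
             mol_type_label = NA_character_)
}

#' Write a results table
#'
#' Writes a rectangular results table as CSV (RFC 4180, UTF-8) or JSON.
#' The CSV round trip is loss-free for strings and integers; doubles are
#' serialized to `digits` significant digits.
#'
#' @param rows a data frame; list columns (nested structures) are an error.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @param digits significant digits for doubles (default 10).
#' @return `invisible(path)`.
#' @export
write_table <- function(rows, path, format = c("csv", "json"), digits = 10) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) stop("'rows' must be a data frame")
  if (any(vapply(rows, is.list, TRUE))) {
    stop("nested structure in a table cell; flatten before writing")
  }
  rows <- as.data.frame(rows)
  isdbl <- vapply(rows, is.double, TRUE)
  rows[isdbl] <- lapply(rows[isdbl], signif, digits = digits)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}
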