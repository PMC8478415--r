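# Pedigree input/output.
#
# A pedigree is an ordinary tibble, one row per family member, in a fixed
# column schema: ID / MotherID / FatherID / Sex identify the family graph;
# isAff<TAG> / Age<TAG> column pairs carry the cancer history for the cancer
# with short tag <TAG> (e.g. isAffBC / AgeBC for breast cancer); CurAge is the
# censoring age (current age, or age at death when isDead is 1); race,
# Ancestry, Twins, riskmod, InterAge, germline gene columns and tumor-marker
# columns are optional. riskmod and InterAge are list-columns in memory and
# are serialized as semicolon-separated tokens in one CSV/TSV cell.

PED_MANDATORY <- c("ID", "MotherID", "FatherID", "Sex")
PED_INT_COLS <- c("ID", "MotherID", "FatherID", "Sex", "isProband", "CurAge",
                  "isDead", "Twins")

#' Read a pedigree from a CSV or TSV file
#'
#' Reads a family history table in the standard pedigree column schema and
#' returns it as a tibble. Files ending in `.tsv` or `.txt` are read as
#' tab-separated, everything else as comma-separated. Missing values are
#' encoded as `NA` or empty cells.
#'
#' @param path Path to a delimited text file with a header row. Mandatory
#'   columns are `ID`, `MotherID`, `FatherID` and `Sex`; cancer history comes
#'   in matched `isAff*`/`Age*` column pairs.
#' @return A tibble with one row per individual. `riskmod` and `InterAge`
#'   (when present) are parsed into list-columns.
#' @seealso [write_pedigree()], [as_pedigree()], [check_pedigree()]
#' @export
#' @examples
#' path <- system.file("extdata", "family_breast_ovarian.csv",
#'                     package = "mendelrisk")
#' ped <- read_pedigree(path)
#' pedigree_cancers(ped)
read_pedigree <- function(path) {
  if (!file.exists(path)) {
    mr_error(paste0("pedigree file not found: ", path), "mendelrisk_io_error")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                          show_col_types = FALSE, progress = FALSE)
  as_pedigree(df)
}

#' Coerce a data frame to the pedigree schema
#'
#' Validates the column schema (mandatory columns, matched `isAff*`/`Age*`
#' pairs, unique positive IDs), coerces column types, and normalizes optional
#' columns. Called by [read_pedigree()]; use it directly for pedigrees built
#' in code.
#'
#' @param df A data frame in the pedigree column schema.
#' @return A tibble in canonical pedigree form.
#' @export
as_pedigree <- function(df) {
  ped <- as_tibble(df)
  attr(ped, "spec") <- NULL
  attr(ped, "problems") <- NULL

  for (col in PED_MANDATORY) {
    if (!col %in% names(ped)) {
      mr_error(paste0("pedigree is missing mandatory column '", col, "'"),
               "mendelrisk_schema_error")
    }
  }

  aff_tags <- sub("^isAff", "", grep("^isAff", names(ped), value = TRUE))
  age_tags <- sub("^Age", "", grep("^Age(?!ncestry)", names(ped),
                                   value = TRUE, perl = TRUE))
  if (length(setdiff(aff_tags, age_tags))) {
    mr_error(paste0("isAff/Age column pair mismatch: no Age column for tag(s) ",
                    paste(setdiff(aff_tags, age_tags), collapse = ", ")),
             "mendelrisk_schema_error")
  }
  if (length(setdiff(age_tags, aff_tags))) {
    mr_error(paste0("isAff/Age column pair mismatch: no isAff column for tag(s) ",
                    paste(setdiff(age_tags, aff_tags), collapse = ", ")),
             "mendelrisk_schema_error")
  }

  if (!"isProband" %in% names(ped)) ped$isProband <- 0L
  if (!"CurAge" %in% names(ped)) ped$CurAge <- NA_integer_
  if (!"isDead" %in% names(ped)) ped$isDead <- NA_integer_
  if (!"Twins" %in% names(ped)) ped$Twins <- 0L
  if (!"race" %in% names(ped)) ped$race <- NA_character_
  if (!"Ancestry" %in% names(ped)) ped$Ancestry <- NA_character_

  int_cols <- c(PED_INT_COLS,
                paste0("isAff", aff_tags), paste0("Age", aff_tags))
  for (col in intersect(int_cols, names(ped))) {
    ped[[col]] <- as.integer(ped[[col]])
  }
  ped$race <- as.character(ped$race)
  ped$Ancestry <- as.character(ped$Ancestry)
  ped$Twins[is.na(ped$Twins)] <- 0L

  if ("riskmod" %in% names(ped)) {
    ped$riskmod <- parse_list_column(ped$riskmod, as.character)
  }
  if ("InterAge" %in% names(ped)) {
    ped$InterAge <- parse_list_column(ped$InterAge, function(x) as.integer(x))
  }

  if (anyNA(ped$ID) || any(ped$ID <= 0L)) {
    mr_error("pedigree IDs must be strictly positive integers",
             "mendelrisk_schema_error")
  }
  if (anyDuplicated(ped$ID)) {
    mr_error(paste0("duplicated pedigree ID(s): ",
                    paste(unique(ped$ID[duplicated(ped$ID)]), collapse = ", ")),
             "mendelrisk_schema_error")
  }
  ped
}

# Semicolon-separated cell -> list column; NA/empty -> length-0 element.
parse_list_column <- function(x, cast) {
  if (is.list(x)) {
    return(lapply(x, function(el) cast(el[!is.na(el)])))
  }
  x <- as.character(x)
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(cast(character(0)))
    cast(trimws(strsplit(cell, ";", fixed = TRUE)[[1]]))
  })
}

#' Write a pedigree to a CSV or TSV file
#'
#' Inverse of [read_pedigree()]: list-columns (`riskmod`, `InterAge`) are
#' collapsed to semicolon-separated tokens and missing values are written as
#' empty cells, so that reading the file back reproduces the pedigree
#' field-for-field.
#'
#' @param ped A pedigree tibble.
#' @param path Output path; `.tsv`/`.txt` selects tab-separated output.
#' @return The path, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  for (col in intersect(c("riskmod", "InterAge"), names(out))) {
    out[[col]] <- vapply(out[[col]], function(el) {
      if (!length(el)) NA_character_ else paste(el, collapse = ";")
    }, character(1))
  }
  out <- out[, !startsWith(names(out), "."), drop = FALSE]
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Cancer tags present in a pedigree
#'
#' @param ped A pedigree tibble.
#' @return Character vector of short cancer tags, in order of appearance of
#'   the `isAff*` columns (empty if the pedigree has no cancer columns).
#' @export
pedigree_cancers <- function(ped) {
  sub("^isAff", "", grep("^isAff", names(ped), value = TRUE))
}

# Column helpers --------------------------------------------------------

aff_col <- function(tag) paste0("isAff", tag)
age_col <- function(tag) paste0("Age", tag)

ped_row <- function(ped, id) ped[match(id, ped$ID), , drop = FALSE]
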