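# Internal canonical column set for a normative-ratings table. Stimulus codes
# are ALWAYS character: IAPS-style codes such as "2345.1" carry meaningful
# decimal suffixes that numeric parsing would destroy.
.norm_fields <- function() {
  c("code", "description", "set_id",
    "val_mean", "val_sd", "val_n",
    "aro_mean", "aro_sd", "aro_n",
    "dom1_mean", "dom1_sd", "dom1_n",
    "dom2_mean", "dom2_sd", "dom2_n")
}

.norm_numeric_fields <- function() setdiff(.norm_fields(),
                                           c("code", "description", "set_id"))

#' Default column mapping for normative-rating files
#'
#' Maps the package's canonical field names to the column headers of the
#' published "AllSubjects" normative technical-report layout
#' (\code{desc}, \code{IAPS}, \code{valmn}, \code{valsd}, \code{aromn},
#' \code{arosd}, \code{dom1mn}, ...). Files that already use the canonical
#' names need no mapping at all. The exact layout of any given norms file
#' is a convention of its distributor, so the mapping is configurable; see
#' [read_norms()].
#'
#' @return Named character vector: canonical field -> file column.
#' @export
default_column_map <- function() {
  c(code = "IAPS", description = "desc", set_id = "set",
    val_mean = "valmn", val_sd = "valsd", val_n = "valn",
    aro_mean = "aromn", aro_sd = "arosd", aro_n = "aron",
    dom1_mean = "dom1mn", dom1_sd = "dom1sd", dom1_n = "dom1n",
    dom2_mean = "dom2mn", dom2_sd = "dom2sd", dom2_n = "dom2n")
}

# detect the delimiter of a header line among comma, semicolon, tab
.detect_delim <- function(header_line) {
  counts <- vapply(c(",", ";", "\t"), function(s) {
    lengths(regmatches(header_line, gregexpr(s, header_line, fixed = TRUE)))
  }, 0L)
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a normative-ratings table
#'
#' Reads a delimited text file of per-stimulus normative statistics into a
#' \code{norm_table} data frame with one row per stimulus and the canonical
#' columns \code{code}, \code{description}, \code{set_id} and, for each of
#' valence, arousal and the two dominance scale variants, \code{*_mean},
#' \code{*_sd} and \code{*_n}. Stimulus codes are read as character and
#' never coerced to numeric. Empty cells become \code{NA} (absent), never
#' zero. Decimal separator is the dot, independent of locale.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param dialect Optional list with elements \code{delimiter} (one of
#'   \code{","}, \code{";"}, \code{"\t"}; auto-detected when \code{NULL})
#'   and \code{columns} (named character vector mapping canonical field
#'   names to file column names; merged over [default_column_map()]).
#'   May also be the path to a YAML file holding those two keys.
#' @return A \code{norm_table}: data frame with the canonical columns, a
#'   \code{provenance} attribute recording the source path and delimiter,
#'   and unknown file columns preserved in an \code{extra} attribute.
#' @seealso [write_table()], [default_column_map()]
#' @export
read_norms <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- yaml::read_yaml(dialect)
  }
  header <- readLines(path, n = 1L)
  delim <- dialect$delimiter
  if (is.null(delim)) delim <- .detect_delim(header)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  cmap <- default_column_map()
  if (!is.null(dialect$columns)) {
    user <- unlist(dialect$columns)
    cmap[names(user)] <- user
  }
  # a canonical name present in the file always wins over the mapped alias
  locate <- function(field) {
    if (field %in% names(raw)) return(field)
    if (!is.na(cmap[field]) && cmap[field] %in% names(raw)) {
      return(unname(cmap[field]))
    }
    NA_character_
  }
  found <- vapply(.norm_fields(), locate, "")
  mandatory <- c("code", "val_mean", "val_sd", "val_n",
                 "aro_mean", "aro_sd", "aro_n")
  missing_col <- mandatory[is.na(found[mandatory])]
  if (length(missing_col)) {
    stop("missing mandatory column(s): ",
         paste(missing_col, collapse = ", "),
         " (configure the column mapping via `dialect`)", call. = FALSE)
  }
  out <- data.frame(matrix(nrow = nrow(raw), ncol = 0L))
  for (f in .norm_fields()) {
    col <- if (is.na(found[f])) rep(NA_character_, nrow(raw)) else raw[[found[f]]]
    col[!is.na(col) & trimws(col) == ""] <- NA_character_
    if (f %in% .norm_numeric_fields()) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf("unparseable numeric value '%s' in column '%s', row %d",
                     col[bad[1L]], f, bad[1L]), call. = FALSE)
      }
      out[[f]] <- num
    } else {
      out[[f]] <- col
    }
  }
  extra <- raw[, setdiff(names(raw), stats::na.omit(found)), drop = FALSE]
  attr(out, "extra") <- extra
  attr(out, "provenance") <- list(path = path, delimiter = delim)
  class(out) <- c("norm_table", "data.frame")
  out
}

#' Construct a norm_table from in-memory vectors
#'
#' @param code Character stimulus codes (mandatory, non-empty).
#' @param ... Any of the canonical columns (see [read_norms()]); omitted
#'   columns are filled with \code{NA}.
#' @return A \code{norm_table} data frame.
#' @export
norm_table <- function(code, ...) {
  code <- as.character(code)
  if (any(is.na(code) | code == "")) {
    stop("stimulus codes must be non-empty", call. = FALSE)
  }
  args <- list(...)
  unknown <- setdiff(names(args), .norm_fields())
  if (length(unknown)) stop("unknown column(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  out <- data.frame(code = code, stringsAsFactors = FALSE)
  for (f in setdiff(.norm_fields(), "code")) {
    if (f %in% names(args)) {
      v <- args[[f]]
      if (f %in% .norm_numeric_fields()) v <- as.numeric(v)
      out[[f]] <- v
    } else {
      out[[f]] <- rep(if (f %in% .norm_numeric_fields()) NA_real_ else
        NA_character_, nrow(out))
    }
  }
  class(out) <- c("norm_table", "data.frame")
  out
}

#' Write a table or report to CSV
#'
#' Writes any of the package's tabular objects -- a \code{norm_table}, a
#' classification, a stimulus selection, a screening/concordance/stability
#' report or a plain data frame -- as a UTF-8, LF-terminated CSV with a
#' header row. Numeric values keep full precision (at least 6 significant
#' digits). A classification is written with columns \code{code},
#' \code{cluster}, \code{uncertainty} and \code{usability_band}.
#'
#' @param path Destination file path.
#' @param x The object to write.
#' @param ... Passed to methods.
#' @return Invisibly, the data frame written.
#' @export
write_table <- function(path, x, ...) UseMethod("write_table", x)

.write_csv <- function(df, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(df)
}

#' @rdname write_table
#' @export
write_table.data.frame <- function(path, x, ...) .write_csv(x, path)

#' @rdname write_table
#' @export
write_table.norm_table <- function(path, x, ...) {
  .write_csv(as.data.frame(x), path)
}

#' @rdname write_table
#' @param bands Optional usability bands for a classification; computed
#'   with default percentiles when missing.
#' @export
write_table.gmm_classification <- function(path, x, bands = NULL, ...) {
  if (is.null(bands)) bands <- usability_bands(x$uncertainty)
  df <- data.frame(code = x$codes, cluster = x$cluster,
                   uncertainty = x$uncertainty, usability_band = bands,
                   stringsAsFactors = FALSE)
  .write_csv(df, path)
}

#' @rdname write_table
#' @export
write_table.screening_report <- function(path, x, ...) {
  .write_csv(as.data.frame(x), path)
}

#' @rdname write_table
#' @export
write_table.stimulus_selection <- function(path, x, ...) {
  .write_csv(x$table, path)
}

#' @rdname write_table
#' @export
write_table.stability_report <- function(path, x, ...) {
  .write_csv(x$reps, path)
}

#' @export
print.norm_table <- function(x, ...) {
  if (!is.null(x$code)) {
    cat(sprintf("Normative ratings table: %d stimuli (%d unique codes)\n",
                nrow(x), length(unique(x$code))))
  }
  NextMethod()
}

# working PAD matrix of a screened table (valence, arousal, dominance)
.pad_matrix <- function(table) {
  stopifnot(all(c("val_mean", "aro_mean", "dom_mean") %in% names(table)))
  m <- as.matrix(table[, c("val_mean", "aro_mean", "dom_mean")])
  rownames(m) <- table$code
  colnames(m) <- c("valence", "arousal", "dominance")
  m
}
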