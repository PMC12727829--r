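# Readers/writers for the long-format quantification, annotation, spectral
# library and standard-composition tables, plus SILAC label-mass arithmetic
# and library refinement. All tables are UTF-8 TSV with "." decimal separator
# and the empty string as the missing value; intensities are linear-scale and
# are never log-transformed by any reader or writer.

# Monoisotopic mass differences (Da), CODATA/NIST values.
C13_MINUS_C12 <- 1.0033548378
N15_MINUS_N14 <- 0.9970348937

#' Canonical amino-acid residues
#'
#' The 20 canonical one-letter residue codes accepted in stripped peptide
#' sequences.
#' @keywords internal
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

QUANT_MANDATORY <- c("run_id", "study_id", "matrix", "platform_id",
                     "sample_id", "group", "protein_group", "stripped_seq",
                     "modified_seq", "charge", "channel", "intensity")
QUANT_OPTIONAL <- c("rt", "fragment_id", "fragment_intensity")
MATRIX_LEVELS <- c("EDTA", "citrate", "heparin", "serum", "other")

#' Build a precursor identifier
#'
#' A precursor is a peptide ion species defined by modified sequence and
#' charge state; its identifier is `"<modified_seq>/<charge>"`.
#'
#' @param modified_seq Character vector of modified peptide sequences.
#' @param charge Integer vector of charge states.
#' @return Character vector of precursor identifiers.
#' @export
precursor_id <- function(modified_seq, charge) {
  paste0(modified_seq, "/", as.integer(charge))
}

#' Strip modifications from a peptide sequence
#'
#' Removes bracketed or parenthesised modification annotations, leaving the
#' plain residue string.
#'
#' @param seq Character vector of modified sequences.
#' @return Character vector of stripped sequences.
#' @export
strip_modifications <- function(seq) {
  out <- gsub("\\(([^()]*)\\)|\\[([^][]*)\\]", "", seq)
  gsub("[^A-Z]", "", out)
}

validate_quant_records <- function(df) {
  problems <- character(nrow(df))
  add <- function(p, idx, msg) {
    p[idx] <- ifelse(nzchar(p[idx]), paste(p[idx], msg, sep = "; "), msg)
    p
  }
  bad_charge <- !is.na(df$charge) & (df$charge < 1L | df$charge > 6L)
  problems <- add(problems, bad_charge, "charge outside [1, 6]")
  problems <- add(problems, is.na(df$charge), "charge missing")
  bad_channel <- !(df$channel %in% c("L", "H"))
  problems <- add(problems, bad_channel, "channel not L/H")
  bad_matrix <- !(df$matrix %in% MATRIX_LEVELS)
  problems <- add(problems, bad_matrix,
                  paste0("matrix not one of ", paste(MATRIX_LEVELS, collapse = "/")))
  res_ok <- vapply(strsplit(df$stripped_seq, ""), function(x) {
    length(x) > 0L && all(x %in% AA_CANONICAL)
  }, logical(1))
  problems <- add(problems, !res_ok, "non-canonical residue in stripped_seq")
  problems
}

#' Read a long-format precursor quantification table
#'
#' Reads a DIA-report-style long TSV with one row per (run, precursor,
#' channel) observation. Mandatory columns are `run_id`, `study_id`,
#' `matrix`, `platform_id`, `sample_id`, `group`, `protein_group`,
#' `stripped_seq`, `modified_seq`, `charge`, `channel` and `intensity`;
#' `rt` (minutes), `fragment_id` and `fragment_intensity` are optional.
#' Intensities are on the linear scale.
#'
#' Rows failing row-level type checks (charge range, channel code, matrix
#' label, non-canonical residues) are removed from the returned table but
#' reported via a warning and the `"validation_report"` attribute; they are
#' never silently dropped. A negative intensity anywhere is a hard
#' validation error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Table dialect; only `"long_tsv"` is defined.
#' @return A `quant_table` (data frame) of validated records.
#' @export
read_quant_table <- function(path, dialect = "long_tsv") {
  dialect <- match.arg(dialect, "long_tsv")
  if (!file.exists(path)) stop("quant table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(QUANT_MANDATORY, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$charge <- suppressWarnings(as.integer(df$charge))
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  for (col in intersect(c("rt", "fragment_intensity"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  as_quant_table(df)
}

#' Construct a quant_table from a data frame
#'
#' Validates records built in code against the same rules as
#' [read_quant_table()]: negative intensities are an error, rows failing
#' type checks are excluded and reported in the `"validation_report"`
#' attribute.
#'
#' @param df A data frame with the mandatory quantification columns.
#' @return A `quant_table`.
#' @export
as_quant_table <- function(df) {
  missing_cols <- setdiff(QUANT_MANDATORY, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.na(df$intensity) & df$intensity < 0)) {
    stop("validation error: negative intensity values present")
  }
  problems <- validate_quant_records(df)
  bad <- nzchar(problems)
  report <- data.frame(row = which(bad), problem = problems[bad],
                       stringsAsFactors = FALSE)
  if (nrow(report) > 0L) {
    warning(nrow(report), " row(s) failed validation and were excluded; ",
            "see attr(x, 'validation_report')")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation_report") <- report
  class(out) <- c("quant_table", "data.frame")
  out
}

#' @exportS3Method base::print
print.quant_table <- function(x, ...) {
  cat("quant_table: ", nrow(x), " records, ",
      length(unique(x$run_id)), " runs, ",
      length(unique(precursor_id(x$modified_seq, x$charge))), " precursors, ",
      "channels {", paste(sort(unique(x$channel)), collapse = ", "), "}\n",
      sep = "")
  rep <- attr(x, "validation_report")
  if (!is.null(rep) && nrow(rep) > 0L) {
    cat("  (", nrow(rep), " invalid input row(s) excluded)\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write a quantification table
#'
#' Inverse of [read_quant_table()]; missing values are written as empty
#' strings so that read-write-read is the identity.
#'
#' @param x A `quant_table` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a peptide annotation table
#'
#' Columns: `peptide` (stripped sequence), `protein_group`, `proteotypic`
#' (`TRUE`/`FALSE`), optional `synthesis_score` (external annotation, not
#' recomputed here).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("peptide", "protein_group", "proteotypic")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$proteotypic <- as.logical(df$proteotypic)
  df
}

#' Read / write a standard-composition table
#'
#' Columns: `peptide`, `pg_per_ul` (assigned concentration), `tier`.
#'
#' @param path Path to a TSV file.
#' @return A data frame with one row per peptide.
#' @export
read_composition <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("peptide", "pg_per_ul", "tier")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$pg_per_ul <- as.numeric(df$pg_per_ul)
  df$tier <- as.integer(df$tier)
  df
}

#' @rdname read_composition
#' @param x A composition data frame.
#' @export
write_composition <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

LIB_COLUMNS <- c("ModifiedSequence", "PrecursorCharge", "FragmentId",
                 "FragmentMz", "ExcludeFromAssay", "Channel")

#' Read / write a spectral library table
#'
#' TSV with columns `ModifiedSequence`, `PrecursorCharge`, `FragmentId`
#' (ion series + index, optionally `^charge`), `FragmentMz` (Da),
#' `ExcludeFromAssay` (`T`/`F`) and `Channel` (`L`/`H`).
#'
#' @param path Path to a TSV file.
#' @return A data frame with `ExcludeFromAssay` as logical.
#' @export
read_spectral_library <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(LIB_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$PrecursorCharge <- as.integer(df$PrecursorCharge)
  df$FragmentMz <- as.numeric(df$FragmentMz)
  df$ExcludeFromAssay <- df$ExcludeFromAssay %in% c("T", "TRUE")
  if (!all(df$Channel %in% c("L", "H"))) stop("Channel must be L or H")
  df
}

#' @rdname read_spectral_library
#' @param x A spectral library data frame.
#' @export
write_spectral_library <- function(x, path) {
  x$ExcludeFromAssay <- ifelse(x$ExcludeFromAssay, "T", "F")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' SILAC label scheme
#'
#' Residue-specific heavy mass shifts for C-terminal lysine/arginine
#' labeling with uniformly substituted 13C and 15N: K carries 6 carbons and
#' 2 nitrogens, R 6 carbons and 4 nitrogens, giving shifts of 8.014199 and
#' 10.008269 Da respectively.
#'
#' @param position_rule `"c_terminal_only"` (shift applied only to the final
#'   residue when it is K or R, the default for tryptic SIL standards) or
#'   `"all_KR"`.
#' @return A `label_scheme` list with `residue_shifts` and `position_rule`.
#' @export
label_scheme <- function(position_rule = c("c_terminal_only", "all_KR")) {
  position_rule <- match.arg(position_rule)
  structure(
    list(
      residue_shifts = c(K = 6 * C13_MINUS_C12 + 2 * N15_MINUS_N14,
                         R = 6 * C13_MINUS_C12 + 4 * N15_MINUS_N14),
      position_rule = position_rule
    ),
    class = "label_scheme"
  )
}

#' Heavy-label mass shift for a residue
#'
#' @param residue `"K"` or `"R"`.
#' @param scheme A [label_scheme()].
#' @param channel `"H"` for the heavy channel; the light channel carries no
#'   shift and returns 0 for any residue.
#' @return Mass shift in Da.
#' @export
heavy_mass_shift <- function(residue, scheme = label_scheme(), channel = "H") {
  if (identical(channel, "L")) return(rep(0, length(residue)))
  bad <- !(residue %in% names(scheme$residue_shifts))
  if (any(bad)) {
    stop("unsupported residue for heavy labeling: ",
         paste(unique(residue[bad]), collapse = ", "))
  }
  unname(scheme$residue_shifts[residue])
}

parse_fragment_id <- function(fragment_id) {
  series <- substr(fragment_id, 1L, 1L)
  charge <- rep(1L, length(fragment_id))
  has_z <- grepl("\\^", fragment_id)
  charge[has_z] <- as.integer(sub(".*\\^", "", fragment_id[has_z]))
  list(series = series, charge = charge)
}

#' Refine a SILAC spectral library for a standard panel
#'
#' Restricts the heavy channel to panel peptides with the label on the
#' C-terminal lysine or arginine only, and marks all b-series fragments of
#' panel peptides as excluded from assay quantification (b-ions do not
#' carry the C-terminal label, so their light and heavy signals are
#' indistinguishable); y-series fragments are retained for quantification.
#' Heavy entries for panel peptides absent from the input heavy channel are
#' generated from the light entries, shifting the fragment m/z of
#' C-terminal ion series (y, x, z) by the label mass over the fragment
#' charge.
#'
#' @param lib A spectral library data frame (see [read_spectral_library()]).
#' @param panel Character vector of panel peptide modified sequences.
#' @param scheme A [label_scheme()].
#' @return The refined library; peptides that could not be labeled are
#'   listed in the `"refinement_report"` attribute.
#' @export
refine_silac_library <- function(lib, panel, scheme = label_scheme()) {
  report <- list(missing_from_library = character(),
                 non_kr_terminus = character())
  in_lib <- panel %in% lib$ModifiedSequence
  if (any(!in_lib)) {
    report$missing_from_library <- panel[!in_lib]
    warning("panel peptide(s) absent from library: ",
            paste(panel[!in_lib], collapse = ", "))
  }
  light <- lib[lib$Channel == "L", , drop = FALSE]
  heavy <- lib[lib$Channel == "H", , drop = FALSE]
  heavy <- heavy[heavy$ModifiedSequence %in% panel, , drop = FALSE]

  cterm <- function(seq) {
    s <- strip_modifications(seq)
    substr(s, nchar(s), nchar(s))
  }
  labelable <- function(seq) cterm(seq) %in% names(scheme$residue_shifts)

  bad_term <- !labelable(heavy$ModifiedSequence)
  if (any(bad_term)) {
    report$non_kr_terminus <- unique(heavy$ModifiedSequence[bad_term])
    warning("peptide(s) without C-terminal K/R excluded from heavy channel: ",
            paste(report$non_kr_terminus, collapse = ", "))
    heavy <- heavy[!bad_term, , drop = FALSE]
  }

  need_h <- setdiff(intersect(panel, light$ModifiedSequence),
                    heavy$ModifiedSequence)
  if (length(need_h) > 0L) {
    src <- light[light$ModifiedSequence %in% need_h, , drop = FALSE]
    ok <- labelable(src$ModifiedSequence)
    if (any(!ok)) {
      extra <- setdiff(unique(src$ModifiedSequence[!ok]), report$non_kr_terminus)
      if (length(extra) > 0L) {
        report$non_kr_terminus <- c(report$non_kr_terminus, extra)
        warning("peptide(s) without C-terminal K/R excluded from heavy channel: ",
                paste(extra, collapse = ", "))
      }
      src <- src[ok, , drop = FALSE]
    }
    if (nrow(src) > 0L) {
      frag <- parse_fragment_id(src$FragmentId)
      shift <- heavy_mass_shift(cterm(src$ModifiedSequence), scheme)
      cterm_series <- frag$series %in% c("y", "x", "z")
      src$FragmentMz <- src$FragmentMz +
        ifelse(cterm_series, shift / frag$charge, 0)
      src$Channel <- "H"
      heavy <- rbind(heavy, src)
    }
  }

  out <- rbind(light, heavy)
  is_panel <- out$ModifiedSequence %in% panel
  is_b <- parse_fragment_id(out$FragmentId)$series == "b"
  out$ExcludeFromAssay[is_panel & is_b] <- TRUE
  rownames(out) <- NULL
  attr(out, "refinement_report") <- report
  out
}
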