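# Peak-list and proteome FASTA input/output.
#
# Peak lists are the already-picked (m/z, intensity) pairs exported by the
# acquisition software; no peak picking from profile spectra happens here.

#' Construct a peak list
#'
#' A peak list holds one spectrum's (m/z, intensity) pairs together with
#' sample metadata. Peaks are stored sorted ascending by m/z; rows sharing an
#' identical m/z are merged by summing their intensities (this preserves total
#' ion signal).
#'
#' @param mz Numeric vector of mass-to-charge values in Da (singly-charged
#'   assumption), all > 0.
#' @param intensity Numeric vector of intensities (arbitrary units, >= 0),
#'   same length as \code{mz}.
#' @param spectrum_id Non-empty character scalar identifying the spectrum.
#' @param meta Named list of sample metadata; recognised fields are
#'   \code{treatment}, \code{dose_uM}, \code{time_days}, \code{replicate} and
#'   \code{is_control}, but arbitrary fields are kept.
#' @return An object of class \code{"peaklist"}: a list with \code{spectrum_id},
#'   \code{peaks} (data.frame with columns \code{mz}, \code{intensity}) and
#'   \code{meta}.
#' @export
peaklist <- function(mz, intensity, spectrum_id, meta = list()) {
  if (!is.character(spectrum_id) || length(spectrum_id) != 1L ||
      is.na(spectrum_id) || nchar(spectrum_id) == 0L) {
    stop("'spectrum_id' must be a non-empty string")
  }
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have the same length")
  }
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z values must be positive and finite")
  if (any(!is.finite(intensity)) || any(intensity < 0)) stop("all intensities must be >= 0 and finite")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(
    list(
      spectrum_id = spectrum_id,
      peaks = data.frame(mz = mz, intensity = intensity),
      meta = meta
    ),
    class = "peaklist"
  )
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("peaklist '%s': %d peaks", x$spectrum_id, nrow(x$peaks)))
  if (nrow(x$peaks) > 0) {
    cat(sprintf(", m/z %.2f-%.2f", min(x$peaks$mz), max(x$peaks$mz)))
  }
  cat("\n")
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(k) paste0(k, "=", format(x$meta[[k]])), "")
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a peak list from a text export
#'
#' Reads peak lists in the two dialects commonly produced when exporting
#' picked peaks: plain two-column text (m/z then intensity, whitespace or tab
#' separated) and CSV with an \code{mz,intensity} header. Lines starting with
#' \code{#} and blank lines are skipped. Duplicate m/z rows are merged by
#' summing intensity; output is sorted ascending by m/z.
#'
#' @param path Path to the file.
#' @param dialect \code{"auto"} (default; CSV is detected from a header line
#'   or comma-separated values), \code{"txt"} or \code{"csv"}.
#' @param spectrum_id Spectrum identifier; defaults to the file name without
#'   extension.
#' @param meta Sample metadata list, as in \code{\link{peaklist}}.
#' @return A \code{\link{peaklist}}.
#' @export
read_peaklist <- function(path, dialect = c("auto", "txt", "csv"),
                          spectrum_id = NULL, meta = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (is.null(spectrum_id)) {
    spectrum_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop(sprintf("empty peak-list file: '%s'", path))
  body <- lines[idx]

  if (dialect == "auto") {
    dialect <- if (grepl(",", body[1L], fixed = TRUE)) "csv" else "txt"
  }
  sep_re <- if (dialect == "csv") "\\s*,\\s*" else "\\s+"
  # a CSV header line ("mz,intensity") is tolerated and skipped
  if (dialect == "csv" && grepl("^\\s*m/?z\\s*,", body[1L], ignore.case = TRUE)) {
    body <- body[-1L]; idx <- idx[-1L]
    if (length(body) == 0L) stop(sprintf("empty peak-list file: '%s'", path))
  }

  n <- length(body)
  mz <- numeric(n); intensity <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(body[i]), sep_re)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2]))) {
      stop(sprintf("cannot parse peak-list line %d of '%s': '%s'",
                   idx[i], path, body[i]))
    }
    mz[i] <- vals[1L]; intensity[i] <- vals[2L]
  }
  peaklist(mz, intensity, spectrum_id = spectrum_id, meta = meta)
}

#' Write a peak list as two-column text
#'
#' Writes one peak per line, m/z then intensity, tab separated, with enough
#' digits for a faithful read-back.
#'
#' @param x A \code{\link{peaklist}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  lines <- sprintf("%s\t%s",
                   formatC(x$peaks$mz, format = "g", digits = 12),
                   formatC(x$peaks$intensity, format = "g", digits = 12))
  writeLines(lines, path)
  invisible(path)
}

.standard_aa <- rownames(.residue_formulas)

#' Read a proteome FASTA
#'
#' Reads a multi-record protein FASTA. UniProt-style headers
#' (\code{db|ACCESSION|ENTRY_NAME description}) are parsed so that the entry
#' name becomes the accession and the trailing text the description; plain
#' headers are kept verbatim as the accession. Records containing residues
#' outside the 20-letter standard alphabet (B, J, Z, X, U, O, ...) are
#' retained but flagged non-computable; mass-based operations skip them with
#' a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame of class \code{"proteome"} with columns
#'   \code{accession}, \code{description}, \code{sequence} and
#'   \code{computable} (logical).
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop(sprintf("no FASTA records in '%s'", path))
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  first_word <- sub("\\s.*$", "", headers)
  rest <- sub("^\\S+\\s*", "", headers)
  uniprot <- grepl("^[^|]+\\|[^|]+\\|\\S+$", first_word)
  accession <- ifelse(uniprot, sub("^[^|]+\\|[^|]+\\|", "", first_word), first_word)
  description <- rest
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("FASTA record '%s' has an empty sequence",
                 accession[which(nchar(seqs) == 0L)[1L]]))
  }
  computable <- !grepl(sprintf("[^%s]", paste(.standard_aa, collapse = "")), seqs)
  out <- data.frame(
    accession = accession,
    description = description,
    sequence = seqs,
    computable = computable,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("proteome", "data.frame")
  out
}

#' Write protein records as FASTA
#'
#' @param proteome A data.frame with columns \code{accession},
#'   \code{description} and \code{sequence}.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return \code{path}, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    hdr <- paste0(">", proteome$accession[i],
                  ifelse(nchar(desc[i]) > 0, paste0(" ", desc[i]), ""))
    writeLines(hdr, con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
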