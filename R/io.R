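#' Write a record as delimited text
#'
#' One sample per line, preceded by comment headers carrying the sampling
#' rate, subject and lead (`# fs=1000`), so a file is self-describing.
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_text <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", record$fs),
    sprintf("# subject=%s", record$subject_id),
    sprintf("# lead=%s", record$lead),
    sprintf("%.10g", record$samples)
  ), con)
  invisible(path)
}

#' Read a delimited-text record
#'
#' @param path File written by [write_signal_text()] (or any one-sample-per-
#'   line file with a `# fs=<Hz>` header comment).
#' @return An [ecg_record()].
#' @export
read_signal_text <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- sub("^#\\s*", "", lines[hdr])
  get <- function(key, default = NA_character_) {
    hit <- grep(paste0("^", key, "="), meta, value = TRUE)
    if (length(hit) == 0) default else sub(paste0("^", key, "="), "", hit[1])
  }
  fs <- suppressWarnings(as.numeric(get("fs")))
  if (is.na(fs)) stop("missing or malformed `# fs=<Hz>` header", call. = FALSE)
  ecg_record(as.numeric(lines[!hdr]), fs = fs,
             subject_id = get("subject", NA_character_),
             lead = get("lead", "I"))
}

#' Write a beat dataset as matrix + label files
#'
#' The beat matrix (`n_beats x beat_length`, tab-separated) goes to
#' `<prefix>_beats.tsv` and the per-beat subject labels to
#' `<prefix>_labels.tsv`.
#'
#' @param beats Tibble from [segment_beats()] / [synthesize_cohort()] with
#'   `samples` and `subject_id` columns.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_beats <- function(beats, prefix) {
  stopifnot(is.data.frame(beats), all(c("samples", "subject_id") %in% names(beats)))
  m <- do.call(rbind, beats$samples)
  beats_path <- paste0(prefix, "_beats.tsv")
  labels_path <- paste0(prefix, "_labels.tsv")
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     beats_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(as.character(beats$subject_id), labels_path)
  invisible(c(beats = beats_path, labels = labels_path))
}

#' Read a beat dataset written by [write_beats()]
#'
#' @param prefix Path prefix used at write time.
#' @return Tibble with `subject_id`, `beat` and `samples` columns.
#' @export
read_beats <- function(prefix) {
  m <- as.matrix(utils::read.table(paste0(prefix, "_beats.tsv"), sep = "\t"))
  labels <- readLines(paste0(prefix, "_labels.tsv"))
  if (nrow(m) != length(labels)) stop("beat and label files disagree", call. = FALSE)
  tibble::tibble(
    subject_id = labels,
    beat = stats::ave(seq_along(labels), labels, FUN = seq_along),
    samples = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  )
}

# ---- minimal WFDB (PhysioNet waveform-database) support --------------------
#
# Covers the common subset of the format: a `<record>.hea` header naming one
# signal file in format 16 (16-bit little-endian two's-complement, samples
# interleaved across signals) with per-signal gain, ADC zero and lead
# description. That is the layout used by the public diagnostic ECG archives.

#' Write a multi-lead record in WFDB format
#'
#' Intended for building test fixtures and interchange: quantises each
#' channel with the given gain and writes a format-16 signal file plus
#' header.
#'
#' @param signals Numeric matrix, one column per lead (physical units, mV).
#' @param fs Sampling rate (Hz).
#' @param leads Character vector of lead names, one per column.
#' @param record_name Record base name (files `<record_name>.hea` / `.dat`).
#' @param dir Output directory.
#' @param gain ADC units per mV (default 2000, i.e. resolution 0.5 uV).
#' @return Record path prefix (`file.path(dir, record_name)`), invisibly.
#' @export
write_wfdb_record <- function(signals, fs, leads, record_name, dir = ".",
                              gain = 2000) {
  signals <- as.matrix(signals)
  if (ncol(signals) != length(leads)) {
    stop("`leads` must name every signal column", call. = FALSE)
  }
  adc <- round(signals * gain)
  if (any(abs(adc) > 32767)) stop("signal exceeds 16-bit range at this gain", call. = FALSE)
  n <- nrow(adc); nsig <- ncol(adc)
  hea <- c(
    sprintf("%s %d %.10g %d", record_name, nsig, fs, n),
    sprintf("%s.dat 16 %.10g(0)/mV 16 0 0 0 0 %s", record_name, gain, leads)
  )
  writeLines(hea, file.path(dir, paste0(record_name, ".hea")))
  interleaved <- as.integer(t(adc))          # sample-major, signals interleaved
  con <- file(file.path(dir, paste0(record_name, ".dat")), "wb")
  on.exit(close(con))
  writeBin(interleaved, con, size = 2L, endian = "little")
  invisible(file.path(dir, record_name))
}

#' Read one lead of a WFDB record
#'
#' Parses the header, selects the named lead, reads the format-16 signal
#' file and converts ADC counts to physical units using the header's gain
#' and baseline.
#'
#' @param path Record path prefix (with or without `.hea`).
#' @param lead Lead name to extract (default `"I"`).
#' @return An [ecg_record()] for the requested lead.
#' @export
read_wfdb_record <- function(path, lead = "I") {
  path <- sub("\\.hea$", "", path)
  hea <- readLines(paste0(path, ".hea"))
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed WFDB header", call. = FALSE)
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig_lines <- hea[1 + seq_len(nsig)]
  parse_sig <- function(line) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    gain_tok <- tok[3]
    gain <- as.numeric(sub("^([-0-9.eE+]+).*", "\\1", gain_tok))
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_tok))
    } else 0
    list(file = tok[1], format = tok[2], gain = gain, baseline = baseline,
         lead = tok[length(tok)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  lead_names <- vapply(sigs, `[[`, character(1), "lead")
  j <- match(lead, lead_names)
  if (is.na(j)) {
    stop(sprintf("lead '%s' not present; available: %s", lead,
                 paste(lead_names, collapse = ", ")), call. = FALSE)
  }
  if (sigs[[j]]$format != "16") {
    stop("only WFDB signal format 16 is supported", call. = FALSE)
  }
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n * nsig, size = 2L, signed = TRUE,
                 endian = "little")
  adc <- matrix(raw, ncol = nsig, byrow = TRUE)
  samples <- (adc[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain
  ecg_record(samples, fs = fs, subject_id = basename(path), lead = lead)
}
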