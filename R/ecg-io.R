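#' Construct an ECG record object
#'
#' @param signals List of equal-length numeric vectors, one per channel
#'   (physical units).
#' @param fs Sampling frequency in Hz.
#' @param lead_names Character vector of lead names (may be empty strings
#'   when unknown).
#' @param record_id Record identifier string.
#' @param analysis_channel,paired_channel 1-based channel indices; see
#'   [read_wfdb_record()] for the selection policy.
#' @return An object of class `af_ecg_record`.
#' @export
ecg_record <- function(signals, fs, lead_names = rep("", length(signals)),
                       record_id = "record", analysis_channel = 1L,
                       paired_channel = NA_integer_) {
  if (fs <= 0) stop_af("fs must be > 0")
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) > 1) stop_af("all channels must have equal length")
  structure(
    list(signals = signals, fs = fs, lead_names = lead_names,
         record_id = record_id, analysis_channel = as.integer(analysis_channel),
         paired_channel = as.integer(paired_channel)),
    class = "af_ecg_record"
  )
}

# Select the analysis channel: prefer a lead named "II", then "I"; when no
# names are available fall back to channel 1. The paired channel is the other
# channel of a two-channel record.
select_channels <- function(lead_names) {
  nm <- toupper(trimws(lead_names))
  analysis <- if (any(nm == "II")) which(nm == "II")[1] else if (any(nm == "I")) {
    which(nm == "I")[1]
  } else 1L
  paired <- if (length(nm) >= 2) setdiff(seq_along(nm), analysis)[1] else {
    NA_integer_
  }
  list(analysis = as.integer(analysis), paired = as.integer(paired))
}

#' Read a PhysioNet WFDB record (header + signal file)
#'
#' Supports signal formats 16 (16-bit little-endian) and 212 (packed 12-bit
#' pairs), the formats used by the PhysioNet AF databases. Samples are
#' converted to physical units via `(adc - baseline) / gain`. The analysis
#' channel follows the lead-name preference "II", then "I", then channel 1;
#' on single-channel records pairing is disabled with a warning.
#'
#' @param path Path to the record (with or without the `.hea` extension).
#' @return An [ecg_record()] with `analysis_channel` and `paired_channel`
#'   set.
#' @export
read_wfdb_record <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop_af("cannot read WFDB header: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- strsplit(rec[1], "/")[[1]][1]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(strsplit(rec[3], "/")[[1]][1]) else 250
  n_samp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_

  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_field <- f[3]
    baseline <- NA_real_
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    }
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = sub("x.*|:.*|\\+.*", "", f[2]), gain = gain,
         baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_file <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat_file)) stop_af("cannot read WFDB signal file: %s",
                                      dat_file)
  fmt <- sigs[[1]]$fmt
  raw <- readBin(dat_file, "raw", n = file.info(dat_file)$size)
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   endian = "little", signed = TRUE)
      matrix(v, nrow = n_sig)
    },
    "212" = decode_fmt212(raw, n_sig),
    stop_af("unsupported WFDB signal format: %s", fmt)
  )
  if (!is.na(n_samp)) adc <- adc[, seq_len(min(ncol(adc), n_samp)), drop = FALSE]
  signals <- lapply(seq_len(n_sig), function(i) {
    (adc[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  })
  lead_names <- vapply(sigs, function(s) s$desc, character(1))
  ch <- select_channels(lead_names)
  if (n_sig < 2) {
    warning("single-channel record: lead pairing disabled", call. = FALSE)
  }
  ecg_record(signals, fs, lead_names, record_name,
             analysis_channel = ch$analysis, paired_channel = ch$paired)
}

# Format 212 packs two 12-bit samples into 3 bytes.
decode_fmt212 <- function(raw, n_sig) {
  nb <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(nb)])
  b1 <- b[seq(1, nb, 3)]; b2 <- b[seq(2, nb, 3)]; b3 <- b[seq(3, nb, 3)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 0x0F), 8L), b1)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 0xF0), 4L), b3)
  fix <- function(v) ifelse(v > 2047L, v - 4096L, v)
  inter <- as.vector(rbind(fix(s1), fix(s2)))
  matrix(inter[seq_len((length(inter) %/% n_sig) * n_sig)], nrow = n_sig)
}

#' Read a WFDB annotation file (MIT format)
#'
#' Parses the binary MIT annotation format and returns one row per
#' annotation event. Rhythm changes appear in the `aux` column as strings
#' with a leading `(`, e.g. `"(AFIB"`.
#'
#' @param path Path to the annotation file (e.g. `record.atr`).
#' @return A tibble with columns `sample` (0-based), `type` (annotation type
#'   code) and `aux` (auxiliary string, `NA` when absent).
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) stop_af("cannot read annotation file: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  b <- as.integer(raw)
  i <- 1L
  t_cur <- 0
  samples <- numeric(0); types <- integer(0); auxs <- character(0)
  pending_aux <- NA_character_
  while (i + 1L <= length(b)) {
    word <- b[i] + 256L * b[i + 1L]
    i <- i + 2L
    code <- word %/% 1024L
    inc <- word %% 1024L
    if (code == 0L && inc == 0L) break
    if (code == 59L) {                      # SKIP: 4-byte interval follows
      if (i + 3L > length(b)) break
      hi <- b[i] + 256L * b[i + 1L]
      lo <- b[i + 2L] + 256L * b[i + 3L]
      t_cur <- t_cur + hi * 65536 + lo
      i <- i + 4L
    } else if (code == 63L) {               # AUX: `inc` bytes, padded to even
      len <- inc
      aux_bytes <- b[i:(i + len - 1L)]
      pending_aux <- rawToChar(as.raw(aux_bytes[aux_bytes != 0L]))
      i <- i + len + (len %% 2L)
      if (length(samples) > 0 && is.na(auxs[length(auxs)])) {
        auxs[length(auxs)] <- pending_aux
      }
      pending_aux <- NA_character_
    } else if (code %in% c(60L, 61L, 62L)) { # NUM/SUB/CHN modifiers: ignore
    } else {
      t_cur <- t_cur + inc
      samples <- c(samples, t_cur)
      types <- c(types, code)
      auxs <- c(auxs, NA_character_)
    }
  }
  tibble::tibble(sample = samples, type = types, aux = auxs)
}

#' Build rhythm intervals from annotation events
#'
#' Each rhythm-change event (an `aux` string with a leading `(`) opens an
#' interval that is closed by the next rhythm-change event or by the record
#' end, so the intervals tile `[first event, record_length)` with no gaps or
#' overlaps. Coordinates are 0-based, half-open `[start, end)` sample
#' offsets, the WFDB convention.
#'
#' @param events A data frame with columns `sample` (0-based, non-decreasing)
#'   and `aux` (rhythm-change strings such as `"(AFIB"`; rows with `NA` aux
#'   are ignored), e.g. from [read_wfdb_annotations()].
#' @param record_length Record length in samples.
#' @return A list of rhythm intervals, each a list with `start_sample`,
#'   `end_sample` (exclusive) and `rhythm_code` (leading `(` stripped).
#' @export
parse_rhythm_annotations <- function(events, record_length) {
  stopifnot(is.data.frame(events))
  ev <- events[!is.na(events$aux) & grepl("^\\(", events$aux), , drop = FALSE]
  if (nrow(ev) == 0) return(list())
  if (is.unsorted(ev$sample)) stop_af("annotation samples are non-monotonic")
  if (any(ev$sample < 0) || any(ev$sample >= record_length)) {
    stop_af("annotation sample outside [0, record_length)")
  }
  starts <- ev$sample
  ends <- c(ev$sample[-1], record_length)
  keep <- ends > starts
  mapply(function(s, e, code) {
    list(start_sample = s, end_sample = e,
         rhythm_code = sub("^\\(", "", code))
  }, starts[keep], ends[keep], ev$aux[keep], SIMPLIFY = FALSE)
}

#' Map a rhythm code to the binary AF label
#'
#' AF and atrial flutter (codes `AFIB` and `AFL`, case-insensitive, leading
#' `(` stripped) map to 1; every other rhythm maps to 0. Unknown codes map
#' to 0 and are tallied in the `af_unknown_rhythms` option for audit.
#'
#' @param code Character vector of rhythm codes.
#' @return Integer vector of 0/1 labels.
#' @export
rhythm_to_binary <- function(code) {
  stopifnot(is.character(code), all(nzchar(code)))
  cl <- toupper(sub("^\\(", "", code))
  known <- c("AFIB", "AFL", "N", "NSR", "SBR", "B", "T", "VT", "SVTA", "AB",
             "BII", "IVR", "NOD", "P", "PREX", "VFL", "J", "E", "NONAF")
  unk <- setdiff(unique(cl), known)
  if (length(unk) > 0) {
    tally <- getOption("af_unknown_rhythms", character(0))
    options(af_unknown_rhythms = c(tally, unk))
  }
  as.integer(cl %in% c("AFIB", "AFL"))
}

# ---- segment store -----------------------------------------------------------

#' Construct a segment store
#'
#' The container for preprocessed dual-lead segment sets: a matrix of
#' primary-lead segments, the matching paired-lead matrix, optional 0/1
#' labels, the sampling rate, optional ground-truth R peaks and per-segment
#' provenance.
#'
#' @param segments,paired_segments Numeric matrices of identical shape,
#'   one row per segment.
#' @param labels Optional integer vector (0 = non-AF, 1 = AF), one per
#'   segment, or `NULL` for unlabeled sets.
#' @param fs Sampling frequency in Hz.
#' @param r_peaks Optional list of 1-based R-peak index vectors.
#' @param provenance Optional tibble with columns `record_id`,
#'   `start_sample`.
#' @return An object of class `af_segment_store`.
#' @export
segment_store <- function(segments, paired_segments, labels = NULL, fs = 128,
                          r_peaks = NULL, provenance = NULL) {
  stopifnot(is.matrix(segments), is.matrix(paired_segments),
            all(dim(segments) == dim(paired_segments)))
  if (!is.null(labels) && length(labels) != nrow(segments)) {
    stop_af("labels must have one entry per segment")
  }
  structure(
    list(segments = segments, paired_segments = paired_segments,
         labels = if (is.null(labels)) NULL else as.integer(labels),
         fs = fs, r_peaks = r_peaks, provenance = provenance),
    class = "af_segment_store"
  )
}

#' @export
print.af_segment_store <- function(x, ...) {
  cat(sprintf("<af_segment_store> %d segments x %d samples at %g Hz (%s)\n",
              nrow(x$segments), ncol(x$segments), x$fs,
              if (is.null(x$labels)) "unlabeled" else
                sprintf("%d AF / %d non-AF", sum(x$labels == 1),
                        sum(x$labels == 0))))
  invisible(x)
}

subset_store <- function(store, keep) {
  segment_store(
    segments = store$segments[keep, , drop = FALSE],
    paired_segments = store$paired_segments[keep, , drop = FALSE],
    labels = if (is.null(store$labels)) NULL else store$labels[keep],
    fs = store$fs,
    r_peaks = if (is.null(store$r_peaks)) NULL else store$r_peaks[keep],
    provenance = if (is.null(store$provenance)) NULL else {
      store$provenance[keep, , drop = FALSE]
    }
  )
}

STORE_FORMAT_VERSION <- 1L

#' Save / load a segment store
#'
#' Serializes the store with an explicit format version; arrays round-trip
#' bit-exactly and optional fields (labels, R peaks) stay absent rather than
#' being zero-filled. A version mismatch or corrupted file raises an error.
#'
#' @param store A [segment_store()].
#' @param path File path.
#' @return `load_store` returns the stored [segment_store()];
#'   `save_store` returns `path` invisibly.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "af_segment_store"))
  saveRDS(list(format = "afcontrast-segment-store",
               version = STORE_FORMAT_VERSION, store = store), path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_af("corrupted store file: %s", path))
  if (!is.list(obj) || !identical(obj$format, "afcontrast-segment-store")) {
    stop_af("not a segment-store file: %s", path)
  }
  if (!identical(obj$version, STORE_FORMAT_VERSION)) {
    stop_af("segment-store version mismatch: file has %s, package supports %s",
            obj$version, STORE_FORMAT_VERSION)
  }
  obj$store
}
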