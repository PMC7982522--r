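#' Write an acoustic signal as a WAV file
#'
#' Minimal RIFF/WAVE writer, IEEE float-32 (format 3) or signed 16-bit PCM.
#' Float is the default because radiated pressures in Pa are not confined to
#' `[-1, 1]`.
#'
#' @param signal An [acoustic_signal()].
#' @param path Output path.
#' @param format `"float32"` or `"pcm16"` (pcm16 clips to `[-1, 1]`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(signal, "acoustic_signal"))
  format <- match.arg(format)
  x <- signal$samples
  fs <- as.integer(signal$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  bytes_per <- if (format == "float32") 4L else 2L
  data_len <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_len)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)
  w16(if (format == "float32") 3L else 1L)  # format tag
  w16(1L)                                   # mono
  w32(fs)
  w32(fs * bytes_per)
  w16(bytes_per)
  w16(8L * bytes_per)
  writeChar("data", con, eos = NULL)
  w32(data_len)
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file as an acoustic signal
#'
#' Reads IEEE float-32 or 16-bit PCM mono RIFF/WAVE files (the formats
#' [write_wav()] produces).
#'
#' @param path WAV file path.
#' @param mic_distance Distance metadata to attach, in m.
#' @param label Microphone label.
#' @return An [acoustic_signal()].
#' @export
read_wav <- function(path, mic_distance = 1, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_tag <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- r32()
    if (id == "fmt ") {
      fmt_tag <- r16()
      n_ch <- r16()
      fs <- r32()
      r32(); r16()
      bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
      if (n_ch != 1) stop("only mono WAV supported")
    } else if (id == "data") {
      if (is.null(fmt_tag)) stop("data chunk before fmt chunk")
      n <- size / (bits / 8)
      x <- if (fmt_tag == 3 && bits == 32) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else if (fmt_tag == 1 && bits == 16) {
        readBin(con, "integer", n = n, size = 2, endian = "little") / 32767
      } else stop("unsupported WAV format (tag ", fmt_tag, ", ", bits, " bit)")
      return(acoustic_signal(x, fs, mic_distance, label))
    } else {
      readBin(con, "raw", size)
    }
  }
}

#' Read a pressure time series from a two-column CSV
#'
#' Expects columns `time_s` and `pressure_pa` on a uniform grid.
#'
#' @param path CSV path.
#' @param mic_distance Distance metadata in m.
#' @return An [acoustic_signal()].
#' @export
read_signal_csv <- function(path, mic_distance = 1) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_pa") %in% names(d))) {
    stop("CSV must have columns 'time_s' and 'pressure_pa'")
  }
  dt <- diff(d$time_s)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("time grid must be uniform")
  acoustic_signal(d$pressure_pa, 1 / dt[1], mic_distance,
                  label = basename(path))
}

#' Export a flow series to CSV
#'
#' Columns `phase`, `Q_l_s`, `dp_Pa`, `wall_pressure_Pa`.
#'
#' @param flow A [solve_flow()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  stopifnot(inherits(flow, "flow_series"))
  d <- data.frame(phase = flow$phase, Q_l_s = flow$Q_l_s,
                  dp_Pa = attr(flow, "dp_Pa"),
                  wall_pressure_Pa = flow$wall_pressure_Pa)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export a motion field to long-format CSV
#'
#' Columns `fold`, `z_mm`, `phase`, `displacement_mm`, `velocity_m_s`.
#'
#' @param motion A [build_motion()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(motion, path) {
  stopifnot(inherits(motion, "motion_field"))
  grid <- expand.grid(fold = c("upper", "lower"),
                      z_mm = motion$z_mm, phase = motion$phase,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$displacement_mm <- as.vector(motion$displacement_mm)
  grid$velocity_m_s <- as.vector(motion$velocity_m_s)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param report A [run_case()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  report$series <- NULL
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
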