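#' Read and write mono PCM16 WAV files
#'
#' Minimal single-channel 16-bit RIFF/WAVE I/O for synthetic scenes.
#' `write_scene_wav()` scales the waveform by `scale` (default: its peak
#' absolute value) before quantizing, and returns the scale used so
#' absolute sample amplitudes can be restored on read.
#'
#' @param waveform Numeric vector.
#' @param path File path.
#' @param fs_hz Sampling rate in Hz.
#' @param scale Count value mapped to full scale (32767).
#' @return `write_scene_wav()` invisibly returns `scale`; `read_scene_wav()`
#'   returns a list with `waveform` and `fs_hz`.
#' @export
write_scene_wav <- function(waveform, path, fs_hz, scale = max(abs(waveform), 1e-12)) {
  check_fs(fs_hz)
  pcm <- as.integer(pmax(-32767, pmin(32767, round(waveform / scale * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(scale)
}

#' @rdname write_scene_wav
#' @export
read_scene_wav <- function(path, scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stopf("%s is not a RIFF file", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stopf("%s is not a WAVE file", path)
  fs_hz <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stopf("no data chunk found in %s", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stopf("only mono PCM WAV supported")
      fs_hz <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      return(list(waveform = pcm / 32767 * scale, fs_hz = fs_hz))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}
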