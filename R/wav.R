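# Minimal RIFF/WAVE writer and reader. 32-bit IEEE float (format 3, the
# package default: lossless headroom) and 16-bit PCM (format 1) are supported.
# No audio package ships in this toolchain, hence the small hand-written codec.

#' Write stereo audio to a WAV file
#'
#' @param audio A [stereo_audio()] object.
#' @param path Output file path.
#' @param bit_depth `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bit_depth = c("float32", "pcm16")) {
  stopifnot(inherits(audio, "stereo_audio"))
  bit_depth <- match.arg(bit_depth)
  fs <- as.integer(round(audio$sample_rate))
  n <- length(audio$left)
  inter <- as.numeric(rbind(audio$left, audio$right))  # interleave L,R
  con <- file(path, "wb")
  on.exit(close(con))
  if (bit_depth == "float32") {
    fmt <- 3L; bits <- 32L; data_bytes <- 8L * n
  } else {
    fmt <- 1L; bits <- 16L; data_bytes <- 4L * n
  }
  block_align <- 2L * bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * block_align, con, size = 4, endian = "little") # byte rate
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(inter, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a stereo WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A [stereo_audio()] object.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; fs <- NULL; bits <- NULL; nch <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      nch <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", n = size - 16L))
    } else if (id == "data") {
      if (fmt == 3L && bits == 32L) {
        samples <- readBin(con, "double", n = size %/% 4L, size = 4,
                           endian = "little")
      } else if (fmt == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                           endian = "little") / 32767
      } else stop("unsupported WAV encoding (format ", fmt, ", ", bits, " bit)")
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  if (nch != 2L) stop("only stereo files are supported")
  m <- matrix(samples, nrow = 2)
  stereo_audio(m[1, ], m[2, ], fs)
}
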