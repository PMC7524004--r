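# Delimited-text serialization of LFP series, detected events, and PI curves,
# with provenance headers. All outputs are deterministic: identical inputs
# give byte-identical files.

fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with one byte only touches the low 8 bits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiplication in split 16-bit halves (doubles only
    # hold 53 bits exactly, a direct product would lose precision)
    h <- (h %% 65536 * p + (h %/% 65536 * p) %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

provenance_header <- function(kind, seed = NA, config = NULL) {
  c(sprintf("# swdnet %s", kind),
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("swdnet"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else
              fnv1a_hash(utils::capture.output(utils::str(config)))))
}

#' Write / read LFP channels as tab-separated text
#'
#' Serializes the three LFP channels with a commented provenance header and a
#' column header row (`time_s` plus channel names). Times are in seconds.
#'
#' @param lfp an `swd_lfp`.
#' @param path file path.
#' @param seed,config optional provenance recorded in the header.
#' @return `write_lfp()` returns `path` invisibly; `read_lfp()` returns an
#'   `swd_lfp`.
#' @export
write_lfp <- function(lfp, path, seed = NA, config = NULL) {
  stopifnot(inherits(lfp, "swd_lfp"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_header("lfp", seed, config),
               sprintf("# f_samp: %.17g", lfp$f_samp)), con)
  df <- data.frame(time_s = sprintf("%.8f", lfp$time))
  for (ch in colnames(lfp$channels))
    df[[ch]] <- sprintf("%.10g", lfp$channels[, ch])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 50L)
  fs_line <- grep("^# f_samp: ", lines, value = TRUE)
  if (length(fs_line) != 1L) stop("not an swdnet LFP file: ", path)
  f_samp <- as.numeric(sub("^# f_samp: ", "", fs_line))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  ch <- as.matrix(df[, -1L, drop = FALSE])
  structure(list(time = df$time_s, channels = ch, f_samp = f_samp),
            class = "swd_lfp")
}

#' Write detected events or PI curves as tab-separated text
#'
#' @param df a data frame (e.g. from [detect_swd()] or the `pi` component of
#'   [sliding_pi()]).
#' @param path file path.
#' @param kind short label recorded in the header.
#' @param seed,config optional provenance.
#' @return `path`, invisibly.
#' @export
write_table_report <- function(df, path, kind = "report", seed = NA,
                               config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(kind, seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
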