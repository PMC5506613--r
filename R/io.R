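#' Write an EIT frame sequence to a text container
#'
#' Plain-text container: a key/value header (`subject_id`, `session_label`,
#' `sampling_rate`, `n_frames`, `n_rows`, `n_cols`) followed by one
#' whitespace-delimited block per frame, row-major, full double precision
#' (17 significant digits), so a write/read round trip is bit-exact.
#'
#' @param seq a [frame_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(seq, path) {
  stopifnot(inherits(seq, "eit_frames"))
  d <- dim(seq$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# eitsbt frames v1",
               paste0("subject_id: ", seq$subject_id),
               paste0("session_label: ", seq$session_label),
               paste0("sampling_rate: ", format(seq$sampling_rate, digits = 17)),
               paste0("n_frames: ", d[1]),
               paste0("n_rows: ", d[2]),
               paste0("n_cols: ", d[3]),
               ""), con)
  for (i in seq_len(d[1])) {
    fr <- t(seq$frames[i, , ])  # row-major lines
    writeLines(paste(apply(matrix(formatC(fr, digits = 17, format = "g"),
                                  d[3], d[2]), 2, paste, collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an EIT frame sequence from a text container
#'
#' @param path file written by [write_frames()] (or assembled by hand in
#'   the same layout).
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr_end <- which(lines == "")[1]
  if (is.na(hdr_end)) stop("malformed frame file: no header terminator",
                           call. = FALSE)
  hdr <- lines[seq_len(hdr_end - 1)]
  hdr <- hdr[!startsWith(hdr, "#")]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  need <- c("subject_id", "session_label", "sampling_rate",
            "n_frames", "n_rows", "n_cols")
  missing <- setdiff(need, keys)
  if (length(missing) > 0)
    stop("frame file header missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  get <- function(k) vals[match(k, keys)]
  nf <- as.integer(get("n_frames"))
  nr <- as.integer(get("n_rows"))
  nc <- as.integer(get("n_cols"))
  body <- lines[(hdr_end + 1):length(lines)]
  nums <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(nums) != nf * nr * nc)
    stop(sprintf("truncated frame file: expected %d values, found %d",
                 nf * nr * nc, length(nums)), call. = FALSE)
  frames <- array(0, dim = c(nf, nr, nc))
  per <- nr * nc
  for (i in seq_len(nf)) {
    block <- nums[((i - 1) * per + 1):(i * per)]
    frames[i, , ] <- matrix(block, nr, nc, byrow = TRUE)
  }
  frame_sequence(frames, as.numeric(get("sampling_rate")),
                 get("session_label"), get("subject_id"))
}

#' Read and write run configuration files
#'
#' The run configuration is an [eit_config()] serialized as YAML; every
#' field has a documented default, and a write/read round trip is lossless.
#'
#' @param path YAML file path.
#' @return [read_run_config()]: an `eit_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  cfg <- eit_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_run_config
#' @param config an [eit_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "eit_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical (key-sorted) YAML serialization; stamped with the
#' seed onto every output table.
#'
#' @param config an [eit_config()].
#' @return character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "eit_config"))
  vals <- unclass(config)
  vals <- vals[order(names(vals))]
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(vals, tf)
  unname(tools::md5sum(tf))
}

#' Write / read a provenance-stamped CSV table
#'
#' Plain comma-separated UTF-8 tables with a header row and a leading
#' comment line `# eitsbt config_hash=<md5> seed=<n>` recording how the
#' table was produced.
#'
#' @param df data frame.
#' @param path file path.
#' @param config the [eit_config()] that produced the table.
#' @export
write_table_csv <- function(df, path, config = eit_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eitsbt config_hash=%s seed=%d",
                     config_hash(config), config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @return [read_table_csv()]: the data frame, with the provenance line in
#'   attributes `config_hash` and `seed`.
#' @export
read_table_csv <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "# eitsbt")) {
    m <- regmatches(first, regexec("config_hash=(\\S+) seed=(\\S+)", first))[[1]]
    attr(df, "config_hash") <- m[2]
    attr(df, "seed") <- as.integer(m[3])
  }
  df
}
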